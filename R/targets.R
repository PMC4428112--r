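#' Define the classification targets
#'
#' A target table names the targets (ordered; the order fixes the integer
#' target IDs used everywhere else), maps each input sequence ID to its
#' target label (several sequences may share one label — e.g. all genomes of
#' a genus form one target), and optionally declares chromosome arm pairs.
#' For a declared arm pair, k-mers found in exactly the two arms and in no
#' other target are not discarded as common but diverted to the pair's
#' centromere pseudo-target, so objects from the centromeric overlap can be
#' recognized as such. Pseudo-targets carry no input sequences of their own
#' and their IDs follow the regular target IDs.
#'
#' @param seq_to_target named character vector: `names()` are sequence IDs,
#'   values are target labels. Alternatively a two-column data.frame
#'   (`seq_id`, `label`).
#' @param labels optional character vector fixing the target order; defaults
#'   to order of first appearance in `seq_to_target`.
#' @param arm_pairs optional data.frame with columns `long`, `short`,
#'   `centromere`: two arm labels (which must be targets) and the label of
#'   the centromere pseudo-target (which must not be).
#' @return an object of class `diskmer_targets`.
#' @examples
#' target_table(c(g1 = "EcoliK12", g2 = "EcoliK12", g3 = "Styphi"))
#' @export
target_table <- function(seq_to_target, labels = NULL, arm_pairs = NULL) {
  if (is.data.frame(seq_to_target)) {
    stopifnot(ncol(seq_to_target) >= 2)
    seq_to_target <- setNames(as.character(seq_to_target[[2]]),
                              as.character(seq_to_target[[1]]))
  }
  stopifnot(is.character(seq_to_target), length(seq_to_target) > 0,
            !is.null(names(seq_to_target)), all(nzchar(names(seq_to_target))))
  if (anyDuplicated(names(seq_to_target)))
    stop("duplicated sequence IDs in seq_to_target")
  if (is.null(labels)) {
    labels <- unique(unname(seq_to_target))
  } else {
    labels <- as.character(labels)
    if (anyDuplicated(labels)) stop("target labels must be unique")
    missing <- setdiff(unique(seq_to_target), labels)
    if (length(missing))
      stop("labels used in seq_to_target but not declared: ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(arm_pairs)) {
    arm_pairs <- as.data.frame(arm_pairs, stringsAsFactors = FALSE)
    stopifnot(all(c("long", "short", "centromere") %in% names(arm_pairs)))
    arm_pairs <- arm_pairs[c("long", "short", "centromere")]
    for (col in names(arm_pairs)) arm_pairs[[col]] <- as.character(arm_pairs[[col]])
    bad <- setdiff(c(arm_pairs$long, arm_pairs$short), labels)
    if (length(bad))
      stop("arm pair references unknown target label(s): ",
           paste(bad, collapse = ", "))
    if (any(arm_pairs$centromere %in% labels) ||
        anyDuplicated(arm_pairs$centromere))
      stop("centromere pseudo-labels must be unique and distinct from targets")
    if (any(arm_pairs$long == arm_pairs$short))
      stop("an arm pair must name two different targets")
  }
  structure(list(labels = labels, seq_to_target = seq_to_target,
                 arm_pairs = arm_pairs),
            class = "diskmer_targets")
}

# all assignable labels: real targets then centromere pseudo-targets
all_labels <- function(table) {
  c(table$labels, if (!is.null(table$arm_pairs)) table$arm_pairs$centromere)
}

#' @export
print.diskmer_targets <- function(x, ...) {
  cat("diskmer target table: ", length(x$labels), " target(s), ",
      length(x$seq_to_target), " input sequence(s)\n", sep = "")
  if (!is.null(x$arm_pairs))
    cat("arm pairs:", paste(sprintf("%s/%s -> %s", x$arm_pairs$long,
                                    x$arm_pairs$short, x$arm_pairs$centromere),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Read a targets-definition file
#'
#' The file is a two-column TSV, `sequence_id_or_path<TAB>target_label`, one
#' line per input sequence. Header comment lines of the form
#' `#armpair <long> <short> <centromere>` declare chromosome arm pairs;
#' other `#` lines are ignored.
#'
#' @param path path to the TSV file.
#' @return a [target_table()] object.
#' @export
read_targets_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  arm_lines <- grep("^#armpair\\b", lines, value = TRUE)
  arm_pairs <- NULL
  if (length(arm_lines)) {
    parts <- lapply(strsplit(trimws(sub("^#armpair", "", arm_lines)),
                             "[ \t]+"), function(p) {
      if (length(p) != 3)
        stop("malformed #armpair line (need: long short centromere)")
      p
    })
    arm_pairs <- data.frame(long = vapply(parts, `[`, "", 1),
                            short = vapply(parts, `[`, "", 2),
                            centromere = vapply(parts, `[`, "", 3),
                            stringsAsFactors = FALSE)
  }
  data_lines <- lines[!startsWith(lines, "#")]
  if (!length(data_lines)) stop("no target definitions in ", path)
  fields <- strsplit(data_lines, "\t")
  bad <- which(vapply(fields, length, 0L) < 2)
  if (length(bad))
    stop("malformed targets line ", bad[1], ": expected two TAB-separated fields")
  target_table(setNames(vapply(fields, `[`, "", 2),
                        vapply(fields, `[`, "", 1)),
               arm_pairs = arm_pairs)
}

#' Write a targets-definition file
#'
#' Inverse of [read_targets_tsv()].
#'
#' @param table a [target_table()] object.
#' @param path output path.
#' @export
write_targets_tsv <- function(table, path) {
  stopifnot(inherits(table, "diskmer_targets"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(table$arm_pairs))
    writeLines(sprintf("#armpair %s %s %s", table$arm_pairs$long,
                       table$arm_pairs$short, table$arm_pairs$centromere), con)
  writeLines(sprintf("%s\t%s", names(table$seq_to_target),
                     unname(table$seq_to_target)), con)
  invisible(path)
}
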