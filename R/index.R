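# numeric order for decimal code strings (no leading zeros): by length, then
# lexicographically
order_codes <- function(codes) order(nchar(codes), codes, method = "radix")

#' Tabulate the k-mer spectrum of a set of targets
#'
#' First stage of index construction: every window of every target sequence
#' is canonicalized and tabulated. Each distinct canonical k-mer records the
#' first target containing it, the number of distinct targets containing it,
#' and its total occurrence count over all targets. Sequences sharing a
#' target label count as one target.
#'
#' @param sequences named character vector of target sequences; names must
#'   appear in `table$seq_to_target`.
#' @param table a [target_table()].
#' @param k k-mer length (1..32).
#' @return data.frame of class `diskmer_raw_counts` with columns `code`,
#'   `target_id` (first target containing the k-mer, 1-based into
#'   `table$labels`), `last_target` (last distinct one; together with
#'   `target_id` this identifies the pair when `n_targets == 2`),
#'   `n_targets` and `occurrences`, sorted by code. Attributes `k` and
#'   `table` carry the construction parameters.
#' @export
count_target_kmers <- function(sequences, table, k) {
  stopifnot(inherits(table, "diskmer_targets"), is.character(sequences))
  if (length(sequences) == 0) stop("empty target set")
  ids <- names(sequences)
  if (is.null(ids) || !all(ids %in% names(table$seq_to_target)))
    stop("every sequence must be named with an ID present in the target table")
  tid <- match(table$seq_to_target[ids], table$labels)
  ord <- order(tid)  # cpp_count_kmers requires grouping by target
  res <- cpp_count_kmers(unname(sequences[ord]), tid[ord] - 1L,
                         as.integer(k))
  out <- data.frame(code = res$code, target_id = res$first_target,
                    last_target = res$last_target, n_targets = res$n_targets,
                    occurrences = res$occurrences, stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  attr(out, "table") <- table
  class(out) <- c("diskmer_raw_counts", "data.frame")
  out
}

# raw counts from per-target canonical k-mer -> count maps (k-mer
# distribution file inputs); maps is a list named by target label, each a
# named numeric vector (names = canonical codes)
raw_counts_from_maps <- function(maps, table, k) {
  stopifnot(all(names(maps) %in% table$labels))
  tid <- match(names(maps), table$labels)
  df <- do.call(rbind, lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    if (!length(m)) return(NULL)
    data.frame(code = names(m), target_id = tid[i], count = unname(m),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) stop("empty target set")
  df <- df[order(nchar(df$code), df$code, df$target_id, method = "radix"), ]
  runs <- rle(df$code)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(code = runs$values,
                    target_id = df$target_id[starts],
                    last_target = df$target_id[ends],
                    n_targets = runs$lengths,
                    occurrences = as.integer(vapply(seq_along(starts),
                      function(i) sum(df$count[starts[i]:ends[i]]), 0)),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  attr(out, "table") <- table
  class(out) <- c("diskmer_raw_counts", "data.frame")
  out
}

#' Reduce a raw k-mer table to the discriminative index
#'
#' Removes every k-mer present in more than one target, with one exception:
#' a k-mer present in exactly the two arms of a declared arm pair (and in no
#' other target) is re-assigned to that pair's centromere pseudo-target.
#' After this discriminative filtering, k-mers occurring fewer than
#' `min_occurrence` times in total are dropped — rare k-mers tend to be
#' spurious when targets are built from reads or draft assemblies.
#'
#' @param raw output of [count_target_kmers()].
#' @param min_occurrence minimum total occurrence count to keep a k-mer
#'   (default 1 = keep all).
#' @param sequences optional named character vector of the original target
#'   sequences; retained in the index, and required later for
#'   `light_stride` sampling which is defined on sequence positions.
#' @return an object of class `diskmer_index`: the per-target discriminative
#'   k-mer sets (pairwise disjoint by construction) with `k`, the target
#'   table, `min_occurrence` and a `sampling` state of `"none"`.
#' @export
make_discriminative <- function(raw, min_occurrence = 1L, sequences = NULL) {
  stopifnot(inherits(raw, "diskmer_raw_counts"), min_occurrence >= 1)
  table <- attr(raw, "table")
  k <- attr(raw, "k")
  keep <- raw$n_targets == 1L
  target_id <- raw$target_id
  if (!is.null(table$arm_pairs) && nrow(table$arm_pairs)) {
    for (i in seq_len(nrow(table$arm_pairs))) {
      idl <- match(table$arm_pairs$long[i], table$labels)
      ids <- match(table$arm_pairs$short[i], table$labels)
      cen_id <- length(table$labels) + i
      sel <- raw$n_targets == 2L &
        ((raw$target_id == idl & raw$last_target == ids) |
         (raw$target_id == ids & raw$last_target == idl))
      keep[sel] <- TRUE
      target_id[sel] <- cen_id
    }
  }
  keep <- keep & raw$occurrences >= min_occurrence
  entries <- data.frame(code = raw$code[keep], target_id = target_id[keep],
                        occurrences = raw$occurrences[keep],
                        stringsAsFactors = FALSE)
  if (!is.null(sequences)) {
    stopifnot(is.character(sequences),
              all(names(sequences) %in% names(table$seq_to_target)))
  }
  structure(list(k = k, entries = entries, table = table,
                 min_occurrence = as.integer(min_occurrence),
                 sampling = "none", sequences = sequences),
            class = "diskmer_index")
}

#' Build a discriminative k-mer index from target sequences
#'
#' Convenience wrapper: [count_target_kmers()] followed by
#' [make_discriminative()], retaining the input sequences in the index.
#'
#' @inheritParams count_target_kmers
#' @inheritParams make_discriminative
#' @return a `diskmer_index`.
#' @examples
#' tab <- target_table(c(s1 = "T1", s2 = "T2"))
#' idx <- build_index(c(s1 = "ACGTACGT", s2 = "ACGTTTTT"), tab, k = 4)
#' idx$entries  # ACGT, shared by both targets, has been removed
#' @export
build_index <- function(sequences, table, k, min_occurrence = 1L) {
  raw <- count_target_kmers(sequences, table, k)
  make_discriminative(raw, min_occurrence = min_occurrence,
                      sequences = sequences)
}

#' Sample a discriminative index for the default or light mode
#'
#' `default_half` keeps about half of each target's discriminative k-mers:
#' entries at even ranks (0, 2, 4, ...) of the target's code-sorted set.
#' `light_stride` implements the low-memory variant: it requires k = 27 and
#' keeps, per original target sequence, only k-mers starting at positions
#' that are multiples of 5 x 27 = 135 — one 27-mer window kept, the next
#' four non-overlapping ones skipped — provided they are still in the
#' discriminative set.
#'
#' @param index a `diskmer_index` with `sampling == "none"`.
#' @param mode `"default_half"` or `"light_stride"`.
#' @return the sampled `diskmer_index` (entries are a subset of the input's).
#' @export
sample_index <- function(index, mode = c("default_half", "light_stride")) {
  stopifnot(inherits(index, "diskmer_index"))
  mode <- match.arg(mode)
  if (index$sampling != "none")
    stop("index is already sampled (", index$sampling, ")")
  ent <- index$entries
  if (mode == "default_half") {
    # entries are code-sorted; rank within target = order of appearance
    rank0 <- stats::ave(seq_len(nrow(ent)), ent$target_id,
                        FUN = seq_along) - 1L
    index$entries <- ent[rank0 %% 2L == 0L, , drop = FALSE]
    rownames(index$entries) <- NULL
    index$sampling <- "half"
  } else {
    if (index$k != 27L)
      stop("light_stride sampling requires k = 27 (index has k = ",
           index$k, ")")
    if (is.null(index$sequences))
      stop("light_stride sampling needs the original target sequences; ",
           "build the index with build_index() or pass sequences= to ",
           "make_discriminative()")
    sampled <- unlist(lapply(unname(index$sequences), function(s) {
      w <- cpp_extract(s, 27L)
      w$code[w$pos %% 135L == 0L]
    }), use.names = FALSE)
    index$entries <- ent[ent$code %in% sampled, , drop = FALSE]
    rownames(index$entries) <- NULL
    index$sampling <- "light_stride"
  }
  index
}

#' @export
print.diskmer_index <- function(x, ...) {
  per <- table(factor(x$entries$target_id,
                      levels = seq_along(all_labels(x$table))))
  cat("diskmer index: k = ", x$k, ", ", nrow(x$entries),
      " discriminative k-mers, min_occurrence = ", x$min_occurrence,
      ", sampling = ", x$sampling, "\n", sep = "")
  df <- data.frame(target = all_labels(x$table),
                   discriminative_kmers = as.integer(per))
  print(df, row.names = FALSE)
  invisible(x)
}

sampling_codes <- c(none = 0L, half = 1L, light_stride = 2L)

#' Save / load a discriminative index
#'
#' The index is written as a binary file (magic string `DKMERIX1`, format
#' version, k, min_occurrence, sampling state, target label table,
#' code-sorted entry records, and any retained target sequences).
#' `load_index()` reproduces the index bit-exactly, including target label
#' order and hence target IDs. Files with a wrong magic string or format
#' version, or truncated files, raise explicit errors.
#'
#' @param index a `diskmer_index`.
#' @param path file path.
#' @return `save_index()` returns `path` invisibly; `load_index()` returns
#'   the `diskmer_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "diskmer_index"))
  tab <- index$table
  seqs <- index$sequences
  seq_ids <- names(seqs)
  if (is.null(seqs)) {
    seqs <- character(0)
    seq_ids <- character(0)
    seq_tid <- integer(0)
  } else {
    seq_tid <- match(tab$seq_to_target[seq_ids], tab$labels)
  }
  labels <- all_labels(tab)
  # arm-pair structure rides along in the label strings: pseudo-labels are
  # stored after the arms as "long|short>centromere" triplet lines
  armspec <- if (is.null(tab$arm_pairs)) character(0) else
    sprintf("%s\t%s\t%s", tab$arm_pairs$long, tab$arm_pairs$short,
            tab$arm_pairs$centromere)
  meta <- c(sprintf("nlabels\t%d", length(tab$labels)),
            sprintf("label\t%s", labels),
            sprintf("seqmap\t%s\t%s", names(tab$seq_to_target),
                    unname(tab$seq_to_target)),
            sprintf("armpair\t%s", armspec))
  cpp_save_index(path.expand(path), index$k, index$min_occurrence,
                 sampling_codes[[index$sampling]], meta,
                 index$entries$code, index$entries$target_id,
                 index$entries$occurrences, seq_ids, seq_tid,
                 unname(seqs))
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  raw <- cpp_load_index(path.expand(path))
  meta <- raw$labels
  get_fields <- function(tag) {
    sel <- startsWith(meta, paste0(tag, "\t"))
    sub(paste0("^", tag, "\t"), "", meta[sel])
  }
  nlabels <- as.integer(get_fields("nlabels"))
  labels_all <- get_fields("label")
  seqmap <- strsplit(get_fields("seqmap"), "\t", fixed = TRUE)
  arm_lines <- strsplit(get_fields("armpair"), "\t", fixed = TRUE)
  arm_pairs <- if (length(arm_lines))
    data.frame(long = vapply(arm_lines, `[`, "", 1),
               short = vapply(arm_lines, `[`, "", 2),
               centromere = vapply(arm_lines, `[`, "", 3),
               stringsAsFactors = FALSE)
  table <- target_table(setNames(vapply(seqmap, `[`, "", 2),
                                 vapply(seqmap, `[`, "", 1)),
                        labels = labels_all[seq_len(nlabels)],
                        arm_pairs = arm_pairs)
  sequences <- NULL
  if (length(raw$seq_ids))
    sequences <- setNames(raw$seqs, raw$seq_ids)
  structure(list(
    k = raw$k,
    entries = data.frame(code = raw$code, target_id = raw$target_id,
                         occurrences = raw$occurrences,
                         stringsAsFactors = FALSE),
    table = table,
    min_occurrence = raw$min_occurrence,
    sampling = names(sampling_codes)[raw$sampling + 1L],
    sequences = sequences), class = "diskmer_index")
}
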