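#' Classify objects against a discriminative index
#'
#' Each object (read, contig, transcript) is scanned window by window; a
#' window scores a hit for target t when its canonical k-mer is in t's
#' discriminative set (each window counts once, repeated k-mers count per
#' occurrence). The object is assigned to the target with the most hits,
#' with confidence h1/(h1+h2) where h1 and h2 are the best and second-best
#' per-target hit counts. With zero hits the object is unassigned. When two
#' targets tie at the top the smaller target ID is assigned, `tie` is set
#' and the confidence is 0.5.
#'
#' Modes:
#' * `full` — every window is queried; per-target hit counts are returned in
#'   the `"hits"` attribute. Requires an unsampled index.
#' * `default` — runs against a half-sampled index (see [sample_index()])
#'   and stops querying an object's windows as soon as one target has
#'   collected at least half of the total possible hits
#'   (ceiling(n_kmers/2)); scores reflect the windows queried up to that
#'   point. An unsampled index is half-sampled on the fly.
#' * `express` — only non-overlapping windows (start positions 0, k, 2k,
#'   ...) are queried and the object is assigned to the first target that
#'   obtains a hit (h1 = 1, h2 = 0, confidence undefined). Any sampling.
#' * `light` — full scoring against a `light_stride`-sampled k = 27 index.
#'
#' @param objects named character vector of sequences (names are object
#'   IDs), or a data.frame with columns `id` and `sequence` (e.g. from
#'   [read_sequences()]).
#' @param index a `diskmer_index`.
#' @param mode one of `"full"`, `"default"`, `"express"`, `"light"`.
#' @param chunk_size process objects in chunks of this many sequences;
#'   results are independent of chunking (default: one chunk).
#' @return data.frame of class `diskmer_results`, one row per object:
#'   `object_id`, `n_kmers` (valid windows in the object), `assignment`
#'   (target label, or `NA` when unassigned), `h1`, `h2`, `confidence`
#'   (`NA` when unassigned or in express mode), `tie`. In full/light mode
#'   the `"hits"` attribute holds the per-target hit-count matrix.
#' @export
classify_objects <- function(objects, index,
                             mode = c("full", "default", "express", "light"),
                             chunk_size = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "diskmer_index"))
  if (is.data.frame(objects))
    objects <- setNames(as.character(objects$sequence),
                        as.character(objects$id))
  stopifnot(is.character(objects))
  if (is.null(names(objects)))
    names(objects) <- sprintf("object%d", seq_along(objects))

  if (mode == "full" && index$sampling != "none")
    stop("full mode requires an unsampled index (sampling = ",
         index$sampling, ")")
  if (mode == "default" && index$sampling == "none")
    index <- sample_index(index, "default_half")
  if (mode == "default" && index$sampling != "half")
    stop("default mode requires half-sampled index")
  if (mode == "light") {
    if (index$k != 27L)
      stop("light mode requires k = 27 (index has k = ", index$k, ")")
    if (index$sampling == "none") index <- sample_index(index, "light_stride")
    if (index$sampling != "light_stride")
      stop("light mode requires a light_stride-sampled index")
  }

  labels <- all_labels(index$table)
  cpp_mode <- switch(mode, full = 0L, light = 0L, default = 1L, express = 2L)
  want_hits <- mode %in% c("full", "light")

  chunks <- if (is.null(chunk_size)) list(seq_along(objects)) else
    split(seq_along(objects),
          ceiling(seq_along(objects) / max(1L, as.integer(chunk_size))))
  parts <- lapply(chunks, function(ix) {
    res <- cpp_classify(unname(objects[ix]), index$entries$code,
                        index$entries$target_id, index$k, length(labels),
                        cpp_mode, want_hits)
    df <- data.frame(
      object_id = names(objects)[ix],
      n_kmers = res$n_kmers,
      assignment = ifelse(is.na(res$target), NA_character_,
                          labels[res$target]),
      h1 = res$h1, h2 = res$h2,
      confidence = ifelse(res$h1 > 0 & cpp_mode != 2L,
                          res$h1 / (res$h1 + res$h2), NA_real_),
      tie = res$tie, stringsAsFactors = FALSE)
    if (want_hits) attr(df, "hits") <- res$hits
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  if (want_hits) {
    hits <- do.call(rbind, lapply(parts, attr, "hits"))
    dimnames(hits) <- list(out$object_id, labels)
    attr(out, "hits") <- hits
  }
  attr(out, "mode") <- mode
  attr(out, "labels") <- labels
  class(out) <- c("diskmer_results", "data.frame")
  out
}

#' @rdname classify_objects
#' @export
classify_full <- function(objects, index)
  classify_objects(objects, index, mode = "full")

#' @rdname classify_objects
#' @export
classify_default <- function(objects, index)
  classify_objects(objects, index, mode = "default")

#' @rdname classify_objects
#' @export
classify_express <- function(objects, index)
  classify_objects(objects, index, mode = "express")

#' @rdname classify_objects
#' @export
classify_light <- function(objects, index)
  classify_objects(objects, index, mode = "light")

#' Evaluate classification results against known truth
#'
#' Computes precision (correct assignments / total assignments), sensitivity
#' (correct assignments / total objects) and the assignment rate (assigned /
#' total), plus the mean confidence over assignments and the same statistics
#' restricted to high-confidence assignments — those with confidence
#' strictly greater than `high_conf_threshold` (default 0.75).
#'
#' @param results a `diskmer_results` data.frame from [classify_objects()].
#' @param truth named character vector mapping every `object_id` to its true
#'   target label, or a data.frame with columns `object_id` and `label`.
#' @param high_conf_threshold confidence cut-off for the high-confidence
#'   subset; the comparison is strict (`confidence > threshold`).
#' @return an object of class `diskmer_eval`: a list with `precision`,
#'   `sensitivity`, `assignment_rate`, `mean_confidence`,
#'   `high_conf_precision`, `high_conf_rate`, and counts `n_objects`,
#'   `n_assigned`, `n_correct`. With zero assigned objects, precision is
#'   `NaN` with a warning.
#' @export
evaluate_classification <- function(results, truth,
                                    high_conf_threshold = 0.75) {
  if (is.data.frame(truth))
    truth <- setNames(as.character(truth$label),
                      as.character(truth$object_id))
  missing <- setdiff(results$object_id, names(truth))
  if (length(missing))
    stop("object ID(s) absent from truth: ",
         paste(head(missing, 5), collapse = ", "))
  tr <- truth[results$object_id]
  assigned <- !is.na(results$assignment)
  correct <- assigned & results$assignment == tr
  n <- nrow(results)
  n_assigned <- sum(assigned)
  if (n_assigned == 0) warning("no objects were assigned; precision is NaN")
  conf <- results$confidence
  high <- assigned & !is.na(conf) & conf > high_conf_threshold
  structure(list(
    precision = sum(correct) / n_assigned,
    sensitivity = sum(correct) / n,
    assignment_rate = n_assigned / n,
    mean_confidence = if (any(assigned & !is.na(conf)))
      mean(conf[assigned & !is.na(conf)]) else NaN,
    high_conf_precision = if (any(high)) sum(correct & high) / sum(high)
      else NaN,
    high_conf_rate = sum(high) / n,
    n_objects = n, n_assigned = n_assigned, n_correct = sum(correct),
    high_conf_threshold = high_conf_threshold), class = "diskmer_eval")
}

#' @export
print.diskmer_eval <- function(x, ...) {
  cat(sprintf(
    paste0("diskmer evaluation (%d objects, %d assigned, %d correct)\n",
           "  precision:            %.4f\n",
           "  sensitivity:          %.4f\n",
           "  assignment rate:      %.4f\n",
           "  mean confidence:      %.4f\n",
           "  high-conf (> %.2f) precision: %.4f  rate: %.4f\n"),
    x$n_objects, x$n_assigned, x$n_correct, x$precision, x$sensitivity,
    x$assignment_rate, x$mean_confidence, x$high_conf_threshold,
    x$high_conf_precision, x$high_conf_rate))
  invisible(x)
}
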