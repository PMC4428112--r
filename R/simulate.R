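random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a synthetic target community
#'
#' Generates `n_targets` i.i.d. uniform-ACGT genomes, optionally planting
#' shared blocks: each block is one random sequence copied verbatim into two
#' randomly chosen genomes at non-overlapping positions. Shared blocks
#' create regions whose k-mers are common to two targets and therefore
#' removed from the discriminative index — reads drawn wholly inside a block
#' are unclassifiable by design, which is the main classifier property the
#' simulator exists to probe.
#'
#' @param n_targets number of genomes/targets (>= 1).
#' @param genome_len genome length in bp; must exceed
#'   `shared_block_len * n_shared_blocks`.
#' @param shared_block_len length of each shared block (bp).
#' @param n_shared_blocks number of shared blocks to plant.
#' @param seed integer seed; identical seed and parameters give a
#'   byte-identical community.
#' @return an object of class `diskmer_community`: list with `genomes`
#'   (named character vector, labels `T01`, `T02`, ...), `shared_blocks`
#'   (list of `list(sequence, labels, positions)`, positions 0-based),
#'   `table` (a [target_table()]) and `seed`.
#' @export
make_community <- function(n_targets, genome_len, shared_block_len = 0,
                           n_shared_blocks = 0, seed) {
  stopifnot(n_targets >= 1, genome_len >= 1, shared_block_len >= 0,
            n_shared_blocks >= 0)
  if (n_shared_blocks > 0 && shared_block_len == 0)
    stop("shared blocks requested with zero length")
  if (genome_len <= shared_block_len * n_shared_blocks)
    stop("genome_len must exceed shared_block_len * n_shared_blocks")
  if (n_shared_blocks > 0 && n_targets < 2)
    stop("shared blocks need at least two targets")
  labels <- sprintf("T%02d", seq_len(n_targets))
  withr::with_seed(seed, {
    genomes <- setNames(vapply(seq_len(n_targets),
                               function(i) random_dna(genome_len),
                               character(1)), labels)
    occupied <- rep(list(integer(0)), n_targets)  # occupied bp positions
    shared_blocks <- vector("list", n_shared_blocks)
    for (b in seq_len(n_shared_blocks)) {
      block <- random_dna(shared_block_len)
      into <- sample(n_targets, 2)
      pos <- integer(2)
      for (j in 1:2) {
        g <- into[j]
        placed <- FALSE
        for (try in 1:1000) {
          p <- sample.int(genome_len - shared_block_len + 1L, 1)
          span <- p:(p + shared_block_len - 1L)
          if (!any(span %in% occupied[[g]])) {
            occupied[[g]] <- c(occupied[[g]], span)
            substr(genomes[g], p, p + shared_block_len - 1L) <- block
            pos[j] <- p - 1L  # report 0-based
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place shared block ", b,
               " without overlap; genome too crowded")
      }
      shared_blocks[[b]] <- list(sequence = block, labels = labels[into],
                                 positions = pos)
    }
  })
  structure(list(genomes = genomes, shared_blocks = shared_blocks,
                 table = target_table(setNames(labels, labels)),
                 seed = seed,
                 params = list(n_targets = n_targets,
                               genome_len = genome_len,
                               shared_block_len = shared_block_len,
                               n_shared_blocks = n_shared_blocks)),
            class = "diskmer_community")
}

#' @export
print.diskmer_community <- function(x, ...) {
  cat("diskmer synthetic community: ", length(x$genomes), " genome(s) of ",
      x$params$genome_len, " bp, ", x$params$n_shared_blocks,
      " shared block(s) of ", x$params$shared_block_len, " bp (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Sample labelled reads from a synthetic community
#'
#' Draws reads uniformly over genomes and start positions and applies a
#' substitution-only error model: each base is independently replaced, with
#' probability `error_rate`, by one of the three other bases chosen
#' uniformly. No indels are introduced, so the recorded source position
#' stays exact. The truth is carried both in the returned columns and
#' encoded in the read IDs as `readN|label|pos`.
#'
#' @param community a [make_community()] object.
#' @param n_reads number of reads.
#' @param read_len read length (<= genome length).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed; same seed reproduces the reads exactly.
#' @return data.frame of class `diskmer_reads` with columns `id`,
#'   `sequence`, `quality` (constant "I"), `label` (source target) and
#'   `pos` (0-based source position).
#' @export
sample_reads <- function(community, n_reads, read_len, error_rate = 0,
                         seed) {
  stopifnot(inherits(community, "diskmer_community"), n_reads >= 1,
            read_len >= 1, read_len <= community$params$genome_len,
            error_rate >= 0, error_rate < 1)
  genomes <- community$genomes
  glen <- community$params$genome_len
  withr::with_seed(seed, {
    src <- sample(length(genomes), n_reads, replace = TRUE)
    pos <- sample.int(glen - read_len + 1L, n_reads, replace = TRUE)
    reads <- substring(genomes[src], pos, pos + read_len - 1L)
    if (error_rate > 0) {
      chars <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                      nrow = read_len)
      err <- which(runif(length(chars)) < error_rate)
      if (length(err)) {
        bases <- c("A", "C", "G", "T")
        # shift by 1..3 positions in the base alphabet: always a different base
        cur <- match(chars[err], bases)
        chars[err] <- bases[((cur - 1L +
                              sample.int(3L, length(err), replace = TRUE))
                             %% 4L) + 1L]
      }
      reads <- apply(chars, 2, paste, collapse = "")
    }
  })
  labels <- names(genomes)[src]
  ids <- sprintf("read%06d|%s|%d", seq_len(n_reads), labels, pos - 1L)
  structure(data.frame(id = ids, sequence = unname(reads),
                       quality = strrep("I", read_len), label = labels,
                       pos = pos - 1L, stringsAsFactors = FALSE),
            class = c("diskmer_reads", "data.frame"))
}

#' Recover the truth table from simulated reads
#'
#' @param reads a `diskmer_reads` data.frame (or any data.frame with `id`
#'   and `label` columns).
#' @return named character vector `object_id -> true label`, the `truth`
#'   format of [evaluate_classification()].
#' @export
reads_truth <- function(reads) {
  setNames(as.character(reads$label), as.character(reads$id))
}
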