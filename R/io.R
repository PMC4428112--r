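# open a (possibly gzip-compressed) text file; gzfile() reads plain text too
open_text <- function(path) gzfile(path.expand(path), "rt")

sniff_format <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("cannot sniff format of empty file ", path)
    if (nzchar(trimws(line))) break
  }
  first <- substr(trimws(line), 1, 1)
  if (first == ">") "fasta" else if (first == "@") "fastq" else
    stop("cannot determine format of ", path,
         ": first record starts with '", first, "', expected '>' or '@'")
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTA (multi-line records) is parsed with Biostrings; FASTQ with a
#' validating four-line-record reader so that malformed records are
#' rejected with the offending line number. Gzip-compressed files are
#' decoded transparently. Record IDs are the first whitespace-delimited
#' token of the header; FASTQ qualities are carried along but never used in
#' classification.
#'
#' @param path input file (optionally `.gz`).
#' @param format `"fasta"`, `"fastq"`, or `"auto"` to sniff `>` vs `@` on
#'   the first non-blank line.
#' @return data.frame with columns `id`, `sequence` and (FASTQ only)
#'   `quality`, in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- sniff_format(path)
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path, format = "fasta")
    ids <- sub("\\s.*$", "", names(set))
    if (any(!nzchar(ids))) stop("FASTA record with empty ID in ", path)
    return(data.frame(id = ids, sequence = as.character(set),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  read_fastq_checked(path)
}

read_fastq_checked <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  # trailing blank lines are tolerated; blank lines inside records are not
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines))
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error in ", path, " at line ", length(lines),
         ": file does not consist of four-line records")
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  sep <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ parse error in ", path, " at line ", (bad[1] - 1) * 4 + 1,
         ": header does not start with '@'")
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop("FASTQ parse error in ", path, " at line ", (bad[1] - 1) * 4 + 3,
         ": separator line does not start with '+'")
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad))
    stop("FASTQ parse error in ", path, " at line ", (bad[1] - 1) * 4 + 4,
         ": quality length (", nchar(qual[bad[1]]),
         ") differs from sequence length (", nchar(seqs[bad[1]]), ")")
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  if (any(!nzchar(ids)))
    stop("FASTQ parse error in ", path, ": record with empty ID")
  data.frame(id = ids, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector (names become headers) or a
#'   data.frame with `id` and `sequence` columns.
#' @param path output path (`.gz` for compressed output).
#' @param width line width for wrapping.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  if (is.data.frame(sequences))
    sequences <- setNames(as.character(sequences$sequence),
                          as.character(sequences$id))
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path.expand(path), width = width,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   columns (constant quality "I" is used when absent).
#' @param path output path (`.gz` for compressed output).
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$quality)) reads$quality else
    strrep("I", nchar(reads$sequence))
  stopifnot(all(nchar(qual) == nchar(reads$sequence)))
  con <- if (endsWith(path, ".gz")) gzfile(path.expand(path), "wt") else
    file(path.expand(path), "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' Read a k-mer distribution text file
#'
#' Each data line holds one k-mer and its occurrence count, whitespace
#' separated; lines starting with `#` are skipped. K-mers are
#' canonicalized, and counts of k-mers sharing one canonical form are
#' summed, so the result can substitute for a target sequence during index
#' construction.
#'
#' @param path input file.
#' @param k expected k-mer length; a line with a k-mer of another length is
#'   an error naming the line.
#' @return named numeric vector: canonical k-mer code -> total count,
#'   sorted by code.
#' @export
read_kmer_distribution <- function(path, k) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (!length(fields)) return(setNames(numeric(0), character(0)))
  bad <- which(vapply(fields, length, 0L) != 2)
  if (length(bad))
    stop("k-mer distribution parse error in ", path, " at line ",
         lineno[bad[1]], ": expected 'kmer count'")
  kmers <- vapply(fields, `[`, "", 1)
  bad <- which(nchar(kmers) != k)
  if (length(bad))
    stop("k-mer distribution parse error in ", path, " at line ",
         lineno[bad[1]], ": k-mer length ", nchar(kmers[bad[1]]),
         " differs from k = ", k)
  counts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad))
    stop("k-mer distribution parse error in ", path, " at line ",
         lineno[bad[1]], ": count is not a non-negative integer")
  codes <- canonical_kmer(encode_kmer(kmers), k)
  merged <- tapply(counts, codes, sum)
  out <- setNames(as.numeric(merged), names(merged))
  out[order_codes(names(out))]
}

#' Write / read per-object classification results as CSV
#'
#' Columns: `object_id`, `n_kmers`, `assignment` (`UNASSIGNED` for
#' unassigned objects), `h1`, `h2`, `confidence` (4 decimals, empty when
#' undefined) and `tie`; in full/light mode one extra column per target
#' label holds that target's hit count.
#'
#' @param results a `diskmer_results` data.frame.
#' @param path output path.
#' @export
write_results_csv <- function(results, path) {
  df <- data.frame(
    object_id = results$object_id,
    n_kmers = results$n_kmers,
    assignment = ifelse(is.na(results$assignment), "UNASSIGNED",
                        results$assignment),
    h1 = results$h1, h2 = results$h2,
    confidence = ifelse(is.na(results$confidence), "",
                        sprintf("%.4f", results$confidence)),
    tie = results$tie, stringsAsFactors = FALSE)
  hits <- attr(results, "hits")
  if (!is.null(hits)) df <- cbind(df, as.data.frame(hits, row.names = NULL))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(object_id = "character"))
  df$assignment[df$assignment == "UNASSIGNED"] <- NA_character_
  df$confidence <- suppressWarnings(as.numeric(df$confidence))
  df
}

#' Write a truth table TSV for simulated reads
#'
#' @param reads a `diskmer_reads` data.frame.
#' @param path output path.
#' @export
write_truth_tsv <- function(reads, path) {
  utils::write.table(data.frame(object_id = reads$id, label = reads$label,
                                pos = reads$pos),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @param path path to a truth TSV written by [write_truth_tsv()].
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(object_id = "character",
                                         label = "character"))
  setNames(df$label, df$object_id)
}
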