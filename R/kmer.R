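#' Encode k-mers as packed 2-bit integer codes
#'
#' Packs a DNA word into an integer with 2 bits per base (A = 0, C = 1,
#' G = 2, T = 3; first base in the most significant bits), supporting k up
#' to 32. Codes are returned as decimal strings because 4^k exceeds exact
#' double precision for k > 26; they compare equal as strings and can be
#' turned back into sequence with [decode_kmer()].
#'
#' Input is case-insensitive and U is treated as T. Any other character
#' (N, IUPAC ambiguity codes) is an error: ambiguous windows cannot be
#' encoded and are skipped by [extract_kmers()].
#'
#' @param kmers character vector of DNA words, each of length 1..32.
#' @return character vector of decimal k-mer codes.
#' @examples
#' encode_kmer(c("AAAA", "ACGT", "TTTT"))  # "0" "27" "255"
#' @export
encode_kmer <- function(kmers) {
  stopifnot(is.character(kmers))
  cpp_encode(kmers)
}

#' Decode packed k-mer codes back to sequence
#'
#' @param codes character vector of decimal k-mer codes (see [encode_kmer()]).
#' @param k k-mer length in bases (1..32).
#' @return character vector of DNA words of length `k`.
#' @examples
#' decode_kmer("27", k = 4)  # "ACGT"
#' @export
decode_kmer <- function(codes, k) {
  cpp_decode(as.character(codes), as.integer(k))
}

#' Reverse complement of packed k-mer codes
#'
#' @inheritParams decode_kmer
#' @return character vector of codes of the reverse-complemented k-mers.
#' @examples
#' decode_kmer(revcomp_kmer(encode_kmer("AACG"), 4), 4)  # "CGTT"
#' @export
revcomp_kmer <- function(codes, k) {
  cpp_revcomp(as.character(codes), as.integer(k))
}

#' Canonical (strand-independent) form of packed k-mer codes
#'
#' The canonical form is the smaller of a code and its reverse complement
#' under integer order, so a k-mer and its reverse complement share one
#' representative. The index stores only canonical codes and object windows
#' are canonicalized before lookup, which makes matching strand-independent
#' with a single query per window.
#'
#' @inheritParams decode_kmer
#' @return character vector of canonical codes; idempotent.
#' @examples
#' canonical_kmer(encode_kmer("TTTT"), 4) == encode_kmer("AAAA")
#' @export
canonical_kmer <- function(codes, k) {
  cpp_canonical(as.character(codes), as.integer(k))
}

#' Extract the canonical k-mers of a sequence
#'
#' Slides a window of width `k` over the sequence and reports one canonical
#' code per window made entirely of unambiguous bases (A, C, G, T/U, any
#' case). Windows containing any other character are skipped; a sequence
#' shorter than `k` yields zero rows. Positions are 0-based window starts.
#'
#' @param seq a single nucleotide string.
#' @param k k-mer length in bases (1..32).
#' @return data.frame with columns `pos` (integer, 0-based) and `code`
#'   (character, canonical k-mer code), one row per valid window in
#'   left-to-right order.
#' @examples
#' extract_kmers("ACGNT", k = 2)  # windows GN and NT are skipped
#' @export
extract_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  res <- cpp_extract(seq, as.integer(k))
  data.frame(pos = res$pos, code = res$code, stringsAsFactors = FALSE)
}

# reverse complement of a plain sequence string (keeps ambiguity codes as N)
revcomp_seq <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTUacgtu", "TGCAAtgcaa", paste(rev(strsplit(s, "")[[1]]),
                                             collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
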