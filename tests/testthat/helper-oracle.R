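# Brute-force string-space oracle, independent of the package's C++ path.
# K-mers are plain strings; canonical form is the lexicographic minimum of a
# window and its reverse complement, which coincides with integer order of
# the 2-bit encoding because A < C < G < T both ways.

o_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

o_canonical <- function(s) {
  rc <- o_revcomp(s)
  if (rc < s) rc else s
}

# canonical k-mer of every valid window, in order; invalid windows skipped
o_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  w <- toupper(w)
  w <- w[grepl("^[ACGT]+$", w)]
  vapply(w, o_canonical, character(1), USE.NAMES = FALSE)
}

# per-target canonical k-mer multisets -> discriminative sets, applying the
# arm-pair centromere rule and the min-occurrence filter by enumeration over
# every k-mer string seen in any target
o_index <- function(seqs, labels, k, min_occurrence = 1, arm_pairs = NULL) {
  stopifnot(length(seqs) == length(labels))
  per_target <- lapply(split(seqs, factor(labels, levels = unique(labels))),
                       function(ss) unlist(lapply(ss, o_windows, k = k)))
  tlabels <- names(per_target)
  all_kmers <- unique(unlist(per_target, use.names = FALSE))
  in_mat <- vapply(per_target, function(s) all_kmers %in% s,
                   logical(length(all_kmers)))
  if (is.null(dim(in_mat))) in_mat <- matrix(in_mat, nrow = 1)
  occ_total <- rowSums(vapply(per_target, function(s) {
    tb <- table(s)
    v <- as.numeric(tb[all_kmers])
    v[is.na(v)] <- 0
    v
  }, numeric(length(all_kmers))))
  n_t <- rowSums(in_mat)
  assign_to <- rep(NA_character_, length(all_kmers))
  assign_to[n_t == 1] <- tlabels[apply(in_mat[n_t == 1, , drop = FALSE], 1,
                                       which)]
  if (!is.null(arm_pairs)) {
    two <- which(n_t == 2)
    for (i in two) {
      tt <- tlabels[in_mat[i, ]]
      hit <- which((arm_pairs$long %in% tt) & (arm_pairs$short %in% tt))
      if (length(hit) == 1) assign_to[i] <- arm_pairs$centromere[hit]
    }
  }
  keep <- !is.na(assign_to) & occ_total >= min_occurrence
  split(all_kmers[keep], assign_to[keep])  # label -> kmer set
}

# per-target hit counts of one read against oracle discriminative sets
o_classify <- function(read, sets, labels, k) {
  w <- o_windows(read, k)
  vapply(labels, function(l) {
    s <- sets[[l]]
    if (is.null(s)) 0L else sum(w %in% s)
  }, 0L)
}

# random ACGT string helper for tests
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
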