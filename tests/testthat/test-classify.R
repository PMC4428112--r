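# toy index used throughout: T1 = {CGTA, GTAC}, T2 = {AAAA, AAAC, AACG}
toy_index <- function() {
  build_index(c(s1 = "ACGTACGT", s2 = "ACGTTTTT"),
              target_table(c(s1 = "T1", s2 = "T2")), k = 4)
}

test_that("full mode counts per-window hits and scores confidence", {
  res <- classify_full(c(r = "CGTACG"), toy_index())
  expect_equal(res$n_kmers, 3L)
  expect_equal(res$assignment, "T1")
  expect_equal(res$h1, 3L)  # windows CGTA, GTAC, TACG->CGTA
  expect_equal(res$h2, 0L)
  expect_equal(res$confidence, 1.0)
  hits <- attr(res, "hits")
  expect_equal(unname(hits[1, ]), c(3L, 0L))
  expect_equal(colnames(hits), c("T1", "T2"))
})

test_that("objects with no discriminative k-mers stay unassigned", {
  res <- classify_full(c(r1 = "GGGGGG", r2 = "AC"), toy_index())
  expect_true(all(is.na(res$assignment)))
  expect_true(all(is.na(res$confidence)))
  expect_equal(res$n_kmers, c(3L, 0L))  # r2 shorter than k
})

test_that("confidence is h1/(h1+h2) and ties assign the smaller target id", {
  idx <- toy_index()
  # windows CGTA, GTAC, TACG->CGTA hit T1; AAAA hits T2; ACGA/CGAA/GAAA miss
  res <- classify_full(c(r = "CGTACGAAAA"), idx)
  expect_equal(res$h1, 3L)
  expect_equal(res$h2, 1L)
  expect_equal(res$confidence, 0.75)
  expect_equal(res$assignment, "T1")
  expect_false(res$tie)
  # exact tie: one CGTA window vs one AAAA window -> smaller target id,
  # tie flag set, confidence 0.5
  res2 <- classify_full(c(r = "CGTAAAA"), idx)
  expect_equal(res2$h1, 1L)
  expect_equal(res2$h2, 1L)
  expect_true(res2$tie)
  expect_equal(res2$confidence, 0.5)
  expect_equal(res2$assignment, "T1")
})

test_that("full-mode hit counts equal the brute-force matcher on random data", {
  set.seed(101)
  for (rep in 1:4) {
    n_t <- sample(2:5, 1)
    k <- sample(c(5, 7, 11), 1)
    labels <- sprintf("T%d", seq_len(n_t))
    seqs <- setNames(vapply(seq_len(n_t), function(i) rand_seq(800),
                            character(1)), labels)
    tab <- target_table(setNames(labels, labels))
    idx <- build_index(seqs, tab, k = k)
    sets <- o_index(unname(seqs), labels, k)
    reads <- vapply(1:50, function(i) {
      g <- sample(n_t, 1)
      p <- sample(800 - 80, 1)
      substr(seqs[[g]], p, p + 79)
    }, character(1))
    names(reads) <- sprintf("r%d", seq_along(reads))
    res <- classify_full(reads, idx)
    hits <- attr(res, "hits")
    for (i in seq_along(reads)) {
      expect_equal(unname(hits[i, labels]),
                   unname(o_classify(reads[[i]], sets, labels, k)))
    }
  }
})

test_that("hit vectors are invariant under reverse complement", {
  set.seed(103)
  tab <- target_table(c(a = "T1", b = "T2", c = "T3"))
  idx <- build_index(c(a = rand_seq(600), b = rand_seq(600),
                       c = rand_seq(600)), tab, k = 9)
  reads <- vapply(1:30, function(i)
    substr(idx$sequences[[sample(3, 1)]], (p <- sample(500, 1)), p + 70),
    character(1))
  names(reads) <- sprintf("r%d", seq_along(reads))
  fwd <- classify_full(reads, idx)
  rev <- classify_full(setNames(vapply(reads, o_revcomp, "",
                                       USE.NAMES = FALSE), names(reads)), idx)
  expect_identical(attr(fwd, "hits"), attr(rev, "hits"))
  expect_identical(fwd$assignment, rev$assignment)
})

test_that("reads from a verbatim shared segment get zero hits", {
  set.seed(107)
  block <- rand_seq(300)
  tab <- target_table(c(a = "T1", b = "T2"))
  idx <- build_index(c(a = paste0(rand_seq(400), block),
                       b = paste0(block, rand_seq(400))), tab, k = 11)
  inside <- vapply(seq(1, 220, by = 40), function(p)
    substr(block, p, p + 79), character(1))
  res <- classify_full(setNames(inside, sprintf("r%d", seq_along(inside))),
                       idx)
  expect_true(all(is.na(res$assignment)))
  expect_true(all(attr(res, "hits") == 0))
})

test_that("default mode stops early once a target has half the possible hits", {
  idx <- toy_index()
  half <- sample_index(idx, "default_half")
  res <- classify_default(c(r = "CGTACG"), half)
  # half index keeps CGTA for T1; windows 1 and 3 hit it, reaching the
  # ceil(3/2) = 2 threshold
  expect_equal(res$assignment, "T1")
  expect_equal(res$h1, 2L)
  # a read hitting only one target in full mode can never flip in default
  set.seed(109)
  tab <- target_table(c(a = "T1", b = "T2"))
  idx2 <- build_index(c(a = rand_seq(1000), b = rand_seq(1000)), tab, k = 9)
  reads <- vapply(1:60, function(i) {
    g <- sample(2, 1)
    p <- sample(900, 1)
    substr(idx2$sequences[[g]], p, p + 60)
  }, character(1))
  names(reads) <- sprintf("r%d", seq_along(reads))
  full <- classify_full(reads, idx2)
  def <- classify_default(reads, sample_index(idx2, "default_half"))
  conf1 <- !is.na(full$confidence) & full$confidence == 1
  both <- conf1 & !is.na(def$assignment)
  expect_true(all(def$assignment[both] == full$assignment[both]))
  expect_true(all(is.na(def$assignment) | def$assignment %in%
                    c("T1", "T2")))
})

test_that("default-mode early stop halts at ceil(n_kmers/2) accumulated hits", {
  # T1 = {AC, CA}, T2 = {CC}; half-sampling keeps AC for T1
  tab <- target_table(c(a = "T1", b = "T2"))
  idx <- build_index(c(a = "CACACAC", b = "GGGGGGG"), tab, k = 2)
  half <- sample_index(idx, "default_half")
  expect_identical(decode_kmer(half$entries$code[half$entries$target_id == 1],
                               2), "AC")
  # read CACACAC: 6 windows, threshold 3; AC occurs at windows 2, 4, 6, so
  # querying stops exactly when the count reaches 3 (full mode would give 6)
  res <- classify_default(c(r = "CACACAC"), half)
  expect_equal(res$n_kmers, 6L)
  expect_equal(res$h1, 3L)
  expect_equal(res$assignment, "T1")
  full <- classify_full(c(r = "CACACAC"), idx)
  expect_equal(full$h1, 6L)
})

test_that("express mode queries non-overlapping windows and takes the first hit", {
  idx <- toy_index()
  # length 8, k 4: positions 0 and 4 only; position 0 CGTA hits T1
  res <- classify_express(c(r = "CGTAAAAA"), idx)
  expect_equal(res$assignment, "T1")
  expect_equal(res$h1, 1L)
  expect_equal(res$h2, 0L)
  expect_true(is.na(res$confidence))
  # position 0 misses (ACGT removed as common), position 4 AAAA hits T2
  res2 <- classify_express(c(r = "ACGTAAAA"), idx)
  expect_equal(res2$assignment, "T2")
  # windows that only overlap (not aligned to stride) are not queried:
  # GGCGTAGG has CGTA at position 2 but positions 0/4 miss
  res3 <- classify_express(c(r = "GGCGTAGG"), idx)
  expect_true(is.na(res3$assignment))
})

test_that("an object drawn from one target can hit at most one target", {
  set.seed(113)
  tab <- target_table(c(a = "T1", b = "T2", c = "T3"))
  idx <- build_index(c(a = rand_seq(900), b = rand_seq(900),
                       c = rand_seq(900)), tab, k = 13)
  reads <- vapply(1:100, function(i) {
    g <- sample(3, 1)
    p <- sample(800, 1)
    substr(idx$sequences[[g]], p, p + 70)
  }, character(1))
  names(reads) <- sprintf("r%d", seq_along(reads))
  hits <- attr(classify_full(reads, idx), "hits")
  expect_true(all(rowSums(hits > 0) <= 1))
})

test_that("light mode classifies against the strided 27-mer index", {
  set.seed(127)
  tab <- target_table(c(a = "T1", b = "T2"))
  seqs <- c(a = rand_seq(600), b = rand_seq(600))
  idx <- build_index(seqs, tab, k = 27)
  light <- sample_index(idx, "light_stride")
  # a read covering the sampled window at position 0 of T1 is assigned
  r_hit <- substr(seqs[["a"]], 1, 60)
  res <- classify_light(c(r = r_hit), light)
  expect_equal(res$assignment, "T1")
  # a read strictly inside a skipped stretch misses every sampled k-mer:
  # sampled starts are 0,135,...; window starts 30..60 are unsampled
  r_miss <- substr(seqs[["a"]], 31, 120)  # covers starts 30..93
  res2 <- classify_light(c(r = r_miss), light)
  expect_true(is.na(res2$assignment))
  expect_error(classify_light(c(r = r_hit),
                              build_index(seqs, tab, k = 21)), "k = 27")
})

test_that("evaluation implements the precision/sensitivity definitions", {
  res <- data.frame(
    object_id = sprintf("r%d", 1:10),
    n_kmers = 10L,
    assignment = c(rep("A", 8), "B", NA),
    h1 = c(rep(5L, 9), 0L), h2 = 0L,
    confidence = c(rep(1, 4), rep(0.8, 2), rep(0.75, 2), 0.6, NA),
    tie = FALSE, stringsAsFactors = FALSE)
  truth <- setNames(c(rep("A", 9), "B"), res$object_id)
  ev <- evaluate_classification(res, truth)
  expect_equal(ev$precision, 8 / 9)
  expect_equal(ev$sensitivity, 0.8)
  expect_equal(ev$assignment_rate, 0.9)
  # confidence exactly 0.75 counts as LOW confidence (strict threshold)
  expect_equal(ev$high_conf_rate, 6 / 10)
  expect_equal(ev$high_conf_precision, 1.0)
  ev2 <- evaluate_classification(res, setNames(rep("A", 10), res$object_id))
  expect_equal(ev2$precision, 8 / 9)
  expect_equal(ev2$sensitivity, 0.8)
})

test_that("degenerate evaluations warn or fail loudly", {
  res <- data.frame(object_id = "r1", n_kmers = 5L,
                    assignment = NA_character_, h1 = 0L, h2 = 0L,
                    confidence = NA_real_, tie = FALSE,
                    stringsAsFactors = FALSE)
  expect_warning(ev <- evaluate_classification(res, c(r1 = "A")),
                 "no objects were assigned")
  expect_true(is.nan(ev$precision))
  expect_error(evaluate_classification(res, c(other = "A")),
               "absent from truth")
})

test_that("chunked classification is identical to one-shot", {
  set.seed(131)
  tab <- target_table(c(a = "T1", b = "T2"))
  idx <- build_index(c(a = rand_seq(500), b = rand_seq(500)), tab, k = 9)
  reads <- setNames(vapply(1:25, function(i)
    substr(idx$sequences[[sample(2, 1)]], (p <- sample(400, 1)), p + 60),
    character(1)), sprintf("r%d", 1:25))
  one <- classify_full(reads, idx)
  chunked <- classify_objects(reads, idx, mode = "full", chunk_size = 4)
  expect_identical(as.data.frame(one), as.data.frame(chunked))
  expect_identical(attr(one, "hits"), attr(chunked, "hits"))
})
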