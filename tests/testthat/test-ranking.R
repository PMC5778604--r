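mk_protein <- function(seq, ms, me, reads = 10L) {
  structure(list(variant = new_variant("chr1", 1, "A", "T"),
                 amino_acids = seq, mutant_aa_interval = c(ms, me),
                 num_supporting_reads = reads, source_transcripts = "T1",
                 is_frameshift = FALSE),
            class = "ProteinSequenceCandidate")
}

test_that("candidate_windows enumerates exactly the covering windows", {
  # 30 residues, single mutant at index 14: starts 0..5 -> 6 windows
  p <- mk_protein(paste(rep("ADEFGHIKLM", 3), collapse = ""), 14L, 15L)
  w <- candidate_windows(p, 25L)
  # combinatorial oracle: starts in [0, L-W] that contain the interval
  L <- 30L; W <- 25L
  starts_oracle <- Filter(function(s) s <= 14 && s + W >= 15, 0:(L - W))
  expect_length(w, length(starts_oracle))
  expect_length(w, 6L)
  for (k in seq_along(w)) {
    expect_identical(nchar(w[[k]]$peptide), 25L)
    mi <- w[[k]]$mutant_interval
    expect_identical(substr(w[[k]]$peptide, mi[1] + 1, mi[2]),
                     substr(p$amino_acids, 15, 15))
  }

  # mutant at index 0: single window
  p0 <- mk_protein(paste(rep("ADEFGHIKLM", 3), collapse = ""), 0L, 1L)
  expect_length(candidate_windows(p0, 25L), 1L)

  # sequence shorter than the window: one whole-sequence window, flagged
  ps <- mk_protein(strrep("A", 20), 10L, 11L)
  ws <- candidate_windows(ps, 25L)
  expect_length(ws, 1L)
  expect_identical(ws[[1]]$flags, "short")

  # mutant interval wider than the window: flagged, covers the start
  pw <- mk_protein(strrep("A", 60), 5L, 55L)
  ww <- candidate_windows(pw, 25L)
  expect_true(all(vapply(ww, function(x) "mutant_truncated" %in% x$flags, logical(1))))
  expect_true(all(vapply(ww, function(x) x$mutant_interval[1] < 25, logical(1))))
})

test_that("mutant_epitopes enumerates overlap-positive subpeptides", {
  pep <- paste(rep("ACDEF", 5), collapse = "")  # 25-mer
  # mutant residue at index 12, lengths {9}: starts 4..12 -> 9 nine-mers
  eps <- mutant_epitopes(pep, c(12L, 13L), lengths = 9)
  expect_length(eps, 9L)
  oracle <- vapply(4:12, function(s) substr(pep, s + 1, s + 9), character(1))
  expect_identical(eps, oracle)

  # whole peptide mutant: all subpeptides of all lengths
  eps_all <- mutant_epitopes(pep, c(0L, 25L), lengths = 8:11)
  expect_length(eps_all, (25 - 8 + 1) + (25 - 9 + 1) + (25 - 10 + 1) + (25 - 11 + 1))

  expect_length(mutant_epitopes(pep, c(12L, 13L), lengths = integer(0)), 0L)
})

test_that("binding_score equals the brute-force nested sum to machine precision", {
  pred <- toy_predictor()
  pep <- "MTEYKLVVVGAGGVGKSALTIQLIQ"  # 25-mer
  eps <- mutant_epitopes(pep, c(12L, 13L), lengths = 8:11)
  expect_length(eps, 8 + 9 + 10 + 11)
  als <- toy_hla
  got <- binding_score(eps, als, pred)
  want <- oracle_binding_sum(eps, als, pred)
  expect_equal(got, want, tolerance = 1e-12)

  # additivity: duplicating the allele list doubles the score
  expect_equal(binding_score(eps, c(als, als), pred), 2 * got, tolerance = 1e-12)
  # single epitope at the midpoint affinity scores exactly 0.5
  tab <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\taffinity_nM", "AAAAAAAAA\tHLA-A*02:01\t500"), tab)
  expect_identical(binding_score("AAAAAAAAA", "HLA-A*02:01",
                                 load_affinity_table(tab)), 0.5)
})

test_that("expression and total scores follow the declared transforms", {
  expect_identical(expression_score(0), 0)
  expect_identical(expression_score(16), 4)
  expect_identical(expression_score(16, "identity"), 16)
  expect_identical(expression_score(16, "log1p"), log1p(16))
  counts <- c(0, 1, 5, 20, 100)
  expect_true(all(diff(vapply(counts, expression_score, numeric(1))) > 0))

  expect_identical(total_score(0, 99), 0)
  expect_identical(total_score(2, 3.5), 7)
  expect_equal(total_score(2, 3 * 5), 5 * total_score(2, 3), tolerance = 1e-12)
})

mk_scored <- function(pos, peptide, expr, bind, flags = character(0)) {
  fl <- structure(list(set = flags, detail = list()), class = "ManufacturabilityFlags")
  structure(list(variant = new_variant("chr1", pos, "A", "T"),
                 peptide = peptide, mutant_interval = c(12L, 13L),
                 expression_score = expr, binding_score = bind,
                 total_score = expr * bind, manufacturability = fl,
                 num_supporting_reads = round(expr^2),
                 source_transcripts = "T1", window_flags = character(0)),
            class = "VaccinePeptideCandidate")
}

test_that("rank_candidates sorts, truncates and is permutation-invariant", {
  set.seed(123)
  cands <- lapply(1:30, function(i) {
    mk_scored(i * 100, strrep(LETTERS[(i %% 20) + 1], 25), sqrt(i), 10 + i %% 7)
  })
  rep1 <- rank_candidates(cands, max_candidates = 15)
  expect_length(rep1$candidates, 15L)
  scores <- vapply(rep1$candidates, `[[`, numeric(1), "total_score")
  expect_true(all(diff(scores) <= 0))

  rep2 <- rank_candidates(cands[sample(30)], max_candidates = 15)
  expect_identical(report_as_data_frame(rep1), report_as_data_frame(rep2))

  rep3 <- suppressMessages(rank_candidates(cands[1:4], max_candidates = 15))
  expect_length(rep3$candidates, 4L)
})

test_that("ties break by manufacturability flags then peptide, deterministically", {
  a <- mk_scored(100, "BBBBBBBBBBBBBBBBBBBBBBBBB", 2, 5, flags = "excess_cysteine")
  b <- mk_scored(200, "AAAAAAAAAAAAAAAAAAAAAAAAA", 2, 5)
  rep <- rank_candidates(list(a, b), max_candidates = 15)
  expect_identical(rep$candidates[[1]]$peptide, b$peptide)

  # equal flags: lexicographically smaller peptide first
  c1 <- mk_scored(100, "ZZZZZ", 2, 5)
  c2 <- mk_scored(200, "MMMMM", 2, 5)
  rep2 <- rank_candidates(list(c1, c2), max_candidates = 15)
  expect_identical(rep2$candidates[[1]]$peptide, "MMMMM")
})

test_that("per-variant best-window choice is monotone in the binding score", {
  # two windows of one variant: higher binding wins (same expression)
  w1 <- mk_scored(100, "AAAAAAAAAAAAAAAAAAAAAAAAA", 3, 4)
  w2 <- mk_scored(100, "CCCCCCCCCCCCCCCCCCCCCCCCC", 3, 9)
  rep <- rank_candidates(list(w1, w2), max_candidates = 15)
  expect_length(rep$candidates, 1L)
  expect_identical(rep$candidates[[1]]$peptide, w2$peptide)
})

test_that("the 25-residue window corresponds to 75 coding nucleotides", {
  expect_identical(coding_span_nt(25L), 75L)
  # and translating a 75-nt coding stretch yields exactly 25 residues
  set.seed(4)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 75, replace = TRUE), collapse = "")
    if (!grepl("\\*", oracle_translate(s)) && nchar(oracle_translate(s)) == 25) break
  }
  expect_identical(nchar(translate_cds(s)), 25L)
})
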