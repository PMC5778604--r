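test_that("read_vcf converts coordinates, trims and splits multi-allelics", {
  path <- write_vcf(c("chr1\t100\t.\tA\tT\t.\tPASS\t.",
                      "chr1\t200\t.\tAT\tA\t.\tPASS\t.",
                      "chr1\t300\t.\tA\tT,G\t.\tPASS\t."))
  vs <- read_vcf(path)
  expect_length(vs, 4L)
  expect_identical(vs[[1]]$pos, 99L)
  expect_identical(vs[[1]]$ref, "A")
  expect_identical(vs[[1]]$alt, "T")
  # deletion trimmed to its minimal representation
  expect_identical(vs[[2]]$pos, 200L)
  expect_identical(vs[[2]]$ref, "T")
  expect_identical(vs[[2]]$alt, "")
  # multi-allelic split
  expect_identical(vs[[3]]$alt, "T")
  expect_identical(vs[[4]]$alt, "G")
})

test_that("non-PASS rows are dropped unless keep_nonpass", {
  path <- write_vcf(c("chr1\t100\t.\tA\tT\t.\tPASS\t.",
                      "chr1\t200\t.\tC\tG\t.\tlowqual\t."))
  expect_length(suppressMessages(read_vcf(path)), 1L)
  expect_length(read_vcf(path, keep_nonpass = TRUE), 2L)
})

test_that("normalize_variant trims, checks the reference and is idempotent", {
  g <- ref_from_string("AAAAAAAAAACAGAAAAA")
  v <- new_variant("chr1", 10, "CAG", "CTG")
  n1 <- normalize_variant(v, g)
  expect_identical(n1$pos, 11L)
  expect_identical(n1$ref, "A")
  expect_identical(n1$alt, "T")
  expect_identical(normalize_variant(n1, g), n1)
  expect_error(normalize_variant(new_variant("chr1", 10, "GGG", "T"), g),
               "mismatch")
})

test_that("indels are left-aligned to the brute-force leftmost position", {
  # deletion of one T stated at the rightmost T of a TTT run
  s <- "ACGATTTGCA"
  g <- ref_from_string(s)
  v <- new_variant("chr1", 6, "T", "")
  n <- normalize_variant(v, g)
  expect_identical(n$pos, oracle_leftmost_indel_pos(s, 6L, "T", ""))
  expect_identical(n$pos, 4L)

  # insertion inside a homopolymer run shifts to the run start
  v2 <- new_variant("chr1", 7, "", "T")
  n2 <- normalize_variant(v2, g)
  expect_identical(n2$pos, oracle_leftmost_indel_pos(s, 7L, "", "T"))

  # random indels against the enumeration oracle
  set.seed(7)
  s2 <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE, prob = c(.4, .1, .1, .4)),
              collapse = "")
  g2 <- ref_from_string(s2)
  for (i in 1:10) {
    p <- sample(5:40, 1)
    del_len <- sample(1:2, 1)
    v <- new_variant("chr1", p, substr(s2, p + 1, p + del_len), "")
    n <- normalize_variant(v, g2)
    expect_identical(n$pos,
                     oracle_leftmost_indel_pos(s2, p, substr(s2, p + 1, p + del_len), ""))
    expect_identical(normalize_variant(n, g2), n)
  }
})

# one coding transcript over a simple CDS for effect tests
effect_env <- local({
  cds <- "ATGGCCTTTGGGAAACCCTAA"  # M A F G K P *
  g <- ref_from_string(cds)
  t1 <- new_transcript("T1", "G1", "chr1", "+", rbind(c(0L, 21L)), c(0L, 21L))
  list(g = g, t = t1, cds = cds)
})

test_that("annotate_effects classifies SNV categories", {
  g <- effect_env$g; t1 <- effect_env$t
  # GCC -> GCG, both Ala: silent
  e <- annotate_effects(new_variant("chr1", 5, "C", "G"), list(t1), g)
  expect_identical(e[[1]]$category, "silent")
  # ATG -> GTG at CDS start: start_lost
  e <- annotate_effects(new_variant("chr1", 0, "A", "G"), list(t1), g)
  expect_identical(e[[1]]$category, "start_lost")
  # TTT -> TAT: missense at aa 2
  e <- annotate_effects(new_variant("chr1", 7, "T", "A"), list(t1), g)
  expect_identical(e[[1]]$category, "missense")
  expect_identical(e[[1]]$aa_pos, 2L)
  # AAA -> TAA: stop_gained
  e <- annotate_effects(new_variant("chr1", 12, "A", "T"), list(t1), g)
  expect_identical(e[[1]]$category, "stop_gained")
  # TAA stop -> CAA: stop_lost
  e <- annotate_effects(new_variant("chr1", 18, "T", "C"), list(t1), g)
  expect_identical(e[[1]]$category, "stop_lost")
  # no overlap: empty list
  expect_length(annotate_effects(new_variant("chr1", 40, "A", "T"), list(t1),
                                 ref_from_string(strrep("A", 60))), 0L)
})

test_that("indel effects: frameshift vs in-frame, with aa_pos from the oracle", {
  g <- effect_env$g; t1 <- effect_env$t; cds <- effect_env$cds
  # 1-nt insertion mid-CDS: frameshift; first altered codon from re-translation
  v <- new_variant("chr1", 7, "", "G")
  e <- annotate_effects(v, list(t1), g)
  expect_identical(e[[1]]$category, "frameshift")
  edited <- paste0(substr(cds, 1, 7), "G", substr(cds, 8, nchar(cds)))
  ref_p <- oracle_translate(cds); mut_p <- oracle_translate(edited)
  exp_pos <- which(strsplit(ref_p, "")[[1]][1:min(nchar(ref_p), nchar(mut_p))] !=
                   strsplit(mut_p, "")[[1]][1:min(nchar(ref_p), nchar(mut_p))])[1] - 1L
  expect_identical(e[[1]]$aa_pos, exp_pos)
  # 3-nt deletion: inframe_deletion
  e <- annotate_effects(new_variant("chr1", 6, "TTT", ""), list(t1), g)
  expect_identical(e[[1]]$category, "inframe_deletion")
  # 3-nt insertion: inframe_insertion
  e <- annotate_effects(new_variant("chr1", 6, "", "CAT"), list(t1), g)
  expect_identical(e[[1]]$category, "inframe_insertion")
})

test_that("planted coding SNVs agree with a full-CDS re-translation oracle", {
  set.seed(31)
  cds_body <- c("ATG", replicate(20, {
    repeat {
      cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA")) break
    }
    cod
  }), "TAA")
  cds <- paste(cds_body, collapse = "")
  g <- ref_from_string(cds)
  t1 <- new_transcript("T1", "G1", "chr1", "+", rbind(c(0L, nchar(cds))),
                       c(0L, nchar(cds)))
  for (i in 1:25) {
    p <- sample(0:(nchar(cds) - 1L), 1)
    ref_b <- substr(cds, p + 1, p + 1)
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
    e <- annotate_effects(new_variant("chr1", p, ref_b, alt_b), list(t1), g)[[1]]
    edited <- cds
    substr(edited, p + 1, p + 1) <- alt_b
    ref_p <- oracle_translate(cds); mut_p <- oracle_translate(edited)
    expected <- if (identical(ref_p, mut_p)) "silent"
                else if (p < 3 && oracle_translate(substr(edited, 1, 3)) != "M") "start_lost"
                else if (nchar(mut_p) < nchar(ref_p)) "stop_gained"
                else if (nchar(mut_p) > nchar(ref_p)) "stop_lost"
                else "missense"
    expect_identical(e$category, expected,
                     label = sprintf("pos %d %s>%s: %s", p, ref_b, alt_b, e$category))
  }
})

test_that("intronic and noncoding placements are classified, minus strand works", {
  # two exons, CDS on both; variant in the intron
  s <- paste0("ATGGCC", strrep("T", 10), "AAATAA")
  g <- ref_from_string(s)
  t1 <- new_transcript("T1", "G1", "chr1", "+", rbind(c(0L, 6L), c(16L, 22L)),
                       c(0L, 22L))
  e <- suppressMessages(annotate_effects(new_variant("chr1", 10, "T", "A"), list(t1), g))
  expect_identical(e[[1]]$category, "intronic")

  # minus-strand missense: genomic plus-strand alt maps through revcomp
  cds <- "ATGGCCTTTGGGAAACCCTAA"
  gm <- ref_from_string(oracle_revcomp(cds))
  tm <- new_transcript("TM", "G1", "chr1", "-", rbind(c(0L, 21L)), c(0L, 21L))
  expect_identical(spliced_cds(tm, gm), cds)
  # coding TTT codon at CDS offsets 6..8 = genomic positions 12..14 (reversed)
  e <- annotate_effects(new_variant("chr1", 13, "A", "T"), list(tm), gm)
  expect_identical(e[[1]]$category, "missense")
  expect_identical(e[[1]]$aa_pos, 2L)
})

test_that("filter_nonsilent keeps exactly the protein-altering categories", {
  mk <- function(cat) structure(list(variant = new_variant("chr1", 1, "A", "T"),
                                     transcript_id = "T", category = cat,
                                     aa_pos = NA_integer_),
                                class = "VariantEffect")
  cats <- c("silent", "missense", "inframe_insertion", "inframe_deletion",
            "frameshift", "stop_gained", "stop_lost", "noncoding", "intronic")
  kept <- filter_nonsilent(lapply(cats, mk))
  expect_setequal(vapply(kept, `[[`, character(1), "category"),
                  c("missense", "inframe_insertion", "inframe_deletion",
                    "frameshift", "stop_lost"))
  expect_identical(filter_nonsilent(list()), list())
})
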