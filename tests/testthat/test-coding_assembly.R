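mk_read <- function(name, prefix, allele, suffix) {
  structure(list(read_name = name, prefix = prefix, allele = allele,
                 suffix = suffix, mapq = 60L, base_qualities = integer(0)),
            class = "AlleleRead")
}

test_that("group_reads_by_sequence groups by overlap agreement", {
  # identical reads -> one group, count 2
  g <- group_reads_by_sequence(list(mk_read("a", "ACG", "T", "GGA"),
                                    mk_read("b", "ACG", "T", "GGA")))
  expect_length(g, 1L)
  expect_identical(g[[1]]$count, 2L)

  # agreeing reads of different lengths -> one group spanning the union
  g <- group_reads_by_sequence(list(mk_read("a", "TACG", "T", "GG"),
                                    mk_read("b", "ACG", "T", "GGA")))
  expect_length(g, 1L)
  expect_identical(g[[1]]$prefix, "TACG")
  expect_identical(g[[1]]$suffix, "GGA")

  # a disagreement at one overlapping base -> two groups
  g <- group_reads_by_sequence(list(mk_read("a", "ACG", "T", "GGA"),
                                    mk_read("b", "ACG", "T", "GCA")))
  expect_length(g, 2L)
})

test_that("assemble_most_abundant picks the largest group with deterministic tie-breaks", {
  v <- new_variant("chr1", 10, "A", "T")
  reads <- c(lapply(1:12, function(i) mk_read(paste0("x", i), "AAA", "T", "CCC")),
             lapply(1:3, function(i) mk_read(paste0("y", i), "AAA", "T", "CGC")))
  cand <- assemble_most_abundant(group_reads_by_sequence(reads), v, min_reads = 3)
  expect_identical(cand$cdna, "AAATCCC")
  expect_length(cand$supporting_read_names, 12L)
  expect_identical(cand$variant_interval, c(3L, 4L))

  # equal counts: longer consensus wins, then lexicographic
  reads_tie <- list(mk_read("a", "GAAA", "T", "CCC"), mk_read("b", "AAA", "T", "CCCA"))
  # both singleton groups? no: these agree on overlap -> one group; force split
  reads_tie <- list(mk_read("a", "GAAA", "T", "CCC"), mk_read("b", "AAA", "T", "CGC"))
  cand2 <- assemble_most_abundant(group_reads_by_sequence(reads_tie), v, min_reads = 1)
  expect_identical(cand2$cdna, "GAAATCCC")  # longer consensus

  expect_message(
    expect_null(assemble_most_abundant(group_reads_by_sequence(list()), v, 3)),
    "no read group")
})

test_that("exact grouping equals brute-force subset enumeration (<= 12 reads)", {
  set.seed(17)
  v <- new_variant("chr1", 50, "A", "G")
  for (trial in 1:8) {
    # reads drawn from a 41-nt haplotype with sprinkled errors
    hap <- paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE), collapse = "")
    anchor <- 21L  # allele base index within hap
    reads <- lapply(1:10, function(i) {
      s <- sample(1:11, 1)          # read start within hap
      e <- sample(31:41, 1)         # read end
      bases <- strsplit(substr(hap, s, e), "", fixed = TRUE)[[1]]
      idx <- anchor - s + 1L
      bases[idx] <- "G"             # the alt allele
      if (runif(1) < 0.5) {         # sprinkle one error outside the allele
        j <- sample(setdiff(seq_along(bases), idx), 1)
        bases[j] <- sample(setdiff(c("A", "C", "G", "T"), bases[j]), 1)
      }
      mk_read(paste0("r", i),
              paste(bases[seq_len(idx - 1L)], collapse = ""),
              "G",
              paste(bases[seq.int(idx + 1L, length(bases))], collapse = ""))
    })
    got <- assemble_most_abundant(group_reads_by_sequence(reads), v, min_reads = 1)
    want <- oracle_best_read_subset(reads)
    expect_identical(length(got$supporting_read_names), want$count)
    expect_identical(got$cdna, want$consensus)
  }
})

test_that("adjacent germline variants are phased into the assembled candidate", {
  fx <- phase_fixture()
  g <- load_reference(fx$fasta)
  tx <- load_annotations(fx$gtf)
  al <- load_alignments(fx$sam)
  vs <- suppressMessages(read_vcf(fx$vcf))
  for (i in seq_along(vs)) {
    v <- normalize_variant(vs[[i]], g)
    man <- fx$manifest$variants[[i]]
    grp <- collect_reads(al, v)
    cand <- assemble_most_abundant(group_reads_by_sequence(grp$alt_reads), v)
    ps <- translate_candidate(anchor_to_transcript(cand, tx, g))
    # the translated candidate carries BOTH the somatic and the neighbor
    # allele: it equals the phased expectation, not the naive one-variant edit
    expect_identical(ps$amino_acids, man$expected_protein_window,
                     label = sprintf("variant %d phased window", i))
    expect_false(identical(ps$amino_acids, man$naive_protein_window))
  }
})

test_that("anchoring establishes the frame on plus, minus and spliced transcripts", {
  fx <- mixed_fixture()
  g <- load_reference(fx$fasta)
  tx <- load_annotations(fx$gtf)
  al <- load_alignments(fx$sam)
  vs <- suppressMessages(read_vcf(fx$vcf))
  for (i in seq_along(vs)) {
    v <- normalize_variant(vs[[i]], g)
    man <- fx$manifest$variants[[i]]
    if (man$type == "silent") next
    grp <- collect_reads(al, v)
    cand <- assemble_most_abundant(group_reads_by_sequence(grp$alt_reads), v)
    anch <- anchor_to_transcript(cand, tx, g)
    expect_identical(anch$transcript_id, man$transcript)
    ps <- translate_candidate(anch)
    lbl <- sprintf("variant %d (%s, %s strand)", i, man$type,
                   tx[[man$transcript]]$strand)
    if (man$type == "snv") {
      # substitution: the read-assembled window equals the window obtained
      # by editing the annotated CDS directly (independent route)
      expect_identical(ps$amino_acids, man$expected_protein_window, label = lbl)
      expect_identical(unlist(ps$mutant_aa_interval),
                       as.integer(unlist(man$expected_mutant_interval)),
                       label = lbl)
    } else {
      # frameshift indel: the expected window runs to the end of the CDS
      # translation, the assembled one only as far as the reads reach
      expect_identical(substr(man$expected_protein_window, 1, nchar(ps$amino_acids)),
                       ps$amino_acids, label = lbl)
      # at least the 12-residue flank plus one mutant residue survives even
      # when the frameshifted frame stops early
      expect_gte(nchar(ps$amino_acids), 13L)
    }
  }
})

test_that("translate_candidate computes mutant intervals and boundary flags", {
  # in-frame SNV: single mutant residue
  v <- new_variant("chr1", 0, "C", "T")
  cand <- structure(list(variant = v, cdna = "ATGGTCTTTGGG",
                         variant_interval = c(4L, 5L),
                         supporting_read_names = c("a", "b", "c"),
                         frame_offset = 0L, transcript_id = "T1",
                         orientation = "+", is_frameshift = FALSE),
                    class = "CodingSequenceCandidate")
  ps <- translate_candidate(cand)
  expect_identical(ps$amino_acids, "MVFG")
  expect_identical(ps$mutant_aa_interval, c(1L, 2L))
  expect_identical(ps$num_supporting_reads, 3L)

  # frameshift: mutant interval extends to the end of translation
  cand_fs <- cand
  cand_fs$is_frameshift <- TRUE
  ps_fs <- translate_candidate(cand_fs)
  expect_identical(ps_fs$mutant_aa_interval[2], nchar(ps_fs$amino_acids))

  # stop before the mutant interval: dropped with message
  cand_stop <- cand
  cand_stop$cdna <- "TGAGTCTTT"
  expect_message(expect_null(translate_candidate(cand_stop)), "stop codon")
})
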