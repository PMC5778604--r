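# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (Biostrings calls, brute-force
# enumeration) kept separate from the code paths they check.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_translate <- function(cds, frame_offset = 0L) {
  s <- substr(cds, frame_offset + 1L, nchar(cds))
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  if (nchar(s) == 0L) return("")
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(s), if.fuzzy.codon = "X")))
  sub("\\*.*$", "", aa)
}

# brute-force enumeration of equivalent left-shifted representations of a
# pure indel; returns the smallest admissible 0-based position
oracle_leftmost_indel_pos <- function(genome_str, pos, ref, alt) {
  apply_edit <- function(p, r, a) {
    paste0(substr(genome_str, 1L, p), a,
           substr(genome_str, p + nchar(r) + 1L, nchar(genome_str)))
  }
  target <- apply_edit(pos, ref, alt)
  len <- max(nchar(ref), nchar(alt))
  hits <- integer(0)
  for (p in 0:(nchar(genome_str) - nchar(ref))) {
    r <- substr(genome_str, p + 1L, p + nchar(ref))
    # a candidate representation must produce the same edited string
    if (nchar(alt) == 0L) {
      if (identical(apply_edit(p, r, ""), target)) hits <- c(hits, p)
    } else if (nchar(ref) == 0L) {
      # insertion: infer the inserted bases from the target at p
      a <- substr(target, p + 1L, p + nchar(alt))
      if (identical(apply_edit(p, "", a), target)) hits <- c(hits, p)
    }
  }
  min(hits)
}

# brute-force best mutually-compatible read subset (n <= 14): maximum
# cardinality, ties by longer consensus then lexicographically smaller
oracle_best_read_subset <- function(reads) {
  n <- length(reads)
  stopifnot(n <= 14L)
  # absolute coordinates relative to the variant anchor (allele starts at 0)
  expanded <- lapply(reads, function(r) {
    chars <- strsplit(paste0(r$prefix, r$allele, r$suffix), "", fixed = TRUE)[[1]]
    list(pos = seq_along(chars) - nchar(r$prefix) - 1L, chars = chars)
  })
  compat <- function(i, j) {
    common <- intersect(expanded[[i]]$pos, expanded[[j]]$pos)
    all(expanded[[i]]$chars[match(common, expanded[[i]]$pos)] ==
        expanded[[j]]$chars[match(common, expanded[[j]]$pos)])
  }
  best <- NULL
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE
    for (i in idx) for (j in idx) if (i < j && !compat(i, j)) { ok <- FALSE; break }
    if (!ok) next
    pos <- sort(unique(unlist(lapply(expanded[idx], `[[`, "pos"))))
    chars <- character(length(pos))
    for (i in idx) {
      chars[match(expanded[[i]]$pos, pos)] <- expanded[[i]]$chars
    }
    cons <- paste(chars, collapse = "")
    cand <- list(count = length(idx), consensus = cons)
    if (is.null(best) || cand$count > best$count ||
        (cand$count == best$count && nchar(cand$consensus) > nchar(best$consensus)) ||
        (cand$count == best$count && nchar(cand$consensus) == nchar(best$consensus) &&
         cand$consensus < best$consensus)) {
      best <- cand
    }
  }
  best
}

# brute-force nested-loop binding score
oracle_binding_sum <- function(epitopes, alleles, predictor, midpoint = 500, slope = 1) {
  total <- 0
  for (ep in epitopes) {
    for (al in alleles) {
      aff <- predict_binding(predictor, ep, al)$affinity_nM
      total <- total + 1 / (1 + exp(slope * (log(aff) - log(midpoint))))
    }
  }
  total
}
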