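# Vaccine peptide windows, scoring and ranking. TotalScore is the exact
# product of an expression score (a concave transform of the
# mutation-supporting RNA read count) and a binding score (sum of
# logistic-normalized predicted affinities of all mutant epitopes across
# all patient alleles and epitope lengths).

#' Coding-sequence span of a vaccine peptide window
#'
#' @param n_residues peptide length in residues (default 25)
#' @return the number of coding nucleotides the window is translated from
#' @export
coding_span_nt <- function(n_residues = 25L) 3L * as.integer(n_residues)

#' Enumerate candidate vaccine peptide windows
#'
#' All windows of `vaccine_peptide_length` residues (shorter at sequence
#' boundaries) that fully contain the mutant residue interval. When the
#' mutant interval itself exceeds the window (long frameshift), windows
#' covering its start are emitted and flagged.
#'
#' @param p a `ProteinSequenceCandidate`
#' @param vaccine_peptide_length window length in residues (default 25)
#' @return list of windows: `peptide`, `mutant_interval` (within window),
#'   `flags` (character vector; may include "short", "mutant_truncated")
#' @export
candidate_windows <- function(p, vaccine_peptide_length = 25L) {
  stopifnot(inherits(p, "ProteinSequenceCandidate"))
  W <- as.integer(vaccine_peptide_length)
  L <- nchar(p$amino_acids)
  ms <- p$mutant_aa_interval[1L]; me <- p$mutant_aa_interval[2L]
  if (me <= ms) stop("empty mutant interval")
  if (L <= W) {
    fl <- if (L < W) "short" else character(0)
    return(list(list(peptide = p$amino_acids, mutant_interval = c(ms, me),
                     flags = fl)))
  }
  if (me - ms > W) {
    # frameshift longer than the window: cover the start of the mutant run
    starts <- seq.int(max(0L, ms - W + 1L), min(ms, L - W))
    return(lapply(starts, function(s) {
      list(peptide = substr(p$amino_acids, s + 1L, s + W),
           mutant_interval = c(ms - s, W),
           flags = "mutant_truncated")
    }))
  }
  starts <- seq.int(max(0L, me - W), min(ms, L - W))
  lapply(starts, function(s) {
    list(peptide = substr(p$amino_acids, s + 1L, s + W),
         mutant_interval = c(ms - s, me - s),
         flags = character(0))
  })
}

#' Enumerate mutant epitopes within a vaccine peptide
#'
#' Every subpeptide of each configured length that overlaps at least one
#' mutant residue; wild-type-only subpeptides are excluded.
#'
#' @param peptide vaccine peptide string
#' @param mutant_interval 0-based half-open mutant residue interval
#' @param lengths epitope lengths (default 8:11)
#' @return character vector of epitope sequences (one entry per position,
#'   duplicates possible in repetitive sequence)
#' @export
mutant_epitopes <- function(peptide, mutant_interval, lengths = 8:11) {
  L <- nchar(peptide)
  ms <- mutant_interval[1L]; me <- mutant_interval[2L]
  out <- character(0)
  for (k in sort(as.integer(lengths))) {
    if (k > L) next
    starts <- 0:(L - k)
    keep <- starts < me & (starts + k) > ms
    out <- c(out, substring(peptide, starts[keep] + 1L, starts[keep] + k))
  }
  out
}

#' MHC binding score of a set of mutant epitopes
#'
#' Sum over every (epitope, allele) pair of the logistic-normalized
#' predicted affinity. Additive and order-independent.
#'
#' @param epitopes character vector of mutant epitopes
#' @param alleles patient HLA alleles
#' @param predictor an `MHCPredictor`
#' @param midpoint_nM,slope normalization parameters (see
#'   [normalize_affinity()])
#' @return non-negative score
#' @export
binding_score <- function(epitopes, alleles, predictor,
                          midpoint_nM = 500, slope = 1) {
  if (length(epitopes) == 0L || length(alleles) == 0L) return(0)
  preds <- predict_binding(predictor, epitopes, alleles)
  sum(normalize_affinity(preds$affinity_nM, midpoint_nM, slope))
}

#' Expression score from the mutation-supporting read count
#'
#' The raw RNA read count supporting the mutant allele, passed through a
#' concave monotone transform (default square root) so that expression does
#' not swamp binding in the product score.
#'
#' @param alt_read_count non-negative integer read count
#' @param transform "sqrt" (default), "identity" or "log1p"
#' @return non-negative score
#' @export
expression_score <- function(alt_read_count, transform = c("sqrt", "identity", "log1p")) {
  transform <- match.arg(transform)
  stopifnot(alt_read_count >= 0)
  switch(transform,
         sqrt = sqrt(alt_read_count),
         identity = as.numeric(alt_read_count),
         log1p = log1p(alt_read_count))
}

#' Combined vaccine peptide score
#'
#' Exact product of expression and binding scores: abundance and MHC
#' affinity are treated as independent prerequisites for immunogenicity,
#' so a variant with either factor zero cannot rank.
#'
#' @param expression_score,binding_score non-negative reals
#' @return their product
#' @export
total_score <- function(expression_score, binding_score) {
  stopifnot(expression_score >= 0, binding_score >= 0)
  expression_score * binding_score
}

#' Rank per-variant vaccine peptide candidates
#'
#' For each variant the best window is chosen (highest total score; ties:
#' fewest manufacturability flags, then lexicographically smaller peptide).
#' Variants are then sorted by total score descending and the report is
#' truncated to `max_candidates`. Fully deterministic: equal-score variants
#' order by (fewer flags, peptide, variant coordinate).
#'
#' @param candidates list of `VaccinePeptideCandidate` (one or more windows
#'   per variant, as built by the pipeline)
#' @param max_candidates report size cap (default 15)
#' @return a `RankedReport`
#' @export
rank_candidates <- function(candidates, max_candidates = 15L) {
  if (length(candidates) == 0L) {
    warning("no scored candidates: empty report")
    return(structure(list(candidates = list(), n_input_variants = 0L),
                     class = "RankedReport"))
  }
  vid <- vapply(candidates, function(x) variant_id(x$variant), character(1))
  best <- lapply(split(seq_along(candidates), vid), function(idx) {
    xs <- candidates[idx]
    sc <- vapply(xs, `[[`, numeric(1), "total_score")
    nf <- vapply(xs, function(x) manufacturability_rank_key(x$manufacturability),
                 integer(1))
    pep <- vapply(xs, `[[`, character(1), "peptide")
    xs[[order(-sc, nf, pep, method = "radix")[1L]]]
  })
  sc <- vapply(best, `[[`, numeric(1), "total_score")
  nf <- vapply(best, function(x) manufacturability_rank_key(x$manufacturability),
               integer(1))
  pep <- vapply(best, `[[`, character(1), "peptide")
  coord <- vapply(best, function(x) sprintf("%s:%012d", x$variant$contig, x$variant$pos),
                  character(1))
  ord <- order(-sc, nf, pep, coord, method = "radix")
  best <- unname(best[ord])
  n_all <- length(best)
  if (n_all > max_candidates) best <- best[seq_len(max_candidates)]
  if (n_all < max_candidates) {
    message("only ", n_all, " candidate(s) for a report of up to ",
            max_candidates, " (consider more sensitive upstream calling)")
  }
  structure(list(candidates = best, n_input_variants = n_all),
            class = "RankedReport")
}

#' @export
print.RankedReport <- function(x, ...) {
  cat("RankedReport:", length(x$candidates), "candidate(s)\n")
  for (i in seq_along(x$candidates)) {
    cc <- x$candidates[[i]]
    cat(sprintf("%3d. %s  %s  total=%.4f (expr=%.3f x bind=%.4f)%s\n",
                i, variant_id(cc$variant), cc$peptide, cc$total_score,
                cc$expression_score, cc$binding_score,
                if (length(cc$manufacturability$set)) {
                  paste0("  [", paste(cc$manufacturability$set, collapse = ";"), "]")
                } else ""))
  }
  invisible(x)
}
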