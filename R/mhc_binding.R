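# Pluggable Class I peptide-MHC affinity prediction plus logistic affinity
# normalization. The built-in "toy" predictor is a deterministic,
# position-weight stand-in for a real predictor (e.g. NetMHCpan), so the
# whole pipeline is testable offline; real predictions can be supplied as a
# pre-computed TSV affinity table.

#' Normalize an HLA Class I allele name
#'
#' Accepts common dialects ("A0201", "HLA-A02:01", "A*02:01", "hla-b_0702")
#' and returns the canonical `HLA-<gene>*<group>:<protein>` form.
#'
#' @param raw allele name in any accepted dialect
#' @return canonical allele name string
#' @export
normalize_allele_name <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw))) {
    stop("empty HLA allele name; accepted dialects: 'HLA-A*02:01', ",
         "'HLA-A02:01', 'A*02:01', 'A0201'")
  }
  x <- toupper(trimws(raw))
  x <- sub("^HLA[-_]?", "", x)
  m <- regmatches(x, regexec("^([A-Z]+[0-9]*)[*_]?([0-9]{2,3})[:_]?([0-9]{2,3})$", x))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse HLA allele '", raw, "'; accepted dialects: ",
         "'HLA-A*02:01', 'HLA-A02:01', 'A*02:01', 'A0201'")
  }
  sprintf("HLA-%s*%s:%s", m[2L], m[3L], m[4L])
}

# --- toy predictor ----------------------------------------------------------

# Anchor-residue preference tables for the built-in toy predictor: a weight
# in [0, 1] for the residue at position 2 (P2) and at the C-terminus
# (P-omega), loosely following published binding motifs. Residues absent
# from a table score 0.
.TOY_ANCHORS <- list(
  "HLA-A*01:01" = list(p2 = c(T = 1, S = 0.8, V = 0.4), pc = c(Y = 1, F = 0.5)),
  "HLA-A*02:01" = list(p2 = c(L = 1, M = 0.8, I = 0.5), pc = c(V = 1, L = 0.8, I = 0.6)),
  "HLA-A*03:01" = list(p2 = c(L = 1, V = 0.7, M = 0.5), pc = c(K = 1, R = 0.8)),
  "HLA-B*07:02" = list(p2 = c(P = 1, A = 0.4), pc = c(L = 1, F = 0.7, M = 0.5)),
  "HLA-B*08:01" = list(p2 = c(K = 0.6, R = 0.5, A = 0.4), pc = c(L = 1, I = 0.5)),
  "HLA-C*07:01" = list(p2 = c(Y = 1, F = 0.6), pc = c(L = 1, F = 0.6, Y = 0.4)),
  "HLA-C*07:02" = list(p2 = c(Y = 1, F = 0.6), pc = c(Y = 1, L = 0.7, F = 0.5))
)

.TOY_LENGTH_PREF <- c("8" = 0.25, "9" = 1, "10" = 0.5, "11" = 0.25)

.MAX_AFFINITY_NM <- 50000

# closed-form toy affinity: anchor-weight score in [0, 1] mapped
# log-linearly onto [1, 50000] nM (stronger anchors -> lower nM)
.toy_affinity <- function(peptide, allele) {
  tab <- .TOY_ANCHORS[[allele]]
  n <- nchar(peptide)
  p2 <- substr(peptide, 2L, 2L)
  pc <- substr(peptide, n, n)
  w2 <- tab$p2[p2]; if (is.na(w2)) w2 <- 0
  wc <- tab$pc[pc]; if (is.na(wc)) wc <- 0
  lp <- .TOY_LENGTH_PREF[as.character(n)]; if (is.na(lp)) lp <- 0
  score <- 0.45 * w2 + 0.45 * wc + 0.10 * lp
  unname(.MAX_AFFINITY_NM^(1 - score))
}

#' Built-in deterministic toy peptide-MHC predictor
#'
#' Scores the P2 and C-terminal anchor residues against a small built-in
#' per-allele preference table and maps the score log-linearly onto the
#' `[1, 50000]` nM range. Deterministic across runs and platforms; intended
#' purely as a stand-in so the pipeline runs without an external predictor.
#'
#' @return an `MHCPredictor`
#' @export
toy_predictor <- function() {
  structure(list(
    name = "toy",
    supported_alleles = names(.TOY_ANCHORS),
    predict = function(peptides, alleles) {
      bad <- setdiff(alleles, names(.TOY_ANCHORS))
      if (length(bad)) {
        stop("unsupported allele(s) for the toy predictor: ",
             paste(bad, collapse = ", "), "; supported: ",
             paste(names(.TOY_ANCHORS), collapse = ", "))
      }
      grid <- expand.grid(peptide = peptides, allele = alleles,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      grid$affinity_nM <- mapply(.toy_affinity, grid$peptide, grid$allele,
                                 USE.NAMES = FALSE)
      grid
    }
  ), class = "MHCPredictor")
}

#' Predictor answering from a pre-computed affinity table
#'
#' @param path TSV with header columns `peptide`, `allele`, `affinity_nM`
#'   (e.g. exported NetMHCpan predictions)
#' @return an `MHCPredictor`; querying a (peptide, allele) pair absent from
#'   the table is an error naming the pair
#' @export
load_affinity_table <- function(path) {
  if (!file.exists(path)) stop("affinity table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "affinity_nM")
  if (!all(need %in% names(tab))) {
    stop("affinity table must have columns: ", paste(need, collapse = ", "))
  }
  tab$allele <- vapply(tab$allele, normalize_allele_name, character(1))
  key <- paste(tab$peptide, tab$allele, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k) {
      length(unique(tab$affinity_nM[key == k])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("conflicting duplicate rows in affinity table for: ",
           paste(gsub("\r", "/", unique(dup)[conflict]), collapse = ", "))
    }
    tab <- tab[!duplicated(key), ]
    key <- key[!duplicated(key)]
  }
  if (any(tab$affinity_nM <= 0)) stop("non-positive affinity in table")
  lookup <- stats::setNames(tab$affinity_nM, key)
  structure(list(
    name = "table",
    supported_alleles = unique(tab$allele),
    predict = function(peptides, alleles) {
      grid <- expand.grid(peptide = peptides, allele = alleles,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      k <- paste(grid$peptide, grid$allele, sep = "\r")
      miss <- is.na(lookup[k])
      if (any(miss)) {
        stop("affinity table has no entry for: ",
             paste(paste(grid$peptide[miss], grid$allele[miss]), collapse = "; "))
      }
      grid$affinity_nM <- unname(lookup[k])
      grid
    }
  ), class = "MHCPredictor")
}

#' Predict peptide-MHC binding for all (peptide, allele) pairs
#'
#' @param predictor an `MHCPredictor`
#' @param peptides character vector of 8-11-mer peptides
#' @param alleles character vector of HLA allele names (any accepted dialect)
#' @return data.frame with one row per (peptide, allele) pair: `peptide`,
#'   `allele`, `affinity_nM`
#' @export
predict_binding <- function(predictor, peptides, alleles) {
  stopifnot(inherits(predictor, "MHCPredictor"))
  if (length(peptides) == 0L || length(alleles) == 0L) {
    return(data.frame(peptide = character(0), allele = character(0),
                      affinity_nM = numeric(0)))
  }
  alleles <- vapply(alleles, normalize_allele_name, character(1), USE.NAMES = FALSE)
  res <- predictor$predict(peptides, alleles)
  if (nrow(res) != length(peptides) * length(alleles)) {
    stop("predictor returned ", nrow(res), " rows for ",
         length(peptides) * length(alleles), " (peptide, allele) pairs")
  }
  res
}

#' Logistic normalization of a binding affinity
#'
#' Maps an IC50 affinity (nM) to a score in (0, 1), decreasing in affinity,
#' with `score(midpoint_nM) = 0.5` exactly:
#' `1 / (1 + exp(slope * (log(affinity) - log(midpoint))))`.
#' The default midpoint of 500 nM anchors the score at the classical
#' binder threshold; the slope (on the natural-log scale) is configurable.
#'
#' @param affinity_nM positive affinity (vectorized)
#' @param midpoint_nM affinity mapped to score 0.5 (default 500)
#' @param slope positive logistic slope on the log-affinity scale (default 1)
#' @return normalized score(s) in (0, 1)
#' @export
normalize_affinity <- function(affinity_nM, midpoint_nM = 500, slope = 1) {
  if (any(!is.finite(affinity_nM)) || any(affinity_nM <= 0)) {
    stop("affinity must be positive and finite")
  }
  stopifnot(midpoint_nM > 0, slope > 0)
  1 / (1 + exp(slope * (log(affinity_nM) - log(midpoint_nM))))
}
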