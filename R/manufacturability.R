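# Heuristic screening for solid-phase peptide synthesis feasibility. Flags
# never change scores: they demote only on exact score ties (default) or,
# in strict mode, exclude flagged peptides entirely.

# Kyte-Doolittle hydropathy index; X (unknown residue) scores 0 so flags
# stay conservative
.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

mean_hydropathy <- function(residues) {
  h <- .KYTE_DOOLITTLE[residues]
  h[is.na(h)] <- 0
  mean(h)
}

#' Manufacturability flags of a peptide
#'
#' Screens for common solid-phase synthesis failure modes:
#' * `excess_cysteine`: cysteine count >= `max_cysteines` (default 3)
#' * `n_terminal_gln_glu_cys`: first residue is Q, E or C
#' * `asparagine_proline_bond`: "NP" occurs anywhere
#' * `extreme_hydrophobicity`: mean Kyte-Doolittle hydropathy >
#'   `hydropathy_threshold` (default 2.5)
#' * `hydrophobic_c_terminus`: mean hydropathy of the final
#'   `c_terminal_window` residues (default 7) > `hydropathy_threshold`
#'
#' @param peptide non-empty amino-acid string (X tolerated)
#' @param max_cysteines cysteine-count threshold
#' @param hydropathy_threshold mean-hydropathy threshold
#' @param c_terminal_window length of the C-terminal window
#' @return a `ManufacturabilityFlags` object: `set` (names of raised
#'   flags, in the fixed flag order) and `detail` (per-flag trigger detail)
#' @export
manufacturability_flags <- function(peptide, max_cysteines = 3L,
                                    hydropathy_threshold = 2.5,
                                    c_terminal_window = 7L) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop("empty peptide")
  }
  res <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  n_cys <- sum(res == "C")
  mean_h <- mean_hydropathy(res)
  cterm <- res[seq.int(max(1L, length(res) - c_terminal_window + 1L), length(res))]
  cterm_h <- mean_hydropathy(cterm)
  flags <- c(
    excess_cysteine = n_cys >= max_cysteines,
    n_terminal_gln_glu_cys = res[1L] %in% c("Q", "E", "C"),
    asparagine_proline_bond = grepl("NP", peptide, fixed = TRUE),
    extreme_hydrophobicity = mean_h > hydropathy_threshold,
    hydrophobic_c_terminus = cterm_h > hydropathy_threshold
  )
  structure(list(
    set = names(flags)[flags],
    detail = list(cysteine_count = n_cys, n_terminal = res[1L],
                  mean_hydropathy = mean_h, c_terminal_hydropathy = cterm_h)
  ), class = "ManufacturabilityFlags")
}

#' Tie-break key from manufacturability flags
#'
#' The number of raised flags; used only to break exact score ties in
#' ranking, never to alter a score.
#'
#' @param flags a `ManufacturabilityFlags` object (or `NULL`)
#' @return integer flag count
#' @export
manufacturability_rank_key <- function(flags) {
  if (is.null(flags)) return(0L)
  stopifnot(inherits(flags, "ManufacturabilityFlags"))
  length(flags$set)
}

#' @export
print.ManufacturabilityFlags <- function(x, ...) {
  if (length(x$set) == 0L) cat("ManufacturabilityFlags: none\n")
  else cat("ManufacturabilityFlags:", paste(x$set, collapse = "; "), "\n")
  invisible(x)
}
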