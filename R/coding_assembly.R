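# Assemble the most abundant mutant coding sequence from alt reads anchored
# at the variant, establish the reading frame from transcript annotation,
# and translate. Because the consensus is built from whole reads, germline
# or somatic variants present on the supporting reads are retained in the
# consensus — adjacent variants within read length are phased for free.

# --- read grouping ----------------------------------------------------------

# Two alt reads (anchored at the same variant allele) are compatible when
# their sequences agree on every overlapping position relative to the
# anchor: the shorter prefix must be a suffix of the longer, and the shorter
# suffix a prefix of the longer.
.compatible <- function(p1, s1, p2, s2) {
  np <- min(nchar(p1), nchar(p2))
  if (np > 0L &&
      substr(p1, nchar(p1) - np + 1L, nchar(p1)) !=
      substr(p2, nchar(p2) - np + 1L, nchar(p2))) return(FALSE)
  ns <- min(nchar(s1), nchar(s2))
  if (ns > 0L && substr(s1, 1L, ns) != substr(s2, 1L, ns)) return(FALSE)
  TRUE
}

# maximal cliques of an undirected graph (adjacency matrix), Bron-Kerbosch;
# n is small (<= exact grouping threshold) so no pivoting is needed
.maximal_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      out[[length(out) + 1L]] <<- R
      return(invisible(NULL))
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out
}

#' Group mutation-supporting reads by sequence compatibility
#'
#' Reads (all supporting the same variant allele) are grouped by agreement
#' on every overlapping position relative to the variant anchor; each
#' group's consensus spans the union of its reads. For up to
#' `exact_threshold` reads the groups are extracted exactly: the largest
#' mutually-compatible read set is found by maximal-clique search, removed,
#' and the search repeats. Beyond the threshold a deterministic greedy
#' insertion (longest span first, then lexicographic) is used.
#'
#' @param alt_reads list of `AlleleRead` (the `alt_reads` of an
#'   [collect_reads()] result)
#' @param exact_threshold maximum read count for exact grouping (default 20)
#' @return list of groups, each with `prefix`, `allele`, `suffix`, `count`,
#'   `read_names`; sorted by decreasing count (ties: longer consensus, then
#'   lexicographically smaller consensus)
#' @export
group_reads_by_sequence <- function(alt_reads, exact_threshold = 20L) {
  if (length(alt_reads) == 0L) return(list())
  if (length(alt_reads) <= exact_threshold) {
    return(.group_exact(alt_reads))
  }
  span <- vapply(alt_reads, function(r) nchar(r$prefix) + nchar(r$suffix), integer(1))
  key <- vapply(alt_reads, function(r) paste(r$prefix, r$allele, r$suffix, sep = "|"),
                character(1))
  nm <- vapply(alt_reads, `[[`, character(1), "read_name")
  ord <- order(-span, key, nm, method = "radix")
  groups <- list()
  for (i in ord) {
    r <- alt_reads[[i]]
    placed <- FALSE
    for (k in seq_along(groups)) {
      gr <- groups[[k]]
      if (identical(gr$allele, r$allele) &&
          .compatible(gr$prefix, gr$suffix, r$prefix, r$suffix)) {
        if (nchar(r$prefix) > nchar(gr$prefix)) gr$prefix <- r$prefix
        if (nchar(r$suffix) > nchar(gr$suffix)) gr$suffix <- r$suffix
        gr$count <- gr$count + 1L
        gr$read_names <- c(gr$read_names, r$read_name)
        groups[[k]] <- gr
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- list(prefix = r$prefix, allele = r$allele,
                                            suffix = r$suffix, count = 1L,
                                            read_names = r$read_name)
    }
  }
  cons <- vapply(groups, function(g) paste0(g$prefix, g$allele, g$suffix), character(1))
  cnt <- vapply(groups, `[[`, integer(1), "count")
  groups[order(-cnt, -nchar(cons), cons, method = "radix")]
}

# exact grouping: repeatedly extract the best mutually-compatible read set
# (largest; ties by longer consensus, then lexicographically smaller)
.group_exact <- function(alt_reads) {
  groups <- list()
  remaining <- alt_reads
  while (length(remaining) > 0L) {
    n <- length(remaining)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j) {
          ok <- identical(remaining[[i]]$allele, remaining[[j]]$allele) &&
            .compatible(remaining[[i]]$prefix, remaining[[i]]$suffix,
                        remaining[[j]]$prefix, remaining[[j]]$suffix)
          adj[i, j] <- ok; adj[j, i] <- ok
        }
      }
    }
    cliques <- .maximal_cliques(adj)
    build <- function(idx) {
      xs <- remaining[idx]
      pre <- vapply(xs, `[[`, character(1), "prefix")
      suf <- vapply(xs, `[[`, character(1), "suffix")
      list(prefix = pre[which.max(nchar(pre))],
           allele = xs[[1L]]$allele,
           suffix = suf[which.max(nchar(suf))],
           count = length(xs),
           read_names = vapply(xs, `[[`, character(1), "read_name"))
    }
    built <- lapply(cliques, build)
    cons <- vapply(built, function(g) paste0(g$prefix, g$allele, g$suffix), character(1))
    cnt <- vapply(built, `[[`, integer(1), "count")
    best <- order(-cnt, -nchar(cons), cons, method = "radix")[1L]
    groups[[length(groups) + 1L]] <- built[[best]]
    remaining <- remaining[-cliques[[best]]]
  }
  cons <- vapply(groups, function(g) paste0(g$prefix, g$allele, g$suffix), character(1))
  cnt <- vapply(groups, `[[`, integer(1), "count")
  groups[order(-cnt, -nchar(cons), cons, method = "radix")]
}

#' Pick the most abundant coding-sequence candidate
#'
#' Returns the group with the largest supporting-read count (ties broken by
#' longer consensus, then lexicographically smaller sequence) as a
#' `CodingSequenceCandidate` in genomic plus-strand orientation. Groups
#' below `min_reads` are ignored; `NULL` is returned (with a message) when
#' no group qualifies.
#'
#' @param groups output of [group_reads_by_sequence()]
#' @param v the `Variant` the reads support
#' @param min_reads minimum supporting reads (default 3)
#' @return a `CodingSequenceCandidate` or `NULL`
#' @export
assemble_most_abundant <- function(groups, v, min_reads = 3L) {
  keep <- Filter(function(g) g$count >= min_reads, groups)
  if (length(keep) == 0L) {
    message("variant ", variant_id(v), ": no read group with >= ", min_reads,
            " supporting reads")
    return(NULL)
  }
  g <- keep[[1L]]  # groups are already sorted by the tie-break order
  cdna <- paste0(g$prefix, g$allele, g$suffix)
  structure(list(
    variant = v,
    cdna = cdna,
    variant_interval = c(nchar(g$prefix), nchar(g$prefix) + nchar(g$allele)),
    supporting_read_names = g$read_names,
    frame_offset = NA_integer_,
    transcript_id = NA_character_,
    orientation = "+"
  ), class = "CodingSequenceCandidate")
}

# --- transcript anchoring ---------------------------------------------------

# CDS coordinate (0-based, coding order) of the first base of the variant's
# edit; for insertions, the coding index before which the insertion falls.
.variant_cds_coord <- function(v, t) {
  ref_len <- nchar(v$ref)
  if (t$strand == "+") {
    if (ref_len > 0L) cds_index_of(t, v$pos)
    else {
      i <- cds_index_of(t, v$pos)
      if (is.na(i)) NA_integer_ else i
    }
  } else {
    if (ref_len > 0L) cds_index_of(t, v$pos + ref_len - 1L)
    else {
      i <- cds_index_of(t, v$pos - 1L)
      if (is.na(i)) NA_integer_ else i
    }
  }
}

#' Anchor an assembled consensus to a transcript reading frame
#'
#' Reorients the consensus to the coding strand, trims it to the portion
#' overlapping the transcript's spliced CDS, and computes the frame offset
#' of the first complete codon. When several coding transcripts match, the
#' one giving the longest in-frame overlap with the CDS wins (ties: longer
#' CDS, then lexicographically smaller id).
#'
#' @param cand a `CodingSequenceCandidate` from [assemble_most_abundant()]
#' @param transcripts list of `Transcript`
#' @param g a `ReferenceGenome`
#' @return the anchored candidate (with `frame_offset`, `transcript_id`,
#'   `is_frameshift`), or `NULL` when no transcript yields a frame
#' @export
anchor_to_transcript <- function(cand, transcripts, g) {
  stopifnot(inherits(cand, "CodingSequenceCandidate"))
  v <- cand$variant
  cands <- list()
  for (t in transcripts) {
    if (!t$coding || t$contig != v$contig) next
    i <- .variant_cds_coord(v, t)
    if (is.na(i)) next
    a <- .anchor_one(cand, v, t, i)
    if (!is.null(a)) cands[[length(cands) + 1L]] <- a
  }
  if (length(cands) == 0L) {
    message("variant ", variant_id(v), ": no transcript yields a reading frame")
    return(NULL)
  }
  ov <- vapply(cands, `[[`, integer(1), "cds_overlap")
  cl <- vapply(cands, `[[`, integer(1), "cds_len")
  id <- vapply(cands, `[[`, character(1), "transcript_id")
  cands[[order(-ov, -cl, id, method = "radix")[1L]]]
}

.anchor_one <- function(cand, v, t, i) {
  prefix_len <- cand$variant_interval[1L]
  suffix_len <- nchar(cand$cdna) - cand$variant_interval[2L]
  allele_len <- cand$variant_interval[2L] - cand$variant_interval[1L]
  if (t$strand == "+") {
    cdna <- cand$cdna
    vi <- cand$variant_interval
    lead <- prefix_len
  } else {
    cdna <- revcomp(cand$cdna)
    n <- nchar(cand$cdna)
    vi <- c(n - cand$variant_interval[2L], n - cand$variant_interval[1L])
    lead <- suffix_len
  }
  # for insertions, .variant_cds_coord already returns the coding index of
  # the insertion point (the base the insertion precedes in coding order)
  vstart_cds <- i
  d0 <- vstart_cds - lead            # CDS coordinate of the cdna's first base
  cds_len <- length(cds_genomic_positions(t))
  # trim to the CDS-overlapping portion
  trim_left <- max(0L, -d0)
  end_cds <- d0 + nchar(cdna)        # CDS coordinate one past the cdna's last base
  trim_right <- max(0L, end_cds - cds_len)
  if (trim_left + trim_right >= nchar(cdna)) return(NULL)
  cdna_t <- substr(cdna, trim_left + 1L, nchar(cdna) - trim_right)
  vi_t <- pmin(pmax(vi - trim_left, 0L), nchar(cdna_t))
  d <- max(d0, 0L)
  frame_offset <- (3L - (d %% 3L)) %% 3L
  len_shift <- nchar(v$alt) - nchar(v$ref)
  structure(list(
    variant = v,
    cdna = cdna_t,
    variant_interval = as.integer(vi_t),
    supporting_read_names = cand$supporting_read_names,
    frame_offset = frame_offset,
    transcript_id = t$id,
    orientation = t$strand,
    cds_overlap = nchar(cdna_t),
    cds_len = cds_len,
    is_frameshift = (len_shift %% 3L) != 0L
  ), class = "CodingSequenceCandidate")
}

# --- translation ------------------------------------------------------------

#' Translate an anchored coding-sequence candidate
#'
#' Translates from the candidate's frame offset, computes the mutant residue
#' interval from the variant's nucleotide interval (for frameshifts, every
#' residue downstream of the shift is mutant), and trims the protein to at
#' most `peptide_radius` residues either side of the mutant interval.
#'
#' @param cand an anchored `CodingSequenceCandidate`
#' @param peptide_radius residues retained either side of the mutation
#'   (default 12, supporting 25-mer vaccine windows downstream)
#' @return a `ProteinSequenceCandidate`, or `NULL` (with a message) when a
#'   stop codon precedes the mutant interval or no mutant residue survives
#' @export
translate_candidate <- function(cand, peptide_radius = 12L) {
  stopifnot(inherits(cand, "CodingSequenceCandidate"), !is.na(cand$frame_offset))
  prot <- translate_cds(cand$cdna, cand$frame_offset)
  L <- nchar(prot)
  vs <- cand$variant_interval[1L] - cand$frame_offset
  ve <- cand$variant_interval[2L] - cand$frame_offset
  aa_start <- max(0L, vs %/% 3L)
  aa_end <- if (isTRUE(cand$is_frameshift)) L
            else max(aa_start + 1L, as.integer(ceiling(ve / 3)))
  if (aa_start >= L) {
    message("variant ", variant_id(cand$variant),
            ": stop codon before the mutant interval; candidate dropped")
    return(NULL)
  }
  aa_end <- min(aa_end, L)
  keep_start <- max(0L, aa_start - peptide_radius)
  keep_end <- min(L, aa_end + peptide_radius)
  amino_acids <- substr(prot, keep_start + 1L, keep_end)
  structure(list(
    variant = cand$variant,
    amino_acids = amino_acids,
    mutant_aa_interval = c(aa_start - keep_start, aa_end - keep_start),
    num_supporting_reads = length(unique(cand$supporting_read_names)),
    source_transcripts = cand$transcript_id,
    is_frameshift = isTRUE(cand$is_frameshift)
  ), class = "ProteinSequenceCandidate")
}

#' @export
print.ProteinSequenceCandidate <- function(x, ...) {
  cat(sprintf("ProteinSequenceCandidate %s: %s [mutant %d-%d), %d read(s), %s\n",
              variant_id(x$variant), x$amino_acids,
              x$mutant_aa_interval[1], x$mutant_aa_interval[2],
              x$num_supporting_reads, x$source_transcripts))
  invisible(x)
}
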