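# Variant normalization and protein-level effect classification. This module
# is a filter (drop silent / non-protein-altering variants); the candidate
# protein sequence itself always comes from RNA evidence (coding_assembly).

#' Construct a variant
#'
#' @param contig contig name
#' @param pos 0-based genomic start of the reference allele (for a pure
#'   insertion, the base before which the insertion occurs)
#' @param ref reference allele (may be empty after trimming)
#' @param alt alternate allele (may be empty)
#' @param provenance "somatic" or "germline"
#' @return a `Variant`
#' @export
new_variant <- function(contig, pos, ref, alt, provenance = "somatic") {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) && !nzchar(alt)) stop("variant with empty ref and alt")
  stopifnot(provenance %in% c("somatic", "germline"))
  structure(list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
                 provenance = provenance),
            class = "Variant")
}

#' @export
print.Variant <- function(x, ...) {
  cat(variant_id(x), sprintf("(%s)\n", x$provenance))
  invisible(x)
}

#' Human-readable variant identifier (contig:pos ref>alt, 0-based)
#' @param v a `Variant`
#' @export
variant_id <- function(v) {
  sprintf("%s:%d %s>%s", v$contig, v$pos,
          if (nzchar(v$ref)) v$ref else "-", if (nzchar(v$alt)) v$alt else "-")
}

# trim shared suffix then shared prefix, adjusting pos
variant_trim <- function(v) {
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt)) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  new_variant(v$contig, pos, ref, alt, v$provenance)
}

#' Read somatic variants from a VCF file
#'
#' VCF 1-based positions are converted to 0-based; multi-allelic rows are
#' split into one variant per alternate allele; shared prefix/suffix bases
#' are trimmed (left alignment against the reference requires
#' [normalize_variant()]).
#'
#' @param path path to an (uncompressed or bgzipped) VCF
#' @param keep_nonpass keep rows whose FILTER is not PASS/"." (default FALSE)
#' @param provenance provenance label attached to every variant
#' @return list of `Variant` objects
#' @export
read_vcf <- function(path, keep_nonpass = FALSE, provenance = "somatic") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) == 0L) return(list())
  filt <- rr$FILTER
  keep <- keep_nonpass | is.na(filt) | filt %in% c("PASS", ".")
  n_skip <- sum(!keep)
  if (n_skip > 0L) message(n_skip, " VCF row(s) skipped by FILTER")
  rr <- rr[keep]
  out <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    out[[i]] <- variant_trim(new_variant(
      contig = as.character(GenomicRanges::seqnames(rr)[i]),
      pos = GenomicRanges::start(rr)[i] - 1L,
      ref = as.character(rr$REF[i]),
      alt = as.character(rr$ALT[i]),
      provenance = provenance
    ))
  }
  out
}

#' Normalize a variant against the reference
#'
#' Trims shared prefix/suffix bases and left-aligns pure insertions and
#' deletions until a mismatching reference base blocks the shift. The
#' operation is idempotent, and errors if the stated reference allele does
#' not match the genome.
#'
#' @param v a `Variant`
#' @param g a `ReferenceGenome`
#' @return the normalized `Variant`
#' @export
normalize_variant <- function(v, g) {
  if (nzchar(v$ref)) {
    obs <- genome_seq(g, v$contig, v$pos, v$pos + nchar(v$ref))
    if (obs != v$ref) {
      stop(sprintf("reference mismatch at %s:%d: VCF says %s, genome has %s",
                   v$contig, v$pos, v$ref, obs))
    }
  }
  v <- variant_trim(v)
  # left-align a pure indel: shift while the base entering from the left
  # equals the base leaving on the right of the inserted/deleted sequence
  is_ins <- !nzchar(v$ref) && nzchar(v$alt)
  is_del <- nzchar(v$ref) && !nzchar(v$alt)
  if (is_ins || is_del) {
    seqs <- if (is_ins) v$alt else v$ref
    pos <- v$pos
    while (pos > 0L) {
      prev <- genome_seq(g, v$contig, pos - 1L, pos)
      if (prev != substr(seqs, nchar(seqs), nchar(seqs))) break
      seqs <- paste0(prev, substr(seqs, 1L, nchar(seqs) - 1L))
      pos <- pos - 1L
    }
    v <- new_variant(v$contig, pos,
                     if (is_del) seqs else "", if (is_ins) seqs else "",
                     v$provenance)
  }
  v
}

# --- effect classification --------------------------------------------------

# 0-based coding index at which to apply the edit, plus strand-oriented
# ref/alt; NA index when the edit cannot be placed inside the spliced CDS
.cds_edit <- function(v, t) {
  ref_len <- nchar(v$ref)
  if (t$strand == "+") {
    i <- cds_index_of(t, v$pos)
    list(i = i, ref = v$ref, alt = v$alt)
  } else {
    # first coding base of the edit is the variant's highest genomic base;
    # a pure insertion between genomic pos-1 and pos lands, in coding
    # orientation, before the base at genomic pos-1
    i <- if (ref_len > 0L) cds_index_of(t, v$pos + ref_len - 1L)
         else cds_index_of(t, v$pos - 1L)
    list(i = i, ref = revcomp(v$ref), alt = revcomp(v$alt))
  }
}

# edit the spliced CDS string at coding index i
.apply_cds_edit <- function(cds, i, ref, alt) {
  paste0(substr(cds, 1L, i), alt, substr(cds, i + nchar(ref) + 1L, nchar(cds)))
}

#' Classify the protein-level effect of a variant, per transcript
#'
#' For every transcript overlapping the variant, the spliced CDS is edited
#' and re-translated; the effect category is derived by comparing reference
#' and mutant translations. Variants inside exons but outside the CDS are
#' `noncoding`; variants inside the transcript span but outside exons are
#' `intronic` (variants within 2 nt of an intron boundary are additionally
#' noted as splice-region via message).
#'
#' @param v a normalized `Variant`
#' @param transcripts list of `Transcript` objects
#' @param g a `ReferenceGenome`
#' @return list of `VariantEffect` objects (one per overlapping transcript)
#' @export
annotate_effects <- function(v, transcripts, g) {
  ref_len <- nchar(v$ref)
  v_start <- v$pos
  v_end <- v$pos + max(ref_len, 0L)
  out <- list()
  for (t in transcripts) {
    if (t$contig != v$contig) next
    span <- transcript_span(t)
    # an insertion "overlaps" when its junction lies strictly inside the span
    overlaps <- if (ref_len > 0L) (v_start < span[2L] && v_end > span[1L])
                else (v_start > span[1L] && v_start < span[2L])
    if (!overlaps) next
    out[[length(out) + 1L]] <- .effect_for_transcript(v, t, g)
  }
  out
}

.effect_for_transcript <- function(v, t, g) {
  mk <- function(category, aa_pos = NA_integer_) {
    structure(list(variant = v, transcript_id = t$id, category = category,
                   aa_pos = aa_pos), class = "VariantEffect")
  }
  if (!t$coding) return(mk("noncoding"))
  ref_len <- nchar(v$ref)
  in_exon <- function(p) any(p >= t$exons[, 1L] & p < t$exons[, 2L])
  probe <- if (ref_len > 0L) seq.int(v$pos, v$pos + ref_len - 1L) else c(v$pos - 1L, v$pos)
  if (!all(vapply(probe, in_exon, logical(1)))) {
    # inside span but (partly) outside exons
    near_edge <- any(vapply(probe, function(p) {
      any(abs(p - c(t$exons[, 1L], t$exons[, 2L])) <= 2L)
    }, logical(1)))
    if (near_edge) message("variant ", variant_id(v), " lies in the splice region of ", t$id)
    return(mk("intronic"))
  }
  ed <- .cds_edit(v, t)
  if (is.na(ed$i)) return(mk("noncoding"))
  if (ref_len > 0L) {
    # the whole ref allele must sit inside the spliced CDS
    last_g <- if (t$strand == "+") v$pos + ref_len - 1L else v$pos
    if (is.na(cds_index_of(t, last_g))) return(mk("noncoding"))
  }
  cds <- suppressWarnings(spliced_cds(t, g))
  mut <- .apply_cds_edit(cds, ed$i, ed$ref, ed$alt)
  ref_prot <- translate_cds(cds)
  mut_prot <- translate_cds(mut)
  len_shift <- nchar(ed$alt) - nchar(ed$ref)
  first_diff <- .first_diff(ref_prot, mut_prot)
  aa_pos <- if (is.na(first_diff)) ed$i %/% 3L else first_diff
  if (len_shift %% 3L != 0L) return(mk("frameshift", aa_pos))
  if (len_shift == 0L) {
    if (identical(ref_prot, mut_prot)) return(mk("silent"))
    if (ed$i < 3L && substr(mut, 1L, 3L) != substr(cds, 1L, 3L) &&
        translate_cds(substr(mut, 1L, 3L)) != "M") {
      return(mk("start_lost", 0L))
    }
    if (nchar(mut_prot) < nchar(ref_prot)) return(mk("stop_gained", aa_pos))
    if (nchar(mut_prot) > nchar(ref_prot)) return(mk("stop_lost", aa_pos))
    return(mk("missense", aa_pos))
  }
  if (identical(ref_prot, mut_prot)) return(mk("silent"))
  if (len_shift > 0L) mk("inframe_insertion", aa_pos) else mk("inframe_deletion", aa_pos)
}

# 0-based index of the first differing residue, NA when one is a prefix of
# the other and no interior difference exists
.first_diff <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0L) {
    av <- strsplit(a, "", fixed = TRUE)[[1]][seq_len(n)]
    bv <- strsplit(b, "", fixed = TRUE)[[1]][seq_len(n)]
    d <- which(av != bv)
    if (length(d)) return(d[1L] - 1L)
  }
  if (nchar(a) != nchar(b)) return(n)
  NA_integer_
}

#' @export
print.VariantEffect <- function(x, ...) {
  cat(sprintf("%s on %s: %s%s\n", variant_id(x$variant), x$transcript_id,
              x$category,
              if (!is.na(x$aa_pos)) sprintf(" (aa %d)", x$aa_pos) else ""))
  invisible(x)
}

# categories that alter the protein sequence and leave novel residues to
# target; stop_gained is excluded (no novel residues downstream of the stop)
.NONSILENT <- c("missense", "inframe_insertion", "inframe_deletion",
                "frameshift", "stop_lost")

#' Keep only protein-altering effects
#'
#' Retains missense, in-frame indels, frameshift and stop-lost effects;
#' silent, noncoding, intronic and stop-gained effects are dropped
#' (a stop-gained variant yields no novel mutant residues to vaccinate
#' against).
#'
#' @param effects list of `VariantEffect`
#' @return filtered list
#' @export
filter_nonsilent <- function(effects) {
  Filter(function(e) e$category %in% .NONSILENT, effects)
}
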