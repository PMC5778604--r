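# Tumor RNA read evidence at a variant locus: decompose each overlapping
# alignment via its CIGAR into (prefix, allele, suffix) around the variant
# interval and partition reads by the allele they support. The alt read
# count is the allele-specific expression estimate consumed by the ranking
# module.

.FLAG_UNMAPPED  <- 4L
.FLAG_SECONDARY <- 256L
.FLAG_DUP       <- 1024L
.FLAG_SUPPL     <- 2048L

#' Load read alignments from SAM or BAM
#'
#' SAM input is converted to BAM via Rsamtools before scanning, so both
#' extensions behave identically. Returns an `AlignmentSet`: a plain list of
#' per-read records (name, flag, contig, 0-based position, MAPQ, CIGAR,
#' sequence, qualities).
#'
#' @param path path to a `.sam` or `.bam` file (headered)
#' @return an `AlignmentSet`
#' @export
load_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  n <- length(res$qname)
  reads <- vector("list", n)
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  for (i in seq_len(n)) {
    cig <- res$cigar[i]
    span <- if (is.na(cig)) 0L else {
      ops <- regmatches(cig, gregexpr("\\d+[MDN=X]", cig))[[1]]
      sum(as.integer(sub(".$", "", ops)))
    }
    reads[[i]] <- list(
      name = res$qname[i], flag = res$flag[i],
      contig = as.character(res$rname[i]),
      pos0 = res$pos[i] - 1L, end0 = res$pos[i] - 1L + span,
      mapq = res$mapq[i],
      cigar = cig, seq = seqs[i], qual = quals[i]
    )
  }
  structure(list(reads = reads), class = "AlignmentSet")
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat("AlignmentSet:", length(x$reads), "read(s)\n")
  invisible(x)
}

# Walk a CIGAR string over a read, producing a per-query-base map:
#   qpos (1-based into seq), refpos (0-based, NA for inserted bases),
#   anchor (for inserted bases: the ref position before which they sit),
#   clipped (soft-clip flag)
# plus the set of reference positions skipped by N (introns) and deleted by D.
cigar_walk <- function(cigar, pos0, seq_len) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  q <- 0L; r <- pos0
  qpos <- integer(0); refpos <- integer(0); anchor <- integer(0); clipped <- logical(0)
  n_skipped <- integer(0); deleted <- integer(0)
  for (k in seq_along(kinds)) {
    len <- lens[k]
    switch(kinds[k],
      "M" = , "=" = , "X" = {
        qpos <- c(qpos, q + seq_len(len)); refpos <- c(refpos, r + seq_len(len) - 1L)
        anchor <- c(anchor, rep(NA_integer_, len)); clipped <- c(clipped, rep(FALSE, len))
        q <- q + len; r <- r + len
      },
      "I" = {
        qpos <- c(qpos, q + seq_len(len)); refpos <- c(refpos, rep(NA_integer_, len))
        anchor <- c(anchor, rep(r, len)); clipped <- c(clipped, rep(FALSE, len))
        q <- q + len
      },
      "D" = { deleted <- c(deleted, r + seq_len(len) - 1L); r <- r + len },
      "N" = { n_skipped <- c(n_skipped, r + seq_len(len) - 1L); r <- r + len },
      "S" = {
        qpos <- c(qpos, q + seq_len(len)); refpos <- c(refpos, rep(NA_integer_, len))
        anchor <- c(anchor, rep(NA_integer_, len)); clipped <- c(clipped, rep(TRUE, len))
        q <- q + len
      },
      "H" = NULL, "P" = NULL
    )
  }
  if (q != seq_len) stop("CIGAR/SEQ length mismatch")
  list(qpos = qpos, refpos = refpos, anchor = anchor, clipped = clipped,
       n_skipped = n_skipped, deleted = deleted,
       ref_span = c(pos0, r))
}

# Decompose one read around a variant interval into an AlleleRead, or NULL
# when the read does not fully cover the locus / fails base-quality checks /
# spans the locus through an intron gap ("other" with no base evidence).
decompose_read <- function(read, v, min_baseq = 20L) {
  ref_len <- nchar(v$ref)
  vstart <- v$pos; vend <- v$pos + ref_len
  w <- tryCatch(cigar_walk(read$cigar, read$pos0, nchar(read$seq)),
                error = function(e) NULL)
  if (is.null(w)) return(structure("cigar_mismatch", class = "read_skip"))
  # coverage requirement: the alignment's reference span must contain the
  # locus with at least one aligned base on each side of an insertion point
  if (ref_len > 0L) {
    if (w$ref_span[1L] > vstart || w$ref_span[2L] < vend) return(NULL)
  } else {
    if (w$ref_span[1L] >= vstart || w$ref_span[2L] <= vstart) return(NULL)
  }
  if (ref_len > 0L) {
    locus <- seq.int(vstart, vend - 1L)
    if (any(locus %in% w$n_skipped)) return(structure("n_gap", class = "read_skip"))
  } else {
    if ((vstart - 1L) %in% w$n_skipped || vstart %in% w$n_skipped) {
      return(structure("n_gap", class = "read_skip"))
    }
  }
  keep <- !w$clipped
  qpos <- w$qpos[keep]; refpos <- w$refpos[keep]; anchor <- w$anchor[keep]
  aligned <- !is.na(refpos)
  part <- character(length(qpos))
  if (ref_len > 0L) {
    part[aligned] <- ifelse(refpos[aligned] < vstart, "prefix",
                     ifelse(refpos[aligned] >= vend, "suffix", "allele"))
    part[!aligned] <- ifelse(anchor[!aligned] <= vstart, "prefix",
                      ifelse(anchor[!aligned] > vend, "suffix", "allele"))
  } else {
    part[aligned] <- ifelse(refpos[aligned] < vstart, "prefix", "suffix")
    part[!aligned] <- ifelse(anchor[!aligned] < vstart, "prefix",
                      ifelse(anchor[!aligned] > vstart, "suffix", "allele"))
  }
  bases <- strsplit(read$seq, "", fixed = TRUE)[[1]][qpos]
  phred <- phred_from_qual(read$qual)
  quals <- if (length(phred)) phred[qpos] else rep(NA_integer_, length(qpos))
  allele_q <- quals[part == "allele"]
  if (length(allele_q) == 0L) {
    # deletion/ref-skip support: check the two flanking bases instead
    pq <- quals[part == "prefix"]; sq <- quals[part == "suffix"]
    allele_q <- c(if (length(pq)) pq[length(pq)], if (length(sq)) sq[1L])
  }
  if (length(allele_q) && any(!is.na(allele_q) & allele_q < min_baseq)) {
    return(structure("low_baseq", class = "read_skip"))
  }
  structure(list(
    read_name = read$name,
    prefix = paste(bases[part == "prefix"], collapse = ""),
    allele = paste(bases[part == "allele"], collapse = ""),
    suffix = paste(bases[part == "suffix"], collapse = ""),
    mapq = read$mapq,
    base_qualities = unname(quals)
  ), class = "AlleleRead")
}

#' Collect and partition RNA reads at a variant locus
#'
#' Reads failing the filters (default: MAPQ >= 1, duplicate flag unset,
#' secondary/supplementary unset, every base over the variant locus with
#' base quality >= `min_baseq`) are excluded. Remaining reads that fully
#' cover the locus are decomposed via their CIGAR and partitioned into
#' alt / ref / other by exact allele match. Reads spanning the locus through
#' an intron (N) gap carry no base evidence and are assigned to `other`.
#'
#' @param alignments an `AlignmentSet` (see [load_alignments()])
#' @param v a normalized `Variant`
#' @param min_mapq minimum mapping quality (default 1)
#' @param min_baseq minimum base quality over the locus (default 20)
#' @return an `AlleleReadGroup` with fields `variant`, `alt_reads`,
#'   `ref_reads`, `other_reads`, `n_skipped`
#' @export
collect_reads <- function(alignments, v, min_mapq = 1L, min_baseq = 20L) {
  stopifnot(inherits(alignments, "AlignmentSet"), inherits(v, "Variant"))
  alt <- list(); ref <- list(); other <- list(); skipped <- 0L
  v_end <- v$pos + nchar(v$ref)
  for (read in alignments$reads) {
    if (is.na(read$pos0) || is.na(read$contig) || read$contig != v$contig) next
    # cheap reference-span reject before the full CIGAR walk
    if (!is.null(read$end0) && (read$pos0 > v$pos || read$end0 < v_end)) next
    if (bitwAnd(read$flag, .FLAG_UNMAPPED + .FLAG_SECONDARY + .FLAG_DUP + .FLAG_SUPPL) != 0L) next
    if (is.na(read$mapq) || read$mapq < min_mapq) next
    ar <- decompose_read(read, v, min_baseq = min_baseq)
    if (is.null(ar)) next
    if (inherits(ar, "read_skip")) {
      if (ar == "n_gap") {
        # no base evidence at the site: counted as "other" without sequence
        other[[length(other) + 1L]] <- structure(
          list(read_name = read$name, prefix = "", allele = NA_character_,
               suffix = "", mapq = read$mapq, base_qualities = integer(0)),
          class = "AlleleRead")
      } else skipped <- skipped + 1L
      next
    }
    if (identical(ar$allele, v$alt) && !identical(v$alt, v$ref)) {
      alt[[length(alt) + 1L]] <- ar
    } else if (identical(ar$allele, v$ref)) {
      ref[[length(ref) + 1L]] <- ar
    } else {
      other[[length(other) + 1L]] <- ar
    }
  }
  structure(list(variant = v, alt_reads = alt, ref_reads = ref,
                 other_reads = other, n_skipped = skipped),
            class = "AlleleReadGroup")
}

#' @export
print.AlleleReadGroup <- function(x, ...) {
  cat(sprintf("AlleleReadGroup %s: %d alt / %d ref / %d other (%d skipped)\n",
              variant_id(x$variant), length(x$alt_reads), length(x$ref_reads),
              length(x$other_reads), x$n_skipped))
  invisible(x)
}

#' Mutation-supporting read count (allele-specific expression)
#'
#' By default two mates of one template both supporting the alt allele count
#' once (fragment counting); `count_mates_separately = TRUE` restores plain
#' read counting.
#'
#' @param group an `AlleleReadGroup`
#' @param count_mates_separately count reads rather than templates
#' @return integer count
#' @export
alt_read_count <- function(group, count_mates_separately = FALSE) {
  stopifnot(inherits(group, "AlleleReadGroup"))
  if (count_mates_separately) return(length(group$alt_reads))
  length(unique(vapply(group$alt_reads, `[[`, character(1), "read_name")))
}
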