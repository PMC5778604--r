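# Deterministic generator of toy genomes, transcript annotations, somatic
# variants and spliced RNA read alignments, so every pipeline stage is
# testable without downloads. Ground truth (per-read haplotype labels,
# per-variant expected protein windows) is recorded in a JSON manifest.
#
# The stated world: 125-bp single-end RNA reads, per-variant depth 60 at
# alt fraction 0.5, base error rate 0.001 by default; transcripts carry a
# 60-codon CDS (ATG + 58 non-stop codons + stop), optionally split over two
# exons by a 90-nt intron; phased neighbor variants sit 21 nt (7 codons)
# from the somatic variant, within the 125-bp read span.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

#' Specify a synthetic fixture
#'
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of the specification object including this seed
#' @param contig contig name
#' @param read_length RNA read length in bp (default 125)
#' @param base_error_rate per-base substitution error probability
#' @param transcripts list of transcript layouts: `list(id, gene, strand,
#'   n_exons (1 or 2), cds_codons)`
#' @param variants list of planted variants: `list(tx, cds_offset, type
#'   ("snv", "silent", "ins", "del"), len, alt_fraction, depth, neighbors)`
#'   where `neighbors` is a list of `list(cds_offset, type = "snv")`
#'   germline variants planted on the somatic (alt) haplotype
#' @return a `FixtureSpec`
#' @export
fixture_spec <- function(seed = 1L, contig = "chr1", read_length = 125L,
                         base_error_rate = 0.001,
                         transcripts, variants) {
  stopifnot(read_length >= 30L, base_error_rate >= 0, base_error_rate < 0.5)
  tx_ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(tx_ids)) stop("duplicate transcript ids in fixture spec")
  for (v in variants) {
    if (!v$tx %in% tx_ids) stop("variant references unknown transcript ", v$tx)
    if (is.null(v$depth) || v$depth <= 0L) stop("variant depth must be positive")
  }
  structure(list(seed = as.integer(seed), contig = contig,
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 transcripts = transcripts, variants = variants),
            class = "FixtureSpec")
}

#' Convenience fixture layout
#'
#' Lays out `n_variants` transcripts in tandem along one contig with
#' alternating strands (every third transcript split over two exons), one
#' somatic variant per transcript placed mid-CDS.
#'
#' @param n_variants number of transcripts/variants
#' @param seed fixture seed
#' @param depth per-variant read depth (default 60)
#' @param alt_fraction fraction of reads drawn from the mutant haplotype
#' @param base_error_rate per-base error probability
#' @param with_neighbor plant a germline SNV 21 nt downstream of each
#'   somatic variant, on the mutant haplotype (exercises phasing)
#' @param types recycled vector of variant types
#' @param depths optional per-variant depth vector (overrides `depth`)
#' @return a `FixtureSpec`
#' @export
simple_fixture_spec <- function(n_variants = 1L, seed = 1L, depth = 60L,
                                alt_fraction = 0.5, base_error_rate = 0.001,
                                with_neighbor = FALSE,
                                types = "snv", depths = NULL) {
  types <- rep_len(types, n_variants)
  if (is.null(depths)) depths <- rep_len(depth, n_variants)
  transcripts <- lapply(seq_len(n_variants), function(i) {
    list(id = sprintf("TX%03d", i), gene = sprintf("GENE%03d", i),
         strand = if (i %% 2L == 0L) "-" else "+",
         n_exons = if (i %% 3L == 0L) 2L else 1L,
         cds_codons = 60L)
  })
  variants <- lapply(seq_len(n_variants), function(i) {
    list(tx = sprintf("TX%03d", i), cds_offset = 90L + (i %% 3L),
         type = types[i], len = 1L,
         alt_fraction = alt_fraction, depth = as.integer(depths[i]),
         neighbors = if (with_neighbor) list(list(cds_offset = 111L + (i %% 3L),
                                                  type = "snv")) else list())
  })
  fixture_spec(seed = seed, transcripts = transcripts, variants = variants,
               read_length = 125L, base_error_rate = base_error_rate)
}

# random CDS: ATG + non-stop codons + TAA
.random_cds <- function(n_codons) {
  body <- character(n_codons - 2L)
  for (i in seq_along(body)) {
    repeat {
      cod <- paste(sample(.BASES, 3L, replace = TRUE), collapse = "")
      if (!cod %in% .STOP_CODONS) break
    }
    body[i] <- cod
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

.complement <- function(b) chartr("ACGTN", "TGCAN", b)

# pick an SNV alt base at a CDS offset: missense (aa changes, no stop) or
# silent (aa unchanged); deterministic scan order A,C,G,T
.choose_snv_alt <- function(cds, offset, silent = FALSE) {
  ci <- offset %/% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  p <- offset %% 3L + 1L
  ref_b <- substr(codon, p, p)
  ref_aa <- translate_cds(codon)
  for (b in .BASES) {
    if (b == ref_b) next
    mut <- codon
    substr(mut, p, p) <- b
    if (mut %in% .STOP_CODONS) next
    aa <- translate_cds(mut)
    if (silent && aa == ref_aa) return(b)
    if (!silent && aa != ref_aa) return(b)
  }
  NA_character_
}

# edit a CDS string at a coding offset; returns the edited CDS
.edit_cds <- function(cds, offset, ref_len, alt) {
  paste0(substr(cds, 1L, offset), alt,
         substr(cds, offset + ref_len + 1L, nchar(cds)))
}

# lay out transcripts along the contig; returns per-transcript geometry
.layout_transcripts <- function(spec) {
  cursor <- 200L
  intron <- 90L
  lapply(spec$transcripts, function(tx) {
    n_nt <- tx$cds_codons * 3L
    if (isTRUE(tx$n_exons == 2)) {
      half <- (n_nt %/% 2L) - ((n_nt %/% 2L) %% 3L)  # split at a codon boundary
      exons <- rbind(c(cursor, cursor + half),
                     c(cursor + half + intron, cursor + half + intron + (n_nt - half)))
    } else {
      exons <- rbind(c(cursor, cursor + n_nt))
    }
    span <- exons[nrow(exons), 2L] - cursor
    out <- list(id = tx$id, gene = tx$gene, strand = tx$strand, exons = exons,
                cds = c(exons[1L, 1L], exons[nrow(exons), 2L]),
                cds_codons = tx$cds_codons, start = cursor)
    cursor <<- cursor + span + 130L
    out
  })
}

# run-length encode a CIGAR op sequence into a string
.cigar_string <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Generate a synthetic fixture on disk
#'
#' Writes `genome.fasta`, `annotations.gtf`, `somatic.vcf`, `reads.sam` and
#' `manifest.json` under `out_dir`. Reads are emitted already aligned
#' (coordinate-sorted SAM with correct CIGARs, including N operations
#' across introns and I/D operations for indel haplotypes); alt-haplotype
#' reads carry the somatic variant plus all planted neighbor variants.
#' Byte-identical output for identical specs.
#'
#' @param spec a `FixtureSpec`
#' @param out_dir output directory (created if needed)
#' @return (invisibly) a list with the file paths and the manifest
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  geom <- .layout_transcripts(spec)
  names(geom) <- vapply(geom, `[[`, character(1), "id")
  contig_len <- geom[[length(geom)]]$exons[nrow(geom[[length(geom)]]$exons), 2L] + 200L

  genome <- sample(.BASES, contig_len, replace = TRUE)

  # write each transcript's CDS into the genome (coding order -> genomic)
  tx_objs <- list(); tx_cds <- list()
  for (gm in geom) {
    cds <- .random_cds(gm$cds_codons)
    t <- new_transcript(gm$id, gm$gene, spec$contig, gm$strand, gm$exons, gm$cds)
    P <- cds_genomic_positions(t)
    bases <- strsplit(cds, "", fixed = TRUE)[[1]]
    if (gm$strand == "-") bases <- .complement(bases)
    genome[P + 1L] <- bases
    tx_objs[[gm$id]] <- t
    tx_cds[[gm$id]] <- cds
  }

  # resolve planted variants into coding-level and genomic-level edits
  planted <- lapply(seq_along(spec$variants), function(vi) {
    pv <- spec$variants[[vi]]
    t <- tx_objs[[pv$tx]]
    cds <- tx_cds[[pv$tx]]
    P <- cds_genomic_positions(t)
    resolve <- function(cds_offset, type, len, current_cds) {
      if (type %in% c("snv", "silent")) {
        # scan forward deterministically until an offset admits the wanted
        # change (e.g. a synonymous alternative for "silent")
        for (off in cds_offset + 0:29) {
          alt <- .choose_snv_alt(current_cds, off, silent = type == "silent")
          if (!is.na(alt)) return(list(cds_offset = off, ref_len = 1L, alt = alt))
        }
        stop("no suitable alt base near CDS offset ", cds_offset)
      } else if (type == "ins") {
        # insert len non-stop-forming bases; scan deterministically
        ins <- strrep("G", len)
        cand <- .edit_cds(current_cds, cds_offset, 0L, ins)
        if (nchar(translate_cds(cand)) <= cds_offset %/% 3L) ins <- strrep("A", len)
        list(cds_offset = cds_offset, ref_len = 0L, alt = ins)
      } else if (type == "del") {
        list(cds_offset = cds_offset, ref_len = as.integer(len), alt = "")
      } else stop("unknown variant type: ", type)
    }
    som <- resolve(pv$cds_offset, pv$type, pv$len %||% 1L, cds)
    # indel edits must fall strictly inside one exon in genomic space;
    # shift the coding offset forward (codon-preserving steps of 3) until
    # the insertion point / deleted run is genomically contiguous
    interior <- function(ed) {
      if (ed$ref_len > 0L) {
        gpos <- P[(ed$cds_offset + 1L):(ed$cds_offset + ed$ref_len)]
        all(abs(diff(sort(gpos))) == 1L) &&
          abs(P[ed$cds_offset + 1L] - P[ed$cds_offset]) == 1L
      } else {
        abs(P[ed$cds_offset + 1L] - P[ed$cds_offset]) == 1L
      }
    }
    is_indel <- som$ref_len == 0L || !nzchar(som$alt)
    if (is_indel) while (!interior(som)) som$cds_offset <- som$cds_offset + 3L
    nbrs <- lapply(pv$neighbors %||% list(), function(nb) {
      resolve(nb$cds_offset, nb$type %||% "snv", nb$len %||% 1L, cds)
    })
    # genomic form of a coding-level edit, left-aligned against the genome
    # (mirrors VCF normalization) so read CIGARs and the pipeline's
    # normalized variant agree on indel placement
    exonic <- function(p) any(p >= t$exons[, 1L] & p < t$exons[, 2L])
    to_genomic <- function(ed) {
      if (ed$ref_len > 0L) {
        gpos <- P[(ed$cds_offset + 1L):(ed$cds_offset + ed$ref_len)]
        gstart <- min(gpos)
        if (!all(sort(gpos) == seq.int(gstart, gstart + ed$ref_len - 1L))) {
          stop("planted multi-base edit spans an intron; move it inside one exon")
        }
        alt <- if (t$strand == "+") ed$alt else revcomp(ed$alt)
        if (!nzchar(alt)) {  # deletion: left-align within the exon
          while (gstart > 0L && exonic(gstart - 1L) &&
                 genome[gstart] == genome[gstart + ed$ref_len]) {
            gstart <- gstart - 1L
          }
        }
        ref <- paste(genome[seq.int(gstart, gstart + ed$ref_len - 1L) + 1L],
                     collapse = "")
        list(pos = gstart, ref = ref, alt = alt)
      } else {
        # insertion before coding index cds_offset
        pos <- if (t$strand == "+") P[ed$cds_offset + 1L]
               else P[ed$cds_offset + 1L] + 1L
        alt <- if (t$strand == "+") ed$alt else revcomp(ed$alt)
        while (pos > 0L && exonic(pos - 1L) &&
               genome[pos] == substr(alt, nchar(alt), nchar(alt))) {
          alt <- paste0(genome[pos], substr(alt, 1L, nchar(alt) - 1L))
          pos <- pos - 1L
        }
        list(pos = pos, ref = "", alt = alt)
      }
    }
    som_g <- to_genomic(som)
    nbrs_g <- lapply(nbrs, to_genomic)
    # map the (left-aligned) genomic edits back to coding space so the
    # expected protein windows use the same placement the pipeline will
    to_coding <- function(vg) {
      alt_c <- if (t$strand == "+") vg$alt else revcomp(vg$alt)
      off <- if (nzchar(vg$ref)) {
        if (t$strand == "+") match(vg$pos, P) - 1L
        else match(vg$pos + nchar(vg$ref) - 1L, P) - 1L
      } else {
        if (t$strand == "+") match(vg$pos, P) - 1L
        else match(vg$pos - 1L, P) - 1L
      }
      list(cds_offset = off, ref_len = nchar(vg$ref), alt = alt_c)
    }
    list(spec = pv, transcript = t, cds = cds,
         som = to_coding(som_g), som_g = som_g,
         nbrs = lapply(nbrs_g, to_coding), nbrs_g = nbrs_g)
  })

  # --- reads ---------------------------------------------------------------
  sam_records <- list()
  read_truth <- list()
  for (pl in planted) {
    t <- pl$transcript
    exon_pos <- unlist(lapply(seq_len(nrow(t$exons)), function(i) {
      seq.int(t$exons[i, 1L], t$exons[i, 2L] - 1L)
    }), use.names = FALSE)
    ref_elems <- list(gpos = exon_pos, base = genome[exon_pos + 1L])

    apply_edits <- function(elems, edits) {
      deleted <- integer(0)
      for (ed in edits) {
        if (nzchar(ed$ref) && nzchar(ed$alt) && nchar(ed$ref) == nchar(ed$alt)) {
          idx <- match(ed$pos, elems$gpos)
          elems$base[idx] <- ed$alt
        } else if (nzchar(ed$ref)) {  # deletion
          gone <- seq.int(ed$pos, ed$pos + nchar(ed$ref) - 1L)
          keep <- !(elems$gpos %in% gone)
          deleted <- c(deleted, gone)
          elems$gpos <- elems$gpos[keep]; elems$base <- elems$base[keep]
        } else {                       # insertion before ed$pos
          at <- match(ed$pos, elems$gpos)
          ins_b <- strsplit(ed$alt, "", fixed = TRUE)[[1]]
          elems$gpos <- append(elems$gpos, rep(NA_integer_, length(ins_b)), after = at - 1L)
          elems$base <- append(elems$base, ins_b, after = at - 1L)
        }
      }
      list(elems = elems, deleted = deleted)
    }

    alt_h <- apply_edits(ref_elems, c(list(pl$som_g), pl$nbrs_g))

    # element index window every read must cover, per haplotype
    cover_window <- function(elems, vg, is_alt) {
      if (nzchar(vg$ref)) {
        if (is_alt && !nzchar(vg$alt)) {  # deletion on alt haplotype: junction
          lo <- max(which(elems$gpos < vg$pos & !is.na(elems$gpos)))
          c(lo, lo + 1L)
        } else {
          idx <- which(!is.na(elems$gpos) & elems$gpos >= vg$pos &
                       elems$gpos < vg$pos + nchar(vg$ref))
          c(min(idx) - 1L, max(idx) + 1L)
        }
      } else {
        if (is_alt) {  # insertion present: cover inserted run plus flanks
          at <- match(vg$pos, elems$gpos)
          ins_idx <- which(is.na(elems$gpos))
          ins_idx <- ins_idx[ins_idx < at]
          c(min(ins_idx) - 1L, at)
        } else {       # junction on reference haplotype
          at <- match(vg$pos, elems$gpos)
          c(at - 1L, at)
        }
      }
    }

    n_alt <- round(pl$spec$depth * pl$spec$alt_fraction)
    n_ref <- pl$spec$depth - n_alt
    rl <- spec$read_length

    emit_reads <- function(elems, deleted, n, label, win) {
      N <- length(elems$gpos)
      s_lo <- max(1L, win[2L] - rl + 1L)
      s_hi <- min(win[1L], N - rl + 1L)
      if (s_hi < s_lo) stop("read length too short to cover the planted locus")
      starts <- sample(seq.int(s_lo, s_hi), n, replace = TRUE)
      for (j in seq_len(n)) {
        s <- starts[j]
        sl <- seq.int(s, s + rl - 1L)
        bases <- elems$base[sl]
        gp <- elems$gpos[sl]
        n_err <- 0L
        if (spec$base_error_rate > 0) {
          err <- which(stats::runif(rl) < spec$base_error_rate)
          for (e in err) {
            bases[e] <- sample(setdiff(.BASES, bases[e]), 1L)
          }
          n_err <- length(err)
        }
        # CIGAR from the gpos pattern of the slice
        ops <- character(0)
        prev <- NA_integer_
        for (k in seq_len(rl)) {
          if (is.na(gp[k])) { ops <- c(ops, "I"); next }
          if (!is.na(prev) && gp[k] > prev + 1L) {
            gap <- seq.int(prev + 1L, gp[k] - 1L)
            ops <- c(ops, ifelse(gap %in% deleted, "D", "N"))
          }
          ops <- c(ops, "M")
          prev <- gp[k]
        }
        pos1 <- min(gp, na.rm = TRUE) + 1L
        name <- sprintf("%s_%s_%03d", pl$transcript$id, label, j)
        sam_records[[length(sam_records) + 1L]] <<- list(
          qname = name, flag = 0L, rname = spec$contig, pos = pos1,
          mapq = 60L, cigar = .cigar_string(ops),
          seq = paste(bases, collapse = ""), qual = strrep("?", rl)
        )
        read_truth[[length(read_truth) + 1L]] <<- list(
          name = name, variant_tx = pl$transcript$id, haplotype = label,
          n_errors = n_err
        )
      }
    }

    emit_reads(alt_h$elems, alt_h$deleted, n_alt, "alt",
               cover_window(alt_h$elems, pl$som_g, is_alt = TRUE))
    emit_reads(ref_elems, integer(0), n_ref, "ref",
               cover_window(ref_elems, pl$som_g, is_alt = FALSE))
  }

  # --- expected protein windows (direct CDS edit; independent of reads) ----
  expected <- lapply(planted, function(pl) {
    cds <- pl$cds
    apply_coding <- function(cds, eds) {
      # apply right-to-left so earlier offsets stay valid
      ord <- order(vapply(eds, `[[`, integer(1), "cds_offset"), decreasing = TRUE)
      for (ed in eds[ord]) cds <- .edit_cds(cds, ed$cds_offset, ed$ref_len, ed$alt)
      cds
    }
    window <- function(edited, som) {
      prot <- translate_cds(edited)
      vs <- som$cds_offset; ve <- som$cds_offset + nchar(som$alt)
      fs <- (nchar(som$alt) - som$ref_len) %% 3L != 0L
      aa_start <- vs %/% 3L
      aa_end <- if (fs) nchar(prot) else max(aa_start + 1L, as.integer(ceiling(ve / 3)))
      aa_end <- min(aa_end, nchar(prot))
      ks <- max(0L, aa_start - 12L); ke <- min(nchar(prot), aa_end + 12L)
      list(window = substr(prot, ks + 1L, ke),
           mutant_interval = c(aa_start - ks, aa_end - ks))
    }
    phased <- window(apply_coding(cds, c(list(pl$som), pl$nbrs)), pl$som)
    naive <- window(apply_coding(cds, list(pl$som)), pl$som)
    vg <- pl$som_g
    list(
      transcript = pl$transcript$id,
      variant = list(contig = spec$contig, pos = vg$pos, ref = vg$ref, alt = vg$alt),
      neighbors = lapply(pl$nbrs_g, function(x) {
        list(contig = spec$contig, pos = x$pos, ref = x$ref, alt = x$alt)
      }),
      type = pl$spec$type,
      depth = pl$spec$depth,
      alt_fraction = pl$spec$alt_fraction,
      n_alt_reads = round(pl$spec$depth * pl$spec$alt_fraction),
      expected_protein_window = phased$window,
      expected_mutant_interval = phased$mutant_interval,
      naive_protein_window = naive$window
    )
  })

  paths <- list(
    fasta = file.path(out_dir, "genome.fasta"),
    gtf = file.path(out_dir, "annotations.gtf"),
    vcf = file.path(out_dir, "somatic.vcf"),
    sam = file.path(out_dir, "reads.sam"),
    manifest = file.path(out_dir, "manifest.json")
  )

  # FASTA
  seq_str <- paste(genome, collapse = "")
  wrapped <- substring(seq_str, seq(1L, contig_len, 70L),
                       pmin(seq(1L, contig_len, 70L) + 69L, contig_len))
  writeLines(c(paste0(">", spec$contig), wrapped), paths$fasta)

  # GTF (1-based closed)
  gtf <- character(0)
  for (gm in geom) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gm$gene, gm$id)
    cum <- 0L
    segs <- if (gm$strand == "-") rev(seq_len(nrow(gm$exons))) else seq_len(nrow(gm$exons))
    frames <- integer(nrow(gm$exons))
    for (i in segs) {
      frames[i] <- (3L - (cum %% 3L)) %% 3L
      cum <- cum + (gm$exons[i, 2L] - gm$exons[i, 1L])
    }
    for (i in seq_len(nrow(gm$exons))) {
      gtf <- c(gtf,
        paste(spec$contig, "neopept", "exon", gm$exons[i, 1L] + 1L, gm$exons[i, 2L],
              ".", gm$strand, ".", attrs, sep = "\t"),
        paste(spec$contig, "neopept", "CDS", gm$exons[i, 1L] + 1L, gm$exons[i, 2L],
              ".", gm$strand, frames[i], attrs, sep = "\t"))
    }
  }
  writeLines(gtf, paths$gtf)

  # VCF (anchored indel representation, 1-based)
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", spec$contig, contig_len),
           '##FILTER=<ID=PASS,Description="All filters passed">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  vrows <- lapply(planted, function(pl) {
    vg <- pl$som_g
    if (nzchar(vg$ref) && nzchar(vg$alt)) {
      list(pos1 = vg$pos + 1L, ref = vg$ref, alt = vg$alt)
    } else if (nzchar(vg$ref)) {  # deletion, anchor on the previous base
      anchor <- genome[vg$pos]     # 0-based pos-1 -> R index pos
      list(pos1 = vg$pos, ref = paste0(anchor, vg$ref), alt = anchor)
    } else {                       # insertion, anchor on the previous base
      anchor <- genome[vg$pos]
      list(pos1 = vg$pos, ref = anchor, alt = paste0(anchor, vg$alt))
    }
  })
  ord <- order(vapply(vrows, `[[`, integer(1), "pos1"))
  for (i in ord) {
    r <- vrows[[i]]
    vcf <- c(vcf, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                          spec$contig, r$pos1, r$ref, r$alt))
  }
  writeLines(vcf, paths$vcf)

  # SAM (coordinate-sorted)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", spec$contig, contig_len))
  pos_v <- vapply(sam_records, `[[`, integer(1), "pos")
  nm_v <- vapply(sam_records, `[[`, character(1), "qname")
  lines <- vapply(sam_records[order(pos_v, nm_v, method = "radix")], function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0L, 0L,
          r$seq, r$qual, sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), paths$sam)

  manifest <- list(
    seed = spec$seed, contig = spec$contig, contig_length = contig_len,
    read_length = spec$read_length, base_error_rate = spec$base_error_rate,
    variants = expected, reads = read_truth
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(fasta = paths$fasta, gtf = paths$gtf, vcf = paths$vcf,
                 sam = paths$sam, manifest_path = paths$manifest,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
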