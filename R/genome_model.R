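# Reference genome + transcript annotation model: spliced CDS extraction and
# translation. Internal coordinates are 0-based half-open everywhere;
# conversion to/from 1-based closed happens only in the GTF/VCF readers and
# the report writers.

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased on load. Contig names are taken as the first
#' whitespace-delimited word of each FASTA header.
#'
#' @param path path to a FASTA file
#' @return a `ReferenceGenome` object (named contig sequences)
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop("duplicate contig names in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  contigs <- toupper(as.character(seqs))
  if (any(!nzchar(contigs))) stop("empty sequence in FASTA: ", path)
  names(contigs) <- nms
  structure(list(contigs = contigs), class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$contigs), "contig(s)\n")
  for (nm in names(x$contigs)) cat("  ", nm, ": ", nchar(x$contigs[[nm]]), " bp\n", sep = "")
  invisible(x)
}

#' Fetch a genomic interval
#'
#' @param g a `ReferenceGenome`
#' @param contig contig name
#' @param start,end 0-based half-open interval
#' @return the nucleotide string of length `end - start`
#' @export
genome_seq <- function(g, contig, start, end) {
  stopifnot(inherits(g, "ReferenceGenome"))
  if (!contig %in% names(g$contigs)) stop("unknown contig: ", contig)
  len <- nchar(g$contigs[[contig]])
  if (start < 0 || end > len || start > end) {
    stop(sprintf("interval [%d, %d) outside contig %s (length %d)",
                 start, end, contig, len))
  }
  substr(g$contigs[[contig]], start + 1L, end)
}

#' Construct a transcript model
#'
#' @param id transcript identifier
#' @param gene gene identifier
#' @param contig contig name
#' @param strand "+" or "-"
#' @param exons two-column matrix of 0-based half-open genomic intervals,
#'   sorted by start, non-overlapping
#' @param cds genomic interval `c(start, end)` of the coding region, or
#'   `NULL` for a non-coding transcript
#' @return a `Transcript` object
#' @export
new_transcript <- function(id, gene, contig, strand, exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript ", id)
  }
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon in transcript ", id)
  coding <- !is.null(cds)
  if (coding) {
    cds <- as.integer(cds)
    covered <- sum(pmax(0L, pmin(exons[, 2L], cds[2L]) - pmax(exons[, 1L], cds[1L])))
    want <- sum(vapply(seq_len(nrow(exons)), function(i) {
      max(0L, min(exons[i, 2L], cds[2L]) - max(exons[i, 1L], cds[1L]))
    }, integer(1)))
    if (cds[1L] < exons[1L, 1L] || cds[2L] > exons[nrow(exons), 2L])
      stop("CDS outside exon span in transcript ", id)
    if (want < 3L) stop("spliced CDS shorter than one codon in transcript ", id)
  }
  structure(list(id = id, gene = gene, contig = contig, strand = strand,
                 exons = exons, cds = cds, coding = coding),
            class = "Transcript")
}

#' @export
print.Transcript <- function(x, ...) {
  cat(sprintf("Transcript %s (%s) %s:%s strand %s, %d exon(s)%s\n",
              x$id, x$gene, x$contig,
              paste0(x$exons[1, 1], "-", x$exons[nrow(x$exons), 2]),
              x$strand, nrow(x$exons),
              if (x$coding) sprintf(", CDS [%d, %d)", x$cds[1], x$cds[2]) else ", non-coding"))
  invisible(x)
}

#' Load transcript annotations from GTF
#'
#' Only `exon` and `CDS` feature rows are consulted. GTF 1-based closed
#' coordinates are converted to internal 0-based half-open on read.
#' Transcripts without any CDS row are retained but flagged non-coding.
#'
#' @param path path to a GTF file
#' @return list of `Transcript` objects, named by transcript id
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no exon/CDS records in GTF: ", path)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type   = as.character(gr$type),
    tx     = as.character(gr$transcript_id),
    gene   = if (!is.null(gr$gene_id)) as.character(gr$gene_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- lapply(split(df, df$tx), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    cd <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cd  # tolerate CDS-only annotations
    cds <- if (nrow(cd)) c(min(cd$start0), max(cd$end0)) else NULL
    new_transcript(id = d$tx[1L], gene = d$gene[1L], contig = d$contig[1L],
                   strand = d$strand[1L],
                   exons = cbind(ex$start0, ex$end0), cds = cds)
  })
  out[c_sort(names(out))]
}

# exon segments overlapping the CDS, as a matrix in genomic order
cds_segments <- function(t) {
  stopifnot(inherits(t, "Transcript"), t$coding)
  segs <- cbind(pmax(t$exons[, 1L], t$cds[1L]), pmin(t$exons[, 2L], t$cds[2L]))
  segs[segs[, 2L] > segs[, 1L], , drop = FALSE]
}

# 0-based genomic positions of the spliced CDS, in coding (5'->3') order
cds_genomic_positions <- function(t) {
  segs <- cds_segments(t)
  pos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    seq.int(segs[i, 1L], segs[i, 2L] - 1L)
  }), use.names = FALSE)
  if (t$strand == "-") rev(pos) else pos
}

# coding-order index (0-based) of a genomic position within the spliced CDS,
# or NA when the position is not coding
cds_index_of <- function(t, gpos) {
  idx <- match(gpos, cds_genomic_positions(t))
  if (is.na(idx)) NA_integer_ else idx - 1L
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the CDS-overlapping exon segments and reverse-complements
#' for minus-strand transcripts, yielding the 5'->3' coding sequence. A
#' length that is not a multiple of 3 is tolerated (truncated annotation)
#' and reported via a warning.
#'
#' @param t a coding `Transcript`
#' @param g a `ReferenceGenome`
#' @return nucleotide string
#' @export
spliced_cds <- function(t, g) {
  segs <- cds_segments(t)
  s <- paste(vapply(seq_len(nrow(segs)), function(i) {
    genome_seq(g, t$contig, segs[i, 1L], segs[i, 2L])
  }, character(1)), collapse = "")
  if (t$strand == "-") s <- revcomp(s)
  if (nchar(s) %% 3L != 0L) {
    warning("spliced CDS of ", t$id, " is not a multiple of 3 (truncated annotation?)")
  }
  s
}

# genomic span [start, end) of a transcript
transcript_span <- function(t) {
  c(t$exons[1L, 1L], t$exons[nrow(t$exons), 2L])
}
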