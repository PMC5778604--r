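# In-code fixture builders shared across test files. Generated fixtures are
# cached per session key so expensive ones are built once.

ref_from_string <- function(seq, name = "chr1") {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", name), seq), path)
  load_reference(path)
}

write_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

# minimal headered SAM writer; records: list(qname, flag, pos1, mapq, cigar,
# seq, qual); qual defaults to Q30 throughout
write_sam <- function(records, contig = "chr1", contig_len = 1000L) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  lines <- vapply(records, function(r) {
    paste(r$qname, r$flag %||% 0L, contig, r$pos1, r$mapq %||% 60L, r$cigar,
          "*", 0L, 0L, r$seq, r$qual %||% strrep("?", nchar(r$seq)), sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_vcf <- function(rows, contig = "chr1", contig_len = 1000L) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, spec) {
  if (is.null(.fx_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("neopept_fx_", key))
    .fx_cache[[key]] <- generate_fixture(spec, dir)
  }
  .fx_cache[[key]]
}

# error-free phasing fixture: 3 variants, each with a germline neighbor
# 21 nt downstream, on +/- strands, one 2-exon transcript
phase_fixture <- function() {
  cached_fixture("phase", simple_fixture_spec(
    n_variants = 3L, seed = 7L, base_error_rate = 0, with_neighbor = TRUE))
}

# error-free mixed-type fixture (snv/ins/del on both strands)
mixed_fixture <- function() {
  cached_fixture("mixed", simple_fixture_spec(
    n_variants = 6L, seed = 11L, base_error_rate = 0,
    types = c("snv", "ins", "del", "snv", "del", "ins")))
}

toy_hla <- c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02",
             "HLA-B*08:01", "HLA-C*07:01", "HLA-C*07:02")

pipeline_cfg <- function(fx, out_dir = NULL, hla = toy_hla, ...) {
  pipeline_config(vcf = fx$vcf, bam = fx$sam, ref = fx$fasta, gtf = fx$gtf,
                  hla = hla, out_dir = out_dir, ...)
}

run_quiet <- function(config) {
  suppressMessages(suppressWarnings(run_pipeline(config)))
}
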