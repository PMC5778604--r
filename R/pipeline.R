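# End-to-end in-process orchestration: variant effects -> read evidence ->
# coding assembly -> MHC binding -> ranking -> manufacturability, with CSV
# and JSON report emission and a structured drop-log accounting for every
# input variant.

#' Pipeline configuration
#'
#' All tunables of the pipeline in one validated object; the effective
#' configuration is serialized verbatim into every report for
#' reproducibility. Unknown arguments are rejected.
#'
#' @param vcf,bam,ref,gtf input file paths (somatic VCF, RNA SAM/BAM,
#'   reference FASTA, transcript GTF)
#' @param hla character vector of patient HLA Class I alleles (any accepted
#'   dialect), or a single comma-separated string, or a path to a
#'   plain-text allele list (one per line)
#' @param predictor "toy" or "table"
#' @param affinity_table TSV path (required when `predictor = "table"`)
#' @param out_dir report output directory, or `NULL` for no files
#' @param min_alt_rna_reads minimum mutation-supporting reads (default 3)
#' @param peptide_length vaccine peptide window length (default 25)
#' @param epitope_lengths epitope lengths scored (default 8:11)
#' @param max_candidates report size cap (default 15)
#' @param binding_midpoint_nm,binding_slope affinity normalization
#'   parameters (defaults 500 nM, 1)
#' @param expression_transform "sqrt", "identity" or "log1p"
#' @param manufacturability "flags" (annotate + tie-break), "off", or
#'   "strict" (exclude flagged peptides)
#' @param min_mapq,min_baseq read filters (defaults 1, 20)
#' @param keep_nonpass keep non-PASS VCF rows
#' @param count_mates_separately count reads, not templates
#' @param resume skip recomputation when outputs exist for identical inputs
#' @return a `PipelineConfig`
#' @export
pipeline_config <- function(vcf, bam, ref, gtf, hla,
                            predictor = c("toy", "table"),
                            affinity_table = NULL,
                            out_dir = NULL,
                            min_alt_rna_reads = 3L,
                            peptide_length = 25L,
                            epitope_lengths = 8:11,
                            max_candidates = 15L,
                            binding_midpoint_nm = 500,
                            binding_slope = 1,
                            expression_transform = c("sqrt", "identity", "log1p"),
                            manufacturability = c("flags", "off", "strict"),
                            min_mapq = 1L, min_baseq = 20L,
                            keep_nonpass = FALSE,
                            count_mates_separately = FALSE,
                            resume = FALSE) {
  predictor <- match.arg(predictor)
  expression_transform <- match.arg(expression_transform)
  manufacturability <- match.arg(manufacturability)
  if (predictor == "table" && is.null(affinity_table)) {
    stop("predictor = 'table' requires an affinity_table path")
  }
  if (length(hla) == 1L && file.exists(hla) && !grepl("[*,]", hla)) {
    hla <- readLines(hla, warn = FALSE)
  }
  hla <- trimws(unlist(strsplit(hla, ",", fixed = TRUE)))
  hla <- hla[nzchar(hla)]
  if (length(hla) == 0L) stop("no HLA alleles given")
  hla <- vapply(hla, normalize_allele_name, character(1), USE.NAMES = FALSE)
  structure(list(
    vcf = vcf, bam = bam, ref = ref, gtf = gtf, hla = hla,
    predictor = predictor, affinity_table = affinity_table, out_dir = out_dir,
    min_alt_rna_reads = as.integer(min_alt_rna_reads),
    peptide_length = as.integer(peptide_length),
    epitope_lengths = as.integer(epitope_lengths),
    max_candidates = as.integer(max_candidates),
    binding_midpoint_nm = binding_midpoint_nm,
    binding_slope = binding_slope,
    expression_transform = expression_transform,
    manufacturability = manufacturability,
    min_mapq = as.integer(min_mapq), min_baseq = as.integer(min_baseq),
    keep_nonpass = keep_nonpass,
    count_mates_separately = count_mates_separately,
    resume = resume
  ), class = "PipelineConfig")
}

# serializable view of the config (input paths + tunables); out_dir and
# resume are execution details, not part of the scientific configuration
.config_list <- function(config) {
  cfg <- unclass(config)
  cfg$resume <- NULL
  cfg$out_dir <- NULL
  cfg
}

.input_digest <- function(config) {
  files <- c(config$vcf, config$bam, config$ref, config$gtf, config$affinity_table)
  files <- files[!vapply(files, is.null, logical(1))]
  paste(c(unname(tools::md5sum(unlist(files))),
          jsonlite::toJSON(.config_list(config), auto_unbox = TRUE)),
        collapse = "|")
}

#' Run the vaccine peptide selection pipeline
#'
#' Executes effect annotation, RNA read evidence collection, mutant coding
#' sequence assembly, translation, window/epitope enumeration, binding and
#' expression scoring, manufacturability screening and ranking. Every input
#' variant ends up either in the report or in the drop-log with a reason.
#'
#' When `config$out_dir` is set, writes `candidates.csv`, `candidates.json`,
#' `drops.jsonl` and `effective_config.json`.
#'
#' @param config a `PipelineConfig`
#' @return a `RankedReport` (with `drops` and `config` attached)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$out_dir) && isTRUE(config$resume)) {
    marker <- file.path(config$out_dir, ".neopept_inputs")
    json <- file.path(config$out_dir, "candidates.json")
    if (file.exists(marker) && file.exists(json) &&
        identical(readLines(marker, warn = FALSE), .input_digest(config))) {
      message("resume: inputs unchanged, reusing existing report in ", config$out_dir)
      prev <- jsonlite::read_json(json)
      return(invisible(structure(list(candidates = prev$candidates,
                                      n_input_variants = length(prev$candidates),
                                      resumed = TRUE),
                                 class = "RankedReport")))
    }
  }

  g <- load_reference(config$ref)
  transcripts <- load_annotations(config$gtf)
  variants <- read_vcf(config$vcf, keep_nonpass = config$keep_nonpass)
  alignments <- load_alignments(config$bam)

  # contig consistency before any compute
  tx_contigs <- unique(vapply(transcripts, `[[`, character(1), "contig"))
  v_contigs <- unique(vapply(variants, `[[`, character(1), "contig"))
  missing <- setdiff(union(tx_contigs, v_contigs), names(g$contigs))
  if (length(missing)) {
    stop("contig(s) absent from the reference FASTA: ",
         paste(missing, collapse = ", "))
  }

  pred <- switch(config$predictor,
                 toy = toy_predictor(),
                 table = load_affinity_table(config$affinity_table))

  drops <- list()
  scored <- list()
  for (v in variants) {
    v <- normalize_variant(v, g)
    vid <- variant_id(v)
    effects <- annotate_effects(v, transcripts, g)
    keep_eff <- filter_nonsilent(effects)
    if (length(keep_eff) == 0L) {
      cats <- unique(vapply(effects, `[[`, character(1), "category"))
      drops[[length(drops) + 1L]] <- drop_record(
        vid, "variant_effects",
        if (length(cats)) paste0("no protein-altering effect (",
                                 paste(cats, collapse = ","), ")")
        else "no overlapping transcript")
      next
    }
    group <- collect_reads(alignments, v, min_mapq = config$min_mapq,
                           min_baseq = config$min_baseq)
    n_alt <- alt_read_count(group, config$count_mates_separately)
    if (n_alt < config$min_alt_rna_reads) {
      drops[[length(drops) + 1L]] <- drop_record(
        vid, "read_evidence",
        sprintf("%d mutation-supporting read(s) < min_alt_rna_reads = %d",
                n_alt, config$min_alt_rna_reads))
      next
    }
    groups <- group_reads_by_sequence(group$alt_reads)
    cand <- withCallingHandlers(
      assemble_most_abundant(groups, v, min_reads = config$min_alt_rna_reads),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(cand)) {
      drops[[length(drops) + 1L]] <- drop_record(
        vid, "coding_assembly", "no read group meets min_alt_rna_reads")
      next
    }
    anchored <- withCallingHandlers(
      anchor_to_transcript(cand, transcripts, g),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(anchored)) {
      drops[[length(drops) + 1L]] <- drop_record(
        vid, "coding_assembly", "no transcript yields a reading frame")
      next
    }
    prot <- withCallingHandlers(
      translate_candidate(anchored,
                          peptide_radius = (config$peptide_length - 1L) %/% 2L),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(prot)) {
      drops[[length(drops) + 1L]] <- drop_record(
        vid, "coding_assembly", "stop codon before the mutant interval")
      next
    }
    expr <- expression_score(n_alt, config$expression_transform)
    windows <- candidate_windows(prot, config$peptide_length)
    for (w in windows) {
      eps <- mutant_epitopes(w$peptide, w$mutant_interval, config$epitope_lengths)
      bind <- binding_score(eps, config$hla, pred,
                            midpoint_nM = config$binding_midpoint_nm,
                            slope = config$binding_slope)
      flags <- if (config$manufacturability == "off") NULL
               else manufacturability_flags(w$peptide)
      if (config$manufacturability == "strict" && length(flags$set)) next
      scored[[length(scored) + 1L]] <- structure(list(
        variant = v,
        peptide = w$peptide,
        mutant_interval = w$mutant_interval,
        expression_score = expr,
        binding_score = bind,
        total_score = total_score(expr, bind),
        manufacturability = flags,
        num_supporting_reads = n_alt,
        source_transcripts = prot$source_transcripts,
        window_flags = w$flags
      ), class = "VaccinePeptideCandidate")
    }
    if (config$manufacturability == "strict" &&
        !any(vapply(scored, function(x) identical(x$variant, v), logical(1)))) {
      drops[[length(drops) + 1L]] <- drop_record(
        vid, "manufacturability", "all windows excluded by strict screening")
    }
  }

  report <- withCallingHandlers(
    rank_candidates(scored, config$max_candidates),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  report$drops <- drops
  report$config <- .config_list(config)

  if (!is.null(config$out_dir)) write_reports(report, config)
  invisible(report)
}

# --- report writers ---------------------------------------------------------

#' Ranked report as a data frame (one row per candidate)
#' @param report a `RankedReport`
#' @export
report_as_data_frame <- function(report) {
  if (length(report$candidates) == 0L) {
    return(data.frame(rank = integer(0), contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0), peptide = character(0),
                      mutant_start = integer(0), mutant_end = integer(0),
                      expression_score = numeric(0), binding_score = numeric(0),
                      total_score = numeric(0), supporting_reads = integer(0),
                      transcript = character(0), manufacturability = character(0)))
  }
  do.call(rbind, lapply(seq_along(report$candidates), function(i) {
    cc <- report$candidates[[i]]
    data.frame(
      rank = i, contig = cc$variant$contig, pos = cc$variant$pos,
      ref = cc$variant$ref, alt = cc$variant$alt, peptide = cc$peptide,
      mutant_start = cc$mutant_interval[1L], mutant_end = cc$mutant_interval[2L],
      expression_score = cc$expression_score, binding_score = cc$binding_score,
      total_score = cc$total_score, supporting_reads = cc$num_supporting_reads,
      transcript = cc$source_transcripts,
      manufacturability = paste(if (is.null(cc$manufacturability)) character(0)
                                else cc$manufacturability$set, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
}

write_reports <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- report_as_data_frame(report)
  utils::write.csv(df, file.path(config$out_dir, "candidates.csv"),
                   row.names = FALSE)
  json <- list(
    config = .config_list(config),
    candidates = lapply(seq_along(report$candidates), function(i) {
      cc <- report$candidates[[i]]
      list(rank = i,
           variant = list(contig = cc$variant$contig, pos = cc$variant$pos,
                          ref = cc$variant$ref, alt = cc$variant$alt),
           peptide = cc$peptide,
           mutant_interval = cc$mutant_interval,
           expression_score = cc$expression_score,
           binding_score = cc$binding_score,
           total_score = cc$total_score,
           supporting_reads = cc$num_supporting_reads,
           transcript = cc$source_transcripts,
           manufacturability = if (is.null(cc$manufacturability)) list()
                               else as.list(cc$manufacturability$set),
           window_flags = as.list(cc$window_flags))
    })
  )
  jsonlite::write_json(json, file.path(config$out_dir, "candidates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  drop_lines <- vapply(report$drops, function(d) {
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE))
  }, character(1))
  writeLines(drop_lines, file.path(config$out_dir, "drops.jsonl"))
  jsonlite::write_json(.config_list(config),
                       file.path(config$out_dir, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(.input_digest(config), file.path(config$out_dir, ".neopept_inputs"))
  invisible(NULL)
}
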