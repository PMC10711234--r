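param_digest <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(params, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

file_digests <- function(paths) {
  md5 <- tools::md5sum(paths)
  as.list(stats::setNames(unname(md5), basename(paths)))
}

load_manifest <- function(path) {
  if (!file.exists(path)) return(list(stages = list()))
  tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
           error = function(e) {
             warning("run manifest unreadable (", conditionMessage(e),
                     "); all stages will re-run")
             list(stages = list())
           })
}

save_manifest <- function(manifest, path) {
  write_atomic(path, function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  })
}

stage_is_fresh <- function(manifest, stage, inputs, params, outputs) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  if (!identical(as.character(rec$params), as.character(param_digest(params)))) {
    return(FALSE)
  }
  cur <- file_digests(inputs)
  old <- rec$inputs
  identical(lapply(cur, as.character)[sort(names(cur))],
            lapply(old, as.character)[sort(names(old))])
}

stage_record <- function(inputs, params, outputs) {
  list(inputs = file_digests(inputs), params = param_digest(params),
       outputs = as.list(basename(outputs)))
}

# write via a temp file in the same directory + atomic rename, so a failed
# stage never leaves a partial file at a final output path
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

count_fastq_reads <- function(path) {
  n <- length(readLines(path, warn = FALSE))
  if (n %% 4L != 0L) warning("FASTQ ", path, " line count not divisible by 4")
  n %/% 4L
}

discover_samples <- function(config) {
  if (!is.null(config$samples)) return(config$samples)
  if (is.null(config$alignment_dir)) {
    stop("config error: no 'samples' map and no 'alignment_dir' to scan")
  }
  files <- list.files(config$alignment_dir, pattern = "\\.(sam|bam)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L) {
    stop("no SAM/BAM files found in ", config$alignment_dir)
  }
  stats::setNames(files, sub("\\.(sam|bam)$", "", basename(files),
                             ignore.case = TRUE))
}

pipeline_paths <- function(config, sample = NULL) {
  genome_name <- sub("\\.(fa|fasta|fna)$", "", basename(config$genome_fasta),
                     ignore.case = TRUE)
  inter <- file.path(config$output_dir, "intermediate", genome_name)
  p <- list(
    genome_name = genome_name,
    intermediate = inter,
    manifest = file.path(config$output_dir, "manifest.json"),
    masked_genome = file.path(inter, "artificial_genome.fa"),
    rrna_fasta = file.path(inter, "rRNA_transcripts.fa"),
    mask_log = file.path(inter, "mask_log.bed"),
    genes_tsv = file.path(inter, "rRNA_genes.tsv"))
  if (!is.null(sample)) {
    sdir <- file.path(inter, sample)
    rdir <- file.path(config$output_dir, "result", genome_name, sample)
    p$sample_inter <- sdir
    p$result <- rdir
    p$filtered <- file.path(sdir, "filtered_alignments.tsv")
    p$excl <- file.path(sdir, "exclusivity.tsv")
    p$records <- file.path(sdir, "rsRNA_records.tsv")
    p$annotation <- file.path(rdir, paste0(sample, "_rsRNA_annotation.csv"))
    p$class_counts <- file.path(rdir, paste0(sample, "_class_counts.tsv"))
    p$abundance <- file.path(rdir, paste0(sample, "_abundance_summary.tsv"))
    p$html <- file.path(rdir, paste0(sample, "_report.html"))
  }
  p
}

reference_stage_def <- function(config) {
  p <- pipeline_paths(config)
  list(name = "reference",
       inputs = c(config$genome_fasta, config$species_NCBI_feature_table),
       params = list(flank = config$flank, header_map = config$header_map),
       outputs = c(p$masked_genome, p$rrna_fasta, p$mask_log, p$genes_tsv))
}

run_reference_stage <- function(config) {
  p <- pipeline_paths(config)
  dir.create(p$intermediate, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(config$genome_fasta)
  genes <- parse_feature_table(config$species_NCBI_feature_table,
                               config$header_map)
  hv <- validate_genome_headers(names(genome))
  if (!hv$valid) {
    warning("genome headers violating the chr[Num]/chrMt/chrPt convention: ",
            paste(hv$violations, collapse = ", "))
  }
  masked <- mask_genome(genome, genes, config$flank)
  tx <- extract_rrna_sequences(genome, genes)
  write_atomic(p$masked_genome, function(f) write_fasta(masked$sequences, f))
  write_atomic(p$rrna_fasta, function(f) write_fasta(tx, f))
  write_atomic(p$mask_log, function(f) write_mask_log(masked, f))
  write_atomic(p$genes_tsv, function(f) {
    utils::write.table(genes, f, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  genes
}

read_genes_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chromosome = "character"))
}

run_filter_stage <- function(config, sample, sam_path, genes) {
  p <- pipeline_paths(config, sample)
  dir.create(p$sample_inter, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignments(sam_path)
  total <- attr(aln, "total_reads")
  over <- aln$hit_count > config$max_hits
  if (any(over)) {
    warning(sum(over), " alignment(s) exceed max_hits=", config$max_hits,
            " and are dropped")
    aln <- aln[!over, , drop = FALSE]
  }
  space <- rrna_space(genes, config$flank)
  part <- partition_rrna_exclusive(aln, space)
  retained <- part$retained
  # one alignment per read for quantification (primary = first record)
  retained <- retained[!duplicated(retained$read_id), , drop = FALSE]
  table_reads <- gene_relative_coords(retained, genes)
  trimmed <- if (!is.null(config$trimmed_dir))
    file.path(config$trimmed_dir, paste0(sample, ".fastq")) else ""
  library_total <- if (nzchar(trimmed) && file.exists(trimmed))
    count_fastq_reads(trimmed) else total
  stats_df <- data.frame(
    n_total_reads = part$stats$n_total_reads,
    n_rrna_exclusive = part$stats$n_rrna_exclusive,
    n_ambiguous = part$stats$n_ambiguous,
    n_non_rrna = part$stats$n_non_rrna,
    library_total = library_total)
  write_atomic(p$filtered, function(f) {
    utils::write.table(table_reads, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  write_atomic(p$excl, function(f) {
    utils::write.table(stats_df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(p)
}

run_classify_stage <- function(config, sample, genes) {
  p <- pipeline_paths(config, sample)
  reads <- utils::read.table(p$filtered, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  stats_df <- utils::read.table(p$excl, sep = "\t", header = TRUE)
  reads <- length_filter(reads, c(config$length_min, config$length_max))
  loci <- aggregate_loci(reads)
  ctx <- library_context(stats_df$library_total[1L],
                         min_rpm = config$min_rpm,
                         max_difference = config$max_difference,
                         length_range = c(config$length_min,
                                          config$length_max))
  confident <- filter_confident(loci, ctx)
  records <- build_records(confident, genes, config$full_span)
  write_atomic(p$records, function(f) {
    utils::write.table(records, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(p)
}

run_report_stage <- function(config, sample) {
  p <- pipeline_paths(config, sample)
  records <- utils::read.table(p$records, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  stats_df <- utils::read.table(p$excl, sep = "\t", header = TRUE)
  stats <- structure(as.list(stats_df[1L, c("n_total_reads",
                                            "n_rrna_exclusive",
                                            "n_ambiguous", "n_non_rrna")]),
                     class = "exclusivity_stats")
  dir.create(p$result, showWarnings = FALSE, recursive = TRUE)
  # the reported outputs show sense records unless antisense counting is
  # enabled; records.tsv keeps everything either way
  headline <- if (config$count_antisense) records else
    records[records$sense, , drop = FALSE]
  write_atomic(p$annotation, function(f) write_annotation_csv(headline, f))
  write_atomic(p$class_counts, function(f) write_class_counts(headline, f))
  write_atomic(p$abundance, function(f) {
    write_abundance_summary(headline, f, config$top_n)
  })
  figures <- suppressWarnings(
    make_figures(headline, file.path(p$result, "figures"), sample))
  summ <- sample_summary(headline, stats)
  write_atomic(p$html, function(f) {
    write_html_report(headline, summ, figures, f, sample)
  })
  structure(list(annotation_csv_path = p$annotation,
                 abundance_path = p$abundance,
                 class_counts_path = p$class_counts,
                 html_path = p$html, figure_paths = figures),
            class = "report_bundle")
}

sample_stage_defs <- function(config, sample, sam_path) {
  p <- pipeline_paths(config, sample)
  # downstream stages inherit the reference stage's identity, so editing the
  # genome or feature table re-runs the whole chain even when intermediate
  # files happen to be byte-identical
  ref_def <- reference_stage_def(config)
  upstream <- list(ref = list(inputs = file_digests(ref_def$inputs),
                              params = ref_def$params))
  thresholds <- list(upstream = upstream,
                     min_rpm = config$min_rpm,
                     max_difference = config$max_difference,
                     length = c(config$length_min, config$length_max),
                     max_hits = config$max_hits, flank = config$flank,
                     full_span = config$full_span,
                     count_antisense = config$count_antisense,
                     top_n = config$top_n)
  trimmed <- if (!is.null(config$trimmed_dir))
    file.path(config$trimmed_dir, paste0(sample, ".fastq")) else character()
  trimmed <- trimmed[file.exists(trimmed)]
  list(
    filter = list(name = paste0("filter:", sample),
                  inputs = c(sam_path, p$genes_tsv, trimmed),
                  params = thresholds[c("upstream", "max_hits", "flank")],
                  outputs = c(p$filtered, p$excl)),
    classify = list(name = paste0("classify:", sample),
                    inputs = c(p$filtered, p$excl, p$genes_tsv),
                    params = thresholds[c("upstream", "min_rpm",
                                          "max_difference", "length",
                                          "full_span")],
                    outputs = p$records),
    report = list(name = paste0("report:", sample),
                  inputs = c(p$records, p$excl),
                  params = thresholds[c("upstream", "count_antisense",
                                        "top_n")],
                  outputs = c(p$annotation, p$class_counts, p$abundance,
                              p$html)))
}

#' Run the rsRNA annotation pipeline
#'
#' Executes the stage graph (reference building, exclusivity filtering,
#' classification/quantification, reporting) for each sample, with
#' content-digest freshness checks: a stage whose inputs, parameters and
#' outputs are unchanged since the recorded run is skipped. A failing
#' stage aborts its sample but other samples continue.
#'
#' @param config a [load_config()] result (or path to a YAML file).
#' @param samples named character vector of SAM/BAM paths; defaults to the
#'   config's `samples` map or a scan of `alignment_dir`.
#' @return list with `bundles` (per-sample `report_bundle`), `status`
#'   (`data.frame` of stage actions), `errors` (per-sample messages) and
#'   `exit_code` (0 ok, 1 sample failures).
#' @export
run_pipeline <- function(config, samples = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  samples <- samples %||% discover_samples(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_paths(config)
  manifest <- load_manifest(p$manifest)
  status <- list()
  changed <- FALSE
  note <- function(stage, sample, action) {
    status[[length(status) + 1L]] <<- data.frame(
      stage = stage, sample = sample, action = action,
      stringsAsFactors = FALSE)
    message("[", action, "] ", stage)
  }

  ref_def <- reference_stage_def(config)
  if (stage_is_fresh(manifest, ref_def$name, ref_def$inputs, ref_def$params,
                     ref_def$outputs)) {
    note("reference", "-", "skipped (fresh)")
    genes <- read_genes_tsv(p$genes_tsv)
  } else {
    genes <- run_reference_stage(config)
    manifest$stages[[ref_def$name]] <-
      stage_record(ref_def$inputs, ref_def$params, ref_def$outputs)
    changed <- TRUE
    note("reference", "-", "run")
  }

  bundles <- list()
  errors <- list()
  for (sample in names(samples)) {
    res <- tryCatch({
      defs <- sample_stage_defs(config, sample, samples[[sample]])
      for (st in c("filter", "classify", "report")) {
        d <- defs[[st]]
        if (stage_is_fresh(manifest, d$name, d$inputs, d$params, d$outputs)) {
          note(d$name, sample, "skipped (fresh)")
        } else {
          switch(st,
                 filter = run_filter_stage(config, sample, samples[[sample]],
                                           genes),
                 classify = run_classify_stage(config, sample, genes),
                 report = run_report_stage(config, sample))
          manifest$stages[[d$name]] <-
            stage_record(d$inputs, d$params, d$outputs)
          changed <- TRUE
          note(d$name, sample, "run")
        }
      }
      sp <- pipeline_paths(config, sample)
      structure(list(annotation_csv_path = sp$annotation,
                     abundance_path = sp$abundance,
                     class_counts_path = sp$class_counts,
                     html_path = sp$html,
                     figure_paths = list.files(file.path(sp$result, "figures"),
                                               full.names = TRUE)),
                class = "report_bundle")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sample]] <- conditionMessage(res)
      note(paste0("sample:", sample), sample, "failed")
      warning("sample ", sample, " failed: ", conditionMessage(res))
    } else {
      bundles[[sample]] <- res
    }
  }
  if (changed) save_manifest(manifest, p$manifest)
  list(bundles = bundles,
       status = do.call(rbind, status),
       errors = errors,
       exit_code = if (length(errors)) 1L else 0L)
}

#' Plan a pipeline run without executing it
#'
#' Evaluates freshness for every stage and reports whether it would run or
#' be skipped; nothing is written. An unreadable manifest falls back (with
#' a warning) to planning every stage.
#'
#' @inheritParams run_pipeline
#' @return `data.frame` with `stage`, `sample`, `action` (`"would run"` /
#'   `"would skip"`).
#' @export
dry_run <- function(config, samples = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  samples <- samples %||% discover_samples(config)
  p <- pipeline_paths(config)
  manifest <- load_manifest(p$manifest)
  plan <- list()
  add <- function(stage, sample, fresh) {
    plan[[length(plan) + 1L]] <<- data.frame(
      stage = stage, sample = sample,
      action = if (fresh) "would skip" else "would run",
      stringsAsFactors = FALSE)
  }
  ref_def <- reference_stage_def(config)
  add("reference", "-",
      stage_is_fresh(manifest, ref_def$name, ref_def$inputs, ref_def$params,
                     ref_def$outputs))
  for (sample in names(samples)) {
    defs <- sample_stage_defs(config, sample, samples[[sample]])
    for (d in defs) {
      add(d$name, sample,
          stage_is_fresh(manifest, d$name, d$inputs, d$params, d$outputs))
    }
  }
  out <- do.call(rbind, plan)
  for (i in seq_len(nrow(out))) {
    message(format(out$stage[i], width = 28), " ", out$action[i])
  }
  out
}
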