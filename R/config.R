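config_defaults <- list(
  search_strategy = "host",
  genome_fasta = NULL,
  species_NCBI_feature_table = NULL,
  trimmed_dir = NULL,
  alignment_dir = NULL,
  samples = NULL,
  output_dir = "rsRNA_out",
  min_rpm = 10,
  max_difference = 4L,
  length_min = 16L,
  length_max = 40L,
  max_hits = 50L,
  max_mismatch_rate = 0.05,
  flank = 0L,
  top_n = 5L,
  full_span = "rRF-5",
  count_antisense = FALSE,
  header_map = NULL,
  modification_sites = NULL,
  seed = 1L)

canonical_key <- function(keys) {
  known <- names(config_defaults)
  idx <- match(tolower(keys), tolower(known))
  out <- known[idx]
  out[is.na(idx)] <- keys[is.na(idx)]
  out
}

#' Load and validate a pipeline configuration (YAML)
#'
#' Keys mirror the documented YAML spellings (`Search_strategy`,
#' `genome_fasta`, `species_NCBI_feature_table`, ...) and are matched
#' case-insensitively; a nested `reference_genome:` block is flattened.
#' Absent optional keys take documented defaults (`min_rpm` 10,
#' `max_difference` 4, lengths 16-40, `max_hits` 50, `flank` 0); unknown
#' keys trigger a warning.
#'
#' @param path YAML file.
#' @return list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config error: ", path, " is not a YAML mapping")
  if (!is.null(raw$reference_genome) && is.list(raw$reference_genome)) {
    raw <- c(raw[names(raw) != "reference_genome"], raw$reference_genome)
  }
  names(raw) <- canonical_key(names(raw))
  unknown <- setdiff(names(raw), names(config_defaults))
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
    raw <- raw[names(raw) %in% names(config_defaults)]
  }
  cfg <- config_defaults
  cfg[names(raw)] <- raw
  if (identical(tolower(cfg$search_strategy), "host")) {
    for (key in c("genome_fasta", "species_NCBI_feature_table")) {
      if (is.null(cfg[[key]])) {
        stop("config error: required key '", key, "' is missing")
      }
    }
  }
  if (!is.null(cfg$header_map)) cfg$header_map <- unlist(cfg$header_map)
  if (!is.null(cfg$samples)) cfg$samples <- unlist(cfg$samples)
  stopifnot(cfg$min_rpm >= 0, cfg$max_difference >= 0,
            cfg$length_min >= 1, cfg$length_min <= cfg$length_max,
            cfg$max_hits >= 1, cfg$flank >= 0,
            cfg$max_mismatch_rate >= 0, cfg$max_mismatch_rate <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Serialize a configuration to canonical YAML
#'
#' Keys are emitted in a fixed order with all defaults materialized, so
#' `dump_config(load_config(x))` is a canonical form and loading it back
#' reproduces the same configuration.
#'
#' @param config a `pipeline_config`.
#' @param path optional output file; when `NULL` the YAML string is
#'   returned.
#' @return YAML string (invisibly when `path` is given).
#' @export
dump_config <- function(config, path = NULL) {
  x <- unclass(config)[names(config_defaults)]
  x <- x[!vapply(x, is.null, logical(1L))]
  if (!is.null(x$header_map)) x$header_map <- as.list(x$header_map)
  if (!is.null(x$samples)) x$samples <- as.list(x$samples)
  out <- yaml::as.yaml(x)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("rsRNA pipeline configuration\n")
  cat("  genome_fasta:", x$genome_fasta %||% "<unset>", "\n")
  cat("  feature table:", x$species_NCBI_feature_table %||% "<unset>", "\n")
  cat(sprintf("  thresholds: min_rpm %s, max_difference <%s, length %d-%d, max_hits %d, flank %d\n",
              x$min_rpm, x$max_difference, x$length_min, x$length_max,
              x$max_hits, x$flank))
  invisible(x)
}
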