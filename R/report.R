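#' Assemble the rsRNA record table for reporting
#'
#' Joins confident loci with per-gene annotation (category, rRNA type,
#' organellar origin, parental coordinates).
#'
#' @param loci confident loci from [filter_confident()].
#' @param genes rRNA gene table.
#' @param full_span category for full-span fragments (see
#'   [classify_rrf()]).
#' @return `data.frame` of rsRNA records.
#' @export
build_records <- function(loci, genes, full_span = "rRF-5") {
  gi <- match(loci$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("loci reference unknown gene id(s)")
  g <- genes[gi, , drop = FALSE]
  data.frame(
    category = if (nrow(loci)) classify_rrf(loci$gene_start, loci$gene_end,
                                            g$length, full_span) else character(),
    gene_id = loci$gene_id,
    rrna_type = g$rrna_type,
    origin = g$origin,
    rrna_info = sprintf("%s|%s|%s:%d-%d(%s)", loci$gene_id, g$rrna_type,
                        g$fasta_header, g$start, g$end, g$strand),
    gene_start = loci$gene_start,
    gene_end = loci$gene_end,
    sequence = loci$sequence,
    length = nchar(loci$sequence),
    fasta_header = loci$fasta_header,
    genomic_start = loci$genomic_start,
    genomic_end = loci$genomic_end,
    genomic_strand = loci$genomic_strand,
    sense = loci$sense,
    difference = loci$difference,
    rpm = loci$rpm,
    seq_count = loci$seq_count,
    count = loci$count,
    stringsAsFactors = FALSE)
}

annotation_columns <- c("Category", "rRNA_info", "Gene_Start", "Gene End",
                        "Sequence", "Length", "Genomic Start", "Genomic End",
                        "Difference", "RPM", "Seq_count", "count")

records_sorted <- function(records) {
  ord <- order(records$origin, records$gene_id, records$gene_start)
  records[ord, , drop = FALSE]
}

#' Write the annotated rsRNA table (CSV)
#'
#' Twelve comma-separated columns in fixed order: `Category`, `rRNA_info`,
#' `Gene_Start`, `Gene End`, `Sequence`, `Length`, `Genomic Start`,
#' `Genomic End`, `Difference`, `RPM`, `Seq_count`, `count` (the mixed
#' header spellings are intentional and kept stable). RPM is rendered with
#' two decimals; rows are sorted by (origin, gene id, gene start).
#'
#' @param records rsRNA record table from [build_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(records, path) {
  records <- records_sorted(records)
  lines <- paste(annotation_columns, collapse = ",")
  if (nrow(records) > 0L) {
    body <- paste(records$category, records$rrna_info, records$gene_start,
                  records$gene_end, records$sequence, records$length,
                  records$genomic_start, records$genomic_end,
                  records$difference, sprintf("%.2f", records$rpm),
                  records$seq_count, records$count, sep = ",")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back an annotation CSV
#'
#' @param path CSV written by [write_annotation_csv()].
#' @return `data.frame` with the literal column names.
#' @export
read_annotation_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = c(RPM = "character"))
}

rrf_categories <- c("rRF-5", "rRF-3", "rRF-i")

#' Write per-class record counts (TSV)
#'
#' Two columns: class and count, one row per category (zero rows
#' included); counts sum to the number of records.
#'
#' @inheritParams write_annotation_csv
#' @return `path`, invisibly.
#' @export
write_class_counts <- function(records, path) {
  counts <- table(factor(records$category, levels = rrf_categories))
  df <- data.frame(Category = rrf_categories,
                   Count = as.integer(counts[rrf_categories]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the abundance summary (eight columns)
#'
#' The most abundant records per rRNA type (top `top_n` by RPM, ties
#' broken by RPM descending then sequence ascending), with eight columns:
#' `rRNA_type`, `Origin`, `Category`, `Sequence`, `Length`, `RPM`,
#' `Seq_count`, `count`.
#'
#' @inheritParams write_annotation_csv
#' @param top_n rows kept per rRNA type (default 5).
#' @return `path`, invisibly.
#' @export
write_abundance_summary <- function(records, path, top_n = 5L) {
  pick <- unlist(lapply(split(seq_len(nrow(records)), records$rrna_type),
                        function(idx) {
    sub <- records[idx, , drop = FALSE]
    idx[order(-sub$rpm, sub$sequence)][seq_len(min(top_n, length(idx)))]
  }), use.names = FALSE)
  sub <- records[pick, , drop = FALSE]
  df <- data.frame(rRNA_type = sub$rrna_type, Origin = sub$origin,
                   Category = sub$category, Sequence = sub$sequence,
                   Length = sub$length, RPM = sprintf("%.2f", sub$rpm),
                   Seq_count = sub$seq_count, count = sub$count,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the per-sample summary
#'
#' @param records rsRNA record table.
#' @param stats optional `exclusivity_stats`.
#' @return list of class `sample_summary` with per-category counts,
#'   per-origin counts, the record length distribution and the
#'   rRNA-exclusive read fraction.
#' @export
sample_summary <- function(records, stats = NULL) {
  structure(list(
    category_counts = table(factor(records$category, levels = rrf_categories)),
    origin_counts = table(factor(records$origin,
                                 levels = c("nuclear", "mitochondrial",
                                            "chloroplastic"))),
    length_distribution = table(records$length),
    exclusivity = stats,
    exclusive_fraction = if (!is.null(stats) && stats$n_total_reads > 0)
      stats$n_rrna_exclusive / stats$n_total_reads else NA_real_),
    class = "sample_summary")
}

#' Draw summary figures (pie, bar, two box plots)
#'
#' Pie: record share by organellar origin. Bar: per-category record
#' counts. Box plots: fragment length and RPM distributions per category.
#' Each figure is written in both PNG and SVG.
#'
#' @param records rsRNA record table.
#' @param out_dir output directory.
#' @param prefix filename prefix.
#' @return character vector of written paths (empty, with a warning, for
#'   empty input).
#' @export
make_figures <- function(records, out_dir, prefix = "rsRNA") {
  if (nrow(records) == 0L) {
    warning("no records; skipping figures")
    return(character())
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  draw <- list(
    origin_pie = function() {
      tab <- table(records$origin)
      graphics::pie(tab, main = "rsRNA records by organellar origin",
                    col = c("#66c2a5", "#fc8d62", "#8da0cb")[seq_along(tab)])
    },
    category_bar = function() {
      tab <- table(factor(records$category, levels = rrf_categories))
      graphics::barplot(tab, main = "rsRNA category counts",
                        ylab = "records", col = "#8da0cb")
    },
    length_box = function() {
      graphics::boxplot(length ~ factor(category, levels = rrf_categories),
                        data = records, main = "Fragment length by category",
                        xlab = "", ylab = "length (nt)", col = "#66c2a5")
    },
    rpm_box = function() {
      graphics::boxplot(rpm ~ factor(category, levels = rrf_categories),
                        data = records, main = "Abundance by category",
                        xlab = "", ylab = "RPM", log = "y", col = "#fc8d62")
    })
  paths <- character()
  for (nm in names(draw)) {
    png_path <- file.path(out_dir, paste0(prefix, "_", nm, ".png"))
    grDevices::png(png_path, width = 720, height = 560)
    draw[[nm]]()
    grDevices::dev.off()
    svg_path <- file.path(out_dir, paste0(prefix, "_", nm, ".svg"))
    grDevices::svg(svg_path, width = 7.2, height = 5.6)
    draw[[nm]]()
    grDevices::dev.off()
    paths <- c(paths, png_path, svg_path)
  }
  paths
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a self-contained HTML report
#'
#' Contains the per-category and per-origin summaries, the embedded
#' figures (base64 PNG), and the full annotation table with an additional
#' dot-bracket structure column (see [fold_dot_bracket()]). Only
#' post-filter (confident) records appear. Missing figure files degrade to
#' logged placeholders.
#'
#' @param records rsRNA record table.
#' @param summary a [sample_summary()].
#' @param figures character vector of figure paths (PNG files are
#'   embedded).
#' @param path output HTML path.
#' @param sample sample label shown in the title.
#' @return `path`, invisibly.
#' @export
write_html_report <- function(records, summary, figures, path,
                              sample = "sample") {
  records <- records_sorted(records)
  db <- vapply(records$sequence, fold_dot_bracket, "", USE.NAMES = FALSE)
  tab_rows <- if (nrow(records)) {
    cells <- cbind(records$category, html_escape(records$rrna_info),
                   records$gene_start, records$gene_end, records$sequence,
                   records$length, records$genomic_start,
                   records$genomic_end, records$difference,
                   sprintf("%.2f", records$rpm), records$seq_count,
                   records$count, db)
    paste0("<tr><td>",
           apply(cells, 1L, paste, collapse = "</td><td>"),
           "</td></tr>", collapse = "\n")
  } else ""
  cat_rows <- paste0("<tr><td>", names(summary$category_counts), "</td><td>",
                     as.integer(summary$category_counts), "</td></tr>",
                     collapse = "\n")
  org_rows <- paste0("<tr><td>", names(summary$origin_counts), "</td><td>",
                     as.integer(summary$origin_counts), "</td></tr>",
                     collapse = "\n")
  pngs <- figures[grepl("\\.png$", figures)]
  img_tags <- vapply(pngs, function(f) {
    if (!file.exists(f)) {
      message("figure missing, placeholder used: ", f)
      return(paste0("<p class='missing'>[figure not available: ",
                    html_escape(basename(f)), "]</p>"))
    }
    raw <- readBin(f, "raw", file.info(f)$size)
    paste0("<img alt='", html_escape(basename(f)),
           "' src='data:image/png;base64,", jsonlite::base64_enc(raw), "'/>")
  }, "", USE.NAMES = FALSE)
  excl <- if (!is.null(summary$exclusivity)) {
    sprintf("<p>rRNA-space exclusive reads: %d of %d (%.1f%%)</p>",
            summary$exclusivity$n_rrna_exclusive,
            summary$exclusivity$n_total_reads,
            100 * summary$exclusive_fraction)
  } else ""
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset='utf-8'/>\n",
    "<title>rsRNA report - ", html_escape(sample), "</title>\n",
    "<style>body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:90%}",
    "img{max-width:680px;display:block;margin:1em 0}",
    ".missing{color:#a00}</style>\n</head>\n<body>\n",
    "<h1>rsRNA annotation report: ", html_escape(sample), "</h1>\n",
    excl,
    "<h2>Records per category</h2>\n<table>", cat_rows, "</table>\n",
    "<h2>Records per organellar origin</h2>\n<table>", org_rows,
    "</table>\n",
    "<h2>Figures</h2>\n", paste(img_tags, collapse = "\n"), "\n",
    "<h2>Annotated rsRNAs</h2>\n<table id='records'>\n<tr><th>",
    paste(c(annotation_columns, "Dot_bracket"), collapse = "</th><th>"),
    "</th></tr>\n", tab_rows, "\n</table>\n</body>\n</html>\n")
  writeLines(html, path)
  invisible(path)
}
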