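demo_records <- function(n = 3L) {
  fx <- build_fixture(small_spec())
  cfgd <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- load_config(minimal_config(cfgd, fx$dir))
  run_pipeline(cfg)
  p <- file.path(cfg$output_dir, "intermediate", "genome", "s1",
                 "rsRNA_records.tsv")
  utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

test_that("annotation CSV carries the twelve fixed columns and round-trips", {
  path <- tempfile(fileext = ".csv")
  empty <- build_records(
    cbind(make_genes("chr1", 1, 10)[0, c("gene_id", "fasta_header")],
          data.frame(gene_start = integer(), gene_end = integer(),
                     sense = logical(), genomic_start = integer(),
                     genomic_end = integer(), genomic_strand = character(),
                     sequence = character(), difference = integer(),
                     seq_count = integer(), count = integer(),
                     rpm = numeric())),
    make_genes("chr1", 1, 10))
  write_annotation_csv(empty, path)
  expect_equal(readLines(path),
               paste(c("Category", "rRNA_info", "Gene_Start", "Gene End",
                       "Sequence", "Length", "Genomic Start", "Genomic End",
                       "Difference", "RPM", "Seq_count", "count"),
                     collapse = ","))

  recs <- local({
    rec <- demo_records()
    rec
  })
  write_annotation_csv(recs, path)
  back <- read_annotation_csv(path)
  expect_equal(nrow(back), nrow(recs))
  expect_equal(names(back),
               c("Category", "rRNA_info", "Gene_Start", "Gene End",
                 "Sequence", "Length", "Genomic Start", "Genomic End",
                 "Difference", "RPM", "Seq_count", "count"))
  # round trip: writing the parsed table again is byte-identical
  ord <- order(recs$origin, recs$gene_id, recs$gene_start)
  expect_equal(back$Sequence, recs$sequence[ord])
  expect_equal(back$count, recs$count[ord])
  expect_equal(back$RPM, sprintf("%.2f", recs$rpm[ord]))
  path2 <- tempfile(fileext = ".csv")
  writeLines(c(paste(names(back), collapse = ","),
               apply(back, 1L, function(r) paste(trimws(r), collapse = ","))),
             path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("single-record CSV has two lines of twelve fields", {
  genes <- make_genes("chr1", 101, 400, gene_id = "g")
  loci <- data.frame(gene_id = "g", gene_start = 1L, gene_end = 20L,
                     sense = TRUE, fasta_header = "chr1",
                     genomic_start = 101L, genomic_end = 120L,
                     genomic_strand = "+", sequence = strrep("A", 20L),
                     difference = 0L, seq_count = 5L, count = 5L,
                     rpm = 50, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_annotation_csv(build_records(loci, genes), path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  expect_equal(lengths(strsplit(lines, ",")), c(12L, 12L))
})

test_that("class counts cover all categories and sum to the record count", {
  recs <- data.frame(category = c(rep("rRF-5", 3L), rep("rRF-i", 2L)))
  path <- tempfile(fileext = ".tsv")
  write_class_counts(recs, path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(tab$Category, c("rRF-5", "rRF-3", "rRF-i"))
  expect_equal(tab$Count, c(3L, 0L, 2L))
  expect_equal(sum(tab$Count), nrow(recs))

  write_class_counts(recs[0, , drop = FALSE], path)
  tab0 <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(tab0$Count, c(0L, 0L, 0L))
})

test_that("abundance summary reports top-N per rRNA type with deterministic ties", {
  recs <- data.frame(
    rrna_type = "18S", origin = "nuclear", category = "rRF-5",
    sequence = c("GG", "AA", "CC", "TT", "AT", "CG", "TA"),
    length = 2L, rpm = c(70, 50, 50, 40, 30, 20, 10),
    seq_count = 1L, count = 1L, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_abundance_summary(recs, path, top_n = 5L)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 5L)
  expect_equal(names(tab), c("rRNA_type", "Origin", "Category", "Sequence",
                             "Length", "RPM", "Seq_count", "count"))
  # RPM desc, then sequence asc among the tied 50s
  expect_equal(tab$Sequence, c("GG", "AA", "CC", "TT", "AT"))
})

test_that("dot-bracket folding maximizes pairs and stays balanced", {
  expect_equal(fold_dot_bracket("AAAA"), "....")
  expect_equal(fold_dot_bracket("GGGAAAACCC"), "(((....)))")
  expect_error(fold_dot_bracket("ACGX"), "non-nucleotide")

  set.seed(21)
  for (rep in 1:40) {
    n <- sample(1:12, 1L)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    db <- fold_dot_bracket(s)
    expect_equal(nchar(db), n)
    expect_equal(lengths(regmatches(db, gregexpr("\\(", db))),
                 lengths(regmatches(db, gregexpr("\\)", db))))
    expect_equal(count_pairs(db), enum_max_pairs(s))
  }
})

test_that("HTML report embeds the table, dot-bracket column and figures", {
  recs <- demo_records()
  outdir <- withr::local_tempdir()
  figs <- make_figures(recs, outdir)
  expect_true(all(file.exists(figs)))
  expect_true(any(grepl("\\.png$", figs)) && any(grepl("\\.svg$", figs)))

  html <- file.path(outdir, "report.html")
  summ <- sample_summary(recs)
  write_html_report(recs, summ, figs, html, sample = "s1")
  doc <- paste(readLines(html), collapse = "\n")
  expect_equal(lengths(regmatches(doc, gregexpr("<tr><td>", doc))),
               nrow(recs) + 6L)  # records + 3 categories + 3 origins
  expect_match(doc, "Dot_bracket")
  expect_match(doc, "data:image/png;base64")

  # empty input: valid HTML with empty table; no figures, but a warning
  expect_warning(none <- make_figures(recs[0, , drop = FALSE], outdir),
                 "no records")
  expect_length(none, 0L)
  html0 <- file.path(outdir, "empty.html")
  write_html_report(recs[0, , drop = FALSE],
                    sample_summary(recs[0, , drop = FALSE]),
                    character(), html0)
  expect_match(paste(readLines(html0), collapse = "\n"), "</html>")

  # missing figure files degrade to placeholders
  html1 <- file.path(outdir, "missing_fig.html")
  expect_message(
    write_html_report(recs, summ, file.path(outdir, "ghost.png"), html1),
    "placeholder")
  expect_match(paste(readLines(html1), collapse = "\n"), "not available")
})

test_that("class-count totals equal annotation CSV data rows", {
  recs <- demo_records()
  csv <- tempfile(fileext = ".csv")
  tsv <- tempfile(fileext = ".tsv")
  write_annotation_csv(recs, csv)
  write_class_counts(recs, tsv)
  counts <- utils::read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(sum(counts$Count), length(readLines(csv)) - 1L)
})
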