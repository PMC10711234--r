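test_that("positional classification follows the anchoring rules", {
  expect_equal(classify_rrf(1, 24, 1808), "rRF-5")
  expect_equal(classify_rrf(1785, 1808, 1808), "rRF-3")
  expect_equal(classify_rrf(50, 70, 1808), "rRF-i")
  expect_equal(classify_rrf(1, 1808, 1808), "rRF-5")  # full span
  expect_equal(classify_rrf(1, 20, 20, full_span = "rRF-3"), "rRF-3")
  expect_error(classify_rrf(0, 10, 100), "outside")
  expect_error(classify_rrf(5, 101, 100), "outside")
})

test_that("categories are total, mutually exclusive, and count to L(L+1)/2", {
  L <- 20L
  grid <- expand.grid(s = 1:L, e = 1:L)
  grid <- grid[grid$s <= grid$e, ]
  cats <- classify_rrf(grid$s, grid$e, L)
  expect_equal(nrow(grid), L * (L + 1L) / 2L)
  expect_true(all(cats %in% c("rRF-5", "rRF-3", "rRF-i")))
  tab <- table(cats)
  expect_equal(sum(tab), 210L)
  # brute-force re-derivation per interval
  brute <- apply(grid, 1L, function(r) {
    if (r[["s"]] == 1L) "rRF-5"
    else if (r[["e"]] == L) "rRF-3"
    else "rRF-i"
  })
  expect_equal(as.vector(cats), as.vector(brute))
})

test_that("length filtering keeps 16-40 nt inclusive", {
  recs <- data.frame(sequence = strrep("A", c(15, 16, 40, 41)))
  kept <- length_filter(recs)
  expect_equal(nchar(kept$sequence), c(16L, 40L))
  expect_equal(nrow(length_filter(recs[0, , drop = FALSE])), 0L)
})

read_row <- function(seq, diff = 0L, gene_id = "g", s = 10L, e = NULL,
                     sense = TRUE) {
  e <- e %||% (s + nchar(seq) - 1L)
  data.frame(read_id = "r", sequence = seq, gene_id = gene_id,
             gene_start = s, gene_end = e, sense = sense,
             difference = diff, hit_count = 1L, fasta_header = "chr1",
             genomic_start = 100L + s, genomic_end = 100L + e,
             genomic_strand = "+", stringsAsFactors = FALSE)
}

test_that("locus aggregation picks the predominant sequence with stated tie-breaks", {
  reads <- rbind(read_row("AAAA"), read_row("AAAA"), read_row("AAAA"),
                 read_row("AAAT", diff = 1L))
  loci <- aggregate_loci(reads)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$sequence, "AAAA")
  expect_equal(loci$seq_count, 3L)
  expect_equal(loci$count, 4L)

  tied <- rbind(read_row("AAAT", diff = 1L), read_row("AAAT", diff = 1L),
                read_row("AAAA"), read_row("AAAA"))
  expect_equal(aggregate_loci(tied)$sequence, "AAAA")  # lower difference

  lex <- rbind(read_row("AAAC"), read_row("AAAC"),
               read_row("AAAA"), read_row("AAAA"))
  expect_equal(aggregate_loci(lex)$sequence, "AAAA")  # lexicographic
})

test_that("aggregation recovers fixture loci with injected minor variants", {
  fx <- build_fixture(small_spec(minor_variant_frac = 0.5))
  aln <- read_alignments(fx$sam)
  reads <- gene_relative_coords(aln, fx$ref$genes)
  loci <- aggregate_loci(reads)
  truth <- fx$sim$truth_loci
  expect_true(any(loci$seq_count < loci$count))  # variants present
  key <- function(d) paste(d$gene_id, d$gene_start, d$gene_end, d$sense)
  m <- match(key(truth), key(loci))
  expect_false(anyNA(m))
  expect_equal(loci$sequence[m], truth$sequence)
  expect_equal(loci$seq_count[m], truth$seq_count)
  expect_equal(loci$count[m], truth$count)
})

test_that("count conservation: locus counts sum to retained reads per gene", {
  fx <- build_fixture(small_spec(minor_variant_frac = 0.3))
  reads <- gene_relative_coords(read_alignments(fx$sam), fx$ref$genes)
  loci <- aggregate_loci(reads)
  per_gene_loci <- tapply(loci$count, loci$gene_id, sum)
  per_gene_reads <- table(reads$gene_id)
  expect_equal(as.integer(per_gene_loci[names(per_gene_reads)]),
               as.integer(per_gene_reads))
})

test_that("RPM follows count / library_total * 1e6 and is linear", {
  expect_equal(compute_rpm(0, 1e6), 0)
  expect_equal(compute_rpm(25, 2e6), 12.5)
  expect_equal(compute_rpm(10, 1e6), 10)
  expect_error(compute_rpm(5, 0), "positive")
  set.seed(3)
  counts <- sample.int(1e5, 200L)
  totals <- sample(1e5:1e7, 200L)
  expect_equal(compute_rpm(counts, totals), counts / totals * 1e6)
  expect_equal(compute_rpm(2 * counts, 2 * totals),
               compute_rpm(counts, totals))
})

locus_row <- function(count, diff = 0L, gs = 10L, ge = 30L, gene = "g",
                      seq = strrep("A", ge - gs + 1L), gstart = NULL) {
  data.frame(gene_id = gene, gene_start = gs, gene_end = ge, sense = TRUE,
             fasta_header = "chr1", genomic_start = gstart %||% (100L + gs),
             genomic_end = (gstart %||% (100L + gs)) + (ge - gs),
             genomic_strand = "+", sequence = seq, difference = diff,
             seq_count = count, count = count, stringsAsFactors = FALSE)
}

test_that("confidence filter enforces strict <4 differences and >=10 RPM", {
  ctx <- library_context(1e6)
  expect_equal(nrow(filter_confident(locus_row(100, diff = 4L), ctx)), 0L)
  expect_equal(nrow(filter_confident(locus_row(100, diff = 3L), ctx)), 1L)
  # 10 reads in a million = exactly 10 RPM -> retained; 9.99 excluded
  expect_equal(nrow(filter_confident(locus_row(10), ctx)), 1L)
  ctx2 <- library_context(1000100)
  expect_equal(nrow(filter_confident(locus_row(10), ctx2)), 0L)
})

test_that("co-located low-abundance loci fold into the surviving locus count", {
  major <- locus_row(50, gs = 10L, ge = 30L, gstart = 500L)
  minor <- locus_row(2, gs = 12L, ge = 32L, gene = "g2", seq = strrep("C", 21),
                     gstart = 500L)
  minor$genomic_end <- major$genomic_end  # identical genomic coordinates
  ctx <- library_context(1e6, min_rpm = 10)
  out <- filter_confident(rbind(major, minor), ctx)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, major$sequence)
  expect_equal(out$count, 52L)
  expect_equal(out$rpm, 52)
  # distinct genomic positions stay separate
  out2 <- filter_confident(rbind(locus_row(50, gstart = 500L),
                                 locus_row(40, gs = 60L, ge = 80L,
                                           gstart = 900L)),
                           ctx)
  expect_equal(nrow(out2), 2L)
})

test_that("modification-site overlap matches brute-force containment", {
  records <- data.frame(gene_id = c("g", "g", "h"),
                        gene_start = c(10L, 40L, 5L),
                        gene_end = c(30L, 60L, 25L))
  sites <- data.frame(gene_id = c("g", "g", "g", "h", "h"),
                      position = c(20L, 31L, 45L, 5L, 26L),
                      type = c("methylation", "methylation",
                               "pseudouridylation", "methylation",
                               "pseudouridylation"))
  ann <- annotate_modification_overlap(records, sites)
  expect_equal(ann$per_record[[1L]], 1L)
  expect_equal(ann$per_record[[2L]], 3L)
  expect_equal(ann$per_record[[3L]], 4L)
  expect_equal(ann$totals, c(methylation = 2L, pseudouridylation = 1L))

  # brute force over random instances
  set.seed(9)
  for (rep in 1:20) {
    recs <- data.frame(gene_id = sample(c("g", "h"), 8L, replace = TRUE),
                       gene_start = sample.int(80L, 8L))
    recs$gene_end <- recs$gene_start + sample.int(30L, 8L)
    st <- data.frame(gene_id = sample(c("g", "h"), 12L, replace = TRUE),
                     position = sample.int(120L, 12L),
                     type = sample(c("methylation", "pseudouridylation"),
                                   12L, replace = TRUE))
    ann <- annotate_modification_overlap(recs, st)
    brute <- matrix(FALSE, nrow(recs), nrow(st))
    for (i in seq_len(nrow(recs))) for (j in seq_len(nrow(st))) {
      brute[i, j] <- recs$gene_id[i] == st$gene_id[j] &&
        recs$gene_start[i] <= st$position[j] &&
        st$position[j] <= recs$gene_end[i]
    }
    for (i in seq_len(nrow(recs))) {
      expect_equal(ann$per_record[[i]], which(brute[i, ]))
    }
    hit <- which(apply(brute, 2L, any))
    for (tp in names(ann$totals)) {
      expect_equal(unname(ann$totals[tp]), sum(st$type[hit] == tp))
    }
  }
})

test_that("out-of-bounds modification sites are skipped with a warning", {
  genes <- make_genes("chr1", 101, 200, gene_id = "g")
  records <- data.frame(gene_id = "g", gene_start = 10L, gene_end = 90L)
  sites <- data.frame(gene_id = "g", position = c(50L, 150L),
                      type = "methylation")
  expect_warning(
    ann <- annotate_modification_overlap(records, sites, genes),
    "outside")
  expect_equal(ann$totals, c(methylation = 1L))
})
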