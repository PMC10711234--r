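test_that("difference counting trusts NM, else MD + CIGAR indels", {
  expect_equal(compute_difference("24M", nm = 0), 0L)
  expect_equal(compute_difference("10M1I13M", nm = 3), 3L)
  expect_equal(compute_difference("10M2D10M", md = "10^AC10"), 2L)
  expect_equal(compute_difference("5M1I5M", md = "3T6"), 2L)
  expect_equal(compute_difference("10=2X8=", nm = NA, md = NA), 2L)
  expect_error(compute_difference("20M"), "undeterminable")
})

sam_header <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000")

test_that("SAM reading skips unmapped records, keeps orientation, errors on bad lines", {
  expect_equal(nrow(read_alignments(write_sam(sam_header))), 0L)

  lines <- c(sam_header,
             "r1\t0\tchr1\t101\t255\t4M\t*\t0\t0\tACGT\tIIII\tNM:i:0",
             "r2\t16\tchr1\t201\t255\t4M\t*\t0\t0\tACGT\tIIII\tNM:i:1",
             "r3\t4\t*\t0\t0\t*\t*\t0\t0\tGGGG\tIIII")
  aln <- read_alignments(write_sam(lines))
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$strand, c("+", "-"))
  # reverse-strand SEQ is reported back in as-sequenced orientation
  expect_equal(aln$sequence[2L], "ACGT")
  expect_equal(aln$target_end, c(104L, 204L))
  expect_equal(attr(aln, "total_reads"), 3L)

  bad <- write_sam(c(sam_header, "r1\t0\tchr1"))
  expect_error(read_alignments(bad), "line 3")

  nocig <- c(sam_header, "r1\t0\tchr1\t10\t255\t*\t*\t0\t0\tACGT\tIIII")
  expect_warning(read_alignments(write_sam(nocig)), "CIGAR")
})

test_that("hit counts come from NH when present, else from record multiplicity", {
  lines <- c(sam_header,
             "r1\t0\tchr1\t10\t255\t4M\t*\t0\t0\tACGT\tIIII\tNM:i:0\tNH:i:7",
             "r2\t0\tchr1\t20\t255\t4M\t*\t0\t0\tACGT\tIIII\tNM:i:0",
             "r2\t256\tchr1\t90\t255\t4M\t*\t0\t0\tACGT\tIIII\tNM:i:0")
  aln <- read_alignments(write_sam(lines))
  expect_equal(aln$hit_count[aln$read_id == "r1"], 7L)
  expect_equal(unique(aln$hit_count[aln$read_id == "r2"]), 2L)
})

test_that("fixture SAM records reproduce the simulation truth", {
  fx <- build_fixture(small_spec())
  aln <- read_alignments(fx$sam)
  truth <- fx$sim$reads
  clean <- truth[truth$status == "clean", ]
  m <- match(clean$read_id, aln$read_id)
  expect_false(anyNA(m))
  expect_equal(aln$target_id[m], clean$gene_id)
  expect_equal(aln$target_start[m], clean$gene_start)
  expect_equal(aln$target_end[m], clean$gene_end)
  expect_equal(aln$strand[m] == "+", clean$sense)
  expect_equal(aln$sequence[m], clean$sequence)
  expect_equal(aln$difference[m], clean$n_mismatches)
})

test_that("exclusivity partition retains only reads wholly inside rRNA space", {
  genes <- make_genes("chr1", c(101, 501), c(200, 600),
                      gene_id = c("gA", "gB"))
  space <- rrna_space(genes)
  aln <- rbind(
    make_aln("both_rrna", "gA", 5, 24),
    make_aln("both_rrna", "gB", 11, 30),
    make_aln("mixed", "gA", 5, 24),
    make_aln("mixed", "chr1", 700, 719),
    make_aln("decoy_only", "chr1", 800, 819),
    make_aln("genomic_rrna", "chr1", 120, 139))
  part <- partition_rrna_exclusive(aln, space)
  s <- part$stats
  expect_equal(s$n_total_reads, 4L)
  expect_equal(s$n_rrna_exclusive, 2L)
  expect_equal(s$n_ambiguous, 1L)
  expect_equal(s$n_non_rrna, 1L)
  expect_setequal(unique(part$retained$read_id),
                  c("both_rrna", "genomic_rrna"))
  # partition completeness
  expect_equal(s$n_total_reads,
               s$n_rrna_exclusive + s$n_ambiguous + s$n_non_rrna)
})

test_that("fixture decoy/ambiguous mix yields the injected exclusivity split", {
  fx <- build_fixture(small_spec(decoy_frac = 0.1, ambiguous_frac = 0.1))
  aln <- read_alignments(fx$sam)
  part <- partition_rrna_exclusive(aln, rrna_space(fx$ref$genes))
  s <- part$stats
  expect_equal(s$n_total_reads, 600L)
  expect_equal(s$n_rrna_exclusive, 480L)
  expect_equal(s$n_ambiguous, 60L)
  expect_equal(s$n_non_rrna, 60L)
})

test_that("gene-relative coordinates handle both strands and mapping modes", {
  genes <- make_genes("chr1", 101, 200, "+", gene_id = "gP")
  aln <- make_aln("r1", "chr1", 101, 124)
  out <- gene_relative_coords(aln, genes)
  expect_equal(c(out$gene_start, out$gene_end), c(1L, 24L))
  expect_true(out$sense)

  out2 <- gene_relative_coords(make_aln("r2", "chr1", 150, 170), genes)
  expect_equal(c(out2$gene_start, out2$gene_end), c(50L, 70L))

  gneg <- make_genes("chr1", 101, 200, "-", gene_id = "gN")
  out3 <- gene_relative_coords(make_aln("r3", "chr1", 177, 200, strand = "-"),
                               gneg)
  expect_equal(c(out3$gene_start, out3$gene_end), c(1L, 24L))
  expect_true(out3$sense)

  # transcript-mapped alignments are already 5'-anchored
  out4 <- gene_relative_coords(make_aln("r4", "gN", 1, 24), gneg)
  expect_equal(c(out4$gene_start, out4$gene_end), c(1L, 24L))
  expect_true(out4$sense)
  expect_equal(out4$genomic_strand, "-")

  expect_warning(
    hang <- gene_relative_coords(make_aln("r5", "chr1", 190, 213), gneg),
    "hanging")
  expect_equal(nrow(hang), 0L)
})

test_that("genomic -> gene-relative -> genomic is a bijection on both strands", {
  set.seed(5)
  for (strand in c("+", "-")) {
    genes <- make_genes("chr1", 1001, 1500, strand, gene_id = "g")
    for (rep in 1:25) {
      s <- sample(1001:1470, 1L)
      e <- min(1500L, s + sample(15:39, 1L))
      rstrand <- sample(c("+", "-"), 1L)
      out <- gene_relative_coords(make_aln("r", "chr1", s, e, strand = rstrand),
                                  genes)
      expect_equal(c(out$genomic_start, out$genomic_end), c(s, e))
      expect_equal(out$sense, rstrand == strand)
      # and the transcript window maps back through the stated transform
      if (strand == "-") {
        expect_equal(out$gene_start, genes$end - e + 1L)
        expect_equal(out$gene_end, genes$end - s + 1L)
      } else {
        expect_equal(out$gene_start, s - genes$start + 1L)
        expect_equal(out$gene_end, e - genes$start + 1L)
      }
    }
  }
})
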