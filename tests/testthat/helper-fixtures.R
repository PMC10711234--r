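# shared helpers: small fixture spec, tiny constructors, brute-force oracles

small_spec <- function(...) {
  fixture_spec(seed = 7L, n_reads = 600L, n_loci = 12L,
               gene_length_range = c(120L, 250L), ...)
}

make_genes <- function(fasta_header, start, end, strand = "+",
                       gene_id = NULL, rrna_type = "18S") {
  n <- max(length(fasta_header), length(start))
  fasta_header <- rep_len(fasta_header, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  strand <- rep_len(strand, n)
  data.frame(
    gene_id = gene_id %||% paste0("G", seq_len(n)),
    chromosome = sub("^chr", "", fasta_header),
    fasta_header = fasta_header,
    start = as.integer(start), end = as.integer(end), strand = strand,
    rrna_type = rep_len(rrna_type, n),
    origin = ifelse(fasta_header == "chrMt", "mitochondrial",
                    ifelse(fasta_header == "chrPt", "chloroplastic",
                           "nuclear")),
    length = as.integer(end - start + 1L),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_aln <- function(read_id, target_id, start, end, strand = "+",
                     difference = 0L, sequence = NULL, hit_count = 1L) {
  n <- length(read_id)
  data.frame(read_id = read_id,
             sequence = sequence %||% strrep("A", end - start + 1L),
             target_id = rep_len(target_id, n),
             target_start = as.integer(rep_len(start, n)),
             target_end = as.integer(rep_len(end, n)),
             strand = rep_len(strand, n),
             difference = as.integer(rep_len(difference, n)),
             hit_count = as.integer(rep_len(hit_count, n)),
             stringsAsFactors = FALSE)
}

# NCBI-dialect feature table text from minimal row tuples
make_feature_table <- function(rows) {
  cols <- c("feature", "class", "assembly", "assembly_unit", "seq_type",
            "chromosome", "genomic_accession", "start", "end", "strand",
            "product_accession", "non-redundant_refseq", "related_accession",
            "name", "symbol", "GeneID", "locus_tag",
            "feature_interval_length", "product_length", "attributes")
  lines <- paste0("# ", paste(cols, collapse = "\t"))
  for (r in rows) {
    v <- rep("", length(cols))
    names(v) <- cols
    v[names(r)] <- unlist(r)
    lines <- c(lines, paste(v, collapse = "\t"))
  }
  lines
}

write_feature_table <- function(rows, path = tempfile(fileext = ".txt")) {
  writeLines(make_feature_table(rows), path)
  path
}

ft_row <- function(feature = "rRNA", chromosome = "1", start = 10,
                   end = 100, strand = "+", name = "18S ribosomal RNA",
                   locus_tag = paste0("LT", start)) {
  list(feature = feature, class = "rRNA", chromosome = chromosome,
       start = as.character(start), end = as.character(end), strand = strand,
       name = name, locus_tag = locus_tag)
}

# per-base brute-force masking oracle
mask_oracle <- function(genome, genes, flank = 0L) {
  out <- genome
  for (hdr in names(genome)) {
    bases <- strsplit(genome[[hdr]], "")[[1L]]
    for (i in which(genes$fasta_header == hdr)) {
      lo <- max(1L, genes$start[i] - flank)
      hi <- min(length(bases), genes$end[i] + flank)
      if (lo <= hi) bases[lo:hi] <- "N"
    }
    out[[hdr]] <- paste(bases, collapse = "")
  }
  out
}

# exhaustive enumeration of all legal secondary structures (non-crossing
# pair sets, canonical + wobble pairs, loop >= min_loop); returns the
# maximal pair count -- deliberately explores every structure rather than
# tabulating
enum_max_pairs <- function(sequence, min_loop = 3L) {
  b <- strsplit(chartr("tT", "uU", toupper(sequence)), "")[[1L]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  go <- function(i, j) {
    if (i >= j) return(0L)
    best <- go(i + 1L, j)
    k <- i + min_loop + 1L
    while (k <= j) {
      if (paste0(b[i], b[k]) %in% ok) {
        best <- max(best, 1L + go(i + 1L, k - 1L) + go(k + 1L, j))
      }
      k <- k + 1L
    }
    best
  }
  if (length(b) == 0L) return(0L)
  go(1L, length(b))
}

random_genome <- function(n_chrom = 2L, max_len = 1000L) {
  g <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(50:max_len, 1L),
                 replace = TRUE), collapse = "")
  }, "")
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

random_gene_set <- function(genome, n_genes = 3L) {
  rows <- lapply(seq_len(n_genes), function(i) {
    hdr <- sample(names(genome), 1L)
    L <- nchar(genome[[hdr]])
    s <- sample.int(L, 1L)
    e <- min(L, s + sample.int(60L, 1L))
    make_genes(hdr, s, e, sample(c("+", "-"), 1L),
               gene_id = paste0("RG", i))
  })
  do.call(rbind, rows)
}

write_sam <- function(lines, path = tempfile(fileext = ".sam")) {
  writeLines(lines, path)
  path
}

minimal_config <- function(dir, fixture_dir, extra = character()) {
  path <- file.path(dir, "config.yaml")
  writeLines(c(
    'Search_strategy: "host"',
    paste0('genome_fasta: "', file.path(fixture_dir, "genome.fa"), '"'),
    paste0('species_NCBI_feature_table: "',
           file.path(fixture_dir, "feature_table.txt"), '"'),
    "samples:",
    paste0('  s1: "', file.path(fixture_dir, "alignments.sam"), '"'),
    paste0('output_dir: "', file.path(dir, "out"), '"'),
    extra), path)
  path
}

# build reference + reads + SAM for a spec in a temp dir
build_fixture <- function(spec, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ref <- generate_reference(spec, dir)
  sim <- simulate_reads(spec, ref, dir)
  sam <- simulate_alignments(sim, ref, file.path(dir, "alignments.sam"))
  list(ref = ref, sim = sim, sam = sam, dir = dir)
}
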