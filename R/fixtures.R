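`%||%` <- function(a, b) if (is.null(a)) b else a

# sample one element of x, even when length(x) == 1
resample1 <- function(x) x[sample.int(length(x), 1L)]

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Describe a synthetic rsRNA data set
#'
#' The defaults describe the reference evaluation scenario used throughout
#' the package: a toy genome with six rRNA genes (four nuclear, alternating
#' strands, plus one mitochondrial and one plastid gene), 5,000 error-free
#' small-RNA reads drawn from 40 fragment loci with a 5'-skewed category
#' mix, and no decoy or ambiguous reads. Noise (per-base mismatches),
#' decoy reads from non-rRNA genome space, ambiguous multi-mappers and
#' co-located minor sequence variants are all switched on explicitly.
#'
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param n_nuclear,n_mt,n_pt rRNA gene counts per compartment.
#' @param gene_length_range rRNA gene length bounds (nt).
#' @param category_mix named fractions for `rRF-5`/`rRF-3`/`rRF-i` loci
#'   (must sum to 1).
#' @param antisense_frac fraction of loci on the antisense strand.
#' @param n_loci number of fragment loci to plant.
#' @param n_reads total reads (including decoy and ambiguous reads).
#' @param mismatch_rate per-base substitution probability.
#' @param minor_variant_frac fraction of loci that carry a co-located
#'   minor sequence variant (single substitution, ~20% of the locus reads).
#' @param decoy_frac,ambiguous_frac fractions of `n_reads` that are decoy
#'   (non-rRNA) or ambiguous (rRNA + genomic multi-mapper) reads.
#' @param length_range read length bounds.
#' @param library_total RPM denominator; defaults to `n_reads`.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_nuclear = 4L, n_mt = 1L, n_pt = 1L,
                         gene_length_range = c(150L, 400L),
                         category_mix = c("rRF-5" = 0.5, "rRF-3" = 0.2,
                                          "rRF-i" = 0.3),
                         antisense_frac = 0.1, n_loci = 40L,
                         n_reads = 5000L, mismatch_rate = 0,
                         minor_variant_frac = 0, decoy_frac = 0,
                         ambiguous_frac = 0, length_range = c(16L, 40L),
                         library_total = NULL) {
  stopifnot(n_nuclear >= 0, n_mt >= 0, n_pt >= 0, n_loci > 0, n_reads > 0,
            abs(sum(category_mix) - 1) < 1e-8,
            all(category_mix >= 0),
            antisense_frac >= 0, antisense_frac <= 1,
            mismatch_rate >= 0, mismatch_rate <= 1,
            minor_variant_frac >= 0, minor_variant_frac <= 1,
            decoy_frac >= 0, ambiguous_frac >= 0,
            decoy_frac + ambiguous_frac < 1,
            length_range[1L] <= length_range[2L])
  names(category_mix) <- c("rRF-5", "rRF-3", "rRF-i")
  structure(list(seed = as.integer(seed), n_nuclear = n_nuclear,
                 n_mt = n_mt, n_pt = n_pt,
                 gene_length_range = gene_length_range,
                 category_mix = category_mix,
                 antisense_frac = antisense_frac, n_loci = n_loci,
                 n_reads = n_reads, mismatch_rate = mismatch_rate,
                 minor_variant_frac = minor_variant_frac,
                 decoy_frac = decoy_frac, ambiguous_frac = ambiguous_frac,
                 length_range = length_range,
                 library_total = library_total %||% n_reads),
            class = "fixture_spec")
}

feature_table_columns <- c(
  "feature", "class", "assembly", "assembly_unit", "seq_type", "chromosome",
  "genomic_accession", "start", "end", "strand", "product_accession",
  "non-redundant_refseq", "related_accession", "name", "symbol", "GeneID",
  "locus_tag", "feature_interval_length", "product_length", "attributes")

rrna_type_cycle <- list(nuclear = c("18S", "25S", "5.8S", "5S"),
                        mitochondrial = c("26S", "18S", "5S"),
                        chloroplastic = c("16S", "23S", "5S"))

#' Generate a synthetic genome, feature table and truth gene list
#'
#' Builds a toy genome with headers `chr1`, `chr2`, `chrMt`, `chrPt`,
#' places non-overlapping rRNA genes on alternating strands, and writes a
#' feature table in the NCBI assembly dialect (with `gene` companion rows,
#' which parsers must ignore) alongside the genome FASTA and a truth gene
#' table. Identical seeds give byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `genome` (named character), `genes` (truth gene
#'   table, same layout as [parse_feature_table()] output), `transcripts`
#'   (named character) and `paths`.
#' @export
generate_reference <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  plan <- data.frame(fasta_header = character(), label = character(),
                     origin = character(), stringsAsFactors = FALSE)
  if (spec$n_nuclear > 0L) {
    hdr <- rep(c("chr1", "chr2"), length.out = spec$n_nuclear)
    plan <- rbind(plan, data.frame(
      fasta_header = hdr, label = sub("^chr", "", hdr), origin = "nuclear",
      stringsAsFactors = FALSE))
  }
  if (spec$n_mt > 0L) {
    plan <- rbind(plan, data.frame(
      fasta_header = rep("chrMt", spec$n_mt), label = "MT",
      origin = "mitochondrial", stringsAsFactors = FALSE))
  }
  if (spec$n_pt > 0L) {
    plan <- rbind(plan, data.frame(
      fasta_header = rep("chrPt", spec$n_pt), label = "Pltd",
      origin = "chloroplastic", stringsAsFactors = FALSE))
  }

  headers <- c("chr1", "chr2", "chrMt", "chrPt")
  labels <- c(chr1 = "1", chr2 = "2", chrMt = "MT", chrPt = "Pltd")
  genome <- character()
  gene_rows <- list()
  gene_no <- 0L
  for (hdr in headers) {
    idx <- which(plan$fasta_header == hdr)
    seq_parts <- random_dna(sample(200:400, 1L))
    cursor <- nchar(seq_parts)
    for (k in seq_along(idx)) {
      gene_no <- gene_no + 1L
      glen <- resample1(spec$gene_length_range[1L]:spec$gene_length_range[2L])
      gseq <- random_dna(glen)
      start <- cursor + 1L
      end <- cursor + glen
      origin <- plan$origin[idx[k]]
      types <- rrna_type_cycle[[origin]]
      gene_rows[[gene_no]] <- data.frame(
        gene_id = sprintf("RRN%02d", gene_no),
        chromosome = unname(labels[hdr]),
        fasta_header = hdr,
        start = start, end = end,
        strand = if (gene_no %% 2L == 1L) "+" else "-",
        rrna_type = types[(k - 1L) %% length(types) + 1L],
        origin = origin, length = glen,
        stringsAsFactors = FALSE)
      gap <- random_dna(sample(150:300, 1L))
      seq_parts <- paste0(seq_parts, gseq, gap)
      cursor <- nchar(seq_parts)
    }
    genome[[hdr]] <- paste0(seq_parts, random_dna(sample(100:200, 1L)))
  }
  genes <- if (gene_no > 0L) do.call(rbind, gene_rows) else
    parse_feature_table_empty()
  genes <- genes[order(genes$fasta_header, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  ft_lines <- paste0("# ", paste(feature_table_columns, collapse = "\t"))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    common <- c("GCF_000000000.1", "Primary Assembly", "chromosome",
                g$chromosome, paste0("NC_9", sprintf("%05d", i), ".1"),
                g$start, g$end, g$strand)
    gene_row <- c("gene", "rRNA", common, "", "", "",
                  "", g$gene_id, as.character(1000L + i), g$gene_id,
                  g$length, "", "")
    rrna_row <- c("rRNA", "rRNA", common,
                  paste0("NR_", sprintf("%06d", i), ".1"), "", "",
                  paste0(g$rrna_type, " ribosomal RNA"), g$gene_id,
                  as.character(1000L + i), g$gene_id, g$length, g$length, "")
    ft_lines <- c(ft_lines, paste(gene_row, collapse = "\t"),
                  paste(rrna_row, collapse = "\t"))
  }

  paths <- list(genome = file.path(dir, "genome.fa"),
                feature_table = file.path(dir, "feature_table.txt"),
                genes_truth = file.path(dir, "genes_truth.tsv"))
  write_fasta(genome, paths$genome)
  writeLines(ft_lines, paths$feature_table)
  utils::write.table(genes, paths$genes_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(genome = genome, genes = genes,
       transcripts = extract_rrna_sequences(genome, genes),
       paths = paths)
}

parse_feature_table_empty <- function() {
  data.frame(gene_id = character(), chromosome = character(),
             fasta_header = character(), start = integer(), end = integer(),
             strand = character(), rrna_type = character(),
             origin = character(), length = integer(),
             stringsAsFactors = FALSE)
}

substitute_base <- function(seq, pos) {
  for (p in pos) {
    old <- substr(seq, p, p)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(seq, p, p) <- new
  }
  seq
}

#' Simulate small-RNA reads with a truth table
#'
#' Plants `n_loci` fragment loci on the reference transcripts according to
#' the category mix (5'-anchored loci start at transcript position 1,
#' 3'-anchored loci end at the final position, internal loci are strictly
#' inside), distributes the clean reads over loci multinomially, injects
#' per-base mismatches at `mismatch_rate`, and adds optional co-located
#' minor variants, ambiguous multi-mappers and decoy reads from non-rRNA
#' genome space. Writes a FASTQ (constant quality `I`), a per-read truth
#' table and a per-locus truth table.
#'
#' @param spec a [fixture_spec()].
#' @param ref reference from [generate_reference()].
#' @param dir output directory.
#' @return list with `reads` (per-read truth `data.frame`), `truth_loci`
#'   (per-locus truth `data.frame`) and `paths`.
#' @export
simulate_reads <- function(spec, ref, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)
  genes <- ref$genes
  if (nrow(genes) == 0L) stop("reference has no rRNA genes")
  tx <- ref$transcripts

  n_amb <- round(spec$n_reads * spec$ambiguous_frac)
  n_decoy <- round(spec$n_reads * spec$decoy_frac)
  n_clean <- spec$n_reads - n_amb - n_decoy

  # plan distinct loci
  loci <- list()
  seen <- character()
  tries <- 0L
  while (length(loci) < spec$n_loci) {
    tries <- tries + 1L
    if (tries > 1000L * spec$n_loci) {
      stop("could not place ", spec$n_loci, " distinct loci")
    }
    gi <- sample(nrow(genes), 1L)
    L <- genes$length[gi]
    len <- resample1(spec$length_range[1L]:min(spec$length_range[2L], L - 2L))
    category <- sample(names(spec$category_mix), 1L,
                       prob = spec$category_mix)
    if (category == "rRF-5") {
      s <- 1L
    } else if (category == "rRF-3") {
      s <- L - len + 1L
    } else {
      s <- resample1(2L:(L - len))
    }
    e <- s + len - 1L
    sense <- stats::runif(1L) >= spec$antisense_frac
    key <- paste(genes$gene_id[gi], s, e, sense)
    if (key %in% seen) next
    seen <- c(seen, key)
    loci[[length(loci) + 1L]] <- list(gene_id = genes$gene_id[gi], gi = gi,
                                      gene_start = s, gene_end = e,
                                      sense = sense, category = category,
                                      length = len)
  }

  w <- stats::rgamma(spec$n_loci, shape = 2)
  counts <- as.vector(stats::rmultinom(1L, n_clean, w))

  reads <- list()
  read_no <- 0L
  next_id <- function() {
    read_no <<- read_no + 1L
    sprintf("read%06d", read_no)
  }
  for (li in seq_along(loci)) {
    lc <- loci[[li]]
    if (counts[li] == 0L) next
    base <- substr(tx[[lc$gene_id]], lc$gene_start, lc$gene_end)
    if (!lc$sense) base <- revcomp(base)
    n_var <- 0L
    var_seq <- NA_character_
    if (spec$minor_variant_frac > 0 && counts[li] >= 4L &&
        stats::runif(1L) < spec$minor_variant_frac) {
      n_var <- max(1L, floor(counts[li] * 0.2))
      var_seq <- substitute_base(base, sample(lc$length, 1L))
    }
    for (r in seq_len(counts[li])) {
      is_var <- r > counts[li] - n_var
      s <- if (is_var) var_seq else base
      nmis <- if (is_var) 1L else 0L
      if (!is_var && spec$mismatch_rate > 0) {
        pos <- which(stats::runif(lc$length) < spec$mismatch_rate)
        if (length(pos)) {
          s <- substitute_base(s, pos)
          nmis <- length(pos)
        }
      }
      reads[[length(reads) + 1L]] <- data.frame(
        read_id = next_id(), status = "clean", gene_id = lc$gene_id,
        category = lc$category, gene_start = lc$gene_start,
        gene_end = lc$gene_end, sense = lc$sense, sequence = s,
        length = lc$length, n_mismatches = nmis,
        decoy_chrom = NA_character_, decoy_start = NA_integer_,
        decoy_end = NA_integer_, decoy_strand = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  sample_decoy_interval <- function(len) {
    repeat {
      hdr <- sample(names(ref$genome), 1L,
                    prob = nchar(ref$genome))
      L <- nchar(ref$genome[[hdr]])
      if (L < len) next
      st <- sample(L - len + 1L, 1L)
      en <- st + len - 1L
      clash <- any(genes$fasta_header == hdr & genes$start <= en &
                     st <= genes$end)
      if (!clash) return(list(chrom = hdr, start = st, end = en))
    }
  }

  if (n_amb > 0L) {
    for (r in seq_len(n_amb)) {
      lc <- loci[[sample(spec$n_loci, 1L)]]
      base <- substr(tx[[lc$gene_id]], lc$gene_start, lc$gene_end)
      if (!lc$sense) base <- revcomp(base)
      iv <- sample_decoy_interval(lc$length)
      reads[[length(reads) + 1L]] <- data.frame(
        read_id = next_id(), status = "ambiguous", gene_id = lc$gene_id,
        category = lc$category, gene_start = lc$gene_start,
        gene_end = lc$gene_end, sense = lc$sense, sequence = base,
        length = lc$length, n_mismatches = 0L,
        decoy_chrom = iv$chrom, decoy_start = iv$start, decoy_end = iv$end,
        decoy_strand = "+", stringsAsFactors = FALSE)
    }
  }
  if (n_decoy > 0L) {
    for (r in seq_len(n_decoy)) {
      len <- resample1(spec$length_range[1L]:spec$length_range[2L])
      iv <- sample_decoy_interval(len)
      strand <- sample(c("+", "-"), 1L)
      s <- substr(ref$genome[[iv$chrom]], iv$start, iv$end)
      if (strand == "-") s <- revcomp(s)
      reads[[length(reads) + 1L]] <- data.frame(
        read_id = next_id(), status = "decoy", gene_id = NA_character_,
        category = NA_character_, gene_start = NA_integer_,
        gene_end = NA_integer_, sense = NA, sequence = s, length = len,
        n_mismatches = 0L, decoy_chrom = iv$chrom, decoy_start = iv$start,
        decoy_end = iv$end, decoy_strand = strand, stringsAsFactors = FALSE)
    }
  }

  reads <- do.call(rbind, reads)
  rownames(reads) <- NULL

  truth_loci <- truth_loci_from_reads(reads, loci, spec$library_total)

  paths <- list(fastq = file.path(dir, "reads.fastq"),
                truth_reads = file.path(dir, "truth_reads.tsv"),
                truth_loci = file.path(dir, "truth_loci.tsv"))
  fq <- character(4L * nrow(reads))
  fq[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  fq[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$sequence
  fq[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  fq[seq(4L, by = 4L, length.out = nrow(reads))] <- strrep("I", reads$length)
  writeLines(fq, paths$fastq)
  utils::write.table(reads, paths$truth_reads, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth_loci, paths$truth_loci, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(reads = reads, truth_loci = truth_loci, paths = paths)
}

# independent tabulation of the expected locus table (majority sequence,
# ties towards lower mismatch count then lexicographic order)
truth_loci_from_reads <- function(reads, loci, library_total) {
  clean <- reads[reads$status == "clean", , drop = FALSE]
  if (nrow(clean) == 0L) {
    return(data.frame(gene_id = character(), category = character(),
                      gene_start = integer(), gene_end = integer(),
                      sense = logical(), sequence = character(),
                      difference = integer(), seq_count = integer(),
                      count = integer(), rpm = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(clean$gene_id, clean$gene_start, clean$gene_end, clean$sense)
  rows <- lapply(split(seq_len(nrow(clean)), key), function(idx) {
    sub <- clean[idx, , drop = FALSE]
    tab <- table(sub$sequence)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      mm <- vapply(top, function(x) min(sub$n_mismatches[sub$sequence == x]),
                   0L)
      top <- sort(top[mm == min(mm)])
    }
    data.frame(gene_id = sub$gene_id[1L], category = sub$category[1L],
               gene_start = sub$gene_start[1L], gene_end = sub$gene_end[1L],
               sense = sub$sense[1L], sequence = top[[1L]],
               difference = min(sub$n_mismatches[sub$sequence == top[[1L]]]),
               seq_count = sum(sub$sequence == top[[1L]]),
               count = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rpm <- out$count / library_total * 1e6
  out <- out[order(out$gene_id, out$gene_start, out$gene_end, !out$sense), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit truth-placement SAM alignments for simulated reads
#'
#' Writes one SAM record per rRNA-derived read against the extracted
#' transcript reference (antisense reads get FLAG bit 16), a second
#' genomic record for ambiguous reads (secondary, NH=2), and a genomic
#' record for decoys. CIGAR is `<len>M` and NM carries the injected
#' mismatch count; no heuristic alignment is performed.
#'
#' @param sim result of [simulate_reads()].
#' @param ref result of [generate_reference()].
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
simulate_alignments <- function(sim, ref, path) {
  reads <- sim$reads
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref$genome), "\tLN:",
                  nchar(ref$genome)),
           paste0("@SQ\tSN:", ref$genes$gene_id, "\tLN:", ref$genes$length))
  qual <- strrep("I", reads$length)
  cigar <- paste0(reads$length, "M")
  recs <- character()

  rr <- reads$status %in% c("clean", "ambiguous")
  if (any(rr)) {
    flag <- ifelse(reads$sense[rr], 0L, 16L)
    seq_out <- ifelse(reads$sense[rr], reads$sequence[rr],
                      revcomp(reads$sequence[rr]))
    nh <- ifelse(reads$status[rr] == "ambiguous", 2L, 1L)
    recs <- c(recs, paste(
      reads$read_id[rr], flag, reads$gene_id[rr], reads$gene_start[rr],
      255L, cigar[rr], "*", 0L, 0L, seq_out, qual[rr],
      paste0("NM:i:", reads$n_mismatches[rr]), paste0("NH:i:", nh),
      sep = "\t"))
  }
  amb <- reads$status == "ambiguous"
  if (any(amb)) {
    flag <- 256L + ifelse(reads$decoy_strand[amb] == "-", 16L, 0L)
    seq_out <- ifelse(reads$decoy_strand[amb] == "-",
                      revcomp(reads$sequence[amb]), reads$sequence[amb])
    recs <- c(recs, paste(
      reads$read_id[amb], flag, reads$decoy_chrom[amb],
      reads$decoy_start[amb], 255L, cigar[amb], "*", 0L, 0L, seq_out,
      qual[amb], "NM:i:0", "NH:i:2", sep = "\t"))
  }
  dec <- reads$status == "decoy"
  if (any(dec)) {
    flag <- ifelse(reads$decoy_strand[dec] == "-", 16L, 0L)
    seq_out <- ifelse(reads$decoy_strand[dec] == "-",
                      revcomp(reads$sequence[dec]), reads$sequence[dec])
    recs <- c(recs, paste(
      reads$read_id[dec], flag, reads$decoy_chrom[dec],
      reads$decoy_start[dec], 255L, cigar[dec], "*", 0L, 0L, seq_out,
      qual[dec], "NM:i:0", "NH:i:1", sep = "\t"))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
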