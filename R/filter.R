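#' Define rRNA space for exclusivity testing
#'
#' rRNA space is the union of the extracted rRNA transcript references
#' (identified by `gene_id`) and the genomic intervals occupied by the
#' annotated rRNA genes, extended by the masking flank. Only the annotated
#' rRNA interval (plus flank, when configured) counts as rRNA space.
#'
#' @param genes rRNA gene table ([parse_feature_table()]).
#' @param flank flank width used during masking (default 0).
#' @return list with `gene_ids` and `intervals` (`data.frame` of
#'   `fasta_header`, `start`, `end`).
#' @export
rrna_space <- function(genes, flank = 0L) {
  list(gene_ids = genes$gene_id,
       intervals = data.frame(
         fasta_header = genes$fasta_header,
         start = pmax(1L, genes$start - as.integer(flank)),
         end = genes$end + as.integer(flank),
         stringsAsFactors = FALSE))
}

in_rrna_space <- function(alignments, space) {
  inr <- alignments$target_id %in% space$gene_ids
  gen <- which(!inr)
  if (length(gen)) {
    iv <- space$intervals
    inr[gen] <- vapply(gen, function(i) {
      any(iv$fasta_header == alignments$target_id[i] &
            iv$start <= alignments$target_start[i] &
            alignments$target_end[i] <= iv$end)
    }, logical(1L))
  }
  inr
}

#' Partition reads by exclusivity of rRNA-space mapping
#'
#' A read is retained only if all of its reported alignments fall inside
#' rRNA space; reads with a mixture of rRNA and non-rRNA alignments are
#' ambiguous and dropped, and reads aligning only outside rRNA space are
#' non-rRNA. This prevents ambiguous reads from non-rRNA regions from
#' contaminating downstream rsRNA calls.
#'
#' @param alignments alignment table from [read_alignments()].
#' @param space rRNA space from [rrna_space()].
#' @return list with `retained` (alignment rows of exclusively-mapping
#'   reads) and `stats`, an `exclusivity_stats` list with
#'   `n_total_reads`, `n_rrna_exclusive`, `n_ambiguous`, `n_non_rrna`.
#' @export
partition_rrna_exclusive <- function(alignments, space) {
  inr <- in_rrna_space(alignments, space)
  ids <- alignments$read_id
  all_in <- tapply(inr, ids, all)
  any_in <- tapply(inr, ids, any)
  uids <- names(all_in)
  status <- ifelse(all_in, "rrna_exclusive",
                   ifelse(any_in, "ambiguous", "non_rrna"))
  retained_ids <- uids[status == "rrna_exclusive"]
  stats <- structure(list(
    n_total_reads = length(uids),
    n_rrna_exclusive = sum(status == "rrna_exclusive"),
    n_ambiguous = sum(status == "ambiguous"),
    n_non_rrna = sum(status == "non_rrna")),
    class = "exclusivity_stats")
  list(retained = alignments[ids %in% retained_ids, , drop = FALSE],
       stats = stats)
}

#' @export
print.exclusivity_stats <- function(x, ...) {
  cat(sprintf(
    "Exclusivity: %d reads; %d rRNA-exclusive (%.1f%%), %d ambiguous, %d non-rRNA\n",
    x$n_total_reads, x$n_rrna_exclusive,
    if (x$n_total_reads > 0) 100 * x$n_rrna_exclusive / x$n_total_reads else 0,
    x$n_ambiguous, x$n_non_rrna))
  invisible(x)
}

#' Convert alignments to transcript-relative (gene) coordinates
#'
#' Alignments may target the extracted rRNA transcripts directly (target id
#' is a `gene_id`) or the genome; both are normalized to 1-based transcript
#' coordinates where position 1 is the transcript 5' end. For a
#' minus-strand gene mapped genomically, `gene_start = gene_end_genomic -
#' target_end + 1` and `gene_end = gene_end_genomic - target_start + 1`.
#' `sense` is TRUE when the read strand matches the gene strand.
#' Genomically-mapped reads that hang off a transcript end are dropped
#' with a warning (fragment categories are defined only within the
#' transcript).
#'
#' @param alignments alignment table (typically the `retained` element of
#'   [partition_rrna_exclusive()]).
#' @param genes rRNA gene table.
#' @return `data.frame` with one row per alignment: `read_id`, `sequence`,
#'   `gene_id`, `gene_start`, `gene_end`, `sense`, `difference`,
#'   `hit_count`, plus genomic coordinates `fasta_header`,
#'   `genomic_start`, `genomic_end`, `genomic_strand`.
#' @export
gene_relative_coords <- function(alignments, genes) {
  n <- nrow(alignments)
  gidx <- match(alignments$target_id, genes$gene_id)
  is_tx <- !is.na(gidx)
  gs <- integer(n)
  ge <- integer(n)
  sense <- logical(n)
  keep <- rep(TRUE, n)

  # genomic targets: locate the containing gene (genomic reads are the
  # minority; transcript hits dominate)
  for (i in which(!is_tx)) {
    hit <- which(genes$fasta_header == alignments$target_id[i] &
                   genes$start <= alignments$target_end[i] &
                   alignments$target_start[i] <= genes$end)
    if (length(hit) == 0L) {
      stop("alignment of read ", alignments$read_id[i], " at ",
           alignments$target_id[i], ":", alignments$target_start[i], "-",
           alignments$target_end[i], " overlaps no annotated rRNA gene")
    }
    gidx[i] <- hit[1L]
    if (alignments$target_start[i] < genes$start[hit[1L]] ||
        alignments$target_end[i] > genes$end[hit[1L]]) {
      keep[i] <- FALSE  # hangs off the transcript end
    }
  }
  g <- genes[gidx, , drop = FALSE]

  t <- which(is_tx)
  if (length(t)) {
    gs[t] <- alignments$target_start[t]
    ge[t] <- alignments$target_end[t]
    bad <- t[gs[t] < 1L | ge[t] > g$length[t]]
    if (length(bad)) {
      stop("alignment of read ", alignments$read_id[bad[1L]],
           " lies outside transcript ", g$gene_id[bad[1L]])
    }
    sense[t] <- alignments$strand[t] == "+"
  }
  w <- which(!is_tx & keep)
  if (length(w)) {
    plus <- g$strand[w] == "+"
    gs[w] <- ifelse(plus, alignments$target_start[w] - g$start[w] + 1L,
                    g$end[w] - alignments$target_end[w] + 1L)
    ge[w] <- ifelse(plus, alignments$target_end[w] - g$start[w] + 1L,
                    g$end[w] - alignments$target_start[w] + 1L)
    sense[w] <- alignments$strand[w] == g$strand[w]
  }
  if (any(!keep)) {
    warning("dropped ", sum(!keep),
            " alignment(s) hanging off a transcript end")
  }

  # genomic footprint of the transcript window, on the gene's chromosome
  plus <- g$strand == "+"
  gstart <- ifelse(plus, g$start + gs - 1L, g$end - ge + 1L)
  gend <- ifelse(plus, g$start + ge - 1L, g$end - gs + 1L)
  gstrand <- ifelse(sense, g$strand, ifelse(g$strand == "+", "-", "+"))

  res <- data.frame(
    read_id = alignments$read_id, sequence = alignments$sequence,
    gene_id = g$gene_id, gene_start = gs, gene_end = ge, sense = sense,
    difference = alignments$difference, hit_count = alignments$hit_count,
    fasta_header = g$fasta_header,
    genomic_start = as.integer(gstart), genomic_end = as.integer(gend),
    genomic_strand = gstrand, stringsAsFactors = FALSE)
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
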