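#' Classify a fragment by its position on the rRNA transcript
#'
#' Fragments starting at transcript position 1 are 5'-anchored (`rRF-5`);
#' fragments ending at the final transcript position (without starting at
#' 1) are 3'-anchored (`rRF-3`); everything else is internal (`rRF-i`).
#' Full-span fragments (position 1 to the transcript end) take the
#' `full_span` category, `rRF-5` by default, consistent with the strong 5'
#' skew of observed rsRNA populations.
#'
#' @param gene_start,gene_end 1-based transcript coordinates (vectors).
#' @param gene_length transcript length(s) in nucleotides.
#' @param full_span category assigned to full-span fragments.
#' @return character vector of categories.
#' @export
classify_rrf <- function(gene_start, gene_end, gene_length,
                         full_span = "rRF-5") {
  full_span <- match.arg(full_span, c("rRF-5", "rRF-3", "rRF-i"))
  if (any(gene_start < 1L | gene_end > gene_length | gene_start > gene_end)) {
    stop("coordinates outside [1, gene_length]")
  }
  ifelse(gene_start == 1L & gene_end == gene_length, full_span,
         ifelse(gene_start == 1L, "rRF-5",
                ifelse(gene_end == gene_length, "rRF-3", "rRF-i")))
}

#' Filter read-level records by read length
#'
#' rsRNAs range from 16 to 40 nucleotides; both bounds are inclusive.
#'
#' @param records `data.frame` with a `sequence` column.
#' @param range length bounds, default `c(16, 40)`.
#' @return filtered `data.frame`.
#' @export
length_filter <- function(records, range = c(16L, 40L)) {
  len <- nchar(records$sequence)
  out <- records[len >= range[1L] & len <= range[2L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate classified reads into loci with a predominant sequence
#'
#' Reads are grouped by (`gene_id`, `gene_start`, `gene_end`, `sense`).
#' Each locus reports `count` (all reads in the group), a representative
#' `sequence` (the most frequent unique sequence; ties broken towards the
#' lower difference, then lexicographically), `seq_count` (reads carrying
#' the representative sequence) and `difference` (the smallest difference
#' among reads carrying the representative sequence).
#'
#' @param reads read-level table from [gene_relative_coords()].
#' @return locus-level `data.frame`.
#' @export
aggregate_loci <- function(reads) {
  if (nrow(reads) == 0L) {
    return(cbind(reads[, c("gene_id", "gene_start", "gene_end", "sense",
                           "fasta_header", "genomic_start", "genomic_end",
                           "genomic_strand")],
                 data.frame(sequence = character(), difference = integer(),
                            seq_count = integer(), count = integer())))
  }
  key <- paste(reads$gene_id, reads$gene_start, reads$gene_end, reads$sense,
               sep = "\r")
  groups <- split(seq_len(nrow(reads)), key)
  rows <- lapply(groups, function(idx) {
    sub <- reads[idx, , drop = FALSE]
    seq_tab <- table(sub$sequence)
    top <- names(seq_tab)[seq_tab == max(seq_tab)]
    if (length(top) > 1L) {
      mindiff <- vapply(top, function(s) min(sub$difference[sub$sequence == s]),
                        0L)
      top <- top[mindiff == min(mindiff)]
      top <- sort(top)
    }
    rep_seq <- top[[1L]]
    data.frame(
      gene_id = sub$gene_id[1L], gene_start = sub$gene_start[1L],
      gene_end = sub$gene_end[1L], sense = sub$sense[1L],
      fasta_header = sub$fasta_header[1L],
      genomic_start = sub$genomic_start[1L],
      genomic_end = sub$genomic_end[1L],
      genomic_strand = sub$genomic_strand[1L],
      sequence = rep_seq,
      difference = min(sub$difference[sub$sequence == rep_seq]),
      seq_count = sum(sub$sequence == rep_seq),
      count = nrow(sub),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$gene_start, out$gene_end, !out$sense), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads-per-million normalization
#'
#' `rpm = count / library_total * 1e6`.
#'
#' @param count read count(s) at a locus.
#' @param library_total total number of small-RNA reads in the library.
#' @return numeric RPM value(s).
#' @export
compute_rpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  count / library_total * 1e6
}

#' Library-level quantification context
#'
#' @param library_total RPM denominator (total reads in the library).
#' @param min_rpm minimum abundance, inclusive (default 10).
#' @param max_difference maximum difference, exclusive (default 4: loci
#'   with fewer than 4 differences are kept).
#' @param length_range inclusive read-length bounds (default 16-40).
#' @return list of class `library_context`.
#' @export
library_context <- function(library_total, min_rpm = 10,
                            max_difference = 4L,
                            length_range = c(16L, 40L)) {
  stopifnot(library_total > 0, min_rpm >= 0,
            length(length_range) == 2L, length_range[1L] <= length_range[2L])
  structure(list(library_total = library_total, min_rpm = min_rpm,
                 max_difference = max_difference,
                 length_range = length_range),
            class = "library_context")
}

#' Retain confident rsRNA loci
#'
#' Applies the confidence thresholds: difference strictly below
#' `max_difference` and RPM at least `min_rpm`. Where several loci share
#' identical genomic coordinates and strand, the low-abundance co-located
#' entries are dropped but their reads are folded into the surviving
#' locus's `count` (and its RPM recomputed), so the overall read count is
#' maintained.
#'
#' @param loci locus table from [aggregate_loci()].
#' @param ctx a [library_context()].
#' @return confident locus table with an `rpm` column, sorted by
#'   (`gene_id`, `gene_start`).
#' @export
filter_confident <- function(loci, ctx) {
  stopifnot(inherits(ctx, "library_context"))
  loci <- loci[loci$difference < ctx$max_difference, , drop = FALSE]
  if (nrow(loci) > 0L) {
    loci$rpm <- compute_rpm(loci$count, ctx$library_total)
    key <- paste(loci$fasta_header, loci$genomic_start, loci$genomic_end,
                 loci$genomic_strand, sep = "\r")
    merged <- lapply(split(seq_len(nrow(loci)), key), function(idx) {
      if (length(idx) == 1L) return(loci[idx, , drop = FALSE])
      sub <- loci[idx, , drop = FALSE]
      sub <- sub[order(-sub$rpm, sub$sequence), , drop = FALSE]
      sub$count[1L] <- sum(sub$count)
      sub[1L, , drop = FALSE]
    })
    loci <- do.call(rbind, merged)
    loci$rpm <- compute_rpm(loci$count, ctx$library_total)
  } else {
    loci$rpm <- numeric(0)
  }
  loci <- loci[loci$rpm >= ctx$min_rpm, , drop = FALSE]
  loci <- loci[order(loci$gene_id, loci$gene_start, loci$gene_end), ,
               drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Annotate rsRNA records with rRNA modification-site overlap
#'
#' A site overlaps a record when it lies on the same gene and its 1-based
#' transcript position falls inside `[gene_start, gene_end]`. Totals count
#' distinct sites overlapped by at least one record, per modification
#' type.
#'
#' @param records rsRNA record table (rows carry `gene_id`, `gene_start`,
#'   `gene_end`).
#' @param sites `data.frame` with columns `gene_id`, `position` (1-based
#'   transcript coordinate) and `type` (e.g. `"methylation"`,
#'   `"pseudouridylation"`).
#' @param genes optional gene table; when given, sites whose position
#'   exceeds the gene length are skipped with a warning.
#' @return list with `per_record` (list, one integer vector of site row
#'   indices per record) and `totals` (named integer vector per type).
#' @export
annotate_modification_overlap <- function(records, sites, genes = NULL) {
  if (!is.null(genes)) {
    glen <- genes$length[match(sites$gene_id, genes$gene_id)]
    bad <- !is.na(glen) & (sites$position < 1L | sites$position > glen)
    if (any(bad)) {
      warning("skipping ", sum(bad), " modification site(s) outside gene bounds")
      sites <- sites[!bad, , drop = FALSE]
    }
  }
  per_record <- lapply(seq_len(nrow(records)), function(i) {
    which(sites$gene_id == records$gene_id[i] &
            sites$position >= records$gene_start[i] &
            sites$position <= records$gene_end[i])
  })
  hit_sites <- unique(unlist(per_record))
  types <- sort(unique(as.character(sites$type)))
  totals <- vapply(types, function(tp) {
    sum(sites$type[hit_sites] == tp)
  }, integer(1L))
  list(per_record = per_record, totals = totals)
}

#' Read a modification-site table
#'
#' Expects a TSV with three columns: rRNA gene id, 1-based transcript
#' position, and modification type.
#'
#' @param path TSV file.
#' @return `data.frame` with `gene_id`, `position`, `type`.
#' @export
read_modification_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("gene_id", "position", "type")
  df$position <- as.integer(df$position)
  df
}
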