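#' Read a genome FASTA into a named character vector
#'
#' Headers are truncated at the first whitespace, matching common aligner
#' behaviour.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  toupper(as.character(set))
}

#' Write named sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome) || is.null(names(genome))) {
    stop("genome must be a named character vector or DNAStringSet")
  }
  toupper(genome)
}

#' Mask rRNA genes in a genome to build an artificial reference
#'
#' Replaces every base inside each gene interval, extended by `flank`
#' nucleotides on both sides and clipped at the sequence ends, with `'N'`.
#' Overlapping masked intervals merge; masking is idempotent and preserves
#' sequence lengths. The resulting "artificial" genome makes rRNA-space vs
#' genome-space read origin unambiguous: a read can only align to rRNA
#' sequence via the separate transcript reference.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences keyed by FASTA header.
#' @param genes rRNA gene table as returned by [parse_feature_table()].
#' @param flank non-negative flank width in nucleotides (default 0).
#' @return list of class `masked_genome` with elements `sequences` (named
#'   character vector, same lengths as input) and `mask_log` (`data.frame`
#'   with `fasta_header`, `masked_start`, `masked_end`, `gene_id`; one row
#'   per gene, coordinates 1-based inclusive after flank clipping).
#' @export
mask_genome <- function(genome, genes, flank = 0L) {
  genome <- as_genome(genome)
  stopifnot(flank >= 0)
  absent <- setdiff(genes$fasta_header, names(genome))
  if (length(absent)) {
    bad <- genes$gene_id[genes$fasta_header %in% absent]
    stop("gene(s) ", paste(bad, collapse = ", "),
         " lie on header(s) absent from the genome: ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(genes)
  masked_start <- integer(n)
  masked_end <- integer(n)
  if (n > 0L) {
    seq_len_of <- nchar(genome)[genes$fasta_header]
    masked_start <- pmax(1L, genes$start - as.integer(flank))
    masked_end <- pmin(seq_len_of, genes$end + as.integer(flank))
  }
  log <- data.frame(
    fasta_header = as.character(genes$fasta_header),
    masked_start = as.integer(masked_start),
    masked_end = as.integer(masked_end),
    gene_id = as.character(genes$gene_id),
    stringsAsFactors = FALSE)
  sequences <- genome
  for (hdr in unique(log$fasta_header)) {
    iv <- log[log$fasta_header == hdr, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(iv$masked_start, iv$masked_end))
    s <- sequences[[hdr]]
    for (k in seq_along(merged)) {
      st <- IRanges::start(merged)[k]
      en <- IRanges::end(merged)[k]
      substr(s, st, en) <- strrep("N", en - st + 1L)
    }
    sequences[[hdr]] <- s
  }
  structure(list(sequences = sequences, mask_log = log),
            class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  cat("Artificial (rRNA-masked) genome:", length(x$sequences),
      "sequence(s),", nrow(x$mask_log), "masked interval(s)\n")
  invisible(x)
}

#' Extract rRNA transcript sequences from a genome
#'
#' One record per gene, named by `gene_id`. Minus-strand genes are
#' reverse-complemented so that position 1 of every returned sequence is
#' the transcript 5' end. These transcripts form the rRNA reference that
#' accompanies the masked genome during alignment.
#'
#' @inheritParams mask_genome
#' @return named character vector of transcript sequences.
#' @export
extract_rrna_sequences <- function(genome, genes) {
  genome <- as_genome(genome)
  absent <- setdiff(genes$fasta_header, names(genome))
  if (length(absent)) {
    bad <- genes$gene_id[genes$fasta_header %in% absent]
    stop("gene(s) ", paste(bad, collapse = ", "),
         " lie on header(s) absent from the genome: ",
         paste(absent, collapse = ", "))
  }
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- substr(genome[[genes$fasta_header[i]]], genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") s <- revcomp(s)
    out[i] <- s
  }
  names(out) <- genes$gene_id
  out
}

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write the mask log as a BED file
#'
#' Coordinates are emitted 0-based half-open per the BED convention.
#'
#' @param masked a `masked_genome` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_log <- function(masked, path) {
  log <- masked$mask_log
  bed <- data.frame(log$fasta_header, log$masked_start - 1L, log$masked_end,
                    log$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
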