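#' Map an NCBI chromosome label to a canonical FASTA header
#'
#' Genome FASTA headers follow the `chr<integer>` / `chrMt` / `chrPt`
#' convention, while NCBI assembly feature tables use bare labels such as
#' `"1"`, `"MT"` or `"Pltd"`. This helper normalizes a label to the
#' corresponding header, with organellar synonyms recognized
#' case-insensitively. Unmappable labels give `NA`.
#'
#' @param label character vector of chromosome labels.
#' @param header_map optional named character vector of user overrides,
#'   `label -> fasta_header`; exact matches win over the built-in rules.
#' @return character vector of FASTA headers (`NA` where unmappable).
#' @export
map_chromosome_label <- function(label, header_map = NULL) {
  label <- as.character(label)
  out <- rep(NA_character_, length(label))
  if (!is.null(header_map)) {
    hit <- match(label, names(header_map))
    out[!is.na(hit)] <- unname(header_map[hit[!is.na(hit)]])
  }
  todo <- is.na(out)
  stripped <- sub("^chr", "", label, ignore.case = TRUE)
  mt <- tolower(stripped) %in% c("mt", "mitochondrion", "mito")
  pt <- tolower(stripped) %in% c("pltd", "pt", "chloroplast", "plastid")
  num <- grepl("^[0-9]+$", stripped)
  out[todo & mt] <- "chrMt"
  out[todo & pt] <- "chrPt"
  out[todo & !mt & !pt & num] <- paste0("chr", stripped[todo & !mt & !pt & num])
  out
}

#' Parse rRNA genes from an NCBI assembly feature table
#'
#' Reads a tab-delimited NCBI assembly feature table (the
#' `*_feature_table.txt` file distributed with RefSeq assemblies), keeps the
#' rows whose `feature` field equals `"rRNA"` and returns them as a gene
#' table. The rRNA feature row carries the transcript interval; `gene` rows
#' of class rRNA are deliberately ignored to avoid double-counting.
#'
#' @param path path to the feature table (plain text, `#`-prefixed header
#'   line starting with `# feature`).
#' @param header_map optional named character vector mapping feature-table
#'   chromosome labels to FASTA headers (see [map_chromosome_label()]).
#' @return a `data.frame` with one row per rRNA gene and columns
#'   `gene_id`, `chromosome`, `fasta_header`, `start`, `end`, `strand`,
#'   `rrna_type`, `origin`, `length`, ordered by (`fasta_header`, `start`).
#'   Rows on chromosomes that cannot be mapped to a header are skipped with
#'   a warning.
#' @export
parse_feature_table <- function(path, header_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#\\s*feature", lines)
  if (length(hdr_idx) == 0L) {
    stop("feature-table format error: no header line starting with '# feature' in ", path)
  }
  cols <- strsplit(sub("^#\\s*", "", lines[hdr_idx[1L]]), "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(cols)) {
    stop("feature-table format error: duplicate column names: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  required <- c("feature", "chromosome", "start", "end", "strand")
  missing <- setdiff(required, cols)
  if (length(missing)) {
    stop("feature-table format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  body <- lines[-seq_len(hdr_idx[1L])]
  body <- body[!grepl("^#", body) & nzchar(body)]
  empty_genes <- data.frame(
    gene_id = character(), chromosome = character(), fasta_header = character(),
    start = integer(), end = integer(), strand = character(),
    rrna_type = character(), origin = character(), length = integer(),
    stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty_genes)

  fields <- strsplit(body, "\t", fixed = TRUE)
  get <- function(rec, col) {
    i <- match(col, cols)
    if (length(rec) >= i) rec[[i]] else ""
  }
  feat <- vapply(fields, get, "", col = "feature")
  keep <- which(feat == "rRNA")
  if (length(keep) == 0L) return(empty_genes)

  rows <- lapply(keep, function(i) {
    rec <- fields[[i]]
    chrom <- get(rec, "chromosome")
    start <- suppressWarnings(as.integer(get(rec, "start")))
    end <- suppressWarnings(as.integer(get(rec, "end")))
    strand <- get(rec, "strand")
    if (is.na(start) || is.na(end) || start > end) {
      stop("feature-table record error: bad interval in data row ", i,
           " (chromosome ", chrom, ", start ", get(rec, "start"),
           ", end ", get(rec, "end"), ")")
    }
    if (!strand %in% c("+", "-")) {
      stop("feature-table record error: strand '", strand, "' in data row ", i)
    }
    name <- get(rec, "name")
    symbol <- get(rec, "symbol")
    locus_tag <- get(rec, "locus_tag")
    type <- regmatches(name, regexpr("[0-9]+(\\.[0-9]+)?S", name))
    if (length(type) == 0L || !nzchar(type)) {
      type <- regmatches(symbol, regexpr("[0-9]+(\\.[0-9]+)?S", symbol))
    }
    list(chromosome = chrom, start = start, end = end, strand = strand,
         rrna_type = if (length(type) && nzchar(type)) type[[1L]] else "rRNA",
         locus_tag = locus_tag, name = name)
  })
  chrom <- vapply(rows, `[[`, "", "chromosome")
  fasta_header <- map_chromosome_label(chrom, header_map)
  unmapped <- is.na(fasta_header)
  if (any(unmapped)) {
    warning("skipping ", sum(unmapped), " rRNA row(s) on unmapped chromosome label(s): ",
            paste(unique(chrom[unmapped]), collapse = ", "))
    rows <- rows[!unmapped]
    chrom <- chrom[!unmapped]
    fasta_header <- fasta_header[!unmapped]
  }
  if (length(rows) == 0L) return(empty_genes)
  start <- vapply(rows, `[[`, 0L, "start")
  end <- vapply(rows, `[[`, 0L, "end")
  locus_tag <- vapply(rows, `[[`, "", "locus_tag")
  gene_id <- ifelse(nzchar(locus_tag), locus_tag,
                    paste0(vapply(rows, `[[`, "", "rrna_type"), "_",
                           fasta_header, "_", start, "_", end))
  genes <- data.frame(
    gene_id = gene_id,
    chromosome = chrom,
    fasta_header = fasta_header,
    start = start,
    end = end,
    strand = vapply(rows, `[[`, "", "strand"),
    rrna_type = vapply(rows, `[[`, "", "rrna_type"),
    origin = origin_from_header(fasta_header),
    length = end - start + 1L,
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$fasta_header, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

origin_from_header <- function(fasta_header) {
  ifelse(fasta_header == "chrMt", "mitochondrial",
         ifelse(fasta_header == "chrPt", "chloroplastic", "nuclear"))
}

#' Validate genome FASTA headers against the naming convention
#'
#' Headers must match `chr<integer>` (zero padding allowed), `chrMt`
#' (mitochondrion) or `chrPt` (plastid).
#'
#' @param headers character vector of FASTA headers, or a
#'   `Biostrings::DNAStringSet` whose names are checked.
#' @return list with `valid` (logical scalar) and `violations` (character
#'   vector of offending headers; empty iff valid).
#' @export
validate_genome_headers <- function(headers) {
  if (inherits(headers, "DNAStringSet")) headers <- names(headers)
  ok <- grepl("^chr([0-9]+|Mt|Pt)$", headers)
  list(valid = all(ok), violations = headers[!ok])
}
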