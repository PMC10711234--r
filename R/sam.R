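cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) stop("invalid CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  list(op = op, len = len)
}

cigar_ref_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

md_mismatches <- function(md) {
  # MD grammar: [0-9]+ ( [A-Z] | \^[A-Z]+ )* — bare letters are mismatches,
  # ^-prefixed runs are deletions from the reference.
  md <- gsub("\\^[A-Z]+", "", md)
  nchar(gsub("[0-9]", "", md))
}

#' Count alignment differences (mismatches + inserted + deleted bases)
#'
#' The per-alignment "difference" is the edit distance between read and
#' reference over the aligned portion: mismatching bases plus inserted plus
#' deleted bases. The aligner-reported `NM` tag is authoritative when
#' present; otherwise mismatches are recovered from the `MD` tag (or from
#' explicit `X` CIGAR operations) and combined with the CIGAR's `I`/`D`
#' base counts. Soft-clipped bases are not differences.
#'
#' @param cigar CIGAR string.
#' @param nm optional integer `NM` tag value.
#' @param md optional `MD` tag string.
#' @return integer difference count.
#' @export
compute_difference <- function(cigar, nm = NA, md = NA) {
  if (!is.na(nm)) return(as.integer(nm))
  ops <- cigar_ops(cigar)
  ins <- sum(ops$len[ops$op == "I"])
  del <- sum(ops$len[ops$op == "D"])
  if (!is.na(md) && nzchar(md)) {
    return(as.integer(md_mismatches(md) + ins + del))
  }
  if (any(ops$op == "M")) {
    stop("difference undeterminable: no NM or MD tag and CIGAR '", cigar,
         "' uses M (match-or-mismatch) operations")
  }
  as.integer(sum(ops$len[ops$op == "X"]) + ins + del)
}

sam_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub("^..:.:", "", hit[[1L]])
}

#' Read SAM/BAM alignments into an alignment table
#'
#' Parses mapped records from a SAM (plain text) or BAM file into a
#' `data.frame` of per-alignment rows. Unmapped records are skipped but
#' counted towards the library total; records without a CIGAR are skipped
#' with a warning. The read sequence is reported in as-sequenced
#' orientation (reverse-complemented back for reverse-strand alignments).
#'
#' @param path SAM or BAM file.
#' @return `data.frame` with columns `read_id`, `sequence`, `target_id`,
#'   `target_start`, `target_end` (1-based inclusive), `strand` (`+`/`-`
#'   relative to target), `difference`, `hit_count` (NH tag when present,
#'   else the number of records sharing the read id). Attribute
#'   `total_reads` carries the number of distinct read ids seen, mapped or
#'   not, for use as an RPM denominator.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    recs <- read_bam_records(path)
  } else {
    recs <- read_sam_records(path)
  }
  recs
}

empty_alignments <- function(total_reads = 0L) {
  out <- data.frame(read_id = character(), sequence = character(),
                    target_id = character(), target_start = integer(),
                    target_end = integer(), strand = character(),
                    difference = integer(), hit_count = integer(),
                    stringsAsFactors = FALSE)
  attr(out, "total_reads") <- total_reads
  out
}

finish_alignments <- function(read_id, sequence, target_id, target_start,
                              cigar, flag, nm, md, nh, all_qnames) {
  n <- length(read_id)
  if (n == 0L) return(empty_alignments(length(unique(all_qnames))))
  target_end <- target_start +
    vapply(cigar, cigar_ref_span, 0L, USE.NAMES = FALSE) - 1L
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  seq_out <- sequence
  rev <- strand == "-" & !is.na(sequence) & sequence != "*"
  if (any(rev)) seq_out[rev] <- revcomp(sequence[rev])
  difference <- mapply(compute_difference, cigar, nm, md, USE.NAMES = FALSE)
  hit_count <- nh
  missing_nh <- is.na(hit_count)
  if (any(missing_nh)) {
    tab <- table(read_id)
    hit_count[missing_nh] <- as.integer(tab[read_id[missing_nh]])
  }
  out <- data.frame(read_id = read_id, sequence = seq_out,
                    target_id = target_id, target_start = target_start,
                    target_end = target_end, strand = strand,
                    difference = as.integer(difference),
                    hit_count = as.integer(hit_count),
                    stringsAsFactors = FALSE)
  attr(out, "total_reads") <- length(unique(all_qnames))
  out
}

read_sam_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  if (length(body_idx) == 0L) return(empty_alignments())
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- body_idx[which(nf < 11L)[1L]]
    stop("malformed SAM line ", bad, " in ", path, ": fewer than 11 fields")
  }
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(flag)) {
    bad <- body_idx[which(is.na(flag))[1L]]
    stop("malformed SAM line ", bad, " in ", path, ": non-integer FLAG")
  }
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- vapply(fields, `[[`, "", 6L)
  no_cigar <- mapped & cigar == "*"
  if (any(no_cigar)) {
    warning("skipping ", sum(no_cigar), " mapped record(s) without CIGAR in ",
            path)
  }
  keep <- mapped & !no_cigar
  f <- fields[keep]
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  tags <- lapply(f, function(x) if (length(x) > 11L) x[12:length(x)] else character())
  nm <- suppressWarnings(as.integer(vapply(tags, sam_tag, "", tag = "NM")))
  md <- vapply(tags, sam_tag, "", tag = "MD")
  nh <- suppressWarnings(as.integer(vapply(tags, sam_tag, "", tag = "NH")))
  finish_alignments(
    read_id = qname[keep],
    sequence = vapply(f, `[[`, "", 10L),
    target_id = vapply(f, `[[`, "", 3L),
    target_start = pos,
    cigar = cigar[keep],
    flag = flag[keep],
    nm = nm, md = md, nh = nh,
    all_qnames = qname)
}

read_bam_records <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "MD", "NH"))
  res <- Rsamtools::scanBam(path, param = p)[[1L]]
  mapped <- bitwAnd(res$flag, 4L) == 0L & !is.na(res$pos)
  finish_alignments(
    read_id = res$qname[mapped],
    sequence = as.character(res$seq)[mapped],
    target_id = as.character(res$rname)[mapped],
    target_start = res$pos[mapped],
    cigar = res$cigar[mapped],
    flag = res$flag[mapped],
    nm = if (is.null(res$tag$NM)) rep(NA_integer_, sum(mapped)) else res$tag$NM[mapped],
    md = if (is.null(res$tag$MD)) rep(NA_character_, sum(mapped)) else res$tag$MD[mapped],
    nh = if (is.null(res$tag$NH)) rep(NA_integer_, sum(mapped)) else res$tag$NH[mapped],
    all_qnames = res$qname)
}
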