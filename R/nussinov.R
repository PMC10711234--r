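rna_pairs <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE, GU = TRUE,
               UG = TRUE)

can_pair <- function(a, b) {
  isTRUE(rna_pairs[paste0(a, b)])
}

#' Predict a secondary structure in dot-bracket notation
#'
#' Base-pair maximization (Nussinov dynamic programming) over canonical
#' Watson-Crick pairs plus the G-U wobble, with a minimum hairpin loop of
#' `min_loop` unpaired bases. The traceback is deterministic: when several
#' structures achieve the maximal pair count, the pairing that closes
#' earliest wins (leftmost 5' partner, then smallest 3' partner). `T` is
#' read as `U`. A `fold_fun` hook allows plugging in an external
#' (e.g. thermodynamic) folding engine returning a dot-bracket string.
#'
#' @param sequence RNA/DNA string over `A`, `C`, `G`, `U`/`T`.
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @param fold_fun optional function `sequence -> dot-bracket string`.
#' @return dot-bracket string of the same length as `sequence`.
#' @export
fold_dot_bracket <- function(sequence, min_loop = 3L, fold_fun = NULL) {
  if (!is.null(fold_fun)) return(fold_fun(sequence))
  s <- chartr("tT", "uU", sequence)
  b <- strsplit(toupper(s), "")[[1L]]
  if (length(b) && any(!b %in% c("A", "C", "G", "U"))) {
    stop("non-nucleotide character in sequence: ",
         paste(unique(b[!b %in% c("A", "C", "G", "U")]), collapse = ", "))
  }
  n <- length(b)
  if (n == 0L) return("")
  N <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 2L):n) {
      for (i in seq_len(n - span + 1L)) {
        j <- i + span - 1L
        best <- N[i + 1L, j]
        for (k in (i + min_loop + 1L):j) {
          if (can_pair(b[i], b[k])) {
            v <- 1L +
              (if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L) +
              (if (k + 1L <= j) N[k + 1L, j] else 0L)
            if (v > best) best <- v
          }
        }
        N[i, j] <- best
      }
    }
  }
  struct <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      target <- N[i, j]
      if (target == 0L) return(invisible())
      paired <- FALSE
      if (j - i > min_loop) {
        for (k in (i + min_loop + 1L):j) {
          if (can_pair(b[i], b[k])) {
            v <- 1L +
              (if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L) +
              (if (k + 1L <= j) N[k + 1L, j] else 0L)
            if (v == target) {
              struct[i] <<- "("
              struct[k] <<- ")"
              if (k - 1L >= i + 1L) trace(i + 1L, k - 1L)
              i <- k + 1L
              paired <- TRUE
              break
            }
          }
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  trace(1L, n)
  paste(struct, collapse = "")
}

#' Count base pairs in a dot-bracket string
#'
#' @param db dot-bracket string.
#' @return integer pair count.
#' @export
count_pairs <- function(db) {
  lengths(regmatches(db, gregexpr("(", db, fixed = TRUE)))
}
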