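# Progressive multiple alignment of per-genome flanks and degenerate
# consensus calling.
#
# The aligner is a deterministic progressive scheme: all pairwise global
# alignments (match +1, mismatch -1, gap open -4, gap extend -1) give a
# similarity matrix; sequences are joined most-central-first (ties broken by
# sequence content, then name, so the result does not depend on input
# order); each sequence is aligned to the growing profile.

MSA_MATCH <- 1
MSA_MISMATCH <- 1
MSA_GAP_OPEN <- 4
MSA_GAP_EXT <- 1

profile_matrix <- function(rows) {
  # rows: character matrix (sequences x columns)
  prof <- matrix(0, 5, ncol(rows))
  keys <- c("A", "C", "G", "T", "-")
  for (k in seq_along(keys)) {
    prof[k, ] <- colMeans(rows == keys[k])
  }
  prof
}

#' Multiple alignment of per-genome flank sequences
#'
#' @param flanks named character vector (genome_id -> DNA string), at least
#'   one sequence; a single sequence yields a degenerate alignment equal to
#'   the input, with a warning.
#' @return an object of class `flank_alignment`: list with `rows` (named
#'   character vector of equal-length gapped sequences) and `ncol`.
#' @export
align_flanks <- function(flanks) {
  stopifnot(is.character(flanks), length(flanks) >= 1)
  if (any(!nzchar(flanks))) {
    msat_error("msat_alignment_error", "empty flank sequence")
  }
  flanks <- toupper(flanks)
  if (is.null(names(flanks))) names(flanks) <- paste0("seq", seq_along(flanks))
  if (length(flanks) == 1) {
    warning("single sequence: degenerate alignment equal to the input")
    return(structure(list(rows = flanks, ncol = nchar(flanks)),
                     class = "flank_alignment"))
  }
  n <- length(flanks)
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- nw_affine_cpp(flanks[[i]], flanks[[j]], MSA_MATCH, MSA_MISMATCH,
                         MSA_GAP_OPEN, MSA_GAP_EXT)
      sim[i, j] <- sim[j, i] <- a$score
    }
  }
  avg <- rowMeans(sim)
  # deterministic joining order independent of the input order
  ord <- order(-avg, unname(flanks), names(flanks))
  rowmat <- matrix(strsplit(flanks[[ord[1]]], "", fixed = TRUE)[[1]],
                   nrow = 1)
  taken <- names(flanks)[ord[1]]
  for (k in ord[-1]) {
    prof <- profile_matrix(rowmat)
    pa <- profile_align_cpp(prof, flanks[[k]], MSA_MATCH, MSA_MISMATCH,
                            MSA_GAP_OPEN, MSA_GAP_EXT)
    ops <- pa$ops
    newrow <- character(length(ops))
    newmat <- matrix("-", nrow(rowmat) + 1, length(ops))
    pi <- 0L
    si <- 0L
    schars <- strsplit(flanks[[k]], "", fixed = TRUE)[[1]]
    for (ci in seq_along(ops)) {
      op <- ops[ci]
      if (op == 1L) {
        pi <- pi + 1L; si <- si + 1L
        newmat[seq_len(nrow(rowmat)), ci] <- rowmat[, pi]
        newmat[nrow(rowmat) + 1, ci] <- schars[si]
      } else if (op == 2L) {
        pi <- pi + 1L
        newmat[seq_len(nrow(rowmat)), ci] <- rowmat[, pi]
      } else {
        si <- si + 1L
        newmat[nrow(rowmat) + 1, ci] <- schars[si]
      }
    }
    rowmat <- newmat
    taken <- c(taken, names(flanks)[k])
  }
  rows <- apply(rowmat, 1, paste, collapse = "")
  names(rows) <- taken
  rows <- rows[names(flanks)] # restore input order for presentation
  structure(list(rows = rows, ncol = nchar(rows[[1]])),
            class = "flank_alignment")
}

#' @export
print.flank_alignment <- function(x, ...) {
  cat(sprintf("<flank_alignment> %d sequence(s) x %d column(s)\n",
              length(x$rows), x$ncol))
  invisible(x)
}

#' Call a degenerate IUPAC consensus from a flank alignment
#'
#' Per column: a unanimous base is kept; exactly two distinct bases with no
#' gap give the two-fold IUPAC code; three or more bases, or any gap, give N;
#' all-gap columns are dropped. With `min_support < 1`, bases observed in
#' less than `1 - min_support` of the rows are ignored before the rule is
#' applied.
#'
#' @param alignment a `flank_alignment`.
#' @param min_support fraction of rows a column's base set must cover.
#' @return list with `sequence` (IUPAC string) and `support` (integer vector
#'   of non-gap rows per kept column).
#' @export
call_consensus <- function(alignment, min_support = 1.0) {
  stopifnot(inherits(alignment, "flank_alignment"))
  mat <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  out <- character(0)
  support <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    nongap <- col[col != "-"]
    if (length(nongap) == 0) next # all-gap column dropped
    support <- c(support, length(nongap))
    if (length(nongap) < length(col)) {
      out <- c(out, "N")
      next
    }
    tab <- table(nongap)
    if (min_support < 1) {
      tab <- tab[tab / length(col) >= (1 - min_support)]
      if (length(tab) == 0) tab <- table(nongap)
    }
    bases <- names(tab)
    code <- if (length(bases) <= 2) iupac_code_for(bases) else "N"
    out <- c(out, code)
  }
  list(sequence = paste(out, collapse = ""), support = support)
}
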