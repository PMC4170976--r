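# Primer design on degenerate consensus flanks.
#
# Candidate windows (18-27 bp) are enumerated on the left consensus (forward
# primer) and on the right consensus (reverse primer, reported 5'->3' on the
# opposite strand).  Melting temperature uses the unified nearest-neighbor
# duplex parameters at 50 mM monovalent salt and 50 nM total oligo,
# evaluated over every expansion of the degenerate codes; N is substituted
# by the least-stable base (A) for the minimum and the most-stable (G) for
# the maximum.

# Unified NN parameters: dH kcal/mol, dS cal/(mol K)
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# terminal (initiation) corrections per end
INIT_DH <- c(GC = 0.1, AT = 2.3)
INIT_DS <- c(GC = -2.8, AT = 4.1)

tm_plain <- function(seq, monovalent = 0.05, oligo = 50e-9) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  steps <- paste0(chars[-n], chars[-1])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (endb in chars[c(1, n)]) {
    key <- if (endb %in% c("G", "C")) "GC" else "AT"
    dh <- dh + INIT_DH[[key]]
    ds <- ds + INIT_DS[[key]]
  }
  ds <- ds + 0.368 * (n - 1) * log(monovalent)
  dh * 1000 / (ds + 1.987 * log(oligo / 4)) - 273.15
}

expand_degenerate <- function(primer, n_as = NULL) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  sets <- lapply(chars, function(c) {
    if (c == "N") {
      if (is.null(n_as)) c("A", "C", "G", "T") else n_as
    } else IUPAC_SETS[[c]]
  })
  n_comb <- prod(lengths(sets))
  if (n_comb > 4096) {
    msat_error("msat_primer_error",
               sprintf("too many degenerate expansions (%d) for '%s'",
                       n_comb, primer))
  }
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

#' Melting temperature range of a (possibly degenerate) primer
#'
#' Nearest-neighbor duplex thermodynamics (unified parameter set, 50 mM
#' monovalent salt, 50 nM total oligo), evaluated over every expansion of
#' the degenerate IUPAC codes. N positions are substituted by the
#' least-stable base for the minimum and the most-stable base for the
#' maximum.
#'
#' @param primer IUPAC DNA string, length >= 8, at least one non-N base.
#' @param monovalent monovalent cation concentration (mol/L).
#' @param oligo total oligo concentration (mol/L).
#' @return named numeric vector `c(tm_min, tm_max)` in degrees Celsius.
#' @export
melting_temperature <- function(primer, monovalent = 0.05, oligo = 50e-9) {
  primer <- toupper(primer)
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  if (length(chars) < 8) {
    msat_error("msat_primer_error", "primer shorter than 8 bases")
  }
  if (all(chars == "N")) {
    msat_error("msat_primer_error", "all-N primer has no defined Tm")
  }
  if (!all(chars %in% names(IUPAC_SETS))) {
    msat_error("msat_alphabet_error",
               sprintf("illegal character in primer '%s'", primer))
  }
  lo <- min(vapply(expand_degenerate(primer, n_as = "A"), tm_plain,
                   numeric(1), monovalent, oligo))
  hi <- max(vapply(expand_degenerate(primer, n_as = "G"), tm_plain,
                   numeric(1), monovalent, oligo))
  c(tm_min = lo, tm_max = hi)
}

gc_range <- function(primer) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  lo <- mean(vapply(chars, function(c) {
    all(IUPAC_SETS[[c]] %in% c("G", "C"))
  }, logical(1)))
  hi <- mean(vapply(chars, function(c) {
    any(IUPAC_SETS[[c]] %in% c("G", "C"))
  }, logical(1)))
  c(gc_min = lo, gc_max = hi)
}

count_ns <- function(primer) {
  sum(strsplit(primer, "", fixed = TRUE)[[1]] == "N")
}

count_degenerate <- function(primer) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  sum(!chars %in% c(DNA_BASES, "N"))
}

max_identical_run <- function(primer) {
  r <- rle(strsplit(primer, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' Primer design constraints
#'
#' @param len_min,len_max primer length window (bases).
#' @param tm_min,tm_max acceptable melting-temperature window (deg C),
#'   applied across all degenerate expansions.
#' @param tm_opt optimum Tm used for ranking.
#' @param gc_min,gc_max GC-fraction window.
#' @param max_ns maximum unknown (N) bases summed over a pair.
#' @param max_degenerate maximum non-N ambiguity codes summed over a pair.
#' @param max_homorun longest permitted run of identical bases.
#' @param max_product maximum predicted product size (bp) on the consensus.
#' @param max_candidates_per_side cap on single-primer candidates paired
#'   exhaustively (ranked by |Tm - tm_opt| first).
#' @return a list of constraint values.
#' @export
primer_constraints <- function(len_min = 18, len_max = 27, tm_min = 52,
                               tm_max = 63, tm_opt = 60, gc_min = 0.2,
                               gc_max = 0.8, max_ns = 4, max_degenerate = 3,
                               max_homorun = 4, max_product = 600,
                               max_candidates_per_side = 100) {
  as.list(environment())
}

single_candidates <- function(consensus, side, constraints) {
  n <- nchar(consensus)
  rejects <- c(too_short = 0L, max_ns = 0L, max_degenerate = 0L, gc = 0L,
               tm = 0L, homorun = 0L, bad_3prime = 0L)
  out <- list()
  for (len in constraints$len_min:constraints$len_max) {
    if (len > n) { rejects["too_short"] <- rejects["too_short"] + 1L; next }
    for (s in 0:(n - len)) {
      win <- substr(consensus, s + 1L, s + len)
      primer <- if (side == "left") win else revcomp(win)
      ns <- count_ns(primer)
      if (ns > constraints$max_ns) {
        rejects["max_ns"] <- rejects["max_ns"] + 1L; next
      }
      deg <- count_degenerate(primer)
      if (deg > constraints$max_degenerate) {
        rejects["max_degenerate"] <- rejects["max_degenerate"] + 1L; next
      }
      last <- substr(primer, len, len)
      if (!last %in% DNA_BASES) {
        rejects["bad_3prime"] <- rejects["bad_3prime"] + 1L; next
      }
      if (max_identical_run(primer) > constraints$max_homorun) {
        rejects["homorun"] <- rejects["homorun"] + 1L; next
      }
      gc <- gc_range(primer)
      if (gc["gc_min"] < constraints$gc_min || gc["gc_max"] > constraints$gc_max) {
        rejects["gc"] <- rejects["gc"] + 1L; next
      }
      tm <- melting_temperature(primer)
      if (tm["tm_min"] < constraints$tm_min || tm["tm_max"] > constraints$tm_max) {
        rejects["tm"] <- rejects["tm"] + 1L; next
      }
      out[[length(out) + 1]] <- data.frame(
        primer = primer, start = s, end = s + len, length = len,
        tm_min = unname(tm["tm_min"]), tm_max = unname(tm["tm_max"]),
        gc_min = unname(gc["gc_min"]), gc_max = unname(gc["gc_max"]),
        n_count = ns, degenerate_count = deg, stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(out)) do.call(rbind, out) else NULL
  list(candidates = cand, rejects = rejects)
}

#' Design primer pairs on a pair of consensus flanks
#'
#' Enumerates forward-primer windows on the left consensus and reverse-primer
#' windows on the right consensus (the reverse primer is reported 5'->3' on
#' the opposite strand), applies the single-primer and pair constraints, and
#' ranks accepted pairs by |Tm_f - Tm_r| (midpoint Tm), then mean distance of
#' the pair's Tm from the optimum.
#'
#' @param left,right consensus objects from [call_consensus()] (or plain
#'   IUPAC strings) for the left and right flank.
#' @param constraints from [primer_constraints()].
#' @param core_len length of the repeat tract between the two consensi, used
#'   for product-size accounting on the consensus (default 0).
#' @return a `data.frame` of ranked pairs (forward, reverse, positions, Tm
#'   and GC ranges, n_count, degenerate_count, product size on the
#'   consensus), with a `rejections` attribute counting discarded candidate
#'   classes.
#' @export
design_primers <- function(left, right, constraints = primer_constraints(),
                           core_len = 0) {
  lc <- if (is.list(left)) left$sequence else left
  rc <- if (is.list(right)) right$sequence else right
  stopifnot(is.character(lc), is.character(rc))
  empty <- data.frame(forward = character(0), reverse = character(0),
                      forward_start = integer(0), forward_end = integer(0),
                      reverse_start = integer(0), reverse_end = integer(0),
                      tm_forward_min = numeric(0), tm_forward_max = numeric(0),
                      tm_reverse_min = numeric(0), tm_reverse_max = numeric(0),
                      gc_forward_min = numeric(0), gc_forward_max = numeric(0),
                      gc_reverse_min = numeric(0), gc_reverse_max = numeric(0),
                      n_count = integer(0), degenerate_count = integer(0),
                      product_size = integer(0), stringsAsFactors = FALSE)
  if (nchar(lc) < constraints$len_min || nchar(rc) < constraints$len_min) {
    attr(empty, "rejections") <- c(consensus_too_short = 1L)
    return(empty)
  }
  fl <- single_candidates(lc, "left", constraints)
  fr <- single_candidates(rc, "right", constraints)
  rejections <- fl$rejects + fr$rejects
  if (is.null(fl$candidates) || is.null(fr$candidates)) {
    attr(empty, "rejections") <- rejections
    return(empty)
  }
  cap <- constraints$max_candidates_per_side
  trim <- function(df) {
    mid <- (df$tm_min + df$tm_max) / 2
    df[order(abs(mid - constraints$tm_opt))[seq_len(min(nrow(df), cap))], ,
       drop = FALSE]
  }
  f <- trim(fl$candidates)
  r <- trim(fr$candidates)
  pairs <- list()
  pair_rejects <- c(pair_max_ns = 0L, pair_max_degenerate = 0L,
                    product_size = 0L)
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      ns <- f$n_count[i] + r$n_count[j]
      if (ns > constraints$max_ns) {
        pair_rejects["pair_max_ns"] <- pair_rejects["pair_max_ns"] + 1L
        next
      }
      deg <- f$degenerate_count[i] + r$degenerate_count[j]
      if (deg > constraints$max_degenerate) {
        pair_rejects["pair_max_degenerate"] <-
          pair_rejects["pair_max_degenerate"] + 1L
        next
      }
      # product on the consensus: forward start .. end of left consensus,
      # the repeat tract, then right consensus start .. reverse-window end
      product <- (nchar(lc) - f$start[i]) + core_len + r$end[j]
      if (product > constraints$max_product) {
        pair_rejects["product_size"] <- pair_rejects["product_size"] + 1L
        next
      }
      pairs[[length(pairs) + 1]] <- data.frame(
        forward = f$primer[i], reverse = r$primer[j],
        forward_start = f$start[i], forward_end = f$end[i],
        reverse_start = r$start[j], reverse_end = r$end[j],
        tm_forward_min = f$tm_min[i], tm_forward_max = f$tm_max[i],
        tm_reverse_min = r$tm_min[j], tm_reverse_max = r$tm_max[j],
        gc_forward_min = f$gc_min[i], gc_forward_max = f$gc_max[i],
        gc_reverse_min = r$gc_min[j], gc_reverse_max = r$gc_max[j],
        n_count = ns, degenerate_count = deg, product_size = product,
        stringsAsFactors = FALSE)
    }
  }
  rejections <- c(rejections, pair_rejects)
  if (!length(pairs)) {
    attr(empty, "rejections") <- rejections
    return(empty)
  }
  out <- do.call(rbind, pairs)
  tmf <- (out$tm_forward_min + out$tm_forward_max) / 2
  tmr <- (out$tm_reverse_min + out$tm_reverse_max) / 2
  out <- out[order(abs(tmf - tmr),
                   (abs(tmf - constraints$tm_opt) +
                    abs(tmr - constraints$tm_opt)) / 2,
                   out$forward_start, out$reverse_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Predicted product sizes per genome for a primer pair
#'
#' Maps the primer windows from consensus coordinates through each genome's
#' row of the flank alignments, adding that genome's repeat tract length.
#'
#' @param pair one row of [design_primers()] output.
#' @param left_aln,right_aln `flank_alignment` objects for the two flanks.
#' @param tract_lengths named numeric vector: genome_id -> repeat tract
#'   length in that genome (bp).
#' @return named numeric vector of product sizes (bp) per genome.
#' @export
product_sizes <- function(pair, left_aln, right_aln, tract_lengths) {
  # consensus position -> ungapped row position, per genome
  map_pos <- function(aln, gid, cpos) {
    row <- strsplit(aln$rows[[gid]], "", fixed = TRUE)[[1]]
    nongap_cols <- which(row != "-")
    # consensus drops all-gap columns; rebuild that mapping
    mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
    keep <- which(colSums(mat != "-") > 0)
    col <- keep[cpos + 1L] # 0-based consensus pos -> alignment column
    sum(row[seq_len(col)] != "-") # 1-based row position at/before col
  }
  vapply(names(tract_lengths), function(gid) {
    llen <- sum(strsplit(left_aln$rows[[gid]], "", fixed = TRUE)[[1]] != "-")
    fpos <- map_pos(left_aln, gid, pair$forward_start)
    rpos <- map_pos(right_aln, gid, pair$reverse_end - 1L)
    (llen - fpos + 1L) + tract_lengths[[gid]] + rpos
  }, numeric(1))
}
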