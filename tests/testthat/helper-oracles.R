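# Independent oracles used by the property and acceptance tests.  These are
# deliberately separate implementations: plain-R full-matrix dynamic
# programming with no banding and no seeding, plus reference alignments via
# Biostrings::pairwiseAlignment.

# Exhaustive tandem-alignment scorer: for every period, a full (unbanded)
# local DP of the sequence against itself, where an alignment may only start
# by pairing position i with i - period (the defining copy), and each cell
# carries the origin of its earlier copy.  Returns every maximal-scoring
# candidate segment per origin with total score (including the first-copy
# bonus) >= min_score, then resolves overlaps by (score desc, period asc,
# start asc).
oracle_tandem <- function(s, min_score = 50, mismatch_weight = 5,
                          max_period = 5, match_weight = 2,
                          indel_weight = 7) {
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  cand <- list()
  for (p in seq_len(max_period)) {
    if (n < p + 1) next
    # H[i, j]: best local score ending with s[i] paired to s[j] (1-based),
    # O[i, j]: start of the earlier copy (0-based)
    H <- matrix(-Inf, n, n)
    O <- matrix(-1L, n, n)
    best <- list()
    for (i in (p + 1):n) {
      for (j in 1:(i - 1)) {
        sub <- if (chars[i] == chars[j]) match_weight else -mismatch_weight
        h <- -Inf
        o <- -1L
        if (i > 1 && j > 1 && H[i - 1, j - 1] > 0) {
          h <- H[i - 1, j - 1] + sub
          o <- O[i - 1, j - 1]
        }
        if (j == i - p && sub > h) { # fresh start at the defining offset
          h <- sub
          o <- j - 1L
        }
        if (i > 1 && H[i - 1, j] > 0) {
          g <- H[i - 1, j] - indel_weight
          if (g > h) { h <- g; o <- O[i - 1, j] }
        }
        if (j > 1 && H[i, j - 1] > 0) {
          g <- H[i, j - 1] - indel_weight
          if (g > h) { h <- g; o <- O[i, j - 1] }
        }
        if (h > 0) {
          H[i, j] <- h
          O[i, j] <- o
          total <- h + match_weight * p
          if (total >= min_score) {
            key <- as.character(o)
            if (is.null(best[[key]]) || total > best[[key]][1]) {
              best[[key]] <- c(total, i)
            }
          }
        }
      }
    }
    for (key in names(best)) {
      cand[[length(cand) + 1]] <- data.frame(
        start = as.integer(key), end = best[[key]][2],
        period = p, score = best[[key]][1])
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), score = integer(0)))
  }
  cand <- do.call(rbind, cand)
  # discard candidates whose longest-run unit repeats a shorter unit (the
  # primitive-period candidate explains them); then resolve overlaps by the
  # alignment score with the first-copy bonus stripped, period, start
  is_primitive_call <- vapply(seq_len(nrow(cand)), function(i) {
    u <- oracle_run_unit(chars, cand$start[i], cand$end[i], cand$period[i])
    oracle_is_primitive(u)
  }, logical(1))
  cand <- cand[is_primitive_call, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), score = integer(0)))
  }
  h <- cand$score - match_weight * cand$period
  cand <- cand[order(-h, cand$period, cand$start), , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- kept & cand$start[i] < cand$end & cand$end[i] > cand$start
    if (!any(ov)) kept[i] <- TRUE
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Unit (as character vector window) with the longest exact forward run in
# [start, end); written independently of the package's scan.
oracle_run_unit <- function(chars, start, end, p) {
  win <- chars[(start + 1):end]
  L <- length(win)
  if (L < p) return(paste(win, collapse = ""))
  best_u <- paste(win[1:p], collapse = "")
  best_r <- 0L
  for (o in 0:(L - p)) {
    u <- win[(o + 1):(o + p)]
    r <- 1L
    j <- o + p
    while (j + p <= L && all(win[(j + 1):(j + p)] == u)) {
      r <- r + 1L
      j <- j + p
    }
    if (r > best_r) {
      best_r <- r
      best_u <- paste(u, collapse = "")
    }
  }
  best_u
}

oracle_is_primitive <- function(unit) {
  p <- nchar(unit)
  if (p <= 1) return(TRUE)
  u <- strsplit(unit, "", fixed = TRUE)[[1]]
  for (d in seq_len(p - 1)) {
    if (p %% d != 0) next
    if (all(u == rep(u[1:d], p / d))) return(FALSE)
  }
  TRUE
}

# Full Smith-Waterman with the mask semantics of the flank search ('#'
# aligns to anything at zero score, gaps adjacent to '#' are free, masked
# and free-gap columns excluded from identity).  Plain R, affine gaps.
oracle_sw_masked <- function(q, t, match_weight = 1, mismatch_weight = 2,
                             gap_open = 5, gap_ext = 2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  m <- length(qc)
  n <- length(tc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    mask <- qc[i - 1] == "#"
    go <- if (mask) 0 else gap_open
    ge <- if (mask) 0 else gap_ext
    for (j in 2:(n + 1)) {
      sub <- if (mask) 0
      else if (qc[i - 1] == tc[j - 1] && qc[i - 1] %in% c("A", "C", "G", "T"))
        match_weight
      else -mismatch_weight
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
    }
  }
  max(H)
}

# Nearest-neighbor melting temperatures computed independently with
# Biopython (Bio.SeqUtils.MeltingTemp.Tm_NN, unified parameters DNA_NN3,
# Na = 50 mM, total oligo 50 nM) and frozen here.
BIOPYTHON_TM <- c(
  AGCGGATCTAGTGGTCTTGG = 53.0443,
  ATGGAGGGGAGTAAGAGCGA = 53.7573,
  ACGTACGTACGTACGTACGT = 53.0967,
  TTTTTTTTATATATATAT = 25.6811,
  GCGCGCGCGCGCGCGCGC = 74.0472
)

# random genotype table for property tests
random_genotype_table <- function(n, loci = "L1", sizes = c(230, 234, 238),
                                  freqs = c(0.5, 0.3, 0.2), f = 0, seed = 1) {
  spec <- setNames(rep(list(list(sizes = sizes, freqs = freqs)),
                       length(loci)), loci)
  simulate_genotypes(pop_model(spec, f = f, n = n, seed = seed))
}

make_table <- function(a1, a2, loci = "L1") {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  conmsat:::new_genotype_table(paste0("ind", seq_len(nrow(a1))), loci, a1, a2)
}
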