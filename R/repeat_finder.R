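# Tandem repeat detection by scored self-alignment.
#
# A repeat tract of period p scores its best tandem alignment: every base of
# the first motif copy counts as a match, later positions are aligned to the
# copy one period earlier (match +2, mismatch -mismatch_weight, indel -7,
# with wraparound drift allowed within a band of +/- 2p).  Tracts are
# reported when the score reaches `min_score`; overlapping calls at
# different periods are resolved to the highest score, then the shortest
# period, then the smallest start.

#' Canonical representative of a repeat motif
#'
#' The lexicographically smallest string among all rotations of the unit and
#' all rotations of its reverse complement, so that motifs can be compared
#' across strands and repeat phases. Idempotent.
#'
#' @param unit DNA string of length 1-5 over A/C/G/T.
#' @return the canonical motif string.
#' @export
canonical_motif <- function(unit) {
  chars <- strsplit(toupper(unit), "", fixed = TRUE)[[1]]
  if (length(chars) < 1 || !all(chars %in% DNA_BASES)) {
    msat_error("msat_alphabet_error",
               sprintf("motif '%s' contains non-ACGT characters", unit))
  }
  rots <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n) - 1L, function(k) {
      paste0(substr(s, k + 1, n), substr(s, 1, k))
    }, character(1))
  }
  min(c(rots(paste(chars, collapse = "")), rots(revcomp(unit))))
}

#' Detect tandem repeats in a DNA sequence
#'
#' Scans one sequence for tandem repeats of period 1 to `max_period` by a
#' banded wraparound self-alignment. N runs are never inside a reported
#' locus. Coordinates are 0-based half-open.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param min_score minimum alignment score for a reported tract.
#' @param mismatch_weight positive penalty per mismatch.
#' @param max_period largest repeat unit length considered.
#' @param match_weight score per matching base.
#' @param indel_weight positive penalty per indel.
#' @return a `data.frame` with columns start, end, motif (canonical), period,
#'   copy_number, score, max_perfect_run, is_homopolymer.
#' @export
find_tandem_repeats <- function(sequence, min_score = 50, mismatch_weight = 5,
                                max_period = 5, match_weight = 2,
                                indel_weight = 7) {
  stopifnot(min_score > 0, max_period >= 1)
  sequence <- toupper(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      motif = character(0), period = integer(0),
                      copy_number = numeric(0), score = integer(0),
                      max_perfect_run = integer(0),
                      is_homopolymer = logical(0),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) == 0) return(empty)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(DNA_BASES, "N"))
  if (length(bad)) {
    msat_error("msat_alphabet_error",
               sprintf("illegal character '%s' at offset %d", chars[bad[1]],
                       bad[1] - 1L))
  }
  # N runs partition the sequence; repeats are called per clean chunk
  m <- gregexpr("[ACGT]+", sequence)[[1]]
  if (m[1] == -1) return(empty)
  cand <- list()
  for (ci in seq_along(m)) {
    off <- as.integer(m[ci]) - 1L
    chunk <- substr(sequence, m[ci], m[ci] + attr(m, "match.length")[ci] - 1L)
    for (p in seq_len(max_period)) {
      hits <- tandem_scan_cpp(chunk, p, match_weight, mismatch_weight,
                              indel_weight, min_score)
      if (nrow(hits)) {
        hits$start <- hits$start + off
        hits$end <- hits$end + off
        hits$period <- p
        cand[[length(cand) + 1]] <- hits
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # a call whose longest-run unit is a repetition of a shorter unit is
  # better explained at the primitive period, where a candidate also exists
  cand_unit <- vapply(seq_len(nrow(cand)), function(i) {
    best_unit(sequence, cand$start[i], cand$end[i], cand$period[i])
  }, character(1))
  cand <- cand[vapply(cand_unit, primitive_period, integer(1)) ==
                 cand$period, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # overlap resolution: higher alignment score (first-copy bonus stripped so
  # longer periods get no built-in edge), then smaller period, then smaller
  # start
  h <- cand$score - match_weight * cand$period
  cand <- cand[order(-h, cand$period, cand$start), , drop = FALSE]
  kept <- integer(0)
  kept_start <- integer(0)
  kept_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s < kept_end & e > kept_start)) {
      kept <- c(kept, i)
      kept_start <- c(kept_start, s)
      kept_end <- c(kept_end, e)
    }
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  # the repeat unit is read at the start of the longest perfect run, not at
  # the tract boundary, which chance flank matches can extend off-phase
  unit <- vapply(seq_len(nrow(cand)), function(i) {
    best_unit(sequence, cand$start[i], cand$end[i], cand$period[i])
  }, character(1))
  out <- data.frame(
    start = cand$start,
    end = cand$end,
    motif = vapply(unit, canonical_motif, character(1), USE.NAMES = FALSE),
    period = cand$period,
    copy_number = (cand$end - cand$start) / cand$period,
    score = cand$score,
    stringsAsFactors = FALSE
  )
  out$max_perfect_run <- vapply(seq_len(nrow(out)), function(i) {
    max_perfect_run(sequence, out$start[i], out$end[i], unit[i])
  }, integer(1))
  out$is_homopolymer <- out$period == 1L
  rownames(out) <- NULL
  out
}

#' Detect tandem repeats across all contigs of a genome
#'
#' @param genome an `msat_genome`.
#' @inheritParams find_tandem_repeats
#' @return as [find_tandem_repeats()] with an extra `contig` column.
#' @export
genome_tandem_repeats <- function(genome, min_score = 50, mismatch_weight = 5,
                                  max_period = 5, match_weight = 2,
                                  indel_weight = 7) {
  stopifnot(inherits(genome, "msat_genome"))
  res <- lapply(names(genome$contigs), function(cn) {
    df <- find_tandem_repeats(genome$contigs[[cn]], min_score,
                              mismatch_weight, max_period, match_weight,
                              indel_weight)
    if (nrow(df)) df <- cbind(contig = cn, df, stringsAsFactors = FALSE)
    df
  })
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (!length(res)) {
    return(cbind(contig = character(0), find_tandem_repeats("")))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Smallest d such that the unit is a repetition of its first d characters.
primitive_period <- function(unit) {
  p <- nchar(unit)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && unit == strrep(substr(unit, 1, d), p / d)) return(d)
  }
  p
}

# Unit of length p with the longest forward run of exact copies inside
# [start, end); ties broken by the earliest offset.
best_unit <- function(sequence, start, end, p) {
  tract <- substr(sequence, start + 1L, end)
  n <- nchar(tract)
  if (n < p) return(substr(tract, 1, p))
  best <- substr(tract, 1, p)
  best_run <- 0L
  i <- 0L
  while (i + p <= n) {
    u <- substr(tract, i + 1L, i + p)
    run <- 1L
    j <- i + p
    while (j + p <= n && substr(tract, j + 1L, j + p) == u) {
      run <- run + 1L
      j <- j + p
    }
    if (run > best_run) {
      best_run <- run
      best <- u
    }
    i <- i + 1L
  }
  best
}

#' Longest run of consecutive exact motif copies in a tract
#'
#' The largest k such that some rotation of the repeat unit occurs k times
#' consecutively and exactly within `[start, end)`. Taking the maximum over
#' rotations makes the count independent of the phase at which the tract
#' boundary was called.
#'
#' @param sequence DNA string containing the tract.
#' @param start,end 0-based half-open tract coordinates.
#' @param unit repeat unit as it appears in the tract (locus orientation).
#' @param rotations take the maximum over rotations of `unit` (default TRUE).
#' @return integer count of consecutive perfect copies.
#' @export
max_perfect_run <- function(sequence, start, end, unit, rotations = TRUE) {
  tract <- substr(sequence, start + 1L, end)
  p <- nchar(unit)
  if (nchar(tract) < p) return(0L)
  rots <- if (rotations) {
    vapply(seq_len(p) - 1L, function(k) {
      paste0(substr(unit, k + 1, p), substr(unit, 1, k))
    }, character(1))
  } else unit
  best <- 0L
  n <- nchar(tract)
  for (r in unique(rots)) {
    for (phase in 0:(p - 1L)) {
      run <- 0L
      i <- phase
      while (i + p <= n) {
        if (substr(tract, i + 1L, i + p) == r) {
          run <- run + 1L
          best <- max(best, run)
          i <- i + p
        } else {
          run <- 0L
          i <- i + p
        }
      }
      if (p == 1L) break
    }
  }
  best
}

#' Write detected repeats to TSV
#'
#' @param repeats data.frame from [genome_tandem_repeats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeats_tsv <- function(repeats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 0-based, half-open", con)
  write.table(repeats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
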