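# Cross-genome conserved-flank search.
#
# For each repeat locus a masked query is built: up to `flank_len` bases on
# each side of the tract, with the tract itself replaced by mask characters
# ('#') so that only flank similarity can drive hits.  The query is searched
# against every genome on both strands by exact word seeding followed by a
# full mask-aware local alignment of each candidate window.  Hits below the
# identity threshold are dropped; a locus is conserved_unique only when every
# genome (including the query's own) has exactly one qualifying hit, and a
# repeat search at each hit records whether the tract itself is conserved.

MASK_CHAR <- "#"

#' Build a repeat-masked flank query for a locus
#'
#' @param genome the `msat_genome` the locus was detected in.
#' @param locus one row of [genome_tandem_repeats()] output (or a list with
#'   contig, start, end, motif, period).
#' @param flank_len flank length in bp on each side (default 200).
#' @return an object of class `masked_query`.
#' @export
build_masked_query <- function(genome, locus, flank_len = 200) {
  stopifnot(inherits(genome, "msat_genome"))
  if (flank_len <= 0) {
    msat_error("msat_query_error", "flank_len must be positive: flanks are required for the search")
  }
  contig <- as.character(locus$contig)
  if (!contig %in% names(genome$contigs)) {
    msat_error("msat_query_error", sprintf("contig '%s' not in genome '%s'",
                                           contig, genome$genome_id))
  }
  seq <- genome$contigs[[contig]]
  n <- nchar(seq)
  start <- locus$start
  end <- locus$end
  if (start < 0 || end > n || start >= end) {
    msat_error("msat_query_error",
               sprintf("locus [%d,%d) out of bounds for contig '%s' (%d bp)",
                       start, end, contig, n))
  }
  lstart <- max(0L, start - flank_len)
  rend <- min(n, end + flank_len)
  structure(list(
    locus_id = if (!is.null(locus$locus_id)) locus$locus_id else
      sprintf("%s:%s:%d-%d", genome$genome_id, contig, start, end),
    genome_id = genome$genome_id,
    contig = contig,
    start = start, end = end,
    motif = locus$motif,
    period = locus$period,
    left_flank = substr(seq, lstart + 1L, start),
    right_flank = substr(seq, end + 1L, rend),
    flank_len = flank_len,
    truncated_left = (start - lstart) < flank_len,
    truncated_right = (rend - end) < flank_len
  ), class = "masked_query")
}

#' @export
print.masked_query <- function(x, ...) {
  cat(sprintf("<masked_query> %s motif=%s flanks %d/%d bp core %d bp\n",
              x$locus_id, x$motif, nchar(x$left_flank), nchar(x$right_flank),
              x$end - x$start))
  invisible(x)
}

query_string <- function(query) {
  paste0(query$left_flank, strrep(MASK_CHAR, query$end - query$start),
         query$right_flank)
}

# Candidate target windows from word seeds, grouped by alignment diagonal.
seed_windows <- function(qs, target_seq, word_size, diag_slack = 60,
                         pad = 60) {
  hits <- seed_hits_cpp(qs, target_seq, word_size)
  if (!length(hits$qpos)) return(NULL)
  d <- hits$tpos - hits$qpos
  o <- order(d, hits$tpos)
  d <- d[o]; qp <- hits$qpos[o]; tp <- hits$tpos[o]
  qlen <- nchar(qs); tlen <- nchar(target_seq)
  grp <- cumsum(c(TRUE, diff(d) > diag_slack))
  wins <- lapply(split(seq_along(d), grp), function(idx) {
    c(max(0L, min(tp[idx] - qp[idx]) - pad),
      min(tlen, max(tp[idx] + (qlen - qp[idx])) + pad))
  })
  # merge overlapping windows
  wins <- wins[order(vapply(wins, `[`, numeric(1), 1))]
  merged <- list(wins[[1]])
  for (w in wins[-1]) {
    last <- merged[[length(merged)]]
    if (w[1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], w[2]))
    } else merged[[length(merged) + 1]] <- w
  }
  merged
}

#' Search one genome for a masked flank query
#'
#' Seeded local alignment on both strands: exact `word_size`-mer seeding on
#' unmasked query positions, then a full mask-aware affine local alignment of
#' each candidate window. Mask characters align to anything at zero score and
#' are excluded from the identity denominator. Hits whose identity falls
#' below `identity_min` are dropped; hits overlapping by at least half are
#' merged, keeping the higher score. Coordinates are reported on the target's
#' forward strand; `strand` gives the orientation of the match.
#'
#' @param query a `masked_query`.
#' @param target an `msat_genome`.
#' @param word_size exact seed length.
#' @param identity_min minimum identity (matches / unmasked alignment
#'   columns) in `[0,1]`.
#' @param match_weight,mismatch_weight,gap_open,gap_ext alignment scoring.
#' @param min_flank_cov fraction of each flank a hit must cover to qualify
#'   for uniqueness assessment.
#' @param min_hit_score minimum local-alignment score for a reported hit;
#'   filters chance seed pairs bridged at no cost by the masked core.
#' @return a `data.frame` of hits: genome_id, contig, start, end, strand,
#'   score, identity, aligned_columns, covers_both_flanks.
#' @export
search_genome <- function(query, target, word_size = 11, identity_min = 0.60,
                          match_weight = 1, mismatch_weight = 2,
                          gap_open = 5, gap_ext = 2, min_flank_cov = 0.5,
                          min_hit_score = 40) {
  stopifnot(inherits(query, "masked_query"), inherits(target, "msat_genome"))
  if (nchar(query$left_flank) == 0 && nchar(query$right_flank) == 0) {
    msat_error("msat_query_error", "query has empty flanks")
  }
  qs_fwd <- query_string(query)
  qlen <- nchar(qs_fwd)
  llen <- nchar(query$left_flank)
  rlen <- nchar(query$right_flank)
  core <- query$end - query$start
  # the minus strand is searched with the reverse-complemented query so the
  # (long) target never needs reverse complementing
  qs_rev <- revcomp(qs_fwd)
  hits <- list()
  for (contig in names(target$contigs)) {
    tseq <- target$contigs[[contig]]
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") qs_fwd else qs_rev
      wins <- seed_windows(qs, tseq, word_size)
      if (is.null(wins)) next
      for (w in wins) {
        wseq <- substr(tseq, w[1] + 1L, w[2])
        aln <- sw_masked_cpp(qs, wseq, match_weight, mismatch_weight,
                             gap_open, gap_ext)
        if (aln$score < min_hit_score || aln$columns == 0) next
        # local alignment consumes a contiguous query range [qstart, qend);
        # map to forward-query coordinates on the minus strand
        q0 <- if (strand == "+") aln$qstart else qlen - aln$qend
        q1 <- if (strand == "+") aln$qend else qlen - aln$qstart
        cov_left <- if (llen > 0) {
          max(0, min(q1, llen) - q0) / llen
        } else 1
        cov_right <- if (rlen > 0) {
          max(0, q1 - max(q0, llen + core)) / rlen
        } else 1
        ts <- w[1] + aln$tstart
        te <- w[1] + aln$tend
        hits[[length(hits) + 1]] <- data.frame(
          genome_id = target$genome_id, contig = contig, start = ts, end = te,
          strand = strand, score = aln$score,
          identity = aln$matches / aln$columns,
          aligned_columns = aln$columns,
          cov_left = cov_left, cov_right = cov_right,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(genome_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      identity = numeric(0), aligned_columns = numeric(0),
                      cov_left = numeric(0), cov_right = numeric(0),
                      covers_both_flanks = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  hits <- hits[hits$identity >= identity_min, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  # merge hits on the same contig whose intervals overlap >= 50%
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j == i || !keep[j]) next
      if (hits$contig[i] != hits$contig[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov >= 0.5 * shorter) keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$covers_both_flanks <- hits$cov_left >= min_flank_cov &
    hits$cov_right >= min_flank_cov
  hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assess cross-genome conservation of a masked query
#'
#' Searches every genome of the set and classifies the locus:
#' `conserved_unique` when every genome has exactly one qualifying hit
#' (identity and both-flank coverage pass); `non_unique` when any genome has
#' several; `missing_in_genome` when a genome has no hit at all;
#' `low_identity` when a genome has hits but none qualifying;
#' `repeat_absent` when flanks are conserved and unique everywhere but no
#' genome's hit interval contains a confirmed repeat. For each unique hit a
#' tandem-repeat search (same detector settings as discovery) is run on the
#' hit interval padded by `confirm_pad` bp.
#'
#' @param query a `masked_query`.
#' @param genomes an `msat_genome_set` (at least 2 genomes).
#' @param identity_min minimum hit identity.
#' @param min_score,mismatch_weight,max_period detector settings for repeat
#'   confirmation.
#' @param confirm_pad padding around the hit interval for confirmation.
#' @param ... passed to [search_genome()].
#' @return an object of class `conserved_locus`: list with `query`, `hits`
#'   (per genome), `status`, and `motif_table` (per-genome data.frame with
#'   repeat_confirmed, motif, max_perfect_run, contig, start, end, strand).
#' @export
assess_conservation <- function(query, genomes, identity_min = 0.60,
                                min_score = 50, mismatch_weight = 5,
                                max_period = 5, confirm_pad = 50, ...) {
  stopifnot(inherits(query, "masked_query"))
  if (length(genomes) < 2) {
    msat_error("msat_query_error", "conservation assessment needs >= 2 genomes")
  }
  hits <- lapply(genomes, function(g) {
    search_genome(query, g, identity_min = identity_min, ...)
  })
  n_any <- vapply(hits, nrow, integer(1))
  n_pass <- vapply(hits, function(h) sum(h$covers_both_flanks), integer(1))
  status <- if (any(n_pass > 1)) "non_unique"
  else if (any(n_any == 0)) "missing_in_genome"
  else if (any(n_pass == 0)) "low_identity"
  else "conserved_unique"
  motif_table <- NULL
  if (status == "conserved_unique") {
    rows <- lapply(names(genomes), function(gid) {
      h <- hits[[gid]][hits[[gid]]$covers_both_flanks, , drop = FALSE][1, ]
      pad_s <- max(0L, h$start - confirm_pad)
      contig_seq <- genomes[[gid]]$contigs[[h$contig]]
      pad_e <- min(nchar(contig_seq), h$end + confirm_pad)
      reps <- find_tandem_repeats(substr(contig_seq, pad_s + 1L, pad_e),
                                  min_score = min_score,
                                  mismatch_weight = mismatch_weight,
                                  max_period = max_period)
      reps <- reps[!reps$is_homopolymer | query$period == 1L, , drop = FALSE]
      confirmed <- nrow(reps) > 0
      best <- if (confirmed) reps[which.max(reps$score), ] else NULL
      data.frame(
        genome_id = gid, contig = h$contig, start = h$start, end = h$end,
        strand = h$strand, identity = h$identity,
        repeat_confirmed = confirmed,
        motif = if (confirmed) best$motif else NA_character_,
        max_perfect_run = if (confirmed) best$max_perfect_run else 0L,
        tract_start = if (confirmed) pad_s + best$start else NA_integer_,
        tract_end = if (confirmed) pad_s + best$end else NA_integer_,
        stringsAsFactors = FALSE)
    })
    motif_table <- do.call(rbind, rows)
    rownames(motif_table) <- NULL
    if (!any(motif_table$repeat_confirmed)) status <- "repeat_absent"
  }
  structure(list(query = query, hits = hits, status = status,
                 motif_table = motif_table),
            class = "conserved_locus")
}

#' @export
print.conserved_locus <- function(x, ...) {
  cat(sprintf("<conserved_locus> %s status=%s (%d genomes)\n",
              x$query$locus_id, x$status, length(x$hits)))
  invisible(x)
}

#' Run the full discovery pipeline on a genome set
#'
#' Detects tandem repeats in the query genome, builds masked flank queries
#' (homopolymer tracts are excluded by default), and assesses each query's
#' conservation across all genomes of the set.
#'
#' @param genomes an `msat_genome_set`.
#' @param query_genome genome_id used for repeat discovery (default: first).
#' @param flank_len flank length for queries.
#' @param min_score,mismatch_weight,max_period detector settings.
#' @param include_homopolymers include period-1 tracts as queries.
#' @param identity_min hit identity threshold.
#' @param ... passed to [assess_conservation()].
#' @return a list of `conserved_locus` objects, named by locus id.
#' @export
discover_conserved_loci <- function(genomes, query_genome = names(genomes)[1],
                                    flank_len = 200, min_score = 50,
                                    mismatch_weight = 5, max_period = 5,
                                    include_homopolymers = FALSE,
                                    identity_min = 0.60, ...) {
  qg <- genomes[[query_genome]]
  reps <- genome_tandem_repeats(qg, min_score = min_score,
                                mismatch_weight = mismatch_weight,
                                max_period = max_period)
  if (!include_homopolymers) {
    reps <- reps[!reps$is_homopolymer, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(reps))) {
    q <- build_masked_query(qg, reps[i, ], flank_len = flank_len)
    out[[q$locus_id]] <- assess_conservation(q, genomes,
                                             identity_min = identity_min,
                                             min_score = min_score,
                                             mismatch_weight = mismatch_weight,
                                             max_period = max_period, ...)
  }
  out
}

#' Write search hits as a 12-column tabular alignment dump
#'
#' One row per hit in the familiar 12-column tabular dialect (query id,
#' target id, percent identity, alignment length, mismatches, gap openings,
#' query start/end, target start/end, E-value, score). Gap openings are not
#' tracked separately and the search has no E-value model; those columns
#' hold NA. Coordinates here are 1-based inclusive, with target start > end
#' on the minus strand, per the dialect's convention.
#'
#' @param query the `masked_query` the hits belong to.
#' @param hits data.frame from [search_genome()].
#' @param path output path; the file is appended to if it exists.
#' @return `path`, invisibly.
#' @export
write_hits_tabular <- function(query, hits, path) {
  n <- nrow(hits)
  qlen <- nchar(query$left_flank) + (query$end - query$start) +
    nchar(query$right_flank)
  mism <- round(hits$aligned_columns * (1 - hits$identity))
  df <- data.frame(
    qseqid = rep(query$locus_id, n),
    sseqid = paste(hits$genome_id, hits$contig, sep = ":"),
    pident = round(100 * hits$identity, 2),
    length = hits$aligned_columns,
    mismatch = mism,
    gapopen = NA_integer_,
    qstart = rep(1L, n),
    qend = rep(qlen, n),
    sstart = ifelse(hits$strand == "+", hits$start + 1L, hits$end),
    send = ifelse(hits$strand == "+", hits$end, hits$start + 1L),
    evalue = NA_real_,
    bitscore = hits$score,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = file.exists(path))
  invisible(path)
}

#' Tabulate conservation results
#'
#' @param loci list of `conserved_locus` objects.
#' @return a `data.frame` with one row per locus: locus_id, status, motif,
#'   n_genomes_hit, n_repeat_confirmed.
#' @export
conservation_summary <- function(loci) {
  rows <- lapply(loci, function(cl) {
    data.frame(
      locus_id = cl$query$locus_id,
      status = cl$status,
      motif = cl$query$motif,
      n_genomes_hit = sum(vapply(cl$hits, nrow, integer(1)) > 0),
      n_repeat_confirmed = if (is.null(cl$motif_table)) 0L else
        sum(cl$motif_table$repeat_confirmed),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
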