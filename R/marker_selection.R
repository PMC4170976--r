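# Locus selection filters and physical linkage.
#
# A conserved locus is selected when its repeat motif is confirmed in at
# least `presence_min` of the genomes AND it shows at least `run_min`
# consecutive perfect motif copies in more than one genome (strictly more
# than one by default: run_genomes_min = 2).  Loci sharing a contig in any
# genome are physically linked regardless of statistical LD.

#' Apply locus-selection filters to assessed conserved loci
#'
#' @param loci list of `conserved_locus` objects.
#' @param presence_min fraction of genomes in which the repeat motif must be
#'   confirmed.
#' @param run_min minimum consecutive perfect motif copies.
#' @param run_genomes_min number of genomes that must reach `run_min`.
#' @param run_mode `"perfect"` counts consecutive exact copies;
#'   `"total"` uses total copy number including interruptions.
#' @return a `data.frame` (class `selection_report`): locus_id, status,
#'   motif_presence_count, n_genomes, passes_presence, passes_depth,
#'   selected.
#' @export
select_loci <- function(loci, presence_min = 0.75, run_min = 10,
                        run_genomes_min = 2, run_mode = c("perfect", "total")) {
  run_mode <- match.arg(run_mode)
  rows <- lapply(loci, function(cl) {
    k <- length(cl$hits)
    if (is.null(cl$motif_table)) {
      return(data.frame(locus_id = cl$query$locus_id, status = cl$status,
                        motif_presence_count = 0L, n_genomes = k,
                        passes_presence = FALSE, passes_depth = FALSE,
                        selected = FALSE, stringsAsFactors = FALSE))
    }
    mt <- cl$motif_table
    presence <- sum(mt$repeat_confirmed)
    runs <- if (run_mode == "perfect") {
      mt$max_perfect_run
    } else {
      # total copy number of the confirmed tract
      ifelse(mt$repeat_confirmed, (mt$end - mt$start) / nchar(cl$query$motif),
             0)
    }
    depth <- sum(runs >= run_min, na.rm = TRUE) >= run_genomes_min
    pres <- presence >= presence_min * k
    data.frame(locus_id = cl$query$locus_id, status = cl$status,
               motif_presence_count = presence, n_genomes = k,
               passes_presence = pres, passes_depth = depth,
               selected = cl$status == "conserved_unique" && pres && depth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("selection_report", "data.frame")
  out
}

#' Physical linkage of selected loci
#'
#' Two selected loci are physically linked in a genome when their unique
#' hits fall on the same contig.  Pairs are symmetric and deduplicated.
#'
#' @param selection a `selection_report`.
#' @param loci the list of `conserved_locus` objects the report was built
#'   from.
#' @return list with `by_contig` (data.frame genome_id, contig, locus_id)
#'   and `pairs` (data.frame genome_id, contig, locus_a, locus_b).
#' @export
physical_linkage <- function(selection, loci) {
  sel_ids <- selection$locus_id[selection$selected]
  placements <- list()
  for (cl in loci) {
    if (!cl$query$locus_id %in% sel_ids || is.null(cl$motif_table)) next
    placements[[length(placements) + 1]] <- data.frame(
      genome_id = cl$motif_table$genome_id,
      contig = cl$motif_table$contig,
      locus_id = cl$query$locus_id, stringsAsFactors = FALSE)
  }
  empty_pairs <- data.frame(genome_id = character(0), contig = character(0),
                            locus_a = character(0), locus_b = character(0),
                            stringsAsFactors = FALSE)
  if (!length(placements)) {
    return(list(by_contig = empty_pairs[, c("genome_id", "contig")],
                pairs = empty_pairs))
  }
  by_contig <- do.call(rbind, placements)
  pairs <- list()
  for (key in unique(paste(by_contig$genome_id, by_contig$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ids <- sort(unique(by_contig$locus_id[
      by_contig$genome_id == parts[1] & by_contig$contig == parts[2]]))
    if (length(ids) < 2) next
    cmb <- utils::combn(ids, 2)
    pairs[[length(pairs) + 1]] <- data.frame(
      genome_id = parts[1], contig = parts[2],
      locus_a = cmb[1, ], locus_b = cmb[2, ], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else empty_pairs
  rownames(pairs) <- NULL
  list(by_contig = by_contig, pairs = pairs)
}
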