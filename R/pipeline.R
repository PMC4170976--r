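# End-to-end panel design: conserved loci -> per-genome flanks -> consensus
# -> primers.

# Oriented flank sequences for one conserved locus: each genome's hit region
# is put into query orientation, the repeat tract is located inside it, and
# the sequence on each side of the tract is returned.
locus_flanks <- function(conserved, genomes, min_score = 50,
                         mismatch_weight = 5, max_period = 5) {
  mt <- conserved$motif_table
  left <- character(0)
  right <- character(0)
  tract_len <- numeric(0)
  for (i in seq_len(nrow(mt))) {
    if (!mt$repeat_confirmed[i]) next
    gid <- mt$genome_id[i]
    contig_seq <- genomes[[gid]]$contigs[[mt$contig[i]]]
    pad_s <- max(0L, mt$start[i] - 50L)
    pad_e <- min(nchar(contig_seq), mt$end[i] + 50L)
    seg <- substr(contig_seq, pad_s + 1L, pad_e)
    if (mt$strand[i] == "-") seg <- revcomp(seg)
    reps <- find_tandem_repeats(seg, min_score = min_score,
                                mismatch_weight = mismatch_weight,
                                max_period = max_period)
    reps <- reps[!reps$is_homopolymer, , drop = FALSE]
    if (!nrow(reps)) next
    best <- reps[which.max(reps$score), ]
    left[gid] <- substr(seg, 1, best$start)
    right[gid] <- substr(seg, best$end + 1L, nchar(seg))
    tract_len[gid] <- best$end - best$start
  }
  list(left = left, right = right, tract_len = tract_len)
}

#' Design consensus primers for selected conserved loci
#'
#' For each selected locus, the per-genome flank sequences (in query
#' orientation) are multiply aligned, collapsed to a degenerate consensus,
#' and primer pairs are designed on the consensus; per-genome product sizes
#' are predicted through the flank alignments.
#'
#' @param loci list of `conserved_locus` objects.
#' @param selection a `selection_report` from [select_loci()]; only selected
#'   loci are designed.
#' @param genomes the `msat_genome_set` the loci were assessed against.
#' @param constraints primer constraints ([primer_constraints()]).
#' @param top_pairs primer pairs retained per locus.
#' @return named list per locus: `consensus_left`, `consensus_right`,
#'   `primers` (data.frame, best `top_pairs` pairs with per-genome
#'   `product_size.<genome>` columns), `alignments`.
#' @export
design_panel <- function(loci, selection, genomes,
                         constraints = primer_constraints(), top_pairs = 5) {
  out <- list()
  for (cl in loci) {
    id <- cl$query$locus_id
    if (!id %in% selection$locus_id[selection$selected]) next
    fl <- locus_flanks(cl, genomes)
    if (length(fl$left) < 2) next
    la <- align_flanks(fl$left)
    ra <- align_flanks(fl$right)
    lcons <- call_consensus(la)
    rcons <- call_consensus(ra)
    primers <- design_primers(lcons, rcons, constraints,
                              core_len = round(mean(fl$tract_len)))
    if (nrow(primers)) {
      primers <- primers[seq_len(min(top_pairs, nrow(primers))), ,
                         drop = FALSE]
      ps <- t(vapply(seq_len(nrow(primers)), function(i) {
        product_sizes(primers[i, ], la, ra, fl$tract_len)
      }, numeric(length(fl$tract_len))))
      colnames(ps) <- paste0("product_size.", names(fl$tract_len))
      primers <- cbind(primers, ps)
    }
    out[[id]] <- list(consensus_left = lcons$sequence,
                      consensus_right = rcons$sequence,
                      primers = primers,
                      alignments = list(left = la, right = ra))
  }
  out
}
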