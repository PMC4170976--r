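# Masked flank queries and the cross-genome conserved-flank search.

one_contig_genome <- function(seq, id = "g1", contig = "chr1") {
  structure(list(genome_id = id, contigs = setNames(seq, contig),
                 softmask = setNames(list(integer(0)), contig)),
            class = "msat_genome")
}

planted_locus <- function(flank = 200, copies = 13, motif = "AG",
                          lead = 500, tail = 500, seed = 1) {
  set.seed(seed)
  tract <- strrep(motif, copies)
  left <- conmsat:::random_dna(flank)
  right <- conmsat:::random_dna(flank)
  seq <- paste0(conmsat:::random_dna(lead), left, tract, right,
                conmsat:::random_dna(tail))
  list(seq = seq, left = left, right = right,
       start = lead + flank, end = lead + flank + nchar(tract),
       motif = motif, period = nchar(motif))
}

test_that("masked queries have the right geometry and truncation flags", {
  pl <- planted_locus()
  g <- one_contig_genome(pl$seq)
  locus <- list(contig = "chr1", start = pl$start, end = pl$end,
                motif = pl$motif, period = pl$period)
  q <- build_masked_query(g, locus)
  expect_equal(nchar(q$left_flank), 200)
  expect_equal(nchar(q$right_flank), 200)
  expect_equal(q$left_flank, pl$left)
  expect_equal(q$right_flank, pl$right)
  expect_false(q$truncated_left || q$truncated_right)
  qs <- conmsat:::query_string(q)
  expect_equal(nchar(qs), 400 + (pl$end - pl$start))
  expect_equal(substr(qs, 201, 201 + pl$end - pl$start - 1),
               strrep("#", pl$end - pl$start))

  # locus near the contig edge truncates the flank and flags it
  g2 <- one_contig_genome(substr(pl$seq, pl$start - 49, nchar(pl$seq)))
  locus2 <- list(contig = "chr1", start = 50, end = 50 + pl$end - pl$start,
                 motif = pl$motif, period = pl$period)
  q2 <- build_masked_query(g2, locus2)
  expect_equal(nchar(q2$left_flank), 50)
  expect_true(q2$truncated_left)
  expect_false(q2$truncated_right)

  expect_error(build_masked_query(g, locus, flank_len = 0),
               class = "msat_query_error")
  bad <- list(contig = "chr1", start = nchar(pl$seq), end = nchar(pl$seq) + 10,
              motif = "AG", period = 2)
  expect_error(build_masked_query(g, bad), class = "msat_query_error")
})

test_that("an exact copy of both flanks is found at identity 1 on both strands", {
  pl <- planted_locus(seed = 2)
  g <- one_contig_genome(pl$seq)
  locus <- list(contig = "chr1", start = pl$start, end = pl$end,
                motif = pl$motif, period = pl$period)
  q <- build_masked_query(g, locus)
  # the target carries the same flanks around a different tract length
  target_seq <- paste0(conmsat:::random_dna(300), pl$left, strrep("AG", 20),
                       pl$right, conmsat:::random_dna(300))
  tg <- one_contig_genome(target_seq, id = "t1")
  hits <- search_genome(q, tg)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 1.0)
  expect_true(hits$covers_both_flanks)
  expect_equal(hits$start, 300)
  expect_equal(hits$end, 300 + 400 + 40)

  rc <- one_contig_genome(revcomp(target_seq), id = "t2")
  hits_rc <- search_genome(q, rc)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$identity, 1.0)
  n <- nchar(target_seq)
  expect_equal(hits_rc$start, n - hits$end)
  expect_equal(hits_rc$end, n - hits$start)
})

test_that("heavily diverged flanks fall below the identity threshold", {
  pl <- planted_locus(seed = 3)
  g <- one_contig_genome(pl$seq)
  locus <- list(contig = "chr1", start = pl$start, end = pl$end,
                motif = pl$motif, period = pl$period)
  q <- build_masked_query(g, locus)
  set.seed(33)
  target_seq <- paste0(conmsat:::random_dna(300),
                       conmsat:::mutate_dna(pl$left, 0.45),
                       strrep("AG", 12),
                       conmsat:::mutate_dna(pl$right, 0.45),
                       conmsat:::random_dna(300))
  tg <- one_contig_genome(target_seq, id = "t1")
  hits <- search_genome(q, tg)
  expect_true(nrow(hits) == 0 || all(!hits$covers_both_flanks))
})

test_that("search agrees with reference Smith-Waterman on unmasked flanks", {
  # flank-only query (no repeat core): identical scoring model as a plain
  # local alignment, checked against Biostrings::pairwiseAlignment
  set.seed(44)
  for (rep in 1:8) {
    flank <- conmsat:::random_dna(120)
    target_seq <- paste0(conmsat:::random_dna(sample(300:900, 1)),
                         conmsat:::mutate_dna(flank, runif(1, 0, 0.2)),
                         conmsat:::random_dna(sample(300:900, 1)))
    q <- structure(list(locus_id = "q", genome_id = "g", contig = "chr1",
                        start = 0, end = 0, motif = "AG", period = 2,
                        left_flank = flank, right_flank = "",
                        flank_len = 120, truncated_left = FALSE,
                        truncated_right = FALSE), class = "masked_query")
    tg <- one_contig_genome(target_seq, id = "t")
    hits <- search_genome(q, tg, identity_min = 0, min_flank_cov = 0,
                          min_hit_score = 1)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)
    ref <- Biostrings::pairwiseAlignment(flank, target_seq, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(max(hits$score), Biostrings::score(ref))
    # equal-scoring local optima may tie; the best hit must cover the
    # reference optimum's interval
    best <- hits[which.max(hits$score), ]
    sub <- Biostrings::subject(ref)
    expect_lt(max(best$start, Biostrings::start(sub) - 1),
              min(best$end, Biostrings::end(sub)))
  }
})

test_that("masked search matches the brute-force masked Smith-Waterman", {
  set.seed(55)
  for (rep in 1:6) {
    q <- paste0(conmsat:::random_dna(40), strrep("#", sample(10:25, 1)),
                conmsat:::random_dna(40))
    t <- paste0(conmsat:::random_dna(60),
                conmsat:::mutate_dna(gsub("#", "", q), 0.1),
                conmsat:::random_dna(60))
    got <- sw_masked_cpp(q, t, 1L, 2L, 5L, 2L)
    expect_equal(got$score, oracle_sw_masked(q, t))
  }
})

test_that("conservation assessment classifies planted configurations", {
  pl <- planted_locus(seed = 5, copies = 14)
  base <- pl$seq
  g1 <- one_contig_genome(base, "g1")
  locus <- list(contig = "chr1", start = pl$start, end = pl$end,
                motif = pl$motif, period = pl$period)
  q <- build_masked_query(g1, locus)

  # identical genomes: conserved_unique, repeat confirmed everywhere
  gs <- genome_set(lapply(1:4, function(i) one_contig_genome(base, paste0("g", i))))
  cl <- assess_conservation(q, gs)
  expect_equal(cl$status, "conserved_unique")
  expect_equal(nrow(cl$motif_table), 4)
  expect_true(all(cl$motif_table$repeat_confirmed))
  expect_equal(unique(cl$motif_table$motif), canonical_motif(pl$motif))
  expect_true(all(cl$motif_table$identity == 1))

  # flank region duplicated on a second contig: non_unique
  dup <- structure(list(
    genome_id = "g2", contigs = c(chr1 = base,
                                  chr2 = substr(base, 400, 1600)),
    softmask = list(chr1 = integer(0), chr2 = integer(0))),
    class = "msat_genome")
  cl2 <- assess_conservation(q, genome_set(list(g1, dup)))
  expect_equal(cl2$status, "non_unique")

  # conserved flanks but repeat tract deleted: still conserved_unique with
  # repeat_confirmed FALSE for that genome
  no_tract <- one_contig_genome(
    paste0(substr(base, 1, pl$start), substr(base, pl$end + 1, nchar(base))),
    "g3")
  cl3 <- assess_conservation(q, genome_set(list(g1, no_tract)))
  expect_equal(cl3$status, "conserved_unique")
  mt <- cl3$motif_table
  expect_true(mt$repeat_confirmed[mt$genome_id == "g1"])
  expect_false(mt$repeat_confirmed[mt$genome_id == "g3"])

  # unrelated genome: missing entirely
  set.seed(99)
  unrelated <- one_contig_genome(conmsat:::random_dna(nchar(base)), "g4")
  cl4 <- assess_conservation(q, genome_set(list(g1, unrelated)))
  expect_equal(cl4$status, "missing_in_genome")

  expect_error(assess_conservation(q, genome_set(list(g1))),
               class = "msat_query_error")
})

test_that("a query searched against its own genome returns itself at identity 1", {
  gs <- make_genome_set(3, 3, 0.05, c(12, 15), genome_length = 30000,
                        seed = 21)
  reps <- genome_tandem_repeats(gs$genomes[[1]])
  reps <- reps[!reps$is_homopolymer, ]
  for (i in seq_len(nrow(reps))) {
    q <- build_masked_query(gs$genomes[[1]], reps[i, ])
    hits <- search_genome(q, gs$genomes[[1]])
    self <- hits[hits$covers_both_flanks, ]
    expect_equal(nrow(self), 1)
    expect_equal(self$identity, 1.0)
    expect_lte(self$start, reps$start[i] - 190)
    expect_gte(self$end, reps$end[i] + 190)
  }
})

test_that("the tabular hit dump has 12 columns and strand-aware coordinates", {
  pl <- planted_locus(seed = 61)
  g <- one_contig_genome(pl$seq)
  locus <- list(contig = "chr1", start = pl$start, end = pl$end,
                motif = pl$motif, period = pl$period)
  q <- build_masked_query(g, locus)
  tg <- one_contig_genome(revcomp(pl$seq), id = "t1")
  hits <- search_genome(q, tg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tabular(q, hits, path)
  dump <- read.delim(path, header = FALSE)
  expect_equal(ncol(dump), 12)
  expect_equal(nrow(dump), nrow(hits))
  # minus-strand hit: target start > end, 1-based inclusive
  expect_true(all(dump$V9 > dump$V10))
  expect_equal(dump$V3, round(100 * hits$identity, 2))
})
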