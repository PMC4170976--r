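# Synthetic data with known ground truth: genome sets carrying planted
# conserved microsatellites, and genotype samples under Hardy-Weinberg
# equilibrium or a given inbreeding coefficient.

random_motif <- function(period) {
  repeat {
    m <- paste(sample(DNA_BASES, period, replace = TRUE), collapse = "")
    chars <- strsplit(m, "", fixed = TRUE)[[1]]
    if (length(unique(chars)) < 2) next # homopolymer
    # primitive unit: not a repetition of a shorter unit
    primitive <- TRUE
    for (d in seq_len(period - 1)) {
      if (period %% d == 0 &&
          m == strrep(substr(m, 1, d), period / d)) {
        primitive <- FALSE
        break
      }
    }
    if (primitive) return(m)
  }
}

#' Generate a genome set with planted conserved microsatellites
#'
#' An ancestral flank pair and repeat motif are drawn for each planted
#' locus.  Every genome receives a copy of each locus: the flanks with
#' i.i.d. substitutions at rate `flank_divergence`, the repeat tract with a
#' genome-specific copy number drawn uniformly from `repeat_copy_range`.
#' The background sequence is i.i.d. uniform ACGT, re-randomised per genome,
#' so only the planted flanks are conserved across genomes.  Byte-identical
#' output for a fixed seed.
#'
#' @param k_genomes number of genomes (>= 2).
#' @param n_loci number of planted loci.
#' @param flank_divergence per-base substitution rate in `[0, 0.5)`.
#' @param repeat_copy_range `c(min, max)` motif copies per genome.
#' @param genome_length contig length in bp per genome.
#' @param seed integer seed.
#' @param motif_periods candidate motif lengths for planted repeats.
#' @param flank_len length of the conserved flank on each side (bp).
#' @return list with `genomes` (an `msat_genome_set`) and `truth` (a
#'   `data.frame`: locus_id, genome_id, contig, start, end, motif, period,
#'   copies).
#' @export
make_genome_set <- function(k_genomes, n_loci, flank_divergence = 0.05,
                            repeat_copy_range = c(10, 15),
                            genome_length = 200000, seed = 1,
                            motif_periods = 3:5, flank_len = 220) {
  stopifnot(k_genomes >= 2, n_loci >= 0,
            flank_divergence >= 0, flank_divergence < 0.5)
  with_seed(seed, {
    max_cassette <- 2 * flank_len + max(repeat_copy_range) * max(motif_periods)
    if (n_loci > 0 && n_loci * (max_cassette + 100) > genome_length) {
      msat_error("msat_synth_error",
                 sprintf("%d loci do not fit in %d bp", n_loci, genome_length))
    }
    anc <- lapply(seq_len(n_loci), function(i) {
      list(locus_id = sprintf("planted%02d", i),
           motif = random_motif(sample(motif_periods, 1)),
           left = random_dna(flank_len),
           right = random_dna(flank_len))
    })
    genomes <- vector("list", k_genomes)
    truth <- list()
    for (g in seq_len(k_genomes)) {
      gid <- sprintf("genome%02d", g)
      # planted cassettes at evenly spaced slots, remainder random background
      if (n_loci > 0) {
        slot <- genome_length %/% n_loci
        pieces <- character(0)
        pos <- 0L
        for (i in seq_len(n_loci)) {
          copies <- sample(repeat_copy_range[1]:repeat_copy_range[2], 1)
          tract <- strrep(anc[[i]]$motif, copies)
          cassette <- paste0(mutate_dna(anc[[i]]$left, flank_divergence),
                             tract,
                             mutate_dna(anc[[i]]$right, flank_divergence))
          lead <- slot - nchar(cassette)
          pieces <- c(pieces, random_dna(lead %/% 2), cassette,
                      random_dna(lead - lead %/% 2))
          start <- pos + (lead %/% 2) + flank_len
          truth[[length(truth) + 1]] <- data.frame(
            locus_id = anc[[i]]$locus_id, genome_id = gid, contig = "chr1",
            start = start, end = start + nchar(tract),
            motif = canonical_motif(anc[[i]]$motif),
            period = nchar(anc[[i]]$motif), copies = copies,
            stringsAsFactors = FALSE)
          pos <- pos + slot
        }
        pieces <- c(pieces, random_dna(genome_length - pos))
        contig <- paste(pieces, collapse = "")
      } else {
        contig <- random_dna(genome_length)
      }
      genomes[[g]] <- structure(
        list(genome_id = gid, contigs = c(chr1 = contig),
             softmask = list(chr1 = integer(0))),
        class = "msat_genome")
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(locus_id = character(0), genome_id = character(0),
                 contig = character(0), start = integer(0), end = integer(0),
                 motif = character(0), period = integer(0),
                 copies = integer(0), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(genomes = genome_set(genomes), truth = truth)
  })
}

#' Specify a single-population genotype model
#'
#' @param loci named list: locus_id -> list(sizes = allele sizes in bp,
#'   freqs = allele frequencies summing to 1).
#' @param f inbreeding coefficient in `[0, 1]`.
#' @param n number of diploid individuals.
#' @param seed integer seed.
#' @return a `pop_model` object.
#' @export
pop_model <- function(loci, f = 0, n, seed = 1) {
  stopifnot(f >= 0, f <= 1, n >= 1)
  for (l in loci) {
    stopifnot(length(l$sizes) == length(l$freqs),
              abs(sum(l$freqs) - 1) < 1e-9)
  }
  structure(list(loci = loci, f = f, n = n, seed = seed),
            class = "pop_model")
}

#' Simulate diploid genotypes under an inbreeding model
#'
#' Each individual's genotype at each locus is drawn with
#' P(homozygote i) = p_i^2 + f p_i (1 - p_i) and
#' P(heterozygote ij) = 2 p_i p_j (1 - f); f = 0 is Hardy-Weinberg
#' equilibrium and f = 1 yields no heterozygotes.  Deterministic per seed.
#'
#' @param model a [pop_model()].
#' @return a `genotype_table`.
#' @export
simulate_genotypes <- function(model) {
  stopifnot(inherits(model, "pop_model"))
  with_seed(model$seed, {
    n <- model$n
    loci <- names(model$loci)
    a1 <- a2 <- matrix(NA_real_, n, length(loci))
    for (j in seq_along(loci)) {
      sizes <- model$loci[[j]]$sizes
      p <- model$loci[[j]]$freqs
      # draw identity-by-descent, then one or two allele copies
      ibd <- runif(n) < model$f
      x1 <- sample(sizes, n, replace = TRUE, prob = p)
      x2 <- sample(sizes, n, replace = TRUE, prob = p)
      x2[ibd] <- x1[ibd]
      a1[, j] <- pmin(x1, x2)
      a2[, j] <- pmax(x1, x2)
    }
    new_genotype_table(sprintf("ind%03d", seq_len(n)), loci, a1, a2)
  })
}
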