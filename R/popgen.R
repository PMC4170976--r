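# Population-genetic evaluation of genotyped markers.
#
# Observed heterozygosity is the fraction of heterozygous individuals.
# Expected heterozygosity is Nei's unbiased gene diversity,
# He = (2n / (2n - 1)) (1 - sum p_i^2), which corrects the naive estimator
# for sample size.  Hardy-Weinberg deviation is tested by a Monte-Carlo
# randomisation of the 2n allele copies into diploid pairings, using
# f = 1 - Ho/He as the statistic; genotypic linkage disequilibrium by a
# log-likelihood G statistic with one locus's genotypes permuted among
# individuals.  Permutation p-values use the add-one convention
# p = (1 + #extreme) / (B + 1).

locus_alleles <- function(table, locus) {
  j <- match(locus, table$loci)
  if (is.na(j)) {
    msat_error("msat_locus_error", sprintf("locus '%s' not in table", locus))
  }
  a1 <- table$a1[, j]
  a2 <- table$a2[, j]
  ok <- !is.na(a1) & !is.na(a2)
  list(a1 = a1[ok], a2 = a2[ok], n = sum(ok))
}

#' Allele frequencies at a locus
#'
#' Frequencies are computed over the 2n allele copies of fully genotyped
#' individuals; individuals with missing data at the locus are excluded.
#'
#' @param table a `genotype_table`.
#' @param locus locus id.
#' @return list with locus, n, freqs (named numeric, names = allele sizes),
#'   A (allele count), size_range `c(min, max)`.
#' @export
allele_frequencies <- function(table, locus) {
  al <- locus_alleles(table, locus)
  if (al$n == 0) {
    msat_error("msat_locus_error",
               sprintf("no genotyped individuals at locus '%s'", locus))
  }
  copies <- c(al$a1, al$a2)
  tab <- table(copies)
  freqs <- as.numeric(tab) / length(copies)
  names(freqs) <- names(tab)
  list(locus = locus, n = al$n, freqs = freqs, A = length(freqs),
       size_range = range(copies))
}

#' Observed heterozygosity at a locus
#'
#' @inheritParams allele_frequencies
#' @return fraction of genotyped individuals that are heterozygous.
#' @export
observed_heterozygosity <- function(table, locus) {
  al <- locus_alleles(table, locus)
  if (al$n == 0) {
    msat_error("msat_locus_error",
               sprintf("no genotyped individuals at locus '%s'", locus))
  }
  mean(al$a1 != al$a2)
}

#' Nei's unbiased expected heterozygosity
#'
#' He = (2n / (2n - 1)) (1 - sum p_i^2); 0 for a monomorphic locus.
#'
#' @param freqs output of [allele_frequencies()], or a numeric vector of
#'   allele frequencies (then `n` must be given).
#' @param n number of diploid individuals (when `freqs` is a plain vector).
#' @return unbiased expected heterozygosity in `[0, 1]`.
#' @export
expected_heterozygosity_unbiased <- function(freqs, n = NULL) {
  if (is.list(freqs)) {
    n <- freqs$n
    p <- freqs$freqs
  } else p <- freqs
  stopifnot(!is.null(n), n >= 1, abs(sum(p) - 1) < 1e-9)
  if (length(p) <= 1) return(0)
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

he_from_alleles <- function(a1, a2) {
  copies <- c(a1, a2)
  p <- as.numeric(table(copies)) / length(copies)
  n <- length(a1)
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

# log conditional probability of a genotype configuration given the allele
# counts (used by the probability-statistic HWE mode)
log_genotype_prob <- function(a1, a2) {
  n <- length(a1)
  het <- sum(a1 != a2)
  key <- paste(pmin(a1, a2), pmax(a1, a2))
  geno_counts <- table(key)
  allele_counts <- table(c(a1, a2))
  lfactorial(n) - sum(lfactorial(geno_counts)) + het * log(2) +
    sum(lfactorial(allele_counts)) - lfactorial(2 * n)
}

#' Monte-Carlo test for Hardy-Weinberg deviation
#'
#' Randomises the 2n observed allele copies into diploid pairings.  With
#' `statistic = "f"` (default) the statistic is f = 1 - Ho/He, compared
#' two-sided on |f|; with `statistic = "prob"` the statistic is the
#' conditional probability of the genotype configuration, and configurations
#' at most as probable as the observed one count as extreme.
#'
#' @param table a `genotype_table`.
#' @param locus locus id (must be polymorphic, n >= 2).
#' @param permutations number of Monte-Carlo randomisations.
#' @param seed integer seed; the test is deterministic for a fixed seed.
#' @param statistic `"f"` or `"prob"`.
#' @return list with p.value, statistic, f_obs (or log_prob_obs),
#'   permutations, seed.
#' @export
hwe_test <- function(table, locus, permutations = 10000, seed = NULL,
                     statistic = c("f", "prob")) {
  statistic <- match.arg(statistic)
  al <- locus_alleles(table, locus)
  if (al$n < 2) {
    msat_error("msat_locus_error", sprintf("locus '%s': n < 2", locus))
  }
  copies <- c(rbind(al$a1, al$a2)) # interleaved so pairs are adjacent
  if (length(unique(copies)) < 2) {
    msat_error("msat_locus_error",
               sprintf("locus '%s' is monomorphic: HWE test undefined", locus))
  }
  n <- al$n
  odd <- seq(1, 2 * n, by = 2)
  even <- odd + 1
  with_seed(seed, {
    if (statistic == "f") {
      he <- he_from_alleles(al$a1, al$a2)
      f_obs <- 1 - mean(al$a1 != al$a2) / he
      extreme <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample(copies)
        ho_b <- mean(perm[odd] != perm[even])
        if (abs(1 - ho_b / he) >= abs(f_obs) - 1e-12) extreme <- extreme + 1L
      }
      list(p.value = (1 + extreme) / (permutations + 1), statistic = "f",
           f_obs = f_obs, permutations = permutations, seed = seed)
    } else {
      lp_obs <- log_genotype_prob(al$a1, al$a2)
      extreme <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample(copies)
        if (log_genotype_prob(perm[odd], perm[even]) <= lp_obs + 1e-12) {
          extreme <- extreme + 1L
        }
      }
      list(p.value = (1 + extreme) / (permutations + 1), statistic = "prob",
           log_prob_obs = lp_obs, permutations = permutations, seed = seed)
    }
  })
}

#' Monte-Carlo test for genotypic linkage disequilibrium
#'
#' Log-likelihood G statistic on the two-locus genotype contingency table;
#' the null is generated by permuting one locus's genotypes among the
#' individuals genotyped at both loci.
#'
#' @param table a `genotype_table`.
#' @param locusA,locusB locus ids (both polymorphic, >= 2 shared
#'   individuals).
#' @param permutations number of permutations.
#' @param seed integer seed.
#' @return list with p.value, g_obs, n, permutations, seed.
#' @export
ld_test <- function(table, locusA, locusB, permutations = 10000,
                    seed = NULL) {
  ja <- match(locusA, table$loci)
  jb <- match(locusB, table$loci)
  if (is.na(ja) || is.na(jb)) {
    msat_error("msat_locus_error", "locus not in table")
  }
  ok <- !is.na(table$a1[, ja]) & !is.na(table$a1[, jb])
  if (sum(ok) < 2) {
    msat_error("msat_locus_error",
               "fewer than 2 individuals genotyped at both loci")
  }
  ga <- paste(table$a1[ok, ja], table$a2[ok, ja])
  gb <- paste(table$a1[ok, jb], table$a2[ok, jb])
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2) {
    msat_error("msat_locus_error", "monomorphic locus: LD test undefined")
  }
  g_stat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- tab > 0
    2 * sum(tab[idx] * log(tab[idx] / e[idx]))
  }
  g_obs <- g_stat(ga, gb)
  with_seed(seed, {
    extreme <- 0L
    for (b in seq_len(permutations)) {
      if (g_stat(ga, sample(gb)) >= g_obs - 1e-12) extreme <- extreme + 1L
    }
    list(p.value = (1 + extreme) / (permutations + 1), g_obs = g_obs,
         n = length(ga), permutations = permutations, seed = seed)
  })
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise significance level.
#' @param n_tests number of tests performed (>= 1).
#' @return per-test significance threshold alpha / n_tests.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) {
    msat_error("msat_popgen_error", "n_tests must be >= 1")
  }
  alpha / n_tests
}

#' Per-locus summary statistics
#'
#' @param table a `genotype_table`.
#' @param locus locus id.
#' @param species optional species/population label carried into the row.
#' @param seed seed for the HWE randomisation.
#' @param permutations HWE permutations.
#' @param hwe_alpha significance level for the deviation flag.
#' @return a one-row `data.frame`: locus, species, amplified, n, A, size_min,
#'   size_max, ho, he, hwe_p, hwe_deviates.
#' @export
summarize_locus <- function(table, locus, species = NA_character_,
                            seed = NULL, permutations = 10000,
                            hwe_alpha = 0.05) {
  freqs <- allele_frequencies(table, locus)
  ho <- observed_heterozygosity(table, locus)
  he <- expected_heterozygosity_unbiased(freqs)
  if (freqs$A > 1) {
    hw <- hwe_test(table, locus, permutations = permutations, seed = seed)
    hwe_p <- hw$p.value
    dev <- hwe_p < hwe_alpha
  } else {
    hwe_p <- NA_real_
    dev <- FALSE
  }
  data.frame(locus = locus, species = species, amplified = TRUE,
             n = freqs$n, A = freqs$A,
             size_min = freqs$size_range[1], size_max = freqs$size_range[2],
             ho = ho, he = he, hwe_p = hwe_p, hwe_deviates = dev,
             stringsAsFactors = FALSE)
}

#' Summaries for every locus of a table
#'
#' @inheritParams summarize_locus
#' @return a `data.frame` with one row per locus (see [summarize_locus()]).
#' @export
summarize_table <- function(table, species = NA_character_, seed = NULL,
                            permutations = 10000, hwe_alpha = 0.05) {
  rows <- lapply(seq_along(table$loci), function(j) {
    summarize_locus(table, table$loci[j], species = species,
                    seed = if (is.null(seed)) NULL else seed + j,
                    permutations = permutations, hwe_alpha = hwe_alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate marker-panel summaries across species
#'
#' Per species, counts polymorphic loci (A > 1 among amplified) and
#' polymorphic loci not deviating from HWE; the per-species counts are
#' averaged across species (sample SD).  Allele number, Ho and He are
#' averaged by pooling all polymorphic-in-HWE loci across species (sample
#' SD) — pooling, not averaging species means, is what characterises the
#' marker panel as a whole.
#'
#' @param summaries a `data.frame` with columns species, amplified, A, ho,
#'   he, hwe_deviates (logical or "yes"/"no"), e.g. [load_table2_fixture()]
#'   output or rows from [summarize_table()].
#' @return list with `per_species` (data.frame species, n_amplified,
#'   n_polymorphic, n_polymorphic_hwe), `mean_polymorphic`,
#'   `sd_polymorphic`, `mean_polymorphic_hwe`, `sd_polymorphic_hwe`,
#'   `n_pooled`, and pooled `mean_A`, `sd_A`, `mean_ho`, `sd_ho`, `mean_he`,
#'   `sd_he` (NA-flagged when no locus qualifies).
#' @export
aggregate_summaries <- function(summaries) {
  stopifnot(all(c("species", "amplified", "A", "ho", "he", "hwe_deviates")
                %in% names(summaries)))
  dev <- summaries$hwe_deviates
  if (!is.logical(dev)) dev <- dev == "yes"
  amp <- summaries$amplified
  poly <- amp & !is.na(summaries$A) & summaries$A > 1
  inhwe <- poly & !dev
  species <- sort(unique(summaries$species))
  per_species <- data.frame(
    species = species,
    n_amplified = vapply(species, function(s) sum(amp[summaries$species == s]),
                         integer(1)),
    n_polymorphic = vapply(species, function(s)
      sum(poly[summaries$species == s]), integer(1)),
    n_polymorphic_hwe = vapply(species, function(s)
      sum(inhwe[summaries$species == s]), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_species) <- NULL
  pool <- summaries[inhwe, , drop = FALSE]
  pooled <- function(f, x) if (nrow(pool)) f(x) else NA_real_
  list(
    per_species = per_species,
    mean_polymorphic = mean(per_species$n_polymorphic),
    sd_polymorphic = sd(per_species$n_polymorphic),
    mean_polymorphic_hwe = mean(per_species$n_polymorphic_hwe),
    sd_polymorphic_hwe = sd(per_species$n_polymorphic_hwe),
    n_pooled = nrow(pool),
    mean_A = pooled(mean, pool$A), sd_A = pooled(sd, pool$A),
    mean_ho = pooled(mean, pool$ho), sd_ho = pooled(sd, pool$ho),
    mean_he = pooled(mean, pool$he), sd_he = pooled(sd, pool$he))
}
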