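# Heterozygosity, Hardy-Weinberg and LD permutation tests, aggregates.

test_that("allele frequencies come from fully genotyped individuals", {
  tab <- make_table(c(rep(230, 9), 230), c(rep(230, 8), 250, 250))
  f <- allele_frequencies(tab, "L1")
  expect_equal(f$n, 10)
  expect_equal(unname(f$freqs), c(0.9, 0.1))
  expect_equal(f$A, 2)
  expect_equal(f$size_range, c(230, 250))

  # one individual missing: n = 9, frequencies over 18 copies
  tab2 <- make_table(c(rep(230, 9), NA), c(rep(230, 8), 250, NA))
  f2 <- allele_frequencies(tab2, "L1")
  expect_equal(f2$n, 9)
  expect_equal(unname(f2$freqs), c(17 / 18, 1 / 18))

  # all identical homozygotes
  f3 <- allele_frequencies(make_table(rep(100, 5), rep(100, 5)), "L1")
  expect_equal(f3$A, 1)
  expect_equal(unname(f3$freqs), 1)

  tab4 <- make_table(NA_real_, NA_real_)
  expect_error(allele_frequencies(tab4, "L1"), class = "msat_locus_error")
  expect_error(allele_frequencies(tab, "nope"), class = "msat_locus_error")
})

test_that("observed heterozygosity is the heterozygote fraction", {
  expect_equal(observed_heterozygosity(
    make_table(c(rep(230, 8), 230, 230), c(rep(230, 8), 250, 250)), "L1"),
    0.2)
  expect_equal(observed_heterozygosity(
    make_table(rep(100, 6), rep(100, 6)), "L1"), 0)
  expect_equal(observed_heterozygosity(
    make_table(rep(100, 6), rep(104, 6)), "L1"), 1)
})

test_that("unbiased He matches its closed form and prints as the table row", {
  # n = 10, p = 0.9/0.1: (20/19)(1 - 0.82) = 0.1895 -> 0.19
  tab <- make_table(c(rep(230, 9), 230), c(rep(230, 8), 250, 250))
  he <- expected_heterozygosity_unbiased(allele_frequencies(tab, "L1"))
  expect_equal(he, (20 / 19) * (1 - 0.9^2 - 0.1^2))
  expect_equal(round(he, 2), 0.19)
  # monomorphic: exactly 0
  expect_equal(expected_heterozygosity_unbiased(
    allele_frequencies(make_table(rep(1, 4), rep(1, 4)), "L1")), 0)
  # large-n limit for two equifrequent alleles approaches 0.5
  expect_equal(expected_heterozygosity_unbiased(c(0.5, 0.5), n = 1e9), 0.5,
               tolerance = 1e-8)
})

test_that("unbiased He equals the brute-force definition on random tables", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    sizes <- seq(200, by = 4, length.out = sample(2:6, 1))
    p <- as.numeric(rmultinom(1, 50, rep(1, length(sizes))) / 50)
    if (any(p == 0)) next
    tab <- random_genotype_table(n, sizes = sizes, freqs = p, seed = rep)
    f <- allele_frequencies(tab, "L1")
    copies <- c(tab$a1[, 1], tab$a2[, 1])
    brute <- (2 * n / (2 * n - 1)) *
      (1 - sum((table(copies) / (2 * n))^2))
    expect_equal(expected_heterozygosity_unbiased(f), brute)
    expect_true(f$A == 1 || expected_heterozygosity_unbiased(f) > 0)
  }
})

test_that("HWE test flags heterozygote deficit and excess", {
  # 20 individuals, two alleles at 0.5, zero heterozygotes
  tab <- make_table(c(rep(100, 10), rep(120, 10)),
                    c(rep(100, 10), rep(120, 10)))
  r <- hwe_test(tab, "L1", permutations = 4999, seed = 1)
  expect_lt(r$p.value, 0.001)
  expect_equal(r$f_obs, 1)
  # perfect heterozygote excess (all heterozygous, n = 10)
  tab2 <- make_table(rep(100, 10), rep(120, 10))
  r2 <- hwe_test(tab2, "L1", permutations = 1999, seed = 1)
  expect_lt(r2$p.value, 0.05)
  expect_lt(r2$f_obs, 0)
  # monomorphic locus: undefined
  expect_error(hwe_test(make_table(rep(1, 5), rep(1, 5)), "L1"),
               class = "msat_locus_error")
})

test_that("permutation p-values are seed-deterministic and label-invariant", {
  tab <- random_genotype_table(25, sizes = c(230, 234, 238),
                               freqs = c(0.5, 0.3, 0.2), f = 0.3, seed = 4)
  p1 <- hwe_test(tab, "L1", permutations = 500, seed = 42)$p.value
  p2 <- hwe_test(tab, "L1", permutations = 500, seed = 42)$p.value
  expect_identical(p1, p2)
  p3 <- hwe_test(tab, "L1", permutations = 500, seed = 43)$p.value
  # relabelling allele sizes does not change the statistic's distribution
  relab <- tab
  relab$a1 <- relab$a1 * 3 + 1000
  relab$a2 <- relab$a2 * 3 + 1000
  expect_identical(hwe_test(relab, "L1", permutations = 500, seed = 42)$p.value,
                   p1)
  expect_false(isTRUE(all.equal(p1, 0))) # add-one convention: never zero
  expect_gte(min(p1, p3), 1 / 501)
})

test_that("the probability-statistic mode agrees on clear-cut cases", {
  tab <- make_table(c(rep(100, 10), rep(120, 10)),
                    c(rep(100, 10), rep(120, 10)))
  r <- hwe_test(tab, "L1", permutations = 1999, seed = 7,
                statistic = "prob")
  expect_lt(r$p.value, 0.01)
  tabok <- random_genotype_table(30, seed = 11)
  r2 <- hwe_test(tabok, "L1", permutations = 999, seed = 7,
                 statistic = "prob")
  expect_gt(r2$p.value, 0.05)
})

test_that("LD test: duplicated locus gives the minimal attainable p", {
  tt <- random_genotype_table(20, sizes = c(1, 2, 3), freqs = c(.4, .4, .2),
                              seed = 9)
  tab <- make_table(cbind(tt$a1, tt$a1), cbind(tt$a2, tt$a2),
                    loci = c("A", "B"))
  r <- ld_test(tab, "A", "B", permutations = 999, seed = 2)
  expect_equal(r$p.value, 1 / 1000)
  # deterministic under the seed
  expect_identical(ld_test(tab, "A", "B", permutations = 999, seed = 2)$p.value,
                   r$p.value)
})

test_that("LD test preconditions: polymorphism and shared individuals", {
  tt <- random_genotype_table(10, sizes = c(1, 2), freqs = c(.6, .4), seed = 3)
  mono <- make_table(cbind(tt$a1, rep(7, 10)), cbind(tt$a2, rep(7, 10)),
                     loci = c("A", "B"))
  expect_error(ld_test(mono, "A", "B"), class = "msat_locus_error")
  two <- make_table(cbind(tt$a1, c(1, 2, rep(NA, 8))),
                    cbind(tt$a2, c(1, 2, rep(NA, 8))), loci = c("A", "B"))
  few <- make_table(cbind(tt$a1, c(1, rep(NA, 9))),
                    cbind(tt$a2, c(2, rep(NA, 9))), loci = c("A", "B"))
  expect_error(ld_test(few, "A", "B"), class = "msat_locus_error")
})

test_that("independent loci are not flagged as associated", {
  set.seed(12)
  rejections <- 0L
  n_rep <- 40L
  for (rep in seq_len(n_rep)) {
    tab <- random_genotype_table(25, loci = c("A", "B"),
                                 sizes = c(1, 2, 3), freqs = c(.5, .3, .2),
                                 seed = 1000 + rep)
    if (ld_test(tab, "A", "B", permutations = 199,
                seed = rep)$p.value <= 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, qbinom(0.999, n_rep, 0.05) + 1)
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), class = "msat_popgen_error")
})

test_that("locus summaries assemble the component statistics", {
  tab <- random_genotype_table(10, sizes = c(230, 250), freqs = c(0.9, 0.1),
                               seed = 21)
  s <- summarize_locus(tab, "L1", species = "sp", seed = 5,
                       permutations = 999)
  f <- allele_frequencies(tab, "L1")
  expect_equal(s$n, f$n)
  expect_equal(s$A, f$A)
  expect_equal(s$ho, observed_heterozygosity(tab, "L1"))
  expect_equal(s$he, expected_heterozygosity_unbiased(f))
  expect_equal(s$size_min, f$size_range[1])
  if (s$A > 1) expect_false(is.na(s$hwe_p))

  mono <- make_table(rep(100, 8), rep(100, 8))
  sm <- summarize_locus(mono, "L1")
  expect_equal(sm$A, 1)
  expect_equal(sm$ho, 0)
  expect_equal(sm$he, 0)
  expect_true(is.na(sm$hwe_p))
  expect_false(sm$hwe_deviates)

  empty <- make_table(NA_real_, NA_real_)
  expect_error(summarize_locus(empty, "L1"), class = "msat_locus_error")
})

test_that("aggregates reproduce the published panel characterisation", {
  agg <- aggregate_summaries(load_table2_fixture())
  expect_equal(round(agg$mean_polymorphic, 2), 12.83)
  expect_equal(round(agg$sd_polymorphic, 2), 6.15)
  expect_equal(round(agg$mean_A, 2), 4.59)
  expect_equal(round(agg$sd_A, 2), 2.41)
  expect_equal(round(agg$mean_ho, 3), 0.534)
  expect_equal(round(agg$sd_ho, 2), 0.22)
  expect_equal(round(agg$mean_he, 2), 0.61)
  expect_equal(round(agg$sd_he, 2), 0.22)
  # the per-species polymorphic-and-HWE counts pool to 66 loci (11.0 per
  # species; the published 11.16 is not reproducible from the table)
  expect_equal(agg$n_pooled, 66)
  expect_equal(agg$mean_polymorphic_hwe, 11)
  expect_equal(sum(agg$per_species$n_polymorphic_hwe), agg$n_pooled)
})

test_that("aggregates flag species without polymorphic loci", {
  df <- data.frame(species = "only", amplified = TRUE, A = 1, ho = 0, he = 0,
                   hwe_deviates = FALSE)
  agg <- aggregate_summaries(df)
  expect_equal(agg$per_species$n_polymorphic, 0)
  expect_true(is.na(agg$mean_A))
  expect_true(is.na(agg$mean_ho))
})
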