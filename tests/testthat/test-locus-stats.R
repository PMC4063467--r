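test_that("heterozygosity matches closed forms and is relabel-invariant", {
  ## monomorphic locus
  mono <- dataset_from_genotypes(rep(100L, 8), rep(100L, 8))
  expect_equal(unname(heterozygosity(mono, "L1")), c(0, 0))
  ## n = 5 diploids, two alleles at 0.5: unbiased He = (10/9) * 0.5
  d <- dataset_from_genotypes(c(100, 100, 102, 100, 102),
                              c(100, 102, 102, 102, 100))
  h <- heterozygosity(d, "L1")
  expect_equal(unname(h["He"]), 10 / 9 * 0.5, tolerance = 1e-12)
  expect_equal(unname(h["Ho"]), 3 / 5)
  expect_equal(unname(heterozygosity(d, "L1", unbiased = FALSE)["He"]),
               0.5)
  ## relabeling alleles leaves He and Ho unchanged
  d2 <- dataset_from_genotypes(ifelse(d$allele1[, 1] == 100, 880, 770),
                               ifelse(d$allele2[, 1] == 100, 880, 770))
  expect_equal(heterozygosity(d2, "L1"), h)
  ## large-sample He approaches plug-in truth
  set.seed(4)
  p <- c(0.5, 0.3, 0.2)
  g1 <- sample(c(100L, 102L, 104L), 1000, TRUE, p)
  g2 <- sample(c(100L, 102L, 104L), 1000, TRUE, p)
  big <- dataset_from_genotypes(g1, g2)
  expect_lt(abs(heterozygosity(big, "L1")["He"] - (1 - sum(p^2))), 0.01)
})

test_that("FIS jackknife covers zero under HWE and detects the Wahlund effect", {
  ## boundary: all heterozygous, two alleles -> FIS = -1
  allhet <- genotype_dataset(
    matrix(100L, 9, 1, dimnames = list(NULL, "L1")),
    matrix(102L, 9, 1, dimnames = list(NULL, "L1")),
    sprintf("i%d", 1:9), rep(c("a", "b", "c"), each = 3),
    data.frame(id = c("a", "b", "c"), name = c("a", "b", "c"),
               latitude = c(28, 27.5, 27), longitude = -97))
  fj <- fis_with_jackknife(allhet, "L1")
  expect_equal(fj$fis, -1)
  expect_error(fis_with_jackknife(tiny_dataset(), "locA"), ">= 3 groups")

  ## null coverage: HWE groups, CI should usually cover 0
  set.seed(21)
  cover <- replicate(30, {
    g1 <- sample(c(100L, 102L), 150, TRUE)
    g2 <- sample(c(100L, 102L), 150, TRUE)
    d <- genotype_dataset(
      matrix(g1, ncol = 1, dimnames = list(NULL, "L1")),
      matrix(g2, ncol = 1, dimnames = list(NULL, "L1")),
      sprintf("i%d", 1:150), rep(c("a", "b", "c", "d", "e"), each = 30),
      data.frame(id = letters[1:5], name = letters[1:5],
                 latitude = 28:24, longitude = -97))
    fj <- fis_with_jackknife(d, "L1")
    fj$ci[1] <= 0 && fj$ci[2] >= 0
  })
  expect_gte(mean(cover), 0.8)

  ## mechanical-mix groups: positive FIS, CI excludes 0
  fr <- draw_divergent_frequencies(1, 2, 0.8, seed = 6)
  mech <- simulate_mechanical_mix_model(fr$north, fr$south,
                                        rep(0.5, 4), 80, seed = 7)
  fj2 <- fis_with_jackknife(mech$dataset, "L01")
  expect_gt(fj2$fis, 0)
  expect_true(fj2$significant)
})

test_that("Monte-Carlo HWE p matches full enumeration on small biallelic tables", {
  ## all 2-allele tables with n <= 6 here (the acceptance suite covers
  ## n <= 10); MC tolerance 0.02
  for (n in 3:6) {
    for (nA in 1:n) {
      hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
      for (h in hs) {
        aa <- (nA - h) / 2; bb <- n - aa - h
        exact <- hwe_enum_pvalue(aa, h, bb)
        mc <- hwe_exact_test(hwe_table_dataset(aa, h, bb),
                             "L1", n_mc = 4000, seed = 77)
        expect_lt(abs(mc - exact), 0.02)
      }
    }
  }
  ## monomorphic convention and iteration floor
  expect_equal(hwe_exact_test(dataset_from_genotypes(rep(100L, 5),
                                                     rep(100L, 5)),
                              "L1"), 1)
  expect_error(hwe_exact_test(tiny_dataset(), "locA", n_mc = 10),
               "1000")
})

test_that("HWE p-values are roughly uniform for hybrid-swarm samples", {
  fr <- draw_divergent_frequencies(1, 6, 0.4, seed = 13)
  set.seed(14)
  ps <- replicate(60, {
    sw <- simulate_hybrid_swarm_model(fr$north, fr$south, 0.5, 60,
                                      seed = sample.int(1e6, 1))
    hwe_exact_test(sw$dataset, "L01", n_mc = 1000,
                   seed = sample.int(1e6, 1))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("EM haplotype likelihood matches the grid oracle on 2x2 cases", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 40
    ## draw genotypes with some built-in LD
    h <- c(0.4, 0.1, 0.1, 0.4)
    hap <- matrix(c(100L, 200L, 100L, 202L, 102L, 200L, 102L, 202L),
                  4, 2, byrow = TRUE)
    pick <- function() hap[sample.int(4, 1, prob = h), ]
    g <- replicate(2 * n, pick())
    y1a <- g[1, seq(1, 2 * n, 2)]; y1b <- g[2, seq(1, 2 * n, 2)]
    y2a <- g[1, seq(2, 2 * n, 2)]; y2b <- g[2, seq(2, 2 * n, 2)]
    fit <- contactzone:::em_haplotypes(y1a, y2a, y1b, y2b)
    oracle <- haplo_grid_loglik(y1a, y2a, y1b, y2b)
    expect_lt(abs(fit$loglik - oracle), 1e-6)
    expect_equal(sum(fit$haplotypes), 1, tolerance = 1e-9)
  }
})

test_that("LD test finds mixture-induced disequilibrium and stays null otherwise", {
  fr <- draw_divergent_frequencies(2, 2, 0.9, seed = 41)
  mech <- simulate_mechanical_mix_model(fr$north, fr$south, 0.5, 100,
                                        seed = 42)
  lt <- ld_lr_test(mech$dataset, "L01", "L02", n_permutations = 100,
                   seed = 43)
  expect_lt(lt$p, 0.01)
  expect_gt(lt$lr, 0)
  ## independent loci in one panmictic pool: p not extreme
  sw <- simulate_hybrid_swarm_model(fr$north, fr$south, 0.5, 100,
                                    seed = 44)
  lt0 <- ld_lr_test(sw$dataset, "L01", "L02", n_permutations = 100,
                    seed = 45)
  expect_gt(lt0$p, 0.025)
  expect_error(ld_lr_test(tiny_dataset(), "locA", "locB"), ">= 10")
})

test_that("sequential Bonferroni reproduces hand-worked cases and its sandwich property", {
  expect_equal(sequential_bonferroni(c(0.001, 0.04), 0.05), c(TRUE, TRUE))
  expect_equal(sequential_bonferroni(c(0.03, 0.04), 0.05),
               c(FALSE, FALSE))
  expect_equal(sequential_bonferroni(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(sequential_bonferroni(numeric(0)), logical(0))
  ## Holm rejects a superset of Bonferroni and a subset of unadjusted
  set.seed(55)
  for (i in 1:25) {
    p <- stats::runif(sample(2:12, 1))^sample(1:3, 1)
    holm <- sequential_bonferroni(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(holm[bonf]))
    expect_true(all(raw[holm]))
  }
})

test_that("null-allele screen gates on the mean Chakraborty estimate", {
  ## Ho = He in all samples -> 0, pass
  d <- hwe_site_pair(0.5, 0.5, n = 200, seed = 61)
  scr <- null_allele_screen(d, "L1")
  expect_lt(scr$mean_null_freq, 0.05)
  expect_true(scr$pass)
  ## planted nulls at 0.2 -> fail
  plan <- data.frame(latitude = c(28.5, 27.5), n = 300,
                     composition = c("pure_north", "pure_south"), r = NA)
  s1 <- simulate_dataset(sim_config(n_loci = 3, alleles_per_locus = 10,
                                    site_plan = plan,
                                    null_allele_rate = 0.2, seed = 62))
  scr1 <- null_allele_screen(s1$dataset, "L01")
  expect_gt(scr1$mean_null_freq, 0.05)
  expect_false(scr1$pass)
  ## Ho > He truncates at zero
  allhet <- dataset_from_genotypes(rep(100L, 10), rep(102L, 10))
  expect_equal(null_allele_screen(allhet, "L1")$mean_null_freq, 0)
})

test_that("duplicate-run genotyping error rate counts discordant unordered pairs", {
  mk <- function(g1, g2) dataset_from_genotypes(g1, g2)
  base1 <- rep(100L, 60); base2 <- rep(102L, 60)
  r1 <- mk(base1, base2)
  ## one discordant duplicate of 60 -> 0.017 (Table-2-style value)
  g2b <- base2; g2b[1] <- 104L
  r2 <- mk(base1, g2b)
  expect_equal(unname(genotyping_error_rate(r1, r2)), 1 / 60,
               tolerance = 1e-9)
  expect_equal(round(unname(genotyping_error_rate(r1, r2)), 3), 0.017)
  ## identical runs -> 0; order within genotype ignored
  r3 <- mk(base2, base1)
  expect_equal(unname(genotyping_error_rate(r1, r3)), 0)
  ## all discordant -> 1; missing pairs excluded
  r4 <- mk(rep(104L, 60), rep(106L, 60))
  expect_equal(unname(genotyping_error_rate(r1, r4)), 1)
  g1m <- base1; g1m[1:10] <- NA
  suppressWarnings(r5 <- mk(g1m, ifelse(is.na(g1m), NA, base2)))
  expect_equal(unname(genotyping_error_rate(r5, r1)), 0)
})
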