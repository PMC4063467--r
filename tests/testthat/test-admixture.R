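test_that("pure individuals at strong divergence get own-cluster Q above 0.9", {
  sim <- simulate_dataset(sim_config(site_plan = macro_site_plan(45),
                                     seed = 71))
  qm <- fit_admixture(sim$dataset, mode = "em")
  north <- sim$truth$site_plan$composition == "pure_north"
  q1 <- qm$Q[, 1]
  is_north <- sim$dataset$ind$site %in% sim$truth$site_plan$id[north]
  expect_gt(mean(q1[is_north] > 0.9), 0.95)
  expect_gt(mean(q1[!is_north] < 0.1), 0.95)
  expect_true(all(abs(rowSums(qm$Q) - 1) < 1e-9))
})

test_that("allele relabeling leaves Q unchanged up to cluster label", {
  plan <- data.frame(latitude = c(28.5, 27.5), n = 40,
                     composition = c("pure_north", "pure_south"), r = NA)
  sim <- simulate_dataset(sim_config(n_loci = 5, alleles_per_locus = 6,
                                     site_plan = plan, seed = 72))
  d <- sim$dataset
  qm <- fit_admixture(d, mode = "em")
  ## relabel every allele (order-preserving shift keeps sorted order)
  d2 <- d
  d2$allele1 <- d$allele1 + 500L
  d2$allele2 <- d$allele2 + 500L
  d2$loci <- lapply(d$loci, function(a) a + 500L)
  qm2 <- fit_admixture(d2, mode = "em")
  expect_lt(max(abs(qm$Q[, 1] - qm2$Q[, 1])), 1e-8)
})

test_that("gibbs and EM modes agree on well-separated data", {
  ## the Gibbs posterior mean carries Beta-prior shrinkage of order
  ## 1/(2L + 2) that the maximum-likelihood EM fixed point does not, so
  ## agreement within 0.05 needs enough allele copies per individual:
  ## 24 loci keeps the shrinkage safely inside the contract
  plan <- data.frame(latitude = c(28.5, 27.5), n = 40,
                     composition = c("pure_north", "pure_south"), r = NA)
  sim <- simulate_dataset(sim_config(n_loci = 24, alleles_per_locus = 8,
                                     target_fct = 0.5,
                                     site_plan = plan, seed = 73))
  em <- fit_admixture(sim$dataset, mode = "em")
  gb <- fit_admixture(sim$dataset, mode = "gibbs", burn_in = 1000,
                      n_iter = 6000, seed = 74)
  expect_lt(mean(abs(em$Q[, 1] - gb$Q[, 1])), 0.05)
})

test_that("no-structure data give Q centred at one half", {
  set.seed(75)
  n <- 80
  g <- function() sample(c(100L, 102L, 104L), n, TRUE)
  a1 <- cbind(L1 = g(), L2 = g(), L3 = g())
  a2 <- cbind(L1 = g(), L2 = g(), L3 = g())
  d <- genotype_dataset(a1, a2, sprintf("i%d", 1:n),
                        rep(c("a", "b"), each = n / 2),
                        data.frame(id = c("a", "b"), name = c("a", "b"),
                                   latitude = c(28, 27), longitude = -97))
  qm <- fit_admixture(d, mode = "em")
  expect_lt(abs(mean(qm$Q[, 1]) - 0.5), 0.15)
})

test_that("supervised scoring solves the closed-form reference cases", {
  ## pure references at fixed differences
  fn <- list(L1 = c(`100` = 1, `102` = 0))
  fs <- list(L1 = c(`100` = 0, `102` = 1))
  ## F1 individuals: Q = 0.5 by likelihood symmetry
  f1 <- dataset_from_genotypes(rep(100L, 10), rep(102L, 10))
  q <- ancestry_scores(f1, fn, fs)
  expect_equal(unname(q), rep(0.5, 10), tolerance = 0.02)
  ## pure-north query: Q -> 1
  pn <- dataset_from_genotypes(rep(100L, 10), rep(100L, 10))
  expect_gt(min(ancestry_scores(pn, fn, fs)), 0.99)
  ## all genotypes missing: prior mean
  suppressWarnings(
    miss <- dataset_from_genotypes(rep(NA_integer_, 4),
                                   rep(NA_integer_, 4)))
  miss$loci$L1 <- c(100L, 102L)
  expect_equal(unname(ancestry_scores(miss, fn, fs)), rep(0.5, 4))
})

test_that("fit_supervised estimates references and flags small groups", {
  sim <- simulate_dataset(sim_config(site_plan = macro_site_plan(30),
                                     seed = 76))
  refs <- list(northern = sim$truth$site_plan$id[1:5],
               southern = sim$truth$site_plan$id[6:10])
  sup <- fit_supervised(sim$dataset, refs)
  un <- fit_admixture(sim$dataset, mode = "em")
  expect_lt(mean(abs(sup$Q[, 1] - un$Q[, 1])), 0.05)
  expect_error(fit_supervised(sim$dataset,
                              list(northern = character(0),
                                   southern = refs$southern)),
               "no reference")
})

test_that("sample_mean_q is the arithmetic mean and ancestry recovery is accurate", {
  qm <- structure(list(
    Q = cbind(Q1 = c(0.9, 0.5), Q2 = c(0.1, 0.5)),
    ind = data.frame(id = c("i1", "i2"), site = c("s", "s"))),
    class = "qmatrix")
  expect_equal(unname(sample_mean_q(qm, "s")), c(0.7, 0.3))
  expect_error(sample_mean_q(qm, "zzz"), "no individuals")

  ## mechanical_mix(0.68) site mean Q tracks the composition, and
  ## per-individual ancestry error stays below 0.1 at Fct 0.4, 11 loci
  plan <- rbind(macro_site_plan(45)[c(1:2, 9:10), ],
                data.frame(id = "MIX", latitude = 27.9, n = 45,
                           composition = "mechanical_mix", r = 0.68))
  sim <- simulate_dataset(sim_config(site_plan = plan, seed = 77))
  qm2 <- fit_admixture(sim$dataset, mode = "em")
  mq <- sample_mean_q(qm2, "MIX")
  true_mix <- mean(sim$truth$ancestry[sim$dataset$ind$site == "MIX"])
  expect_lt(abs(mq[1] - true_mix), 0.1)
  mae <- mean(abs(qm2$Q[, 1] - sim$truth$ancestry))
  expect_lte(mae, 0.1)
})
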