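region_map <- function(plan) {
  r <- ifelse(plan$composition == "pure_north", "northern", "southern")
  stats::setNames(r, plan$id)
}

test_that("maximal and null divergence give Fct at the boundaries", {
  ## regions fixed for alternative alleles at every locus -> Fct = 1
  ## (8 sites so the site-permutation null has enough distinct
  ## partitions for a small p)
  ids <- c(paste0("n", 1:4), paste0("s", 1:4))
  a_n <- matrix(100L, 40, 2, dimnames = list(NULL, c("L1", "L2")))
  a_s <- matrix(102L, 40, 2, dimnames = list(NULL, c("L1", "L2")))
  d <- genotype_dataset(rbind(a_n, a_s), rbind(a_n, a_s),
                        sprintf("i%d", 1:80), rep(ids, each = 10),
                        data.frame(id = ids, name = ids,
                                   latitude = c(29, 28.8, 28.6, 28.4,
                                                27, 26.8, 26.6, 26.4),
                                   longitude = -97))
  res <- amova(d, stats::setNames(rep(c("northern", "southern"),
                                      each = 4), ids),
               n_permutations = 200, seed = 1)
  expect_equal(res$Fct, 1, tolerance = 1e-9)
  expect_lt(res$p_fct, 0.05)

  ## identical frequencies everywhere -> Fct ~ 0, p not extreme
  d0 <- hwe_site_pair(0.5, 0.5, n = 80, seed = 2)
  res0 <- amova(d0, c(N = "northern", S = "southern"),
                n_permutations = 200, seed = 3)
  expect_lt(abs(res0$Fct), 0.05)
})

test_that("variance components tie to the SSD decomposition", {
  sim <- simulate_dataset(sim_config(site_plan = macro_site_plan(20),
                                     seed = 81))
  res <- amova(sim$dataset, region_map(sim$truth$site_plan),
               n_permutations = 100, seed = 4)
  ## total SSD equals the sum of its parts
  expect_equal(unname(res$ssd["total"]),
               unname(sum(res$ssd[c("among_regions", "among_sites",
                                    "within_sites")])),
               tolerance = 1e-9 * res$ssd["total"])
  expect_true(all(is.finite(res$sigma)))
  expect_true(res$Fct >= -1 && res$Fct <= 1)
})

test_that("AMOVA recovers the planted divergence", {
  sim <- simulate_dataset(sim_config(seed = 82))
  res <- amova(sim$dataset, region_map(sim$truth$site_plan),
               n_permutations = 500, seed = 5)
  expect_gt(res$Fct, 0.3)
  expect_lt(res$Fct, 0.5)
  expect_lt(abs(res$Fct - sim$truth$realized_fct), 0.06)
  expect_lt(res$p_fct, 0.05)
})

test_that("permutation p-values are valid under the null", {
  ## four exchangeable sites, two per region, identical frequencies:
  ## the Fsc permutation p should be roughly uniform on its grid
  set.seed(83)
  mk_null <- function(seed) {
    set.seed(seed)
    g <- function(m) sample(c(100L, 102L, 104L), m, TRUE)
    sites <- data.frame(id = c("n1", "n2", "s1", "s2"),
                        name = c("n1", "n2", "s1", "s2"),
                        latitude = c(28.6, 28.4, 27.6, 27.4),
                        longitude = -97)
    genotype_dataset(cbind(L1 = g(80), L2 = g(80)),
                     cbind(L1 = g(80), L2 = g(80)),
                     sprintf("i%d", 1:80),
                     rep(c("n1", "n2", "s1", "s2"), each = 20), sites)
  }
  regions <- c(n1 = "northern", n2 = "northern",
               s1 = "southern", s2 = "southern")
  ps <- replicate(40, amova(mk_null(sample.int(1e6, 1)), regions,
                            n_permutations = 99,
                            seed = sample.int(1e6, 1))$p_fsc)
  expect_gt(mean(ps > 0.5), 0.25)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("site classification follows the Q thresholds", {
  expect_equal(classify_site(c(0.97, 0.03))$category, "northern")
  expect_equal(classify_site(c(0.32, 0.68))$category, "mixed")
  expect_equal(classify_site(c(0.5, 0.5))$category, "mixed")
  mid <- classify_site(c(0.25, 0.75))
  expect_equal(mid$category, "southern")
  expect_true(mid$provisional)
  expect_error(classify_site(c(0.5, 0.5), mixed_threshold = 0.4), "<=")
})

test_that("iterative removal isolates planted admixed sites and is deterministic", {
  plan <- rbind(macro_site_plan(30)[c(1:2, 9:10), ],
                data.frame(id = "MIX", latitude = 27.9, n = 30,
                           composition = "hybrid_swarm", r = 0.5))
  sim <- simulate_dataset(sim_config(site_plan = plan, seed = 84))
  qm <- fit_admixture(sim$dataset, mode = "em")
  zone <- iterative_admixed_removal(sim$dataset, qm,
                                    n_permutations = 300, seed = 6)
  expect_identical(zone$removal_order, "MIX")
  expect_identical(unname(zone$category["MIX"]), "mixed")
  expect_gte(zone$final_amova$p_fsc, 0.05)
  ## re-run gives the identical partition
  zone2 <- iterative_admixed_removal(sim$dataset, qm,
                                     n_permutations = 300, seed = 6)
  expect_identical(zone$category, zone2$category)
  expect_identical(zone$removal_order, zone2$removal_order)
})

test_that("homogeneous regions trigger zero removals", {
  sim <- simulate_dataset(sim_config(site_plan = macro_site_plan(25),
                                     seed = 85))
  qm <- fit_admixture(sim$dataset, mode = "em")
  zone <- iterative_admixed_removal(sim$dataset, qm,
                                    n_permutations = 300, seed = 7)
  expect_length(zone$removal_order, 0)
  expect_false(any(zone$category == "mixed"))
})
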