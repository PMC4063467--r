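test_that("Genepop round trip is the identity on genotypes, partition and loci", {
  sim <- simulate_dataset(sim_config(site_plan = macro_site_plan(10),
                                     seed = 5, missing_rate = 0.05))
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(sim$dataset, f)
  back <- read_genepop(f)
  expect_identical(names(back$loci), names(sim$dataset$loci))
  expect_identical(unname(back$allele1), unname(sim$dataset$allele1))
  expect_identical(unname(back$allele2), unname(sim$dataset$allele2))
  ## site partition preserved as a grouping (ids are renamed by Genepop
  ## convention)
  expect_identical(as.integer(factor(back$ind$site,
                                     levels = unique(back$ind$site))),
                   as.integer(factor(sim$dataset$ind$site,
                                     levels = unique(sim$dataset$ind$site))))
  ## second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".gen")
  write_genepop(back, f2, title = readLines(f, n = 1))
  back2 <- read_genepop(f2)
  expect_identical(back2$allele1, back$allele1)
})

test_that("missing-data codes and half-missing promotion follow the convention", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "locB", "pop",
               "a1 , 100102 000000",
               "a2 , 000102 200200",
               "pop",
               "b1 , 102102 200202"), f)
  suppressWarnings(d <- read_genepop(f))
  expect_true(is.na(d$allele1[1, "locB"]) && is.na(d$allele2[1, "locB"]))
  ## half-missing code 000102 promoted to fully missing, with a warning
  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(readLines(f), f2)
  expect_warning(read_genepop(f2), "half-missing")
  expect_true(is.na(d$allele1[2, "locA"]))
  expect_equal(nrow(d$sites), 2)
  expect_equal(nrow(d$ind), 3)
  ## missing writes back as 000000
  out <- withr::local_tempfile(fileext = ".gen")
  write_genepop(d, out)
  expect_true(any(grepl("000000", readLines(out))))
})

test_that("malformed Genepop files are rejected with located errors", {
  corpus <- list(
    no_pop = c("t", "locA", "a1 , 100100"),
    ragged = c("t", "locA", "locB", "pop", "a1 , 100100"),
    bad_code = c("t", "locA", "pop", "a1 , 1001x0"),
    no_comma = c("t", "locA", "pop", "a1  100100"),
    empty = "t")
  for (nm in names(corpus)) {
    f <- withr::local_tempfile(fileext = ".gen")
    writeLines(corpus[[nm]], f)
    expect_error(suppressWarnings(read_genepop(f)), "parse error|short",
                 info = nm)
  }
  ## allele label over 999 cannot be written
  d <- tiny_dataset()
  d$loci$locA <- c(d$loci$locA, 1200L)
  f <- withr::local_tempfile(fileext = ".gen")
  expect_error(write_genepop(d, f), "999")
})

test_that("site metadata reader parses covariates and enforces invariants", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,latitude,longitude,temperature,salinity",
               "SAB,Sabine Reef,29.78,-93.92,23.3,11.8",
               "GAL,Hannah's Reef,29.48,-94.73,21.6,"), f)
  m <- read_site_metadata(f)
  expect_equal(m$salinity[m$id == "SAB"], 11.8)
  expect_true(is.na(m$salinity[m$id == "GAL"]))  # empty cell absent, not 0
  ## invalid latitude
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,latitude,longitude", "X,X,95,-97"), f2)
  expect_error(read_site_metadata(f2), "latitude")
  ## duplicate ids
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,latitude,longitude", "X,X,28,-97", "X,Y,27,-97"), f3)
  expect_error(read_site_metadata(f3), "duplicate")
})

test_that("spat table reader validates the seasonal vocabulary", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area,season,count",
               "north,winter,10", "north,spring,10",
               "north,summer,10", "north,fall,10",
               "south,winter,5", "south,spring,20",
               "south,summer,1", "south,fall,30"), f)
  st <- read_spat_table(f)
  expect_equal(nrow(st), 8)
  expect_equal(st$count[st$area == "north"], rep(10, 4))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area,season,count", "north,autumn,3"), f2)
  expect_error(read_spat_table(f2), "season")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("area,season,count", "north,fall,-3"), f3)
  expect_error(read_spat_table(f3), "non-negative")
})

test_that("allele frequencies sum to one per site and locus", {
  sim <- simulate_dataset(sim_config(site_plan = zone_site_plan(),
                                     seed = 9, missing_rate = 0.1))
  fr <- allele_freqs(sim$dataset)
  for (l in names(fr)) {
    ncop <- attr(fr[[l]], "n_copies")
    sums <- rowSums(fr[[l]])
    expect_true(all(abs(sums[ncop > 0] - 1) < 1e-9), info = l)
    expect_true(all(fr[[l]][ncop > 0, ] >= 0 & fr[[l]][ncop > 0, ] <= 1))
  }
})

test_that("dataset constructor enforces referential invariants", {
  a <- matrix(100L, 2, 1, dimnames = list(NULL, "L1"))
  sites <- data.frame(id = "s1", name = "s1", latitude = 28,
                      longitude = -97)
  expect_error(genotype_dataset(a, a, c("i1", "i2"), c("s1", "s9"), sites),
               "unknown site")
  bad_sites <- data.frame(id = "s1", name = "s1", latitude = 91,
                          longitude = -97)
  expect_error(genotype_dataset(a, a, c("i1", "i2"), c("s1", "s1"),
                                bad_sites), "latitude")
  ## alleles outside the declared locus set
  expect_error(genotype_dataset(a, a, c("i1", "i2"), c("s1", "s1"),
                                sites, loci = list(L1 = 102L)),
               "not in declared set")
})
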