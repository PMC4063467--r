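## Shared fixtures and independent oracles for the test suite.
## Everything is generated in code; no data files.

## tiny hand-built dataset: 2 sites x 3 individuals x 2 loci
tiny_dataset <- function() {
  a1 <- matrix(c(100, 100, 102,   100, 102, 102,
                 200, 202, 200,   202, 202, 200), 6, 2,
               dimnames = list(NULL, c("locA", "locB")))
  a2 <- matrix(c(102, 100, 102,   102, 102, 102,
                 202, 202, 202,   202, 202, 202), 6, 2,
               dimnames = list(NULL, c("locA", "locB")))
  sites <- data.frame(id = c("north1", "south1"),
                      name = c("north1", "south1"),
                      latitude = c(28.5, 27.5), longitude = c(-97, -97))
  genotype_dataset(a1, a2, paste0("i", 1:6),
                   rep(c("north1", "south1"), each = 3), sites)
}

## build a genotype_dataset from explicit per-individual genotype lists
## (one site), for hand-worked statistics
dataset_from_genotypes <- function(g1, g2, locus = "L1",
                                   site = "s1", latitude = 28) {
  sites <- data.frame(id = site, name = site, latitude = latitude,
                      longitude = -97)
  a1 <- matrix(as.integer(g1), ncol = 1, dimnames = list(NULL, locus))
  a2 <- matrix(as.integer(g2), ncol = 1, dimnames = list(NULL, locus))
  genotype_dataset(a1, a2, sprintf("i%03d", seq_along(g1)),
                   rep(site, length(g1)), sites)
}

## two-site dataset with genotypes drawn at explicit frequencies, HWE
hwe_site_pair <- function(pN, pS, n = 50, labels = c(100L, 102L),
                          seed = 1) {
  set.seed(seed)
  draw <- function(p, m) sample(labels, m, replace = TRUE,
                                prob = c(p, 1 - p))
  a1 <- cbind(L1 = c(draw(pN, n), draw(pS, n)))
  a2 <- cbind(L1 = c(draw(pN, n), draw(pS, n)))
  sites <- data.frame(id = c("N", "S"), name = c("N", "S"),
                      latitude = c(28.5, 27.5), longitude = -97)
  genotype_dataset(a1, a2, sprintf("i%03d", 1:(2 * n)),
                   rep(c("N", "S"), each = n), sites)
}

## ----- independent oracle: full-enumeration HWE exact test -----------
## For a biallelic locus with n diploids and nA copies of allele A, the
## genotype table is determined by the heterozygote count h (same parity
## as nA, 0 <= h <= min(nA, 2n - nA)).  Levene conditional probability:
##   P(h | nA) = C * 2^h * n! / (nAA! nAB! nBB!)
## and the exact p-value sums P over tables no more probable than the
## observed one.
hwe_enum_pvalue <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    h * log(2) + lfactorial(n) -
      lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hs == nAB)
  sum(p[p <= p[obs] + 1e-12])
}

## dataset holding one biallelic genotype table at a single site
hwe_table_dataset <- function(nAA, nAB, nBB) {
  g1 <- c(rep(100L, nAA), rep(100L, nAB), rep(102L, nBB))
  g2 <- c(rep(100L, nAA), rep(102L, nAB), rep(102L, nBB))
  dataset_from_genotypes(g1, g2)
}

## ----- independent oracle: grid maximization of the two-locus --------
## haplotype likelihood for unphased genotypes, 2 x 2 alleles.
## Haplotype frequencies are (h11, h12, h21, h22) with margins free; the
## likelihood is maximized by brute force over h11 at fixed observed
## allele frequencies (the EM solution keeps allele frequencies at their
## observed values, so one free parameter remains).
haplo_grid_loglik <- function(y1a, y2a, y1b, y2b, step = 0.001) {
  pa <- mean(c(y1a, y2a) == sort(unique(c(y1a, y2a)))[1])
  pb <- mean(c(y1b, y2b) == sort(unique(c(y1b, y2b)))[1])
  aa <- sort(unique(c(y1a, y2a))); bb <- sort(unique(c(y1b, y2b)))
  loglik <- function(h11) {
    h12 <- pa - h11; h21 <- pb - h11; h22 <- 1 - h11 - h12 - h21
    if (min(h11, h12, h21, h22) < 0) return(-Inf)
    h <- matrix(pmax(c(h11, h21, h12, h22), 1e-300), 2, 2,
                dimnames = list(aa, bb))
    ll <- 0
    for (i in seq_along(y1a)) {
      ha <- c(y1a[i], y2a[i]); hb <- c(y1b[i], y2b[i])
      pr1 <- h[as.character(ha[1]), as.character(hb[1])] *
             h[as.character(ha[2]), as.character(hb[2])]
      pr2 <- h[as.character(ha[1]), as.character(hb[2])] *
             h[as.character(ha[2]), as.character(hb[1])]
      dhet <- ha[1] != ha[2] && hb[1] != hb[2]
      pr <- if (dhet) 2 * pr1 + 2 * pr2
            else if (ha[1] != ha[2] || hb[1] != hb[2]) 2 * pr1
            else pr1
      ll <- ll + log(pr)
    }
    ll
  }
  grid <- seq(max(0, pa + pb - 1), min(pa, pb), by = step)
  best <- max(vapply(grid, loglik, numeric(1)))
  ## refine around the grid optimum
  g0 <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  opt <- stats::optimize(loglik, c(max(0, g0 - step), g0 + step),
                         maximum = TRUE, tol = 1e-12)
  max(best, opt$objective)
}
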