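## Per-locus summary statistics and QC tests.

group_of <- function(dataset, site_ids = NULL) {
  if (is.null(site_ids)) rep(TRUE, nrow(dataset$ind))
  else dataset$ind$site %in% as.character(site_ids)
}

#' Observed and expected heterozygosity at a locus
#'
#' `Ho` is the fraction of heterozygous genotypes among scored
#' individuals; `He` is Nei's (1978) unbiased expected heterozygosity
#' `(2n / (2n - 1)) * (1 - sum(p^2))` from the pooled group frequencies
#' (set `unbiased = FALSE` for the plain gene-diversity `1 - sum(p^2)`).
#'
#' @param dataset a [genotype_dataset()].
#' @param locus locus name.
#' @param site_ids sites defining the group; default all individuals.
#' @param unbiased apply the `2n/(2n-1)` small-sample correction.
#' @return named numeric vector `c(Ho =, He =)`.
#' @export
heterozygosity <- function(dataset, locus, site_ids = NULL,
                           unbiased = TRUE) {
  keep <- group_of(dataset, site_ids)
  x1 <- dataset$allele1[keep, locus]
  x2 <- dataset$allele2[keep, locus]
  ok <- !is.na(x1)
  n <- sum(ok)
  if (n == 0) stop("no scored genotypes at locus ", locus)
  ho <- mean(x1[ok] != x2[ok])
  p <- table(c(x1[ok], x2[ok])) / (2 * n)
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * (2 * n) / (2 * n - 1)
  c(Ho = ho, He = he)
}

#' Multilocus FIS of a single group
#'
#' Nei-style within-group fixation index `1 - sum(Ho) / sum(He)` over
#' loci (ratio of sums), for one pooled group of individuals.  Positive
#' values indicate a heterozygote deficit (e.g. the Wahlund effect on a
#' mechanically mixed reef); [fis_with_jackknife()] provides the
#' Weir-Cockerham estimator with a confidence interval when several
#' groups are available.
#'
#' @param dataset a [genotype_dataset()].
#' @param site_ids sites defining the group; default all individuals.
#' @return scalar FIS.
#' @export
multilocus_fis <- function(dataset, site_ids = NULL) {
  h <- vapply(names(dataset$loci), function(l)
    heterozygosity(dataset, l, site_ids), numeric(2))
  1 - sum(h["Ho", ]) / sum(h["He", ])
}

## Weir & Cockerham (1984) variance components, summed over alleles, for
## each locus.  Returns a matrix (loci x 3) of a, b, c sums.
wc_components <- function(dataset, groups, loci = NULL) {
  if (is.null(loci)) loci <- names(dataset$loci)
  groups <- as.character(groups)
  out <- matrix(0, length(loci), 3,
                dimnames = list(loci, c("a", "b", "c")))
  for (loc in loci) {
    x1 <- dataset$allele1[, loc]
    x2 <- dataset$allele2[, loc]
    ok <- !is.na(x1)
    g <- groups[ok]; y1 <- x1[ok]; y2 <- x2[ok]
    glev <- unique(g)
    r <- length(glev)
    if (r < 2) stop("Weir-Cockerham components need >= 2 groups")
    n_i <- as.numeric(table(factor(g, levels = glev)))
    alleles <- sort(unique(c(y1, y2)))
    if (length(alleles) < 2) next  # monomorphic: no contribution
    gf <- factor(g, levels = glev)
    af1 <- factor(y1, levels = alleles)
    af2 <- factor(y2, levels = alleles)
    cnt <- table(gf, af1) + table(gf, af2)       # copies per group x allele
    p_i <- cnt / (2 * n_i)
    het <- y1 != y2
    ## per-group proportion of individuals heterozygous for each allele
    h_i <- (table(gf[het], af1[het]) + table(gf[het], af2[het])) / n_i
    h_i <- matrix(h_i, r, length(alleles))
    p_i <- matrix(p_i, r, length(alleles))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- colSums(n_i * p_i) / (r * nbar)
    s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
    hbar <- colSums(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    out[loc, ] <- c(sum(a), sum(b), sum(cc))
  }
  out
}

#' Weir-Cockerham F-statistics over groups
#'
#' Multilocus theta (FST analogue) and f (FIS) by summing variance
#' components over alleles and loci.
#'
#' @param dataset a [genotype_dataset()].
#' @param groups character vector, one group label per individual;
#'   default site membership.
#' @param loci loci to use; default all.
#' @return list with `theta`, `f`, and the per-locus component matrix
#'   `components`.
#' @export
wc_fstats <- function(dataset, groups = NULL, loci = NULL) {
  if (is.null(groups)) groups <- dataset$ind$site
  comp <- wc_components(dataset, groups, loci)
  a <- sum(comp[, "a"]); b <- sum(comp[, "b"]); cc <- sum(comp[, "c"])
  theta <- if (a + b + cc > 0) a / (a + b + cc) else 0
  f <- if (b + cc > 0) 1 - cc / (b + cc) else 0
  list(theta = theta, f = f, components = comp)
}

#' FIS with a jackknife confidence interval over groups
#'
#' Weir-Cockerham f at one locus, with a normal-approximation confidence
#' interval from leave-one-group-out jackknifing.  Significance of the
#' within-group heterozygote deficit is read off as "CI excludes zero".
#'
#' @param dataset a [genotype_dataset()].
#' @param locus locus name.
#' @param groups grouping vector (default sites); at least 3 groups.
#' @param conf confidence level.
#' @param type `"normal"` (estimate +/- z * SE) or `"percentile"` over
#'   pseudovalues.
#' @return list with `fis`, `ci` (length-2), `se`, `significant`.
#' @export
fis_with_jackknife <- function(dataset, locus, groups = NULL,
                               conf = 0.95, type = c("normal",
                                                     "percentile")) {
  type <- match.arg(type)
  if (is.null(groups)) groups <- dataset$ind$site
  groups <- as.character(groups)
  glev <- unique(groups)
  g <- length(glev)
  if (g < 3) stop("jackknife over groups needs >= 3 groups")
  est <- wc_fstats(dataset, groups, loci = locus)$f
  loo <- vapply(glev, function(drop) {
    keep <- groups != drop
    sub <- genotype_dataset(dataset$allele1[keep, , drop = FALSE],
                            dataset$allele2[keep, , drop = FALSE],
                            dataset$ind$id[keep], dataset$ind$site[keep],
                            dataset$sites, loci = dataset$loci)
    wc_fstats(sub, groups[keep], loci = locus)$f
  }, numeric(1))
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (type == "normal") est + c(-1, 1) * z * se
        else {
          pseudo <- g * est - (g - 1) * loo
          unname(stats::quantile(pseudo, c((1 - conf) / 2,
                                           1 - (1 - conf) / 2)))
        }
  list(fis = est, ci = ci, se = se,
       significant = ci[1] > 0 || ci[2] < 0)
}

## log conditional probability of a genotype table given allele counts
## (Levene's distribution): terms varying across tables only.
hwe_table_logp <- function(x1, x2) {
  het <- sum(x1 != x2)
  key <- as.numeric(pmin(x1, x2)) * 1e6 + pmax(x1, x2)
  het * log(2) - sum(lfactorial(tabulate(match(key, unique(key)))))
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Exact test in the sense of Guo & Thompson: genotype tables are drawn
#' from the permutation distribution of gene copies conditional on allele
#' counts (shuffle the `2n` copies, pair them), and the p-value is the
#' proportion of tables -- including the observed one -- whose conditional
#' probability does not exceed the observed table's.
#'
#' @param dataset a [genotype_dataset()].
#' @param locus locus name.
#' @param site_ids sites defining the group; default all.
#' @param n_mc Monte-Carlo iterations (>= 1000).
#' @param seed integer seed.
#' @return p-value.  Monomorphic loci return 1 by convention.
#' @export
hwe_exact_test <- function(dataset, locus, site_ids = NULL,
                           n_mc = 10000, seed = NULL) {
  if (n_mc < 1000) stop("n_mc must be >= 1000")
  keep <- group_of(dataset, site_ids)
  x1 <- dataset$allele1[keep, locus]
  x2 <- dataset$allele2[keep, locus]
  ok <- !is.na(x1)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(unique(c(x1, x2))) < 2) return(1)
  obs <- hwe_table_logp(x1, x2)
  pool <- c(x1, x2)
  n <- length(x1)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_mc)) {
      perm <- sample(pool)
      lp <- hwe_table_logp(perm[seq_len(n)], perm[n + seq_len(n)])
      if (lp <= obs + 1e-9) hits <- hits + 1L
    }
    (hits + 1) / (n_mc + 1)
  })
}

## EM estimation of two-locus haplotype frequencies from unphased diploid
## genotypes.  Returns haplotype matrix, log-likelihoods under the fitted
## and the linkage-equilibrium (product) model, and convergence flag.
em_haplotypes <- function(y1a, y2a, y1b, y2b, max_iter = 5000,
                          tol = 1e-10) {
  aa <- sort(unique(c(y1a, y2a)))
  bb <- sort(unique(c(y1b, y2b)))
  ka <- length(aa); kb <- length(bb)
  i1a <- match(y1a, aa); i2a <- match(y2a, aa)
  i1b <- match(y1b, bb); i2b <- match(y2b, bb)
  n <- length(i1a)
  ## linear indices of the two phasings' haplotypes
  idx <- function(i, j) (j - 1L) * ka + i
  h11 <- idx(i1a, i1b); h22 <- idx(i2a, i2b)   # phase 1
  h12 <- idx(i1a, i2b); h21 <- idx(i2a, i1b)   # phase 2
  dhet <- (i1a != i2a) & (i1b != i2b)
  pa <- tabulate(c(i1a, i2a), ka) / (2 * n)
  pb <- tabulate(c(i1b, i2b), kb) / (2 * n)
  geno_loglik <- function(h) {
    g1 <- h[h11] * h[h22]
    g2 <- h[h12] * h[h21]
    same1 <- h11 == h22   # phase-1 haplotypes identical
    pr <- ifelse(same1, g1, 2 * g1)
    pr[dhet] <- 2 * g1[dhet] + 2 * g2[dhet]
    sum(log(pmax(pr, 1e-300)))
  }
  h0 <- as.vector(outer(pa, pb))
  ll0 <- geno_loglik(h0)
  h <- h0
  ll_old <- -Inf
  converged <- FALSE
  cells <- c(h11, h22, h12, h21)
  for (it in seq_len(max_iter)) {
    w <- rep(1, n)
    g1 <- h[h11] * h[h22]
    g2 <- h[h12] * h[h21]
    w[dhet] <- g1[dhet] / pmax(g1[dhet] + g2[dhet], 1e-300)
    ## non-double-het individuals put full weight on phase 1 (the two
    ## phasings coincide); double-hets split w / (1 - w)
    wts <- c(w, w, (1 - w) * dhet, (1 - w) * dhet)
    cnt <- numeric(ka * kb)
    rs <- rowsum(wts, cells)
    cnt[as.integer(rownames(rs))] <- rs
    h <- cnt / (2 * n)
    ll <- geno_loglik(h)
    if (abs(ll - ll_old) < tol * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(haplotypes = matrix(h, ka, kb, dimnames = list(aa, bb)),
       loglik = geno_loglik(h), loglik0 = ll0, converged = converged)
}

#' Likelihood-ratio test of linkage disequilibrium between two loci
#'
#' Haplotype frequencies for unphased diploid genotypes are estimated by
#' EM; the statistic is `2 * (logL(haplotypes) - logL(allele-frequency
#' product))`, and the p-value comes from permuting one locus's genotypes
#' among individuals and re-running the EM.
#'
#' @param dataset a [genotype_dataset()].
#' @param locusA,locusB locus names.
#' @param site_ids sites defining the group; default all.
#' @param n_permutations permutations for the p-value; `0` returns only
#'   the statistic (`p = NA`).
#' @param seed integer seed.
#' @return list with `lr`, `p`, `converged`, `haplotypes`.
#' @export
ld_lr_test <- function(dataset, locusA, locusB, site_ids = NULL,
                       n_permutations = 200, seed = NULL) {
  keep <- group_of(dataset, site_ids)
  y1a <- dataset$allele1[keep, locusA]; y2a <- dataset$allele2[keep, locusA]
  y1b <- dataset$allele1[keep, locusB]; y2b <- dataset$allele2[keep, locusB]
  ok <- !is.na(y1a) & !is.na(y1b)
  if (sum(ok) < 10)
    stop("need >= 10 individuals scored at both loci")
  y1a <- y1a[ok]; y2a <- y2a[ok]; y1b <- y1b[ok]; y2b <- y2b[ok]
  fit <- em_haplotypes(y1a, y2a, y1b, y2b)
  lr <- max(0, 2 * (fit$loglik - fit$loglik0))
  if (!fit$converged)
    warning("EM did not converge for ", locusA, " x ", locusB)
  p <- NA_real_
  if (n_permutations > 0) {
    n <- length(y1a)
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_permutations)) {
        pm <- sample.int(n)
        fb <- em_haplotypes(y1a, y2a, y1b[pm], y2b[pm])
        if (2 * (fb$loglik - fb$loglik0) >= lr - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (n_permutations + 1)
    })
  }
  list(lr = lr, p = p, converged = fit$converged,
       haplotypes = fit$haplotypes)
}

#' Sequential Bonferroni (Holm) significance flags
#'
#' Holm's step-down procedure: sort p ascending, reject while
#' `p(i) <= alpha / (k - i + 1)`, stop at the first failure.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return logical vector of rejections, in input order.
#' @export
sequential_bonferroni <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(logical(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  k <- length(pvalues)
  ord <- order(pvalues)
  reject <- logical(k)
  for (i in seq_len(k)) {
    if (pvalues[ord[i]] <= alpha / (k - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}

#' Screen a locus for null alleles
#'
#' Per sample site, the Chakraborty estimator of null-allele frequency
#' `r = (He - Ho) / (He + Ho)`, truncated at zero; the marker passes when
#' the mean over sites is below `threshold` (0.05), the marker-inclusion
#' rule the pipeline applies.
#'
#' @param dataset a [genotype_dataset()].
#' @param locus locus name.
#' @param threshold pass threshold on the mean estimated null frequency.
#' @return list with `mean_null_freq`, `per_site`, `pass`.
#' @export
null_allele_screen <- function(dataset, locus, threshold = 0.05) {
  per_site <- vapply(dataset$sites$id, function(s) {
    x1 <- dataset$allele1[dataset$ind$site == s, locus]
    x2 <- dataset$allele2[dataset$ind$site == s, locus]
    ok <- !is.na(x1)
    if (!sum(ok)) return(NA_real_)
    h <- heterozygosity(dataset, locus, site_ids = s)
    if (h["Ho"] + h["He"] == 0) return(NA_real_)
    max(0, (h["He"] - h["Ho"]) / (h["He"] + h["Ho"]))
  }, numeric(1))
  if (all(is.na(per_site)))
    stop("no site with scored genotypes at locus ", locus)
  if (anyNA(per_site))
    warning("site(s) without defined estimate skipped at locus ", locus)
  m <- mean(per_site, na.rm = TRUE)
  list(mean_null_freq = m, per_site = per_site,
       pass = m < threshold)
}

#' Genotyping error rate from duplicate runs
#'
#' Fraction of duplicated genotypes whose unordered allele pairs differ
#' between two runs of the same individuals, per locus.  Pairs with a
#' missing genotype in either run are excluded from the denominator.
#'
#' @param run1,run2 [genotype_dataset()] objects holding the same
#'   individuals and loci, genotyped on two occasions.
#' @return named numeric vector of per-locus discordance fractions (`NA`
#'   with a warning for loci without comparable pairs).
#' @export
genotyping_error_rate <- function(run1, run2) {
  stopifnot(identical(names(run1$loci), names(run2$loci)),
            nrow(run1$ind) == nrow(run2$ind))
  out <- vapply(names(run1$loci), function(loc) {
    ok <- !is.na(run1$allele1[, loc]) & !is.na(run2$allele1[, loc])
    if (!sum(ok)) return(NA_real_)
    diff <- run1$allele1[ok, loc] != run2$allele1[ok, loc] |
            run1$allele2[ok, loc] != run2$allele2[ok, loc]
    mean(diff)
  }, numeric(1))
  if (all(is.na(out))) stop("no comparable duplicate pairs at any locus")
  if (anyNA(out)) warning("locus/loci without comparable pairs: ",
                          paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Per-locus summary table
#'
#' Convenience report combining allele counts, heterozygosity, FIS with
#' jackknife CI, and the null-allele screen, one row per locus.
#'
#' @param dataset a [genotype_dataset()].
#' @param conf confidence level for the FIS interval.
#' @return data frame with columns `locus`, `n_alleles`, `Ho`, `He`,
#'   `FIS`, `FIS_low`, `FIS_high`, `null_freq`, `null_pass`.
#' @export
locus_stats_table <- function(dataset, conf = 0.95) {
  do.call(rbind, lapply(names(dataset$loci), function(loc) {
    h <- heterozygosity(dataset, loc)
    fis <- if (length(unique(dataset$ind$site)) >= 3)
      fis_with_jackknife(dataset, loc, conf = conf)
    else list(fis = NA_real_, ci = c(NA_real_, NA_real_))
    ns <- null_allele_screen(dataset, loc)
    data.frame(locus = loc,
               n_alleles = length(dataset$loci[[loc]]),
               Ho = unname(h["Ho"]), He = unname(h["He"]),
               FIS = fis$fis, FIS_low = fis$ci[1], FIS_high = fis$ci[2],
               null_freq = ns$mean_null_freq, null_pass = ns$pass,
               stringsAsFactors = FALSE)
  }))
}
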