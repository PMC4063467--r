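## Hybrid-zone bimodality analysis: do mixed-reef genotypes look like a
## mechanical mixture of the two parental populations (bimodal admixture
## scores, Wahlund heterozygote deficits, linkage disequilibrium) or like
## a hybrid swarm mating at random within the zone (unimodal scores,
## Hardy-Weinberg at pooled frequencies)?

#' Kruskal-Wallis test of admixture-score homogeneity across mixed sites
#'
#' Rank-based test on individual Q1 values grouped by site (chi-square
#' approximation with ties correction, df = k - 1).  Run before pooling
#' mixed sites for the bimodality test.
#'
#' @param qmatrix a `qmatrix`.
#' @param mixed_site_ids at least two site ids, each with at least two
#'   individuals.
#' @return list with `statistic`, `df`, `p`.
#' @export
kruskal_wallis_q <- function(qmatrix, mixed_site_ids) {
  mixed_site_ids <- as.character(mixed_site_ids)
  stopifnot(length(mixed_site_ids) >= 2)
  rows <- qmatrix$ind$site %in% mixed_site_ids
  q <- qmatrix$Q[rows, 1]
  g <- factor(qmatrix$ind$site[rows], levels = mixed_site_ids)
  if (any(table(g) < 2)) stop("each mixed site needs >= 2 individuals")
  if (length(unique(q)) == 1)
    return(list(statistic = 0, df = length(mixed_site_ids) - 1, p = 1))
  kt <- stats::kruskal.test(q, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Simulate genotypes under the mechanical-mixing model
#'
#' Random genotypes drawn from the parental allele frequencies of the two
#' unmixed flanking groups: each simulated individual belongs wholly to
#' one population (northern with the site's expected ratio) and is in
#' Hardy-Weinberg proportions within its source.  No hybrid genotypes are
#' produced by construction.
#'
#' @param north_freqs,south_freqs named per-locus frequency vectors of
#'   the flanking groups (e.g. [pooled_freqs()]).
#' @param per_site_ratio numeric vector of expected northern fractions,
#'   one per simulated site (take them from observed site mean Q).
#' @param n_per_site individuals per simulated site.
#' @param seed integer seed.
#' @return list `dataset` / `truth` as from [simulate_dataset()].
#' @export
simulate_mechanical_mix_model <- function(north_freqs, south_freqs,
                                          per_site_ratio, n_per_site,
                                          seed = NULL) {
  simulate_from_freqs(north_freqs, south_freqs, per_site_ratio,
                      n_per_site, "mechanical_mix", seed)
}

#' Simulate genotypes under the hybrid-swarm model
#'
#' Hardy-Weinberg draws from pooled frequencies: both alleles of every
#' genotype are independent draws from `r * pN + (1 - r) * pS`,
#' emulating random mating within the zone.  When called with the
#' observed pooled frequencies of the mixed samples themselves
#' (`north_freqs = south_freqs = mixed frequencies`, any `r`), this is a
#' plain Hardy-Weinberg resampling of the mixed gene pool.
#'
#' @inheritParams simulate_mechanical_mix_model
#' @return list `dataset` / `truth` as from [simulate_dataset()].
#' @export
simulate_hybrid_swarm_model <- function(north_freqs, south_freqs,
                                        per_site_ratio, n_per_site,
                                        seed = NULL) {
  simulate_from_freqs(north_freqs, south_freqs, per_site_ratio,
                      n_per_site, "hybrid_swarm", seed)
}

## shared engine: build a sim_config-like draw from explicit parental
## frequencies rather than Balding-Nichols draws
simulate_from_freqs <- function(north_freqs, south_freqs, per_site_ratio,
                                n_per_site, composition, seed) {
  stopifnot(length(north_freqs) == length(south_freqs),
            all(per_site_ratio >= 0 & per_site_ratio <= 1))
  check <- vapply(c(north_freqs, south_freqs),
                  function(p) abs(sum(p) - 1) < 1e-6, logical(1))
  if (!all(check)) stop("frequency vectors must sum to 1")
  n_sites <- length(per_site_ratio)
  n_per_site <- rep_len(n_per_site, n_sites)
  with_seed(seed, {
    ntot <- sum(n_per_site)
    L <- length(north_freqs)
    a1 <- a2 <- matrix(NA_integer_, ntot, L)
    colnames(a1) <- colnames(a2) <- names(north_freqs)
    ancestry <- numeric(ntot)
    site_of <- character(ntot)
    row <- 0L
    for (s in seq_len(n_sites)) {
      n <- n_per_site[s]
      r <- per_site_ratio[s]
      idx <- row + seq_len(n); row <- row + n
      site_of[idx] <- sprintf("sim%02d", s)
      src <- if (composition == "mechanical_mix")
        ifelse(stats::runif(n) < r, "N", "S") else rep("H", n)
      ancestry[idx] <- if (composition == "mechanical_mix")
        as.numeric(src == "N") else r
      for (l in seq_len(L)) {
        pn <- north_freqs[[l]]; ps <- south_freqs[[l]]
        labels <- as.integer(names(pn))
        if (composition == "mechanical_mix") {
          isN <- src == "N"
          x1 <- x2 <- integer(n)
          if (any(isN)) {
            x1[isN] <- sample(labels, sum(isN), TRUE, prob = pn)
            x2[isN] <- sample(labels, sum(isN), TRUE, prob = pn)
          }
          if (any(!isN)) {
            x1[!isN] <- sample(labels, sum(!isN), TRUE, prob = ps)
            x2[!isN] <- sample(labels, sum(!isN), TRUE, prob = ps)
          }
        } else {
          pool <- r * pn + (1 - r) * ps
          x1 <- sample(labels, n, TRUE, prob = pool)
          x2 <- sample(labels, n, TRUE, prob = pool)
        }
        a1[idx, l] <- pmin(x1, x2)
        a2[idx, l] <- pmax(x1, x2)
      }
    }
    sites <- data.frame(id = sprintf("sim%02d", seq_len(n_sites)),
                        name = sprintf("sim%02d", seq_len(n_sites)),
                        latitude = 0, longitude = 0,
                        region_label = "mixed",
                        stringsAsFactors = FALSE)
    loci <- lapply(north_freqs, function(p) as.integer(names(p)))
    ds <- genotype_dataset(a1, a2, sprintf("s%05d", seq_len(ntot)),
                           site_of, sites, loci = loci)
    list(dataset = ds, truth = list(ancestry = ancestry,
                                    ratio = per_site_ratio,
                                    composition = composition))
  })
}

#' Hybrid-zone bimodality test by genotype simulation
#'
#' Simulates the pooled mixed samples under both the mechanical-mixing
#' model (parental draws at the observed per-site mixing ratios, taken
#' from site mean Q) and the hybrid-swarm model (Hardy-Weinberg draws
#' from the observed pooled mixed-sample frequencies), scores observed
#' and simulated individuals against the same flanking reference
#' frequencies, and compares the observed Q1 distribution with each
#' simulated distribution by a two-sample Kolmogorov-Smirnov test.
#'
#' The generating model should *not* be rejected and the alternative
#' should be: a bimodal (mechanically mixed) zone retains the mixing
#' model, a unimodal (hybrid-swarm) zone retains the swarm model.
#'
#' @param dataset a [genotype_dataset()] containing the mixed sites and
#'   the flanking reference sites.
#' @param qmatrix a `qmatrix` for `dataset` (site mean Q supplies the
#'   per-site mixing ratios).
#' @param mixed_site_ids the pooled mixed sites.
#' @param reference_sites `list(northern = <ids>, southern = <ids>)` of
#'   unmixed flanking sites.
#' @param n_sim simulated individuals per model (at least the observed
#'   count).
#' @param seed integer seed.
#' @return object of class `bimodality_result` with KS statistics and
#'   p-values versus both models, the observed and simulated Q vectors,
#'   and the hybrid-index histogram of the observed individuals.
#' @export
bimodality_test <- function(dataset, qmatrix, mixed_site_ids,
                            reference_sites, n_sim = 1000,
                            seed = NULL) {
  mixed_site_ids <- as.character(mixed_site_ids)
  n_obs <- sum(dataset$ind$site %in% mixed_site_ids)
  if (n_sim < n_obs) stop("n_sim must be >= number of observed individuals")
  fn <- pooled_freqs(dataset, reference_sites$northern)
  fs <- pooled_freqs(dataset, reference_sites$southern)
  ratios <- vapply(mixed_site_ids,
                   function(s) sample_mean_q(qmatrix, s)[1], numeric(1))
  q_obs <- qmatrix$Q[dataset$ind$site %in% mixed_site_ids, 1]

  with_seed(seed, {
    per_site <- round(n_sim * rep(1 / length(ratios), length(ratios)))
    mech <- simulate_mechanical_mix_model(fn, fs, ratios, per_site)
    fmix <- pooled_freqs(dataset, mixed_site_ids)
    swarm <- simulate_hybrid_swarm_model(fmix, fmix,
                                         rep(0.5, length(ratios)),
                                         per_site)
    q_mech <- ancestry_scores(mech$dataset, fn, fs)
    q_swarm <- ancestry_scores(swarm$dataset, fn, fs)
    ks_mech <- suppressWarnings(stats::ks.test(q_obs, q_mech))
    ks_swarm <- suppressWarnings(stats::ks.test(q_obs, q_swarm))
    structure(list(
      ks_mechanical = list(statistic = unname(ks_mech$statistic),
                           p = ks_mech$p.value),
      ks_hybrid_swarm = list(statistic = unname(ks_swarm$statistic),
                             p = ks_swarm$p.value),
      q_observed = q_obs, q_mechanical = q_mech, q_hybrid_swarm = q_swarm,
      histogram = hybrid_index_histogram(q_obs),
      n_sim = length(q_mech), seed = seed),
      class = "bimodality_result")
  })
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat("Hybrid-zone bimodality test (two-sample Kolmogorov-Smirnov)\n")
  cat(sprintf("  vs mechanical mixing: D = %.3f, p = %.4g\n",
              x$ks_mechanical$statistic, x$ks_mechanical$p))
  cat(sprintf("  vs hybrid swarm:      D = %.3f, p = %.4g\n",
              x$ks_hybrid_swarm$statistic, x$ks_hybrid_swarm$p))
  cat("  hybrid index histogram:",
      paste(x$histogram$counts, collapse = " "), "\n")
  cat(sprintf("  bimodality descriptor = %.2f (>1 bimodal)\n",
              x$histogram$descriptor))
  invisible(x)
}

#' Plot observed versus simulated admixture-score distributions
#'
#' Empirical CDFs of the observed mixed-sample Q1 scores and of the two
#' simulated models (mechanical mixing, hybrid swarm): a bimodal zone
#' tracks the mixing curve, a unimodal one the swarm curve.
#'
#' @param x a `bimodality_result`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.bimodality_result <- function(x, ...) {
  plot(stats::ecdf(x$q_observed), main = "", verticals = TRUE,
       do.points = FALSE, xlim = c(0, 1),
       xlab = "admixture score (Q1)", ylab = "empirical CDF", ...)
  graphics::lines(stats::ecdf(x$q_mechanical), col = "grey50",
                  verticals = TRUE, do.points = FALSE)
  graphics::lines(stats::ecdf(x$q_hybrid_swarm), col = "grey50",
                  lty = 3, verticals = TRUE, do.points = FALSE)
  graphics::legend("topleft", bty = "n", lty = c(1, 1, 3),
                   col = c("black", "grey50", "grey50"),
                   legend = c("observed", "mechanical mix",
                              "hybrid swarm"))
  invisible(x)
}

#' Hybrid-index histogram over ten admixture categories
#'
#' Bins Q1 into `(0, 0.1], (0.1, 0.2], ..., (0.9, 1]` (Q = 0 goes to the
#' first bin; a score near 0.5 indicates an F1 hybrid) and reports a
#' bimodality descriptor: the count in the two outer bins divided by the
#' count in the two central bins plus one.
#'
#' @param q numeric vector of Q1 scores in `[0, 1]`, or a `qmatrix`
#'   (optionally restricted with `individuals`).
#' @param individuals optional individual ids when `q` is a `qmatrix`.
#' @return list with `counts` (length 10), `breaks`, `descriptor`.
#' @export
hybrid_index_histogram <- function(q, individuals = NULL) {
  if (inherits(q, "qmatrix")) {
    Q <- q$Q[, 1]
    if (!is.null(individuals)) Q <- Q[q$ind$id %in% individuals]
    q <- Q
  }
  stopifnot(all(q >= 0 & q <= 1))
  breaks <- seq(0, 1, by = 0.1)
  bin <- findInterval(q, breaks, left.open = TRUE, rightmost.closed = FALSE)
  bin[bin == 0] <- 1L   # q = 0 into the first category
  counts <- tabulate(bin, 10)
  descriptor <- (counts[1] + counts[10]) / (counts[5] + counts[6] + 1)
  list(counts = counts, breaks = breaks, descriptor = descriptor)
}
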