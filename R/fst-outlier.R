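## FST-outlier screening: the neutral expectation of FST as a function
## of heterozygosity is built by coalescent simulation of a symmetric
## island model (100 demes, two sampled), anchored at the trimmed
## multilocus Weir-Cockerham theta of the observed data; observed loci
## far outside the simulated cloud at their heterozygosity are candidate
## targets of directional (high) or balancing (low) selection.

#' Trimmed multilocus Weir-Cockerham theta
#'
#' Multilocus theta recomputed after excluding the loci with the largest
#' and smallest per-locus theta (one per tail, applied when at least 5
#' polymorphic loci are available), a robust anchor for neutral-envelope
#' simulation.
#'
#' @param dataset a [genotype_dataset()].
#' @param groups group labels per individual (e.g. region membership);
#'   default site membership.
#' @return list with `theta_trimmed`, `theta_all`, `per_locus`.
#' @export
trimmed_mean_fst <- function(dataset, groups = NULL) {
  if (is.null(groups)) groups <- dataset$ind$site
  fit <- wc_fstats(dataset, groups)
  comp <- fit$components
  denom <- rowSums(comp)
  poly <- denom > 1e-12
  if (!any(poly)) stop("all loci monomorphic")
  per_locus <- ifelse(poly, comp[, "a"] / denom, NA_real_)
  keep <- which(poly)
  if (length(keep) >= 5) {
    ord <- keep[order(per_locus[keep])]
    keep <- ord[-c(1, length(ord))]
  }
  a <- sum(comp[keep, "a"]); d <- sum(denom[keep])
  list(theta_trimmed = a / d, theta_all = fit$theta,
       per_locus = per_locus)
}

## one locus of the n-island structured coalescent, jump chain only
## (event order is all that matters for the mutation models used).
## Returns integer allele ids for the sampled copies of each deme.
island_locus <- function(n_copies, n_demes, M, theta,
                         model = "infinite_alleles") {
  n_leaves <- sum(n_copies)
  owner <- seq_len(n_leaves)                  # leaf -> lineage id
  deme <- rep(seq_along(n_copies), n_copies)  # lineage id -> deme
  active <- rep(TRUE, n_leaves)
  allele <- rep(NA_integer_, n_leaves)
  offset <- rep(0L, n_leaves)                 # stepwise state
  next_allele <- 0L
  iam <- model == "infinite_alleles"
  repeat {
    ids <- which(active)
    nl <- length(ids)
    if (nl <= 1) break
    k <- tabulate(deme[ids], n_demes)
    coal_by_deme <- k * (k - 1) / 2
    r_coal <- sum(coal_by_deme)
    r_mig <- nl * M / 2
    r_mut <- nl * theta / 2
    u <- stats::runif(1) * (r_coal + r_mig + r_mut)
    if (u < r_coal) {
      dm <- sample.int(n_demes, 1, prob = coal_by_deme)
      pair <- sample(ids[deme[ids] == dm], 2)
      owner[owner == pair[2]] <- pair[1]
      active[pair[2]] <- FALSE
    } else if (u < r_coal + r_mig) {
      ln <- ids[sample.int(nl, 1)]
      new_deme <- sample.int(n_demes - 1, 1)
      if (new_deme >= deme[ln]) new_deme <- new_deme + 1L
      deme[ln] <- new_deme
    } else {
      ln <- ids[sample.int(nl, 1)]
      leaves <- owner == ln
      if (iam) {
        next_allele <- next_allele + 1L
        allele[leaves & is.na(allele)] <- next_allele
        active[ln] <- FALSE
        ## unassigned leaves of this lineage are exactly those flagged;
        ## drop the lineage: its deeper history is irrelevant
      } else {
        offset[leaves] <- offset[leaves] +
          (if (stats::runif(1) < 0.5) -1L else 1L)
      }
    }
  }
  if (iam) allele[is.na(allele)] <- 0L else allele <- 100L + offset
  split(allele, rep(seq_along(n_copies), n_copies))
}

## haploid Weir-Cockerham theta and pooled gene diversity for one locus
haploid_theta_het <- function(alleles_by_deme) {
  labs <- sort(unique(unlist(alleles_by_deme)))
  if (length(labs) < 2) return(c(theta = NA_real_, het = 0))
  cnt <- t(vapply(alleles_by_deme,
                  function(a) tabulate(match(a, labs), length(labs)),
                  numeric(length(labs))))
  n_i <- rowSums(cnt)
  r <- nrow(cnt)
  p_i <- cnt / n_i
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(cnt) / sum(n_i)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  theta <- sum(a) / sum(a + b)
  het <- 1 - sum(pbar^2)
  c(theta = theta, het = het)
}

sim_cloud <- function(n_loci, n_copies, n_demes, M, theta_range, model) {
  out <- matrix(NA_real_, n_loci, 2,
                dimnames = list(NULL, c("het", "theta")))
  for (i in seq_len(n_loci)) {
    th <- exp(stats::runif(1, log(theta_range[1]), log(theta_range[2])))
    al <- island_locus(n_copies, n_demes, M, th, model)
    st <- haploid_theta_het(al)
    out[i, ] <- c(st["het"], st["theta"])
  }
  as.data.frame(out)
}

#' Simulate the neutral FST-heterozygosity envelope
#'
#' Coalescent simulation of two demes sampled from an `n_demes`-deme
#' symmetric island model.  The scaled migration rate is initialized at
#' the island-model expectation `FST = 1 / (1 + M (d/(d-1))^2)` and
#' calibrated by bisection on pilot simulations until the mean simulated
#' theta matches `target_fst` within `tol`.  Per-locus scaled mutation
#' rates are drawn log-uniformly over `mutation_range` so simulated
#' heterozygosities span the observed range; mutation follows the
#' infinite-alleles model by default (stepwise optional).
#'
#' @param target_fst genomic mean FST to anchor, in (0, 0.95).
#' @param sample_sizes diploid individuals sampled per deme (two demes).
#' @param n_sim_loci simulated loci (>= 1000).
#' @param mutation_model `"infinite_alleles"` or `"stepwise"`.
#' @param n_demes demes in the island model.
#' @param mutation_range range of the scaled mutation rate.
#' @param tol calibration tolerance on mean simulated theta.
#' @param pilot_loci loci per calibration step.
#' @param seed integer seed.
#' @return list with `cloud` (data frame `het`, `theta`), `envelope`
#'   (per-heterozygosity-bin 2.5/50/97.5 percent quantiles), `M`,
#'   `settings`.
#' @export
simulate_envelope <- function(target_fst, sample_sizes = c(50, 50),
                              n_sim_loci = 5000,
                              mutation_model = c("infinite_alleles",
                                                 "stepwise"),
                              n_demes = 100,
                              mutation_range = c(0.05, 4),
                              tol = 0.02, pilot_loci = 300,
                              seed = NULL) {
  mutation_model <- match.arg(mutation_model)
  stopifnot(target_fst > 0, target_fst < 0.95, n_sim_loci >= 1000)
  n_copies <- 2 * sample_sizes
  corr <- (n_demes / (n_demes - 1))^2
  M0 <- (1 / target_fst - 1) / corr
  with_seed(seed, {
    mean_theta <- function(M, nl) {
      cl <- sim_cloud(nl, n_copies, n_demes, M, mutation_range,
                      mutation_model)
      mean(cl$theta, na.rm = TRUE)
    }
    lo <- M0 / 8; hi <- M0 * 8
    f_lo <- mean_theta(lo, pilot_loci)
    f_hi <- mean_theta(hi, pilot_loci)
    if (f_lo < target_fst || f_hi > target_fst)
      stop("target FST ", target_fst, " unreachable by migration tuning",
           " (bracket [", signif(f_hi, 3), ", ", signif(f_lo, 3), "])")
    M <- M0
    for (it in seq_len(10)) {
      fm <- mean_theta(M, pilot_loci)
      if (abs(fm - target_fst) <= tol / 2) break
      if (fm > target_fst) lo <- M else hi <- M
      M <- sqrt(lo * hi)
    }
    cloud <- sim_cloud(n_sim_loci, n_copies, n_demes, M, mutation_range,
                       mutation_model)
    realized <- mean(cloud$theta, na.rm = TRUE)
    if (abs(realized - target_fst) > tol + 0.01)
      stop("calibration failed: realized mean theta ", signif(realized, 3),
           " vs target ", target_fst)
    ok <- is.finite(cloud$theta)
    env <- envelope_quantiles(cloud$het[ok], cloud$theta[ok])
    list(cloud = cloud[ok, ], envelope = env, M = M,
         settings = list(target_fst = target_fst,
                         sample_sizes = sample_sizes,
                         n_demes = n_demes, n_sim_loci = n_sim_loci,
                         mutation_model = mutation_model,
                         mutation_range = mutation_range, seed = seed))
  })
}

## running quantiles of theta in equal-count heterozygosity bins,
## lightly smoothed with a 3-bin moving average
envelope_quantiles <- function(het, theta, n_bins = 20) {
  ord <- order(het)
  het <- het[ord]; theta <- theta[ord]
  bin <- ceiling(seq_along(het) / (length(het) / n_bins))
  qs <- t(vapply(split(seq_along(het), bin), function(ix)
    c(mean(het[ix]),
      stats::quantile(theta[ix], c(0.025, 0.5, 0.975), names = FALSE)),
    numeric(4)))
  sm <- function(v) stats::filter(v, rep(1 / 3, 3), sides = 2) |>
    (\(f) ifelse(is.na(f), v, f))()
  data.frame(het = qs[, 1], q025 = sm(qs[, 2]), q50 = sm(qs[, 3]),
             q975 = sm(qs[, 4]))
}

#' Classify observed loci against a simulated neutral cloud
#'
#' Per observed locus, the conditional p-value is the proportion of
#' simulated loci in the locus's heterozygosity window (equal-count
#' windows each holding `window_frac` of the cloud) whose theta does not
#' exceed the observed theta; `low` outliers (`p < 0.025`) suggest
#' balancing selection, `high` outliers (`p > 0.975`) directional
#' selection.  Windows are fixed (not centred on the observed locus):
#' because theta and heterozygosity are strongly linked at high
#' divergence, centring would pin a neutral locus's theta rank to the
#' middle of its window and destroy the calibration of the conditional
#' p-value.
#'
#' @param observed data frame with columns `locus`, `het`, `theta`.
#' @param cloud simulated cloud (`het`, `theta`) from
#'   [simulate_envelope()].
#' @param window_frac fraction of simulated loci per heterozygosity
#'   window.
#' @return data frame `locus`, `het`, `theta`, `p`, `class`
#'   (`low`/`none`/`high`), `evaluable`.
#' @export
classify_outliers <- function(observed, cloud, window_frac = 0.05) {
  stopifnot(nrow(cloud) > 0)
  n_bins <- max(1L, floor(1 / window_frac))
  rng <- range(cloud$het)
  qs <- stats::quantile(cloud$het, seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  bin_of <- function(h) findInterval(h, qs, rightmost.closed = TRUE,
                                     all.inside = TRUE)
  cloud_bin <- bin_of(cloud$het)
  res <- lapply(seq_len(nrow(observed)), function(i) {
    h <- observed$het[i]; th <- observed$theta[i]
    evaluable <- is.finite(h) && is.finite(th) &&
      h >= rng[1] - 0.02 && h <= rng[2] + 0.02
    if (!evaluable)
      return(data.frame(locus = observed$locus[i], het = h, theta = th,
                        p = NA_real_, class = "none", evaluable = FALSE))
    win <- cloud_bin == bin_of(h)
    p <- mean(cloud$theta[win] <= th)
    cls <- if (p < 0.025) "low" else if (p > 0.975) "high" else "none"
    data.frame(locus = observed$locus[i], het = h, theta = th, p = p,
               class = cls, evaluable = TRUE)
  })
  do.call(rbind, res)
}

#' Full FST-outlier scan of a dataset
#'
#' Computes per-locus heterozygosity and Weir-Cockerham theta between
#' the given groups, anchors a neutral island-model envelope at the
#' trimmed multilocus theta, and classifies every locus against it.
#'
#' @param dataset a [genotype_dataset()].
#' @param groups group labels per individual (two regions).
#' @param n_sim_loci simulated loci for the envelope.
#' @param seed integer seed.
#' @param ... passed to [simulate_envelope()].
#' @return object of class `fdist_result`: `observed` classification
#'   table, `cloud`, `envelope`, `target_fst`, `settings`.
#' @export
fst_outlier_scan <- function(dataset, groups, n_sim_loci = 5000,
                             seed = NULL, ...) {
  tm <- trimmed_mean_fst(dataset, groups)
  comp <- wc_fstats(dataset, groups)$components
  denom <- rowSums(comp)
  obs <- data.frame(
    locus = rownames(comp),
    het = vapply(rownames(comp), function(l)
      unname(heterozygosity(dataset, l, unbiased = FALSE)["He"]),
      numeric(1)),
    theta = ifelse(denom > 1e-12, comp[, "a"] / denom, NA_real_),
    stringsAsFactors = FALSE)
  env <- simulate_envelope(tm$theta_trimmed, n_sim_loci = n_sim_loci,
                           seed = seed, ...)
  cls <- classify_outliers(obs, env$cloud)
  structure(list(observed = cls, cloud = env$cloud,
                 envelope = env$envelope,
                 target_fst = tm$theta_trimmed, M = env$M,
                 settings = env$settings),
            class = "fdist_result")
}

#' @export
print.fdist_result <- function(x, ...) {
  cat("FST-outlier scan:", nrow(x$observed), "loci against",
      nrow(x$cloud), "simulated neutral loci\n")
  cat(sprintf("  anchor (trimmed multilocus theta): %.3f; calibrated M = %.3f\n",
              x$target_fst, x$M))
  print(transform(x$observed, p = signif(p, 3),
                  het = round(het, 3), theta = round(theta, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Plot an FST-heterozygosity cloud with its envelope
#'
#' @param x an `fdist_result`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.fdist_result <- function(x, ...) {
  plot(x$cloud$het, x$cloud$theta, col = "grey80", pch = ".",
       xlab = "heterozygosity", ylab = "theta (FST)", ...)
  graphics::lines(x$envelope$het, x$envelope$q50)
  graphics::lines(x$envelope$het, x$envelope$q025, lty = 2)
  graphics::lines(x$envelope$het, x$envelope$q975, lty = 2)
  out <- x$observed$class != "none"
  graphics::points(x$observed$het, x$observed$theta,
                   pch = ifelse(out, 19, 1))
  invisible(x)
}
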