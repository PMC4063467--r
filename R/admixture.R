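## Two-cluster admixture estimation.
##
## Model: each allele copy of individual i at locus l originates from
## cluster k with probability Q[i, k], and is then an independent draw
## from that cluster's allele frequencies P[k, l, ].  Priors are a
## symmetric Dirichlet(alpha = 1) on each Q row and a flat Dirichlet on
## each cluster-locus frequency vector (uncorrelated-frequency model).
## Inference is by Gibbs sampling over copy origins, frequencies and Q,
## or by a deterministic EM-style block relaxation; the two agree closely
## on well-separated data.

## precompute per-locus 0-based allele indices as one long vector layout
admix_index <- function(dataset) {
  n <- nrow(dataset$ind)
  L <- length(dataset$loci)
  lapply(seq_len(L), function(l) {
    labels <- dataset$loci[[l]]
    a <- c(match(dataset$allele1[, l], labels),
           match(dataset$allele2[, l], labels))
    ok <- !is.na(a)
    list(a = a[ok], ind = rep(seq_len(n), 2)[ok],
         k = length(labels))
  })
}

anchor_north <- function(Q, dataset) {
  north_site <- dataset$sites$id[which.max(dataset$sites$latitude)]
  rows <- dataset$ind$site == north_site
  mean(Q[rows, 1]) >= 0.5
}

#' Estimate two-cluster admixture proportions
#'
#' Unsupervised admixture for `K = 2` clusters.  `mode = "gibbs"` runs a
#' Gibbs sampler (posterior-mean Q and cluster frequencies after
#' burn-in); `mode = "em"` runs the deterministic block relaxation to a
#' fixed point.  Cluster labels are anchored geographically: cluster 1 is
#' the majority cluster of the northernmost site, so Q1 reads as
#' "northern ancestry".
#'
#' Convergence of the Gibbs run is checked by comparing posterior-mean Q
#' between the two halves of the sampling phase; the result is flagged
#' (not failed) when more than 5 percent of individuals differ by more
#' than 0.05.
#'
#' @param dataset a [genotype_dataset()].
#' @param K number of clusters; only 2 is supported.
#' @param burn_in,n_iter Gibbs burn-in and sampling iterations
#'   (`n_iter >= burn_in` enforced).
#' @param seed integer seed (Gibbs mode).
#' @param mode `"em"` or `"gibbs"`.
#' @param alpha symmetric Dirichlet hyperparameter on Q rows.
#' @return an object of class `qmatrix`: list with `Q` (individuals x 2,
#'   rows summing to 1), `freqs` (per locus, 2 x alleles cluster
#'   frequencies), `ind`, `sites`, `mode`, `K`, `seed`, `converged`.
#' @export
fit_admixture <- function(dataset, K = 2, burn_in = 5000, n_iter = 45000,
                          seed = NULL, mode = c("em", "gibbs"),
                          alpha = 1) {
  mode <- match.arg(mode)
  if (K != 2) stop("only K = 2 is supported")
  if (n_iter < burn_in) stop("n_iter must be >= burn_in")
  if (mode[1] == "gibbs" && n_iter - burn_in < 10)
    stop("gibbs mode needs at least 10 sampling iterations")
  ix <- admix_index(dataset)
  n <- nrow(dataset$ind)
  L <- length(dataset$loci)

  ## latitude-ranked initialization: north half starts in cluster 1
  lat <- dataset$sites$latitude[match(dataset$ind$site, dataset$sites$id)]
  q1 <- ifelse(lat >= stats::median(dataset$sites$latitude), 0.9, 0.1)

  if (mode == "em") {
    ## initialize cluster frequencies from the latitude-split weights
    P <- lapply(ix, function(e) {
      c1 <- tabulate_weighted(e$a, q1[e$ind], e$k)
      c2 <- tabulate_weighted(e$a, 1 - q1[e$ind], e$k)
      rbind((c1 + 1e-6) / sum(c1 + 1e-6), (c2 + 1e-6) / sum(c2 + 1e-6))
    })
    tot <- numeric(n)
    for (l in seq_len(L)) tot <- tot + tabulate(ix[[l]]$ind, n)
    for (it in seq_len(500)) {
      num1 <- numeric(n)
      for (l in seq_len(L)) {
        e <- ix[[l]]
        w1 <- q1[e$ind] * P[[l]][1, e$a]
        w2 <- (1 - q1[e$ind]) * P[[l]][2, e$a]
        r1 <- w1 / pmax(w1 + w2, 1e-300)
        c1 <- tabulate_weighted(e$a, r1, e$k)
        c2 <- tabulate_weighted(e$a, 1 - r1, e$k)
        P[[l]][1, ] <- (c1 + 1e-6) / sum(c1 + 1e-6)
        P[[l]][2, ] <- (c2 + 1e-6) / sum(c2 + 1e-6)
        num1 <- num1 + tabulate_weighted(e$ind, r1, n)
      }
      q_new <- ifelse(tot > 0, num1 / pmax(tot, 1), 0.5)
      delta <- max(abs(q_new - q1))
      q1 <- q_new
      if (delta < 1e-6) break
    }
    Q <- cbind(q1, 1 - q1)
    converged <- TRUE
  } else {
    res <- with_seed(seed, {
      P <- lapply(ix, function(e) matrix(1 / e$k, 2, e$k))
      qs <- q1
      Qsum1 <- Qsum2 <- numeric(n)
      Psum <- lapply(ix, function(e) matrix(0, 2, e$k))
      kept <- 0L
      half_mark <- burn_in + floor((n_iter - burn_in) / 2)
      Qhalf <- numeric(n)
      for (it in seq_len(n_iter)) {
        n1 <- n2 <- numeric(n)
        for (l in seq_len(L)) {
          e <- ix[[l]]
          w1 <- qs[e$ind] * P[[l]][1, e$a]
          w2 <- (1 - qs[e$ind]) * P[[l]][2, e$a]
          z1 <- stats::runif(length(w1)) < w1 / pmax(w1 + w2, 1e-300)
          cnt1 <- tabulate(e$a[z1], e$k)
          cnt2 <- tabulate(e$a[!z1], e$k)
          g1 <- stats::rgamma(e$k, shape = cnt1 + 1)
          g2 <- stats::rgamma(e$k, shape = cnt2 + 1)
          P[[l]][1, ] <- g1 / sum(g1)
          P[[l]][2, ] <- g2 / sum(g2)
          n1 <- n1 + tabulate(e$ind[z1], n)
          n2 <- n2 + tabulate(e$ind[!z1], n)
        }
        qs <- stats::rbeta(n, alpha + n1, alpha + n2)
        if (it > burn_in) {
          Qsum1 <- Qsum1 + qs
          kept <- kept + 1L
          for (l in seq_len(L)) Psum[[l]] <- Psum[[l]] + P[[l]]
          if (it == half_mark) { Qhalf <- Qsum1; khalf <- kept }
        }
      }
      q_mean <- Qsum1 / kept
      q_first <- Qhalf / khalf
      q_second <- (Qsum1 - Qhalf) / (kept - khalf)
      disc <- mean(abs(q_first - q_second) > 0.05)
      list(q = q_mean, P = lapply(Psum, function(m) m / kept),
           converged = disc <= 0.05)
    })
    q1 <- res$q
    P <- res$P
    Q <- cbind(q1, 1 - q1)
    converged <- res$converged
  }

  if (!anchor_north(Q, dataset)) {
    Q <- Q[, 2:1, drop = FALSE]
    P <- lapply(P, function(m) m[2:1, , drop = FALSE])
  }
  colnames(Q) <- c("Q1", "Q2")
  rownames(Q) <- dataset$ind$id
  for (l in seq_len(L)) colnames(P[[l]]) <- dataset$loci[[l]]
  names(P) <- names(dataset$loci)
  if (!converged)
    warning("admixture run flagged: split-half posterior means disagree")
  structure(list(Q = Q, freqs = P, ind = dataset$ind,
                 sites = dataset$sites, mode = mode, K = 2L,
                 burn_in = burn_in, n_iter = n_iter, seed = seed,
                 converged = converged),
            class = "qmatrix")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat("qmatrix: K =", x$K, "admixture for", nrow(x$Q),
      "individuals (mode:", x$mode, ")\n")
  m <- do.call(rbind, lapply(unique(x$ind$site), function(s)
    sample_mean_q(x, s)))
  rownames(m) <- unique(x$ind$site)
  cat("site mean Q:\n")
  print(round(m, 3))
  invisible(x)
}

#' Score individuals against fixed parental frequencies
#'
#' Per-individual northern ancestry fraction `q` maximizing the
#' likelihood of the individual's allele copies under the two-cluster
#' mixture with fixed cluster frequencies (EM to a fixed point, all
#' individuals in parallel).  Individuals with no scored genotype return
#' the prior mean 0.5.
#'
#' @param dataset a [genotype_dataset()].
#' @param north_freqs,south_freqs named lists of per-locus frequency
#'   vectors (names = allele labels), e.g. from [pooled_freqs()].
#' @param floor small probability added to every allele so queries
#'   carrying alleles unseen in a reference are not degenerate.
#' @return numeric vector of `q` (cluster-1 / northern proportions).
#' @export
ancestry_scores <- function(dataset, north_freqs, south_freqs,
                            floor = 1e-6) {
  n <- nrow(dataset$ind)
  L <- length(dataset$loci)
  P1 <- P2 <- vector("list", L)
  for (l in seq_len(L)) {
    labels <- as.character(dataset$loci[[l]])
    f1 <- north_freqs[[names(dataset$loci)[l]]]
    f2 <- south_freqs[[names(dataset$loci)[l]]]
    m1 <- match(labels, names(f1))
    m2 <- match(labels, names(f2))
    ## keep values on the full reference scale: renormalizing over the
    ## subset of alleles the query happens to carry would distort the
    ## cluster likelihood ratio
    P1[[l]] <- ifelse(is.na(m1), 0, f1[m1]) + floor
    P2[[l]] <- ifelse(is.na(m2), 0, f2[m2]) + floor
  }
  ix <- admix_index(dataset)
  q <- rep(0.5, n)
  tot <- numeric(n)
  for (l in seq_len(L)) tot <- tot + tabulate(ix[[l]]$ind, n)
  for (it in seq_len(500)) {
    num <- numeric(n)
    for (l in seq_len(L)) {
      e <- ix[[l]]
      w1 <- q[e$ind] * P1[[l]][e$a]
      w2 <- (1 - q[e$ind]) * P2[[l]][e$a]
      r1 <- w1 / pmax(w1 + w2, 1e-300)
      num <- num + tabulate_weighted(e$ind, r1, n)
    }
    q_new <- ifelse(tot > 0, num / pmax(tot, 1), 0.5)
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < 1e-9) break
  }
  q
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  rs <- rowsum(w, bin)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' Supervised admixture with reference (flanking) populations
#'
#' Cluster allele frequencies are estimated from the reference
#' individuals (posterior mean under a flat Dirichlet), and every
#' individual -- reference and query alike -- is scored against them with
#' [ancestry_scores()].
#'
#' @param dataset a [genotype_dataset()].
#' @param reference_sites named list `list(northern = <site ids>,
#'   southern = <site ids>)`.
#' @param seed unused (the estimator is deterministic); kept for
#'   interface parity with [fit_admixture()].
#' @return a `qmatrix` object (`mode = "supervised"`).
#' @export
fit_supervised <- function(dataset, reference_sites, seed = NULL) {
  stopifnot(all(c("northern", "southern") %in% names(reference_sites)))
  for (grp in c("northern", "southern")) {
    ids <- reference_sites[[grp]]
    nref <- sum(dataset$ind$site %in% ids)
    if (nref == 0) stop("no reference individuals for group ", grp)
    if (nref < 5)
      warning("reference group ", grp, " has fewer than 5 individuals")
  }
  ## posterior-mean frequencies with a flat Dirichlet prior
  post_freqs <- function(ids) {
    sub <- subset_sites(dataset, ids)
    f <- pooled_freqs(sub)
    for (l in names(f)) {
      ncop <- sum(!is.na(sub$allele1[, l])) * 2
      k <- length(f[[l]])
      cnt <- f[[l]] * ncop
      f[[l]] <- (cnt + 1) / (ncop + k)
    }
    f
  }
  fn <- post_freqs(reference_sites$northern)
  fs <- post_freqs(reference_sites$southern)
  q <- ancestry_scores(dataset, fn, fs, floor = 0)
  Q <- cbind(Q1 = q, Q2 = 1 - q)
  rownames(Q) <- dataset$ind$id
  P <- mapply(function(a, b) rbind(a, b), fn, fs, SIMPLIFY = FALSE)
  structure(list(Q = Q, freqs = P, ind = dataset$ind,
                 sites = dataset$sites, mode = "supervised", K = 2L,
                 burn_in = 0L, n_iter = 0L, seed = seed,
                 converged = TRUE,
                 reference_sites = reference_sites),
            class = "qmatrix")
}

#' Mean admixture proportions of a sample site
#'
#' @param qmatrix a `qmatrix` from [fit_admixture()] or
#'   [fit_supervised()].
#' @param site site id.
#' @return length-2 numeric vector (mean Q1, mean Q2), summing to 1.
#' @export
sample_mean_q <- function(qmatrix, site) {
  rows <- qmatrix$ind$site == site
  if (!any(rows)) stop("no individuals at site ", site)
  colMeans(qmatrix$Q[rows, , drop = FALSE])
}
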