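## Coincidence-concordance (Co-Co) outlier analysis: each clinal locus
## contributes a point (cline midpoint latitude, log cline slope); loci
## outside the 95% / 99% probability-mass contours of a bivariate
## Gaussian kernel density over all points are flagged as candidates for
## locus-specific processes (e.g. balancing selection flattening a
## cline).

## Biased cross-validation criterion for an unconstrained bivariate
## Gaussian kernel bandwidth matrix H.  With S = 2H the Gaussian kernel
## identities give, for q = t(d) %*% solve(H) %*% d / 4,
##   (tr(H grad^2))^2 phi_S(d) = phi_S(d) * (q^2 - 4 q + 2)
## so  BCV(H) = 1 / (4 pi n sqrt(det H))
##            + sum_{i != j} phi_S(d_ij) (q^2 - 4q + 2) / (4 n (n - 1)).
bcv_objective <- function(H, diffs) {
  detH <- H[1, 1] * H[2, 2] - H[1, 2]^2
  if (!is.finite(detH) || detH <= 0) return(Inf)
  Hinv <- solve(H)
  q <- (diffs[, 1]^2 * Hinv[1, 1] + 2 * diffs[, 1] * diffs[, 2] *
          Hinv[1, 2] + diffs[, 2]^2 * Hinv[2, 2]) / 4
  phi <- exp(-q) / (4 * pi * sqrt(detH))
  n <- (1 + sqrt(1 + 8 * nrow(diffs))) / 2   # diffs has n(n-1)/2 rows (i<j)
  psi <- 2 * sum(phi * (q^2 - 4 * q + 2)) / (n * (n - 1))
  1 / (4 * pi * n * sqrt(detH)) + psi / 4
}

#' Biased cross-validation bandwidth matrix for a bivariate sample
#'
#' Numerically minimizes the biased cross-validation criterion over
#' symmetric positive-definite 2 x 2 matrices, parameterized by log
#' standard deviations and an unconstrained correlation.  As with
#' univariate BCV (cf. `bw.bcv`), the criterion decays to zero under
#' extreme oversmoothing, so the search is bounded to a window around the
#' normal-reference bandwidth `n^(-1/3) * cov(x)`; small samples without
#' an interior minimum end up at the (oversmoothing) boundary, which only
#' widens contours.  Falls back to the normal reference with a warning if
#' the optimization fails outright.
#'
#' @param x two-column numeric matrix of points.
#' @return 2 x 2 bandwidth matrix with attribute `"method"` (`"bcv"` or
#'   `"normal_reference"`).
#' @export
bcv_bandwidth <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ## robust scale anchor so one extreme point cannot inflate the search
  ## window (MAD marginals, Kendall-based correlation)
  s1 <- stats::mad(x[, 1]); s2 <- stats::mad(x[, 2])
  if (s1 <= 0) s1 <- stats::sd(x[, 1])
  if (s2 <= 0) s2 <- stats::sd(x[, 2])
  tau <- suppressWarnings(stats::cor(x[, 1], x[, 2], method = "kendall"))
  rho <- if (is.finite(tau)) sin(pi * tau / 2) else 0
  S <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
  Hnr <- n^(-1 / 3) * S
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  diffs <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
  par2H <- function(par) {
    s1 <- exp(par[1]); s2 <- exp(par[2]); rho <- tanh(par[3])
    matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
  }
  start <- c(0.5 * log(Hnr[1, 1]), 0.5 * log(Hnr[2, 2]),
             atanh(max(-0.95, min(0.95,
                                  Hnr[1, 2] / sqrt(Hnr[1, 1] * Hnr[2, 2])))))
  lower <- c(start[1:2] - log(4), atanh(-0.95))
  upper <- c(start[1:2] + log(2), atanh(0.95))
  opt <- try(stats::optim(start, function(p)
    bcv_objective(par2H(p), diffs),
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = 500)), silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value)) {
    warning("BCV bandwidth optimization failed; using normal reference")
    H <- Hnr
    attr(H, "method") <- "normal_reference"
    return(H)
  }
  H <- par2H(opt$par)
  attr(H, "method") <- "bcv"
  H
}

kde2_eval <- function(x, data, H) {
  ## density of the Gaussian-kernel mixture at rows of x
  Hinv <- solve(H)
  detH <- det(H)
  const <- 1 / (2 * pi * sqrt(detH))
  vapply(seq_len(nrow(x)), function(i) {
    d1 <- x[i, 1] - data[, 1]
    d2 <- x[i, 2] - data[, 2]
    q <- d1^2 * Hinv[1, 1] + 2 * d1 * d2 * Hinv[1, 2] + d2^2 * Hinv[2, 2]
    mean(const * exp(-q / 2))
  }, numeric(1))
}

#' Co-Co outlier detection by bivariate kernel density contours
#'
#' Builds the cloud of (cline midpoint, log slope) points, estimates a
#' bivariate Gaussian kernel density with a biased-cross-validation
#' bandwidth matrix, and flags a locus as an outlier at mass level `L`
#' when it lies outside the smallest region containing `L` of the
#' probability mass.  The density at each point is re-estimated without
#' that point (leave-one-out), so a lone extreme point cannot mask
#' itself.  The mass threshold is calibrated by a smoothed bootstrap
#' under the fitted density: `n_mc` replicates each draw a fresh
#' `n`-point sample from the kernel mixture, evaluate the leave-one-out
#' density of one of its points, and the threshold is the `(1 - L)`
#' quantile of those values -- so the flag rate matches the nominal
#' level even at the small `n` typical of cline sets.
#'
#' @param cline_fits cline-fit table (from [cline_analysis()]) or list
#'   of `cline_fit` objects; at least 5 points.
#' @param mass_levels probability-mass levels for the contours.
#' @param n_mc bootstrap replicates used to locate each contour level.
#' @param seed integer seed.
#' @return object of class `coco_result`: `points` data frame with
#'   per-level outlier flags, bandwidth matrix `H`, `bandwidth_method`,
#'   `thresholds`.
#' @export
coco_outliers <- function(cline_fits, mass_levels = c(0.95, 0.99),
                          n_mc = 4000, seed = NULL) {
  df <- as_cline_df(cline_fits)
  df <- df[is.finite(df$midpoint_lat) & is.finite(df$log_slope), ,
           drop = FALSE]
  if (nrow(df) < 5) stop("need >= 5 clinal loci for Co-Co analysis")
  X <- cbind(df$midpoint_lat, df$log_slope)
  if (all(apply(X, 2, function(v) diff(range(v)) < 1e-12)))
    stop("degenerate density: all Co-Co points identical")
  H <- bcv_bandwidth(X)
  n <- nrow(X)
  R <- chol(H)
  with_seed(seed, {
    dens_at_point <- vapply(seq_len(n), function(i)
      kde2_eval(X[i, , drop = FALSE], X[-i, , drop = FALSE], H),
      numeric(1))
    ## per-point smoothed-bootstrap null: for point i, replicate the
    ## statistic under the leave-i-out mixture (draw n points from it,
    ## evaluate the leave-one-out density of the first), so an extreme
    ## point neither masks itself nor contaminates its own threshold
    thresholds <- matrix(NA_real_, n, length(mass_levels))
    for (i in seq_len(n)) {
      rest <- X[-i, , drop = FALSE]
      null_dens <- vapply(seq_len(n_mc), function(b) {
        comp <- sample.int(n - 1, n, replace = TRUE)
        z <- matrix(stats::rnorm(2 * n), n, 2) %*% R
        samp <- rest[comp, , drop = FALSE] + z
        kde2_eval(samp[1, , drop = FALSE], samp[-1, , drop = FALSE], H)
      }, numeric(1))
      thresholds[i, ] <- stats::quantile(null_dens, 1 - mass_levels,
                                         names = FALSE)
    }
    flags <- dens_at_point < thresholds
    colnames(flags) <- sprintf("outlier_%g", 100 * mass_levels)
    out <- cbind(df[c("locus", "marker_class", "midpoint_lat",
                      "log_slope")], as.data.frame(flags))
    structure(list(points = out, H = H,
                   bandwidth_method = attr(H, "method"),
                   mass_levels = mass_levels,
                   thresholds = thresholds,
                   density_at_points = dens_at_point),
              class = "coco_result")
  })
}

#' @export
print.coco_result <- function(x, ...) {
  cat("Co-Co outlier analysis of", nrow(x$points), "clinal loci",
      sprintf("(bandwidth: %s)\n", x$bandwidth_method))
  fl <- x$points[, grep("^outlier_", names(x$points)), drop = FALSE]
  any_out <- rowSums(fl) > 0
  if (any(any_out)) {
    print(x$points[any_out, ], row.names = FALSE)
  } else cat("no outliers at",
             paste(sprintf("%g%%", 100 * x$mass_levels),
                   collapse = " / "), "\n")
  invisible(x)
}

#' Plot a Co-Co cloud with density contours
#'
#' Base-graphics scatter of (midpoint, log slope) with kernel-density
#' contours at the configured mass levels, outliers highlighted.
#'
#' @param x a `coco_result`.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.coco_result <- function(x, ...) {
  pts <- cbind(x$points$midpoint_lat, x$points$log_slope)
  rx <- range(pts[, 1]) + c(-1, 1) * 3 * sqrt(x$H[1, 1])
  ry <- range(pts[, 2]) + c(-1, 1) * 3 * sqrt(x$H[2, 2])
  gx <- seq(rx[1], rx[2], length.out = 80)
  gy <- seq(ry[1], ry[2], length.out = 80)
  grid <- as.matrix(expand.grid(gx, gy))
  dens <- matrix(kde2_eval(grid, pts, x$H), 80, 80)
  samp <- kde2_eval(pts, pts, x$H)
  levels <- stats::quantile(samp, 1 - x$mass_levels, names = FALSE)
  plot(pts, xlab = "cline midpoint (deg latitude)",
       ylab = "log |cline slope|", pch = 19, ...)
  graphics::contour(gx, gy, dens, levels = sort(unique(levels)),
                    add = TRUE, drawlabels = FALSE, lty = c(2, 1))
  out <- rowSums(x$points[, grep("^outlier_", names(x$points)),
                          drop = FALSE]) > 0
  if (any(out))
    graphics::points(pts[out, , drop = FALSE], pch = 1, cex = 2.2)
  invisible(x)
}
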