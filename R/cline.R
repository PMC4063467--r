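## Geographic cline analysis: per-locus allele-frequency clines over
## latitude fitted with the "twice-broken-stick" model -- flat plateau
## frequencies north and south of the transition, a linear segment in
## between -- plus the clinal-locus screen (isolation by distance and
## broken-stick improvement over a straight line).

#' Per-site frequency of the tracked allele at a locus
#'
#' The tracked allele is the one with the largest absolute frequency
#' difference between the northernmost and the southernmost site, so the
#' fitted cline is oriented along the main latitudinal contrast.
#'
#' @param dataset a [genotype_dataset()].
#' @param locus locus name.
#' @return data frame with `site`, `latitude`, `longitude`, `freq`,
#'   `n_copies`, and attribute `"allele"` (the tracked label).
#' @export
tracked_allele_freqs <- function(dataset, locus) {
  f <- allele_freqs(dataset)[[locus]]
  ord <- order(dataset$sites$latitude)
  south <- dataset$sites$id[ord[1]]
  north <- dataset$sites$id[ord[length(ord)]]
  dif <- abs(f[north, ] - f[south, ])
  allele <- colnames(f)[which.max(dif)]
  out <- data.frame(site = dataset$sites$id,
                    latitude = dataset$sites$latitude,
                    longitude = dataset$sites$longitude,
                    freq = f[dataset$sites$id, allele],
                    n_copies = attr(f, "n_copies")[dataset$sites$id],
                    stringsAsFactors = FALSE)
  attr(out, "allele") <- allele
  out
}

## profile residual sum of squares of the twice-broken-stick model:
## given edges, the two plateau frequencies enter linearly
tbs_rss <- function(edges, freq, lat) {
  eS <- edges[1]; eN <- edges[2]
  if (!(eN > eS)) return(list(rss = Inf))
  w <- pmin(1, pmax(0, (lat - eS) / (eN - eS)))   # 0 south, 1 north
  X <- cbind(1 - w, w)
  fit <- stats::lm.fit(X, freq)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {   # all weights equal: plateaus not identifiable
    coefs <- c(mean(freq), mean(freq))
    return(list(rss = sum((freq - mean(freq))^2), p = coefs, w = w))
  }
  list(rss = sum(fit$residuals^2), p = coefs, w = w)
}

#' Fit a twice-broken-stick allele-frequency cline
#'
#' Least-squares fit of the 4-parameter piecewise function
#' `f(lat) = p_south` for `lat <= lat_south_edge`, linear between the
#' edges, `p_north` for `lat >= lat_north_edge`.  Edge initialization is
#' a deterministic grid search over candidate edge pairs (site latitudes
#' and their midpoints), refined by Nelder-Mead on the profiled residual
#' sum of squares.  The cline midpoint is the latitude where the fitted
#' frequency crosses `(p_north + p_south) / 2`, i.e. the centre of the
#' linear segment; slope is per degree latitude, positive when frequency
#' increases northward.
#'
#' @param freq_by_site numeric vector of per-site allele frequencies.
#' @param latitudes matching site latitudes (decimal degrees).
#' @param locus,marker_class labels carried into the result.
#' @return object of class `cline_fit` with fields `p_south`, `p_north`,
#'   `lat_south_edge`, `lat_north_edge`, `midpoint_lat`, `slope`,
#'   `log_slope` (natural log of `|slope|`, floored at 1e-6), `rss`,
#'   `rss_linear`.
#' @export
fit_twice_broken_stick <- function(freq_by_site, latitudes,
                                   locus = NA_character_,
                                   marker_class = "microsatellite") {
  stopifnot(length(freq_by_site) == length(latitudes),
            length(freq_by_site) >= 5)
  ok <- is.finite(freq_by_site) & is.finite(latitudes)
  freq <- freq_by_site[ok]; lat <- latitudes[ok]
  if (diff(range(freq)) < 1e-9)
    stop("zero-slope cline: frequencies do not differ across sites")
  slat <- sort(unique(lat))
  cand <- sort(unique(c(slat, (slat[-1] + slat[-length(slat)]) / 2)))
  best <- list(rss = Inf)
  best_edges <- c(NA, NA)
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (cand[j] <= cand[i]) next
    r <- tbs_rss(c(cand[i], cand[j]), freq, lat)
    if (r$rss < best$rss - 1e-15) {
      best <- r
      best_edges <- c(cand[i], cand[j])
    }
  }
  ## refine edges on (eS, log width) to keep eN > eS
  obj <- function(par) {
    tbs_rss(c(par[1], par[1] + exp(par[2])), freq, lat)$rss
  }
  opt <- stats::optim(c(best_edges[1], log(diff(best_edges))), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  edges <- c(opt$par[1], opt$par[1] + exp(opt$par[2]))
  if (diff(edges) < 1e-6)
    stop("degenerate cline: fitted edges collapse")
  fit <- tbs_rss(edges, freq, lat)
  p <- pmin(1, pmax(0, fit$p))
  p_south <- unname(p[1]); p_north <- unname(p[2])
  if (abs(p_north - p_south) < 1e-9)
    stop("zero-slope cline: fitted plateaus coincide")
  lin <- stats::lm(freq ~ lat)
  structure(list(locus = locus, marker_class = marker_class,
                 p_south = p_south, p_north = p_north,
                 lat_south_edge = edges[1], lat_north_edge = edges[2],
                 midpoint_lat = mean(edges),
                 slope = (p_north - p_south) / diff(edges),
                 log_slope = log(max(abs((p_north - p_south) /
                                           diff(edges)), 1e-6)),
                 rss = fit$rss,
                 rss_linear = sum(stats::residuals(lin)^2),
                 n_sites = length(freq)),
            class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "cline_fit%s: plateaus %.3f (S) -> %.3f (N), edges %.4f..%.4f\n",
    if (is.na(x$locus)) "" else paste0(" [", x$locus, "]"),
    x$p_south, x$p_north, x$lat_south_edge, x$lat_north_edge))
  cat(sprintf("  midpoint %.4f deg, slope %.3f per deg (log|slope| %.3f)\n",
              x$midpoint_lat, x$slope, x$log_slope))
  invisible(x)
}

#' Screen a locus for clinal variation
#'
#' A locus is called clinal when (1) it shows significant isolation by
#' distance -- a Mantel test (999 permutations by default) of pairwise
#' allele-frequency distance against great-circle distance -- and (2) the
#' twice-broken-stick model is a significant improvement over a straight
#' line of frequency on latitude (F-test on residual sums of squares with
#' the 2-parameter difference).
#'
#' @param freq_by_site per-site frequencies of the tracked allele.
#' @param latitudes site latitudes.
#' @param longitudes site longitudes (for great-circle distances);
#'   ignored when `pairwise_geo_dist` is given.
#' @param pairwise_geo_dist optional precomputed distance matrix (km).
#' @param n_permutations Mantel permutations.
#' @param alpha significance level for both criteria.
#' @param seed integer seed (Mantel permutations).
#' @return list with `ibd_p`, `linear_vs_broken_p`, `is_clinal`,
#'   `degenerate`.
#' @export
identify_clinal_locus <- function(freq_by_site, latitudes,
                                  longitudes = NULL,
                                  pairwise_geo_dist = NULL,
                                  n_permutations = 999, alpha = 0.05,
                                  seed = NULL) {
  stopifnot(length(freq_by_site) >= 6)
  if (diff(range(latitudes)) < 0.5)
    stop("sites must span at least 0.5 degrees latitude")
  if (diff(range(freq_by_site)) < 1e-9)
    return(list(ibd_p = NA_real_, linear_vs_broken_p = NA_real_,
                is_clinal = FALSE, degenerate = TRUE))
  if (is.null(pairwise_geo_dist)) {
    if (is.null(longitudes)) longitudes <- rep(0, length(latitudes))
    xy <- cbind(longitudes, latitudes)
    pairwise_geo_dist <- geosphere::distm(xy,
                                          fun = geosphere::distHaversine) / 1000
  }
  d_freq <- as.matrix(stats::dist(freq_by_site))
  ibd_p <- with_seed(seed, {
    m <- vegan::mantel(stats::as.dist(pairwise_geo_dist),
                       stats::as.dist(d_freq),
                       permutations = n_permutations)
    m$signif
  })
  n <- length(freq_by_site)
  fit <- try(fit_twice_broken_stick(freq_by_site, latitudes),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(ibd_p = ibd_p, linear_vs_broken_p = NA_real_,
                is_clinal = FALSE, degenerate = TRUE))
  rss1 <- fit$rss_linear
  rss2 <- fit$rss
  if (rss1 - rss2 < 1e-12 * max(rss1, 1e-12)) {
    f_p <- 1
  } else if (rss2 < 1e-12) {
    f_p <- 0
  } else {
    Fstat <- ((rss1 - rss2) / 2) / (rss2 / (n - 4))
    f_p <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
  }
  list(ibd_p = ibd_p, linear_vs_broken_p = f_p,
       is_clinal = ibd_p < alpha && f_p < alpha, degenerate = FALSE)
}

#' Cline analysis of every locus in a dataset
#'
#' Runs [tracked_allele_freqs()], [identify_clinal_locus()] and
#' [fit_twice_broken_stick()] per locus and assembles one row per locus.
#'
#' @param dataset a [genotype_dataset()].
#' @param marker_class label stored with each fit.
#' @param n_permutations Mantel permutations.
#' @param seed integer seed.
#' @return data frame with the `cline_fit` fields plus `ibd_p`,
#'   `linear_vs_broken_p`, `is_clinal`.
#' @export
cline_analysis <- function(dataset, marker_class = "microsatellite",
                           n_permutations = 999, seed = NULL) {
  rows <- lapply(names(dataset$loci), function(loc) {
    tf <- tracked_allele_freqs(dataset, loc)
    scr <- identify_clinal_locus(tf$freq, tf$latitude, tf$longitude,
                                 n_permutations = n_permutations,
                                 seed = seed)
    fit <- try(fit_twice_broken_stick(tf$freq, tf$latitude, locus = loc,
                                      marker_class = marker_class),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      return(data.frame(locus = loc, marker_class = marker_class,
                        allele = attr(tf, "allele"),
                        p_south = NA_real_, p_north = NA_real_,
                        lat_south_edge = NA_real_,
                        lat_north_edge = NA_real_,
                        midpoint_lat = NA_real_, slope = NA_real_,
                        log_slope = NA_real_, ibd_p = scr$ibd_p,
                        linear_vs_broken_p = scr$linear_vs_broken_p,
                        is_clinal = FALSE, stringsAsFactors = FALSE))
    data.frame(locus = loc, marker_class = marker_class,
               allele = attr(tf, "allele"),
               p_south = fit$p_south, p_north = fit$p_north,
               lat_south_edge = fit$lat_south_edge,
               lat_north_edge = fit$lat_north_edge,
               midpoint_lat = fit$midpoint_lat, slope = fit$slope,
               log_slope = fit$log_slope, ibd_p = scr$ibd_p,
               linear_vs_broken_p = scr$linear_vs_broken_p,
               is_clinal = scr$is_clinal, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch t-tests between marker classes on cline parameters
#'
#' Compares cline midpoints and log-slopes between the two marker
#' classes (e.g. microsatellites versus allozymes) with two-sample
#' t-tests assuming unequal variances.
#'
#' @param cline_fits data frame from [cline_analysis()] (or a list of
#'   `cline_fit` objects) with at least 2 fits per class.
#' @return data frame with rows `midpoint` and `log_slope` and columns
#'   `t`, `df`, `p`.  Degenerate comparisons (no variance anywhere)
#'   return `t = 0, p = 1`.
#' @export
compare_marker_classes <- function(cline_fits) {
  df <- as_cline_df(cline_fits)
  classes <- unique(df$marker_class)
  if (length(classes) != 2) stop("need exactly 2 marker classes")
  if (any(table(df$marker_class) < 2))
    stop("each marker class needs >= 2 fits")
  one <- function(v) {
    x <- df[[v]][df$marker_class == classes[1]]
    y <- df[[v]][df$marker_class == classes[2]]
    tt <- try(stats::t.test(x, y, var.equal = FALSE), silent = TRUE)
    if (inherits(tt, "try-error"))
      return(data.frame(quantity = v, t = 0, df = NA_real_, p = 1))
    data.frame(quantity = v, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }
  rbind(one("midpoint_lat"), one("log_slope"))
}

#' Mean latitudinal cline shift between two datasets, in kilometres
#'
#' `(mean midpoint at time 2 - mean midpoint at time 1) * km_per_degree`;
#' positive values are northward shifts.
#'
#' @param fits_t1,fits_t2 cline-fit tables (or lists of `cline_fit`).
#' @param km_per_degree kilometres per degree latitude (default 111.2,
#'   the mean meridian arc).
#' @return signed shift in km.
#' @export
cline_shift_km <- function(fits_t1, fits_t2, km_per_degree = 111.2) {
  m1 <- as_cline_df(fits_t1)$midpoint_lat
  m2 <- as_cline_df(fits_t2)$midpoint_lat
  m1 <- m1[is.finite(m1)]; m2 <- m2[is.finite(m2)]
  if (!length(m1) || !length(m2)) stop("empty cline-fit list")
  (mean(m2) - mean(m1)) * km_per_degree
}

as_cline_df <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "cline_fit")) x <- list(x)
  do.call(rbind, lapply(x, function(f)
    data.frame(locus = f$locus, marker_class = f$marker_class,
               midpoint_lat = f$midpoint_lat, slope = f$slope,
               log_slope = f$log_slope, stringsAsFactors = FALSE)))
}
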