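## Synthetic contact-zone data with known truth.
##
## Two divergent parental populations (multilocus Fct near 0.4 by default,
## matching the divergence of the oyster contact zone this package was
## built around) are generated under the Balding-Nichols construction and
## sampled at sites along a latitudinal transect.  Mixed reefs can be
## mechanically mixed (two populations co-occurring without interbreeding)
## or hybrid swarms (random mating at pooled frequencies).

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so package functions never
#' perturb global random state.
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) { x <- rep(1, length(alpha)) }
  x / sum(x)
}

#' Multilocus Fct from two sets of population frequencies
#'
#' Parametric (infinite-sample) value of the variance-component fixation
#' index between the two populations: per allele,
#' `s2 = sum((p_i - pbar)^2) / (r - 1)` and the total variance is
#' `pbar * (1 - pbar) + s2 / r`; the multilocus index is the ratio of
#' sums over alleles and loci.  This is the quantity the
#' Weir-Cockerham / AMOVA estimators converge to, and under the
#' Balding-Nichols construction its expectation equals the divergence
#' parameter, so simulated datasets can be calibrated directly against
#' the AMOVA Fct scale.
#'
#' @param north_freqs,south_freqs named lists (one numeric frequency
#'   vector per locus).
#' @return scalar Fct in `[0, 1)`.
#' @export
wright_fct <- function(north_freqs, south_freqs) {
  num <- den <- 0
  for (l in seq_along(north_freqs)) {
    pn <- north_freqs[[l]]; ps <- south_freqs[[l]]
    pbar <- (pn + ps) / 2
    s2 <- (pn - pbar)^2 + (ps - pbar)^2          # divisor r - 1 = 1
    num <- num + sum(s2)
    den <- den + sum(pbar * (1 - pbar) + s2 / 2)
  }
  if (den <= 0) return(0)
  num / den
}

#' Draw divergent parental allele frequencies at a target Fct
#'
#' Per locus, an ancestral frequency vector is drawn from a flat Dirichlet
#' and the two population vectors from `Dirichlet(p * (1 - F) / F)`
#' (Balding-Nichols), giving a one-parameter mapping from `target_fct` to
#' expected divergence.  The draw is repeated until the realized
#' multilocus [wright_fct()] of the returned vectors is within `tol` of
#' the target.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus single count or per-locus vector of allele
#'   numbers.
#' @param target_fct desired multilocus Fct in `[0, 0.95]`.
#' @param seed integer seed.
#' @param tol acceptance half-width on realized Fct (default 0.05).
#' @param max_retries bound on redraws before failing.
#' @return list with `north`, `south` (named lists of frequency vectors,
#'   allele labels as names), `ancestral`, and `realized_fct`.
#' @export
draw_divergent_frequencies <- function(n_loci, alleles_per_locus,
                                       target_fct, seed = NULL,
                                       tol = 0.05, max_retries = 200) {
  stopifnot(n_loci >= 1, target_fct >= 0, target_fct <= 0.95)
  k <- rep_len(alleles_per_locus, n_loci)
  stopifnot(all(k >= 2))
  with_seed(seed, {
    realized <- NA_real_
    for (try in seq_len(max_retries)) {
      north <- south <- anc <- vector("list", n_loci)
      for (l in seq_len(n_loci)) {
        labels <- 100L + 2L * (seq_len(k[l]) - 1L)
        p <- rdirichlet1(rep(1, k[l]))
        if (target_fct < 1e-8) {
          pn <- ps <- p
        } else {
          conc <- (1 - target_fct) / target_fct
          pn <- rdirichlet1(p * conc)
          ps <- rdirichlet1(p * conc)
        }
        names(p) <- names(pn) <- names(ps) <- labels
        anc[[l]] <- p; north[[l]] <- pn; south[[l]] <- ps
      }
      names(anc) <- names(north) <- names(south) <-
        sprintf("L%02d", seq_len(n_loci))
      realized <- wright_fct(north, south)
      ok <- if (target_fct < 1e-8) realized < 0.02
            else abs(realized - target_fct) <= tol
      if (ok)
        return(list(north = north, south = south, ancestral = anc,
                    realized_fct = realized))
    }
    stop("could not reach target Fct ", target_fct, " within +/-", tol,
         " after ", max_retries, " draws (last realized ",
         signif(realized, 3), ")")
  })
}

#' Simulation configuration for a synthetic contact zone
#'
#' The defaults emulate a realistic contact-zone survey of Gulf of
#' Mexico oysters: 11 microsatellite loci with allele counts between 5
#' and 29, parental divergence Fct = 0.4, and noise rates of zero
#' (noise is opt-in).
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus count or per-locus vector; default the 11
#'   observed marker allele counts.
#' @param target_fct parental divergence.
#' @param site_plan data frame with columns `latitude`, `n`,
#'   `composition` (one of `"pure_north"`, `"pure_south"`,
#'   `"mechanical_mix"`, `"hybrid_swarm"`, `"f1_only"`) and `r` (expected
#'   northern fraction; ignored for pure and F1 sites).  Defaults to
#'   [macro_site_plan()].
#' @param null_allele_rate per-locus hidden-null-allele frequency.
#' @param genotyping_error_rate per-allele miscall probability (replace
#'   with a uniformly chosen neighbouring allele label).
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 11,
                       alleles_per_locus = c(5, 10, 29, 25, 9, 11,
                                             24, 6, 6, 9, 22),
                       target_fct = 0.4,
                       site_plan = macro_site_plan(),
                       null_allele_rate = 0,
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_loci >= 1,
            target_fct >= 0, target_fct < 1,
            null_allele_rate >= 0, null_allele_rate <= 1,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  site_plan <- as.data.frame(site_plan)
  req <- c("latitude", "n", "composition")
  stopifnot(all(req %in% names(site_plan)))
  if (is.null(site_plan$r)) site_plan$r <- NA_real_
  if (is.null(site_plan$id))
    site_plan$id <- sprintf("S%02d", seq_len(nrow(site_plan)))
  bad <- setdiff(site_plan$composition,
                 c("pure_north", "pure_south", "mechanical_mix",
                   "hybrid_swarm", "f1_only"))
  if (length(bad)) stop("unknown composition: ", paste(bad, collapse = ", "))
  needs_r <- site_plan$composition %in% c("mechanical_mix", "hybrid_swarm")
  if (any(needs_r & (is.na(site_plan$r) | site_plan$r < 0 | site_plan$r > 1)))
    stop("mixed compositions need r in [0, 1]")
  structure(list(n_loci = n_loci,
                 alleles_per_locus = rep_len(alleles_per_locus, n_loci),
                 target_fct = target_fct, site_plan = site_plan,
                 null_allele_rate = null_allele_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default site plans
#'
#' `macro_site_plan()` mirrors the broad-scale transect: 10 single-reef
#' sites of 45 individuals spanning 26.0-29.8 degrees latitude, five pure
#' northern and five pure southern.  `zone_site_plan()` mirrors the
#' fine-scale contact-zone design: 25 sites of 20 individuals, of which 7
#' northern, 11 southern, and 7 mixed reefs with northern fractions spread
#' around one half.
#'
#' @param n_per_site individuals per site.
#' @param mixed_model composition of the mixed reefs
#'   (`"hybrid_swarm"` or `"mechanical_mix"`).
#' @param mixed_r northern fractions of the 7 mixed reefs.
#' @return a site-plan data frame for [sim_config()].
#' @export
macro_site_plan <- function(n_per_site = 45) {
  data.frame(
    id = sprintf("M%02d", 1:10),
    latitude = c(29.78, 29.48, 28.62, 28.27, 28.14,
                 27.64, 27.40, 26.90, 26.55, 26.02),
    n = n_per_site,
    composition = rep(c("pure_north", "pure_south"), each = 5),
    r = NA_real_)
}

#' @rdname macro_site_plan
#' @export
zone_site_plan <- function(n_per_site = 20,
                           mixed_model = c("hybrid_swarm",
                                           "mechanical_mix"),
                           mixed_r = c(0.35, 0.43, 0.45, 0.50,
                                       0.53, 0.57, 0.65)) {
  mixed_model <- match.arg(mixed_model)
  stopifnot(length(mixed_r) == 7)
  south <- data.frame(id = sprintf("Z%02d", 1:11),
                      latitude = seq(27.60, 27.85, length.out = 11),
                      n = n_per_site, composition = "pure_south",
                      r = NA_real_)
  mixed <- data.frame(id = sprintf("Z%02d", 12:18),
                      latitude = seq(27.87, 27.99, length.out = 7),
                      n = n_per_site, composition = mixed_model,
                      r = mixed_r)
  north <- data.frame(id = sprintf("Z%02d", 19:25),
                      latitude = seq(28.01, 28.15, length.out = 7),
                      n = n_per_site, composition = "pure_north",
                      r = NA_real_)
  rbind(south, mixed, north)
}

#' Impose a latitudinal cline on a site plan
#'
#' Sets each site's expected northern fraction to
#' `r = logistic((latitude - midpoint_lat) / width_deg)` and marks all
#' sites as `hybrid_swarm` (random mating at locally pooled frequencies),
#' so expected allele frequencies follow a smooth latitudinal transition.
#'
#' @param site_plan a site-plan data frame.
#' @param midpoint_lat latitude of the cline centre, degrees.
#' @param width_deg logistic scale parameter, degrees (> 0).
#' @return the site plan with updated `composition`/`r`, with attribute
#'   `"cline_truth"` = list(midpoint, slope at centre in ancestry fraction
#'   per degree).
#' @export
plant_cline <- function(site_plan, midpoint_lat, width_deg) {
  stopifnot(width_deg > 0)
  site_plan <- as.data.frame(site_plan)
  site_plan$r <- stats::plogis((site_plan$latitude - midpoint_lat) /
                               width_deg)
  site_plan$composition <- "hybrid_swarm"
  attr(site_plan, "cline_truth") <-
    list(midpoint = midpoint_lat, slope = 1 / (4 * width_deg))
  site_plan
}

#' Write a simulated dataset with its truth sidecar
#'
#' Serializes a [simulate_dataset()] result: the genotypes in Genepop
#' format (`genotypes.gen`), the per-individual truth as CSV
#' (`truth.csv`: individual, site, true ancestry fraction, source
#' population), the per-site plan (`site_plan.csv`), the parental
#' frequencies (`parental_freqs.csv`, long format) and the generating
#' configuration (`config.json`).
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genepop(sim$dataset, file.path(dir, "genotypes.gen"),
                title = "contactzone simulated dataset")
  utils::write.csv(
    data.frame(individual = sim$dataset$ind$id,
               site = sim$dataset$ind$site,
               ancestry = sim$truth$ancestry,
               source = sim$truth$source),
    file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$site_plan,
                   file.path(dir, "site_plan.csv"), row.names = FALSE)
  freq_rows <- do.call(rbind, lapply(names(sim$truth$north_freqs),
                                     function(l) {
    data.frame(locus = l,
               allele = names(sim$truth$north_freqs[[l]]),
               north = unname(sim$truth$north_freqs[[l]]),
               south = unname(sim$truth$south_freqs[[l]]))
  }))
  utils::write.csv(freq_rows, file.path(dir, "parental_freqs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(realized_fct = sim$truth$realized_fct,
         n_individuals = nrow(sim$dataset$ind),
         n_loci = length(sim$dataset$loci)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a contact-zone genotype dataset with known truth
#'
#' Pure sites draw both alleles of every genotype from one parental
#' population's frequencies (Hardy-Weinberg within the source).
#' `mechanical_mix(r)` assigns each individual a source population
#' (northern with probability `r`) and then draws it as pure -- the
#' Wahlund configuration.  `hybrid_swarm(r)` draws each allele
#' independently from the pooled frequencies `r * pN + (1 - r) * pS`
#' (Hardy-Weinberg in the pooled gene pool).  `f1_only` draws one allele
#' from each parental population.  Null alleles (hidden allele: visible/
#' null heterozygotes are recorded as visible homozygotes, null/null as
#' missing), per-allele miscalls to a neighbouring fragment size, and
#' per-genotype missingness are applied after drawing.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (parental frequencies, realized Fct, per-individual true ancestry
#'   fraction and source, per-site composition).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fr <- draw_divergent_frequencies(config$n_loci,
                                     config$alleles_per_locus,
                                     config$target_fct)
    plan <- config$site_plan
    ntot <- sum(plan$n)
    L <- config$n_loci
    a1 <- a2 <- matrix(NA_integer_, ntot, L)
    locus_names <- names(fr$north)
    colnames(a1) <- colnames(a2) <- locus_names
    ancestry <- numeric(ntot)
    source_pop <- character(ntot)
    site_of <- character(ntot)
    row <- 0L
    for (s in seq_len(nrow(plan))) {
      n <- plan$n[s]
      idx <- row + seq_len(n)
      row <- row + n
      site_of[idx] <- plan$id[s]
      comp <- plan$composition[s]
      r <- plan$r[s]
      src <- switch(comp,
        pure_north = rep("N", n),
        pure_south = rep("S", n),
        mechanical_mix = ifelse(stats::runif(n) < r, "N", "S"),
        hybrid_swarm = rep("H", n),
        f1_only = rep("F1", n))
      source_pop[idx] <- src
      ancestry[idx] <- switch(comp,
        pure_north = 1, pure_south = 0,
        mechanical_mix = as.numeric(src == "N"),
        hybrid_swarm = r, f1_only = 0.5)
      for (l in seq_len(L)) {
        pn <- fr$north[[l]]; ps <- fr$south[[l]]
        labels <- as.integer(names(pn))
        draw <- function(p, m) {
          if (m == 0) integer(0)
          else sample(labels, m, replace = TRUE, prob = p)
        }
        if (comp %in% c("pure_north", "pure_south", "mechanical_mix")) {
          isN <- src == "N"
          x1 <- x2 <- integer(n)
          x1[isN] <- draw(pn, sum(isN)); x2[isN] <- draw(pn, sum(isN))
          x1[!isN] <- draw(ps, sum(!isN)); x2[!isN] <- draw(ps, sum(!isN))
        } else if (comp == "hybrid_swarm") {
          pool <- r * pn + (1 - r) * ps
          x1 <- draw(pool, n); x2 <- draw(pool, n)
        } else {  # f1_only
          x1 <- draw(pn, n); x2 <- draw(ps, n)
        }
        a1[idx, l] <- x1
        a2[idx, l] <- x2
      }
    }

    ## null alleles: each drawn allele is independently null with the
    ## per-locus null frequency; one null -> apparent homozygote, two
    ## nulls -> missing genotype
    if (config$null_allele_rate > 0) {
      for (l in seq_len(L)) {
        n1 <- stats::runif(ntot) < config$null_allele_rate
        n2 <- stats::runif(ntot) < config$null_allele_rate
        both <- n1 & n2
        a1[both, l] <- NA_integer_; a2[both, l] <- NA_integer_
        only1 <- n1 & !n2
        a1[only1, l] <- a2[only1, l]
        only2 <- n2 & !n1
        a2[only2, l] <- a1[only2, l]
      }
    }
    ## genotyping error: replace an allele with a neighbouring label
    if (config$genotyping_error_rate > 0) {
      for (l in seq_len(L)) {
        labels <- as.integer(names(fr$north[[l]]))
        k <- length(labels)
        bump <- function(x) {
          hit <- !is.na(x) & stats::runif(ntot) < config$genotyping_error_rate
          if (!any(hit)) return(x)
          pos <- match(x[hit], labels)
          up <- ifelse(pos == k, -1L,
                       ifelse(pos == 1L, 1L,
                              ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)))
          x[hit] <- labels[pos + up]
          x
        }
        a1[, l] <- bump(a1[, l])
        a2[, l] <- bump(a2[, l])
      }
    }
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(ntot * L) < config$missing_rate, ntot, L)
      a1[drop] <- NA_integer_
      a2[drop] <- NA_integer_
    }
    ## canonical order within genotype
    swap <- !is.na(a1) & a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp

    sites <- data.frame(id = plan$id, name = plan$id,
                        latitude = plan$latitude, longitude = -97.0,
                        region_label = "unassigned",
                        stringsAsFactors = FALSE)
    loci <- lapply(fr$north, function(p) as.integer(names(p)))
    ds <- genotype_dataset(a1, a2,
                           ind_id = sprintf("ind%04d", seq_len(ntot)),
                           site_id = site_of, sites = sites, loci = loci)
    list(dataset = ds,
         truth = list(north_freqs = fr$north, south_freqs = fr$south,
                      realized_fct = fr$realized_fct,
                      ancestry = ancestry, source = source_pop,
                      site_plan = plan))
  })
}
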