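## Hierarchical analysis of molecular variance on allele-identity
## distances (FST-analogue), with permutation tests, plus the
## Q-threshold site classification and the iterative admixed-sample
## removal procedure.

## wide per-individual allele-count matrix: one column per (locus,
## allele), entries 0/1/2; plus scored-copy matrix (individuals x loci)
amova_matrices <- function(dataset) {
  n <- nrow(dataset$ind)
  blocks <- lapply(seq_along(dataset$loci), function(l) {
    labels <- dataset$loci[[l]]
    m <- matrix(0, n, length(labels))
    i1 <- match(dataset$allele1[, l], labels)
    i2 <- match(dataset$allele2[, l], labels)
    ok <- !is.na(i1)
    idx <- which(ok)
    m[cbind(idx, i1[ok])] <- m[cbind(idx, i1[ok])] + 1
    m[cbind(idx, i2[ok])] <- m[cbind(idx, i2[ok])] + 1
    m
  })
  W <- do.call(cbind, blocks)
  col_locus <- rep(seq_along(dataset$loci),
                   vapply(dataset$loci, length, integer(1)))
  S <- vapply(seq_along(dataset$loci), function(l)
    2 * as.numeric(!is.na(dataset$allele1[, l])), numeric(n))
  S <- matrix(S, n, length(dataset$loci))
  list(W = W, S = S, col_locus = col_locus)
}

## per-group, per-locus sums of squared deviations on 0/1 allele-identity
## distance: SSD = (N - sum(c^2)/N) / 2 per locus, vectorized over loci
ssd_by_locus <- function(counts, copies, col_locus) {
  sq <- t(rowsum(t(counts^2), col_locus))
  ifelse(copies > 0, (copies - sq / pmax(copies, 1)) / 2, 0)
}

## variance components given site-level count/copy matrices and a
## site -> region assignment; everything is vectorized across loci so
## the permutation loops stay cheap
amova_components <- function(site_counts, site_copies, col_locus,
                             region_of_site) {
  G <- length(unique(region_of_site))
  P <- nrow(site_counts)
  grp <- factor(region_of_site)
  grp_counts <- rowsum(site_counts, grp)
  grp_copies <- rowsum(site_copies, grp)
  tot_counts <- matrix(colSums(site_counts), 1)
  tot_copies <- matrix(colSums(site_copies), 1)

  ssd_wp <- colSums(ssd_by_locus(site_counts, site_copies, col_locus))
  ssd_wg <- colSums(ssd_by_locus(grp_counts, grp_copies, col_locus))
  ssd_tot <- colSums(ssd_by_locus(tot_counts, tot_copies, col_locus))
  ssd_ap <- ssd_wg - ssd_wp
  ssd_ag <- ssd_tot - ssd_wg

  N <- colSums(site_copies)                       # copies per locus
  np2g <- rowsum(site_copies^2, grp)              # G x L
  sum_np2_by_g <- colSums(np2g / pmax(grp_copies, 1))
  n2 <- (sum_np2_by_g - colSums(site_copies^2) / pmax(N, 1)) / (G - 1)
  n3 <- (N - colSums(grp_copies^2) / pmax(N, 1)) / (G - 1)
  use <- N > 0
  msd_wp <- ssd_wp / pmax(N - P, 1)
  msd_ag <- ssd_ag / (G - 1)
  sigc <- msd_wp
  if (P > G) {
    ## among-site component needs at least one region with > 1 site
    n1 <- (N - sum_np2_by_g) / (P - G)
    sigb <- (ssd_ap / (P - G) - sigc) / n1
  } else {
    n2 <- rep(0, length(N))
    sigb <- rep(0, length(N))
  }
  siga <- (msd_ag - sigc - n2 * sigb) / n3
  list(sigma = c(among_regions = sum(siga[use]),
                 among_sites = sum(sigb[use]),
                 within_sites = sum(sigc[use])),
       ssd = c(among_regions = sum(ssd_ag), among_sites = sum(ssd_ap),
               within_sites = sum(ssd_wp), total = sum(ssd_tot)))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Two-level analysis of molecular variance on allele-identity distances
#' (0/1 per locus, summed over loci): variance is partitioned among
#' regions, among sites within regions, and within sites, giving
#' `Fct = a / (a + b + c)` and `Fsc = b / (b + c)`.  Significance of Fct
#' is assessed by permuting whole sites among regions, and of Fsc by
#' permuting individuals among sites within regions; p-values include
#' the observed configuration (`(b + 1) / (B + 1)`).  With two regions
#' and few sites the Fct null is enumerated completely (all distinct
#' site-to-region assignments) for an exact p whenever that is no more
#' work than `n_permutations` draws.
#'
#' Individuals with no scored genotype at any locus are excluded with a
#' message.
#'
#' @param dataset a [genotype_dataset()].
#' @param regions named character vector mapping site id to region label;
#'   at least two regions, each with at least one site.
#' @param n_permutations permutations for both tests.
#' @param seed integer seed.
#' @param perm_test which permutation tests to run (`"both"`, `"fct"`,
#'   `"fsc"`); skipped tests report `p = NA`.
#' @return object of class `amova_result`: variance components, `Fct`,
#'   `Fsc`, `p_fct`, `p_fsc`, `ssd`, `n_permutations`.
#' @export
amova <- function(dataset, regions, n_permutations = 1000, seed = NULL,
                  perm_test = c("both", "fct", "fsc")) {
  perm_test <- match.arg(perm_test)
  regions <- regions[dataset$sites$id]
  if (anyNA(regions)) stop("every site needs a region assignment")
  if (length(unique(regions)) < 2) stop("need >= 2 regions")
  all_missing <- rowSums(!is.na(dataset$allele1)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " individual(s) with no scored genotypes excluded")
    keep_ids <- dataset$ind$id[!all_missing]
    keep <- !all_missing
    dataset <- genotype_dataset(dataset$allele1[keep, , drop = FALSE],
                                dataset$allele2[keep, , drop = FALSE],
                                keep_ids, dataset$ind$site[keep],
                                dataset$sites, loci = dataset$loci)
  }
  mats <- amova_matrices(dataset)
  site_f <- factor(dataset$ind$site, levels = dataset$sites$id)
  site_counts <- rowsum(mats$W, site_f)
  site_copies <- rowsum(mats$S, site_f)
  region_of_site <- regions[dataset$sites$id]

  obs <- amova_components(site_counts, site_copies, mats$col_locus,
                          region_of_site)
  s <- obs$sigma
  fct <- s[1] / sum(s)
  fsc_defined <- nrow(dataset$sites) > length(unique(region_of_site))
  fsc <- if (fsc_defined) s[2] / (s[2] + s[3]) else NA_real_
  ## degenerate when there is no within-region variation at all
  if (fsc_defined && !is.finite(fsc)) {
    fsc <- NA_real_
    fsc_defined <- FALSE
  }

  with_seed(seed, {
    p_fct <- NA_real_
    if (perm_test %in% c("both", "fct")) {
      ## with two regions and few sites the assignment null is small:
      ## enumerate it completely for an exact p instead of resampling
      P <- nrow(dataset$sites)
      sizes <- table(region_of_site)
      n_distinct <- if (length(sizes) == 2) choose(P, sizes[1]) else Inf
      if (is.finite(n_distinct) && n_distinct <= n_permutations) {
        labs <- names(sizes)
        combos <- utils::combn(P, sizes[1])
        hits_fct <- 0L
        for (b in seq_len(ncol(combos))) {
          perm_regions <- rep(labs[2], P)
          perm_regions[combos[, b]] <- labs[1]
          ps <- amova_components(site_counts, site_copies,
                                 mats$col_locus, perm_regions)$sigma
          if (ps[1] / sum(ps) >= fct - 1e-12) hits_fct <- hits_fct + 1L
        }
        p_fct <- hits_fct / ncol(combos)
      } else {
        hits_fct <- 0L
        for (b in seq_len(n_permutations)) {
          perm_regions <- sample(region_of_site)
          ps <- amova_components(site_counts, site_copies,
                                 mats$col_locus, perm_regions)$sigma
          if (ps[1] / sum(ps) >= fct - 1e-12) hits_fct <- hits_fct + 1L
        }
        p_fct <- (hits_fct + 1) / (n_permutations + 1)
      }
    }

    p_fsc <- NA_real_
    if (perm_test %in% c("both", "fsc") && fsc_defined) {
      ## Fsc: permute individuals among sites within each region
      site_int <- match(dataset$ind$site, dataset$sites$id)
      region_of_ind <- region_of_site[site_int]
      rows_by_region <- split(seq_along(site_int),
                              region_of_ind)
      ## pad with one dummy row per site so rowsum always returns all
      ## sites in fixed order
      pad <- seq_len(nrow(dataset$sites))
      Wp <- rbind(mats$W, matrix(0, length(pad), ncol(mats$W)))
      Sp <- rbind(mats$S, matrix(0, length(pad), ncol(mats$S)))
      hits_fsc <- 0L
      for (b in seq_len(n_permutations)) {
        perm_site <- site_int
        for (rows in rows_by_region)
          perm_site[rows] <- perm_site[rows][sample.int(length(rows))]
        g <- c(perm_site, pad)
        pc <- rowsum(Wp, g)
        pp <- rowsum(Sp, g)
        ps <- amova_components(pc, pp, mats$col_locus,
                               region_of_site)$sigma
        val <- ps[2] / (ps[2] + ps[3])
        if (is.finite(val) && val >= fsc - 1e-12)
          hits_fsc <- hits_fsc + 1L
      }
      p_fsc <- (hits_fsc + 1) / (n_permutations + 1)
    }

    structure(list(sigma = s, ssd = obs$ssd,
                   Fct = unname(fct), Fsc = unname(fsc),
                   p_fct = p_fct, p_fsc = p_fsc,
                   n_permutations = n_permutations,
                   regions = region_of_site),
              class = "amova_result")
  })
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (allele-identity distances)\n")
  tab <- data.frame(component = names(x$sigma),
                    sigma = round(unname(x$sigma), 5),
                    pct = round(100 * unname(x$sigma) / sum(x$sigma), 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Fct = %.4f (p = %.4g), Fsc = %.4f (p = %.4g), %d permutations\n",
              x$Fct, x$p_fct, x$Fsc, x$p_fsc, x$n_permutations))
  invisible(x)
}

#' Classify a site from its mean admixture proportions
#'
#' A site is `mixed` when its largest mean Q is below `mixed_threshold`
#' (default 0.70), `northern`/`southern` when the corresponding entry
#' exceeds `pure_threshold` (default 0.80), and otherwise receives the
#' provisional label of its majority cluster with `provisional = TRUE`.
#'
#' @param mean_q length-2 vector summing to 1 (northern, southern).
#' @param mixed_threshold,pure_threshold classification thresholds with
#'   `0.5 <= mixed_threshold <= pure_threshold`.
#' @return list with `category` and `provisional`.
#' @export
classify_site <- function(mean_q, mixed_threshold = 0.70,
                          pure_threshold = 0.80) {
  if (mixed_threshold < 0.5 || mixed_threshold > pure_threshold ||
      pure_threshold > 1)
    stop("need 0.5 <= mixed_threshold <= pure_threshold <= 1")
  stopifnot(abs(sum(mean_q) - 1) < 1e-6)
  top <- which.max(mean_q)
  label <- c("northern", "southern")[top]
  if (mean_q[top] < mixed_threshold)
    list(category = "mixed", provisional = FALSE)
  else if (mean_q[top] > pure_threshold)
    list(category = label, provisional = FALSE)
  else
    list(category = label, provisional = TRUE)
}

#' Iterative removal of admixed samples from the AMOVA model
#'
#' Starting from a region assignment given by each site's majority mean-Q
#' cluster, the AMOVA is run and, while the among-site component Fsc is
#' significant, the most heavily admixed remaining site (smallest
#' `max(mean Q)`, among sites below `mixed_threshold`; ties broken by
#' site id) is removed and marked `mixed`.  The loop stops when Fsc is no
#' longer significant at `alpha` or no removable site remains.
#'
#' @param dataset a [genotype_dataset()].
#' @param qmatrix a `qmatrix` for the same individuals.
#' @param alpha significance threshold on the Fsc permutation p-value.
#' @param n_permutations permutations per AMOVA.
#' @param mixed_threshold sites with `max(mean Q)` below this are
#'   candidates for removal.
#' @param pure_threshold forwarded to [classify_site()] for the final
#'   labels.
#' @param seed integer seed.
#' @return object of class `zone_partition`: per-site `category`,
#'   `removal_order`, `final_amova`, and the AMOVA trace.
#' @export
iterative_admixed_removal <- function(dataset, qmatrix, alpha = 0.05,
                                      n_permutations = 1000,
                                      mixed_threshold = 0.70,
                                      pure_threshold = 0.80,
                                      seed = NULL) {
  sites <- dataset$sites$id
  mean_q <- t(vapply(sites, function(s) sample_mean_q(qmatrix, s),
                     numeric(2)))
  majority <- ifelse(mean_q[, 1] >= 0.5, "northern", "southern")
  names(majority) <- sites
  max_q <- apply(mean_q, 1, max)
  names(max_q) <- sites

  removed <- character(0)
  trace <- list()
  current <- sites
  step <- 0L
  with_seed(seed, {
    repeat {
      step <- step + 1L
      sub <- subset_sites(dataset, current)
      res <- amova(sub, majority[current],
                   n_permutations = n_permutations, perm_test = "fsc")
      trace[[step]] <- res
      if (is.na(res$p_fsc) || res$p_fsc >= alpha) break
      cand <- current[max_q[current] < mixed_threshold]
      if (!length(cand)) break
      cand <- cand[order(max_q[cand], cand)]
      drop <- cand[1]
      remaining <- setdiff(current, drop)
      if (!all(c("northern", "southern") %in%
               unique(majority[remaining])))
        stop("removal would empty a region; trace has ",
             length(removed), " removals: ",
             paste(removed, collapse = ", "))
      removed <- c(removed, drop)
      current <- remaining
    }
    category <- vapply(sites, function(s) {
      if (s %in% removed) "mixed"
      else classify_site(mean_q[s, ], mixed_threshold,
                         pure_threshold)$category
    }, character(1))
    final <- amova(subset_sites(dataset, current), majority[current],
                   n_permutations = n_permutations)
    structure(list(category = category, removal_order = removed,
                   final_amova = final,
                   trace = trace, mean_q = mean_q),
              class = "zone_partition")
  })
}

#' @export
print.zone_partition <- function(x, ...) {
  cat("zone_partition:", sum(x$category == "northern"), "northern,",
      sum(x$category == "southern"), "southern,",
      sum(x$category == "mixed"), "mixed site(s)\n")
  if (length(x$removal_order))
    cat("removal order:", paste(x$removal_order, collapse = " -> "), "\n")
  cat(sprintf("final Fct = %.4f (p = %.4g), Fsc = %.4f (p = %.4g)\n",
              x$final_amova$Fct, x$final_amova$p_fct,
              x$final_amova$Fsc, x$final_amova$p_fsc))
  invisible(x)
}
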