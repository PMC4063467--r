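#' Construct a codominant multilocus genotype dataset
#'
#' The universal input object of the package: diploid codominant genotypes
#' (individuals x loci) together with the partition of individuals into
#' sample sites and per-site metadata (coordinates, environmental
#' covariates).  Allele identifiers are integer fragment sizes in base
#' pairs, as scored on a sequencer.
#'
#' Genotypes are unordered: microsatellite alleles have no phase, so the
#' two allele columns are stored sorted ascending.  Missingness is
#' per-genotype: a genotype with only one allele scored is promoted to
#' fully missing with a warning.
#'
#' @param allele1,allele2 integer matrices (individuals x loci) of allele
#'   labels; `NA` marks a missing allele.  Column names are locus names.
#' @param ind_id character vector of individual identifiers.
#' @param site_id character vector mapping each individual to a site id.
#' @param sites data frame with columns `id`, `name`, `latitude`,
#'   `longitude`, optionally `region_label` (one of `"unassigned"`,
#'   `"northern"`, `"southern"`, `"mixed"`) and any number of numeric
#'   environmental covariate columns (temperature, salinity, ...).
#' @param loci optional named list giving, per locus, the full sorted
#'   vector of allele labels; defaults to the labels observed in the data.
#'
#' @return An object of class `genotype_dataset` with components
#'   `allele1`, `allele2`, `ind` (data frame `id`, `site`), `sites`, and
#'   `loci` (named list of sorted integer allele labels).
#' @export
genotype_dataset <- function(allele1, allele2, ind_id, site_id, sites,
                             loci = NULL) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  stopifnot(identical(dim(allele1), dim(allele2)))
  n <- nrow(allele1)
  L <- ncol(allele1)
  if (is.null(colnames(allele1))) {
    colnames(allele1) <- colnames(allele2) <- sprintf("L%02d", seq_len(L))
  }
  colnames(allele2) <- colnames(allele1)
  ind_id <- as.character(ind_id)
  site_id <- as.character(site_id)
  stopifnot(length(ind_id) == n, length(site_id) == n)

  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("id", "name", "latitude", "longitude")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols))
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  sites$id <- as.character(sites$id)
  if (anyDuplicated(sites$id))
    stop("duplicate site id(s): ",
         paste(unique(sites$id[duplicated(sites$id)]), collapse = ", "))
  if (any(!is.finite(sites$latitude)) ||
      any(sites$latitude < -90 | sites$latitude > 90))
    stop("site latitude out of [-90, 90]")
  if (any(!is.finite(sites$longitude)) ||
      any(sites$longitude < -180 | sites$longitude > 180))
    stop("site longitude out of [-180, 180]")
  if (is.null(sites$region_label)) sites$region_label <- "unassigned"
  bad_region <- setdiff(unique(sites$region_label),
                        c("unassigned", "northern", "southern", "mixed"))
  if (length(bad_region))
    stop("unknown region label(s): ", paste(bad_region, collapse = ", "))
  unknown_site <- setdiff(site_id, sites$id)
  if (length(unknown_site))
    stop("individual(s) reference unknown site(s): ",
         paste(unique(unknown_site), collapse = ", "))

  ## half-missing genotypes -> fully missing
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) promoted to missing")
    allele1[half] <- NA_integer_
    allele2[half] <- NA_integer_
  }
  ## canonical order within genotype
  swap <- !is.na(allele1) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }

  if (is.null(loci)) {
    loci <- lapply(seq_len(L), function(l)
      sort(unique(c(allele1[, l], allele2[, l]))))
    names(loci) <- colnames(allele1)
  } else {
    if (!identical(sort(names(loci)), sort(colnames(allele1))))
      stop("names of 'loci' do not match genotype matrix columns")
    loci <- loci[colnames(allele1)]
    loci <- lapply(loci, function(a) sort(unique(as.integer(a))))
    for (l in seq_len(L)) {
      seen <- c(allele1[, l], allele2[, l])
      bad <- setdiff(seen[!is.na(seen)], loci[[l]])
      if (length(bad))
        stop("allele(s) not in declared set for locus ",
             colnames(allele1)[l], ": ", paste(bad, collapse = ", "))
    }
  }

  structure(
    list(allele1 = allele1, allele2 = allele2,
         ind = data.frame(id = ind_id, site = site_id,
                          stringsAsFactors = FALSE),
         sites = sites, loci = loci),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$ind), "individuals,",
      length(x$loci), "loci,", nrow(x$sites), "sites\n")
  na <- vapply(x$loci, length, integer(1))
  cat("  alleles per locus:", paste(na, collapse = " "), "\n")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  tab <- table(object$ind$site)
  cat("genotype_dataset with", nrow(object$ind), "individuals at",
      nrow(object$sites), "sites\n")
  print(data.frame(site = names(tab), n = as.integer(tab),
                   row.names = NULL))
  invisible(object)
}

#' Number of individuals / loci in a dataset
#' @param dataset a `genotype_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(dataset) nrow(dataset$ind)

#' @rdname n_individuals
#' @export
n_loci <- function(dataset) length(dataset$loci)

#' Restrict a dataset to a subset of sites or loci
#'
#' @param dataset a `genotype_dataset`.
#' @param site_ids site ids to keep (for `subset_sites`).
#' @param locus_names locus names to keep (for `subset_loci`).
#' @return a new `genotype_dataset`.
#' @export
subset_sites <- function(dataset, site_ids) {
  site_ids <- as.character(site_ids)
  stopifnot(all(site_ids %in% dataset$sites$id))
  keep <- dataset$ind$site %in% site_ids
  genotype_dataset(dataset$allele1[keep, , drop = FALSE],
                   dataset$allele2[keep, , drop = FALSE],
                   dataset$ind$id[keep], dataset$ind$site[keep],
                   dataset$sites[dataset$sites$id %in% site_ids, ,
                                 drop = FALSE],
                   loci = dataset$loci)
}

#' @rdname subset_sites
#' @export
subset_loci <- function(dataset, locus_names) {
  stopifnot(all(locus_names %in% names(dataset$loci)))
  genotype_dataset(dataset$allele1[, locus_names, drop = FALSE],
                   dataset$allele2[, locus_names, drop = FALSE],
                   dataset$ind$id, dataset$ind$site, dataset$sites,
                   loci = dataset$loci[locus_names])
}

#' Combine two datasets sharing the same loci
#'
#' Used to pool observed and simulated individuals before joint scoring.
#' Site tables are merged on site id; individual ids must not collide.
#'
#' @param x,y `genotype_dataset` objects with identical locus sets.
#' @return a `genotype_dataset`.
#' @export
bind_datasets <- function(x, y) {
  stopifnot(identical(names(x$loci), names(y$loci)))
  loci <- mapply(function(a, b) sort(unique(c(a, b))),
                 x$loci, y$loci, SIMPLIFY = FALSE)
  common <- intersect(x$sites$id, y$sites$id)
  ysites <- y$sites[!y$sites$id %in% common, , drop = FALSE]
  cols <- union(names(x$sites), names(ysites))
  pad <- function(df) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[cols]
  }
  sites <- rbind(pad(x$sites), pad(ysites))
  genotype_dataset(rbind(x$allele1, y$allele1),
                   rbind(x$allele2, y$allele2),
                   c(x$ind$id, y$ind$id), c(x$ind$site, y$ind$site),
                   sites, loci = loci)
}

#' Per-group allele frequencies
#'
#' Computes, for every locus, the allele frequency vector in each group of
#' individuals (by default, each sample site).  Frequencies are relative
#' to scored gene copies (2 x non-missing genotypes).
#'
#' @param dataset a `genotype_dataset`.
#' @param groups optional character vector (one entry per individual)
#'   defining the grouping; defaults to site membership.  Use a constant
#'   vector to pool everything.
#' @return a named list, one element per locus: a numeric matrix
#'   (groups x alleles) of frequencies, with attribute `"n_copies"` giving
#'   the scored gene-copy count per group.  Rows of groups with no scored
#'   genotypes are `NaN`.
#' @export
allele_freqs <- function(dataset, groups = NULL) {
  if (is.null(groups)) groups <- dataset$ind$site
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(dataset$ind))
  glev <- unique(groups)
  out <- vector("list", length(dataset$loci))
  names(out) <- names(dataset$loci)
  for (l in seq_along(dataset$loci)) {
    labels <- dataset$loci[[l]]
    a <- c(dataset$allele1[, l], dataset$allele2[, l])
    g <- factor(rep(groups, 2), levels = glev)
    ok <- !is.na(a)
    counts <- table(g[ok], factor(a[ok], levels = labels))
    counts <- matrix(as.numeric(counts), nrow = length(glev),
                     dimnames = list(glev, as.character(labels)))
    ncop <- rowSums(counts)
    freq <- counts / ifelse(ncop > 0, ncop, NA)
    attr(freq, "n_copies") <- ncop
    out[[l]] <- freq
  }
  out
}

#' Pooled allele frequencies over a set of sites
#'
#' Convenience wrapper for [allele_freqs()] pooling all individuals from
#' the given sites into one group.
#'
#' @param dataset a `genotype_dataset`.
#' @param site_ids sites to pool; default all.
#' @return named list, one numeric frequency vector per locus.
#' @export
pooled_freqs <- function(dataset, site_ids = NULL) {
  if (!is.null(site_ids)) dataset <- subset_sites(dataset, site_ids)
  f <- allele_freqs(dataset, groups = rep("all", nrow(dataset$ind)))
  lapply(f, function(m) m["all", ])
}
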