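## End-to-end orchestration: from a genotype file plus site metadata to
## the full set of contact-zone reports (QC, admixture, zone partition,
## HWE/LD tables, bimodality, clines, FST outliers, spatfall), with a
## manifest that makes the run reproducible byte for byte.

#' Seasonal spatfall frequencies
#'
#' Per area, the frequency of each season is its spat presence count
#' divided by the area's total spat presence; areas with no spat at all
#' get frequency 0 everywhere and are flagged.
#'
#' @param spat a spat table from [read_spat_table()] (columns `area`,
#'   `season`, `count`).
#' @return data frame `area`, `season`, `count`, `frequency`, with
#'   attribute `"empty_areas"`.
#' @export
spatfall_frequencies <- function(spat) {
  stopifnot(all(c("area", "season", "count") %in% names(spat)))
  out <- do.call(rbind, lapply(split(spat, spat$area), function(d) {
    tot <- sum(d$count)
    d$frequency <- if (tot > 0) d$count / tot else 0
    d
  }))
  rownames(out) <- NULL
  empties <- unique(spat$area)[tapply(spat$count, spat$area, sum)[
    unique(spat$area)] == 0]
  attr(out, "empty_areas") <- as.character(empties)
  out
}

#' Pipeline configuration
#'
#' Collects the input paths, thresholds, run sizes and the master seed
#' for [run_pipeline()].  Defaults are desk-scale (minutes, not hours);
#' every stochastic stage derives its own sub-seed from `seed`.
#'
#' @param genepop path to the Genepop genotype file, or a
#'   [genotype_dataset()] directly.
#' @param site_metadata optional CSV path (or data frame) of site
#'   coordinates/covariates, merged by site id.
#' @param spat_table optional spat-count CSV path or data frame.
#' @param second_epoch optional earlier/later-epoch dataset (path or
#'   `genotype_dataset`) for the cline-shift comparison.
#' @param mixed_threshold,pure_threshold Q-classification thresholds.
#' @param alpha significance level for the iterative removal and test
#'   tables.
#' @param n_permutations AMOVA permutations.
#' @param hwe_mc Monte-Carlo iterations per HWE test.
#' @param ld_permutations permutations per LD test.
#' @param n_sim_loci simulated loci for the FST-outlier envelope.
#' @param bimodality_n_sim simulated individuals per bimodality model.
#' @param cline_permutations Mantel permutations.
#' @param admixture_mode `"em"` or `"gibbs"`.
#' @param drop_failed_loci drop loci failing the null-allele screen.
#' @param seed master seed (required: no silent nondeterminism).
#' @param outdir output directory for the report bundle.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(genepop, site_metadata = NULL,
                            spat_table = NULL, second_epoch = NULL,
                            mixed_threshold = 0.70,
                            pure_threshold = 0.80, alpha = 0.05,
                            n_permutations = 1000, hwe_mc = 2000,
                            ld_permutations = 100, n_sim_loci = 2000,
                            bimodality_n_sim = 1000,
                            cline_permutations = 999,
                            admixture_mode = "em",
                            drop_failed_loci = TRUE,
                            seed, outdir = tempfile("contactzone_run_")) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(mixed_threshold > 0.5, mixed_threshold <= pure_threshold,
            pure_threshold <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(config, k) (config$seed + 7919L * k) %% 2147483640L

write_stage <- function(df, outdir, name) {
  path <- file.path(outdir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full contact-zone pipeline
#'
#' Ordered stages: (1) load and QC (locus statistics; loci failing the
#' null-allele screen dropped), (2) unsupervised two-cluster admixture,
#' (3) Q-threshold site classification and iterative admixed-sample
#' removal via AMOVA, (4) supervised admixture against the unmixed
#' flanking sites, (5) HWE and LD test tables per group with sequential
#' Bonferroni, (6) hybrid-zone bimodality test, (7) cline identification,
#' twice-broken-stick fits and Co-Co outliers, (8) FST-outlier scan,
#' (9) optional cline shift against a second-epoch dataset, (10)
#' optional spatfall frequencies.  Stages 4 and 6 are skipped with an
#' explicit notice when the partition finds no mixed site.  Every stage
#' writes a CSV into `config$outdir`, and a JSON manifest records the
#' config hash, seed and package version.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_report` with each stage's result
#'   and the paths of the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  notices <- character(0)

  dataset <- if (inherits(config$genepop, "genotype_dataset"))
    config$genepop else read_genepop(config$genepop)
  if (!is.null(config$site_metadata)) {
    meta <- if (is.data.frame(config$site_metadata)) config$site_metadata
            else read_site_metadata(config$site_metadata)
    keep <- intersect(names(meta), setdiff(names(meta), "id"))
    m <- match(dataset$sites$id, meta$id)
    if (anyNA(m)) stop("site metadata missing for site(s): ",
                       paste(dataset$sites$id[is.na(m)], collapse = ", "))
    dataset$sites <- cbind(dataset$sites["id"],
                           meta[m, keep, drop = FALSE])
    rownames(dataset$sites) <- NULL
  }

  ## (1) QC
  qc <- locus_stats_table(dataset)
  files["locus_stats"] <- write_stage(qc, config$outdir, "locus_stats")
  if (config$drop_failed_loci && any(!qc$null_pass)) {
    dropped <- qc$locus[!qc$null_pass]
    notices <- c(notices, paste("loci dropped by null-allele screen:",
                                paste(dropped, collapse = ", ")))
    dataset <- subset_loci(dataset, qc$locus[qc$null_pass])
  }

  ## (2) unsupervised admixture
  qm <- fit_admixture(dataset, mode = config$admixture_mode,
                      seed = stage_seed(config, 2L))
  qdf <- data.frame(individual = dataset$ind$id, site = dataset$ind$site,
                    Q1 = qm$Q[, 1], Q2 = qm$Q[, 2])
  files["qmatrix"] <- write_stage(qdf, config$outdir, "qmatrix")

  ## (3) classification + iterative removal
  zone <- iterative_admixed_removal(
    dataset, qm, alpha = config$alpha,
    n_permutations = config$n_permutations,
    mixed_threshold = config$mixed_threshold,
    pure_threshold = config$pure_threshold,
    seed = stage_seed(config, 3L))
  zdf <- data.frame(site = dataset$sites$id,
                    category = zone$category[dataset$sites$id],
                    mean_Q1 = zone$mean_q[dataset$sites$id, 1],
                    removal_step = match(dataset$sites$id,
                                         zone$removal_order))
  files["zone_partition"] <- write_stage(zdf, config$outdir,
                                         "zone_partition")
  amova_df <- data.frame(component = names(zone$final_amova$sigma),
                         sigma = unname(zone$final_amova$sigma),
                         Fct = zone$final_amova$Fct,
                         Fsc = zone$final_amova$Fsc,
                         p_Fct = zone$final_amova$p_fct,
                         p_Fsc = zone$final_amova$p_fsc)
  files["amova"] <- write_stage(amova_df, config$outdir, "amova")

  north_sites <- names(zone$category)[zone$category == "northern"]
  south_sites <- names(zone$category)[zone$category == "southern"]
  mixed_sites <- names(zone$category)[zone$category == "mixed"]

  ## (4) supervised admixture
  supervised <- NULL
  if (length(mixed_sites)) {
    supervised <- fit_supervised(dataset,
                                 list(northern = north_sites,
                                      southern = south_sites))
    sdf <- data.frame(individual = dataset$ind$id,
                      site = dataset$ind$site,
                      Q1 = supervised$Q[, 1], Q2 = supervised$Q[, 2])
    files["qmatrix_supervised"] <- write_stage(sdf, config$outdir,
                                               "qmatrix_supervised")
  } else {
    notices <- c(notices,
                 "no mixed sites: supervised admixture stage skipped")
  }

  ## (5) HWE / LD tables per group
  groups <- list(northern = north_sites, southern = south_sites)
  if (length(mixed_sites)) groups$mixed <- mixed_sites
  hwe_rows <- list(); ld_rows <- list()
  k <- 0L
  for (g in names(groups)) {
    k <- k + 1L
    for (loc in names(dataset$loci)) {
      p <- hwe_exact_test(dataset, loc, groups[[g]],
                          n_mc = config$hwe_mc,
                          seed = stage_seed(config, 50L + k))
      hwe_rows[[length(hwe_rows) + 1L]] <-
        data.frame(group = g, locus = loc, p = p)
    }
    locs <- names(dataset$loci)
    if (length(locs) >= 2) {
      prs <- utils::combn(locs, 2)
      for (j in seq_len(ncol(prs))) {
        lt <- ld_lr_test(dataset, prs[1, j], prs[2, j], groups[[g]],
                         n_permutations = config$ld_permutations,
                         seed = stage_seed(config, 100L + 10L * k + j))
        ld_rows[[length(ld_rows) + 1L]] <-
          data.frame(group = g, locusA = prs[1, j], locusB = prs[2, j],
                     lr = lt$lr, p = lt$p)
      }
    }
  }
  hwe_tab <- do.call(rbind, hwe_rows)
  hwe_tab$significant <- unlist(lapply(split(hwe_tab, hwe_tab$group),
    function(d) sequential_bonferroni(d$p, config$alpha)))[
      order(order(hwe_tab$group))]
  ld_tab <- do.call(rbind, ld_rows)
  ld_tab$significant <- unlist(lapply(split(ld_tab, ld_tab$group),
    function(d) sequential_bonferroni(d$p, config$alpha)))[
      order(order(ld_tab$group))]
  files["hwe_tests"] <- write_stage(hwe_tab, config$outdir, "hwe_tests")
  files["ld_tests"] <- write_stage(ld_tab, config$outdir, "ld_tests")

  ## (6) bimodality
  bimod <- NULL; kw <- NULL
  if (length(mixed_sites) >= 2) {
    kw <- kruskal_wallis_q(supervised, mixed_sites)
    bimod <- bimodality_test(dataset, supervised, mixed_sites,
                             list(northern = north_sites,
                                  southern = south_sites),
                             n_sim = config$bimodality_n_sim,
                             seed = stage_seed(config, 6L))
    bdf <- data.frame(
      model = c("mechanical_mix", "hybrid_swarm"),
      ks_statistic = c(bimod$ks_mechanical$statistic,
                       bimod$ks_hybrid_swarm$statistic),
      p = c(bimod$ks_mechanical$p, bimod$ks_hybrid_swarm$p),
      kruskal_wallis_chisq = kw$statistic, kruskal_wallis_p = kw$p)
    files["bimodality"] <- write_stage(bdf, config$outdir, "bimodality")
  } else {
    notices <- c(notices,
                 "fewer than 2 mixed sites: bimodality stage skipped")
  }

  ## (7) clines + Co-Co
  clines <- NULL; coco <- NULL
  if (nrow(dataset$sites) >= 6 &&
      diff(range(dataset$sites$latitude)) >= 0.5) {
    clines <- cline_analysis(dataset,
                             n_permutations = config$cline_permutations,
                             seed = stage_seed(config, 7L))
    files["clines"] <- write_stage(clines, config$outdir, "clines")
    clinal <- clines[clines$is_clinal & is.finite(clines$midpoint_lat), ]
    if (nrow(clinal) >= 5) {
      coco <- coco_outliers(clinal, seed = stage_seed(config, 8L))
      files["coco"] <- write_stage(coco$points, config$outdir, "coco")
    } else {
      notices <- c(notices,
                   "fewer than 5 clinal loci: Co-Co stage skipped")
    }
  } else {
    notices <- c(notices, "site layout too small for cline analysis")
  }

  ## (8) FST outliers between regions (unmixed individuals only)
  fdist <- NULL
  pure <- dataset$ind$site %in% c(north_sites, south_sites)
  if (length(north_sites) && length(south_sites)) {
    sub <- subset_sites(dataset, c(north_sites, south_sites))
    grp <- ifelse(sub$ind$site %in% north_sites, "northern", "southern")
    fdist <- fst_outlier_scan(sub, grp,
                              n_sim_loci = config$n_sim_loci,
                              seed = stage_seed(config, 9L))
    files["fst_outliers"] <- write_stage(fdist$observed, config$outdir,
                                         "fst_outliers")
  }

  ## (9) optional second-epoch cline shift
  shift <- NULL
  if (!is.null(config$second_epoch) && !is.null(clines)) {
    ds2 <- if (inherits(config$second_epoch, "genotype_dataset"))
      config$second_epoch else read_genepop(config$second_epoch)
    clines2 <- cline_analysis(ds2,
                              n_permutations = config$cline_permutations,
                              seed = stage_seed(config, 10L))
    shift <- cline_shift_km(clines2, clines)
    files["cline_shift"] <- write_stage(
      data.frame(shift_km = shift,
                 mean_midpoint_epoch1 = mean(clines2$midpoint_lat,
                                             na.rm = TRUE),
                 mean_midpoint_epoch2 = mean(clines$midpoint_lat,
                                             na.rm = TRUE)),
      config$outdir, "cline_shift")
  }

  ## (10) optional spatfall
  spat <- NULL
  if (!is.null(config$spat_table)) {
    st <- if (is.data.frame(config$spat_table)) config$spat_table
          else read_spat_table(config$spat_table)
    spat <- spatfall_frequencies(st)
    files["spatfall"] <- write_stage(spat, config$outdir, "spatfall")
  }

  ## manifest: hash of the configuration (paths excluded so a bundle is
  ## relocatable), seed, versions
  cfg_for_hash <- config[setdiff(names(config), c("outdir"))]
  cfg_json <- jsonlite::toJSON(lapply(cfg_for_hash, function(x)
    if (inherits(x, "genotype_dataset")) "<in-memory dataset>" else x),
    auto_unbox = TRUE, digits = NA)
  tmp <- file.path(config$outdir, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("contactzone")),
    notices = notices, files = as.list(basename(unlist(files))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- file.path(config$outdir, "manifest.json")

  for (msg in notices) message(msg)
  structure(list(dataset = dataset, qc = qc, qmatrix = qm, zone = zone,
                 supervised = supervised, hwe = hwe_tab, ld = ld_tab,
                 kruskal_wallis = kw, bimodality = bimod,
                 clines = clines, coco = coco, fst_outliers = fdist,
                 cline_shift = shift, spatfall = spat,
                 notices = notices, files = files,
                 outdir = config$outdir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("contactzone pipeline report\n")
  cat("  sites:", nrow(x$dataset$sites), " individuals:",
      nrow(x$dataset$ind), " loci:", length(x$dataset$loci), "\n")
  cat(sprintf("  final AMOVA: Fct = %.3f (p = %.3g), Fsc = %.3f (p = %.3g)\n",
              x$zone$final_amova$Fct, x$zone$final_amova$p_fct,
              x$zone$final_amova$Fsc, x$zone$final_amova$p_fsc))
  cat("  partition:", sum(x$zone$category == "northern"), "northern /",
      sum(x$zone$category == "southern"), "southern /",
      sum(x$zone$category == "mixed"), "mixed\n")
  if (!is.null(x$bimodality))
    cat(sprintf("  bimodality: D_mech = %.3f (p = %.3g), D_swarm = %.3f (p = %.3g)\n",
                x$bimodality$ks_mechanical$statistic,
                x$bimodality$ks_mechanical$p,
                x$bimodality$ks_hybrid_swarm$statistic,
                x$bimodality$ks_hybrid_swarm$p))
  if (!is.null(x$cline_shift))
    cat(sprintf("  cline shift: %+.1f km\n", x$cline_shift))
  cat("  outputs in:", x$outdir, "\n")
  for (msg in x$notices) cat("  note:", msg, "\n")
  invisible(x)
}
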