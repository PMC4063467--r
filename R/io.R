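#' Read a Genepop genotype file
#'
#' Parses the diploid Genepop dialect: a title line, one locus name per
#' line (or a single comma-separated line), and `pop` blocks of
#' individuals written as `id ,  aaabbb aaabbb ...` with 2- or 3-digit
#' allele codes.  `00`/`000` codes mark missing alleles; per the
#' package's missingness convention a genotype with one missing allele is
#' promoted to fully missing.
#'
#' Each `pop` block becomes one sample site; the site id is the
#' (whitespace-trimmed) identifier of the block's last individual, the
#' Genepop convention, unless ids repeat, in which case sites are named
#' `pop1`, `pop2`, ...  Coordinates are unknown to the format and set to 0;
#' attach real metadata with [read_site_metadata()].
#'
#' @param path file to read.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("﻿", "", lines)
  if (length(lines) < 2) stop("Genepop parse error: file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop))
    stop("Genepop parse error: no 'pop' separator found")
  if (first_pop < 3)
    stop("Genepop parse error at line ", first_pop,
         ": no locus names before first 'pop'")
  locus_lines <- trimws(lines[2:(first_pop - 1)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  if (length(locus_lines) == 1 && grepl(",", locus_lines)) {
    locus_names <- trimws(strsplit(locus_lines, ",")[[1]])
  } else {
    locus_names <- locus_lines
  }
  if (any(!nzchar(locus_names)))
    stop("Genepop parse error: empty locus name in header")
  L <- length(locus_names)

  pop_idx <- cumsum(is_pop)
  rows <- which(!is_pop & seq_along(lines) > first_pop & nzchar(trimws(lines)))
  ids <- character(0); popn <- integer(0)
  a1 <- a2 <- NULL
  if (length(rows)) {
    a1 <- matrix(NA_integer_, length(rows), L)
    a2 <- matrix(NA_integer_, length(rows), L)
    for (k in seq_along(rows)) {
      i <- rows[k]
      parts <- strsplit(lines[i], ",")[[1]]
      if (length(parts) < 2)
        stop("Genepop parse error at line ", i, ": no ',' separator")
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "\\s+")[[1]]
      codes <- codes[nzchar(codes)]
      if (length(codes) != L)
        stop("Genepop parse error at line ", i, ": expected ", L,
             " genotypes, found ", length(codes))
      w <- nchar(codes)
      if (any(!w %in% c(4L, 6L)) || any(grepl("[^0-9]", codes)))
        stop("Genepop parse error at line ", i,
             ": malformed genotype code")
      half <- w / 2
      x1 <- as.integer(substr(codes, 1, half))
      x2 <- as.integer(substr(codes, half + 1, w))
      x1[x1 == 0L] <- NA_integer_
      x2[x2 == 0L] <- NA_integer_
      a1[k, ] <- x1
      a2[k, ] <- x2
      ids[k] <- id
      popn[k] <- pop_idx[i]
    }
  }
  npop <- max(pop_idx)
  site_ids <- vapply(seq_len(npop), function(p) {
    members <- ids[popn == p]
    if (length(members)) members[length(members)] else paste0("pop", p)
  }, character(1))
  if (anyDuplicated(site_ids)) site_ids <- paste0("pop", seq_len(npop))
  sites <- data.frame(id = site_ids, name = site_ids,
                      latitude = 0, longitude = 0,
                      region_label = "unassigned",
                      stringsAsFactors = FALSE)
  if (is.null(a1)) {
    a1 <- matrix(NA_integer_, 0, L)
    a2 <- matrix(NA_integer_, 0, L)
  }
  colnames(a1) <- colnames(a2) <- locus_names
  if (anyDuplicated(ids)) ids <- paste0(ids, "_", seq_along(ids))
  n_half <- sum(xor(is.na(a1), is.na(a2)))
  if (n_half > 0)
    warning(n_half, " half-missing genotype code(s) promoted to missing")
  suppressWarnings(
    genotype_dataset(a1, a2, ids, site_ids[popn], sites))
}

#' Write a dataset in Genepop format
#'
#' Writes 3-digit diploid codes, one locus name per line, one `pop` block
#' per site (in site-table order).  Missing genotypes become `000000`.
#' Output is UTF-8 with `"\n"` newlines; `read_genepop()` on the result
#' reproduces genotypes, site partition and locus order exactly.
#'
#' @param dataset a `genotype_dataset`.
#' @param path output file.
#' @param title first (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, title = "contactzone export") {
  labels <- unlist(dataset$loci, use.names = FALSE)
  if (length(labels) && max(labels) > 999)
    stop("allele label > 999 cannot be encoded in 3-digit Genepop")
  con <- file(path, open = "wb")
  on.exit(close(con))
  put <- function(x) writeLines(x, con, sep = "\n", useBytes = TRUE)
  put(title)
  put(names(dataset$loci))
  enc <- function(x) sprintf("%03d", ifelse(is.na(x), 0L, x))
  for (s in dataset$sites$id) {
    put("pop")
    rows <- which(dataset$ind$site == s)
    for (i in rows) {
      codes <- paste0(enc(dataset$allele1[i, ]), enc(dataset$allele2[i, ]))
      put(paste0(dataset$ind$id[i], " ,  ", paste(codes, collapse = " ")))
    }
  }
  invisible(path)
}

#' Read a site-metadata CSV
#'
#' Expects columns `id`, `name`, `latitude`, `longitude`; any further
#' numeric columns are kept as environmental covariates (temperature in
#' degrees C, salinity in permille, dissolved oxygen in mg/L, turbidity in
#' NTU, depth in m, ...).  Empty covariate cells stay `NA` (absent), never
#' zero.
#'
#' @param path CSV file.
#' @return a site data frame suitable for [genotype_dataset()].
#' @export
read_site_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  req <- c("id", "name", "latitude", "longitude")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("site metadata lacks column(s): ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate site id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (cc in setdiff(names(df), c("id", "name", "region_label")))
    df[[cc]] <- as.numeric(df[[cc]])
  if (any(is.na(df$latitude)))
    stop("missing latitude in site metadata")
  if (any(df$latitude < -90 | df$latitude > 90))
    stop("site latitude out of [-90, 90]")
  if (any(is.na(df$longitude)) ||
      any(df$longitude < -180 | df$longitude > 180))
    stop("site longitude missing or out of [-180, 180]")
  if (is.null(df$region_label)) df$region_label <- "unassigned"
  df
}

#' Read a seasonal spat-count CSV
#'
#' Expects columns `area`, `season`, `count`; seasons must be one of
#' `winter`, `spring`, `summer`, `fall` (winter = Dec-Feb, spring =
#' Mar-May, summer = Jun-Aug, fall = Sep-Nov) and counts non-negative
#' integers (presence counts of settled juvenile oysters).
#'
#' @param path CSV file.
#' @return data frame with columns `area`, `season` (factor in seasonal
#'   order), `count`.
#' @seealso [spatfall_frequencies()]
#' @export
read_spat_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("area", "season", "count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("spat table lacks column(s): ", paste(miss, collapse = ", "))
  seasons <- c("winter", "spring", "summer", "fall")
  df$season <- tolower(trimws(df$season))
  bad <- setdiff(unique(df$season), seasons)
  if (length(bad))
    stop("unknown season(s): ", paste(bad, collapse = ", "))
  df$count <- as.numeric(df$count)
  if (any(is.na(df$count) | df$count < 0 | df$count != round(df$count)))
    stop("spat counts must be non-negative integers")
  df$season <- factor(df$season, levels = seasons)
  df$area <- as.character(df$area)
  df[c("area", "season", "count")]
}
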