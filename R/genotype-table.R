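#' Multilocus genotype table
#'
#' Container for diploid, codominant genotypes of clonal plants sampled as
#' shoots ("ramets"). Each ramet carries an ordered pair of integer allele
#' codes (microsatellite fragment lengths) at every locus, plus a sampling-site
#' label and, optionally, per-site longitude/latitude.
#'
#' @param alleles integer matrix with one row per ramet and two columns per
#'   locus (columns `2l-1`, `2l` hold the allele pair at locus `l`). Missing
#'   calls use `missing_code`.
#' @param ramet_id character vector of unique ramet labels.
#' @param site character vector of site labels, one per ramet (non-empty).
#' @param locus_names character vector of locus labels.
#' @param coords optional `data.frame` with columns `site`, `lon`, `lat`
#'   (decimal degrees), one row per site.
#' @param missing_code integer sentinel for missing allele calls (default 0).
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(alleles, ramet_id, site, locus_names,
                           coords = NULL, missing_code = 0L) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles)
  if (length(locus_names) < 1L)
    stop("at least one locus is required")
  if (ncol(alleles) != 2L * length(locus_names))
    stop("allele matrix must have exactly 2 columns per locus")
  if (length(ramet_id) != n || length(site) != n)
    stop("ramet_id and site must have one entry per allele-matrix row")
  site <- as.character(site)
  if (any(!nzchar(site)) || anyNA(site))
    stop("site labels must be non-empty")
  if (anyDuplicated(ramet_id))
    stop("ramet_id must be unique")
  bad <- !is.na(alleles) & alleles != missing_code & alleles <= 0L
  if (any(bad))
    stop("allele codes must be positive or the missing sentinel")
  alleles[is.na(alleles)] <- as.integer(missing_code)
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    stopifnot(all(c("site", "lon", "lat") %in% names(coords)))
    coords$site <- as.character(coords$site)
    miss <- setdiff(unique(site), coords$site)
    if (length(miss))
      stop("coords missing for site(s): ", paste(miss, collapse = ", "))
  }
  structure(
    list(alleles = alleles,
         ramet_id = as.character(ramet_id),
         site = site,
         locus_names = as.character(locus_names),
         coords = coords,
         missing_code = as.integer(missing_code)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d ramets, %d loci, %d sites\n",
              nrow(x$alleles), n_loci(x), length(unique(x$site))))
  invisible(x)
}

#' Number of loci in a genotype table
#' @param table a `genotype_table`
#' @export
n_loci <- function(table) length(table$locus_names)

#' Number of ramets in a genotype table
#' @param table a `genotype_table`
#' @export
n_ramets <- function(table) nrow(table$alleles)

#' Site labels, in first-appearance order
#' @param table a `genotype_table`
#' @export
site_names <- function(table) unique(table$site)

# column indices of locus l in the allele matrix
locus_cols <- function(l) c(2L * l - 1L, 2L * l)

#' Subset a genotype table by ramet
#'
#' @param table a `genotype_table`
#' @param idx logical or integer row index
#' @return a `genotype_table` with the selected ramets
#' @export
subset_ramets <- function(table, idx) {
  genotype_table(table$alleles[idx, , drop = FALSE],
                 table$ramet_id[idx], table$site[idx],
                 table$locus_names, table$coords, table$missing_code)
}

#' Per-site allele frequencies
#'
#' Frequencies are computed per locus from non-missing allele copies
#' (pairwise deletion), so each locus's frequencies sum to one.
#'
#' @param table a `genotype_table`
#' @return named list (site) of lists (locus) of named frequency vectors;
#'   allele codes are the names.
#' @export
allele_freqs <- function(table) {
  out <- lapply(site_names(table), function(s) {
    rows <- table$site == s
    lapply(seq_len(n_loci(table)), function(l) {
      a <- as.vector(table$alleles[rows, locus_cols(l)])
      a <- a[a != table$missing_code]
      if (!length(a)) return(stats::setNames(numeric(0), character(0)))
      tab <- table(a)
      stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    })
  })
  stats::setNames(out, site_names(table))
}

# multilocus genotype keys: allele pair sorted within locus, loci joined.
# Identical keys <=> identical MLG regardless of within-locus allele order.
mlg_keys <- function(table) {
  L <- n_loci(table)
  parts <- vapply(seq_len(L), function(l) {
    ab <- table$alleles[, locus_cols(l), drop = FALSE]
    paste(pmin(ab[, 1], ab[, 2]), pmax(ab[, 1], ab[, 2]), sep = "/")
  }, character(n_ramets(table)))
  if (n_ramets(table) == 1L) parts <- matrix(parts, nrow = 1L)
  apply(parts, 1L, paste, collapse = "|")
}

#' Read a genotype file
#'
#' Supports the two text dialects used for microsatellite surveys: classic
#' genepop (2- or 3-digit allele encoding, auto-detected) and a GenAlEx-style
#' CSV with header `ramet,site` followed by two columns per locus.
#'
#' Genepop has no separate site field; sample labels of the form
#' `site:ramet` (as produced by [write_genotypes()]) are split on the colon,
#' otherwise sites are named `pop1`, `pop2`, ... in file order.
#'
#' @param path path to an existing file.
#' @param format `"genepop"` or `"genalex_csv"`.
#' @param coords optional per-site coordinate data.frame (see
#'   [genotype_table()]).
#' @return a validated `genotype_table`; loci and sites keep file order.
#' @export
read_genotypes <- function(path, format = c("genepop", "genalex_csv"),
                           coords = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genepop") read_genepop(path, coords)
  else read_genalex_csv(path, coords)
}

read_genepop <- function(path, coords = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("genepop parse error: file too short")
  pop_at <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_at)) stop("genepop parse error: no 'Pop' line found")
  header <- lines[2:(pop_at[1] - 1L)]
  # locus names may be one per line or comma-separated on one line
  locus_names <- trimws(unlist(strsplit(header, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)
  recs <- list(); ids <- character(); sites <- character()
  pop_bounds <- c(pop_at, length(lines) + 1L)
  for (p in seq_along(pop_at)) {
    body <- lines[seq(pop_bounds[p] + 1L, pop_bounds[p + 1L] - 1L)]
    for (off in seq_along(body)) {
      ln <- body[off]
      lineno <- pop_bounds[p] + off
      halves <- strsplit(ln, ",")[[1]]
      if (length(halves) < 2L)
        stop("genepop parse error at line ", lineno, ": missing comma")
      label <- trimws(halves[1])
      fields <- strsplit(trimws(paste(halves[-1], collapse = ",")),
                         "\\s+")[[1]]
      if (length(fields) != L)
        stop("genepop parse error at line ", lineno, ": expected ", L,
             " locus fields, found ", length(fields))
      w <- unique(nchar(fields))
      if (length(w) != 1L || !(w %in% c(4L, 6L)))
        stop("genepop parse error at line ", lineno,
             ": allele fields must be uniformly 4 or 6 digits")
      d <- w / 2L
      ab <- t(vapply(fields, function(f) {
        c(as.integer(substr(f, 1L, d)), as.integer(substr(f, d + 1L, w)))
      }, integer(2)))
      if (anyNA(ab))
        stop("genepop parse error at line ", lineno, ": non-numeric allele")
      if (grepl(":", label, fixed = TRUE)) {
        sp <- strsplit(label, ":", fixed = TRUE)[[1]]
        sites <- c(sites, sp[1]); ids <- c(ids, sp[2])
      } else {
        sites <- c(sites, paste0("pop", p)); ids <- c(ids, label)
      }
      recs[[length(recs) + 1L]] <- as.vector(t(ab))
    }
  }
  genotype_table(do.call(rbind, recs), ids, sites, locus_names, coords)
}

read_genalex_csv <- function(path, coords = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 4L || !identical(tolower(names(df)[1:2]), c("ramet", "site")))
    stop("genalex parse error: header must start with 'ramet,site'")
  acols <- names(df)[-(1:2)]
  if (length(acols) %% 2L != 0L)
    stop("genalex parse error: odd number of allele columns")
  locus_names <- unique(sub("\\.[12]$", "", acols))
  if (length(locus_names) * 2L != length(acols))
    stop("genalex parse error: allele columns must come in <locus>.1/<locus>.2 pairs")
  mat <- as.matrix(df[, -(1:2)])
  if (!is.numeric(mat)) stop("genalex parse error: non-numeric allele value")
  dimnames(mat) <- NULL
  genotype_table(mat, df[[1]], df[[2]], locus_names, coords)
}

#' Write a genotype table
#'
#' @param table a `genotype_table`.
#' @param path output path.
#' @param format `"genepop"` or `"genalex_csv"`.
#' @param digits genepop allele width per allele (2 or 3).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path,
                            format = c("genepop", "genalex_csv"),
                            digits = 3L) {
  format <- match.arg(format)
  if (format == "genalex_csv") {
    df <- data.frame(ramet = table$ramet_id, site = table$site,
                     check.names = FALSE)
    for (l in seq_len(n_loci(table))) {
      df[[paste0(table$locus_names[l], ".1")]] <-
        table$alleles[, locus_cols(l)[1]]
      df[[paste0(table$locus_names[l], ".2")]] <-
        table$alleles[, locus_cols(l)[2]]
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(digits %in% c(2L, 3L))
  if (any(table$alleles >= 10^digits))
    stop("allele codes too wide for ", digits, "-digit genepop encoding")
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  out <- c("seadrift genotype export", table$locus_names)
  for (s in site_names(table)) {
    out <- c(out, "Pop")
    rows <- which(table$site == s)
    for (i in rows) {
      fields <- vapply(seq_len(n_loci(table)), function(l) {
        ab <- table$alleles[i, locus_cols(l)]
        sprintf(fmt, ab[1], ab[2])
      }, character(1))
      out <- c(out, paste0(s, ":", table$ramet_id[i], " ,  ",
                           paste(fields, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
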