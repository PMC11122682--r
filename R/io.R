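# Readers and writers for the tabular interchange formats. All files are
# plain CSV; writers can prepend '#'-prefixed provenance comments (seed and
# configuration hash), which the readers skip.

series_cols <- c("locality", "year", "host", "n_striped", "n_green", "n_melanic")

#' Read a morph-count time series from CSV
#'
#' Expects columns `locality`, `year`, `host`, `n_striped`, `n_green`,
#' `n_melanic`. Lines starting with `#` are treated as comments.
#' Malformed rows (negative counts, zero totals, duplicated
#' locality-year-host keys) raise errors naming the offending rows.
#'
#' @param path CSV file path.
#' @return Tibble of validated count records.
#' @export
read_morph_series <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_morph_series(x, source = path)
}

#' Validate a morph-count series tibble
#'
#' @param x Data frame of count records.
#' @param source Label used in error messages.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_morph_series <- function(x, source = "series") {
  missing_cols <- setdiff(series_cols, names(x))
  if (length(missing_cols) > 0) {
    stop(source, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cnt <- c("n_striped", "n_green", "n_melanic")
  bad <- which(Reduce(`|`, lapply(x[cnt], function(v) v < 0 | is.na(v))))
  if (length(bad) > 0) {
    stop(source, ": negative or missing counts in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tot <- x$n_striped + x$n_green + x$n_melanic
  if (any(tot < 1)) {
    stop(source, ": zero-total record(s) in row(s) ",
         paste(utils::head(which(tot < 1), 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$locality, x$year, x$host)
  if (anyDuplicated(key)) {
    stop(source, ": duplicated (locality, year, host) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
         call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Write tabular output with provenance comments
#'
#' Writes a CSV preceded by `#`-prefixed comment lines recording the seed
#' and a hash of the generating configuration, so every output file is
#' auditable.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Seed used to produce `x` (optional).
#' @param config Configuration object used to produce `x` (optional;
#'   hashed, not serialised).
#' @return `path`, invisibly.
#' @export
write_with_provenance <- function(x, path, seed = NULL, config = NULL) {
  header <- c(
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config)) paste0("# config_hash: ", rlang::hash(config))
  )
  if (length(header) > 0) {
    writeLines(header, path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

#' Write a morph-count series to CSV
#'
#' @inheritParams write_with_provenance
#' @export
write_morph_series <- function(x, path, seed = NULL, config = NULL) {
  validate_morph_series(x)
  write_with_provenance(x[series_cols], path, seed = seed, config = config)
}

#' Read a transplant-experiment table from CSV
#'
#' Expects columns `bush`, `released_striped`, `released_other`,
#' `recaptured_striped`, `recaptured_other` (plus optional `block`,
#' `release_freq`). Recaptures exceeding releases raise an error.
#'
#' @param path CSV file path.
#' @return Tibble of experiment records.
#' @export
read_experiment <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("bush", "released_striped", "released_other",
            "recaptured_striped", "recaptured_other")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x$recaptured_striped > x$released_striped |
                 x$recaptured_other > x$released_other)
  if (length(bad) > 0) {
    stop(path, ": recaptured exceeds released in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read a genotype dosage matrix from CSV
#'
#' First column is the individual identifier; remaining columns are SNP
#' dosages coded 0/1/2.
#'
#' @param path CSV file path.
#' @return Numeric matrix with individual row names.
#' @export
read_genotype_matrix <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(x[, -1])
  rownames(m) <- as.character(x[[1]])
  storage.mode(m) <- "numeric"
  if (any(!m %in% c(0, 1, 2) & !is.na(m))) {
    stop(path, ": genotype dosages must be coded 0/1/2", call. = FALSE)
  }
  m
}

#' Convert a VCF to a 0/1/2 dosage matrix
#'
#' Thin wrapper over `vcfR` for biallelic SNPs: counts alternate alleles
#' per genotype. Requires the `vcfR` package.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return Individual-by-SNP dosage matrix.
#' @export
vcf_to_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("`vcfR` is required for VCF input", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = FALSE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  m <- apply(gt, 2, count_alt)
  t(matrix(m, nrow = nrow(gt),
           dimnames = list(rownames(gt), colnames(gt))))
}
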