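# Delimited-text I/O for release and mass curves, results tables and the
# dataset manifest. Dialect: comma- or tab-separated, header row, decimal
# point; auto-detected from the header line.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_checked <- function(path, required) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required$any, names(df))
  if (!is.null(required$all) && !all(required$all %in% names(df)))
    stop("file ", path, " is missing column(s): ",
         paste(setdiff(required$all, names(df)), collapse = ", "),
         call. = FALSE)
  if (!is.null(required$any) && !any(required$any %in% names(df)))
    stop("file ", path, " needs one of the columns: ",
         paste(required$any, collapse = ", "), call. = FALSE)
  df
}

check_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(x))
  if (length(bad) > 0)
    stop("file ", path, ": non-numeric value in column '", col,
         "' at data row ", bad[1], call. = FALSE)
  x
}

#' Read a release curve from delimited text
#'
#' Expects a header row with column `time_s` plus either `fraction` or
#' `amount` (comma- or tab-separated, auto-detected). Rows are sorted by
#' time (with a warning when the file was unsorted), duplicate times are
#' averaged, and slightly out-of-range fractions in \[-0.05, 0) or
#' (1, 1.05\] are clipped with a warning; fractions beyond that band are a
#' parse error naming the offending row.
#'
#' @param path Path to the file.
#' @param m_inf Equilibrium amount, required downstream when the file has
#'   an `amount` column and the fit does not co-estimate it.
#' @return A [as_release_curve()] object.
#' @examples
#' # a bundled synthetic curve (EG3-like parameters, sigma = 0.03)
#' p <- system.file("extdata", "synthetic_release_EG3.csv",
#'                  package = "filmrelease")
#' fit_D(read_release_csv(p), film_geometry(0.062))
#' @export
read_release_csv <- function(path, m_inf = NULL) {
  df <- read_delim_checked(path, list(all = "time_s",
                                      any = c("fraction", "amount")))
  t <- check_numeric_col(df, "time_s", path)
  if (is.unsorted(t))
    warning("rows in ", path, " were not sorted by time; sorted",
            call. = FALSE)
  if ("fraction" %in% names(df)) {
    f <- check_numeric_col(df, "fraction", path)
    out_hard <- which(f < -0.05 | f > 1.05)
    if (length(out_hard) > 0)
      stop("file ", path, ": fraction out of [-0.05, 1.05] at data row ",
           out_hard[1], call. = FALSE)
    clip <- f < 0 | f > 1
    if (any(clip)) {
      warning("file ", path, ": ", sum(clip),
              " fraction(s) slightly outside [0, 1] clipped (rows ",
              paste(utils::head(which(clip), 5), collapse = ", "), ")",
              call. = FALSE)
      f <- pmin(pmax(f, 0), 1)
    }
    as_release_curve(t, fraction = f, m_inf = m_inf)
  } else {
    a <- check_numeric_col(df, "amount", path)
    as_release_curve(t, amount = a, m_inf = m_inf)
  }
}

#' Read a film mass series from delimited text
#'
#' Expects columns `time_s` and `mass_g` (same dialect as
#' [read_release_csv()]).
#'
#' @param path Path to the file.
#' @param m0_g Dry film mass in grams.
#' @return A [mass_series()].
#' @export
read_mass_csv <- function(path, m0_g) {
  df <- read_delim_checked(path, list(all = c("time_s", "mass_g"),
                                      any = "mass_g"))
  t <- check_numeric_col(df, "time_s", path)
  m <- check_numeric_col(df, "mass_g", path)
  ord <- order(t)
  if (is.unsorted(t))
    warning("rows in ", path, " were not sorted by time; sorted",
            call. = FALSE)
  mass_series(t[ord], m[ord], m0_g = m0_g)
}

#' Write a release curve to delimited text
#'
#' Full-precision CSV with header `time_s,fraction` (round-trips through
#' [read_release_csv()] bit-identically).
#'
#' @param curve A release curve.
#' @param path Output path.
#' @export
write_release_csv <- function(curve, path) {
  stopifnot(inherits(curve, "release_curve"))
  df <- data.frame(time_s = format(curve$time_s, digits = 17,
                                   scientific = FALSE, trim = TRUE),
                   fraction = format(curve$fraction, digits = 17,
                                     trim = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a synthetic dataset with its ground-truth manifest
#'
#' One CSV per curve plus a YAML `manifest.yml` recording the generating
#' parameters (truth table, seed, scenario settings), so a simulated study
#' can be refit from files alone and audited against its truth.
#'
#' @param dataset A `"release_dataset"`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_release_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "release_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- attr(dataset, "truth")
  scenario <- attr(dataset, "scenario")
  files <- character(length(dataset))
  for (i in seq_along(dataset)) {
    rec <- dataset[[i]]
    files[i] <- paste0(rec$label, ".csv")
    write_release_csv(rec$curve, file.path(dir, files[i]))
  }
  manifest <- list(
    scenario = scenario$name,
    seed = scenario$seed,
    sigma = scenario$sigma,
    noise = scenario$noise,
    package_version = as.character(utils::packageVersion("filmrelease")),
    curves = lapply(seq_along(dataset), function(i) {
      row <- truth[i, ]
      c(list(file = files[i]),
        lapply(as.list(row), function(v)
          if (is.numeric(v)) unname(v) else as.character(v)))
    })
  )
  mpath <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Write a results table with a provenance sidecar
#'
#' Writes the table as CSV (full precision) and a YAML sidecar
#' `<path>.yml` carrying provenance: package version, seed, and the MD5
#' hash of the configuration file when one was used.
#'
#' @param table A data frame of results (one row per film/solvent pair).
#' @param path Output CSV path.
#' @param seed Seed used for any stochastic step (or `NULL`).
#' @param config_path Optional path of the configuration the run came from.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, seed = NULL, config_path = NULL) {
  stopifnot(is.data.frame(table))
  fmt <- table
  for (nm in names(fmt))
    if (is.numeric(fmt[[nm]]))
      fmt[[nm]] <- format(fmt[[nm]], digits = 17, trim = TRUE)
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
  sidecar <- list(
    package_version = as.character(utils::packageVersion("filmrelease")),
    seed = if (is.null(seed)) NA else seed,
    config_md5 = if (is.null(config_path)) NA
                 else unname(tools::md5sum(config_path)),
    n_rows = nrow(table),
    columns = names(table)
  )
  yaml::write_yaml(sidecar, paste0(path, ".yml"))
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return A data frame; the sidecar (if present) is attached as
#'   `attr(, "sidecar")`.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  side <- paste0(path, ".yml")
  if (file.exists(side)) attr(df, "sidecar") <- yaml::read_yaml(side)
  df
}
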