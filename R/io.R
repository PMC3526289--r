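# Plain-text I/O. Curves travel as CSV with "#"-prefixed key=value
# metadata headers so fixtures stay diffable; estimates are written as
# JSON and as a flat TSV row in the conventional table column order
# (Tm, dG298, dH, T.dS298, each with its error).

format_num <- function(x) formatC(x, digits = 15, format = "g")

read_meta_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)=(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

parse_two_col <- function(lines, path, col1, col2) {
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  body <- lines[keep]
  if (length(body) == 0L) {
    stop(sprintf("parse error in '%s': no data lines", path), call. = FALSE)
  }
  header <- strsplit(body[1], ",")[[1]]
  if (length(header) != 2L || trimws(header[1]) != col1 ||
      trimws(header[2]) != col2) {
    stop(sprintf("parse error in '%s' at line %d: expected header '%s,%s'",
                 path, line_no[1], col1, col2), call. = FALSE)
  }
  if (length(body) < 2L) {
    stop(sprintf("parse error in '%s': header but no data rows", path),
         call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(body) - 1L, ncol = 2L)
  for (i in 2:length(body)) {
    fields <- strsplit(body[i], ",")[[1]]
    v <- suppressWarnings(as.numeric(fields))
    if (length(v) != 2L || any(is.na(v))) {
      stop(sprintf("parse error in '%s' at line %d: expected two numeric fields, got '%s'",
                   path, line_no[i], body[i]), call. = FALSE)
    }
    vals[i - 1L, ] <- v
  }
  vals
}

#' Write a melting curve as annotated CSV
#'
#' Columns `temperature_C,signal`, preceded by `#`-prefixed metadata
#' (`Ct_molar`, and when present `pH`, `wavelength_nm`, `buffer`,
#' `heating_rate`).
#'
#' @param curve A [melting_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_melting_csv <- function(curve, path) {
  stopifnot(inherits(curve, "melting_curve"))
  meta <- attr(curve, "meta")
  hdr <- c(sprintf("# Ct_molar=%s", format_num(attr(curve, "Ct"))))
  if (!is.na(meta$pH)) hdr <- c(hdr, sprintf("# pH=%s", format_num(meta$pH)))
  if (!is.na(meta$wavelength_nm)) {
    hdr <- c(hdr, sprintf("# wavelength_nm=%s", format_num(meta$wavelength_nm)))
  }
  if (!is.na(meta$buffer)) hdr <- c(hdr, sprintf("# buffer=%s", meta$buffer))
  if (!is.na(meta$heating_rate)) {
    hdr <- c(hdr, sprintf("# heating_rate=%s", format_num(meta$heating_rate)))
  }
  lines <- c(hdr, "temperature_C,signal",
             paste(format_num(curve$temperature_C), format_num(curve$signal),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a melting curve from annotated CSV
#'
#' Inverse of [write_melting_csv()]. The `Ct_molar` metadata line is
#' mandatory: without the strand concentration the homodimer analysis is
#' undefined. Malformed files fail with the offending line number.
#'
#' @param path Input file path.
#' @return A [melting_curve()].
#' @export
read_melting_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop(sprintf("parse error in '%s': empty file", path), call. = FALSE)
  }
  meta <- read_meta_lines(lines)
  if (is.null(meta$Ct_molar)) {
    stop(sprintf("parse error in '%s': missing '# Ct_molar=' metadata line", path),
         call. = FALSE)
  }
  vals <- parse_two_col(lines, path, "temperature_C", "signal")
  melting_curve(
    vals[, 1], vals[, 2],
    Ct = as.numeric(meta$Ct_molar),
    pH = if (is.null(meta$pH)) NA_real_ else as.numeric(meta$pH),
    wavelength_nm = if (is.null(meta$wavelength_nm)) NA_real_ else as.numeric(meta$wavelength_nm),
    buffer = meta$buffer %||% NA_character_,
    heating_rate = if (is.null(meta$heating_rate)) NA_real_ else as.numeric(meta$heating_rate)
  )
}

#' Write a titration curve as annotated CSV
#'
#' Columns `pH,signal` with optional `# temperature_C=` and `# buffer=`
#' metadata.
#'
#' @param curve A [titration_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  meta <- attr(curve, "meta")
  hdr <- character()
  if (!is.na(meta$temperature_C)) {
    hdr <- c(hdr, sprintf("# temperature_C=%s", format_num(meta$temperature_C)))
  }
  if (!is.na(meta$buffer)) hdr <- c(hdr, sprintf("# buffer=%s", meta$buffer))
  lines <- c(hdr, "pH,signal",
             paste(format_num(curve$pH), format_num(curve$signal), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a titration curve from annotated CSV
#'
#' @param path Input file path.
#' @return A [titration_curve()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop(sprintf("parse error in '%s': empty file", path), call. = FALSE)
  }
  meta <- read_meta_lines(lines)
  vals <- parse_two_col(lines, path, "pH", "signal")
  titration_curve(
    vals[, 1], vals[, 2],
    temperature_C = if (is.null(meta$temperature_C)) NA_real_ else as.numeric(meta$temperature_C),
    buffer = meta$buffer %||% NA_character_
  )
}

#' Flat summary row of a thermodynamic estimate
#'
#' One-row data frame in the conventional reporting order -- Tm, dG298,
#' dH, T.dS298, each followed by its propagated standard error -- for
#' side-by-side comparison across sequences.
#'
#' @param est A `thermo_estimate` carrying derived quantities
#'   ([derived_with_errors()]).
#' @return A one-row data frame with columns `Tm_C`, `se_Tm`, `dG298`,
#'   `se_dG`, `dH`, `se_dH`, `TdS298`, `se_TdS`, `Ct`, `r_squared`.
#' @export
estimate_row <- function(est) {
  stopifnot(inherits(est, "thermo_estimate"))
  if (is.null(est$derived)) {
    stop("estimate has no derived block; run derived_with_errors() first",
         call. = FALSE)
  }
  d <- est$derived
  data.frame(Tm_C = d$Tm_C, se_Tm = d$se_Tm,
             dG298 = d$dG, se_dG = d$se_dG,
             dH = est$params$dH, se_dH = est$se_dH,
             TdS298 = d$TdS, se_TdS = d$se_TdS,
             Ct = d$Ct, r_squared = est$r_squared)
}

#' Write a thermodynamic estimate as JSON
#'
#' @param est A `thermo_estimate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(est, path) {
  stopifnot(inherits(est, "thermo_estimate"))
  payload <- list(
    dH = est$params$dH, dS = est$params$dS,
    se_dH = est$se_dH, se_dS = est$se_dS, cov_dH_dS = est$cov_dH_dS,
    r_squared = est$r_squared, n = est$n,
    molecularity = est$molecularity, Ct = est$Ct,
    derived = est$derived, tm_observed_C = est$tm_observed_C
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write the flat estimate row as TSV
#'
#' @inheritParams write_estimate_json
#' @export
write_estimate_tsv <- function(est, path) {
  utils::write.table(estimate_row(est), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a titration fit as JSON
#'
#' @param fit A `titration_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_json <- function(fit, path) {
  stopifnot(inherits(fit, "titration_fit"))
  payload <- fit[c("pKa_app", "hill", "plateau_low", "plateau_high",
                   "se_pKa", "se_hill", "se_plateau_low", "se_plateau_high",
                   "hill_fixed", "sigma", "extrapolated")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
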