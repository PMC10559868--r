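#' Construct a titration series
#'
#' A titration series is the basic UV-Vis (or fluorescence) binding
#' experiment: a fixed protein concentration monitored at one wavelength
#' while total ligand is stepped up. Stored as a tibble of
#' (`ligand_total`, `signal`) rows carrying the protein concentration,
#' temperature and signal kind as attributes.
#'
#' @param ligand_total Total ligand concentrations, M, strictly increasing,
#'   at least 3 points. A leading 0 (free protein) is allowed.
#' @param signal Non-negative signal readings (AU), same length.
#' @param protein_total Total protein concentration, M (> 0).
#' @param temperature Temperature, K (> 0).
#' @param signal_kind `"absorbance"` or `"fluorescence"`.
#'
#' @return A tibble of class `titration_series` with columns `ligand_total`
#'   and `signal`.
#' @examples
#' titration_series(c(4e-6, 8e-6, 12e-6), c(0.65, 0.64, 0.63),
#'                  protein_total = 15e-6, temperature = 300)
#' @export
titration_series <- function(ligand_total, signal, protein_total,
                             temperature,
                             signal_kind = c("absorbance", "fluorescence")) {
  signal_kind <- match.arg(signal_kind)
  ligand_total <- as.numeric(ligand_total)
  signal <- as.numeric(signal)
  if (length(ligand_total) != length(signal) || length(signal) < 3) {
    abort("Need >= 3 paired (ligand_total, signal) points.",
          class = "bindspectra_error")
  }
  if (any(diff(ligand_total) <= 0)) {
    abort("`ligand_total` must be strictly increasing.",
          class = "bindspectra_error")
  }
  if (any(ligand_total < 0) || any(signal < 0)) {
    abort("Concentrations and signals must be non-negative.",
          class = "bindspectra_error")
  }
  if (protein_total <= 0 || temperature <= 0) {
    abort("Require protein_total > 0 (M) and temperature > 0 (K).",
          class = "bindspectra_error")
  }
  out <- tibble(ligand_total = ligand_total, signal = signal)
  attr(out, "protein_total") <- protein_total
  attr(out, "temperature") <- temperature
  attr(out, "signal_kind") <- signal_kind
  class(out) <- c("titration_series", class(out))
  out
}

#' Endpoint signals of a titration
#'
#' The signal of the free protein (`A0`) and of the fully bound protein
#' (`A_inf`); the two must differ or no binding signal exists.
#'
#' @param A0 Signal of free protein, AU.
#' @param A_inf Signal of fully bound protein, AU.
#' @return A list of class `endpoint_pair`.
#' @export
endpoint_pair <- function(A0, A_inf) {
  if (!is.finite(A0) || !is.finite(A_inf) || A0 == A_inf) {
    abort("Endpoints must be finite and A0 != A_inf.",
          class = "bindspectra_error")
  }
  structure(list(A0 = A0, A_inf = A_inf), class = "endpoint_pair")
}

#' Construct a thermal melting trace
#'
#' Absorbance versus temperature for a protein heated through its unfolding
#' transition. Temperatures are accepted in degrees Celsius or kelvin at
#' input and stored in kelvin.
#'
#' @param temperature Strictly increasing temperatures, at least 8 points.
#' @param signal Signal readings (AU), same length.
#' @param unit `"C"` or `"K"`; the unit of `temperature`.
#' @param label Free-text label (e.g. `"free"` or `"bound"`).
#' @return A tibble of class `melt_trace` with columns `temperature_K` and
#'   `signal`.
#' @export
melt_trace <- function(temperature, signal, unit = c("C", "K"),
                       label = "") {
  unit <- match.arg(unit)
  temperature <- as.numeric(temperature)
  signal <- as.numeric(signal)
  if (length(temperature) != length(signal) || length(signal) < 8) {
    abort("Need >= 8 paired (temperature, signal) points.",
          class = "bindspectra_error")
  }
  if (any(diff(temperature) <= 0)) {
    abort("`temperature` must be strictly increasing.",
          class = "bindspectra_error")
  }
  temperature_K <- if (unit == "C") temperature + 273.15 else temperature
  out <- tibble(temperature_K = temperature_K, signal = signal)
  attr(out, "label") <- label
  class(out) <- c("melt_trace", class(out))
  out
}

#' Construct a kinetic trace
#'
#' Absorbance versus time for an association reaction followed to (or
#' toward) equilibrium at a single wavelength. Endpoint anchors `A0` and
#' `A_inf` are needed by the integrated rate-law transforms; when `A_inf`
#' is not supplied it is estimated as the mean of the final 5 percent of
#' the trace.
#'
#' @param time Strictly increasing times, s, first point >= 0; >= 5 points.
#' @param signal Signal readings (AU), same length.
#' @param A0 Initial signal; defaults to the first reading.
#' @param A_inf Final (equilibrium) signal; defaults to the mean of the
#'   last 5 percent of readings.
#' @return A tibble of class `kinetic_trace` with columns `time` and
#'   `signal`, carrying `A0` and `A_inf` as attributes.
#' @export
kinetic_trace <- function(time, signal, A0 = NULL, A_inf = NULL) {
  time <- as.numeric(time)
  signal <- as.numeric(signal)
  if (length(time) != length(signal) || length(signal) < 5) {
    abort("Need >= 5 paired (time, signal) points.",
          class = "bindspectra_error")
  }
  if (time[1] < 0 || any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing with t0 >= 0.",
          class = "bindspectra_error")
  }
  A0 <- A0 %||% signal[1]
  if (is.null(A_inf)) {
    n_tail <- max(1L, ceiling(0.05 * length(signal)))
    A_inf <- mean(utils::tail(signal, n_tail))
  }
  if (A0 == A_inf) {
    abort("Endpoints coincide (A0 == A_inf): no approach to equilibrium.",
          class = "bindspectra_error")
  }
  out <- tibble(time = time, signal = signal)
  attr(out, "A0") <- A0
  attr(out, "A_inf") <- A_inf
  class(out) <- c("kinetic_trace", class(out))
  out
}

#' Construct a fluorescence quenching series
#'
#' Fluorescence intensity of the protein versus total quencher (ligand)
#' concentration, for Stern-Volmer and double-logarithmic binding
#' analysis.
#'
#' @param Q Quencher concentrations, M, strictly increasing; `Q[1] = 0` is
#'   permitted.
#' @param F_signal Fluorescence intensities (AU, positive), same length.
#' @param F0 Intensity of the unquenched protein; defaults to the reading
#'   at `Q = 0` when present, else the maximum intensity.
#' @param tau0 Unquenched fluorophore lifetime, s (default 1e-8, the
#'   nanosecond-scale tryptophan lifetime).
#' @return A tibble of class `quench_series` with columns `Q` and
#'   `F_signal`, carrying `F0` and `tau0` as attributes.
#' @export
quench_series <- function(Q, F_signal, F0 = NULL, tau0 = 1e-8) {
  Q <- as.numeric(Q)
  F_signal <- as.numeric(F_signal)
  if (length(Q) != length(F_signal) || length(F_signal) < 3) {
    abort("Need >= 3 paired (Q, F) points.", class = "bindspectra_error")
  }
  if (any(Q < 0) || any(diff(Q) <= 0)) {
    abort("`Q` must be non-negative and strictly increasing.",
          class = "bindspectra_error")
  }
  if (any(F_signal <= 0)) {
    abort("Fluorescence intensities must be positive.",
          class = "bindspectra_error")
  }
  if (tau0 <= 0) {
    abort("`tau0` must be positive (seconds).", class = "bindspectra_error")
  }
  F0 <- F0 %||% if (Q[1] == 0) F_signal[1] else max(F_signal)
  # tolerate noise excursions just above F0; warn only on gross violations
  if (max(F_signal) > F0 * 1.02) {
    warn("F0 is well below the largest measured intensity; check the series.")
  }
  out <- tibble(Q = Q, F_signal = F_signal)
  attr(out, "F0") <- F0
  attr(out, "tau0") <- tau0
  class(out) <- c("quench_series", class(out))
  out
}

delim_of <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Input file '%s' does not exist.", path),
          class = "bindspectra_error_io")
  }
  lines <- readLines(path, n = 50, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("No data lines in '%s'.", path),
          class = "bindspectra_error")
  }
  first <- lines[[1]]
  if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else " "
}

read_two_columns <- function(path, required) {
  delim <- delim_of(path)
  df <- if (delim == " ") {
    readr::read_table(path, comment = "#", show_col_types = FALSE)
  } else {
    readr::read_delim(path, delim = delim, comment = "#",
                      show_col_types = FALSE, trim_ws = TRUE)
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")),
          class = "bindspectra_error_io")
  }
  df
}

#' Read experiment traces from delimited text
#'
#' Readers for the four experiment dialects. Files are comma-, tab- or
#' whitespace-delimited with a header row; lines starting with `#` are
#' ignored. Required columns: `ligand_total_M` and `signal` for
#' titrations; `temperature_C` and `signal` for melts; `time_s` and
#' `signal` for kinetics; `Q_M` and `F` for quenching.
#'
#' @param path Path to a delimited text file.
#' @inheritParams titration_series
#' @inheritParams kinetic_trace
#' @inheritParams quench_series
#' @param label Trace label (melts).
#' @return The corresponding series object ([titration_series()],
#'   [melt_trace()], [kinetic_trace()] or [quench_series()]).
#' @export
read_titration <- function(path, protein_total, temperature,
                           signal_kind = "absorbance") {
  df <- read_two_columns(path, c("ligand_total_M", "signal"))
  titration_series(df$ligand_total_M, df$signal,
                   protein_total = protein_total,
                   temperature = temperature, signal_kind = signal_kind)
}

#' @rdname read_titration
#' @export
read_melt <- function(path, label = "") {
  df <- read_two_columns(path, c("temperature_C", "signal"))
  melt_trace(df$temperature_C, df$signal, unit = "C", label = label)
}

#' @rdname read_titration
#' @export
read_kinetic <- function(path, A0 = NULL, A_inf = NULL) {
  df <- read_two_columns(path, c("time_s", "signal"))
  kinetic_trace(df$time_s, df$signal, A0 = A0, A_inf = A_inf)
}

#' @rdname read_titration
#' @export
read_quench <- function(path, F0 = NULL, tau0 = 1e-8) {
  df <- read_two_columns(path, c("Q_M", "F"))
  quench_series(df$Q_M, df$F, F0 = F0, tau0 = tau0)
}

#' Write a series object to delimited text
#'
#' Inverse of the [read_titration()] family: writes the dialect the
#' corresponding reader accepts (CSV with a header row).
#'
#' @param x A series object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  df <- if (inherits(x, "titration_series")) {
    tibble(ligand_total_M = x$ligand_total, signal = x$signal)
  } else if (inherits(x, "melt_trace")) {
    tibble(temperature_C = x$temperature_K - 273.15, signal = x$signal)
  } else if (inherits(x, "kinetic_trace")) {
    tibble(time_s = x$time, signal = x$signal)
  } else if (inherits(x, "quench_series")) {
    tibble(Q_M = x$Q, F = x$F_signal)
  } else {
    abort("Unsupported object for write_series().",
          class = "bindspectra_error")
  }
  readr::write_csv(df, path)
  invisible(path)
}
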