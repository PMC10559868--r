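#' Run a multi-stage binding study from a config
#'
#' End-to-end driver. The config (a JSON file or an equivalent nested
#' list) names the input traces per stage; only configured stages run, so
#' partial studies are fine. Stages:
#'
#' * `isotherm`: a list of entries `{path, protein_total, temperature}`
#'   (temperature in K; optional `A0`). Each is fit by
#'   [double_reciprocal_fit()]; with exactly two temperatures the full
#'   van't Hoff [thermo_table()] is added.
#' * `cooperativity`: `{series (index into isotherm entries, default 1),
#'   g (default 1)}`. Builds binding points (nu from the fitted
#'   endpoints, free ligand from the observed mass balance) and runs
#'   [hill_fit()], [scatchard()], [capacity_diagnostic()] and
#'   [gibbs_per_site()].
#' * `melt`: `{free, bound}` trace paths, fit by [tm_shift()].
#' * `kinetics`: `{path, A0, A_inf}` (anchors optional), run through
#'   [select_order()].
#' * `quench`: `{path, tau0, F0}` (defaults 1e-8 s / at-zero reading),
#'   run through [analyze_quenching()].
#'
#' @param config Path to a JSON config file, or a nested list of the same
#'   shape.
#' @return An object of class `study_report`: a list with one element per
#'   executed stage plus `provenance` (package version and input digests).
#' @export
run_study <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config))
  report <- list()
  inputs <- character()

  if (!is.null(config$isotherm)) {
    entries <- config$isotherm
    fits <- purrr::map(entries, function(e) {
      series <- read_titration(e$path,
                               protein_total = e$protein_total,
                               temperature = e$temperature)
      inputs <<- c(inputs, e$path)
      double_reciprocal_fit(series, A0 = e$A0 %||% NULL)
    })
    report$isotherm <- fits
    if (length(fits) == 2) {
      report$thermo <- thermo_table(fits[[1]], fits[[2]])
    }
  }

  if (!is.null(config$cooperativity)) {
    if (is.null(report$isotherm)) {
      abort("The cooperativity stage needs at least one isotherm entry.",
            class = "bindspectra_error")
    }
    cc <- config$cooperativity
    i <- cc$series %||% 1
    g <- cc$g %||% 1
    e <- config$isotherm[[i]]
    series <- read_titration(e$path, protein_total = e$protein_total,
                             temperature = e$temperature)
    fit <- report$isotherm[[i]]
    curve <- saturation_curve(series, fit$endpoints, g = g)
    points <- tibble(
      nu = curve$nu,
      L_free = pmax(curve$ligand_total - curve$bound, 0)
    )
    hill <- hill_fit(points, g = g)
    params <- binding_parameters(K_b = hill$K_H^(1 / hill$n_H),
                                 g = g, n_H = hill$n_H, K_H = hill$K_H)
    report$cooperativity <- list(
      hill = hill,
      scatchard = scatchard(points[points$L_free > 0 & points$nu > 0, ]),
      capacity = capacity_diagnostic(points, params, e$temperature),
      gibbs_per_site = gibbs_per_site(points[points$L_free > 0, ], hill,
                                      e$temperature)
    )
  }

  if (!is.null(config$melt)) {
    free <- read_melt(config$melt$free, label = "free")
    bound <- read_melt(config$melt$bound, label = "bound")
    inputs <- c(inputs, config$melt$free, config$melt$bound)
    report$melt <- list(
      free = fit_two_state_melt(free),
      bound = fit_two_state_melt(bound),
      shift = tm_shift(free, bound)
    )
  }

  if (!is.null(config$kinetics)) {
    kc <- config$kinetics
    trace <- read_kinetic(kc$path, A0 = kc$A0 %||% NULL,
                          A_inf = kc$A_inf %||% NULL)
    inputs <- c(inputs, kc$path)
    report$kinetics <- select_order(trace)
  }

  if (!is.null(config$quench)) {
    qc <- config$quench
    series <- read_quench(qc$path, F0 = qc$F0 %||% NULL,
                          tau0 = qc$tau0 %||% 1e-8)
    inputs <- c(inputs, qc$path)
    report$quench <- analyze_quenching(series)
  }

  report$provenance <- list(
    package = "bindspectra",
    version = as.character(utils::packageVersion("bindspectra")),
    input_digests = as.list(tools::md5sum(unique(inputs)))
  )
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  stages <- setdiff(names(x), "provenance")
  cat("  stages:", paste(stages, collapse = ", "), "\n")
  if (!is.null(x$thermo)) {
    cat(sprintf("  delta_H = %.1f kJ/mol; driving force: %s\n",
                x$thermo$delta_H_kJ_mol[1], x$thermo$driving_force[1]))
  }
  if (!is.null(x$melt)) {
    cat(sprintf("  delta_T_m = %+.1f K (%s)\n",
                x$melt$shift$delta_T_m_K, x$melt$shift$verdict))
  }
  if (!is.null(x$kinetics)) {
    cat(sprintf("  kinetic order: %s\n", x$kinetics$chosen))
  }
  if (!is.null(x$quench)) {
    cat(sprintf("  quenching: %s (k_q = %.3g M^-1 s^-1)\n",
                x$quench$mechanism, x$quench$k_q))
  }
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' Writes every numeric stage result (with units encoded in the field
#' names) to a JSON document that round-trips losslessly through
#' [jsonlite::read_json()].
#'
#' @param report A [run_study()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  simplify <- function(x) {
    if (inherits(x, "line_fit")) {
      list(slope = x$slope, intercept = x$intercept,
           r_squared = x$r_squared, n_points = x$n_points)
    } else if (inherits(x, "endpoint_pair") ||
               inherits(x, "binding_parameters")) {
      unclass(x)
    } else if (is.data.frame(x)) {
      as.list(as.data.frame(x))
    } else if (is.list(x)) {
      lapply(unclass(x), simplify)
    } else {
      x
    }
  }
  jsonlite::write_json(simplify(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
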