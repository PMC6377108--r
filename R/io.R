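# CSV dataset reading/writing, plain-text model configuration files, and
# machine-readable fit reports.

#' Read a quantal dose-response CSV
#'
#' Expects a header row with one column per stressor dose plus `n`
#' (responders) and `N` (group size); every other column is treated as a
#' dose column, preserving order. Validation failures name the offending
#' row.
#'
#' @param path CSV file path.
#' @return a [quantal_data()] dataset.
#' @examples
#' # a synthetic 8-dose study bundled with the package
#' csv <- system.file("extdata", "synthetic_frechet_study.csv",
#'                    package = "emergentdrf")
#' read_quantal_csv(csv)
#' @export
read_quantal_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("n", "N") %in% names(df))) {
    stop("CSV must contain columns `n` and `N`", call. = FALSE)
  }
  dose_cols <- setdiff(names(df), c("n", "N"))
  if (length(dose_cols) < 1L) {
    stop("CSV must contain at least one dose column", call. = FALSE)
  }
  quantal_data(as.matrix(df[, dose_cols, drop = FALSE]),
               n = df$n, N = df$N, stressors = dose_cols)
}

#' Write a quantal dataset to CSV
#' @param data a [quantal_data()] dataset.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quantal_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a model to a plain-text configuration list
#'
#' The configuration names the model variant and its parameters with the
#' conventional symbols (`c`, `d_b`, `xi`, `eta`, `d0`, `q0..qk`, `mu`,
#' `sigma`, interaction entries as `xi_int_j_k`), plus stressor names and
#' the interaction-kernel choice for mixtures. Round-trips through
#' [model_from_config()], YAML ([write_model_yaml()]) and JSON.
#'
#' @param model a `drf_model`.
#' @return a named list suitable for YAML/JSON serialization.
#' @export
model_to_config <- function(model) {
  cfg <- list(family = model$family,
              params = as.list(model$params))
  if (!identical(model$background, "none")) cfg$background <- model$background
  if (!is.null(model$stressors)) cfg$stressors <- model$stressors
  if (!is.null(model$kernel)) cfg$kernel <- model$kernel
  cfg
}

#' Rebuild a model from a configuration list
#' @param cfg a list as produced by [model_to_config()] (or parsed from
#'   YAML/JSON).
#' @return a `drf_model`.
#' @export
model_from_config <- function(cfg) {
  if (is.null(cfg$family)) stop("config lacks a `family` field", call. = FALSE)
  p <- cfg$params
  bg <- cfg$background %||% "none"
  kern <- cfg$kernel %||% "geometric"
  get_pairs <- function(prefix) {
    nm <- grep(paste0("^", prefix, "_[0-9]+_[0-9]+$"), names(p), value = TRUE)
    if (!length(nm)) return(NULL)
    stats::setNames(as.numeric(unlist(p[nm])),
                    sub(paste0("^", prefix, "_"), "", nm))
  }
  switch(cfg$family,
    frechet = frechet_drf(xi = p$xi, eta = p$eta, d0 = p$d0 %||% 0,
                          background = bg, c = p$c %||% 0, d_b = p$d_b %||% 0),
    lognormal = lognormal_drf(mu = p$mu, sigma = p$sigma, background = bg,
                              c = p$c %||% 0),
    multistage = {
      qn <- grep("^q[0-9]+$", names(p), value = TRUE)
      qn <- qn[order(as.integer(sub("^q", "", qn)))]
      multistage_drf(as.numeric(unlist(p[qn])))
    },
    common_mode = {
      J <- length(grep("^xi_[0-9]+$", names(p)))
      common_mode_drf(
        xi = as.numeric(unlist(p[paste0("xi_", seq_len(J))])),
        eta = p$eta, d0 = p$d0 %||% 0, d_b = p$d_b %||% 0,
        xi_int = get_pairs("xi_int"),
        stressors = cfg$stressors, kernel = kern
      )
    },
    dissimilar = {
      I <- length(grep("^xi_[0-9]+$", names(p)))
      dissimilar_drf(
        xi = as.numeric(unlist(p[paste0("xi_", seq_len(I))])),
        eta = as.numeric(unlist(p[paste0("eta_", seq_len(I))])),
        d0 = as.numeric(unlist(p[paste0("d0_", seq_len(I))])),
        xi_int = get_pairs("xi_int"), d0_int = get_pairs("d0_int"),
        stressors = cfg$stressors, kernel = kern
      )
    },
    stop("unknown model family: ", cfg$family, call. = FALSE)
  )
}

#' Write / read a model configuration as YAML
#' @param model a `drf_model`.
#' @param path file path.
#' @return `path` (write) or a `drf_model` (read).
#' @export
write_model_yaml <- function(model, path) {
  yaml::write_yaml(model_to_config(model), path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  model_from_config(yaml::read_yaml(path))
}

#' Write a machine-readable fit report
#'
#' Emits the Table-1-shaped surface of one or more fits: model label,
#' GOF p-value, parameter name/value pairs, deviance, degrees of freedom,
#' convergence flag and seed. The JSON report embeds the full model
#' configuration, so re-reading it and re-evaluating the model against the
#' data reproduces the stored deviance exactly.
#'
#' @param fits a `drf_fit`, a `drf_comparison`, or a named list of
#'   `drf_fit` objects.
#' @param json optional path for the JSON report.
#' @param csv optional path for the tabular CSV report.
#' @return the report list, invisibly.
#' @export
write_report <- function(fits, json = NULL, csv = NULL) {
  if (inherits(fits, "drf_fit")) fits <- list(fit = fits)
  if (inherits(fits, "drf_comparison")) fits <- fits$fits
  fits <- Filter(function(f) inherits(f, "drf_fit"), fits)
  if (!length(fits)) stop("no successful fits to report", call. = FALSE)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  report <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    list(model = nm, family = f$model$family,
         config = model_to_config(f$model),
         estimates = as.list(f$estimates),
         Y_star = f$Y_star, m = f$m, df = f$df, p_value = f$p_value,
         converged = f$converged, seed = f$seed, adjust = f$adjust)
  })
  names(report) <- names(fits)
  if (!is.null(json)) {
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  if (!is.null(csv)) {
    tab <- do.call(rbind, lapply(report, function(r) {
      data.frame(model = r$model, family = r$family,
                 p_value = if (is.null(r$p_value) || is.na(r$p_value)) NA_real_ else r$p_value,
                 Y_star = r$Y_star, m = r$m, df = r$df,
                 converged = r$converged, seed = r$seed,
                 params = paste(names(r$estimates), "=",
                                vapply(r$estimates, format, "", digits = 17),
                                collapse = "; "),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(tab, csv, row.names = FALSE)
  }
  invisible(report)
}

#' Read a JSON fit report
#' @param path JSON report path.
#' @return the parsed report list; each entry's `config` can be passed to
#'   [model_from_config()].
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
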