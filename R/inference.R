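# Deviance-based maximum-likelihood fitting of any model in the family to
# quantal dose-group data, plotting-position count adjustment, and
# chi-square goodness-of-fit p-values.

#' Quantal dose-response dataset
#'
#' One row per dose group: one or more stressor dose columns, the number of
#' responders `n` and the group size `N`. This is the universal fitting
#' input; [read_quantal_csv()] builds one from a CSV file and
#' [simulate_quantal()] from a model.
#'
#' @param dose numeric vector (single stressor) or matrix/data frame with
#'   one column per stressor; non-negative.
#' @param n integer responders per group, `0 <= n <= N`.
#' @param N positive integer group sizes.
#' @param stressors optional stressor (dose column) names.
#' @return a data frame of class `quantal_data` with the dose columns
#'   followed by `n` and `N`; the stressor names are kept in the
#'   `"stressors"` attribute.
#' @examples
#' quantal_data(dose = c(0, 0.5, 1, 2), n = c(1, 3, 6, 9), N = rep(10, 4))
#' @export
quantal_data <- function(dose, n, N, stressors = NULL) {
  if (is.null(dim(dose))) dose <- matrix(as.numeric(dose), ncol = 1L)
  dose <- as.matrix(dose)
  storage.mode(dose) <- "double"
  if (is.null(stressors)) stressors <- colnames(dose)
  if (is.null(stressors)) {
    stressors <- if (ncol(dose) == 1L) "dose" else paste0("s", seq_len(ncol(dose)))
  }
  colnames(dose) <- stressors
  I <- nrow(dose)
  if (I < 1L) stop("at least one dose group is required", call. = FALSE)
  if (length(n) != I || length(N) != I) {
    stop("`n` and `N` must have one entry per dose group", call. = FALSE)
  }
  for (i in seq_len(I)) {
    if (any(!is.finite(dose[i, ])) || any(dose[i, ] < 0)) {
      stop(sprintf("row %d: doses must be finite and non-negative", i),
           call. = FALSE)
    }
    if (!is.finite(N[i]) || N[i] < 1) {
      stop(sprintf("row %d: N must be a positive integer", i), call. = FALSE)
    }
    if (!is.finite(n[i]) || n[i] < 0 || n[i] > N[i]) {
      stop(sprintf("row %d: need 0 <= n <= N, got n = %s, N = %s",
                   i, n[i], N[i]), call. = FALSE)
    }
  }
  out <- data.frame(dose, n = as.numeric(n), N = as.numeric(N),
                    check.names = FALSE)
  attr(out, "stressors") <- stressors
  class(out) <- c("quantal_data", "data.frame")
  out
}

#' Stressor (dose) column names of a quantal dataset
#' @param data a `quantal_data` (or compatible data frame with `n`, `N`).
#' @return character vector of dose column names.
#' @export
stressor_names <- function(data) {
  s <- attr(data, "stressors")
  if (is.null(s)) s <- setdiff(names(data), c("n", "N", "n_adj"))
  s
}

# dose input for a model from a dataset: a vector for single-stressor
# families, a column-matched matrix for mixtures
model_dose_input <- function(model, data) {
  cols <- stressor_names(data)
  if (!is.null(model$stressors)) {
    J <- length(model$stressors)
    if (all(model$stressors %in% cols)) {
      m <- as.matrix(data[, model$stressors, drop = FALSE])
    } else if (J == length(cols)) {
      m <- as.matrix(data[, cols, drop = FALSE])
    } else {
      stop("dataset columns (", paste(cols, collapse = ", "),
           ") do not match model stressors (",
           paste(model$stressors, collapse = ", "), ")", call. = FALSE)
    }
    storage.mode(m) <- "double"
    return(m)
  }
  if (length(cols) != 1L) {
    stop("single-stressor model requires exactly one dose column; found: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  as.numeric(data[[cols]])
}

#' Plotting-position adjustment of responder counts
#'
#' The count adjustment `min(max(0.25, n), N - 0.25)` that makes dose
#' groups with 0 or N responders usable in the log-based deviance: it
#' accounts for the finite binomial probability of observing at least one
#' responder (or non-responder) had the group been larger. Interior counts
#' (`1 <= n <= N - 1`) are unchanged.
#'
#' @param n responder counts.
#' @param N group sizes (positive).
#' @return adjusted counts in `[0.25, N - 0.25]`.
#' @examples
#' adjust_counts(c(0, 5, 10), c(10, 10, 10))  # 0.25, 5, 9.75
#' @export
adjust_counts <- function(n, N) {
  if (any(!is.finite(N)) || any(N < 1)) {
    stop("`N` must be >= 1 for every group", call. = FALSE)
  }
  if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N", call. = FALSE)
  pmin(pmax(0.25, n), N - 0.25)
}

#' Binomial deviance of a model against quantal data
#'
#' The deviance statistic \eqn{Y^*}, twice the log-likelihood ratio of the
#' saturated binomial model to the candidate model:
#' \deqn{Y^* = 2 \sum_i \Big[ n_i \ln\frac{n_i}{N_i \hat p_i} +
#'   (N_i - n_i) \ln\frac{N_i - n_i}{N_i (1 - \hat p_i)} \Big],}
#' evaluated with plotting-position-adjusted counts by default. Model
#' probabilities are clipped to `[1e-12, 1 - 1e-12]` inside the likelihood
#' only. \eqn{Y^* \ge 0}, with equality iff the model reproduces every
#' observed proportion.
#'
#' @param data a `quantal_data`.
#' @param model a `drf_model`.
#' @param adjust apply [adjust_counts()] first (default `TRUE`; disable to
#'   mirror analyses that used raw counts, where groups with `n = 0` or
#'   `n = N` contribute through the usual `0 log 0 = 0` convention).
#' @return the deviance \eqn{Y^*} (non-negative scalar).
#' @export
deviance_stat <- function(data, model, adjust = TRUE) {
  n <- data$n
  N <- data$N
  if (adjust) n <- adjust_counts(n, N)
  p <- clip_prob(drf_response(model, model_dose_input(model, data)))
  t1 <- ifelse(n > 0, n * log(n / (N * p)), 0)
  t2 <- ifelse(N - n > 0, (N - n) * log((N - n) / (N * (1 - p))), 0)
  2 * sum(t1 + t2)
}

#' Chi-square goodness-of-fit p-value for a deviance
#'
#' Refers the deviance \eqn{Y^*} to a chi-square distribution with
#' \eqn{I - m - 1} degrees of freedom (the extra unit accounts for the
#' assumption of a particular parametric form) and returns the upper-tail
#' probability \eqn{P(\chi^2_{I-m-1} \ge Y^*)}: large values mean the
#' model is compatible with the data. A strict, asymptotically chi-square
#' test.
#'
#' @param Y_star non-negative deviance.
#' @param I number of dose groups.
#' @param m number of *free* (fitted) parameters.
#' @return the p-value, or `NA` when `I - m - 1 < 1` (GOF undefined).
#' @examples
#' gof_pvalue(5.991, I = 5, m = 2)  # about 0.05 on 2 df
#' @export
gof_pvalue <- function(Y_star, I, m) {
  df <- I - m - 1
  if (df < 1) return(NA_real_)
  stats::pchisq(Y_star, df = df, lower.tail = FALSE)
}

# ---- bounds, transforms and the multi-start optimizer ---------------------

# default box and optimisation scale for a parameter, by naming pattern
default_bound <- function(name, max_dose) {
  if (grepl("^xi_int", name))  return(list(lower = -100, upper = 100, scale = "raw"))
  if (grepl("^d0_int", name))  return(list(lower = 0, upper = max(max_dose^2, 1), scale = "raw"))
  if (grepl("^xi", name))      return(list(lower = 1e-6, upper = 1e8, scale = "log"))
  if (grepl("^eta", name))     return(list(lower = 0.05, upper = 50, scale = "log"))
  if (identical(name, "c"))    return(list(lower = 0, upper = 0.999, scale = "raw"))
  if (identical(name, "d_b")) return(list(lower = 0, upper = 1e4, scale = "raw"))
  if (grepl("^d0", name))      return(list(lower = 0, upper = max(max_dose, 1), scale = "raw"))
  if (grepl("^q", name))       return(list(lower = 0, upper = 100, scale = "raw"))
  if (identical(name, "mu"))   return(list(lower = -30, upper = 30, scale = "raw"))
  if (identical(name, "sigma")) return(list(lower = 1e-3, upper = 100, scale = "log"))
  list(lower = -1e6, upper = 1e6, scale = "raw")
}

resolve_bounds <- function(free, bounds, max_dose) {
  out <- lapply(free, function(nm) {
    b <- default_bound(nm, max_dose)
    if (!is.null(bounds[[nm]])) {
      b$lower <- bounds[[nm]][1]
      b$upper <- bounds[[nm]][2]
      if (b$scale == "log" && b$lower <= 0) b$lower <- 1e-12
    }
    b
  })
  names(out) <- free
  out
}

#' Fit a dose-response model to quantal data by deviance minimization
#'
#' Estimates the designated free parameters of any model in the family by
#' minimizing the binomial deviance (equivalently, maximizing the binomial
#' likelihood) with multi-start bounded local optimization: starting
#' points come from a seeded Latin-hypercube over the (transformed)
#' bounds, positive parameters are optimized in log space, and each start
#' runs bounded quasi-Newton (L-BFGS-B) with a Nelder-Mead fallback. The
#' deviance surface can have sharp, narrow minima, so the multi-start is
#' not optional decoration. Deterministic given `seed`.
#'
#' @param data a [quantal_data()] dataset.
#' @param model a `drf_model` supplying the family, fixed parameter values
#'   and starting structure; its current parameter values also serve as
#'   one starting point.
#' @param free character vector naming the parameters to estimate; by
#'   default all parameters except thresholds (names beginning `d0`),
#'   which are conservatively fixed (typically at zero) unless freed
#'   explicitly.
#' @param bounds named list of `c(lower, upper)` overrides of the default
#'   boxes (defaults: scales in `[1e-6, 1e8]`, shapes in `[0.05, 50]`,
#'   `c` in `[0, 0.999]`, `d_b` in `[0, 1e4]`, thresholds in
#'   `[0, max dose]`).
#' @param start optional named vector of starting values for (a subset of)
#'   the free parameters, prepended to the start list.
#' @param seed integer seed for the start-point design (default 0).
#' @param n_starts number of Latin-hypercube starts (default 32).
#' @param adjust apply the plotting-position count adjustment
#'   (default `TRUE`).
#' @return an object of class `drf_fit`: the fitted `model`, `estimates`,
#'   free-parameter count `m`, deviance `Y_star`, degrees of freedom
#'   `df = I - m - 1`, GOF `p_value` (NA when `df < 1`), `converged`
#'   flag, `n_starts`, `seed`, and a `message` for degenerate inputs.
#' @examples
#' set.seed(1)
#' truth <- frechet_drf(xi = 1, eta = 2)
#' dat <- simulate_quantal(truth, dose = c(0.3, 0.6, 1, 1.5, 2.5),
#'                         N = 100, seed = 7)
#' drf_fit(dat, frechet_drf(xi = 0.5, eta = 1), free = c("xi", "eta"),
#'         n_starts = 8)
#' @export
drf_fit <- function(data, model, free = NULL, bounds = list(), start = NULL,
                    seed = 0, n_starts = 32, adjust = TRUE) {
  stopifnot(inherits(model, "drf_model"))
  params <- drf_params(model)
  if (is.null(free)) free <- setdiff(names(params), grep("^d0", names(params), value = TRUE))
  if (length(free) < 1L) stop("at least one free parameter is required", call. = FALSE)
  bad <- setdiff(free, names(params))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)

  dose_in <- model_dose_input(model, data)
  I <- nrow(data)
  n_adj <- if (adjust) adjust_counts(data$n, data$N) else data$n
  N <- data$N
  max_dose <- max(as.numeric(as.matrix(data[, stressor_names(data), drop = FALSE])), 1e-8)

  bnds <- resolve_bounds(free, bounds, max_dose)
  k <- length(free)
  scales <- vapply(bnds, `[[`, "", "scale")
  lo <- vapply(bnds, function(b) b$lower, 0)
  hi <- vapply(bnds, function(b) b$upper, 0)
  is_log <- scales == "log"
  to_t <- function(x) {
    x[is_log] <- log(x[is_log])
    x
  }
  from_t <- function(x) {
    x[is_log] <- exp(x[is_log])
    x
  }
  lo_t <- to_t(lo)
  hi_t <- to_t(hi)

  objective <- function(theta_t) {
    x <- from_t(theta_t)
    m2 <- set_drf_params(model, stats::setNames(x, free))
    p <- tryCatch(clip_prob(drf_response(m2, dose_in)), error = function(e) NULL)
    if (is.null(p) || any(!is.finite(p))) return(1e12)
    t1 <- ifelse(n_adj > 0, n_adj * log(n_adj / (N * p)), 0)
    t2 <- ifelse(N - n_adj > 0, (N - n_adj) * log((N - n_adj) / (N * (1 - p))), 0)
    y <- 2 * sum(t1 + t2)
    if (!is.finite(y)) 1e12 else y
  }

  # start points: seeded Latin hypercube over the transformed box, plus the
  # model's own parameter values and any user-supplied start
  design <- with_local_seed(seed, lhs::randomLHS(max(n_starts, 1L), k))
  starts <- sweep(sweep(design, 2L, hi_t - lo_t, `*`), 2L, lo_t, `+`)
  own <- to_t(pmin(pmax(params[free], lo), hi))
  starts <- rbind(own, starts)
  if (!is.null(start)) {
    s <- params[free]
    s[intersect(names(start), free)] <- start[intersect(names(start), free)]
    starts <- rbind(to_t(pmin(pmax(s, lo), hi)), starts)
  }

  best <- NULL
  for (r in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[r, ], objective, method = "L-BFGS-B",
                   lower = lo_t, upper = hi_t,
                   control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) {
      # fallback: box-clamped derivative-free search
      pen_obj <- function(tt) objective(pmin(pmax(tt, lo_t), hi_t))
      res <- tryCatch(
        if (k == 1L) {
          stats::optim(starts[r, ], pen_obj, method = "Brent",
                       lower = lo_t, upper = hi_t)
        } else {
          stats::optim(starts[r, ], pen_obj, method = "Nelder-Mead",
                       control = list(maxit = 500))
        },
        error = function(e) NULL
      )
      if (!is.null(res)) res$par <- pmin(pmax(res$par, lo_t), hi_t)
    }
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)

  estimates <- stats::setNames(from_t(best$par), free)
  fitted_model <- set_drf_params(model, estimates)
  Y_star <- deviance_stat(data, fitted_model, adjust = adjust)
  m <- length(free)
  df <- I - m - 1

  msg <- NULL
  dose_mat <- as.matrix(data[, stressor_names(data), drop = FALSE])
  if (nrow(unique(dose_mat)) == 1L) {
    msg <- "degenerate data: all groups share one dose vector"
  } else if (all(data$n == 0)) {
    msg <- "degenerate data: no responders in any group"
  } else if (all(data$n == data$N)) {
    msg <- "degenerate data: all subjects responded in every group"
  }
  converged <- is.null(msg) && identical(best$convergence, 0L)

  structure(
    list(model = fitted_model, estimates = estimates, m = m,
         Y_star = Y_star, df = df,
         p_value = gof_pvalue(Y_star, I, m),
         converged = converged, n_starts = nrow(starts), seed = seed,
         adjust = adjust, I = I, message = msg),
    class = "drf_fit"
  )
}

#' @export
print.drf_fit <- function(x, ...) {
  cat(sprintf("<%s fit: %d groups, m = %d free parameter(s)>\n",
              x$model$family, x$I, x$m))
  cat(sprintf("  Y* = %.4f on %d df, GOF p = %s\n", x$Y_star, x$df,
              if (is.na(x$p_value)) "NA (df < 1)" else format(signif(x$p_value, 4))))
  cat("  estimates:", paste(names(x$estimates), "=",
                            signif(x$estimates, 5), collapse = ", "), "\n")
  if (!x$converged) {
    cat("  NOT converged", if (!is.null(x$message)) paste0(" (", x$message, ")"), "\n")
  }
  invisible(x)
}

#' @export
coef.drf_fit <- function(object, ...) object$estimates

#' Fit several model specifications to one dataset
#'
#' Fits each specification to the same data under identical count-
#' adjustment conventions and reports one row per model. p-values are not
#' strictly comparable across model families, so the table reports; it
#' does not rank. A failing specification yields a flagged row without
#' aborting the others.
#'
#' @param data a [quantal_data()] dataset.
#' @param specs named list; each element is either a `drf_model` (fitted
#'   with default `free`) or a list with elements `model` and optionally
#'   `free`, `bounds`, `start`.
#' @param seed,n_starts,adjust passed to [drf_fit()] for every spec.
#' @return an object of class `drf_comparison`: `$fits` (list of
#'   `drf_fit` or error condition) and `$table` (one row per spec with
#'   label, p-value, Y*, m, df, convergence and parameter summary).
#' @export
compare_models <- function(data, specs, seed = 0, n_starts = 32, adjust = TRUE) {
  if (length(specs) < 1L) stop("at least one specification is required", call. = FALSE)
  if (is.null(names(specs))) names(specs) <- paste0("model", seq_along(specs))
  fits <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    if (inherits(sp, "drf_model")) sp <- list(model = sp)
    tryCatch(
      drf_fit(data, sp$model,
              free = sp$free, bounds = sp$bounds %||% list(),
              start = sp$start, seed = seed, n_starts = n_starts,
              adjust = adjust),
      error = function(e) e
    )
  })
  names(fits) <- names(specs)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "error")) {
      data.frame(model = nm, family = NA_character_, p_value = NA_real_,
                 Y_star = NA_real_, m = NA_integer_, df = NA_integer_,
                 converged = FALSE, params = paste("ERROR:", conditionMessage(f)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(model = nm, family = f$model$family, p_value = f$p_value,
                 Y_star = f$Y_star, m = f$m, df = f$df,
                 converged = f$converged,
                 params = paste(names(f$estimates), "=",
                                signif(f$estimates, 6), collapse = "; "),
                 stringsAsFactors = FALSE)
    }
  })
  structure(list(fits = fits, table = do.call(rbind, rows)),
            class = "drf_comparison")
}

#' @export
print.drf_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.drf_comparison <- function(x, ...) x$table

`%||%` <- function(a, b) if (is.null(a)) b else a
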