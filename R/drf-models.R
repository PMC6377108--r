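#' Shifted Frechet dose-response model
#'
#' Constructs the two- or three-parameter Frechet dose-response function
#' (DRF) for a single chronic stressor,
#' \deqn{F(d) = \exp\{-[(d - d_0)/\xi]^{-\eta}\}, \quad d > d_0,}
#' with response exactly 0 at and below the threshold dose \eqn{d_0}. The
#' model arises as the distribution of the critical dose \eqn{D = 1/W} when
#' the severity per unit dose \eqn{W} is Weibull distributed, the emergent
#' outcome of an autocorrelated multiplicative cause chain (see
#' [simulate_chain()]). Depending on \eqn{\eta} the curve is monotone
#' concave (\eqn{\eta \le 1}) or sigmoidal (\eqn{\eta > 1}).
#'
#' Two background-risk variants are supported:
#' \describe{
#'   \item{`"DMB"` (dissimilar-mode background)}{response mixing,
#'     \eqn{c + (1-c) F(d)}: background stressors act along their own
#'     pathway, independent of the stressor analysed.}
#'   \item{`"CMB"` (common-mode background)}{a dimensionless background
#'     "dose" \eqn{d_b} added inside the kernel,
#'     \eqn{\exp\{-[d_b + (d-d_0)/\xi]^{-\eta}\}}: background stress acts by
#'     the same mode as the stressor, so the zero-dose response is
#'     \eqn{\exp(-d_b^{-\eta})}.}
#' }
#'
#' @param xi positive scale parameter (dose units).
#' @param eta positive shape parameter (dimensionless).
#' @param d0 non-negative threshold dose (dose units); default 0.
#' @param background one of `"none"`, `"DMB"`, `"CMB"`.
#' @param c background response fraction in `[0, 1)`; used only for
#'   `background = "DMB"`.
#' @param d_b non-negative dimensionless background stress; used only for
#'   `background = "CMB"`.
#' @return an object of class `c("frechet_drf", "drf_model")`.
#' @seealso [drf_response()], [common_mode_drf()], [dissimilar_drf()]
#' @examples
#' m <- frechet_drf(xi = 0.2719, eta = 2.4126)
#' drf_response(m, c(0, 0.2719, 1))
#' @export
frechet_drf <- function(xi, eta, d0 = 0,
                        background = c("none", "DMB", "CMB"),
                        c = 0, d_b = 0) {
  background <- match.arg(background)
  stop_if_not_scalar_number(xi, "xi")
  stop_if_not_scalar_number(eta, "eta")
  stop_if_not_scalar_number(d0, "d0")
  if (xi <= 0) stop("`xi` must be > 0", call. = FALSE)
  if (eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  if (d0 < 0) stop("`d0` must be >= 0", call. = FALSE)
  params <- c(xi = xi, eta = eta, d0 = d0)
  if (background == "DMB") {
    stop_if_not_scalar_number(c, "c")
    if (c < 0 || c >= 1) stop("`c` must be in [0, 1)", call. = FALSE)
    params <- c(params, c = c)
  } else if (background == "CMB") {
    stop_if_not_scalar_number(d_b, "d_b")
    if (d_b < 0) stop("`d_b` must be >= 0", call. = FALSE)
    params <- c(params, d_b = d_b)
  }
  structure(
    list(family = "frechet", params = params, background = background),
    class = c("frechet_drf", "drf_model")
  )
}

#' Multistage (linearized) dose-response model
#'
#' The classical one-hit/multi-hit comparison model
#' \eqn{F(d) = 1 - \exp(-q_0 - q_1 d - \dots - q_k d^k)} with non-negative
#' coefficients; \eqn{q_0} carries the background response,
#' \eqn{F(0) = 1 - e^{-q_0}}.
#'
#' @param q numeric vector `c(q0, q1, ..., qk)` of non-negative
#'   coefficients, length at least 2 (degree k >= 1); the conventional
#'   two-hit model has degree 2.
#' @return an object of class `c("multistage_drf", "drf_model")`.
#' @examples
#' drf_response(multistage_drf(c(0.0486, 2.2191, 0)), 0)
#' @export
multistage_drf <- function(q = c(0, 0, 0)) {
  if (!is.numeric(q) || length(q) < 2L || anyNA(q)) {
    stop("`q` must be a numeric vector c(q0, ..., qk) with k >= 1", call. = FALSE)
  }
  if (any(q < 0)) stop("all multistage coefficients must be >= 0", call. = FALSE)
  params <- as.numeric(q)
  names(params) <- paste0("q", seq_along(q) - 1L)
  structure(
    list(family = "multistage", params = params, degree = length(q) - 1L,
         background = "none"),
    class = c("multistage_drf", "drf_model")
  )
}

#' Lognormal (probit-in-log-dose) dose-response model
#'
#' The lognormal comparison model: base response
#' \eqn{\Phi((\ln d - \mu)/\sigma)}, defined as 0 at \eqn{d = 0}. Background
#' risk is represented by response mixing \eqn{c + (1-c)\Phi(\cdot)} for
#' both `"DMB"` and `"CMB"` labels; the two labels are retained so fitted
#' rows can be reported under either naming convention, but the functional
#' form is the response-mixing one in both cases (the lognormal has no
#' natural additive "background dose" inside its kernel on the dose scale).
#'
#' @param mu log-dose location.
#' @param sigma positive log-dose spread.
#' @param background one of `"none"`, `"DMB"`, `"CMB"`.
#' @param c background response fraction in `[0, 1)`.
#' @return an object of class `c("lognormal_drf", "drf_model")`.
#' @examples
#' drf_response(lognormal_drf(mu = 0, sigma = 1), exp(1))  # pnorm(1)
#' @export
lognormal_drf <- function(mu, sigma, background = c("none", "DMB", "CMB"),
                          c = 0) {
  background <- match.arg(background)
  stop_if_not_scalar_number(mu, "mu")
  stop_if_not_scalar_number(sigma, "sigma")
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  params <- c(mu = mu, sigma = sigma)
  if (background != "none") {
    stop_if_not_scalar_number(c, "c")
    if (c < 0 || c >= 1) stop("`c` must be in [0, 1)", call. = FALSE)
    params <- c(params, c = c)
  }
  structure(
    list(family = "lognormal", params = params, background = background),
    class = c("lognormal_drf", "drf_model")
  )
}

#' Response probability of a dose-response model
#'
#' Evaluates the fitted or specified model at the given doses. For
#' single-stressor models `dose` is a numeric vector; for mixture models it
#' is a numeric matrix (or data frame) with one column per stressor, one
#' row per dose group.
#'
#' @param model a `drf_model` object.
#' @param dose doses at which to evaluate the response.
#' @param ... unused.
#' @return numeric vector of response probabilities in `[0, 1]`, one per
#'   dose (row).
#' @export
drf_response <- function(model, dose, ...) UseMethod("drf_response")

#' @export
drf_response.frechet_drf <- function(model, dose, ...) {
  dose <- as.numeric(dose)
  p <- model$params
  d_prime <- pmax((dose - p[["d0"]]) / p[["xi"]], 0)
  if (model$background == "CMB") d_prime <- d_prime + p[["d_b"]]
  base <- frechet_kernel(d_prime, p[["eta"]])
  if (model$background == "DMB") p[["c"]] + (1 - p[["c"]]) * base else base
}

#' @export
drf_response.multistage_drf <- function(model, dose, ...) {
  dose <- as.numeric(dose)
  q <- model$params
  powers <- outer(dose, seq_along(q) - 1L, `^`)  # d^0 .. d^k
  1 - exp(-as.numeric(powers %*% q))
}

#' @export
drf_response.lognormal_drf <- function(model, dose, ...) {
  dose <- as.numeric(dose)
  p <- model$params
  base <- numeric(length(dose))
  pos <- dose > 0
  base[pos] <- stats::pnorm((log(dose[pos]) - p[["mu"]]) / p[["sigma"]])
  if (model$background != "none") p[["c"]] + (1 - p[["c"]]) * base else base
}

#' Apply a dissimilar-mode background transform to base response values
#'
#' The response-mixing transform \eqn{c + (1 - c) p} used for
#' dissimilar-mode background (DMB) risk. Exposed as a standalone helper so
#' externally computed base curves can be background-adjusted; model
#' constructors apply it automatically when `background = "DMB"`.
#'
#' @param p base response probabilities in `[0, 1]`.
#' @param c background response fraction in `[0, 1)`.
#' @return adjusted probabilities `c + (1 - c) * p`.
#' @examples
#' apply_dmb(c(0, 0.5, 1), c = 0.3)
#' @export
apply_dmb <- function(p, c) {
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c >= 1) {
    stop("`c` must be a single value in [0, 1)", call. = FALSE)
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("base responses must lie in [0, 1]", call. = FALSE)
  }
  c + (1 - c) * p
}

#' @export
print.drf_model <- function(x, ...) {
  cat(sprintf("<%s dose-response model>\n", x$family))
  if (!identical(x$background, "none")) {
    cat(sprintf("  background: %s\n", x$background))
  }
  cat("  parameters:\n")
  p <- x$params
  cat(paste0("    ", names(p), " = ", signif(p, 6), collapse = "\n"), "\n")
  invisible(x)
}

# flat named parameter vector of any model (used by the fitting machinery)
#' Model parameters as a flat named vector
#' @param model a `drf_model`.
#' @return named numeric vector of all model parameters.
#' @export
drf_params <- function(model) model$params

# replace a subset of parameters by name, revalidating nothing beyond
# names (the optimizer enforces bounds); returns the updated model
set_drf_params <- function(model, theta) {
  bad <- setdiff(names(theta), names(model$params))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  model$params[names(theta)] <- as.numeric(theta)
  model
}
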