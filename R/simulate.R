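# Synthetic-data engine: the autocorrelated multiplicative cause chain that
# generates Weibull-like illness severities and Frechet critical doses, and
# binomial quantal sampling from any model in the family.

#' Simulate the autocorrelated multiplicative cause chain
#'
#' Draws illness severities from the discrete first-order model
#' \eqn{Z = C_0 \prod_{i=1}^{t} C_i}: the dose \eqn{C_0} is compounded
#' through `t` multiplicative cause sizes whose logs are stationary and
#' correlated with marginal mean `cause_log_mean`, marginal standard
#' deviation `cause_log_sd` and pairwise correlation `autocorr_rho`. Also
#' returns the severity per unit dose \eqn{W = Z / C_0} and the critical
#' dose \eqn{D = Z^*/W} for the clinical illness cutoff \eqn{Z^* = 1}
#' (arbitrary severity units), so that \eqn{Z = D \cdot W} holds draw by
#' draw.
#'
#' Correlation among cause sizes is realized by a common-factor
#' (equicorrelated) structure: each log cause size is
#' \eqn{\mu + \sigma(\sqrt{\rho}\,\varepsilon_0 +
#' \sqrt{1-\rho}\,\varepsilon_i)} with a shared shock
#' \eqn{\varepsilon_0} — the "common cause, such as aging or organ
#' damage, impacting multiple functions" — plus an idiosyncratic shock
#' per increment; every pair of log cause sizes (in particular successive
#' ones) then has correlation \eqn{\rho}. This structure, unlike a
#' short-memory autoregression whose log-sum normalizes by the CLT at any
#' \eqn{\rho}, lets the dependence survive aggregation: with
#' `autocorr_rho = 0` and many increments, log-severity is a sum of many
#' comparable independent terms and severity is asymptotically lognormal
#' (the classical independent-causes limit), whereas for strong
#' correlation the common shock dominates the log-sum. With the default
#' left-skewed Gumbel-minimum innovations the strong-correlation limit of
#' severity is exactly Weibull (a Gumbel-minimum log-severity is the
#' Weibull on the natural scale), so a Weibull describes the draws better
#' than a lognormal — the emergent behaviour the chain exists to exhibit.
#' A Gaussian chain (`innovation = "gaussian"`) is available for
#' reference but makes log-severity exactly normal at every
#' `autocorr_rho`.
#'
#' @param t positive integer number of multiplicative increments along the
#'   mode of action.
#' @param n_draws number of severities to draw.
#' @param dose_c0 positive initial dose term \eqn{C_0}.
#' @param cause_log_mean marginal mean of log cause size.
#' @param cause_log_sd positive marginal standard deviation of log cause
#'   size.
#' @param autocorr_rho correlation of (successive) log cause sizes, in
#'   `[0, 1)`.
#' @param innovation `"gumbel"` (default; standardized left-skewed
#'   Gumbel-minimum innovations) or `"gaussian"`.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return a data frame of class `severity_draws` with columns `Z`
#'   (severity), `W` (severity per unit dose) and `D` (critical dose).
#' @examples
#' draws <- simulate_chain(t = 30, n_draws = 100, dose_c0 = 2,
#'                         autocorr_rho = 0.8, seed = 1)
#' all.equal(draws$Z, 2 * draws$W)        # Z = C0 * W
#' all.equal(draws$D * draws$W, rep(1, 100))  # severity at the critical dose is Z* = 1
#' @export
simulate_chain <- function(t = 30, n_draws = 1000, dose_c0 = 1,
                           cause_log_mean = 0, cause_log_sd = 0.1,
                           autocorr_rho = 0.8,
                           innovation = c("gumbel", "gaussian"),
                           seed = 0) {
  innovation <- match.arg(innovation)
  stopifnot(t >= 1, n_draws >= 1, dose_c0 > 0, cause_log_sd > 0,
            autocorr_rho >= 0, autocorr_rho < 1)
  t <- as.integer(t)
  rho <- autocorr_rho

  # innovations standardized to mean 0, sd 1; the gumbel-minimum variant is
  # left-skewed (skewness about -1.14)
  rinnov <- function(n) {
    if (innovation == "gaussian") {
      stats::rnorm(n)
    } else {
      g <- -log(-log(stats::runif(n)))      # standard Gumbel (max)
      (0.5772156649 - g) / (pi / sqrt(6))   # negate + standardize => left skew
    }
  }

  log_z <- with_local_seed(seed, {
    common <- rinnov(n_draws)                       # shared shock per subject
    idio <- matrix(rinnov(n_draws * t), n_draws, t) # one shock per increment
    x <- cause_log_mean +
      cause_log_sd * (sqrt(rho) * common + sqrt(1 - rho) * idio)
    log(dose_c0) + rowSums(x)
  })

  Z <- exp(log_z)
  W <- Z / dose_c0
  out <- data.frame(Z = Z, W = W, D = 1 / W)
  class(out) <- c("severity_draws", "data.frame")
  out
}

#' Sample critical doses from a Weibull severity-per-unit-dose law
#'
#' Draws `n` values of the severity per unit dose
#' \eqn{W \sim \mathrm{Weibull}(k, \lambda)} and returns the critical
#' doses \eqn{D = 1/W} (illness cutoff \eqn{Z^* = 1}). By transformation
#' of variables the empirical distribution of `D` converges to the
#' Frechet dose-response function with shape \eqn{\eta = k} and scale
#' \eqn{\xi = 1/\lambda}; this inverse link between the severity law and
#' the DRF is the structural core of the model family.
#'
#' @param shape Weibull shape `k > 0`.
#' @param scale Weibull scale `lambda > 0`.
#' @param n number of draws.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return numeric vector of critical doses.
#' @examples
#' d <- critical_dose_sample(shape = 2.4, scale = 1, n = 1000, seed = 1)
#' mean(d <= 1)  # approx exp(-1)
#' @export
critical_dose_sample <- function(shape, scale, n, seed = 0) {
  stopifnot(shape > 0, scale > 0, n >= 1)
  w <- with_local_seed(seed, stats::rweibull(n, shape = shape, scale = scale))
  1 / w
}

#' Simulate a quantal dataset from any dose-response model
#'
#' Binomial sampling standing in for a dose-group animal experiment:
#' responders \eqn{n_i \sim \mathrm{Binomial}(N_i, F(d_i))} independently
#' across groups.
#'
#' @param model a `drf_model`.
#' @param dose numeric vector (single stressor) or matrix (one column per
#'   stressor, one row per group).
#' @param N group sizes, recycled across groups.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param stressors optional dose column names (defaults to the model's).
#' @return a [quantal_data()] dataset.
#' @examples
#' simulate_quantal(frechet_drf(xi = 1, eta = 2),
#'                  dose = c(0.25, 0.5, 1, 2), N = 50, seed = 3)
#' @export
simulate_quantal <- function(model, dose, N, seed = 0, stressors = NULL) {
  stopifnot(inherits(model, "drf_model"))
  if (is.null(dim(dose))) {
    if (!is.null(model$stressors) && length(model$stressors) > 1L) {
      stop("mixture models need a dose matrix with one column per stressor",
           call. = FALSE)
    }
    dose_mat <- matrix(as.numeric(dose), ncol = 1L)
  } else {
    dose_mat <- as.matrix(dose)
  }
  p <- drf_response(model, if (ncol(dose_mat) == 1L) dose_mat[, 1L] else dose_mat)
  I <- nrow(dose_mat)
  N <- rep_len(N, I)
  n <- with_local_seed(seed, stats::rbinom(I, size = N, prob = p))
  if (is.null(stressors)) {
    stressors <- if (!is.null(model$stressors)) model$stressors else colnames(dose_mat)
  }
  quantal_data(dose_mat, n = n, N = N, stressors = stressors)
}
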