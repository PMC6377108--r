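# Mixture dose-response models: common-mode dose addition with pairwise
# interaction "doses" and a shared scaled threshold, and dissimilar-mode
# response addition over interaction-adjusted effective doses.

# pairwise interaction kernel; geometric mean keeps the interaction term on
# the same order as the individual doses and vanishes when either dose is 0
interaction_kernel <- function(d_j, d_k, kernel) {
  switch(kernel,
    geometric = sqrt(d_j * d_k),
    product   = d_j * d_k,
    stop("unknown interaction kernel: ", kernel, call. = FALSE)
  )
}

# interaction coefficient matrix from flat params named xi_int_j_k (j < k)
int_matrix <- function(params, n, prefix) {
  m <- matrix(0, n, n)
  if (n < 2L) return(m)
  for (j in seq_len(n - 1L)) {
    for (k in seq((j + 1L), n)) {
      nm <- paste0(prefix, "_", j, "_", k)
      if (nm %in% names(params)) m[j, k] <- m[k, j] <- params[[nm]]
    }
  }
  m
}

as_dose_matrix <- function(dose, J, stressors = NULL) {
  if (is.data.frame(dose)) dose <- as.matrix(dose)
  if (is.null(dim(dose))) {
    dose <- if (J == 1L) matrix(dose, ncol = 1L) else matrix(dose, nrow = 1L)
  }
  if (ncol(dose) != J) {
    stop(sprintf("dose matrix has %d column(s); model expects %d stressors",
                 ncol(dose), J), call. = FALSE)
  }
  if (!is.null(stressors) && !is.null(colnames(dose)) &&
      all(stressors %in% colnames(dose))) {
    dose <- dose[, stressors, drop = FALSE]
  }
  storage.mode(dose) <- "double"
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  dose
}

#' Common-mode mixture dose-response model
#'
#' Dose-addition model for J stressors sharing a toxicological mode of
#' action: toxicity-scaled doses, pairwise interaction "doses" (positive =
#' synergism, negative = antagonism), an optional shared scaled threshold
#' and an optional common-mode background stress are summed into one scaled
#' effective dose fed to a Frechet kernel with a shared shape
#' \eqn{\eta}:
#' \deqn{F(\mathbf d) = \exp\{-[\max(\textstyle\sum_j d_j/\xi_j +
#'   \sum_{j<k} \xi_{j,k}\, g(d_j, d_k) - d_0 + d_b,\; 0)]^{-\eta}\}.}
#' The default interaction kernel is the geometric mean
#' \eqn{g(d_j, d_k) = \sqrt{d_j d_k}}, which keeps interaction terms on the
#' same order as the individual doses; the raw product is available via
#' `kernel = "product"`. Interaction terms are exactly zero whenever either
#' dose of the pair is zero. With \eqn{\eta = 1} and no interactions the
#' model coincides with the log-linear generalized-linear-model form.
#'
#' @param xi positive per-stressor scale parameters, a named or unnamed
#'   numeric vector of length J.
#' @param eta positive shared shape parameter.
#' @param d0 non-negative overall scaled threshold (dimensionless).
#' @param d_b non-negative scaled background stress (dimensionless).
#' @param xi_int pairwise interaction coefficients: a named numeric vector
#'   with names like `"1_2"` (stressor indices, j < k), any sign; omitted
#'   pairs have no interaction.
#' @param stressors character vector of stressor names (defaults to
#'   `names(xi)` or `s1, s2, ...`); used to match dose-table columns.
#' @param kernel `"geometric"` (default) or `"product"` pairwise kernel.
#' @return an object of class `c("common_mode_drf", "drf_model")`.
#' @examples
#' # benzene-toluene antagonism, shared threshold
#' m <- common_mode_drf(xi = c(benzene = 3, toluene = 30), eta = 1,
#'                      d0 = 4.2, xi_int = c("1_2" = -0.095))
#' drf_response(m, cbind(benzene = c(0, 200), toluene = c(0, 100)))
#' @export
common_mode_drf <- function(xi, eta, d0 = 0, d_b = 0, xi_int = NULL,
                            stressors = NULL,
                            kernel = c("geometric", "product")) {
  kernel <- match.arg(kernel)
  if (!is.numeric(xi) || length(xi) < 1L || any(!is.finite(xi)) || any(xi <= 0)) {
    stop("`xi` must be a vector of positive scale parameters", call. = FALSE)
  }
  stop_if_not_scalar_number(eta, "eta")
  stop_if_not_scalar_number(d0, "d0")
  stop_if_not_scalar_number(d_b, "d_b")
  if (eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  if (d0 < 0 || d_b < 0) stop("`d0` and `d_b` must be >= 0", call. = FALSE)
  J <- length(xi)
  if (is.null(stressors)) stressors <- names(xi)
  if (is.null(stressors)) stressors <- paste0("s", seq_len(J))
  if (length(stressors) != J) stop("`stressors` must have length J", call. = FALSE)
  params <- c(stats::setNames(as.numeric(xi), paste0("xi_", seq_len(J))),
              eta = eta, d0 = d0, d_b = d_b)
  if (!is.null(xi_int)) {
    if (is.null(names(xi_int))) {
      stop('`xi_int` must be named, e.g. c("1_2" = -0.095)', call. = FALSE)
    }
    idx <- strsplit(names(xi_int), "_", fixed = TRUE)
    for (i in seq_along(xi_int)) {
      jk <- sort(as.integer(idx[[i]]))
      if (length(jk) != 2L || anyNA(jk) || jk[1] < 1L || jk[2] > J || jk[1] == jk[2]) {
        stop("bad interaction pair name: ", names(xi_int)[i], call. = FALSE)
      }
      params[[paste0("xi_int_", jk[1], "_", jk[2])]] <- as.numeric(xi_int[[i]])
    }
  }
  structure(
    list(family = "common_mode", params = params, J = J,
         stressors = stressors, kernel = kernel, background = "none"),
    class = c("common_mode_drf", "drf_model")
  )
}

#' Scaled effective dose of a common-mode mixture
#'
#' The single scaled effective dose of a common-mode mixture: the sum of
#' toxicity-scaled constituent doses and pairwise interaction terms, less
#' the shared scaled threshold, plus any background stress, floored at 0.
#' Feeding this value to a unit-scale Frechet kernel gives the mixture
#' response; it is also the collapsed scalar dose of a nested common-mode
#' component inside an outer dissimilar-mode model (see
#' [nested_common_mode_dose()]).
#'
#' @param model a `common_mode_drf`.
#' @param dose numeric matrix/data frame (rows = groups, cols = stressors)
#'   or a vector for a single group.
#' @return numeric vector of non-negative scaled effective doses.
#' @export
common_mode_effective_dose <- function(model, dose) {
  stopifnot(inherits(model, "common_mode_drf"))
  d <- as_dose_matrix(dose, model$J, model$stressors)
  p <- model$params
  xi <- p[paste0("xi_", seq_len(model$J))]
  s <- as.numeric(d %*% (1 / xi))
  xm <- int_matrix(p, model$J, "xi_int")
  if (model$J >= 2L) {
    for (j in seq_len(model$J - 1L)) {
      for (k in seq((j + 1L), model$J)) {
        if (xm[j, k] != 0) {
          s <- s + xm[j, k] * interaction_kernel(d[, j], d[, k], model$kernel)
        }
      }
    }
  }
  pmax(s - p[["d0"]] + p[["d_b"]], 0)
}

#' @export
drf_response.common_mode_drf <- function(model, dose, ...) {
  frechet_kernel(common_mode_effective_dose(model, dose),
                 model$params[["eta"]])
}

#' Collapse a common-mode sub-mixture to a scalar dose
#'
#' A component of a dissimilar-mode mixture may itself be a set of
#' stressors acting by a single internal common mode; its constituent doses
#' collapse to one scalar dose-addition coordinate usable as a single dose
#' column of the outer model. Identical to
#' [common_mode_effective_dose()] of the sub-model (with the sub-model's
#' own threshold playing the role of the component threshold).
#'
#' @inheritParams common_mode_effective_dose
#' @param sub_model a `common_mode_drf` describing the internal mixture.
#' @return numeric vector: one collapsed dose per group.
#' @export
nested_common_mode_dose <- function(sub_model, dose) {
  common_mode_effective_dose(sub_model, dose)
}

#' Dissimilar-mode mixture dose-response model
#'
#' Response-addition model for I stressors acting along parallel,
#' largely independent causal pathways to a common endpoint. Each stressor
#' gets its own Frechet parameters \eqn{(\xi_i, \eta_i, d_{0,i})}; pairwise
#' interactions enter as additive adjustments to the scaled effective
#' doses, each with its own interaction threshold \eqn{d_{0\,i,k}} applied
#' to the interaction kernel value:
#' \deqn{d'_i = \max\!\big[\max(d_i - d_{0,i}, 0)/\xi_i +
#'   \textstyle\sum_{k \ne i} \xi_{i,k} \max(h(d_i, d_k) - d_{0\,i,k}, 0),
#'   \; 0\big],}
#' and the mixture response is the probability of the union of the
#' per-pathway illness events under independence,
#' \eqn{1 - \prod_i [1 - F_F(d'_i;\, \xi = 1, \eta_i)]} (the
#' inclusion-exclusion expansion collapses to the complement of the
#' product; the effective doses are already fully scaled, so the outer
#' kernels take unit scale).
#'
#' @param xi positive per-stressor scales, length I.
#' @param eta positive per-stressor shapes, length I.
#' @param d0 non-negative per-stressor threshold doses, length I
#'   (recycled).
#' @param xi_int named pairwise interaction coefficients (`"1_2"` style),
#'   any sign.
#' @param d0_int named non-negative pairwise interaction thresholds, same
#'   naming; applied to the kernel value before the coefficient.
#' @param stressors stressor names; defaults to `names(xi)` or
#'   `s1, s2, ...`.
#' @param kernel `"geometric"` (default) or `"product"` pairwise kernel.
#' @return an object of class `c("dissimilar_drf", "drf_model")`.
#' @examples
#' m <- dissimilar_drf(xi = c(benzene = 6, toluene = 30), eta = c(1, 1),
#'                     d0 = c(10, 125))
#' dissimilar_effective_doses(m, cbind(142, 0))  # (142 - 10)/6 = 22
#' @export
dissimilar_drf <- function(xi, eta, d0 = 0, xi_int = NULL, d0_int = NULL,
                           stressors = NULL,
                           kernel = c("geometric", "product")) {
  kernel <- match.arg(kernel)
  I <- length(xi)
  if (!is.numeric(xi) || I < 1L || any(xi <= 0)) {
    stop("`xi` must be positive, length I", call. = FALSE)
  }
  if (length(eta) != I || any(eta <= 0)) {
    stop("`eta` must be positive, length I", call. = FALSE)
  }
  d0 <- rep_len(d0, I)
  if (any(d0 < 0)) stop("thresholds must be >= 0", call. = FALSE)
  if (is.null(stressors)) stressors <- names(xi)
  if (is.null(stressors)) stressors <- paste0("s", seq_len(I))
  params <- c(
    stats::setNames(as.numeric(xi), paste0("xi_", seq_len(I))),
    stats::setNames(as.numeric(eta), paste0("eta_", seq_len(I))),
    stats::setNames(as.numeric(d0), paste0("d0_", seq_len(I)))
  )
  add_pairs <- function(params, x, prefix, non_negative = FALSE) {
    if (is.null(x)) return(params)
    if (is.null(names(x))) stop("interaction maps must be named", call. = FALSE)
    idx <- strsplit(names(x), "_", fixed = TRUE)
    for (i in seq_along(x)) {
      jk <- sort(as.integer(idx[[i]]))
      if (length(jk) != 2L || anyNA(jk) || jk[1] < 1L || jk[2] > I || jk[1] == jk[2]) {
        stop("bad interaction pair name: ", names(x)[i], call. = FALSE)
      }
      if (non_negative && x[[i]] < 0) {
        stop("interaction thresholds must be >= 0", call. = FALSE)
      }
      params[[paste0(prefix, "_", jk[1], "_", jk[2])]] <- as.numeric(x[[i]])
    }
    params
  }
  params <- add_pairs(params, xi_int, "xi_int")
  params <- add_pairs(params, d0_int, "d0_int", non_negative = TRUE)
  structure(
    list(family = "dissimilar", params = params, I = I,
         stressors = stressors, kernel = kernel, background = "none"),
    class = c("dissimilar_drf", "drf_model")
  )
}

#' Interaction-adjusted scaled effective doses (dissimilar mode)
#'
#' @param model a `dissimilar_drf`.
#' @param dose numeric matrix/data frame of doses (rows = groups).
#' @return numeric matrix of non-negative scaled effective doses, one
#'   column per stressor.
#' @export
dissimilar_effective_doses <- function(model, dose) {
  stopifnot(inherits(model, "dissimilar_drf"))
  d <- as_dose_matrix(dose, model$I, model$stressors)
  p <- model$params
  I <- model$I
  xm <- int_matrix(p, I, "xi_int")
  tm <- int_matrix(p, I, "d0_int")
  out <- matrix(0, nrow(d), I)
  for (i in seq_len(I)) {
    s <- pmax(d[, i] - p[[paste0("d0_", i)]], 0) / p[[paste0("xi_", i)]]
    for (k in seq_len(I)) {
      if (k != i && xm[i, k] != 0) {
        h <- interaction_kernel(d[, i], d[, k], model$kernel)
        s <- s + xm[i, k] * pmax(h - tm[i, k], 0)
      }
    }
    out[, i] <- pmax(s, 0)
  }
  colnames(out) <- model$stressors
  out
}

#' Union response of independent pathways
#'
#' Probability that at least one of I independent pathways causes illness,
#' given fully scaled effective doses: the inclusion-exclusion sum over all
#' non-empty pathway subsets, which under independence collapses to
#' \eqn{1 - \prod_i [1 - F_F(d'_i;\, \xi = 1, \eta_i, d_0 = 0)]}.
#'
#' @param d_prime non-negative scaled effective doses: a vector (one
#'   group) or matrix (rows = groups, cols = pathways).
#' @param eta per-pathway positive shape parameters, length matching the
#'   number of pathways.
#' @return numeric vector of response probabilities.
#' @examples
#' independent_union_response(c(1, 1), eta = c(2, 2))
#' @export
independent_union_response <- function(d_prime, eta) {
  if (is.null(dim(d_prime))) d_prime <- matrix(d_prime, nrow = 1L)
  if (length(eta) != ncol(d_prime)) {
    stop("`eta` must have one entry per pathway", call. = FALSE)
  }
  surv <- vapply(seq_len(ncol(d_prime)), function(i) {
    1 - frechet_kernel(d_prime[, i], eta[i])
  }, numeric(nrow(d_prime)))
  if (is.null(dim(surv))) surv <- matrix(surv, nrow = nrow(d_prime))
  1 - apply(surv, 1L, prod)
}

#' @export
drf_response.dissimilar_drf <- function(model, dose, ...) {
  dp <- dissimilar_effective_doses(model, dose)
  independent_union_response(dp, model$params[paste0("eta_", seq_len(model$I))])
}
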