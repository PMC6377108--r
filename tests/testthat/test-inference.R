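# Deviance-based fitting pipeline: count adjustment, deviance, chi-square
# goodness of fit, and the multi-start optimizer.

test_that("plotting-position adjustment clamps boundary counts only", {
  expect_equal(adjust_counts(0, 10), 0.25)
  expect_equal(adjust_counts(5, 10), 5)
  expect_equal(adjust_counts(10, 10), 9.75)
  # identity on interior counts for a range of group sizes
  for (N in c(2, 10, 48)) {
    n <- 1:(N - 1)
    expect_equal(adjust_counts(n, rep(N, N - 1)), n)
  }
  expect_error(adjust_counts(0, 0), "N")
  expect_error(adjust_counts(5, 4), "n <= N")
})

test_that("deviance matches the binomial log-likelihood-ratio closed form", {
  # saturated model: zero deviance
  dat <- quantal_data(dose = c(1, 2), n = c(3, 7), N = c(10, 10))
  # a model that reproduces the observed proportions exactly: a
  # 2-parameter lognormal through both points
  mu_sig <- solve(rbind(c(1, qnorm(0.3)), c(1, qnorm(0.7))), log(c(1, 2)))
  exact <- lognormal_drf(mu = mu_sig[1], sigma = mu_sig[2])
  expect_equal(drf_response(exact, c(1, 2)), c(0.3, 0.7), tolerance = 1e-12)
  expect_equal(deviance_stat(dat, exact), 0, tolerance = 1e-9)

  # hand-evaluated single group: n_adj = 5, N = 10, p = 0.25
  one <- quantal_data(dose = 1, n = 5, N = 10)
  m25 <- lognormal_drf(mu = qnorm(0.75), sigma = 1)  # F(1) = pnorm(-mu) = 0.25
  expect_equal(drf_response(m25, 1), 0.25)
  expect_equal(deviance_stat(one, m25),
               2 * (5 * log(5 / 2.5) + 5 * log(5 / 7.5)))

  # doubling every n and N doubles the deviance
  two <- quantal_data(dose = 1, n = 10, N = 20)
  expect_equal(deviance_stat(two, m25), 2 * deviance_stat(one, m25))
})

test_that("count adjustment keeps the deviance finite at boundary groups", {
  dat <- quantal_data(dose = c(0.1, 1, 10), n = c(0, 5, 10), N = c(10, 10, 10))
  m <- frechet_drf(xi = 1, eta = 1)
  y <- deviance_stat(dat, m, adjust = TRUE)
  expect_true(is.finite(y) && y >= 0)
  # without adjustment the 0 log 0 = 0 convention still yields finite Y*
  y2 <- deviance_stat(dat, m, adjust = FALSE)
  expect_true(is.finite(y2))
})

test_that("GOF p-value is the chi-square upper tail on I - m - 1 df", {
  expect_equal(gof_pvalue(0, I = 8, m = 2), 1)
  expect_equal(gof_pvalue(qchisq(0.95, df = 2), I = 5, m = 2), 0.05)
  expect_equal(gof_pvalue(5.991, I = 5, m = 2), 0.05, tolerance = 1e-3)
  # decreasing in Y*
  ys <- seq(0, 20, by = 2.5)
  expect_true(all(diff(gof_pvalue(ys, I = 10, m = 3)) < 0))
  # df < 1: undefined, flagged as NA
  expect_true(is.na(gof_pvalue(3, I = 3, m = 2)))
})

test_that("a one-parameter fit to a single group solves F(d; xi) = n_adj/N", {
  dat <- quantal_data(dose = 1, n = 5, N = 10)
  f <- drf_fit(dat, frechet_drf(xi = 1, eta = 2), free = "xi",
               seed = 0, n_starts = 8)
  # closed form: exp(-(d/xi)^-2) = 0.5  =>  xi = d * log(2)^(1/2)
  expect_equal(unname(f$estimates[["xi"]]), log(2)^(1 / 2), tolerance = 1e-4)
  expect_equal(f$Y_star, 0, tolerance = 1e-6)
  expect_true(is.na(f$p_value))  # df = 1 - 1 - 1 < 1
})

test_that("deviance minimization matches exhaustive grid-search binomial ML", {
  dat <- quantal_data(dose = c(0.5, 1, 2), n = c(9, 42, 81), N = rep(100, 3))
  f <- drf_fit(dat, frechet_drf(xi = 0.5, eta = 1), free = c("xi", "eta"),
               seed = 0, n_starts = 16)
  g <- oracle_grid_ml(dat, xi_grid = seq(0.5, 2, by = 0.005),
                      eta_grid = seq(0.5, 4, by = 0.005))
  expect_equal(unname(f$estimates[["xi"]]), g$xi, tolerance = 0.011)
  expect_equal(unname(f$estimates[["eta"]]), g$eta, tolerance = 0.011)
})

test_that("fits are deterministic given seed and are fixed points of refitting", {
  dat <- make_frechet_fixture(seed = 5)
  f1 <- drf_fit(dat, frechet_drf(xi = 0.4, eta = 0.9), free = c("xi", "eta"),
                seed = 3, n_starts = 12)
  f2 <- drf_fit(dat, frechet_drf(xi = 0.4, eta = 0.9), free = c("xi", "eta"),
                seed = 3, n_starts = 12)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$Y_star, f2$Y_star)

  # restarting at the optimum reproduces it
  f3 <- drf_fit(dat, f1$model, free = c("xi", "eta"), start = f1$estimates,
                seed = 3, n_starts = 12)
  expect_equal(f3$estimates, f1$estimates, tolerance = 1e-6)
  expect_lte(f3$Y_star, f1$Y_star + 1e-8)
})

test_that("parameters of a known Frechet model are recovered from simulated data", {
  truth <- c(xi = 1, eta = 2)
  dat <- make_frechet_fixture(seed = 11)
  f <- drf_fit(dat, frechet_drf(xi = 0.4, eta = 0.9), free = c("xi", "eta"),
               seed = 1, n_starts = 16)
  expect_lt(abs(f$estimates[["xi"]] - truth[["xi"]]) / truth[["xi"]], 0.15)
  expect_lt(abs(f$estimates[["eta"]] - truth[["eta"]]) / truth[["eta"]], 0.15)
  expect_true(f$converged)
  expect_equal(f$df, 8 - 2 - 1)
})

test_that("a three-parameter background fit recovers a DMB truth", {
  truth <- frechet_drf(xi = 0.27, eta = 2.4, background = "DMB", c = 0.05)
  dat <- simulate_quantal(truth, dose = c(0, 0.05, 0.1, 0.2, 0.35, 0.5, 0.9, 1.5),
                          N = 400, seed = 9)
  f <- drf_fit(dat, frechet_drf(xi = 1, eta = 1, background = "DMB", c = 0.2),
               free = c("xi", "eta", "c"), seed = 1)
  expect_lt(abs(f$estimates[["xi"]] - 0.27) / 0.27, 0.25)
  expect_lt(abs(f$estimates[["eta"]] - 2.4) / 2.4, 0.25)
  expect_equal(f$m, 3)
})

test_that("the reported GOF p is conservative; the deviance calibrates at I - m df", {
  # refit replicates simulated under a fitted model; the deviance follows
  # chi-square with I - m df, so p at the asymptotic df is uniform while
  # the reported p (strict df = I - m - 1) is stochastically smaller
  doses <- c(0.3, 0.5, 0.7, 0.9, 1.2, 1.6, 2.2, 3.0)
  base_fit <- drf_fit(make_frechet_fixture(seed = 100),
                      frechet_drf(xi = 0.5, eta = 1), free = c("xi", "eta"),
                      seed = 1, n_starts = 8)
  res <- vapply(1:60, function(r) {
    d <- simulate_quantal(base_fit$model, doses, N = 500, seed = 5000 + r)
    f <- drf_fit(d, frechet_drf(xi = 0.5, eta = 1), free = c("xi", "eta"),
                 seed = 1, n_starts = 8)
    c(Y = f$Y_star, p = f$p_value)
  }, c(Y = 0, p = 0))
  p_asym <- pchisq(res["Y", ], df = 8 - 2, lower.tail = FALSE)
  ks <- suppressWarnings(ks.test(p_asym, "punif"))
  expect_gt(ks$p.value, 0.01)
  # strict p never exceeds the asymptotic p
  expect_true(all(res["p", ] <= p_asym + 1e-12))
})

test_that("compare_models reports one row per spec and isolates failures", {
  dat <- simulate_quantal(frechet_drf(xi = 0.3, eta = 2.4,
                                      background = "DMB", c = 0.05),
                          dose = c(0, 0.05, 0.15, 0.3, 0.5, 0.8, 1.2, 2),
                          N = 300, seed = 21)
  specs <- list(
    frechet_dmb = list(model = frechet_drf(xi = 1, eta = 1,
                                           background = "DMB", c = 0.1),
                       free = c("xi", "eta", "c")),
    lognormal_dmb = list(model = lognormal_drf(mu = 0, sigma = 1,
                                               background = "DMB", c = 0.1),
                         free = c("mu", "sigma", "c")),
    multistage = multistage_drf(c(0.01, 0.1, 0.01)),
    broken = list(model = common_mode_drf(xi = c(1, 1), eta = 1))  # J mismatch
  )
  cmp <- compare_models(dat, specs, seed = 2, n_starts = 12)
  tab <- as.data.frame(cmp)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$model, names(specs))
  expect_true(all(is.finite(tab$p_value[1:3])))
  expect_match(tab$params[4], "ERROR")
  expect_true(is.na(tab$p_value[4]))

  # the same spec twice gives identical rows
  cmp2 <- compare_models(dat, specs[c(1, 1)], seed = 2, n_starts = 12)
  expect_identical(cmp2$table$Y_star[1], cmp2$table$Y_star[2])
  expect_identical(cmp2$table$params[1], cmp2$table$params[2])
})

test_that("degenerate datasets return a flagged best-effort fit", {
  dat <- quantal_data(dose = c(1, 2, 3), n = c(0, 0, 0), N = c(20, 20, 20))
  f <- drf_fit(dat, frechet_drf(xi = 1, eta = 1), free = c("xi", "eta"),
               seed = 0, n_starts = 8)
  expect_false(f$converged)
  expect_match(f$message, "degenerate")
  expect_true(is.finite(f$Y_star))

  same_dose <- quantal_data(dose = c(2, 2, 2), n = c(1, 3, 2), N = c(10, 10, 10))
  f2 <- drf_fit(same_dose, frechet_drf(xi = 1, eta = 1), free = "xi",
                seed = 0, n_starts = 8)
  expect_false(f2$converged)
  expect_match(f2$message, "one dose")
})

test_that("fitting a mixture model estimates interaction strength", {
  truth <- common_mode_drf(xi = c(3, 30), eta = 1, d0 = 4.2,
                           xi_int = c("1_2" = -0.095))
  doses <- as.matrix(expand.grid(s1 = c(0, 50, 142, 200),
                                 s2 = c(0, 14, 125, 500)))
  dat <- simulate_quantal(truth, doses, N = 200, seed = 33)
  f <- drf_fit(dat, common_mode_drf(xi = c(1, 10), eta = 1, d0 = 1,
                                    xi_int = c("1_2" = 0)),
               free = c("xi_1", "xi_2", "xi_int_1_2", "d0"),
               bounds = list(xi_int_1_2 = c(-1, 1)),
               seed = 4, n_starts = 24)
  expect_lt(f$estimates[["xi_int_1_2"]], 0)  # antagonism recovered
  expect_equal(f$m, 4)
  expect_true(is.finite(f$p_value))
})
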