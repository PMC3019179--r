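# The estimators are validated against test functions with closed-form
# variance decompositions; designs map the unit cube onto two-fold boxes,
# so oracles rescale their inputs back to [0, 1].

unit_design <- function(k, n, seed = 1) {
  build_design(stats::setNames(rep(1, k), paste0("x", seq_len(k))),
               n = n, seed = seed)
}
to_unit <- function(P) (P - 0.5) / 1.5

test_that("designs have the right geometry, ranges and determinism", {
  base <- c(p1 = 2, p2 = 0.5)
  d <- build_design(base, n = 64, seed = 9)
  expect_equal(dim(d$A), c(64, 2))
  expect_equal(dim(d$B), c(64, 2))
  for (nm in names(base)) {
    expect_gte(min(d$A[, nm], d$B[, nm]), base[[nm]] / 2)
    expect_lte(max(d$A[, nm], d$B[, nm]), base[[nm]] * 2)
  }
  d2 <- build_design(base, n = 64, seed = 9)
  expect_identical(d$A, d2$A)
  expect_error(build_design(base, n = 1), "at least 2")

  # n (k + 2) evaluations: k = 1, n = 4 -> 12 model runs
  d1 <- build_design(c(x = 1), n = 4)
  calls <- 0
  ev <- evaluate_design(d1, function(P) { calls <<- calls + nrow(P); P[, 1] })
  expect_equal(calls, 12)
})

test_that("duplicate design points produce identical outputs (purity)", {
  d <- unit_design(3, 16)
  f <- function(P) rowSums(P)
  ev <- evaluate_design(d, f)
  ev2 <- evaluate_design(d, f)
  expect_identical(ev$YA, ev2$YA)
  expect_identical(ev$YAB, ev2$YAB)
})

test_that("Ishigami indices match the closed-form decomposition", {
  o <- gsa_oracles()$ishigami
  d <- unit_design(3, 2^13, seed = 2)
  ev <- evaluate_design(d, function(P) o$fn(to_unit(P)))
  s <- sensitivity_indices(ev, d)
  expect_equal(as.numeric(s$S1[, 1]), o$S1, tolerance = 0.05)
  expect_equal(as.numeric(s$ST[, 1]), o$ST, tolerance = 0.05)
  # x3 has no first-order effect but a real total effect
  expect_lt(abs(s$S1[3, 1]), 0.05)
  expect_gt(s$ST[3, 1], 0.15)
  # estimator consistency on the oracle
  expect_true(all(s$S1[, 1] <= s$ST[, 1] + 0.05))
  expect_lte(sum(s$S1[, 1]), 1.05)
})

test_that("the additive model is purely first-order with alpha = 1", {
  o <- gsa_oracles()$additive(c(4, 2, 1))
  d <- unit_design(3, 2^12, seed = 3)
  ev <- evaluate_design(d, function(P) o$fn(to_unit(P)))
  s <- sensitivity_indices(ev, d)
  expect_equal(as.numeric(s$S1[, 1]), o$S1, tolerance = 0.05)
  expect_equal(as.numeric(s$ST[, 1]), o$ST, tolerance = 0.05)
  a <- alpha_ratio(s)
  expect_true(all(abs(a[, 1] - 1) < 0.05, na.rm = TRUE))
  # ranking by ST follows |coefficients|
  rk <- rank_parameters(s)
  expect_equal(rk$parameter, c("x1", "x2", "x3"))
})

test_that("a dummy parameter carries no sensitivity", {
  o <- gsa_oracles()$ishigami
  d <- unit_design(4, 2^13, seed = 4)   # 4th input is inert
  ev <- evaluate_design(d, function(P) o$fn(to_unit(P)[, 1:3]))
  s <- sensitivity_indices(ev, d)
  expect_lt(abs(s$S1[4, 1]), 0.02)
  expect_lt(abs(s$ST[4, 1]), 0.02)
})

test_that("alpha is clipped, masked at the noise floor, and interpretable", {
  s <- structure(list(
    S1 = matrix(c(0.4, 0, 0.5), 3, 1),
    ST = matrix(c(0.4, 0.3, 0.01), 3, 1),
    alpha = NULL, V = 1, valid = TRUE), class = "sensitivity_result")
  s$alpha <- pmin(pmax(s$S1 / s$ST, 0), 1)
  s$alpha[s$ST <= 0.02] <- NA
  a <- alpha_ratio(s)
  expect_equal(a[1, 1], 1)       # purely direct
  expect_equal(a[2, 1], 0)       # purely interactive
  expect_true(is.na(a[3, 1]))    # below the noise floor
})

test_that("the variance mask drops low-variance time points", {
  o <- gsa_oracles()$additive(c(1, 1))
  d <- unit_design(2, 256, seed = 5)
  # two output times with very different variances
  f <- function(P) cbind(o$fn(to_unit(P)), 0.01 * o$fn(to_unit(P)))
  ev <- evaluate_design(d, f)
  s <- sensitivity_indices(ev, d)
  expect_equal(mask_low_variance(s, 0)$valid, c(TRUE, TRUE))
  m1 <- mask_low_variance(s, 1)
  expect_equal(m1$valid, c(TRUE, FALSE))
  expect_true(all(is.na(m1$ST[, 2])))
  m10 <- mask_low_variance(s, 0.10)
  expect_equal(m10$valid, c(TRUE, FALSE))
})

test_that("ranking is stable across seeds for well-separated effects", {
  o <- gsa_oracles()$additive(c(5, 2.5, 1))
  top <- sapply(c(11, 12), function(sd) {
    d <- unit_design(3, 2^10, seed = sd)
    ev <- evaluate_design(d, function(P) o$fn(to_unit(P)))
    rank_parameters(sensitivity_indices(ev, d))$parameter[1:3]
  })
  expect_equal(top[, 1], top[, 2])
})

test_that("simulation failures are tolerated up to the abort threshold", {
  d <- unit_design(2, 64, seed = 6)
  f_some <- function(P) ifelse(P[, 1] > 2.05, NA_real_, P[, 1])  # none fail
  ev <- evaluate_design(d, f_some)
  expect_equal(ev$n_fail, 0)
  f_all <- function(P) rep(NA_real_, nrow(P))
  expect_error(evaluate_design(d, f_all), "failed")
})
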