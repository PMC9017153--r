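ksites <- c("site-A", "site-B", "site-C", "site-D", "no-site")

test_that("kinetic parameters order sites and round-trip through theta", {
  p <- kin_params(c("no-site" = 1e-3, "site-A" = 0.1, "site-B" = 0.01),
                  c("site-B" = 0.02, "no-site" = 10, "site-A" = 0.001),
                  background = 0.1)
  expect_equal(names(p$kon), c("site-A", "site-B", "no-site"))
  expect_equal(names(p$koff), names(p$kon))
  th <- kin_theta(p)
  expect_length(th, 7)
  p2 <- kin_params_from_theta(th, names(p$kon))
  expect_equal(p2$kon, p$kon)
  expect_equal(p2$koff, p$koff)
  expect_equal(p2$background, p$background)
  expect_error(kin_params(c("site-A" = 0.1), c("site-A" = 0.01), 0.1))
  expect_error(kin_params(c("no-site" = 0.1, "x" = 0.1),
                          c("no-site" = 0.01), 0.1))
})

test_that("kinetic designs validate their time grid", {
  pool <- c("site-A" = 0.015, "no-site" = 99)
  expect_error(kin_design(pool, 0.15, c(0, 30, 60)))          # < 4 points
  expect_error(kin_design(pool, 0.15, c(0, 60, 30, 90)))      # unsorted
  expect_error(kin_design(pool, 0.15, c(0, 30, 30, 60)))      # duplicated
  d <- kin_design(pool, 0.15, c(0, 30, 60, 120))
  expect_equal(names(d$times), c("t0", "t30", "t60", "t120"))
})

test_that("time-resolved free-protein solver satisfies the mass balance", {
  set.seed(19)
  pool <- setNames(c(0.2, 0.1, 0.05, 0.02, 99), ksites)
  for (i in 1:20) {
    p <- random_kin_params(ksites)
    prot <- exp(runif(1, log(0.05), log(5)))
    t <- exp(runif(1, log(1), log(1e4)))
    A <- solve_free_ago_t(p, pool, prot, t)
    kon <- as.numeric(p$kon); koff <- as.numeric(p$koff)
    s_oracle <- function(a) {
      u <- kon * pool * a / (kon * a + koff)
      v <- kon * pool * prot / (kon * prot + koff)
      u - v * exp(-(kon * a + koff) * t)
    }
    expect_lt(abs(prot - A - sum(s_oracle(A))), 1e-10 * prot)
    expect_true(A > 0 && A <= prot)
  }
  p <- random_kin_params(ksites)
  expect_equal(solve_free_ago_t(p, pool, 0.15, 0), 0.15)
})

test_that("free protein decreases monotonically to steady state", {
  std <- kin_study_conditions(1L)
  grid <- c(0, 10, 30, 100, 300, 1000, 3000, 7200, 2e4)
  A <- vapply(grid, function(t) {
    solve_free_ago_t(std$params, std$design$pool, std$design$protein, t)
  }, numeric(1))
  expect_true(all(diff(A) <= 1e-12))
})

test_that("predicted kinetic compositions follow the relaxation model", {
  set.seed(23)
  pool <- setNames(c(0.2, 0.1, 0.05, 0.02, 99), ksites)
  p <- random_kin_params(ksites)
  prot <- 0.5; t <- 600
  x <- predict_composition_t(p, pool, prot, t)
  A <- attr(x, "free_ago")
  kon <- as.numeric(p$kon); koff <- as.numeric(p$koff)
  u <- kon * pool * A / (kon * A + koff)
  v <- kon * pool * prot / (kon * prot + koff)
  s_oracle <- u - v * exp(-(kon * A + koff) * t)
  free <- pool - s_oracle
  x_oracle <- s_oracle + p$background * free / sum(free)
  expect_equal(as.numeric(x), unname(x_oracle), tolerance = 1e-10)
  expect_equal(sum(attr(x, "p")), 1)
  # t = 0: no specific binding, recovery proportional to the pool
  x0 <- predict_composition_t(p, pool, prot, 0)
  expect_equal(as.numeric(x0),
               unname(p$background * pool / sum(pool)))
})

test_that("kinetic cost differences equal multinomial differences", {
  std <- kin_study_conditions(1L)
  sim <- simulate_kinetic_counts(depth = 1e6, seed = 201)
  p1 <- std$params
  p2 <- kin_params(p1$kon * c(0.5, 2, 1, 1, 1), p1$koff * c(1, 1, 3, 1, 1),
                   background = p1$background * 1.2)
  probs <- function(p) {
    sapply(std$design$times, function(t) {
      attr(predict_composition_t(p, std$design$pool, std$design$protein, t),
           "p")
    })
  }
  dc_pkg <- kinetic_cost(p2, sim$counts, std$design) -
    kinetic_cost(p1, sim$counts, std$design)
  dc_oracle <- multinom_loglik(sim$counts, probs(p1)) -
    multinom_loglik(sim$counts, probs(p2))
  expect_equal(dc_pkg, dc_oracle, tolerance = 1e-8)
})

test_that("analytic kinetic gradients match finite differences", {
  set.seed(29)
  std <- kin_study_conditions(1L)
  sim <- simulate_kinetic_counts(depth = 1e6, seed = 202)
  sites <- names(std$params$kon)
  fn <- function(th) {
    kinetic_cost(kin_params_from_theta(th, sites), sim$counts, std$design)
  }
  for (i in 1:10) {
    th <- kin_theta(std$params) + rnorm(11, 0, 0.3)
    g <- kinetic_gradient(kin_params_from_theta(th, sites), sim$counts,
                          std$design)
    g_fd <- fd_gradient(fn, th)
    rel <- max(abs(unname(g) - g_fd) / pmax(abs(g_fd), 1e-3))
    expect_lt(rel, 1e-4)
  }
})

test_that("the kinetic model relaxes to the equilibrium model", {
  std <- kin_study_conditions(2L)
  p <- std$params
  pool <- std$design$pool
  prot <- std$design$protein
  x_inf <- predict_composition_t(p, pool, prot, 1e9)
  peq <- eq_params(setNames(p$koff / p$kon, names(p$kon)),
                   ago = prot, background = p$background)
  x_eq <- predict_composition(peq, pool, 1)
  expect_equal(as.numeric(x_inf), as.numeric(x_eq), tolerance = 1e-6)
})

test_that("single-start kinetic fits improve on their initialization", {
  std <- kin_study_conditions(1L)
  sim <- simulate_kinetic_counts(depth = 1e6, seed = 203)
  sites <- names(std$params$kon)
  th0 <- kin_theta(std$params) + 0.2
  fit <- fit_kinetics_single_start(sim$counts, std$design, th0)
  expect_s3_class(fit, "KinFitResult")
  expect_lte(fit$cost,
             kinetic_cost(kin_params_from_theta(th0, sites), sim$counts,
                          std$design))
  expect_gt(fit$pearson_r, 0.999)
})

test_that("estimate_kinetics reports rates plus derived dissociation constants", {
  std <- kin_study_conditions(1L)
  sim <- simulate_kinetic_counts(depth = 1e6, seed = 204)
  est <- estimate_kinetics(sim$counts, std$design, n_boot = 1, n_starts = 3,
                           seed = 31)
  expect_s3_class(est, "EstimateSummary")
  expect_equal(est$parameter,
               c(paste0("kon.", ksites), paste0("koff.", ksites),
                 "background", paste0("kd.", ksites)))
  ests <- attr(est, "estimates")
  expect_equal(ests[, "kd.site-A"],
               ests[, "koff.site-A"] / ests[, "kon.site-A"])
  est2 <- estimate_kinetics(sim$counts, std$design, n_boot = 1, n_starts = 3,
                            seed = 31)
  expect_identical(as.data.frame(est), as.data.frame(est2))
})
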