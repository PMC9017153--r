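sites4 <- c("site-A", "site-B", "site-C", "no-site")

test_that("equilibrium parameters order sites and round-trip through theta", {
  p <- eq_params(c("no-site" = 5, "site-A" = 0.02, "site-B" = 0.1),
                 ago = 2.1, background = 0.1)
  expect_equal(names(p$kd), c("site-A", "site-B", "no-site"))
  th <- eq_theta(p)
  expect_length(th, 5)
  p2 <- eq_params_from_theta(th, names(p$kd))
  expect_equal(p2$kd, p$kd)
  expect_equal(p2$ago, p$ago)
  expect_equal(p2$background, p$background)
  expect_error(eq_params(c("site-A" = 0.1), ago = 1, background = 0.1))
  expect_error(eq_params(c("no-site" = -1), ago = 1, background = 0.1))
})

test_that("equilibrium designs require a no-protein sample", {
  pool <- c("site-A" = 0.015, "no-site" = 99)
  expect_error(eq_design(pool, c(a = 0.4, b = 0.1)))
  d <- eq_design(pool, c(a = 0.4, b = 0))
  expect_equal(d$pool, pool)
  pc <- pool_site_concentrations(setNames(c(10, 90), names(pool)), 100)
  d2 <- eq_design(pc, c(a = 0.4, b = 0))
  expect_equal(unname(d2$pool), c(10, 90))
})

test_that("free-protein solver matches a bisection oracle", {
  set.seed(42)
  pool <- setNames(c(0.015, 0.015, 0.015, 99.9), sites4)
  for (i in 1:20) {
    p <- random_eq_params(sites4)
    df <- runif(1, 0.01, 1)
    A <- solve_free_ago(p, pool, df)
    total <- df * p$ago
    f <- function(a) total - a - sum(a * pool / (p$kd + a))
    oracle <- bisect_root(f, 0, total)
    expect_equal(A, oracle, tolerance = 1e-8)
    expect_lt(abs(f(A)), 1e-10 * max(total, 1e-6))
    expect_true(A > 0 && A < total)
  }
  expect_equal(solve_free_ago(random_eq_params(sites4), pool, 0), 0)
})

test_that("predicted compositions follow the binding + background model", {
  set.seed(7)
  pool <- setNames(c(0.2, 0.1, 0.05, 99), sites4)
  p <- random_eq_params(sites4)
  x <- predict_composition(p, pool, 0.4)
  A <- attr(x, "free_ago")
  s_oracle <- A * pool / (p$kd + A)
  free <- pool - s_oracle
  x_oracle <- s_oracle + p$background * free / sum(free)
  expect_equal(as.numeric(x), unname(x_oracle), tolerance = 1e-12)
  expect_equal(unname(attr(x, "s")), unname(s_oracle), tolerance = 1e-12)
  expect_true(all(attr(x, "s") <= pool))
  expect_equal(sum(attr(x, "p")), 1)
  # no protein: recovery is pure background, proportional to the pool
  x0 <- predict_composition(p, pool, 0)
  expect_equal(as.numeric(x0), unname(p$background * pool / sum(pool)))
  # background exceeding the free RNA is a model inconsistency
  pbad <- eq_params(p$kd, ago = p$ago, background = 150)
  expect_error(predict_composition(pbad, pool, 0.4), "background exceeds")
})

test_that("cost differences equal multinomial log-likelihood differences", {
  set.seed(11)
  std <- eq_study_conditions()
  sim <- simulate_equilibrium_counts(depth = 1e6, seed = 101)
  p1 <- std$params
  p2 <- eq_params(p1$kd * c(2, 0.5, 1, 1, 1), ago = p1$ago * 1.3,
                  background = p1$background * 0.8)
  probs <- function(p) {
    sapply(std$design$df, function(df) {
      attr(predict_composition(p, std$design$pool, df), "p")
    })
  }
  dc_pkg <- neg_loglik_cost(p2, sim$counts, std$design) -
    neg_loglik_cost(p1, sim$counts, std$design)
  dc_oracle <- multinom_loglik(sim$counts, probs(p1)) -
    multinom_loglik(sim$counts, probs(p2))
  expect_equal(dc_pkg, dc_oracle, tolerance = 1e-8)
})

test_that("analytic equilibrium gradients match finite differences", {
  set.seed(13)
  std <- eq_study_conditions()
  sim <- simulate_equilibrium_counts(depth = 1e6, seed = 102)
  sites <- names(std$params$kd)
  fn <- function(th) {
    neg_loglik_cost(eq_params_from_theta(th, sites), sim$counts, std$design)
  }
  for (i in 1:10) {
    th <- eq_theta(std$params) + rnorm(7, 0, 0.4)
    g <- cost_gradient(eq_params_from_theta(th, sites), sim$counts,
                       std$design)
    g_fd <- fd_gradient(fn, th)
    rel <- max(abs(unname(g) - g_fd) / pmax(abs(g_fd), 1e-3))
    expect_lt(rel, 1e-4)
  }
})

test_that("single-start fits improve on their initialization", {
  std <- eq_study_conditions()
  sim <- simulate_equilibrium_counts(depth = 1e6, seed = 103)
  sites <- names(std$params$kd)
  th_true <- eq_theta(std$params)
  th0 <- th_true + 0.3
  fit <- fit_single_start(sim$counts, eq_design(std$design$pool,
                                                std$design$df), th0)
  expect_s3_class(fit, "EqFitResult")
  expect_lte(fit$cost, neg_loglik_cost(eq_params_from_theta(th0, sites),
                                       sim$counts, std$design))
  expect_lte(fit$cost, neg_loglik_cost(std$params, sim$counts, std$design))
  expect_gt(fit$pearson_r, 0.999)
  expect_equal(dim(fit$predicted), dim(sim$counts))
  expect_error(fit_single_start(sim$counts, std$design,
                                rep(100, 7)), "outside bounds")
})

test_that("bounds mark the no-site category as weaker", {
  b <- eq_bounds(c("site-A", "no-site"))
  expect_equal(names(b$lower), c("site-A", "no-site", "ago", "background"))
  expect_gt(b$lower[["no-site"]], b$lower[["site-A"]])
  expect_gt(b$upper[["no-site"]], b$upper[["site-A"]])
})

test_that("count resampling preserves totals", {
  set.seed(5)
  cc <- c(1000, 500, 100, 9000)
  r1 <- rbnskit:::.resample_counts(cc, 0.95)
  expect_equal(sum(r1), round(0.95 * sum(cc)))
  expect_true(all(r1 <= cc))
  r2 <- rbnskit:::.resample_counts(cc, 0.95, replace = TRUE)
  expect_equal(sum(r2), round(0.95 * sum(cc)))
})

test_that("estimate_kd returns an ordered, reproducible summary", {
  std <- eq_study_conditions()
  sim <- simulate_equilibrium_counts(depth = 1e6, seed = 104)
  est <- estimate_kd(sim$counts, std$design, n_boot = 2, n_starts = 4,
                     seed = 9)
  expect_s3_class(est, "EstimateSummary")
  expect_equal(est$parameter,
               c(names(std$params$kd), "ago", "background"))
  expect_true(all(est$ci_lo <= est$median + 1e-12))
  expect_true(all(est$median <= est$ci_hi + 1e-12))
  expect_equal(nrow(attr(est, "fits")), 8L)
  expect_gte(est$n_retained[1], 1L)
  est2 <- estimate_kd(sim$counts, std$design, n_boot = 2, n_starts = 4,
                      seed = 9)
  expect_identical(as.data.frame(est), as.data.frame(est2))
  # an unsatisfiable retention threshold is reported, not silently ignored
  expect_error(estimate_kd(sim$counts, std$design, n_boot = 1, n_starts = 2,
                           retain_r = 2, seed = 9), "no fits retained")
})
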