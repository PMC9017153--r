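# Maximum-likelihood estimation of absolute K_D values.
#
# The model: in binding reaction j with dilution factor DF_j, free protein
# A_j satisfies the mass balance
#     DF_j * ago - A_j - sum_i A_j * P_i / (K_i + A_j) = 0,
# specifically bound site i is s_ij = A_j * P_i / (K_i + A_j), and the
# recovered concentration adds a non-specific term distributed in
# proportion to the free site concentrations:
#     x_ij = s_ij + background * (P_i - s_ij) / sum_k (P_k - s_kj).
# Counts per category follow a (negative) multinomial with expected
# frequencies p_ij = x_ij / sum_i x_ij; dropping data-only constants the
# negative log-likelihood is
#     f_cost = sum_j [ ln(sum_i x_ij) * sum_i reads_ij
#                      - sum_i reads_ij * ln(x_ij) ].
# Parameters (K_D per site incl. no-site, stock protein `ago`, and
# `background`) are optimized in log space with an analytic gradient that
# includes the implicit dependence of A_j on the parameters. All
# concentrations are nM.

#' Construct equilibrium model parameters
#'
#' @param kd named numeric vector of dissociation constants in nM; must
#'   include a \code{"no-site"} entry (last).
#' @param ago stock concentration of active protein (nM).
#' @param background total concentration of non-specifically recovered RNA
#'   (nM).
#' @return an object of class \code{EqParams}.
#' @export
eq_params <- function(kd, ago, background) {
  stopifnot(all(kd > 0), ago > 0, background > 0,
            "no-site" %in% names(kd))
  kd <- c(kd[names(kd) != "no-site"], kd["no-site"])
  structure(list(kd = kd, ago = unname(ago),
                 background = unname(background)),
            class = "EqParams")
}

#' Log-space parameter vector of equilibrium parameters
#'
#' theta = (log K_D1, ..., log K_Dm, log ago, log background); the inverse
#' transform is \code{\link{eq_params_from_theta}}.
#'
#' @param params an \code{\link{eq_params}}.
#' @return named numeric vector of length m + 2.
#' @export
eq_theta <- function(params) {
  c(log(params$kd), ago = log(params$ago),
    background = log(params$background))
}

#' @rdname eq_theta
#' @param theta log-space parameter vector.
#' @param site_names site labels (incl. \code{"no-site"}) for the first m
#'   entries.
#' @export
eq_params_from_theta <- function(theta, site_names) {
  m <- length(site_names)
  stopifnot(length(theta) == m + 2L)
  eq_params(setNames(exp(theta[seq_len(m)]), site_names),
            ago = exp(theta[m + 1L]), background = exp(theta[m + 2L]))
}

#' Construct an equilibrium experiment design
#'
#' @param pool a \code{\link{pool_site_concentrations}} result or a named
#'   numeric vector of pool site concentrations in nM (incl.
#'   \code{"no-site"}).
#' @param df named numeric vector of dilution factors (one per sample,
#'   values in [0, 1]); must include a no-protein sample with DF = 0.
#' @return an object of class \code{EqDesign}.
#' @export
eq_design <- function(pool, df) {
  conc <- if (inherits(pool, "PoolComposition")) pool$conc else pool
  stopifnot(all(conc >= 0), "no-site" %in% names(conc),
            all(df >= 0), all(df <= 1), any(df == 0))
  if (is.null(names(df))) names(df) <- paste0("sample", seq_along(df))
  structure(list(pool = conc, df = df), class = "EqDesign")
}

# Free-protein mass-balance residual and its derivative in A
.eq_balance <- function(A, total, P, K) {
  total - A - sum(A * P / (K + A))
}

#' Solve for the free protein concentration of one binding reaction
#'
#' Finds A in (0, DF * ago] such that
#' \code{DF*ago - A - sum_i A*P_i/(K_i + A) = 0}; the root is polished by
#' Newton steps to a residual below \code{1e-10 * max(DF*ago, 1e-6)} nM.
#'
#' @param params an \code{\link{eq_params}}.
#' @param pool named pool concentration vector (nM), same sites as
#'   \code{params$kd}.
#' @param df dilution factor of the reaction; \code{df = 0} returns 0.
#' @return free protein concentration (nM).
#' @export
solve_free_ago <- function(params, pool, df) {
  stopifnot(df >= 0)
  total <- df * params$ago
  if (total == 0) return(0)
  P <- as.numeric(pool[names(params$kd)])
  K <- as.numeric(params$kd)
  tol <- 1e-10 * max(total, 1e-6)
  f <- function(A) .eq_balance(A, total, P, K)
  root <- uniroot(f, interval = c(0, total), tol = .Machine$double.eps^0.75,
                  f.lower = total, f.upper = f(total))$root
  # Newton polish (the balance is strictly decreasing in A)
  for (it in 1:8) {
    res <- f(root)
    if (abs(res) <= tol) break
    dres <- -1 - sum(P * K / (K + root)^2)
    step <- res / dres
    cand <- root - step
    if (!is.finite(cand) || cand <= 0 || cand > total) break
    root <- cand
  }
  if (abs(f(root)) > tol) {
    stop(sprintf("free-protein solve did not converge (residual %.3e)",
                 f(root)))
  }
  root
}

#' Predicted recovered concentration of each site category
#'
#' @inheritParams solve_free_ago
#' @return named numeric vector x (nM) with attributes \code{s}
#'   (specifically bound), \code{free_ago} and \code{p} (expected
#'   frequencies).
#' @export
predict_composition <- function(params, pool, df) {
  P <- as.numeric(pool[names(params$kd)])
  K <- as.numeric(params$kd)
  A <- solve_free_ago(params, pool, df)
  s <- A * P / (K + A)
  free <- P - s
  Fsum <- sum(free)
  if (params$background > Fsum) {
    stop("model inconsistency: background exceeds total free RNA")
  }
  x <- s + params$background * free / Fsum
  names(x) <- names(params$kd)
  structure(x, s = setNames(s, names(x)), free_ago = A, p = x / sum(x))
}

#' Negative log-likelihood cost of equilibrium parameters
#'
#' Equals the negative log negative-multinomial likelihood of the counts
#' up to a data-only additive constant; depends only on the predicted
#' proportions within each sample.
#'
#' @param params an \code{\link{eq_params}}.
#' @param counts sites x samples count matrix (rows must match
#'   \code{names(params$kd)}, columns \code{names(design$df)}).
#' @param design an \code{\link{eq_design}}.
#' @return scalar cost.
#' @export
neg_loglik_cost <- function(params, counts, design) {
  .eq_cost_grad(params, counts, design, gradient = FALSE)$cost
}

#' Analytic gradient of the equilibrium cost in log-parameter space
#'
#' @inheritParams neg_loglik_cost
#' @return named numeric vector d f_cost / d theta_k, length m + 2.
#' @export
cost_gradient <- function(params, counts, design) {
  .eq_cost_grad(params, counts, design, gradient = TRUE)$grad
}

# Shared background-mixing derivative: given dS (m x npar) and the state,
# return dX (m x npar). Includes the explicit background column term.
.mix_grad <- function(dS, s, P, bg, bg_col) {
  free <- P - s
  Fsum <- sum(free)
  colsum <- colSums(dS)
  dX <- dS * (1 - bg / Fsum) +
    outer(bg * free / Fsum^2, colsum)
  dX[, bg_col] <- dX[, bg_col] + bg * free / Fsum
  dX
}

.eq_cost_grad <- function(params, counts, design, gradient = TRUE) {
  stopifnot(inherits(params, "EqParams"), inherits(design, "EqDesign"))
  sites <- names(params$kd)
  counts <- as.matrix(counts)
  if (!all(sites %in% rownames(counts))) {
    stop("count matrix rows must include all modeled sites")
  }
  counts <- counts[sites, names(design$df), drop = FALSE]
  P <- as.numeric(design$pool[sites])
  K <- as.numeric(params$kd)
  bg <- params$background
  m <- length(sites)
  npar <- m + 2L
  cost <- 0
  grad <- numeric(npar)
  penalized <- FALSE
  for (j in seq_along(design$df)) {
    reads <- counts[, j]
    DF <- design$df[j]
    A <- solve_free_ago(params, design$pool, DF)
    s <- A * P / (K + A)
    free <- P - s
    Fsum <- sum(free)
    x <- s + bg * free / Fsum
    if (any(x <= 0 & reads > 0)) {
      # infinite-cost guard: large finite penalty keeps the optimizer away
      cost <- cost + 1e12
      penalized <- TRUE
      next
    }
    pos <- x > 0
    cost <- cost + log(sum(x)) * sum(reads) -
      sum(reads[pos] * log(x[pos]))
    if (!gradient) next
    dfdx <- sum(reads) / sum(x) - ifelse(pos, reads / x, 0)
    # dS: derivative of specific binding w.r.t. each theta
    dS <- matrix(0, m, npar)
    if (DF > 0 && A > 0) {
      u <- A * P / (K + A)^2          # -dS_i/dK_i / K_i term base
      w <- K * P / (K + A)^2          # dS_i/dA
      D <- 1 + sum(P * K / (K + A)^2)
      dA <- c(K * u / D, DF * params$ago / D, 0)
      dS <- outer(w, dA)
      diag_idx <- cbind(seq_len(m), seq_len(m))
      dS[diag_idx] <- dS[diag_idx] - u * K
    }
    dX <- .mix_grad(dS, s, P, bg, bg_col = npar)
    grad <- grad + as.numeric(crossprod(dX, dfdx))
  }
  if (penalized) {
    warning("predicted concentration of zero for an observed category; ",
            "cost penalized")
  }
  names(grad) <- c(sites, "ago", "background")
  list(cost = unname(cost), grad = grad)
}

#' Default log-space box constraints for the equilibrium fit
#'
#' Physically meaningful bounds: 0.1 pM - 100 nM for site K_D, 100 pM -
#' 10,000 nM for the no-site K_D, 100 pM - 100 nM for the protein stock
#' and 5 pM - 5 nM for the background.
#'
#' @param site_names site labels incl. \code{"no-site"}.
#' @return list with \code{lower} and \code{upper} theta vectors.
#' @export
eq_bounds <- function(site_names) {
  m <- length(site_names)
  lower <- c(rep(log(1e-4), m), log(0.1), log(0.005))
  upper <- c(rep(log(100), m), log(100), log(5))
  ns <- which(site_names == "no-site")
  lower[ns] <- log(0.1); upper[ns] <- log(1e4)
  names(lower) <- names(upper) <- c(site_names, "ago", "background")
  list(lower = lower, upper = upper)
}

#' Fit equilibrium parameters from one starting point
#'
#' Bounded L-BFGS-B minimization of the cost with its analytic gradient.
#'
#' @inheritParams neg_loglik_cost
#' @param theta_init initial log-space parameter vector.
#' @param bounds list with \code{lower}/\code{upper} (default
#'   \code{\link{eq_bounds}}).
#' @param maxit iteration cap for the optimizer.
#' @return an \code{EqFitResult}: list with \code{params}, \code{cost},
#'   \code{converged}, \code{at_bounds}, \code{predicted} (counts),
#'   \code{pearson_r} and \code{theta}.
#' @export
fit_single_start <- function(counts, design, theta_init, bounds = NULL,
                             maxit = 500L) {
  sites <- rownames(counts)
  sites <- c(setdiff(sites, "no-site"), "no-site")
  if (is.null(bounds)) bounds <- eq_bounds(sites)
  if (any(theta_init < bounds$lower - 1e-9) ||
      any(theta_init > bounds$upper + 1e-9)) {
    stop("theta_init outside bounds")
  }
  theta_init <- pmin(pmax(theta_init, bounds$lower), bounds$upper)
  fn <- function(th) {
    p <- eq_params_from_theta(th, sites)
    .eq_cost_grad(p, counts, design, gradient = FALSE)$cost
  }
  gr <- function(th) {
    p <- eq_params_from_theta(th, sites)
    unname(.eq_cost_grad(p, counts, design, gradient = TRUE)$grad)
  }
  opt <- tryCatch(
    optim(theta_init, fn, gr, method = "L-BFGS-B",
          lower = bounds$lower, upper = bounds$upper,
          # factr must be tight: the cost is O(reads * log reads), so the
          # default 1e7 would stop with ridge-scale (O(1)) error left
          control = list(maxit = maxit, factr = 10)),
    error = function(e) NULL)
  if (is.null(opt)) {
    return(structure(list(params = NULL, cost = Inf, converged = FALSE,
                          at_bounds = NA, predicted = NULL,
                          pearson_r = NA_real_, theta = theta_init),
                     class = "EqFitResult"))
  }
  pars <- eq_params_from_theta(opt$par, sites)
  pred <- predicted_counts_eq(pars, counts, design)
  obs <- as.matrix(counts)[sites, names(design$df), drop = FALSE]
  r <- suppressWarnings(cor(as.numeric(pred), as.numeric(obs)))
  tol_b <- 1e-6
  at_b <- any(opt$par <= bounds$lower + tol_b | opt$par >= bounds$upper - tol_b)
  structure(list(params = pars, cost = opt$value,
                 converged = opt$convergence == 0, at_bounds = at_b,
                 predicted = pred, pearson_r = r, theta = opt$par),
            class = "EqFitResult")
}

#' Predicted counts under equilibrium parameters
#'
#' Expected frequencies scaled by each sample's sequencing depth.
#'
#' @inheritParams neg_loglik_cost
#' @return sites x samples matrix of expected counts.
#' @export
predicted_counts_eq <- function(params, counts, design) {
  sites <- names(params$kd)
  obs <- as.matrix(counts)[sites, names(design$df), drop = FALSE]
  pred <- sapply(seq_along(design$df), function(j) {
    x <- predict_composition(params, design$pool, design$df[j])
    attr(x, "p") * sum(obs[, j])
  })
  dimnames(pred) <- dimnames(obs)
  pred
}

# Average enrichment of each site over the protein-containing samples,
# used to initialize K_D as 1 / enrichment (nM).
.mean_site_enrichment <- function(counts, design) {
  sites <- rownames(counts)
  obs <- as.matrix(counts)[, names(design$df), drop = FALSE]
  poolfrac <- design$pool[sites] / sum(design$pool[sites])
  prot <- design$df > 0
  freq <- sweep(obs[, prot, drop = FALSE], 2,
                colSums(obs[, prot, drop = FALSE]), "/")
  rowMeans(freq / poolfrac)
}

#' Maximum-likelihood K_D estimation with bootstrap and multi-start
#'
#' Protocol: \code{n_boot} resamples of \code{boot_frac} of the reads of
#' every sample (without replacement), each fit from \code{n_starts}
#' jittered starting points spanning a grid of protein-stock and no-site
#' K_D initial guesses; site K_D values are initialized as the inverse of
#' their average enrichment, the background at 0.1 nM, and all guesses
#' jittered by Gaussian noise in log space. Fits with Pearson correlation
#' (predicted vs observed counts) above \code{retain_r} are pooled;
#' medians and 2.5/97.5 percentiles are reported.
#'
#' @inheritParams neg_loglik_cost
#' @param n_boot number of bootstrap resamples (default 10).
#' @param n_starts number of starting points per resample (default 100).
#' @param boot_frac fraction of reads kept per resample (default 0.95).
#' @param replace resample with replacement instead of subsampling.
#' @param retain_r Pearson retention threshold (default 0.90).
#' @param jitter_sd log-space jitter standard deviation (default 0.1).
#' @param ago_range,nosite_range initial-guess ranges (nM).
#' @param seed master seed for resampling and jitter.
#' @param maxit per-fit optimizer iteration cap.
#' @return an \code{EstimateSummary}: data.frame with parameter, median,
#'   ci_lo, ci_hi, n_retained; attribute \code{fits} holds per-fit
#'   diagnostics and \code{estimates} the retained per-fit estimates.
#' @export
estimate_kd <- function(counts, design, n_boot = 10L, n_starts = 100L,
                        boot_frac = 0.95, replace = FALSE, retain_r = 0.90,
                        jitter_sd = 0.1, ago_range = c(0.5, 25),
                        nosite_range = c(0.5, 10), seed = NULL,
                        maxit = 500L) {
  stopifnot(any(design$df == 0))
  .with_seed(seed, {
    sites <- c(setdiff(rownames(counts), "no-site"), "no-site")
    counts <- as.matrix(counts)[sites, names(design$df), drop = FALSE]
    bounds <- eq_bounds(sites)
    m <- length(sites)
    # start grid: roughly square in (ago, nosite K_D) initial guesses
    n_ago <- max(1L, round(sqrt(n_starts)))
    n_ns <- max(1L, ceiling(n_starts / n_ago))
    ago_grid <- exp(seq(log(ago_range[1]), log(ago_range[2]),
                        length.out = n_ago))
    ns_grid <- exp(seq(log(nosite_range[1]), log(nosite_range[2]),
                       length.out = n_ns))
    grid <- expand.grid(ago = ago_grid, nosite = ns_grid)[seq_len(n_starts), ]
    enr <- .mean_site_enrichment(counts, design)
    kd0 <- pmin(pmax(1 / enr, exp(bounds$lower[seq_len(m)])),
                exp(bounds$upper[seq_len(m)]))
    estimates <- list()
    diagnostics <- list()
    for (b in seq_len(n_boot)) {
      cb <- apply(counts, 2, function(cc) {
        .resample_counts(cc, boot_frac, replace = replace)
      })
      rownames(cb) <- sites
      for (st in seq_len(n_starts)) {
        th0 <- c(log(kd0), log(grid$ago[st]), log(0.1))
        th0[m] <- log(grid$nosite[st])   # no-site K_D from the grid
        th0 <- th0 + rnorm(m + 2L, 0, jitter_sd)
        th0 <- pmin(pmax(th0, bounds$lower), bounds$upper)
        fit <- fit_single_start(cb, design, th0, bounds, maxit = maxit)
        keep <- is.finite(fit$pearson_r) && fit$pearson_r > retain_r
        diagnostics[[length(diagnostics) + 1L]] <- data.frame(
          bootstrap = b, start = st, cost = fit$cost,
          converged = fit$converged, pearson_r = fit$pearson_r,
          at_bounds = fit$at_bounds, retained = keep)
        if (keep) {
          estimates[[length(estimates) + 1L]] <-
            c(fit$params$kd, ago = fit$params$ago,
              background = fit$params$background)
        }
      }
    }
    diagnostics <- do.call(rbind, diagnostics)
    if (!length(estimates)) {
      stop(sprintf(
        "no fits retained (best Pearson r = %.3f); check model/design",
        suppressWarnings(max(diagnostics$pearson_r, na.rm = TRUE))))
    }
    est <- do.call(rbind, estimates)
    .estimate_summary(est, diagnostics)
  })
}

.estimate_summary <- function(est, diagnostics) {
  s <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, median),
    ci_lo = apply(est, 2, quantile, 0.025),
    ci_hi = apply(est, 2, quantile, 0.975),
    n_retained = nrow(est), row.names = NULL)
  stopifnot(all(s$ci_lo <= s$median + 1e-12),
            all(s$median <= s$ci_hi + 1e-12))
  structure(s, class = c("EstimateSummary", "data.frame"),
            fits = diagnostics, estimates = est)
}

# Subsample (or resample) a category count vector to a fraction of its
# total: without replacement this is multivariate hypergeometric.
.resample_counts <- function(counts, frac, replace = FALSE) {
  counts <- round(counts)
  total <- sum(counts)
  depth <- round(frac * total)
  if (replace) {
    as.numeric(rmultinom(1, depth, counts / total))
  } else {
    .rmvhyper(counts, depth)
  }
}
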