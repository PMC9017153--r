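# Maximum-likelihood estimation of binding and dissociation rate
# constants from a time-resolved (pulse-chase style) binding series.
#
# For a reaction containing total protein T (nM) and pool site
# concentrations P_i, the specifically bound concentration of site i at
# time t is
#     s_i(t) = u_i - v_i * exp(-w_i t),
#     u_i = kon_i P_i A / (kon_i A + koff_i),
#     v_i = kon_i P_i T / (kon_i T + koff_i),
#     w_i = kon_i A + koff_i,
# where the free protein A(t) satisfies the mass balance
#     T - A - sum_i s_i(A, t) = 0.
# At t = 0 the balance gives A = T and s_i = 0. Non-specific recovery is
# mixed in exactly as at equilibrium:
#     x_it = s_it + background * (P_i - s_it) / sum_k (P_k - s_kt),
# and counts per time point follow a (negative) multinomial over
# categories. Gradients are analytic, including the implicit dependence
# of A on the parameters:
#     dA/dtheta = -sum_i ds_i/dtheta|_A / (1 + sum_i ds_i/dA).

#' Construct kinetic model parameters
#'
#' @param kon named vector of association rate constants (per nM per s);
#'   must include \code{"no-site"}.
#' @param koff named vector of dissociation rate constants (per s), same
#'   names as \code{kon}.
#' @param background non-specifically recovered RNA concentration (nM).
#' @return an object of class \code{KinParams}.
#' @export
kin_params <- function(kon, koff, background) {
  stopifnot(all(kon > 0), all(koff > 0), background > 0,
            "no-site" %in% names(kon),
            identical(sort(names(kon)), sort(names(koff))))
  ord <- c(setdiff(names(kon), "no-site"), "no-site")
  structure(list(kon = kon[ord], koff = koff[ord],
                 background = unname(background)),
            class = "KinParams")
}

#' Log-space parameter vector of kinetic parameters
#'
#' theta = (log kon_1..m, log koff_1..m, log background).
#'
#' @param params a \code{\link{kin_params}}.
#' @return named numeric vector of length 2m + 1.
#' @export
kin_theta <- function(params) {
  c(setNames(log(params$kon), paste0("kon.", names(params$kon))),
    setNames(log(params$koff), paste0("koff.", names(params$koff))),
    background = log(params$background))
}

#' @rdname kin_theta
#' @param theta log-space parameter vector.
#' @param site_names site labels (incl. \code{"no-site"}).
#' @export
kin_params_from_theta <- function(theta, site_names) {
  m <- length(site_names)
  stopifnot(length(theta) == 2L * m + 1L)
  kin_params(setNames(exp(theta[seq_len(m)]), site_names),
             setNames(exp(theta[m + seq_len(m)]), site_names),
             background = exp(theta[2L * m + 1L]))
}

#' Construct a kinetic experiment design
#'
#' @param pool a \code{\link{pool_site_concentrations}} result or named
#'   numeric vector of pool site concentrations (nM, incl.
#'   \code{"no-site"}).
#' @param protein total active protein concentration in the reaction (nM).
#' @param times numeric vector of sampling times in seconds (>= 4 points;
#'   should include 0).
#' @return an object of class \code{KinDesign}.
#' @export
kin_design <- function(pool, protein, times) {
  conc <- if (inherits(pool, "PoolComposition")) pool$conc else pool
  stopifnot(all(conc >= 0), "no-site" %in% names(conc), protein > 0,
            length(times) >= 4L, all(times >= 0), !is.unsorted(times),
            !anyDuplicated(times))
  names(times) <- paste0("t", times)
  structure(list(pool = conc, protein = protein, times = times),
            class = "KinDesign")
}

# s_i(A, t) and the pieces reused by the gradient
.kin_state <- function(A, P, kon, koff, Tp, t) {
  den_a <- kon * A + koff
  den_T <- kon * Tp + koff
  u <- kon * P * A / den_a
  v <- kon * P * Tp / den_T
  E <- exp(-den_a * t)
  list(s = u - v * E, u = u, v = v, E = E, den_a = den_a, den_T = den_T)
}

#' Solve for the free protein concentration at one time point
#'
#' Finds A in (0, T] with \code{T - A - sum_i s_i(A, t) = 0}. Because
#' every s_i is strictly increasing in A the balance is strictly
#' decreasing, so the root is unique; it is bracketed on (0, T] and
#' polished to a residual below \code{1e-10 * T}.
#'
#' @param params a \code{\link{kin_params}}.
#' @param pool named pool concentration vector (nM).
#' @param protein total protein concentration T (nM).
#' @param t time in seconds; \code{t = 0} returns T exactly.
#' @return free protein concentration (nM).
#' @export
solve_free_ago_t <- function(params, pool, protein, t) {
  stopifnot(t >= 0, protein > 0)
  if (t == 0) return(protein)
  P <- as.numeric(pool[names(params$kon)])
  kon <- as.numeric(params$kon)
  koff <- as.numeric(params$koff)
  f <- function(A) {
    protein - A - sum(.kin_state(A, P, kon, koff, protein, t)$s)
  }
  lo <- protein * 1e-12
  if (f(lo) <= 0) return(lo)
  root <- uniroot(f, interval = c(lo, protein),
                  tol = .Machine$double.eps^0.75)$root
  tol <- 1e-10 * protein
  for (it in 1:8) {
    res <- f(root)
    if (abs(res) <= tol) break
    st <- .kin_state(root, P, kon, koff, protein, t)
    dsdA <- kon * P * koff / st$den_a^2 + st$v * kon * t * st$E
    cand <- root + res / (1 + sum(dsdA))
    if (!is.finite(cand) || cand <= 0 || cand > protein) break
    root <- cand
  }
  root
}

#' Predicted recovered concentration of each category at one time point
#'
#' @inheritParams solve_free_ago_t
#' @return named numeric vector x (nM) with attributes \code{s},
#'   \code{free_ago} and \code{p} (expected frequencies).
#' @export
predict_composition_t <- function(params, pool, protein, t) {
  P <- as.numeric(pool[names(params$kon)])
  A <- solve_free_ago_t(params, pool, protein, t)
  st <- .kin_state(A, P, as.numeric(params$kon), as.numeric(params$koff),
                   protein, t)
  s <- st$s
  free <- P - s
  Fsum <- sum(free)
  if (params$background > Fsum) {
    stop("model inconsistency: background exceeds total free RNA")
  }
  x <- s + params$background * free / Fsum
  names(x) <- names(params$kon)
  structure(x, s = setNames(s, names(x)), free_ago = A, p = x / sum(x))
}

#' Negative log-likelihood cost of kinetic parameters
#'
#' @param params a \code{\link{kin_params}}.
#' @param counts sites x time-points count matrix (columns in the order of
#'   \code{design$times}).
#' @param design a \code{\link{kin_design}}.
#' @return scalar cost (negative log-likelihood up to a data constant).
#' @export
kinetic_cost <- function(params, counts, design) {
  .kin_cost_grad(params, counts, design, gradient = FALSE)$cost
}

#' Analytic gradient of the kinetic cost in log-parameter space
#'
#' @inheritParams kinetic_cost
#' @return named numeric vector of length 2m + 1.
#' @export
kinetic_gradient <- function(params, counts, design) {
  .kin_cost_grad(params, counts, design, gradient = TRUE)$grad
}

.kin_cost_grad <- function(params, counts, design, gradient = TRUE) {
  stopifnot(inherits(params, "KinParams"), inherits(design, "KinDesign"))
  sites <- names(params$kon)
  counts <- as.matrix(counts)
  if (!all(sites %in% rownames(counts))) {
    stop("count matrix rows must include all modeled sites")
  }
  if (ncol(counts) != length(design$times)) {
    stop("count matrix must have one column per time point")
  }
  counts <- counts[sites, , drop = FALSE]
  P <- as.numeric(design$pool[sites])
  kon <- as.numeric(params$kon)
  koff <- as.numeric(params$koff)
  Tp <- design$protein
  bg <- params$background
  m <- length(sites)
  npar <- 2L * m + 1L
  cost <- 0
  grad <- numeric(npar)
  penalized <- FALSE
  for (j in seq_along(design$times)) {
    t <- design$times[j]
    reads <- counts[, j]
    A <- solve_free_ago_t(params, design$pool, Tp, t)
    st <- .kin_state(A, P, kon, koff, Tp, t)
    s <- st$s
    free <- P - s
    Fsum <- sum(free)
    x <- s + bg * free / Fsum
    if (any(x <= 0 & reads > 0)) {
      cost <- cost + 1e12
      penalized <- TRUE
      next
    }
    pos <- x > 0
    cost <- cost + log(sum(x)) * sum(reads) -
      sum(reads[pos] * log(x[pos]))
    if (!gradient) next
    dfdx <- sum(reads) / sum(x) - ifelse(pos, reads / x, 0)
    # explicit partials at fixed A (chain-ruled to log space)
    ds_dkon <- (P * A * koff / st$den_a^2 -
                  st$E * (P * Tp * koff / st$den_T^2 - st$v * A * t)) * kon
    ds_dkoff <- (-kon * P * A / st$den_a^2 +
                   st$E * (kon * P * Tp / st$den_T^2 + st$v * t)) * koff
    ds_dA <- kon * P * koff / st$den_a^2 + st$v * kon * t * st$E
    denom <- 1 + sum(ds_dA)
    dA <- c(-ds_dkon / denom, -ds_dkoff / denom, 0)
    dS <- outer(ds_dA, dA)
    idx <- seq_len(m)
    diag_kon <- cbind(idx, idx)
    diag_koff <- cbind(idx, m + idx)
    dS[diag_kon] <- dS[diag_kon] + ds_dkon
    dS[diag_koff] <- dS[diag_koff] + ds_dkoff
    dX <- .mix_grad(dS, s, P, bg, bg_col = npar)
    grad <- grad + as.numeric(crossprod(dX, dfdx))
  }
  if (penalized) {
    warning("predicted concentration of zero for an observed category; ",
            "cost penalized")
  }
  names(grad) <- c(paste0("kon.", sites), paste0("koff.", sites),
                   "background")
  list(cost = unname(cost), grad = grad)
}

#' Default log-space box constraints for the kinetic fit
#'
#' kon: 1e-4 - 1 per nM per s (all categories); koff: 5e-4 - 20 per s for
#' sites, 5e-4 - 200 per s for the no-site category; background: 5 pM -
#' 10 nM.
#'
#' @param site_names site labels incl. \code{"no-site"}.
#' @return list with \code{lower} and \code{upper} theta vectors.
#' @export
kin_bounds <- function(site_names) {
  m <- length(site_names)
  lower <- c(rep(log(1e-4), m), rep(log(5e-4), m), log(0.005))
  upper <- c(rep(log(1), m), rep(log(20), m), log(10))
  ns <- which(site_names == "no-site")
  upper[m + ns] <- log(200)
  names(lower) <- names(upper) <-
    c(paste0("kon.", site_names), paste0("koff.", site_names), "background")
  list(lower = lower, upper = upper)
}

#' Predicted counts under kinetic parameters
#'
#' @inheritParams kinetic_cost
#' @return sites x time-points matrix of expected counts.
#' @export
predicted_counts_kin <- function(params, counts, design) {
  sites <- names(params$kon)
  obs <- as.matrix(counts)[sites, , drop = FALSE]
  pred <- sapply(seq_along(design$times), function(j) {
    x <- predict_composition_t(params, design$pool, design$protein,
                               design$times[j])
    attr(x, "p") * sum(obs[, j])
  })
  dimnames(pred) <- dimnames(obs)
  pred
}

#' Fit kinetic parameters from one starting point
#'
#' @inheritParams kinetic_cost
#' @param theta_init initial log-space parameter vector.
#' @param bounds list with \code{lower}/\code{upper} (default
#'   \code{\link{kin_bounds}}).
#' @param maxit optimizer iteration cap.
#' @return a \code{KinFitResult}: list with \code{params}, \code{cost},
#'   \code{converged}, \code{at_bounds}, \code{predicted},
#'   \code{pearson_r} and \code{theta}.
#' @export
fit_kinetics_single_start <- function(counts, design, theta_init,
                                      bounds = NULL, maxit = 500L) {
  sites <- rownames(counts)
  sites <- c(setdiff(sites, "no-site"), "no-site")
  if (is.null(bounds)) bounds <- kin_bounds(sites)
  theta_init <- pmin(pmax(theta_init, bounds$lower), bounds$upper)
  fn <- function(th) {
    p <- kin_params_from_theta(th, sites)
    .kin_cost_grad(p, counts, design, gradient = FALSE)$cost
  }
  gr <- function(th) {
    p <- kin_params_from_theta(th, sites)
    unname(.kin_cost_grad(p, counts, design, gradient = TRUE)$grad)
  }
  opt <- tryCatch(
    optim(theta_init, fn, gr, method = "L-BFGS-B",
          lower = bounds$lower, upper = bounds$upper,
          # tight factr: cost magnitude is O(reads * log reads), so the
          # default tolerance would leave O(1) likelihood units on the table
          control = list(maxit = maxit, factr = 10)),
    error = function(e) NULL)
  if (is.null(opt)) {
    return(structure(list(params = NULL, cost = Inf, converged = FALSE,
                          at_bounds = NA, predicted = NULL,
                          pearson_r = NA_real_, theta = theta_init),
                     class = "KinFitResult"))
  }
  pars <- kin_params_from_theta(opt$par, sites)
  pred <- predicted_counts_kin(pars, counts, design)
  obs <- as.matrix(counts)[sites, , drop = FALSE]
  r <- suppressWarnings(cor(as.numeric(pred), as.numeric(obs)))
  tol_b <- 1e-6
  at_b <- any(opt$par <= bounds$lower + tol_b | opt$par >= bounds$upper - tol_b)
  structure(list(params = pars, cost = opt$value,
                 converged = opt$convergence == 0, at_bounds = at_b,
                 predicted = pred, pearson_r = r, theta = opt$par),
            class = "KinFitResult")
}

# Per-site enrichment (site frequency / pool fraction) at each time point
.site_enrichment_t <- function(counts, design) {
  sites <- rownames(counts)
  poolfrac <- design$pool[sites] / sum(design$pool[sites])
  freq <- sweep(counts, 2, colSums(counts), "/")
  sweep(freq, 1, poolfrac, "/")
}

#' Maximum-likelihood rate-constant estimation with bootstrap/multi-start
#'
#' Same protocol as \code{\link{estimate_kd}}: \code{n_boot} subsamples of
#' \code{boot_frac} of each time point's reads, \code{n_starts} jittered
#' starting points each, retention of fits with predicted-versus-observed
#' Pearson correlation above \code{retain_r}. Initial guesses: each site's
#' kon from the early-time enrichment slope,
#' \code{(E(t2) - E(t1)) / ((t2 - t1) * T)}; koff as the inverse of the
#' mean late-time enrichment (so the implied K_D matches the equilibrium
#' initializer); the no-site koff at 100 per s; the background at 0.1 nM.
#' Jitter standard deviations in log space: 0.001 for rate constants,
#' 1 for the no-site koff and 0.1 for the background.
#'
#' @inheritParams kinetic_cost
#' @param n_boot number of resamples (default 10).
#' @param n_starts starting points per resample (default 100).
#' @param boot_frac fraction of reads kept per resample (default 0.95).
#' @param replace resample with replacement instead of subsampling.
#' @param retain_r Pearson retention threshold (default 0.90).
#' @param seed master seed.
#' @param maxit per-fit optimizer iteration cap.
#' @return an \code{EstimateSummary} (see \code{\link{estimate_kd}});
#'   parameters are kon and koff per site plus the background, and derived
#'   rows \code{kd.<site>} report koff/kon in nM.
#' @export
estimate_kinetics <- function(counts, design, n_boot = 10L, n_starts = 100L,
                              boot_frac = 0.95, replace = FALSE,
                              retain_r = 0.90, seed = NULL, maxit = 500L) {
  .with_seed(seed, {
    sites <- c(setdiff(rownames(counts), "no-site"), "no-site")
    counts <- as.matrix(counts)[sites, , drop = FALSE]
    bounds <- kin_bounds(sites)
    m <- length(sites)
    enr <- .site_enrichment_t(counts, design)
    # kon from the initial enrichment slope between the first two
    # available time points. At early times the recovered RNA is
    # background-dominated, so enrichment ~ 1 + (s_i/P_i) * (pool/bg):
    # converting the enrichment slope into a bound-fraction slope with
    # the background's initial guess gives kon ~ d(s_i/P_i)/dt / A with
    # A ~ total protein.
    t1 <- 1L
    t2 <- 2L
    dt <- design$times[t2] - design$times[t1]
    bg0 <- 0.1
    kon0 <- (enr[, t2] - enr[, t1]) * (bg0 / sum(design$pool)) /
      (dt * design$protein)
    kon0 <- pmin(pmax(kon0, exp(bounds$lower[seq_len(m)])),
                 exp(bounds$upper[seq_len(m)]))
    late <- which(design$times >= max(design$times) / 2)
    koff0 <- 1 / rowMeans(enr[, late, drop = FALSE])
    koff0[m] <- 100   # no-site
    koff0 <- pmin(pmax(koff0, exp(bounds$lower[m + seq_len(m)])),
                  exp(bounds$upper[m + seq_len(m)]))
    jit_sd <- c(rep(0.001, 2L * m), 0.1)
    jit_sd[2L * m] <- 1   # no-site koff
    estimates <- list()
    diagnostics <- list()
    for (b in seq_len(n_boot)) {
      cb <- apply(counts, 2, function(cc) {
        .resample_counts(cc, boot_frac, replace = replace)
      })
      rownames(cb) <- sites
      for (st in seq_len(n_starts)) {
        th0 <- c(log(kon0), log(koff0), log(0.1)) +
          rnorm(2L * m + 1L, 0, jit_sd)
        th0 <- pmin(pmax(th0, bounds$lower), bounds$upper)
        fit <- fit_kinetics_single_start(cb, design, th0, bounds,
                                         maxit = maxit)
        keep <- is.finite(fit$pearson_r) && fit$pearson_r > retain_r
        diagnostics[[length(diagnostics) + 1L]] <- data.frame(
          bootstrap = b, start = st, cost = fit$cost,
          converged = fit$converged, pearson_r = fit$pearson_r,
          at_bounds = fit$at_bounds, retained = keep)
        if (keep) {
          p <- fit$params
          estimates[[length(estimates) + 1L]] <- c(
            setNames(p$kon, paste0("kon.", sites)),
            setNames(p$koff, paste0("koff.", sites)),
            background = p$background,
            setNames(p$koff / p$kon, paste0("kd.", sites)))
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
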