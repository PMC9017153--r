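# Bench-planning calculators: active-protein titration, equilibration
# time, and pool copy-number arithmetic.

#' Fit an active-protein titration curve
#'
#' Fits the quadratic (ligand-depletion) binding equation
#' \deqn{f(r) = f_{max} (r + K_D + n - \sqrt{(r + K_D + n)^2 - 4 r n}) /
#'   (2 n)}
#' to fraction-bound measurements at molar ratios r (protein : RNA). The
#' stoichiometric equivalence point n estimates the active protein
#' fraction; in the tight-binding limit (K_D -> 0) the curve is
#' piecewise-linear with its breakpoint at r = n.
#'
#' @param r molar ratios (>= 0), at least 4 points spanning the
#'   breakpoint.
#' @param f fractions bound in [0, 1], same length as \code{r}.
#' @param start optional named list of starting values
#'   (\code{kd_app}, \code{n}, \code{fmax}).
#' @return an object of class \code{TitrationFit}: list with
#'   \code{kd_app}, \code{n}, \code{fmax}, \code{residual_norm},
#'   \code{fitted} and the underlying \code{nls} \code{fit}.
#' @export
fit_titration <- function(r, f, start = NULL) {
  stopifnot(length(r) == length(f), length(r) >= 4,
            all(r >= 0), all(f >= -1e-9), all(f <= 1 + 1e-9))
  if (all(f <= 0)) stop("degenerate titration: all fractions bound are zero")
  if (is.null(start)) {
    fmax0 <- max(f)
    # breakpoint guess: smallest r reaching ~90% of the plateau
    n0 <- suppressWarnings(min(r[f >= 0.9 * fmax0]))
    if (!is.finite(n0) || n0 <= 0) n0 <- stats::median(r[r > 0])
    start <- list(kd_app = max(n0 / 10, 1e-6), n = n0, fmax = fmax0)
  }
  # Levenberg-Marquardt on the residual function directly (nls.lm rather
  # than nlsLM): in the tight-binding limit the solution sits at the
  # kd_app lower bound where the curve's derivative diverges at r = n,
  # and the nls model object nlsLM builds there fails on a singular
  # gradient even though the least-squares problem itself is well posed.
  fit <- minpack.lm::nls.lm(
    par = c(kd_app = start$kd_app, n = start$n, fmax = start$fmax),
    lower = c(kd_app = 1e-12, n = 1e-12, fmax = 1e-12),
    fn = function(p) f - .titration_curve(r, p[1], p[2], p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!(fit$info %in% 1:4)) {
    stop("titration fit did not converge: ", fit$message,
         "\nresiduals at start: ",
         paste(signif(f - .titration_curve(r, start$kd_app, start$n,
                                           start$fmax), 3),
               collapse = ", "))
  }
  cf <- coef(fit)
  fitted_f <- .titration_curve(r, cf["kd_app"], cf["n"], cf["fmax"])
  structure(list(kd_app = unname(cf["kd_app"]), n = unname(cf["n"]),
                 fmax = unname(cf["fmax"]),
                 residual_norm = sqrt(sum((f - fitted_f)^2)),
                 fitted = unname(fitted_f), fit = fit),
            class = "TitrationFit")
}

.titration_curve <- function(r, kd_app, n, fmax) {
  fmax * (r + kd_app + n - sqrt((r + kd_app + n)^2 - 4 * r * n)) / (2 * n)
}

#' Time to reach binding equilibrium
#'
#' Computes the equilibration rate constant
#' \code{k_eq = k_on * conc_protein * conc_site + k_off}, the half-life
#' \code{t_half = ln(2) / k_eq}, and the conservative equilibration time
#' of five half-lives \code{T = 5 * t_half} (analytically 1 - 2^-5 =
#' 96.875\% completion). The default k_eq expression multiplies two
#' concentrations and is therefore not dimensionally standard, but at
#' picomolar concentrations its first term is numerically negligible and
#' it is the conventional planning formula; set
#' \code{pseudo_first_order = TRUE} for the dimensionally consistent
#' relaxation rate \code{k_on * (conc_protein + conc_site) + k_off}.
#'
#' @param k_on association rate constant (per M per s).
#' @param k_off dissociation rate constant (per s).
#' @param conc_protein protein concentration (M).
#' @param conc_site binding-site concentration (M).
#' @param pseudo_first_order use the pseudo-first-order relaxation rate.
#' @return list with \code{k_eq} (per s), \code{t_half} (s), \code{T}
#'   (s) and \code{infinite} (TRUE when k_eq = 0, with T = Inf).
#' @export
equilibration_time <- function(k_on, k_off, conc_protein, conc_site,
                               pseudo_first_order = FALSE) {
  stopifnot(k_on >= 0, k_off >= 0, conc_protein >= 0, conc_site >= 0)
  k_eq <- if (pseudo_first_order) {
    k_on * (conc_protein + conc_site) + k_off
  } else {
    k_on * conc_protein * conc_site + k_off
  }
  if (k_eq == 0) {
    return(list(k_eq = 0, t_half = Inf, T = Inf, infinite = TRUE))
  }
  t_half <- log(2) / k_eq
  list(k_eq = k_eq, t_half = t_half, T = 5 * t_half, infinite = FALSE)
}

#' Expected copies of a specific k-mer in a random pool
#'
#' A pool of \code{amount_pmol} picomoles of oligonucleotides with an
#' L-nt random region contains on average
#' \code{amount_pmol * 1e-12 * N_A * (L - k + 1) / 4^k} copies of any
#' given k-mer ((L - k + 1) windows per molecule, each matching with
#' probability 4^-k).
#'
#' @param amount_pmol pool amount in pmol.
#' @param random_length random-region length L (nt).
#' @param k motif length (<= L).
#' @return expected copy number (numeric).
#' @export
pool_copy_number <- function(amount_pmol, random_length, k) {
  stopifnot(amount_pmol >= 0, random_length >= 1, k >= 1,
            k <= random_length)
  amount_pmol * 1e-12 * .AVOGADRO * (random_length - k + 1) / 4^k
}
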