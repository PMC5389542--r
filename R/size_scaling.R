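# RNA size-scaling models: the radius-of-gyration power law Rg = a * N^nu,
# sphere-diameter conversion, nucleoid-penetrance classification, the
# power calculation that sets the selected pixel fraction F_T, and the
# lower bound on the Hfq-bound sRNA fraction.

#' Construct a radius-of-gyration power-law model
#'
#' Either fit one with [fit_power_law()] or build one directly from known
#' parameters (e.g. a = 3.66 Angstrom, nu = 0.50 for the general RNA fit).
#'
#' @param a Pre-factor in Angstrom (> 0).
#' @param nu Scaling exponent (dimensionless); ~1/3 for compact folds,
#'   0.5 for an ideal chain, ~0.6 for a self-avoiding chain.
#' @param a_sd,nu_sd Parameter standard deviations (NA if unknown).
#' @param adj_r2 Adjusted R-squared of the fit (NA if unknown).
#' @param n_points Number of points behind the fit (NA if unknown).
#' @return Object of class `rg_model`.
#' @export
rg_model <- function(a, nu, a_sd = NA_real_, nu_sd = NA_real_,
                     adj_r2 = NA_real_, n_points = NA_integer_) {
  stopifnot(a > 0)
  structure(list(a = a, nu = nu, a_sd = a_sd, nu_sd = nu_sd,
                 adj_r2 = adj_r2, n_points = n_points),
            class = "rg_model")
}

#' @export
print.rg_model <- function(x, ...) {
  cat(sprintf("<rg_model> Rg = a * N^nu, a = %.4g +/- %.3g A, nu = %.4g +/- %.3g (adj R2 = %.3g, n = %s)\n",
              x$a, x$a_sd, x$nu, x$nu_sd, x$adj_r2,
              ifelse(is.na(x$n_points), "?", x$n_points)))
  invisible(x)
}

#' Fit the power law Rg = a * N^nu by Levenberg-Marquardt
#'
#' Nonlinear least squares in linear (untransformed) Rg space. Parameter
#' standard deviations come from the covariance of the fit,
#' `s^2 (J'J)^-1`; adjusted R-squared uses p = 2 parameters. The fit is
#' deterministic given the data and the initial guess.
#'
#' @param data data.frame with columns `N` (nucleotides) and `rg`
#'   (Angstrom); at least 3 points with distinct N.
#' @param start Initial guess, `c(a, nu)` (default `c(1, 0.5)`).
#' @param max_iter,tol LM iteration controls.
#' @return An `rg_model` with `a`, `nu`, `a_sd`, `nu_sd`, `adj_r2`,
#'   `n_points`, plus `fitted`, `residuals` and `rss`.
#' @export
fit_power_law <- function(data, start = c(1, 0.5), max_iter = 200L,
                          tol = 1e-12) {
  stopifnot(is.data.frame(data), all(c("N", "rg") %in% names(data)))
  N <- as.numeric(data$N); rg <- as.numeric(data$rg)
  if (length(N) < 3) stop("need at least 3 points to fit and estimate SDs")
  if (length(unique(N)) < 2) stop("need at least 2 distinct N values")
  stopifnot(all(N >= 1), all(rg > 0))
  theta <- start
  lambda <- 1e-3
  resid_fn <- function(th) rg - th[1] * N^th[2]
  rss <- sum(resid_fn(theta)^2)
  for (it in seq_len(max_iter)) {
    a <- theta[1]; nu <- theta[2]
    f <- a * N^nu
    J <- cbind(N^nu, a * N^nu * log(N))     # d f / d(a, nu)
    r <- rg - f
    g <- crossprod(J, r)
    H <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:50) {
      A <- H + lambda * diag(diag(H), nrow = 2)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- theta + as.numeric(delta)
      rss_new <- sum(resid_fn(cand)^2)
      if (is.finite(rss_new) && rss_new <= rss) {
        theta <- cand
        lambda <- max(lambda / 10, 1e-12)
        improved <- rss - rss_new
        rss <- rss_new
        step_ok <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) break
    if (improved <= tol * max(rss, 1e-30) &&
        sqrt(sum(delta^2)) <= 1e-10 * (1 + sqrt(sum(theta^2)))) break
  }
  a <- theta[1]; nu <- theta[2]
  if (!is.finite(a) || !is.finite(nu) || a <= 0)
    stop(sprintf("power-law fit failed to converge (a = %g, nu = %g, rss = %g)",
                 a, nu, rss))
  n <- length(N)
  J <- cbind(N^nu, a * N^nu * log(N))
  s2 <- rss / (n - 2)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e)
    stop("singular fit: cannot estimate parameter covariance"))
  tss <- sum((rg - mean(rg))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2 - 1)
  out <- rg_model(a, nu, a_sd = sqrt(cov[1, 1]), nu_sd = sqrt(cov[2, 2]),
                  adj_r2 = adj_r2, n_points = n)
  out$fitted <- a * N^nu
  out$residuals <- rg - out$fitted
  out$rss <- rss
  out
}

#' Predict the radius of gyration for an RNA of N nucleotides
#'
#' @param model An `rg_model`.
#' @param N Length in nucleotides (vectorized, >= 1).
#' @param digits Optional rounding of the reported value (reports in the
#'   literature quote 1 decimal); `NULL` returns full precision.
#' @return Predicted Rg in Angstrom.
#' @export
predict_rg <- function(model, N, digits = NULL) {
  stopifnot(inherits(model, "rg_model"), all(N >= 1))
  out <- model$a * N^model$nu
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Sphere diameter equivalent of a radius of gyration
#'
#' For a uniform solid sphere, `Rg^2 = (3/5) R^2`, so the diameter is
#' `2 * sqrt(5/3) * Rg`.
#'
#' @param rg Radius of gyration in Angstrom (> 0, vectorized).
#' @param digits Optional rounding; `NULL` returns full precision.
#' @return Diameter in Angstrom.
#' @export
sphere_diameter <- function(rg, digits = NULL) {
  stopifnot(all(rg > 0))
  out <- 2 * sqrt(5 / 3) * rg
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Classify expected nucleoid penetrance from RNA size
#'
#' RNAs with Rg below ~80 Angstrom localize in the nucleoid as readily as
#' a uniformly distributed signal; RNAs at or above the full-length
#' untranslated reporter mRNA benchmark (114.3 Angstrom) are strongly
#' excluded; sizes between are intermediate. Boundaries are configurable.
#'
#' @param rg Radius of gyration in Angstrom (vectorized).
#' @param high_below Upper Rg bound for high penetrance (default 80).
#' @param low_at_least Lower Rg bound for low penetrance (default 114.3).
#' @return Factor with levels `high`, `intermediate`, `low`.
#' @export
penetrance_class <- function(rg, high_below = 80, low_at_least = 114.3) {
  stopifnot(all(rg > 0), high_below < low_at_least)
  out <- ifelse(rg < high_below, "high",
                ifelse(rg >= low_at_least, "low", "intermediate"))
  factor(out, levels = c("high", "intermediate", "low"))
}

# required sample size of a two-sided one-sample proportion test (normal
# approximation) to detect p0 -> p1 at the given alpha and power
prop_test_n <- function(p0, p1, alpha, power) {
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  ((za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1))) / (p1 - p0))^2
}

#' Power calculation for the selected pixel fraction F_T
#'
#' Chooses the fraction of highest-intensity pixels to select per channel
#' so that the resulting number of selected reference pixels,
#' `n(F) = F * n_cells * pixels_per_cell`, is just large enough for a
#' two-sided one-sample proportion test (normal approximation) to detect,
#' at the given alpha and power, a shift of the observed overlap away from
#' the null proportion `p0 = F` by `effect_fraction` of the maximal
#' possible shift on either side (decrease: `p1 = F - effect_fraction*F`;
#' increase: `p1 = F + effect_fraction*(1 - F)`). Each side is solved as a
#' fixed point by bisection on (0.001, 0.5) to 1e-5 and the larger
#' required fraction is returned. With the defaults (alpha 0.05, power
#' 0.8, 30 cells of 300 pixels, 30% effect) the result is ~0.0886-0.09,
#' conventionally rounded to 0.1.
#'
#' @param alpha Type-I error (default 0.05).
#' @param power 1 - type-II error (default 0.8).
#' @param n_cells Number of cells measured (default 30).
#' @param pixels_per_cell Pixels per cell (default 300).
#' @param effect_fraction Detectable shift as a fraction of the maximal
#'   shift (default 0.3).
#' @return The required selected fraction F_T, with attribute `sides`
#'   giving the per-side solutions.
#' @export
selected_fraction_power <- function(alpha = 0.05, power = 0.8,
                                    n_cells = 30, pixels_per_cell = 300,
                                    effect_fraction = 0.3) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            effect_fraction > 0, effect_fraction < 1,
            n_cells >= 1, pixels_per_cell >= 1)
  total <- n_cells * pixels_per_cell
  gap <- function(f, side) {
    p1 <- if (side == "decrease") f - effect_fraction * f
    else f + effect_fraction * (1 - f)
    f * total - prop_test_n(f, p1, alpha, power)
  }
  solve_side <- function(side) {
    lo <- 0.001; hi <- 0.5
    if (gap(lo, side) >= 0) return(lo)       # constraint met everywhere
    if (gap(hi, side) < 0)
      stop("no selected fraction in (0.001, 0.5) satisfies the power requirement")
    while (hi - lo > 1e-5) {
      mid <- (lo + hi) / 2
      if (gap(mid, side) >= 0) hi <- mid else lo <- mid
    }
    hi
  }
  sides <- c(decrease = solve_side("decrease"), increase = solve_side("increase"))
  structure(max(sides), sides = sides)
}

#' Lower bound on the Hfq-bound fraction of an sRNA
#'
#' Steady-state protection model: Hfq-bound sRNA is protected from
#' degradation while free sRNA degrades identically in wild-type and
#' deletion strains, so the sRNA level in the `hfq` deletion equals the
#' wild-type free pool. A concentration ratio `r` (deletion / wild-type)
#' therefore implies that at least `1 - r` of the wild-type sRNA was
#' Hfq-bound: a two-fold decrease (r = 0.5) implies >= 50% bound.
#'
#' @param r Concentration ratio deletion/wild-type (> 0). Ratios above 1
#'   imply no bound (returns 0 with a warning).
#' @return The bound-fraction lower bound in `[0, 1]`.
#' @export
hfq_bound_lower_bound <- function(r) {
  if (any(r <= 0)) stop("concentration ratio must be positive")
  out <- 1 - r
  if (any(r > 1)) {
    warning("ratio > 1: concentration rose without Hfq; no bound implied")
    out[r > 1] <- 0
  }
  out
}
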