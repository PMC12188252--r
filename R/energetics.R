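# Closed-form reduced energies for separated Gaussian bumps.
#
# Raw convention: the continuum energy is
#   E[y] = integral of (Eb/2) y''^2 + (K/2) (y - yhat)^m dS,
# and the small-slope excess length is (1/2) integral y'^2 dS = 2*delta_raw.
# For a single bump y = a exp(-S^2/sigma^2) the integrals evaluate to
#   bending      = c_b * a^2 / sigma^3,   c_b = (3/2) sqrt(pi/2)
#   excess length= c_l * a^2 / sigma,     c_l = sqrt(pi/8)
#   interaction  = c_i(m) * a^m * sigma,  c_i(m) = sqrt(pi/m).
# Reduced convention (the solver's): constants are absorbed so that
#   E_red = sum N_k (a_k^2/sigma_k^3 + mu (a_k - ahat_k)^m sigma_k),
#   constraint sum N_k a_k^2 / sigma_k = 2*delta.
# The two are linked by E_raw = Eb * c_b * E_red with
#   mu = (K / (2 Eb)) * c_i(m) / c_b  and  delta_raw = c_l * delta.

#' Exact Gaussian-integral coefficients of the reduced model
#'
#' @return `gauss_coef_bending()` returns `(3/2)*sqrt(pi/2)`, the value of
#'   `(1/2) * integral (d^2/dS^2 exp(-S^2))^2 dS`; `gauss_coef_length()`
#'   returns `sqrt(pi/8)` from `(1/2) * integral (d/dS exp(-S^2))^2 dS`;
#'   `gauss_coef_interaction(m)` returns `sqrt(pi/m)` from
#'   `integral exp(-m S^2) dS`.
#' @export
gauss_coef_bending <- function() 1.5 * sqrt(pi / 2)

#' @rdname gauss_coef_bending
#' @export
gauss_coef_length <- function() sqrt(pi / 8)

#' @rdname gauss_coef_bending
#' @param m Interaction exponent (integer >= 2).
#' @export
gauss_coef_interaction <- function(m) {
  .check_scalar(m, "m", 2, integer = TRUE)
  sqrt(pi / m)
}

#' Material parameters of the two-layer interaction
#'
#' The reduced stiffness ratio `mu` weighs the foundation interaction energy
#' against bending; it may be supplied directly (the usual route) or derived
#' from raw stiffnesses via `mu = (K/(2*Eb)) * c_i(m)/c_b`.
#'
#' @param m Interaction exponent; `m = 2` is a linear (Winkler) foundation,
#'   `m = 4` the quartic interaction that supports hierarchical bifurcation.
#'   Values 2, 3 and 4 are fully supported.
#' @param mu Reduced dimensionless stiffness ratio (>= 0). If `NULL`,
#'   computed from `Eb` and `K`.
#' @param Eb Bending stiffness (> 0).
#' @param K Interaction stiffness (> 0).
#' @param eta Foundation remodelling (memory relaxation) rate, 1/time (>= 0).
#' @return An object of class `material_params`.
#' @examples
#' material_params(m = 4, mu = 30)
#' @export
material_params <- function(m = 4, mu = NULL, Eb = 1, K = 1, eta = 0) {
  .check_scalar(m, "m", 2, integer = TRUE)
  .check_scalar(Eb, "Eb", 0, strict = TRUE)
  .check_scalar(K, "K", 0, strict = TRUE)
  .check_scalar(eta, "eta", 0)
  if (is.null(mu)) mu <- (K / (2 * Eb)) * gauss_coef_interaction(m) / gauss_coef_bending()
  .check_scalar(mu, "mu", 0)
  structure(list(m = as.integer(m), mu = mu, Eb = Eb, K = K, eta = eta),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> m = %d, mu = %.4g, eta = %.4g (Eb = %.3g, K = %.3g)\n",
              x$m, x$mu, x$eta, x$Eb, x$K))
  invisible(x)
}

# raw interaction prefactor K/2 consistent with the reduced mu
.mu_raw <- function(params) {
  params$mu * gauss_coef_bending() / gauss_coef_interaction(params$m)
}

#' Bending energy of one Gaussian bump (raw units)
#'
#' @param a Amplitude (>= 0).
#' @param sigma Width parameter (> 0).
#' @return `c_b * a^2 / sigma^3` with the exact Gaussian-integral coefficient
#'   `c_b = (3/2) sqrt(pi/2)`; scales quadratically in `a`.
#' @export
bump_bending <- function(a, sigma) {
  if (any(a < 0)) stop("'a' must be >= 0", call. = FALSE)
  if (any(sigma <= 0)) stop("'sigma' must be > 0", call. = FALSE)
  gauss_coef_bending() * a^2 / sigma^3
}

#' Small-slope excess length of one Gaussian bump (raw units)
#'
#' @inheritParams bump_bending
#' @return `c_l * a^2 / sigma` with `c_l = sqrt(pi/8)`.
#' @export
bump_excess_length <- function(a, sigma) {
  if (any(a < 0)) stop("'a' must be >= 0", call. = FALSE)
  if (any(sigma <= 0)) stop("'sigma' must be > 0", call. = FALSE)
  gauss_coef_length() * a^2 / sigma
}

#' Foundation interaction energy of one Gaussian bump (raw units)
#'
#' Deflection is measured from the remodelled foundation amplitude `ahat`
#' (co-centred, equal width); `a < ahat` signals an inconsistent state and is
#' rejected so that odd exponents stay one-signed.
#'
#' @param a Amplitude (>= 0).
#' @param ahat Memory amplitude (`0 <= ahat <= a`).
#' @param sigma Width parameter (> 0).
#' @param m Interaction exponent (integer >= 2).
#' @return `c_i(m) * (a - ahat)^m * sigma` with `c_i(m) = sqrt(pi/m)`.
#' @export
bump_interaction <- function(a, ahat = 0, sigma = 1, m = 4) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0", call. = FALSE)
  if (any(a < ahat)) stop("negative penetration: 'a' < 'ahat'", call. = FALSE)
  gauss_coef_interaction(m) * (a - ahat)^m * sigma
}

# Gaussian-sum profile and derivatives from a placed pattern
.profile_funs <- function(pattern, use_memory = FALSE) {
  b <- as.data.frame(pattern)
  amp <- if (use_memory) b$memory else b$amplitude
  list(
    y = function(S) {
      rowSums(vapply(seq_len(nrow(b)), function(i)
        amp[i] * exp(-(S - b$centre[i])^2 / b$sigma[i]^2), numeric(length(S))))
    },
    d1 = function(S) {
      rowSums(vapply(seq_len(nrow(b)), function(i) {
        u <- (S - b$centre[i]) / b$sigma[i]
        amp[i] * (-2 * u / b$sigma[i]) * exp(-u^2)
      }, numeric(length(S))))
    },
    d2 = function(S) {
      rowSums(vapply(seq_len(nrow(b)), function(i) {
        u <- (S - b$centre[i]) / b$sigma[i]
        amp[i] * (4 * u^2 - 2) / b$sigma[i]^2 * exp(-u^2)
      }, numeric(length(S))))
    })
  }

#' Profile function of a pattern
#'
#' @param pattern A placed [hierarchical_pattern()].
#' @param use_memory Evaluate the remodelled foundation profile instead.
#' @return A function `y(S)` evaluating the Gaussian-sum profile.
#' @export
pattern_profile <- function(pattern, use_memory = FALSE) {
  .profile_funs(pattern, use_memory)$y
}

.pattern_separated <- function(pattern) {
  b <- as.data.frame(pattern)
  if (nrow(b) <= 1L) return(TRUE)
  b <- b[order(b$centre), ]
  gaps <- diff(b$centre) - 2 * (head(b$sigma, -1) + tail(b$sigma, -1))
  all(gaps >= -1e-9)
}

# quadrature of the raw integrand on the summed profile (overlap-safe path)
.quadrature_energy_raw <- function(pattern, params, rel.tol = 1e-10) {
  f <- .profile_funs(pattern, FALSE)
  fh <- .profile_funs(pattern, TRUE)
  lim <- pattern$L * 3 + 10 * max(pattern$levels$sigma)
  bend <- integrate(function(S) 0.5 * f$d2(S)^2, -lim, lim,
                    rel.tol = rel.tol, subdivisions = 500L)$value
  mraw <- .mu_raw(params)
  intr <- integrate(function(S) mraw * (f$y(S) - fh$y(S))^params$m, -lim, lim,
                    rel.tol = rel.tol, subdivisions = 500L)$value
  c(bending = bend, interaction = intr)
}

#' Reduced (or raw) mechanical energy of a pattern
#'
#' For separated bumps the energy is the closed-form sum over levels,
#' `E = sum_k N_k (a_k^2/sigma_k^3 + mu (a_k - ahat_k)^m sigma_k)` in reduced
#' units (the raw convention multiplies by `c_b` and carries the exact
#' Gaussian coefficients). If footprints overlap, a warning is issued and the
#' energy falls back to adaptive quadrature of the raw integrand on the
#' summed profile (converted back to the requested convention).
#'
#' @param pattern A [hierarchical_pattern()].
#' @param params A [material_params()].
#' @param convention `"reduced"` (default) or `"raw"`.
#' @return A list of class `energy_breakdown`: `bending`, `interaction`,
#'   `total`, `per_level` (data frame), `convention`.
#' @export
pattern_energy <- function(pattern, params, convention = c("reduced", "raw")) {
  convention <- match.arg(convention)
  stopifnot(inherits(pattern, "hierarchical_pattern"), inherits(params, "material_params"))
  lv <- pattern$levels
  if (nrow(lv) == 0L || all(lv$amplitude == 0)) {
    return(structure(list(bending = 0, interaction = 0, total = 0,
                          per_level = data.frame(level = integer(), bending = numeric(),
                                                 interaction = numeric()),
                          convention = convention), class = "energy_breakdown"))
  }
  if (any(lv$amplitude < lv$memory - 1e-12))
    stop("negative penetration: amplitude < memory", call. = FALSE)
  if (!.pattern_separated(pattern)) {
    warning("bump footprints overlap; falling back to quadrature of the full integrand")
    raw <- .quadrature_energy_raw(pattern, params)
    fac <- if (convention == "raw") 1 else 1 / gauss_coef_bending()
    return(structure(list(bending = raw[["bending"]] * fac,
                          interaction = raw[["interaction"]] * fac,
                          total = sum(raw) * fac, per_level = NULL,
                          convention = convention), class = "energy_breakdown"))
  }
  bend <- lv$N * lv$amplitude^2 / lv$sigma^3
  intr <- params$mu * lv$N * (lv$amplitude - lv$memory)^params$m * lv$sigma
  fac <- if (convention == "raw") gauss_coef_bending() else 1
  structure(list(bending = sum(bend) * fac, interaction = sum(intr) * fac,
                 total = sum(bend + intr) * fac,
                 per_level = data.frame(level = lv$level, bending = bend * fac,
                                        interaction = intr * fac),
                 convention = convention), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> (%s units) total = %.6g  [bending %.6g + interaction %.6g]\n",
              x$convention, x$total, x$bending, x$interaction))
  invisible(x)
}

#' Excess length stored in a pattern
#'
#' @inheritParams pattern_energy
#' @return In reduced units, `sum_k N_k a_k^2 / sigma_k` (equal to `2*delta`
#'   when the length constraint is enforced); the raw convention multiplies
#'   by `c_l = sqrt(pi/8)`.
#' @export
pattern_length <- function(pattern, convention = c("reduced", "raw")) {
  convention <- match.arg(convention)
  stopifnot(inherits(pattern, "hierarchical_pattern"))
  lv <- pattern$levels
  val <- sum(lv$N * lv$amplitude^2 / lv$sigma)
  if (convention == "raw") val * gauss_coef_length() else val
}
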