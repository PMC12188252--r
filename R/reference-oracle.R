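# Direct numerical minimization of the unreduced energy, used to validate the
# separated-Gaussian reduction. Works in the raw convention:
#   E[y] = int (1/2) y''^2 + mu_raw (y)^m dS,   (1/2) int y'^2 dS = 2 delta_raw,
# with mu_raw and delta_raw linked to the solver's reduced (mu, delta) by the
# exact Gaussian coefficients (see energetics). The arc-length functional is
# quadratic in the heights, so the constraint is enforced exactly by radial
# rescaling inside the objective; minimization is then unconstrained.

#' Convert a reduced excess to the raw convention
#'
#' @param delta Reduced excess half-length.
#' @return `delta * sqrt(pi/8)`.
#' @export
delta_raw <- function(delta) delta * gauss_coef_length()

# trapezoid quadrature grid wide enough for Gaussian tails
.quad_grid <- function(L, pad, n = 4001L) {
  S <- seq(-L - pad, L + pad, length.out = n)
  list(S = S, h = S[2] - S[1])
}

#' Full discretized energy minimization
#'
#' Minimizes the raw energy over nodal heights on a uniform grid on
#' `[-L, L]` with clamped-flat ends (`y = y' = 0`), subject to the
#' discretized excess-length constraint (enforced exactly by rescaling the
#' height vector, which leaves an unconstrained smooth problem solved by
#' L-BFGS with an analytic gradient). Starting from a supplied pattern's
#' Gaussian profile, monotone descent guarantees the converged energy is no
#' larger than the ansatz energy at the same excess.
#'
#' @param delta Reduced excess half-length (> 0); converted internally via
#'   [delta_raw()].
#' @param L Domain half-length.
#' @param params A [material_params()].
#' @param n Number of grid nodes (the grid should resolve the smallest bump
#'   footprint with at least 16 nodes).
#' @param init Initial profile: a placed [hierarchical_pattern()] (its
#'   Gaussian profile is sampled) or a numeric vector of length `n`;
#'   `NULL` starts from a single broad cosine hump.
#' @param maxit Maximum optimizer iterations.
#' @return List of class `full_minimum`: grid `S`, heights `y`, `energy_raw`,
#'   `energy_reduced` (`= energy_raw / c_b`), `converged`, `h`.
#' @export
minimize_full <- function(delta, L, params, n = 321L, init = NULL, maxit = 2000L) {
  stopifnot(inherits(params, "material_params"))
  .check_scalar(delta, "delta", 0)
  .check_scalar(L, "L", 0, strict = TRUE)
  S <- seq(-L, L, length.out = n)
  h <- S[2] - S[1]
  m <- params$m
  mraw <- .mu_raw(params)
  d_raw <- delta_raw(delta)
  if (d_raw == 0) {
    return(structure(list(S = S, y = rep(0, n), energy_raw = 0, energy_reduced = 0,
                          converged = TRUE, h = h), class = "full_minimum"))
  }
  # clamped-flat: two fixed zero nodes at each end
  free <- 3:(n - 2)
  nf <- length(free)
  embed <- function(z) { y <- numeric(n); y[free] <- z; y }
  len_of <- function(y) 0.5 * sum(diff(y)^2) / h
  bend_of <- function(y) {
    d2 <- (y[1:(n - 2)] - 2 * y[2:(n - 1)] + y[3:n]) / h^2
    0.5 * h * sum(d2^2)
  }
  energy_of <- function(y) bend_of(y) + mraw * h * sum(y^m)
  # gradients w.r.t. full y
  grad_energy <- function(y) {
    d2 <- (y[1:(n - 2)] - 2 * y[2:(n - 1)] + y[3:n]) / h^2
    g <- numeric(n)
    g[1:(n - 2)] <- g[1:(n - 2)] + d2
    g[2:(n - 1)] <- g[2:(n - 1)] - 2 * d2
    g[3:n] <- g[3:n] + d2
    g <- g * h / h^2
    g + mraw * h * m * y^(m - 1)
  }
  grad_len <- function(y) {
    d1 <- diff(y)
    g <- numeric(n)
    g[1:(n - 1)] <- g[1:(n - 1)] - d1
    g[2:n] <- g[2:n] + d1
    g / h
  }
  obj <- function(z) {
    y0 <- embed(z)
    l0 <- len_of(y0)
    if (l0 <= 0) return(1e10)
    s <- sqrt(2 * d_raw / l0)
    energy_of(s * y0)
  }
  grd <- function(z) {
    y0 <- embed(z)
    l0 <- len_of(y0)
    s <- sqrt(2 * d_raw / l0)
    y <- s * y0
    gE <- grad_energy(y)
    gl <- grad_len(y0)
    # d/dz of s: ds = -s * gl / (2 l0)
    g_full <- s * gE - (sum(gE * y0) * s / (2 * l0)) * gl
    g_full[free]
  }
  y_init <- if (inherits(init, "hierarchical_pattern")) {
    pattern_profile(init)(S)
  } else if (is.numeric(init)) {
    stopifnot(length(init) == n)
    init
  } else {
    cos(pi * S / (2 * L))^2
  }
  z0 <- pmax(y_init[free], 0)
  if (len_of(embed(z0)) <= 0) z0 <- cos(pi * S / (2 * L))[free]^2
  # one-sided deformation (y >= 0): the layer deflects away from the rigid
  # substrate, matching the one-signed Gaussian ansatz
  fit <- optim(z0, obj, grd, method = "L-BFGS-B", lower = 0,
               control = list(maxit = maxit, factr = 1e4))
  y0 <- embed(fit$par)
  s <- sqrt(2 * d_raw / len_of(y0))
  y <- s * y0
  structure(list(S = S, y = y, energy_raw = fit$value,
                 energy_reduced = fit$value / gauss_coef_bending(),
                 converged = fit$convergence == 0, h = h),
            class = "full_minimum")
}

#' @export
print.full_minimum <- function(x, ...) {
  cat(sprintf("<full_minimum> n = %d, E_raw = %.6g (reduced %.6g), converged: %s\n",
              length(x$S), x$energy_raw, x$energy_reduced, x$converged))
  invisible(x)
}

#' Per-footprint amplitudes of a discretized profile
#'
#' @param S,y Grid and heights (e.g. from [minimize_full()]).
#' @param pattern A placed [hierarchical_pattern()] defining the footprints.
#' @return Numeric vector: maximum height within each bump's `4 sigma`
#'   footprint, in the bump order of `as.data.frame(pattern)`.
#' @export
profile_amplitudes <- function(S, y, pattern) {
  b <- as.data.frame(pattern)
  vapply(seq_len(nrow(b)), function(i) {
    sel <- S >= b$centre[i] - 2 * b$sigma[i] & S <= b$centre[i] + 2 * b$sigma[i]
    if (!any(sel)) return(0)
    max(y[sel])
  }, numeric(1))
}

# raw energy and length of an overlapping Gaussian sum, trapezoid quadrature
.gauss_sum_raw <- function(a, sigma, centre, L, mraw, m, n_quad = 4001L) {
  g <- .quad_grid(L, pad = 6 * max(sigma), n = n_quad)
  S <- g$S
  y <- numeric(length(S)); d1 <- numeric(length(S)); d2 <- numeric(length(S))
  for (i in seq_along(a)) {
    u <- (S - centre[i]) / sigma[i]
    e <- exp(-u^2)
    y <- y + a[i] * e
    d1 <- d1 + a[i] * (-2 * u / sigma[i]) * e
    d2 <- d2 + a[i] * (4 * u^2 - 2) / sigma[i]^2 * e
  }
  list(bending = 0.5 * sum(d2^2) * g$h,
       interaction = mraw * sum(y^m) * g$h,
       length = 0.5 * sum(d1^2) * g$h)
}

#' Energy minimization over overlapping Gaussian bumps
#'
#' Keeps the sum-of-Gaussians form but drops the separation assumption:
#' amplitudes, widths and centres of `n_bumps` bumps are jointly optimized
#' with all cross terms evaluated by quadrature. The length constraint is
#' quadratic in the amplitude vector and is enforced exactly by rescaling.
#' Deterministic multi-start (a fixed list of relative perturbations of the
#' initial guess) guards against local minima.
#'
#' @inheritParams minimize_full
#' @param n_bumps Number of bumps.
#' @param init Optional placed [hierarchical_pattern()] supplying initial
#'   widths and centres; default: equally spaced bumps of width `L / (2
#'   n_bumps)`.
#' @param n_starts Number of deterministic starts (>= 1).
#' @return List of class `overlap_minimum`: `a`, `sigma`, `centre`,
#'   `energy_raw`, `energy_reduced`.
#' @export
minimize_overlapping_gaussians <- function(delta, L, params, n_bumps, init = NULL,
                                           n_starts = 3L, maxit = 400L) {
  stopifnot(inherits(params, "material_params"))
  .check_scalar(delta, "delta", 0, strict = TRUE)
  .check_scalar(n_bumps, "n_bumps", 1, integer = TRUE)
  m <- params$m
  mraw <- .mu_raw(params)
  d_raw <- delta_raw(delta)
  if (inherits(init, "hierarchical_pattern")) {
    b <- as.data.frame(init)
    stopifnot(nrow(b) == n_bumps)
    sig0 <- b$sigma; cen0 <- b$centre
  } else {
    sig0 <- rep(L / (2 * n_bumps), n_bumps)
    cen0 <- if (n_bumps == 1L) 0 else seq(-L, L, length.out = n_bumps + 2L)[2:(n_bumps + 1L)]
  }
  unpack <- function(p) {
    u <- abs(p[1:n_bumps])  # one-sided deformation
    sigma <- exp(p[(n_bumps + 1):(2 * n_bumps)])
    centre <- p[(2 * n_bumps + 1):(3 * n_bumps)]
    l0 <- .gauss_sum_raw(u, sigma, centre, L, mraw, m)$length
    s <- if (l0 > 0) sqrt(2 * d_raw / l0) else 0
    list(a = s * u, sigma = sigma, centre = centre)
  }
  obj <- function(p) {
    q <- unpack(p)
    if (any(q$sigma > 4 * L) || any(abs(q$centre) > L)) return(1e8)
    e <- .gauss_sum_raw(q$a, q$sigma, q$centre, L, mraw, m)
    e$bending + e$interaction
  }
  # fixed deterministic perturbation table (no RNG)
  perturb <- list(c(1, 1), c(0.8, 1.15), c(1.25, 0.85), c(0.9, 0.75), c(1.1, 1.3))
  best <- NULL
  for (s in seq_len(min(n_starts, length(perturb)))) {
    p0 <- c(rep(1, n_bumps) * perturb[[s]][1],
            log(sig0 * perturb[[s]][2]), cen0)
    fit <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit * 10L, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  q <- unpack(best$par)
  ord <- order(q$centre)
  structure(list(a = abs(q$a)[ord], sigma = q$sigma[ord], centre = q$centre[ord],
                 energy_raw = best$value,
                 energy_reduced = best$value / gauss_coef_bending(),
                 converged = best$convergence == 0),
            class = "overlap_minimum")
}

#' @export
print.overlap_minimum <- function(x, ...) {
  cat(sprintf("<overlap_minimum> %d bump(s), E_raw = %.6g (reduced %.6g)\n",
              length(x$a), x$energy_raw, x$energy_reduced))
  invisible(x)
}

#' Ansatz-versus-oracle comparison record
#'
#' Convenience wrapper producing the JSON-serializable comparison used in
#' validation runs: separated-ansatz energy versus the overlapping-Gaussian
#' and full-minimization energies at one excess.
#'
#' @param pattern A placed [hierarchical_pattern()] (the separated ansatz).
#' @param params A [material_params()].
#' @param n Grid size for [minimize_full()].
#' @return List with raw energies `separated`, `overlap`, `full`, and
#'   `max_amplitude_deviation` between the ansatz amplitudes and the full
#'   profile's footprint amplitudes.
#' @export
oracle_report <- function(pattern, params, n = 321L) {
  delta <- pattern_length(pattern) / 2
  e_sep <- pattern_energy(pattern, params, convention = "raw")$total
  ov <- minimize_overlapping_gaussians(delta, pattern$L, params,
                                       n_bumps = sum(pattern$levels$N), init = pattern)
  fu <- minimize_full(delta, pattern$L, params, n = n, init = pattern)
  amps <- profile_amplitudes(fu$S, fu$y, pattern)
  list(separated = e_sep, overlap = ov$energy_raw, full = fu$energy_raw,
       max_amplitude_deviation = max(abs(amps - as.data.frame(pattern)$amplitude)))
}
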