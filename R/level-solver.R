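# Quasi-static energy minimization of the reduced Gaussian-bump model.
#
# Eliminating the length constraint with a Lagrange multiplier lambda, the
# stationarity conditions for the reduced energy
#   E = sum_k N_k (a_k^2/sigma_k^3 + mu (a_k - ahat_k)^m sigma_k),
#   sum_k N_k a_k^2 / sigma_k = 2 delta,
# give, per level and with x = a^2, ahat = 0:
#   x_k = [ 2 (lambda sigma_k^2 - 1) / (m mu sigma_k^4) ]^(2/(m-2)),  m > 2,
# active (x_k > 0) exactly when lambda sigma_k^2 > 1. Level k therefore
# bifurcates at the first time lambda(t) sigma_k(t)^2 reaches 1, with
# sigma_k(t) fixed by the fit condition sum_{j<=k} 4 N_j sigma_j = 2 L(t).
# For m = 4 the constraint is linear in lambda and closed-form; otherwise
# lambda is found by monotone root bracketing.

#' Optimal level-1 width from the reduced energy
#'
#' Eliminating `a1` through the length constraint, the level-1 energy is
#' `E1(sigma) = 2*delta/sigma^2 + mu*N1^(1-m/2)*(2*delta)^(m/2)*sigma^(1+m/2)`
#' whose minimizer has the closed form returned here. For `m = 2` the width
#' `mu^(-1/4)` is independent of `delta`; for `m = 4` it scales as
#' `delta^(-1/5)`.
#'
#' @param delta Excess half-length (> 0).
#' @param mu Reduced stiffness ratio (> 0; `mu = 0` has no foundation and no
#'   finite optimum).
#' @param m Interaction exponent (integer >= 2).
#' @param N1 Number of level-1 bumps.
#' @return The width `sigma1` minimizing the reduced level-1 energy.
#' @examples
#' select_sigma1(0.5, mu = 16, m = 2) # = 16^(-1/4) = 0.5
#' @export
select_sigma1 <- function(delta, mu, m, N1 = 1) {
  if (any(delta <= 0)) stop("'delta' must be > 0", call. = FALSE)
  .check_scalar(m, "m", 2, integer = TRUE)
  .check_scalar(N1, "N1", 1, integer = TRUE)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("no foundation: 'mu' must be > 0 for a finite optimal width", call. = FALSE)
  A <- mu * (1 + m / 2) * N1^(1 - m / 2) * (2 * delta)^(m / 2)
  (4 * delta / A)^(1 / (3 + m / 2))
}

#' Level-1 mode selection by maximal fit
#'
#' The reduced energy at the initial buckling decreases with the mode number
#' for `m > 2`, so the selected mode is the largest bump count whose
#' footprints fit in the domain.
#'
#' @param L Domain half-length at onset (> 0).
#' @param sigma1 Level-1 width parameter (> 0).
#' @return Largest integer `N1` with `N1 * 4 * sigma1 <= 2 * L`.
#' @examples
#' select_mode(2, 0.25) # 4
#' @export
select_mode <- function(L, sigma1) {
  .check_scalar(L, "L", 0, strict = TRUE)
  .check_scalar(sigma1, "sigma1", 0, strict = TRUE)
  N1 <- floor(2 * L / (4 * sigma1) + 1e-9)
  if (N1 < 1) stop("pre-buckling: no bump of width 4*sigma1 fits in [-L, L]", call. = FALSE)
  as.integer(N1)
}

#' Level-1 amplitude from the length constraint
#'
#' Before any higher level appears, the constraint `N1 a1^2/sigma1 = 2 delta`
#' fully determines the amplitude; for linear `delta(t)` this is the
#' square-root post-buckling form.
#'
#' @param delta Excess half-length (vectorized, >= 0).
#' @param sigma1 Level-1 width (> 0).
#' @param N1 Level-1 bump count.
#' @return `sqrt(2 * delta * sigma1 / N1)`.
#' @export
level1_amplitude <- function(delta, sigma1, N1 = 1) {
  if (any(delta < 0)) stop("'delta' must be >= 0", call. = FALSE)
  .check_scalar(sigma1, "sigma1", 0, strict = TRUE)
  sqrt(2 * delta * sigma1 / N1)
}

#' Marginal-stability margin for the bifurcation to level 2
#'
#' Derivative of the constrained two-level reduced energy with respect to
#' `a2^2` at `a2 = 0` (scaled by `sigma2/N2`); level 2 can only appear where
#' this margin is negative. For a quadratic interaction (`m = 2`) with the
#' optimal level-1 width `sigma1 = mu^(-1/4)`, the margin equals
#' `1/sigma2^2 - 2/sigma1^2 + mu*sigma2^2 >= 0` for every `sigma2`, which is
#' the no-bifurcation result for a linear foundation force.
#'
#' @param delta Excess half-length.
#' @param sigma1,sigma2 Level widths.
#' @param params A [material_params()].
#' @param N1 Level-1 bump count.
#' @return The margin (negative means level 2 is energetically favourable).
#' @export
level2_onset_margin <- function(delta, sigma1, sigma2, params, N1 = 2) {
  stopifnot(inherits(params, "material_params"))
  m <- params$m; mu <- params$mu
  base <- 1 / sigma2^2 - 1 / sigma1^2 -
    mu * (m / 2) * sigma1^2 * (2 * delta * sigma1 / N1)^(m / 2 - 1)
  if (m == 2) base + mu * sigma2^2 else base
}

# ---- KKT amplitude solves ---------------------------------------------------

# memoryless amplitudes for active-set candidates, general m >= 3
.x_of_lambda <- function(lambda, mu, m, sigma) {
  z <- 2 * (lambda * sigma^2 - 1) / (m * mu * sigma^4)
  ifelse(z > 0, z^(2 / (m - 2)), 0)
}

.lambda_m4 <- function(delta, mu, N, sigma) {
  # all supplied levels assumed active
  (4 * mu * delta + sum(N / sigma^5)) / sum(N / sigma^3)
}

# solve for lambda and amplitudes, no memory; N, sigma over candidate levels
.amplitudes_nomem <- function(delta, mu, m, N, sigma) {
  if (delta <= 0) return(list(a = rep(0, length(N)), lambda = -Inf))
  if (m == 4) {
    act <- rep(TRUE, length(N))
    repeat {
      lam <- .lambda_m4(delta, mu, N[act], sigma[act])
      drop <- act & (lam * sigma^2 <= 1)
      if (!any(drop & act)) break
      act[drop] <- FALSE
      if (!any(act)) stop("infeasible state: no level can carry the excess length")
    }
    x <- ifelse(act, pmax(0, (lam * sigma^2 - 1)) / (2 * mu * sigma^4), 0)
    return(list(a = sqrt(x), lambda = lam))
  }
  G <- function(lam) sum(N * .x_of_lambda(lam, mu, m, sigma) / sigma) - 2 * delta
  lo <- 1 / max(sigma)^2
  hi <- lo * 2 + 1
  while (G(hi) < 0) hi <- hi * 2
  lam <- uniroot(G, c(lo, hi), tol = 1e-13)$root
  list(a = sqrt(.x_of_lambda(lam, mu, m, sigma)), lambda = lam)
}

# single-level stationarity residual with memory offset
.phi_mem <- function(a, lambda, mu, m, sigma, ahat) {
  2 * a / sigma^3 + m * mu * (a - ahat)^(m - 1) * sigma - 2 * lambda * a / sigma
}

.a_of_lambda_mem <- function(lambda, mu, m, sigma, ahat, a_hi) {
  if (ahat <= 0) {
    x <- .x_of_lambda(lambda, mu, m, sigma)
    return(sqrt(x))
  }
  f <- function(a) .phi_mem(a, lambda, mu, m, sigma, ahat)
  lo <- if (m %% 2 == 0) 0 else ahat
  if (f(lo) >= 0) return(lo)
  hi <- max(a_hi, ahat + 1)
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-13)$root
}

# amplitudes with memory offsets ahat (>= 0), general m
.amplitudes_mem <- function(delta, mu, m, N, sigma, ahat) {
  if (all(ahat <= 0)) return(.amplitudes_nomem(delta, mu, m, N, sigma))
  a_hi <- sqrt(2 * max(delta, 1e-12) * max(sigma) / min(N))
  G <- function(lam) {
    a <- vapply(seq_along(N), function(j)
      .a_of_lambda_mem(lam, mu, m, sigma[j], ahat[j], a_hi), numeric(1))
    sum(N * a^2 / sigma) - 2 * delta
  }
  lo <- 0
  while (G(lo) > 0) lo <- lo - max(1, abs(lo)) * 2
  hi <- 1 / min(sigma)^2
  while (G(hi) < 0) hi <- hi * 2
  lam <- uniroot(G, c(lo, hi), tol = 1e-13)$root
  a <- vapply(seq_along(N), function(j)
    .a_of_lambda_mem(lam, mu, m, sigma[j], ahat[j], a_hi), numeric(1))
  list(a = a, lambda = lam)
}

# ---- onset ------------------------------------------------------------------

# first time the optimal single-mode width fits, and the maximal fitting mode
.level1_onset <- function(params, schedule, t_max, N1 = NULL) {
  m <- params$m; mu <- params$mu
  fit <- function(t) {
    d <- schedule$delta(t)
    if (d <= 0) return(-Inf)
    2 * schedule$L(t) - 4 * select_sigma1(d, mu, m, 1)
  }
  t1 <- if (fit(0) >= 0) 0 else {
    if (fit(t_max) < 0)
      stop("pre-buckling: no bump fits within the time horizon", call. = FALSE)
    lo <- 0; hi <- t_max
    for (i in 1:200) { mid <- (lo + hi) / 2; if (fit(mid) >= 0) hi <- mid else lo <- mid }
    hi
  }
  d1 <- schedule$delta(t1)
  if (is.null(N1)) {
    N1 <- 1L
    while (4 * (N1 + 1) * select_sigma1(d1, mu, m, N1 + 1L) <= 2 * schedule$L(t1))
      N1 <- N1 + 1L
  }
  list(t1 = t1, N1 = as.integer(N1), sigma1 = select_sigma1(d1, mu, m, N1))
}

# ---- trajectory container ---------------------------------------------------

.new_trajectory <- function(time, a, ahat, levels, params, schedule, max_level) {
  structure(list(time = time, a = a, ahat = ahat, levels = levels,
                 params = params, schedule = schedule,
                 max_level = max_level), class = "pattern_trajectory")
}

#' @export
print.pattern_trajectory <- function(x, ...) {
  cat(sprintf("<pattern_trajectory> %d time points, %d level(s) attained (of %d requested)\n",
              length(x$time), nrow(x$levels), x$max_level))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' @param x A `pattern_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `t`, `level`, `a`, `ahat`, `sigma`, `N`.
#' @export
as.data.frame.pattern_trajectory <- function(x, ...) {
  K <- nrow(x$levels)
  do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(t = x$time, level = x$levels$level[k], a = x$a[, k],
               ahat = x$ahat[, k], sigma = x$levels$sigma[k], N = x$levels$N[k])
  }))
}

#' Pattern snapshot at a given time
#'
#' @param trajectory A `pattern_trajectory`.
#' @param t Time (snapped to the nearest stored time point).
#' @return A [hierarchical_pattern()] of the levels active at `t`.
#' @export
pattern_at <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "pattern_trajectory"))
  i <- which.min(abs(trajectory$time - t))
  lv <- trajectory$levels
  act <- lv$t_onset <= trajectory$time[i] + 1e-12
  lv <- lv[act, , drop = FALSE]
  if (nrow(lv) == 0L) stop("no level active at the requested time", call. = FALSE)
  levels <- data.frame(level = lv$level, N = lv$N, sigma = lv$sigma,
                       amplitude = trajectory$a[i, act],
                       memory = trajectory$ahat[i, act])
  L <- trajectory$schedule$L(trajectory$time[i])
  seqs <- if (nrow(levels) == 1L) rep(1L, levels$N[1]) else
    intercalation_sequence(levels$N[1], nrow(levels))
  hierarchical_pattern(levels, L = L, sequence = seqs, place = FALSE)
}

# ---- the quasi-static engine ------------------------------------------------

# eta = 0: piecewise-analytic fill between bisection-refined bifurcation times.
# eta > 0: sequential operator splitting (minimize, then relax memory).
.engine <- function(params, schedule, t_max, max_level, dt, N1, eta) {
  m <- params$m; mu <- params$mu
  if (mu <= 0) stop("no foundation: 'mu' must be > 0", call. = FALSE)
  time <- seq(0, t_max, by = dt)
  nt <- length(time)
  ons <- .level1_onset(params, schedule, t_max, N1)
  sig <- ons$sigma1; Nk <- ons$N1; tk <- ons$t1
  Tot <- ons$N1

  if (m == 2 || max_level == 1L) {
    # quadratic foundation never bifurcates to level 2; single-level dynamics
    a <- matrix(0, nt, 1); ah <- matrix(0, nt, 1)
    on_i <- time >= tk - 1e-12
    a[on_i, 1] <- level1_amplitude(pmax(schedule$delta(time[on_i]), 0), sig, Nk)
    if (eta > 0) {
      for (i in which(on_i)[-1])
        ah[i, 1] <- step_memory(ah[i - 1, 1], a[i - 1, 1], eta, dt)
      a[, 1] <- pmax(a[, 1], ah[, 1])
    }
    lv <- data.frame(level = 1L, N = Nk, sigma = sig, t_onset = tk)
    return(.new_trajectory(time, a, ah, lv, params, schedule, max_level))
  }

  if (eta == 0) {
    # grow the level table by root-finding on the marginal-stability condition
    while (length(Nk) < max_level) {
      k <- length(Nk) + 1L
      Nnew <- Tot - 1L
      if (Nnew < 1L) break
      sig_k <- function(t) (schedule$L(t) - 2 * sum(Nk * sig)) / (2 * Nnew)
      Fk <- function(t) {
        s <- sig_k(t)
        if (s <= 0) return(-1)
        lam <- .amplitudes_nomem(schedule$delta(t), mu, m, Nk, sig)$lambda
        lam * s^2 - 1
      }
      if (Fk(t_max) < 0) break
      t_lo <- tk[length(tk)]
      t_new <- if (Fk(t_lo) >= 0) t_lo else uniroot(Fk, c(t_lo, t_max), tol = 1e-12)$root
      s_new <- sig_k(t_new)
      Nk <- c(Nk, Nnew); sig <- c(sig, s_new); tk <- c(tk, t_new)
      Tot <- Tot + Nnew
    }
    K <- length(Nk)
    a <- matrix(0, nt, K); ah <- matrix(0, nt, K)
    for (i in seq_len(nt)) {
      act <- tk <= time[i] + 1e-12
      if (!any(act)) next
      sol <- .amplitudes_nomem(schedule$delta(time[i]), mu, m, Nk[act], sig[act])
      a[i, act] <- sol$a
    }
    lv <- data.frame(level = seq_len(K), N = Nk, sigma = sig, t_onset = tk)
    return(.new_trajectory(time, a, ah, lv, params, schedule, max_level))
  }

  # eta > 0: sequential stepping with activation checks on the grid
  Kmax <- max_level
  Nk_all <- Nk; sig_all <- sig; tk_all <- tk
  a <- matrix(0, nt, Kmax); ah <- matrix(0, nt, Kmax)
  lam_prev <- -Inf
  for (i in seq_len(nt)) {
    t <- time[i]
    if (t < tk_all[1] - 1e-12) next
    # activation of the next level by the current multiplier
    if (length(Nk_all) < Kmax) {
      Nnew <- sum(Nk_all) - 1L
      if (Nnew >= 1L) {
        s_new <- (schedule$L(t) - 2 * sum(Nk_all * sig_all)) / (2 * Nnew)
        if (s_new > 0 && is.finite(lam_prev) && lam_prev * s_new^2 > 1) {
          Nk_all <- c(Nk_all, Nnew); sig_all <- c(sig_all, s_new); tk_all <- c(tk_all, t)
        }
      }
    }
    K <- length(Nk_all)
    ah_cur <- if (i > 1) ah[i - 1, seq_len(K)] else rep(0, K)
    sol <- .amplitudes_mem(schedule$delta(t), mu, m, Nk_all, sig_all, ah_cur)
    a[i, seq_len(K)] <- sol$a
    lam_prev <- sol$lambda
    ah[i, seq_len(K)] <- step_memory(ah_cur, sol$a, eta, dt)
  }
  K <- length(Nk_all)
  lv <- data.frame(level = seq_len(K), N = Nk_all, sigma = sig_all, t_onset = tk_all)
  .new_trajectory(time, a[, seq_len(K), drop = FALSE], ah[, seq_len(K), drop = FALSE],
                  lv, params, schedule, max_level)
}

#' Quasi-static hierarchy of intercalating levels
#'
#' Tracks the memory-less pattern: level-1 onset (optimal width, maximal
#' fitting mode), then recursive bifurcations to higher levels. Level `k`
#' appears at the first time its marginal-stability condition
#' `lambda(t) * sigma_k(t)^2 = 1` holds, with `sigma_k` fixed by the fit
#' condition that all footprints tile the domain at the bifurcation time; the
#' per-level bump counts follow the intercalation series
#' (`N_{k+1}` = current gap count). A quadratic interaction (`m = 2`) never
#' bifurcates past level 1.
#'
#' @param params A [material_params()]; `mu > 0` required.
#' @param schedule A [growth_schedule()].
#' @param t_max Time horizon (dimensionless).
#' @param max_level Deepest level to track.
#' @param dt Output time resolution (bifurcation times are refined by
#'   bisection between grid points).
#' @param N1 Optional forced level-1 bump count (e.g. `2` for the canonical
#'   1.1 starting configuration); default: maximal fitting mode at onset.
#' @return A `pattern_trajectory` with amplitude curves `a_k(t)`, onset
#'   times, widths and counts per level.
#' @examples
#' tr <- solve_hierarchy(material_params(m = 4, mu = 30),
#'                       growth_schedule(L0 = 6, g = 0.1, delta0 = 0.04),
#'                       t_max = 1, max_level = 3, dt = 0.01)
#' tr$levels
#' @export
solve_hierarchy <- function(params, schedule, t_max = 3, max_level = 5, dt = 1e-3,
                            N1 = NULL) {
  stopifnot(inherits(params, "material_params"), inherits(schedule, "growth_schedule"))
  .check_scalar(t_max, "t_max", 0, strict = TRUE)
  .check_scalar(max_level, "max_level", 1, integer = TRUE)
  .engine(params, schedule, t_max, max_level, dt, N1, eta = 0)
}

#' Bifurcation to the second hierarchical level
#'
#' Convenience wrapper around [solve_hierarchy()] capped at two levels,
#' reporting the level-2 onset time, width and amplitude curve. For `m = 2`
#' the bifurcation provably never occurs and the result is flagged
#' accordingly.
#'
#' @inheritParams solve_hierarchy
#' @param level1 Optional precomputed level-1 record (list with `N1`); only
#'   its `N1` is used to force the level-1 mode.
#' @return A list of class `level2_solution`: `bifurcated`, `t2`, `sigma2`,
#'   `N2`, `a2` (amplitude curve on the time grid), `trajectory`.
#' @export
solve_level2 <- function(params, schedule, level1 = NULL, t_max = 3, dt = 1e-3) {
  N1 <- if (!is.null(level1)) level1$N1 else NULL
  tr <- solve_hierarchy(params, schedule, t_max = t_max, max_level = 2L, dt = dt, N1 = N1)
  bif <- nrow(tr$levels) >= 2L && params$m != 2L
  out <- list(bifurcated = bif,
              t2 = if (bif) tr$levels$t_onset[2] else NA_real_,
              sigma2 = if (bif) tr$levels$sigma[2] else NA_real_,
              N2 = if (bif) tr$levels$N[2] else NA_integer_,
              a2 = if (bif) tr$a[, 2] else rep(0, length(tr$time)),
              reason = if (params$m == 2L) "quadratic interaction: no bifurcation" else
                if (!bif) "no onset within the time horizon" else NA_character_,
              trajectory = tr)
  class(out) <- "level2_solution"
  out
}

#' @export
print.level2_solution <- function(x, ...) {
  if (x$bifurcated)
    cat(sprintf("<level2_solution> t2 = %.5g, sigma2 = %.5g, N2 = %d\n", x$t2, x$sigma2, x$N2))
  else cat(sprintf("<level2_solution> no bifurcation (%s)\n", x$reason))
  invisible(x)
}
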