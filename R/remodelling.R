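# Foundation remodelling ("memory"): the rest shape of the foundation relaxes
# towards the deformed shape, d(yhat)/dt = eta * (y - yhat). Within the
# Gaussian reduction yhat shares widths and centres with y, so the law acts on
# the per-level memory amplitudes ahat_k alone.

#' One exact relaxation step of the memory amplitude
#'
#' Integrates `d(ahat)/dt = eta * (a - ahat)` exactly over a step of length
#' `dt` with `a` held fixed: `ahat' = a + (ahat - a) * exp(-eta * dt)`.
#' Relaxation cannot overshoot: `ahat' <= a` whenever `ahat <= a`.
#'
#' @param ahat Current memory amplitude(s).
#' @param a Current deformation amplitude(s).
#' @param eta Relaxation rate (>= 0); `eta = 0` leaves `ahat` unchanged.
#' @param dt Step length (> 0).
#' @return Updated memory amplitude(s).
#' @examples
#' step_memory(0, 1, eta = 1, dt = 1) # 1 - exp(-1)
#' @export
step_memory <- function(ahat, a, eta, dt) {
  .check_scalar(eta, "eta", 0)
  .check_scalar(dt, "dt", 0, strict = TRUE)
  a + (ahat - a) * exp(-eta * dt)
}

#' Hierarchy dynamics with foundation remodelling
#'
#' Operator-splitting evolution: at each time step the reduced energy with
#' interaction terms `mu * (a_k - ahat_k)^m * sigma_k` is minimized under the
#' length constraint (quasi-static equilibrium), then every memory amplitude
#' relaxes towards its deformation amplitude by [step_memory()]. A newly
#' bifurcated level starts with zero memory. With `eta = 0` in `params` the
#' result coincides with [solve_hierarchy()] on the same grid.
#'
#' Memory preserves the amplitude ordering by hierarchical level: relaxing
#' the foundation under the large early levels cheapens their further growth,
#' preventing the overtaking of level 1 by level 2 that the memory-less
#' system can display.
#'
#' @inheritParams solve_hierarchy
#' @return A `pattern_trajectory` including the memory curves `ahat_k(t)`.
#' @export
evolve_with_memory <- function(params, schedule, t_max = 3, max_level = 5, dt = 1e-3,
                               N1 = NULL) {
  stopifnot(inherits(params, "material_params"), inherits(schedule, "growth_schedule"))
  .engine(params, schedule, t_max, max_level, dt, N1, eta = params$eta)
}
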