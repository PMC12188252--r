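# Burst-growth dilation of a pre-existing ridge pattern into spines.
#
# During a secretion burst the excess length delta(t) rises rapidly while the
# domain width is frozen. Two energy-minimizing pathways are compared:
#   linear spines  — every ridge amplifies in place, keeping its ridge width;
#   fractal spines — the level-1 spine takes the domain width (one root per
#     level-1 ridge) and deeper levels grow on the flanks of their parent
#     spine, appearing once the parent amplitude offers enough room.
# Both pathways share the same reduced energy, length constraint and
# marginal-stability machinery as the ridge-phase solver.

#' Build a hierarchical ridge pattern fixture
#'
#' Widths tile the domain (`sum N_k 4 sigma_k = 2 L`) with a fixed per-level
#' width ratio, so the same label sequence on a smaller domain gives a denser
#' pattern with proportionally narrower ridges. Amplitudes are the reduced
#' energy minimizers at the ridge-phase excess `delta`.
#'
#' @param sequence Ridge label sequence, e.g. `c(3, 2, 3, 1, 3, 2, 3)`.
#' @param L Domain half-length.
#' @param params A [material_params()].
#' @param delta Ridge-phase excess half-length (>= 0); amplitudes are the
#'   constrained minimizers at this excess.
#' @param ratio Width ratio between consecutive levels (default 1/2).
#' @return A [hierarchical_pattern()] whose attribute `"delta"` records the
#'   ridge-phase excess.
#' @examples
#' ridge_pattern(c(3, 2, 3, 1, 3, 2, 3), L = 3, params = material_params(m = 4, mu = 10))
#' @export
ridge_pattern <- function(sequence, L, params, delta = 0.04, ratio = 0.5) {
  stopifnot(inherits(params, "material_params"))
  sequence <- as.integer(sequence)
  lvs <- sort(unique(sequence))
  if (!identical(lvs, seq_along(lvs)))
    stop("sequence must use contiguous levels 1..K", call. = FALSE)
  N <- tabulate(sequence)
  sigma1 <- 2 * L / (4 * sum(N * ratio^(seq_along(N) - 1)))
  sigma <- sigma1 * ratio^(seq_along(N) - 1)
  amp <- rep(0, length(N))
  if (delta > 0)
    amp <- .amplitudes_nomem(delta, params$mu, params$m, N, sigma)$a
  pat <- hierarchical_pattern(
    data.frame(level = seq_along(N), N = N, sigma = sigma, amplitude = amp),
    L = L, sequence = sequence)
  attr(pat, "delta") <- delta
  pat
}

# per-time reduced energy of a level table with amplitudes
.levels_energy <- function(N, sigma, a, mu, m) {
  sum(N * a^2 / sigma^3) + mu * sum(N * a^m * sigma)
}

#' Linear-spine dilation of a ridge pattern
#'
#' Every ridge amplifies in place: widths stay at the ridge widths, and at
#' each time the amplitudes minimize the reduced energy under the length
#' constraint `sum N_k a_k^2/sigma_k = 2 delta(t)`. Which levels amplify is
#' decided by the same marginal-stability (multiplier) condition as in the
#' ridge phase; in dense patterns the higher levels may never amplify.
#'
#' @param ridges A [ridge_pattern()] (or any placed [hierarchical_pattern()]).
#' @param burst A `"burst"` [growth_schedule()] whose `delta(t)` is the total
#'   excess (ridge phase included), typically built with
#'   `delta0 = attr(ridges, "delta")`.
#' @param params A [material_params()].
#' @param t_max Burst duration.
#' @param nt Number of stored time points.
#' @return A `pattern_trajectory` over the burst window.
#' @export
dilate_linear <- function(ridges, burst, params, t_max = 1, nt = 101L) {
  stopifnot(inherits(ridges, "hierarchical_pattern"), inherits(burst, "growth_schedule"))
  lv <- ridges$levels
  time <- seq(0, t_max, length.out = nt)
  a <- matrix(0, nt, nrow(lv))
  for (i in seq_len(nt)) {
    d <- burst$delta(time[i])
    if (d > 0)
      a[i, ] <- .amplitudes_nomem(d, params$mu, params$m, lv$N, lv$sigma)$a
  }
  lvout <- data.frame(level = lv$level, N = lv$N, sigma = lv$sigma, t_onset = 0)
  .new_trajectory(time, a, matrix(0, nt, nrow(lv)), lvout, params, burst,
                  max_level = nrow(lv))
}

#' Flank-fit criterion for fractal growth
#'
#' A child bump can appear on a parent's flank once the parent amplitude
#' (the proxy for the available flank length) reaches the child's footprint:
#' `a_parent >= factor * child_sigma`, boundary included.
#'
#' @param parent A [gaussian_bump()] or a numeric parent amplitude.
#' @param child_sigma Width parameter of the prospective child.
#' @param factor Footprint factor (default 4, the footprint convention).
#' @return `TRUE` when the child fits.
#' @export
fractal_fit <- function(parent, child_sigma, factor = 4) {
  a_p <- if (inherits(parent, "gaussian_bump")) parent$amplitude else parent
  .check_scalar(child_sigma, "child_sigma", 0, strict = TRUE)
  a_p >= factor * child_sigma - 1e-12
}

#' Build a fractal spine tree from a ridge pattern
#'
#' The level-1 spine(s) take the domain width: one root per level-1 ridge,
#' each of footprint `2L / N1`. Deeper ridge levels keep their ridge widths
#' and become children on the flanks of the previous level's nodes
#' (`"chain"` policy) or all on the root flanks (`"spread"` policy),
#' distributed round-robin with alternating flank sides. Children are
#' geometric placeholders until the flank-fit criterion activates them
#' during dilation.
#'
#' @param ridges A [ridge_pattern()].
#' @param L Domain half-length (default: the ridge pattern's).
#' @param params A [material_params()].
#' @param policy Child-attachment policy, `"chain"` (default) or `"spread"`.
#' @return An object of class `fractal_tree` with a node data frame
#'   (`id`, `level`, `sigma`, `parent`, `side`, `amplitude`) where `side` is
#'   -1 (left flank) or +1 (right flank); attachment points sit at the parent
#'   inflection `centre + side * sigma_parent`.
#' @export
build_fractal <- function(ridges, L = ridges$L, params, policy = c("chain", "spread")) {
  stopifnot(inherits(ridges, "hierarchical_pattern"))
  policy <- match.arg(policy)
  lv <- ridges$levels
  K <- nrow(lv)
  n_root <- lv$N[1]
  sigma_root <- L / (2 * n_root)
  nodes <- data.frame(id = seq_len(n_root), level = 1L, sigma = sigma_root,
                      parent = NA_integer_, side = 0L, amplitude = 0)
  if (K >= 2L) {
    for (k in 2:K) {
      parents <- if (policy == "chain") nodes$id[nodes$level == k - 1L] else
        nodes$id[nodes$level == 1L]
      nk <- lv$N[k]
      pid <- parents[(seq_len(nk) - 1L) %% length(parents) + 1L]
      side <- ifelse(seq_len(nk) %% 2L == 1L, 1L, -1L)
      nodes <- rbind(nodes, data.frame(id = max(nodes$id) + seq_len(nk), level = k,
                                       sigma = lv$sigma[k], parent = pid,
                                       side = side, amplitude = 0))
    }
  }
  structure(list(nodes = nodes, L = L, ridge_levels = lv, policy = policy),
            class = "fractal_tree")
}

#' @export
print.fractal_tree <- function(x, ...) {
  cat(sprintf("<fractal_tree> %d node(s), %d level(s), policy = %s, L = %.4g\n",
              nrow(x$nodes), max(x$nodes$level), x$policy, x$L))
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' Total mechanical energy of a fractal spine tree
#'
#' Separated-Gaussian additivity extends to flank-attached bumps: the total
#' energy is the sum of each node's reduced bending and interaction terms,
#' and the excess length functional is likewise additive.
#'
#' @param tree A [build_fractal()] tree with node amplitudes set.
#' @param params A [material_params()].
#' @param convention `"reduced"` (default) or `"raw"`.
#' @return An `energy_breakdown`.
#' @export
fractal_energy <- function(tree, params, convention = c("reduced", "raw")) {
  convention <- match.arg(convention)
  stopifnot(inherits(tree, "fractal_tree"), inherits(params, "material_params"))
  nd <- tree$nodes
  bend <- nd$amplitude^2 / nd$sigma^3
  intr <- params$mu * nd$amplitude^params$m * nd$sigma
  fac <- if (convention == "raw") gauss_coef_bending() else 1
  per <- stats::aggregate(cbind(bending = bend, interaction = intr),
                          by = list(level = nd$level), FUN = sum)
  structure(list(bending = sum(bend) * fac, interaction = sum(intr) * fac,
                 total = sum(bend + intr) * fac,
                 per_level = data.frame(level = per$level, bending = per$bending * fac,
                                        interaction = per$interaction * fac),
                 convention = convention), class = "energy_breakdown")
}

#' Fractal-spine dilation of a ridge pattern
#'
#' Amplifies a [build_fractal()] tree over a burst: at each time the
#' amplitudes of the active levels minimize the reduced energy under the
#' shared length constraint, and a deeper level activates (irreversibly)
#' once its parents' amplitude passes the flank-fit criterion
#' [fractal_fit()].
#'
#' @inheritParams dilate_linear
#' @param tree Optional pre-built [build_fractal()] tree.
#' @param policy Passed to [build_fractal()] when `tree` is `NULL`.
#' @return A `pattern_trajectory` (per-level curves) with the final tree in
#'   attribute `"tree"`.
#' @export
dilate_fractal <- function(ridges, burst, params, t_max = 1, nt = 101L,
                           tree = NULL, policy = "chain") {
  stopifnot(inherits(ridges, "hierarchical_pattern"), inherits(burst, "growth_schedule"))
  if (is.null(tree)) tree <- build_fractal(ridges, params = params, policy = policy)
  nd <- tree$nodes
  K <- max(nd$level)
  N <- tabulate(nd$level, nbins = K)
  sigma <- vapply(seq_len(K), function(k) nd$sigma[match(k, nd$level)], numeric(1))
  time <- seq(0, t_max, length.out = nt)
  a <- matrix(0, nt, K)
  active <- 1L
  t_on <- c(0, rep(NA_real_, K - 1L))
  for (i in seq_len(nt)) {
    d <- burst$delta(time[i])
    if (d > 0) {
      idx <- seq_len(active)
      a[i, idx] <- .amplitudes_nomem(d, params$mu, params$m, N[idx], sigma[idx])$a
    }
    # flank-fit activation of the next level (parents are level `active`)
    while (active < K && fractal_fit(a[i, active], sigma[active + 1L])) {
      active <- active + 1L
      t_on[active] <- time[i]
    }
  }
  attained <- !is.na(t_on)
  lvout <- data.frame(level = seq_len(K), N = N, sigma = sigma, t_onset = t_on)[attained, ]
  tr <- .new_trajectory(time, a[, attained, drop = FALSE],
                        matrix(0, nt, sum(attained)), lvout, params, burst,
                        max_level = K)
  nd$amplitude <- a[nt, nd$level]
  tree$nodes <- nd
  attr(tr, "tree") <- tree
  tr
}

#' Compare linear and fractal-like dilation pathways
#'
#' Runs both dilation pathways from the same ridge pattern over the same
#' burst and compares the total reduced energies as functions of time. The
#' selected pathway is the one with the lower energy at the end of the
#' burst. Sparse ridge patterns (wide ridges) favour linear spines, dense
#' patterns favour the fractal-like pathway whose level-1 spine carries the
#' excess at domain width and low curvature.
#'
#' @inheritParams dilate_linear
#' @param burst Optional; defaults to a `"burst"` schedule starting at the
#'   ridge excess with rate `g_burst`.
#' @param g_burst Burst excess rate (used when `burst` is `NULL`).
#' @param policy Fractal attachment policy.
#' @return A list of class `dilation_result`: `linear`, `fractal`
#'   (trajectories), `energy` (data frame `t`, `linear`, `fractal`),
#'   `winner` (`"linear"` or `"fractal"`).
#' @export
compare_dilation <- function(ridges, burst = NULL, params, t_max = 1, nt = 101L,
                             g_burst = 1, policy = "chain") {
  stopifnot(inherits(ridges, "hierarchical_pattern"))
  if (is.null(burst))
    burst <- growth_schedule(L0 = ridges$L, g = 0, delta0 = attr(ridges, "delta") %||% 0,
                             type = "burst", g_burst = g_burst)
  lin <- dilate_linear(ridges, burst, params, t_max = t_max, nt = nt)
  fra <- dilate_fractal(ridges, burst, params, t_max = t_max, nt = nt, policy = policy)
  mu <- params$mu; m <- params$m
  e_of <- function(tr) vapply(seq_along(tr$time), function(i) {
    .levels_energy(tr$levels$N, tr$levels$sigma, tr$a[i, ], mu, m)
  }, numeric(1))
  energy <- data.frame(t = lin$time, linear = e_of(lin), fractal = e_of(fra))
  nlast <- nrow(energy)
  winner <- if (energy$linear[nlast] <= energy$fractal[nlast]) "linear" else "fractal"
  structure(list(linear = lin, fractal = fra, energy = energy, winner = winner),
            class = "dilation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dilation_result <- function(x, ...) {
  n <- nrow(x$energy)
  cat(sprintf("<dilation_result> winner: %s  (E_linear = %.5g, E_fractal = %.5g at t = %.3g)\n",
              x$winner, x$energy$linear[n], x$energy$fractal[n], x$energy$t[n]))
  invisible(x)
}
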