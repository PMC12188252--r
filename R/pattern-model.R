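# Domain types and bookkeeping for hierarchical Gaussian-bump patterns.
#
# Conventions: positions use the symmetric material coordinate S in [-L, L];
# a bump of width parameter sigma occupies a footprint of width 4*sigma;
# hierarchical levels are 1-based, level 1 being the first and largest.

.check_scalar <- function(x, name, lower = -Inf, strict = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

#' Create a single Gaussian bump
#'
#' A bump is the local unit of the pattern: a profile
#' `y(S) = a * exp(-(S - centre)^2 / sigma^2)` with footprint width `4*sigma`.
#' The memory amplitude is the amplitude of the remodelled foundation profile
#' co-centred with the bump (zero for a pristine foundation).
#'
#' @param amplitude Bump amplitude `a` (length units, >= 0).
#' @param sigma Width parameter `sigma` (length units, > 0).
#' @param centre Centre position in `[-L, L]`.
#' @param level Hierarchical level (integer >= 1).
#' @param memory Remodelled (memory) amplitude, `0 <= memory <= amplitude`
#'   whenever memory is initialized at zero and relaxed towards the shape.
#' @return An object of class `gaussian_bump`.
#' @examples
#' gaussian_bump(1, 0.5)
#' @export
gaussian_bump <- function(amplitude, sigma, centre = 0, level = 1L, memory = 0) {
  .check_scalar(amplitude, "amplitude", 0)
  .check_scalar(sigma, "sigma", 0, strict = TRUE)
  .check_scalar(centre, "centre")
  .check_scalar(level, "level", 1, integer = TRUE)
  .check_scalar(memory, "memory", 0)
  structure(list(amplitude = amplitude, sigma = sigma, centre = centre,
                 level = as.integer(level), memory = memory),
            class = "gaussian_bump")
}

#' @export
print.gaussian_bump <- function(x, ...) {
  cat(sprintf("<gaussian_bump> level %d: a = %.4g, sigma = %.4g, centre = %.4g, memory = %.4g\n",
              x$level, x$amplitude, x$sigma, x$centre, x$memory))
  invisible(x)
}

#' Recursive intercalation sequence of hierarchical levels
#'
#' Starting from `N1` level-1 bumps, each deeper level inserts one new bump
#' into every gap between adjacent existing bumps, so the number of new
#' level-(k+1) labels equals (total labels at depth k) - 1. The returned
#' left-to-right label sequence encodes both the spatial order and the
#' temporal order of appearance (1 first, deeper levels later and smaller).
#'
#' @param N1 Number of level-1 bumps (integer >= 2).
#' @param depth Number of hierarchical levels (integer >= 1).
#' @return Integer vector of level labels, left to right.
#' @examples
#' intercalation_sequence(2, 2) # 1 2 1
#' intercalation_sequence(2, 4) # 1 4 3 4 2 4 3 4 1
#' @export
intercalation_sequence <- function(N1, depth) {
  .check_scalar(N1, "N1", 2, integer = TRUE)
  .check_scalar(depth, "depth", 1, integer = TRUE)
  seqs <- rep(1L, N1)
  if (depth == 1L) return(seqs)
  for (k in 2L:depth) {
    n <- length(seqs)
    out <- integer(2L * n - 1L)
    out[seq(1L, 2L * n - 1L, by = 2L)] <- seqs
    out[seq(2L, 2L * n - 2L, by = 2L)] <- k
    seqs <- out
  }
  seqs
}

#' Per-level bump counts implied by intercalation
#'
#' @param N1 Number of level-1 bumps (integer >= 2).
#' @param max_level Deepest level to report.
#' @return Integer vector `N_k` for `k = 1..max_level`; `N_{k+1}` equals the
#'   total number of bumps present at depth `k` minus one (the gap count).
#' @examples
#' level_counts(2, 4) # 2 1 2 4
#' @export
level_counts <- function(N1, max_level) {
  .check_scalar(N1, "N1", 2, integer = TRUE)
  .check_scalar(max_level, "max_level", 1, integer = TRUE)
  N <- integer(max_level)
  N[1] <- as.integer(N1)
  total <- as.integer(N1)
  for (k in seq_len(max_level - 1L)) {
    N[k + 1L] <- total - 1L
    total <- total + N[k + 1L]
  }
  N
}

#' Create a hierarchical pattern of separated Gaussian bumps
#'
#' All bumps of one level share a width `sigma_k`, an amplitude `a_k` and a
#' memory amplitude; the left-to-right arrangement follows the intercalation
#' sequence. Centres are assigned by [place_bumps()] when the pattern fits.
#'
#' @param levels Data frame with columns `level`, `N`, `sigma`, `amplitude`
#'   and optionally `memory` (defaults to 0), one row per hierarchical level
#'   in increasing level order.
#' @param L Domain half-length (> 0); the domain is `[-L, L]`.
#' @param sequence Optional explicit label sequence (e.g. `c(3,2,3,1,3,2,3)`).
#'   Defaults to the intercalation sequence generated from `levels$N[1]`.
#' @param place If `TRUE` (default) and the pattern fits, assign bump centres.
#' @return An object of class `hierarchical_pattern` with fields `levels`,
#'   `L`, `sequence` and `bumps` (per-bump data frame).
#' @examples
#' lv <- data.frame(level = 1:2, N = c(2, 1), sigma = c(0.3, 0.15),
#'                  amplitude = c(0.5, 0.2))
#' hierarchical_pattern(lv, L = 2)
#' @export
hierarchical_pattern <- function(levels, L, sequence = NULL, place = TRUE) {
  stopifnot(is.data.frame(levels))
  req <- c("level", "N", "sigma", "amplitude")
  if (!all(req %in% names(levels)))
    stop("'levels' must have columns level, N, sigma, amplitude", call. = FALSE)
  if (is.null(levels$memory)) levels$memory <- 0
  .check_scalar(L, "L", 0, strict = TRUE)
  if (any(levels$sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  if (any(levels$amplitude < 0)) stop("all amplitudes must be >= 0", call. = FALSE)
  if (any(levels$memory < 0)) stop("all memory amplitudes must be >= 0", call. = FALSE)
  levels <- levels[order(levels$level), , drop = FALSE]
  if (is.null(sequence)) {
    if (levels$N[1] < 2 && nrow(levels) > 1)
      stop("intercalation needs N1 >= 2; supply an explicit 'sequence'", call. = FALSE)
    sequence <- if (nrow(levels) == 1L) rep(1L, levels$N[1]) else
      intercalation_sequence(levels$N[1], nrow(levels))
  }
  sequence <- as.integer(sequence)
  cnt <- tabulate(sequence, nbins = max(levels$level))
  if (!all(cnt[levels$level] == levels$N))
    stop("sequence label counts do not match levels$N", call. = FALSE)
  pat <- structure(list(levels = levels, L = L, sequence = sequence, bumps = NULL),
                   class = "hierarchical_pattern")
  if (place) pat <- place_bumps(pat, strict = FALSE)
  pat
}

#' Total footprint occupancy test
#'
#' @param pattern A [hierarchical_pattern()].
#' @return `TRUE` when the summed footprints fit in the domain,
#'   `sum(N_k * 4 sigma_k) <= 2 L`.
#' @export
pattern_fits <- function(pattern) {
  stopifnot(inherits(pattern, "hierarchical_pattern"))
  sum(pattern$levels$N * 4 * pattern$levels$sigma) <= 2 * pattern$L + 1e-12
}

#' Assign bump centres by equal-gap layout, advecting with growth
#'
#' For an unplaced pattern, footprints (width `4*sigma`) are laid out left to
#' right following the pattern's label sequence, with equal gaps between
#' adjacent footprints and at the two domain ends (n bumps share n+1 equal
#' gaps). Re-placing an already placed pattern into a different `L` advects
#' the centres affinely with the uniform domain expansion: doubling `L`
#' doubles every centre coordinate while the widths stay fixed.
#'
#' @param pattern A [hierarchical_pattern()].
#' @param L Domain half-length to place into (default: the pattern's own).
#' @param strict Reject layouts whose footprints cannot fit (default); with
#'   `strict = FALSE` an overlapping equal-(negative-)gap layout is returned.
#' @return The pattern with an updated `bumps` data frame
#'   (columns `centre`, `sigma`, `amplitude`, `level`, `memory`) and `L`.
#' @export
place_bumps <- function(pattern, L = pattern$L, strict = TRUE) {
  stopifnot(inherits(pattern, "hierarchical_pattern"))
  .check_scalar(L, "L", 0, strict = TRUE)
  if (!is.null(pattern$bumps) && L != pattern$L) {
    # material advection under uniform growth
    pattern$bumps$centre <- pattern$bumps$centre * (L / pattern$L)
    pattern$L <- L
    if (strict && !pattern_fits(pattern))
      stop("insufficient domain: footprints do not fit in [-L, L]", call. = FALSE)
    return(pattern)
  }
  lv <- pattern$levels
  sig <- setNames(lv$sigma, lv$level)[as.character(pattern$sequence)]
  amp <- setNames(lv$amplitude, lv$level)[as.character(pattern$sequence)]
  mem <- setNames(lv$memory, lv$level)[as.character(pattern$sequence)]
  w <- 4 * sig
  n <- length(w)
  gap <- (2 * L - sum(w)) / (n + 1)
  if (strict && gap < -1e-12)
    stop("insufficient domain: footprints do not fit in [-L, L]", call. = FALSE)
  if (gap < 0 && strict) gap <- 0
  left <- -L + gap + cumsum(c(0, w[-n] + gap))
  pattern$bumps <- data.frame(centre = left + w / 2, sigma = as.numeric(sig),
                              amplitude = as.numeric(amp), level = pattern$sequence,
                              memory = as.numeric(mem), row.names = NULL)
  pattern$L <- L
  pattern
}

#' @export
print.hierarchical_pattern <- function(x, ...) {
  cat(sprintf("<hierarchical_pattern> %d level(s), %d bump(s), L = %.4g\n",
              nrow(x$levels), sum(x$levels$N), x$L))
  cat("  sequence:", paste(x$sequence, collapse = "."), "\n")
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.hierarchical_pattern <- function(x, ...) {
  if (is.null(x$bumps)) x <- place_bumps(x)
  x$bumps
}

#' Serialize a pattern snapshot to JSON
#'
#' @param pattern A [hierarchical_pattern()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
pattern_to_json <- function(pattern, path = NULL) {
  stopifnot(inherits(pattern, "hierarchical_pattern"))
  obj <- list(L = pattern$L, sequence = pattern$sequence,
              levels = pattern$levels, bumps = as.data.frame(pattern))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a pattern snapshot from JSON
#'
#' @param path File path or JSON string produced by [pattern_to_json()].
#' @return A [hierarchical_pattern()].
#' @export
pattern_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  hierarchical_pattern(as.data.frame(obj$levels), L = obj$L,
                       sequence = obj$sequence)
}

#' Create a growth schedule for the two-layer system
#'
#' Time is dimensionless (non-dimensionalized on the growth rate of the
#' shorter layer). The default `"linear"` schedule grows the domain,
#' `L(t) = L0 (1 + t)`, with excess half-length `delta(t) = delta0 + g L0 t`
#' increasing at the constant dimensionless rate `g`. The `"burst"` schedule
#' models an episodic secretion burst: `L` is frozen at `L0` while
#' `delta(t) = delta0 + g_burst t` rises rapidly.
#'
#' @param L0 Initial domain half-length (> 0).
#' @param g Dimensionless excess-growth rate (>= 0).
#' @param delta0 Excess half-length already present at the start of the
#'   observation window (>= 0). Hierarchy simulations typically open with a
#'   small positive `delta0` so that an established level-1 pattern exists.
#' @param type `"linear"` or `"burst"`.
#' @param g_burst Burst excess rate; default `100 * g * L0`.
#' @return An object of class `growth_schedule` with function fields
#'   `L(t)`, `delta(t)`, `l(t) = L(t) + delta(t)`.
#' @examples
#' sched <- growth_schedule(L0 = 6, g = 0.1, delta0 = 0.04)
#' sched$delta(1)
#' @export
growth_schedule <- function(L0 = 6, g = 0.1, delta0 = 0, type = c("linear", "burst"),
                            g_burst = NULL) {
  type <- match.arg(type)
  .check_scalar(L0, "L0", 0, strict = TRUE)
  .check_scalar(g, "g", 0)
  .check_scalar(delta0, "delta0", 0)
  if (type == "burst") {
    if (is.null(g_burst)) g_burst <- 100 * g * L0
    .check_scalar(g_burst, "g_burst", 0)
    Lf <- function(t) rep_len(L0, length(t))
    df <- function(t) delta0 + g_burst * t
    rate <- g_burst
  } else {
    Lf <- function(t) L0 * (1 + t)
    df <- function(t) delta0 + g * L0 * t
    rate <- g * L0
  }
  structure(list(L0 = L0, g = g, delta0 = delta0, type = type, rate = rate,
                 L = Lf, delta = df, l = function(t) Lf(t) + df(t)),
            class = "growth_schedule")
}

#' @export
print.growth_schedule <- function(x, ...) {
  cat(sprintf("<growth_schedule> type = %s, L0 = %.4g, g = %.4g, delta0 = %.4g\n",
              x$type, x$L0, x$g, x$delta0))
  invisible(x)
}
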