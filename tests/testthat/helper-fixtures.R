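# Shared fixtures and independent quadrature helpers for the test suite.
# Everything here is built in code; the Gaussian-sum integrals are written
# out independently of the package internals so they can serve as oracles.

fix_params <- function(m = 4, mu = 30, eta = 0) material_params(m = m, mu = mu, eta = eta)

fix_schedule <- function(L0 = 6, g = 0.1, delta0 = 0.04, ...) {
  growth_schedule(L0 = L0, g = g, delta0 = delta0, ...)
}

# independent Gaussian-sum profile and derivatives from a bump table
gauss_sum <- function(b) {
  list(
    y = function(S) Reduce(`+`, lapply(seq_len(nrow(b)), function(i)
      b$amplitude[i] * exp(-(S - b$centre[i])^2 / b$sigma[i]^2))),
    d1 = function(S) Reduce(`+`, lapply(seq_len(nrow(b)), function(i) {
      u <- (S - b$centre[i]) / b$sigma[i]
      b$amplitude[i] * (-2 * u / b$sigma[i]) * exp(-u^2)
    })),
    d2 = function(S) Reduce(`+`, lapply(seq_len(nrow(b)), function(i) {
      u <- (S - b$centre[i]) / b$sigma[i]
      b$amplitude[i] * (4 * u^2 - 2) / b$sigma[i]^2 * exp(-u^2)
    })))
}

# raw-convention quadrature of bending, interaction and excess length
quad_raw <- function(b, mu_raw, m, lim = NULL) {
  if (is.null(lim)) lim <- max(abs(b$centre)) + 10 * max(b$sigma)
  f <- gauss_sum(b)
  list(
    bending = integrate(function(S) 0.5 * f$d2(S)^2, -lim, lim,
                        rel.tol = 1e-11, subdivisions = 800L)$value,
    interaction = mu_raw * integrate(function(S) f$y(S)^m, -lim, lim,
                                     rel.tol = 1e-11, subdivisions = 800L)$value,
    length = integrate(function(S) 0.5 * f$d1(S)^2, -lim, lim,
                       rel.tol = 1e-11, subdivisions = 800L)$value)
}

# reduced two-level energy with a1 eliminated through the length constraint,
# written out directly from the level-2 energy and constraint
reduced_E2_of_a2 <- function(a2, delta, mu, m, N1, N2, sigma1, sigma2) {
  x1 <- (2 * delta - N2 * a2^2 / sigma2) * sigma1 / N1
  if (x1 < 0) return(Inf)
  a1 <- sqrt(x1)
  N1 * a1^2 / sigma1^3 + N2 * a2^2 / sigma2^3 +
    mu * (N1 * a1^m * sigma1 + N2 * a2^m * sigma2)
}

# deterministic linear congruential sequence in (0, 1) for seeds-free loops
lcg_seq <- function(n, seed = 12345) {
  out <- numeric(n)
  s <- seed
  for (i in seq_len(n)) {
    s <- (1103515245 * s + 12345) %% 2147483648
    out[i] <- s / 2147483648
  }
  out
}
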