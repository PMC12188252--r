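# Width/mode selection, bifurcation times and amplitude curves.

test_that("optimal level-1 width has the closed forms and matches 1-D search", {
  # m = 2: delta-independent width mu^(-1/4)
  expect_equal(select_sigma1(0.5, mu = 16, m = 2), 16^(-0.25), tolerance = 1e-12)
  expect_equal(select_sigma1(3, mu = 16, m = 2), select_sigma1(0.01, mu = 16, m = 2))
  # m = 4: width scales as delta^(-1/5)
  r <- select_sigma1(0.2, mu = 30, m = 4) / select_sigma1(0.4, mu = 30, m = 4)
  expect_equal(r, 2^(1 / 5), tolerance = 1e-10)
  # independent 1-D search over the reduced energy
  for (cse in list(c(2, 5, 0.3, 1), c(3, 12, 0.2, 2), c(4, 40, 0.1, 3))) {
    m <- cse[1]; mu <- cse[2]; delta <- cse[3]; N1 <- cse[4]
    E1 <- function(s) 2 * delta / s^2 +
      mu * N1^(1 - m / 2) * (2 * delta)^(m / 2) * s^(1 + m / 2)
    opt <- optimize(E1, c(1e-3, 50), tol = 1e-10)$minimum
    expect_equal(select_sigma1(delta, mu, m, N1), opt, tolerance = 1e-4)
  }
  expect_error(select_sigma1(0.5, mu = 0, m = 4), "foundation")
  expect_error(select_sigma1(0, mu = 3, m = 4), "delta")
})

test_that("mode selection takes the maximal fitting count", {
  expect_identical(select_mode(2, 0.25), 4L)
  expect_error(select_mode(0.4, 0.25), "pre-buckling")
  # reduced level-1 energy decreases with the mode at fixed width and excess
  m <- 4; mu <- 30; delta <- 0.3; s <- 0.4
  E1N <- function(N) 2 * delta / s^2 + mu * N^(1 - m / 2) * (2 * delta)^(m / 2) * s^(1 + m / 2)
  expect_true(all(diff(vapply(1:6, E1N, numeric(1))) < 0))
})

test_that("level-1 amplitude follows the square-root post-buckling law", {
  expect_equal(level1_amplitude(0, 1, 2), 0)
  expect_equal(level1_amplitude(1, 1, 2), 1)
  tt <- seq(0.1, 2, by = 0.1)
  a <- level1_amplitude(0.3 * tt, sigma1 = 0.5, N1 = 3)
  expect_equal(a, sqrt(0.3 * 0.5 * 2 / 3) * sqrt(tt), tolerance = 1e-12)
})

test_that("level-2 solution matches brute-force constrained minimization", {
  p <- fix_params(m = 4, mu = 30)
  s <- fix_schedule()
  sol <- solve_level2(p, s, t_max = 2, dt = 0.005)
  expect_true(sol$bifurcated)
  tr <- sol$trajectory
  N1 <- tr$levels$N[1]; N2 <- tr$levels$N[2]
  s1 <- tr$levels$sigma[1]; s2 <- tr$levels$sigma[2]
  # a2 vanishes at onset and grows after
  i2 <- which(tr$time >= sol$t2)[1:40]
  expect_lt(tr$a[i2[1], 2], 0.05)
  expect_true(all(diff(tr$a[i2, 2]) >= -1e-12))
  # brute force: minimize the reduced two-level energy over a2 directly
  for (tt in quantile(tr$time[tr$time > sol$t2 * 1.05], c(0.1, 0.4, 0.8))) {
    i <- which.min(abs(tr$time - tt))
    delta <- s$delta(tr$time[i])
    a2_max <- sqrt(2 * delta * s2 / N2)
    br <- optimize(reduced_E2_of_a2, c(0, a2_max), delta = delta, mu = p$mu,
                   m = p$m, N1 = N1, N2 = N2, sigma1 = s1, sigma2 = s2,
                   tol = 1e-12)$minimum
    expect_equal(tr$a[i, 2], br, tolerance = 1e-6)
    # a1 from the shared constraint
    a1 <- sqrt((2 * delta - N2 * tr$a[i, 2]^2 / s2) * s1 / N1)
    expect_equal(tr$a[i, 1], a1, tolerance = 1e-9)
  }
})

test_that("quadratic interaction never bifurcates to level 2", {
  for (mu in c(0.1, 1, 10, 100)) {
    p <- material_params(m = 2, mu = mu)
    sol <- solve_level2(p, fix_schedule(L0 = 6, g = 0.2, delta0 = 0.05), t_max = 3, dt = 0.01)
    expect_false(sol$bifurcated)
    expect_match(sol$reason, "quadratic")
    # the onset margin is non-negative for every narrower level-2 width
    s1 <- mu^(-0.25)
    for (s2fac in c(0.1, 0.3, 0.5, 0.8, 0.99))
      for (delta in c(0.01, 0.1, 1, 10))
        expect_gte(level2_onset_margin(delta, s1, s1 * s2fac, p, N1 = 4), 0)
  }
  # contrast: the quartic margin does go negative at large excess
  p4 <- material_params(m = 4, mu = 30)
  s1 <- select_sigma1(0.5, 30, 4, 2)
  expect_lt(level2_onset_margin(5, s1, 0.5 * s1, p4, N1 = 2), 0)
})

test_that("hierarchy trajectories conserve length and order bifurcations", {
  p <- fix_params(m = 4, mu = 30)
  s <- fix_schedule()
  tr <- solve_hierarchy(p, s, t_max = 4, max_level = 5, dt = 0.01)
  expect_gte(nrow(tr$levels), 4)
  expect_true(all(diff(tr$levels$t_onset) > 0))
  # length conservation at every output time past onset
  on <- tr$time >= tr$levels$t_onset[1]
  len <- rowSums(sweep(tr$a[on, ]^2, 2, tr$levels$N / tr$levels$sigma, `*`))
  expect_equal(len, 2 * s$delta(tr$time[on]), tolerance = 1e-9)
  # amplitudes non-decreasing under linear growth without memory
  for (k in seq_len(ncol(tr$a)))
    expect_true(all(diff(tr$a[, k]) >= -1e-10))
  # intercalation counts from the canonical two-primary start
  tr2 <- solve_hierarchy(p, s, t_max = 4, max_level = 4, dt = 0.01, N1 = 2)
  expect_identical(tr2$levels$N, c(2L, 1L, 2L, 4L))
})

test_that("level-1 growth slows when level 2 appears", {
  p <- fix_params(m = 4, mu = 30)
  s <- fix_schedule()
  with2 <- solve_hierarchy(p, s, t_max = 1.5, max_level = 2, dt = 0.005)
  alone <- solve_hierarchy(p, s, t_max = 1.5, max_level = 1, dt = 0.005)
  t2 <- with2$levels$t_onset[2]
  after <- with2$time > t2 + 0.1
  expect_true(all(with2$a[after, 1] < alone$a[after, 1]))
  before <- with2$time < t2
  expect_equal(with2$a[before, 1], alone$a[before, 1], tolerance = 1e-12)
})

test_that("cubic interaction path also minimizes the constrained energy", {
  p <- material_params(m = 3, mu = 20)
  s <- fix_schedule(L0 = 6, g = 0.2, delta0 = 0.1)
  tr <- solve_hierarchy(p, s, t_max = 2, max_level = 3, dt = 0.02)
  on <- tr$time >= tr$levels$t_onset[1]
  len <- rowSums(sweep(tr$a[on, , drop = FALSE]^2, 2,
                       tr$levels$N / tr$levels$sigma, `*`))
  expect_equal(len, 2 * s$delta(tr$time[on]), tolerance = 1e-9)
  if (nrow(tr$levels) >= 2) {
    # brute-force check at one time for m = 3
    i <- length(tr$time)
    delta <- s$delta(tr$time[i])
    N1 <- tr$levels$N[1]; N2 <- tr$levels$N[2]
    s1 <- tr$levels$sigma[1]; s2 <- tr$levels$sigma[2]
    if (nrow(tr$levels) == 2) {
      br <- optimize(reduced_E2_of_a2, c(0, sqrt(2 * delta * s2 / N2)),
                     delta = delta, mu = p$mu, m = 3, N1 = N1, N2 = N2,
                     sigma1 = s1, sigma2 = s2, tol = 1e-12)$minimum
      expect_equal(tr$a[i, 2], br, tolerance = 1e-5)
    }
  }
})

test_that("amplitude onset is square-root in time for linear excess growth", {
  p <- fix_params(m = 4, mu = 30)
  s <- growth_schedule(L0 = 6, g = 0.1, delta0 = 0)
  tr <- solve_hierarchy(p, s, t_max = 0.6, max_level = 1, dt = 0.002)
  t1 <- tr$levels$t_onset[1]
  sel <- tr$time > max(10 * t1, 0.02) & tr$time < 0.5
  fit <- lm(log(tr$a[sel, 1]) ~ log(tr$time[sel] - t1))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.02)
})
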