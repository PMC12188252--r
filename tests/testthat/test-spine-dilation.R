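# Burst dilation: linear versus fractal-like spines.

ridge_seq <- c(3L, 2L, 3L, 1L, 3L, 2L, 3L)

test_that("ridge fixtures tile the domain with the requested density", {
  p <- fix_params(m = 4, mu = 10)
  for (L in c(1, 3)) {
    r <- ridge_pattern(ridge_seq, L = L, params = p, delta = 0.04)
    expect_equal(sum(r$levels$N * 4 * r$levels$sigma), 2 * L, tolerance = 1e-12)
    expect_identical(r$levels$N, c(1L, 2L, 4L))
    expect_true(pattern_fits(r))
    expect_equal(attr(r, "delta"), 0.04)
  }
  # halving L halves every width (density doubles)
  r3 <- ridge_pattern(ridge_seq, L = 3, params = p)
  r1 <- ridge_pattern(ridge_seq, L = 1, params = p)
  expect_equal(r1$levels$sigma, r3$levels$sigma / 3)
})

test_that("linear dilation amplifies in place and conserves length", {
  p <- fix_params(m = 4, mu = 10)
  r <- ridge_pattern(ridge_seq, L = 3, params = p, delta = 0.04)
  burst <- growth_schedule(L0 = 3, g = 0, delta0 = 0.04, type = "burst", g_burst = 1)
  tr <- dilate_linear(r, burst, p, t_max = 1, nt = 41)
  expect_equal(tr$levels$sigma, r$levels$sigma)
  len <- rowSums(sweep(tr$a^2, 2, tr$levels$N / tr$levels$sigma, `*`))
  expect_equal(len, 2 * burst$delta(tr$time), tolerance = 1e-9)
  # constant excess reproduces the ridge amplitudes (no burst)
  still <- growth_schedule(L0 = 3, g = 0, delta0 = 0.04, type = "burst", g_burst = 0)
  tr0 <- dilate_linear(r, still, p, t_max = 1, nt = 5)
  for (i in 1:5) expect_equal(tr0$a[i, ], r$levels$amplitude, tolerance = 1e-9)
  # energy grows with the excess
  e <- vapply(seq_along(tr$time), function(i)
    sum(tr$levels$N * tr$a[i, ]^2 / tr$levels$sigma^3) +
      p$mu * sum(tr$levels$N * tr$a[i, ]^4 * tr$levels$sigma), numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("flank-fit criterion is monotone with boundary included", {
  expect_false(fractal_fit(0, 0.2))
  expect_true(fractal_fit(0.8, 0.2))   # exactly 4*sigma
  expect_true(fractal_fit(gaussian_bump(1, 0.5), 0.2))
  amps <- seq(0, 2, by = 0.05)
  fits <- vapply(amps, fractal_fit, logical(1), child_sigma = 0.3)
  expect_true(all(diff(fits) >= 0)) # once true, stays true
})

test_that("fractal trees attach children per policy with domain-wide roots", {
  p <- fix_params(m = 4, mu = 10)
  r <- ridge_pattern(ridge_seq, L = 1, params = p)
  tree <- build_fractal(r, params = p)
  nd <- tree$nodes
  expect_equal(nd$sigma[nd$level == 1], 0.5)           # 4*sigma_root = 2L
  expect_true(all(is.na(nd$parent[nd$level == 1])))
  # chain policy: level-3 nodes hang off level-2 nodes
  l2 <- nd$id[nd$level == 2]
  expect_true(all(nd$parent[nd$level == 2] %in% nd$id[nd$level == 1]))
  expect_true(all(nd$parent[nd$level == 3] %in% l2))
  # children are narrower than their parents
  for (i in which(!is.na(nd$parent)))
    expect_lt(nd$sigma[i], nd$sigma[match(nd$parent[i], nd$id)])
  # spread policy: everything attaches to the root
  sp <- build_fractal(r, params = p, policy = "spread")$nodes
  expect_true(all(sp$parent[sp$level > 1] %in% sp$id[sp$level == 1]))
  # single-level input degenerates to the linear layout
  r1 <- ridge_pattern(c(1L, 1L), L = 2, params = p)
  t1 <- build_fractal(r1, params = p)
  expect_equal(t1$nodes$sigma, r1$levels$sigma[c(1, 1)])
})

test_that("fractal energy is additive over nodes", {
  p <- fix_params(m = 4, mu = 10)
  r <- ridge_pattern(ridge_seq, L = 1, params = p)
  tree <- build_fractal(r, params = p)
  tree$nodes$amplitude <- c(1, 0.4, 0.4, 0.1, 0.1, 0.1, 0.1)
  e <- fractal_energy(tree, p)
  nd <- tree$nodes
  manual <- sum(nd$amplitude^2 / nd$sigma^3) + p$mu * sum(nd$amplitude^4 * nd$sigma)
  expect_equal(e$total, manual, tolerance = 1e-12)
  # root only
  tree$nodes$amplitude <- c(0.7, rep(0, 6))
  expect_equal(fractal_energy(tree, p)$total,
               0.7^2 / 0.5^3 + p$mu * 0.7^4 * 0.5, tolerance = 1e-12)
})

test_that("zero excess produces no fractal children and equal energies", {
  p <- fix_params(m = 4, mu = 10)
  r <- ridge_pattern(ridge_seq, L = 1, params = p, delta = 0)
  still <- growth_schedule(L0 = 1, g = 0, delta0 = 0, type = "burst", g_burst = 0)
  tr <- dilate_fractal(r, still, p, t_max = 1, nt = 5)
  expect_identical(nrow(tr$levels), 1L) # root never spawns children
  expect_true(all(tr$a == 0))
  res <- compare_dilation(r, still, p, t_max = 1, nt = 5)
  expect_equal(res$energy$linear, rep(0, 5))
  expect_equal(res$energy$fractal, rep(0, 5))
})

test_that("ridge density decides the winning dilation pathway", {
  p <- fix_params(m = 4, mu = 10)
  sparse <- compare_dilation(ridge_pattern(ridge_seq, L = 3, params = p, delta = 0.04),
                             params = p, t_max = 1, nt = 41, g_burst = 1)
  expect_identical(sparse$winner, "linear")
  dense <- compare_dilation(ridge_pattern(ridge_seq, L = 1, params = p, delta = 0.04),
                            params = p, t_max = 1, nt = 41, g_burst = 1)
  expect_identical(dense$winner, "fractal")
  # level ordering preserved along both pathways
  for (res in list(sparse, dense)) for (tr in list(res$linear, res$fractal)) {
    for (k in seq_len(ncol(tr$a) - 1))
      expect_true(all(tr$a[, k] >= tr$a[, k + 1] - 1e-9))
    len <- rowSums(sweep(tr$a^2, 2, tr$levels$N / tr$levels$sigma, `*`))
    expect_equal(len, 2 * tr$schedule$delta(tr$time), tolerance = 1e-9)
  }
  # in the dense linear pathway the level-2 amplification never onsets
  expect_lt(max(dense$linear$a[, 2]), 1e-9)
})
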