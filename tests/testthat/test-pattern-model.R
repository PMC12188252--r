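# Intercalation bookkeeping, bump placement and growth schedules.

test_that("intercalation sequence reproduces the canonical series", {
  expect_identical(intercalation_sequence(2, 1), c(1L, 1L))
  expect_identical(intercalation_sequence(2, 2), c(1L, 2L, 1L))
  expect_identical(intercalation_sequence(2, 3), c(1L, 3L, 2L, 3L, 1L))
  expect_identical(intercalation_sequence(2, 4),
                   c(1L, 4L, 3L, 4L, 2L, 4L, 3L, 4L, 1L))
  # gap-insertion applied by hand for three primaries
  expect_identical(intercalation_sequence(3, 2), c(1L, 2L, 1L, 2L, 1L))
})

test_that("intercalation counts follow the gap rule at every depth", {
  # independent recursion: insert into gaps one by one
  brute <- function(N1, depth) {
    s <- rep(1L, N1)
    for (k in seq_len(depth - 1L) + 1L) {
      out <- s[1]
      for (i in seq_len(length(s) - 1L)) out <- c(out, k, s[i + 1L])
      s <- out
    }
    s
  }
  for (N1 in 2:4) for (d in 1:8) {
    s <- intercalation_sequence(N1, d)
    expect_identical(s, brute(N1, d))
    expect_identical(s, rev(s)) # palindromic
    if (d >= 2) expect_identical(sum(s == d), length(intercalation_sequence(N1, d - 1)) - 1L)
  }
  # closed-form total for two primaries
  for (d in 1:10)
    expect_identical(length(intercalation_sequence(2, d)), as.integer(2^(d - 1) + 1))
  expect_identical(level_counts(2, 4), c(2L, 1L, 2L, 4L))
  expect_identical(level_counts(2, 5), c(2L, 1L, 2L, 4L, 8L))
})

test_that("invalid intercalation arguments are rejected", {
  expect_error(intercalation_sequence(1, 2), "N1")
  expect_error(intercalation_sequence(2, 0), "depth")
  expect_error(intercalation_sequence(2.5, 2), "integer")
  expect_error(level_counts(1, 3), "N1")
})

test_that("equal-gap placement matches hand-solved layouts and advects affinely", {
  lv <- data.frame(level = 1, N = 2, sigma = 0.25, amplitude = 0.1)
  pat <- hierarchical_pattern(lv, L = 1, sequence = c(1L, 1L))
  expect_equal(pat$bumps$centre, c(-0.5, 0.5))
  one <- hierarchical_pattern(data.frame(level = 1, N = 1, sigma = 0.2, amplitude = 0),
                              L = 1, sequence = 1L)
  expect_equal(one$bumps$centre, 0)
  # affine advection under domain doubling
  pat2 <- place_bumps(pat, L = 2)
  expect_equal(pat2$bumps$centre, 2 * pat$bumps$centre)
  # fit violation
  expect_error(place_bumps(pat, L = 0.4), "insufficient domain")
})

test_that("placed footprints never overlap for randomized valid patterns", {
  u <- lcg_seq(60)
  for (r in 1:20) {
    K <- 1 + (r %% 3)
    N <- level_counts(2, max(K, 2))[seq_len(K)]
    sig1 <- 0.2 + 0.5 * u[3 * r - 2]
    sigma <- sig1 * (0.4 + 0.3 * u[3 * r - 1])^(seq_len(K) - 1)
    L <- sum(N * 4 * sigma) / 2 * (1.02 + u[3 * r])
    lv <- data.frame(level = seq_len(K), N = N, sigma = sigma,
                     amplitude = 0.1 * seq(K, 1))
    pat <- hierarchical_pattern(lv, L = L)
    b <- pat$bumps[order(pat$bumps$centre), ]
    if (nrow(b) > 1) {
      gaps <- diff(b$centre) - 2 * (head(b$sigma, -1) + tail(b$sigma, -1))
      expect_true(all(gaps >= -1e-9))
    }
    expect_true(all(abs(b$centre) + 2 * b$sigma <= L + 1e-9))
  }
})

test_that("pattern construction validates its inputs", {
  lv <- data.frame(level = 1:2, N = c(2, 1), sigma = c(0.3, -0.1), amplitude = 0)
  expect_error(hierarchical_pattern(lv, L = 2), "sigma")
  lv$sigma <- c(0.3, 0.15)
  expect_error(hierarchical_pattern(lv, L = 2, sequence = c(1L, 1L, 2L, 2L)),
               "sequence")
  ok <- hierarchical_pattern(lv, L = 2)
  expect_identical(ok$sequence, c(1L, 2L, 1L))
})

test_that("growth schedules satisfy the monotone growth invariants", {
  ts <- seq(0, 5, by = 0.25)
  lin <- growth_schedule(L0 = 2, g = 0.3, delta0 = 0)
  expect_equal(lin$delta(0), 0)
  expect_true(all(diff(lin$L(ts)) > 0))
  expect_true(all(diff(lin$delta(ts)) > 0))
  expect_equal(lin$l(ts), lin$L(ts) + lin$delta(ts))
  bur <- growth_schedule(L0 = 2, g = 0.3, delta0 = 0.1, type = "burst")
  expect_true(all(bur$L(ts) == 2))
  expect_equal(bur$delta(1) - bur$delta(0), 100 * 0.3 * 2)
  expect_error(growth_schedule(L0 = -1), "L0")
})

test_that("pattern snapshots round-trip through JSON", {
  lv <- data.frame(level = 1:2, N = c(2, 1), sigma = c(0.3, 0.15),
                   amplitude = c(0.5, 0.2))
  pat <- hierarchical_pattern(lv, L = 2)
  tmp <- tempfile(fileext = ".json")
  pattern_to_json(pat, tmp)
  back <- pattern_from_json(tmp)
  expect_equal(back$levels$sigma, pat$levels$sigma)
  expect_equal(back$bumps$centre, pat$bumps$centre)
  expect_identical(back$sequence, pat$sequence)
})
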