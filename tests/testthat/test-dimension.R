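test_that("noiseless power laws recover (D, c) for any valid window", {
  s <- make_series(3 * (1:7)^1.7)
  for (w in list(c(1, 7), c(1, 6), c(2, 5), c(3, 7))) {
    fit <- fit_dimension(s, w)
    expect_equal(fit$D, 1.7, tolerance = 1e-9)
    expect_equal(fit$c, 3, tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
  }
  # magnitude rescaling moves c, never D
  s10 <- make_series(10 * 3 * (1:7)^1.7)
  expect_equal(fit_dimension(s10, c(1, 7))$D, fit_dimension(s, c(1, 7))$D,
               tolerance = 1e-12)
  expect_equal(fit_dimension(s10, c(1, 7))$c, 30, tolerance = 1e-9)

  expect_error(fit_dimension(s, c(1, 2)), "at least 3")
  expect_error(fit_dimension(s, c(5, 9)), "exceeds")
  s0 <- make_series(c(0, 2, 3, 4))
  expect_error(fit_dimension(s0, c(1, 4)), "g1")
})

test_that("dimension fits over the bundled windows reproduce the D table", {
  panel <- chick_myogenesis()
  printed <- data.frame(
    breed = rep(c("BR", "WC", "PRW", "YC", "BB", "OMF", "LR", "UG"), each = 2),
    tissue = rep(c("breast", "thigh"), 8),
    D = c(0.400, 0.954, 1.289, 11.211, 0.717, 1.509, 4.104, 3.377,
          2.968, 2.122, 2.984, 1.1325, 3.109, 1.859, 3.740, 0.632))
  fits <- breed_dimension_fits(panel$expression, windows = panel$windows)
  merged <- merge(fits$fits, printed, by = c("breed", "tissue"))
  expect_equal(nrow(merged), 16L)
  expect_true(all(abs(merged$D.x - merged$D.y) < 0.005))
  # MGEFDI from unrounded slopes
  idx <- fits$indices
  expect_equal(idx$mgefdi[idx$breed == "YC"], 1.215, tolerance = 5e-3 / 1.215)
  expect_equal(idx$mgefdi[idx$breed == "UG"], 5.915, tolerance = 5e-3 / 5.915)
  expect_equal(compute_mgefdi(2, 2), 1)
  expect_error(compute_mgefdi(1, 0), "d_thigh = 0")
})

test_that("window selection maximises r2 and honours manual overrides", {
  # manual override always wins
  s <- make_series(3 * (1:7)^2)
  expect_equal(select_window(s, default = c(1, 6), override = c(2, 7)),
               c(2L, 7L))
  # exact power law: the full search range wins (tie broken by length)
  expect_equal(select_window(s, default = c(1, 6)), c(1L, 7L))
  # power law on ranks 3-7 with off-curve points at ranks 1-2
  m <- 2 * (1:7)^1.5
  m[1:2] <- c(0.9 * m[1], 1.2 * m[2]) # still ascending, off the line
  s2 <- make_series(m)
  expect_equal(select_window(s2, default = c(1, 6)), c(3L, 7L))
  expect_error(select_window(make_series(c(1, 2)), default = c(1, 2)),
               "shorter")

  # equivalence with exhaustive enumeration over the same search space
  set.seed(7)
  for (i in 1:10) {
    mags <- sort(abs(stats::rnorm(7, sd = 10)) + 0.05)
    sr <- make_series(mags)
    chosen <- select_window(sr, default = c(1, 6))
    cands <- do.call(rbind, lapply(1:5, function(lo) {
      do.call(rbind, lapply((lo + 2):7, function(hi) {
        c(lo, hi, fit_dimension(sr, c(lo, hi))$r2)
      }))
    }))
    top <- cands[cands[, 3] >= max(cands[, 3]) - 1e-12, , drop = FALSE]
    top <- top[top[, 2] - top[, 1] == max(top[, 2] - top[, 1]), , drop = FALSE]
    best <- top[which.min(top[, 1]), 1:2]
    expect_equal(chosen, as.integer(best))
  }
})

test_that("selected windows recover the dimension under multiplicative noise", {
  n_seed <- 200L
  err <- numeric(n_seed)
  for (s in seq_len(n_seed)) {
    tab <- generate_power_law(
      synth_spec("power_law", n_breeds = 1, n_genes = 7,
                 params = list(c = 1, D = 2), noise_sd = 0.05, seed = s))
    ser <- rank_series(tab, "b1", "breast")
    w <- select_window(ser, default = c(1, 6))
    err[s] <- abs(fit_dimension(ser, w)$D - 2)
  }
  expect_true(all(err <= 0.5))
  expect_gte(mean(err <= 0.3), 0.95)
})

test_that("dimension relates negatively to four-week body weight", {
  panel <- chick_myogenesis()
  fits <- breed_dimension_fits(panel$expression, windows = panel$windows)
  dims_br <- fits$fits[fits$fits$tissue == "breast", c("breed", "D")]
  reg <- dimension_trait_regression(dims_br, panel$phenotypes, "bw28")
  expect_lt(reg$slope, 0)
  expect_true(reg$r2 >= 0 && reg$r2 <= 1)
  # constant trait: zero slope, zero r2
  ph0 <- data.frame(breed = dims_br$breed, bw28 = 100)
  reg0 <- dimension_trait_regression(dims_br, ph0, "bw28")
  expect_equal(reg0$slope, 0)
  expect_equal(reg0$r2, 0)
  # three points on a line
  dl <- data.frame(breed = c("a", "b", "c"), D = 1:3)
  pl <- data.frame(breed = c("a", "b", "c"), bw28 = c(10, 20, 30))
  expect_equal(suppressWarnings(dimension_trait_regression(dl, pl, "bw28"))$r2,
               1, tolerance = 1e-12)
  expect_error(dimension_trait_regression(dl[1:2, ], pl, "bw28"), "3 breeds")
})

test_that("the pointwise log-ratio utility is deprecated but consistent", {
  expect_warning(v <- pointwise_dimension(c(4, 9), c(2, 3)), "deprecated")
  expect_equal(v, log10(c(4, 9)) / log10(c(2, 3)))
})
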