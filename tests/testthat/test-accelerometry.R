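# Static/dynamic decomposition, VeDBA, and fix-anchored windowed means.

test_that("decomposition is exact on constant signals and additive by construction", {
  tr <- make_trace(rep(0, 400), rep(0, 400), rep(1, 400))
  d <- decompose(tr)
  expect_equal(d$sx, rep(0, 400))
  expect_equal(d$sz, rep(1, 400))
  expect_equal(d$dx, rep(0, 400))
  expect_equal(d$dz, rep(0, 400))

  set.seed(1)
  tr <- make_trace(rnorm(500), rnorm(500), 1 + rnorm(500))
  d <- decompose(tr)
  # raw = static + dynamic exactly, every sample, every axis
  expect_equal(d$ax - (d$sx + d$dx), rep(0, 500))
  expect_equal(d$ay - (d$sy + d$dy), rep(0, 500))
  expect_equal(d$az - (d$sz + d$dz), rep(0, 500))
})

test_that("decomposition rejects degenerate traces", {
  expect_error(accel_trace(numeric(0), numeric(0), numeric(0), numeric(0), 40),
               "empty")
  tr <- make_trace(rnorm(10), rnorm(10), rnorm(10))
  tr$time <- rev(tr$time)
  expect_error(decompose(tr), "increasing")
  expect_error(decompose(make_trace(1:5, 1:5, 1:5), window = 0), "positive")
})

test_that("decompose matches the naive sliding-mean oracle to 1e-12", {
  for (rate in c(40, 20)) {
    set.seed(rate)
    n <- 5000
    t <- seq_len(n) / rate
    # sinusoid of period 0.25 s on unit gravity plus noise
    ax <- 0.3 * sin(2 * pi * 4 * t) + rnorm(n, 0, 0.05)
    tr <- accel_trace(t, ax, rnorm(n, 0, 0.05), 1 + rnorm(n, 0, 0.05), rate)
    d <- decompose(tr, window = 2)
    n_win <- round(2 * rate); if (n_win %% 2 == 0) n_win <- n_win + 1
    expect_equal(d$sx, naive_sliding_mean(tr$ax, n_win), tolerance = 1e-12)
    expect_equal(d$sz, naive_sliding_mean(tr$az, n_win), tolerance = 1e-12)
    # interior static stays near gravity for a fast sinusoid
    interior <- (n_win):(n - n_win)
    expect_lt(max(abs(d$sz[interior] -
                      naive_sliding_mean(tr$az, n_win)[interior])), 1e-12)
  }
})

test_that("decomposition with gaps is per-burst (window never crosses a gap)", {
  rate <- 40
  t <- c(seq_len(200) / rate, 1000 + seq_len(200) / rate)
  set.seed(2)
  x <- c(rep(1, 200), rep(5, 200)) + rnorm(400, 0, 0.01)
  tr <- accel_trace(t, x, x, x, rate)
  d <- decompose(tr)
  # static in the first burst never sees the level-5 burst
  expect_lt(max(d$sx[1:200]), 1.05)
  expect_gt(min(d$sx[201:400]), 4.95)
})

test_that("vedba computes the norm of the dynamic components", {
  tr <- make_trace(rnorm(10), rnorm(10), rnorm(10))
  expect_error(vedba(tr), "decompose")
  d <- decompose(tr)
  d$dx <- rep(0, 10); d$dy <- rep(0, 10); d$dz <- rep(0, 10)
  expect_equal(vedba(d)$vedba, rep(0, 10))
  d$dx <- rep(0.1, 10); d$dy <- rep(0.2, 10); d$dz <- rep(0.2, 10)
  expect_equal(vedba(d)$vedba, rep(0.3, 10))
  d$dx <- rep(0.19, 10); d$dy <- rep(0, 10); d$dz <- rep(0, 10)
  expect_equal(vedba(d)$vedba, rep(0.19, 10))
})

test_that("VeDBA is invariant to axis permutation/sign flips and scales linearly", {
  set.seed(3)
  tr <- make_trace(rnorm(300), rnorm(300), 1 + rnorm(300))
  d <- decompose(tr)
  v0 <- vedba(d)$vedba
  # permute and flip the dynamic axes
  d2 <- d
  d2$dx <- -d$dz; d2$dy <- d$dx; d2$dz <- -d$dy
  expect_equal(vedba(d2)$vedba, v0)
  for (k in c(0, 0.5, 3)) {
    dk <- d
    dk$dx <- k * d$dx; dk$dy <- k * d$dy; dk$dz <- k * d$dz
    expect_equal(vedba(dk)$vedba, k * v0)
  }
})

test_that("fix-anchored means match a brute-force window oracle", {
  set.seed(4)
  rate <- 40
  t <- seq_len(8000) / rate
  # leave a gap to exercise partial coverage
  keep <- t < 100 | t > 130
  tr <- accel_trace(t[keep], rnorm(sum(keep)), rnorm(sum(keep)),
                    1 + rnorm(sum(keep)), rate)
  vs <- vedba(decompose(tr))
  fixes <- runif(50, 5, 195)
  got <- mean_vedba_at_fixes(vs, fixes, half_width = 30)
  want <- vapply(fixes, function(f)
    naive_window_mean(as.numeric(vs$time), vs$vedba, f, 30), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  # constant series returns the constant; empty window returns NA not 0
  vs2 <- vs; vs2$vedba <- rep(0.37, nrow(vs2))
  expect_equal(mean_vedba_at_fix(vs2, 50), 0.37)
  expect_true(is.na(mean_vedba_at_fix(vs2, 115, half_width = 10)))
})

test_that("20 Hz and 40 Hz traces of the same signal agree in windowed means", {
  # deterministic dynamic signal on unit gravity, sampled at both rates
  # carriers well below the 20 Hz trace's Nyquist frequency
  f <- function(t) 0.1 * abs(sin(2 * pi * 0.8 * t)) + 0.02
  build <- function(rate) {
    t <- seq(0, 300, by = 1 / rate)
    accel_trace(t, f(t) * sin(2 * pi * 2 * t), f(t) * cos(2 * pi * 2 * t),
                1 + f(t) * sin(2 * pi * 1.3 * t), rate)
  }
  fixes <- seq(40, 260, by = 20)
  m40 <- mean_vedba_at_fixes(vedba(decompose(build(40))), fixes)
  m20 <- mean_vedba_at_fixes(vedba(decompose(build(20))), fixes)
  expect_equal(m20, m40, tolerance = 0.02)
})

test_that("window sensitivity flags the plateau of an autocorrelated series", {
  set.seed(5)
  rate <- 10
  n <- 36000
  # AR(1) VeDBA with ~60 s correlation time
  phi <- exp(-1 / (60 * rate))
  z <- as.numeric(stats::arima.sim(list(ar = phi), n)) * sqrt(1 - phi^2)
  vs <- structure(data.frame(time = seq_len(n) / rate, vedba = 0.1 + 0.02 * z),
                  class = c("vedba_series", "data.frame"))
  fixes <- seq(300, 3300, by = 50)
  widths <- c(10, 30, 60, 120, 240)
  out <- window_sensitivity(vs, fixes, widths)
  expect_equal(nrow(out), length(widths))
  # widening the window averages over the ~60 s correlation time, so the
  # dispersion of per-fix means shrinks steadily toward the plateau
  expect_true(all(diff(out$sd) < 0))
  expect_lt(out$sd[5], out$sd[1] / 1.5)

  # white-noise series: per-fix means are flat in width
  vs2 <- vs; vs2$vedba <- 0.1 + rnorm(n, 0, 0.002)
  out2 <- window_sensitivity(vs2, fixes, widths)
  expect_lt(diff(range(out2$mean)), 0.002)

  # degenerate single-width call
  expect_equal(nrow(window_sensitivity(vs, fixes, 60)), 1L)
  expect_error(window_sensitivity(vs, fixes, c(-1, 10)), "positive")
})

test_that("accel CSV round-trip preserves the trace", {
  tr <- make_trace(rnorm(50), rnorm(50), 1 + rnorm(50))
  tr$time <- as.POSIXct("2014-04-03 08:00:00", tz = "Etc/GMT-2") +
    seq_len(50) / 40
  f <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(tr, f)
  back <- read_accel_csv(f, 40, "Mtest")
  expect_equal(as.numeric(back$time), as.numeric(tr$time), tolerance = 1e-3)
  expect_equal(back$ax, tr$ax, tolerance = 1e-12)
})
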