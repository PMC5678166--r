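# Kruskal-Wallis, partial Mantel, the spatial mixed model, habitat ratios.

test_that("Kruskal-Wallis H matches the hand-computed value and oracle", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 3.857, tolerance = 5e-4)
  expect_equal(kw$H, naive_kw_h(g), tolerance = 1e-12)
  expect_equal(kw$df, 1)

  # identical groups: H = 0, p = 1
  kw2 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw2$H, 0, tolerance = 1e-12)
  expect_equal(kw2$p, 1, tolerance = 1e-12)

  # degenerate all-tied data
  kw3 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(kw3$H, 0)
  expect_equal(kw3$p, 1)

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("exact permutation p agrees with full enumeration at small n", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kruskal_wallis(g, p_method = "exact")$p, 0.1)
  expect_equal(kruskal_wallis(g, p_method = "exact")$p, naive_kw_exact_p(g))
  set.seed(40)
  for (rep in 1:3) {
    g2 <- list(rnorm(4), rnorm(4))
    kw_ex <- kruskal_wallis(g2, p_method = "exact")
    expect_equal(kw_ex$p, naive_kw_exact_p(g2), tolerance = 1e-12)
    # the chi-square approximation is coarse at n = 8 but in the same range
    expect_lt(abs(kruskal_wallis(g2)$p - kw_ex$p), 0.15)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(41)
  g <- list(rnorm(10), rnorm(12, 0.5), rnorm(8, 1))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(g, function(x) 3 * x - 7))$H, h0,
               tolerance = 1e-12)
})

test_that("partial Mantel statistic behaves as a partial correlation", {
  a <- sym0(12, 1); c <- sym0(12, 3)
  r_self <- partial_mantel(a, a, c, n_perm = 99)$R
  expect_equal(r_self, 1, tolerance = 1e-9)

  # constant control reduces exactly to the simple Mantel correlation
  b <- sym0(12, 2)
  konst <- matrix(1, 12, 12); diag(konst) <- 0
  r <- partial_mantel(a, b, konst, n_perm = 99)$R
  lt <- lower.tri(a)
  expect_equal(r, cor(a[lt], b[lt]), tolerance = 1e-12)

  # invariant to adding a constant to all off-diagonal entries of a
  a2 <- a + 5; diag(a2) <- 0
  expect_equal(partial_mantel(a2, b, c, n_perm = 99, seed = 4)$R,
               partial_mantel(a, b, c, n_perm = 99, seed = 4)$R,
               tolerance = 1e-12)

  # matches the textbook partial-correlation formula
  expect_equal(partial_mantel(a, b, c, n_perm = 99)$R,
               naive_partial_mantel_r(a, b, c), tolerance = 1e-12)

  expect_error(partial_mantel(a, b[1:5, 1:5], c), "equal size")
})

test_that("partial Mantel agrees with vegan's implementation", {
  a <- sym0(15, 10); b <- sym0(15, 11); c <- sym0(15, 12)
  ours <- partial_mantel(a, b, c, n_perm = 99)$R
  veg <- vegan::mantel.partial(as.dist(a), as.dist(b), as.dist(c),
                               permutations = 0)$statistic
  expect_equal(ours, unname(veg), tolerance = 1e-10)
})

test_that("exhaustive enumeration at n = 5 matches the independent oracle", {
  a <- sym0(5, 21); b <- sym0(5, 22); c <- sym0(5, 23)
  got <- partial_mantel(a, b, c, exhaustive = TRUE)
  want <- naive_partial_mantel_exhaustive(a, b, c)
  expect_equal(got$n_perm, 120)
  expect_equal(got$R, want$R, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("spatial mixed model recovers a known slope", {
  # 50 replicates, slope 0.5, intercept sd 0.2, no spatial correlation:
  # the 95% CI must cover the truth in at least 90% of fits
  set.seed(50)
  cover <- 0
  for (r in 1:50) {
    d <- do.call(rbind, lapply(1:6, function(m) {
      n <- 40
      risk <- sample(0:22, n, TRUE)
      a_m <- rnorm(1, 0, 0.2)
      data.frame(male_id = sprintf("M%d", m), risk_score = risk,
                 x = runif(n, 0, 3000), y = runif(n, 0, 1500),
                 mean_vedba = exp(-2.5 + a_m + 0.5 * risk + rnorm(n, 0, 0.3)))
    }))
    fit <- fit_vedba_lmm(d, spatial = FALSE)
    if (abs(fit$slope - 0.5) <= 1.96 * fit$se) cover <- cover + 1
  }
  expect_gte(cover, 45)
})

test_that("noiseless data on the fixed-effects line give the exact slope", {
  d <- do.call(rbind, lapply(1:4, function(m) {
    risk <- 0:22
    data.frame(male_id = sprintf("M%d", m), risk_score = risk,
               x = risk * 10, y = risk * 5,
               mean_vedba = exp(-2 + 0.1 * m + 0.5 * risk))
  }))
  fit <- fit_vedba_lmm(d)
  expect_equal(fit$slope, 0.5, tolerance = 1e-6)
  expect_equal(fit$method, "degenerate_zero_residual_ls")
})

test_that("with one observation per male the GLS slope equals OLS", {
  set.seed(51)
  d <- data.frame(male_id = sprintf("M%d", 1:40),
                  risk_score = sample(0:22, 40, TRUE),
                  x = runif(40), y = runif(40))
  d$mean_vedba <- exp(-2 + 0.3 * d$risk_score + rnorm(40, 0, 0.4))
  fit <- fit_vedba_lmm(d, spatial = FALSE)
  ols <- coef(lm(log(mean_vedba) ~ risk_score, data = d))[2]
  expect_equal(fit$slope, unname(ols), tolerance = 1e-8)
})

test_that("exponential range and nugget are recovered within a factor of two", {
  set.seed(52)
  range_true <- 300; nugget_true <- 0.3; sigma <- 0.4
  d <- do.call(rbind, lapply(1:3, function(m) {
    n <- 220
    xy <- cbind(runif(n, 0, 3000), runif(n, 0, 1500))
    dd <- as.matrix(dist(xy))
    corr <- (1 - nugget_true) * exp(-dd / range_true)
    diag(corr) <- 1
    err <- sigma * drop(rnorm(n) %*% chol(corr))
    risk <- sample(0:22, n, TRUE)
    data.frame(male_id = sprintf("M%d", m), risk_score = risk,
               x = xy[, 1], y = xy[, 2],
               mean_vedba = exp(-2 + 0.05 * risk + err))
  }))
  fit <- fit_vedba_lmm(d, spatial = TRUE)
  expect_true(fit$range > range_true / 2 && fit$range < range_true * 2)
  expect_true(fit$nugget > nugget_true / 2 && fit$nugget < nugget_true * 2)
  expect_equal(fit$slope, 0.05, tolerance = 0.5)
})

test_that("habitat ratios divide urban by non-urban stratum means", {
  grid <- data.frame(habitat = factor(c("urban", "fynbos")),
                     energy = c(0.4, 0.1), risk = c(20, 1))
  ann <- data.frame(habitat = factor(c("urban", "fynbos")),
                    mean_vedba = c(0.2, 0.2))
  hr <- habitat_ratios(grid, ann)
  expect_equal(hr$energy_ratio, 4)
  expect_equal(hr$risk_ratio, 20)
  expect_equal(hr$vedba_ratio, 1)
  # empty stratum: undefined and flagged
  grid2 <- data.frame(habitat = factor("fynbos", levels = c("fynbos", "urban")),
                      energy = 0.1, risk = 2)
  hr2 <- habitat_ratios(grid2)
  expect_true(is.na(hr2$energy_ratio))
  expect_true("energy" %in% hr2$flags)
})
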