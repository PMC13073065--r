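test_that("logistic curve has its defining analytic properties", {
  # half capacity at t = L
  expect_equal(logistic_eval(50, K = 100, r = 0.1, L = 50), 50)
  # asymptote
  expect_equal(logistic_eval(1e6, K = 100, r = 0.1, L = 50), 100)
  # closed form at t = L + 1/r: K / (1 + e^-1)
  expect_equal(logistic_eval(60, K = 100, r = 0.1, L = 50),
               100 / (1 + exp(-1)), tolerance = 1e-12)
  # strictly increasing, bounded by (0, K)
  t <- seq(0, 120, by = 0.1)
  g <- logistic_eval(t, K = 80, r = 0.15, L = 40)
  expect_true(all(diff(g) > 0))
  expect_true(all(g > 0 & g < 80))
})

test_that("maximum slope of the logistic is r*K/4 at t = L", {
  for (p in list(c(100, 0.1, 50), c(55, 0.28, 22), c(180, 0.06, 75))) {
    t <- seq(0, 2 * p[3] + 60, by = 0.01)
    g <- logistic_eval(t, K = p[1], r = p[2], L = p[3])
    slopes <- diff(g) / diff(t)
    i <- which.max(slopes)
    expect_equal(max(slopes), p[2] * p[1] / 4, tolerance = 1e-3)
    expect_equal((t[i] + t[i + 1]) / 2, p[3], tolerance = 0.02)
  }
})

test_that("noiseless curves are recovered essentially exactly", {
  t <- seq(0, 120, by = 3.5)
  y <- logistic_eval(t, K = 120, r = 0.08, L = 40)
  fit <- fit_growth_curve(t, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["K"]), 120, tolerance = 1e-6)
  expect_equal(unname(fit$params["r"]), 0.08, tolerance = 1e-6)
  expect_equal(unname(fit$params["L"]), 40, tolerance = 1e-6)
})

test_that("curves with 2% noise recover K and L accurately", {
  t <- seq(0, 120, by = 3.5)
  set.seed(4021)
  relK <- relL <- numeric(20)
  for (rep in 1:20) {
    y <- logistic_eval(t, K = 120, r = 0.08, L = 40) + rnorm(length(t), 0, 2.4)
    fit <- fit_growth_curve(t, pmax(y, 0))
    relK[rep] <- abs(fit$params[["K"]] / 120 - 1)
    relL[rep] <- abs(fit$params[["L"]] / 40 - 1)
  }
  # typical-case precision: K within 2%, L within 5%; the free background
  # parameter widens the K tail slightly, which stays under 7%
  expect_lt(median(relK), 0.02)
  expect_lt(median(relL), 0.05)
  expect_lt(max(relK), 0.07)
  expect_lt(max(relL), 0.05)
})

test_that("fits are scale- and shift-equivariant", {
  t <- seq(0, 120, by = 3.5)
  y <- logistic_eval(t, K = 90, r = 0.12, L = 55)
  base <- fit_growth_curve(t, y)$params
  scaled <- fit_growth_curve(t, y * 3.7)$params
  expect_equal(unname(scaled["K"] / base["K"]), 3.7, tolerance = 1e-6)
  expect_equal(unname(scaled["r"]), unname(base["r"]), tolerance = 1e-6)
  expect_equal(unname(scaled["L"]), unname(base["L"]), tolerance = 1e-6)
  shifted <- fit_growth_curve(t + 11, y)$params
  expect_equal(unname(shifted["L"] - base["L"]), 11, tolerance = 1e-5)
  expect_equal(unname(shifted["K"]), unname(base["K"]), tolerance = 1e-6)
})

test_that("degenerate series are flagged, not fitted", {
  flat <- fit_growth_curve(seq(0, 40, by = 4), rep(7, 11))
  expect_false(flat$converged)
  expect_equal(flat$flags, "non_grower")
  expect_null(flat$params)

  short <- fit_growth_curve(c(0, 4, 8), c(1, 2, 3))
  expect_equal(short$flags, "insufficient_data")
})

test_that("fit_screen covers every spot, plants flags, ignores row order", {
  sim <- small_screen(seed = 41, n_genes = 40)
  del <- sim$series[sim$series$plate == "D01", ]
  # flatten 6 spots at the untreated condition
  flat_cols <- 1:6
  sel <- del$condition_ugml == 0 & del$row == "A" & del$col %in% flat_cols
  del$intensity[sel] <- 5
  fits <- fit_screen(del)
  expect_equal(nrow(fits), 40 * 3)
  expect_equal(sum(fits$flags == "non_grower"), 6)

  set.seed(1)
  perm <- del[sample(nrow(del)), ]
  expect_identical(fit_screen(perm), fits)
})

test_that("array QC flags high failure fractions and spatial blocks", {
  sim <- small_screen(seed = 42, n_genes = 384)
  fits <- fit_screen(sim$series[sim$series$plate == "D01" &
                                  sim$series$condition_ugml == 0, ])
  expect_true(qc_arrays(fits)$passed)

  # scattered failures below threshold
  f2 <- fits
  f2$flags[f2$row == "A" & f2$col %in% c(3, 17)] <- "poor_fit"
  expect_true(qc_arrays(f2)$passed)

  # 4x4 block of 16 failures -> spatial flag even though 16/384 < 10%
  f3 <- fits
  f3$flags[f3$row %in% c("E", "F", "G", "H") & f3$col %in% 5:8] <- "poor_fit"
  qc3 <- qc_arrays(f3)
  expect_true(qc3$spatial_flag)
  expect_false(qc3$passed)

  # 50 scattered failures -> fraction 0.13 > 0.10
  f4 <- fits
  idx <- seq(1, 384, length.out = 50)
  f4$flags[round(idx)] <- "poor_fit"
  qc4 <- qc_arrays(f4)
  expect_equal(qc4$fraction_failed, 50 / 384, tolerance = 1e-12)
  expect_false(qc4$passed)
})
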