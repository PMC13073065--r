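test_that("plate standardization follows the z-score formula", {
  # (CPP - plate median) / reference sd
  expect_equal(standardize_plate(c(100, 110, 90), reference_sd = 5),
               c(0, 2, -2))
  # CPP at the plate median -> z = 0
  z <- standardize_plate(c(95, 100, 105), reference_sd = 4)
  expect_equal(z[2], 0)
  expect_equal(standardize_plate(c(100, 100, 100), 5), c(0, 0, 0))
  # adding a constant to every CPP leaves z unchanged (median shift cancels)
  x <- c(88, 97, 103, 111, 140)
  expect_equal(standardize_plate(x + 13, 6), standardize_plate(x, 6))
  expect_error(standardize_plate(x, 0), "degenerate reference")
  expect_error(standardize_plate(c(1, NA, NA, NA), 1), "50%")
})

test_that("adjusted z-scores subtract the untreated z-score", {
  expect_equal(adjust_zscores(-3.1, -3.1), 0)   # proportional response
  expect_equal(adjust_zscores(-2.5, -6.5), 4)   # fitness-defect suppressor
  expect_true(is.na(adjust_zscores(NA, 1)))
})

test_that("interaction classes follow the sign rules with magnitude tie-break", {
  # strong suppressor pattern: positive adjK, negative adjL
  expect_equal(classify_interaction(4.0, -6.6), "suppressor")
  # strong enhancer by K alone
  expect_equal(classify_interaction(-10.4, NA), "enhancer")
  expect_equal(classify_interaction(0, 0), "neutral")
  # sub-threshold values stay neutral
  expect_equal(classify_interaction(1.9, -1.9), "neutral")
  # conflicting rules: label follows the larger magnitude
  expect_equal(classify_interaction(3, 5), "enhancer")    # adjL=+5 beats adjK=+3
  expect_equal(classify_interaction(5, 3), "suppressor")  # adjK=+5 beats adjL=+3
  expect_equal(classify_interaction(4, 4), "neutral")     # exact tie
  expect_true(is.na(classify_interaction(NA, NA)))
  # vectorized
  expect_equal(classify_interaction(c(4, -4), c(-6, 6)),
               c("suppressor", "enhancer"))
})

test_that("outlier ranking sorts, breaks ties alphabetically, and warns", {
  tab <- data.frame(strain = c("BBB", "AAA", "CCC", "DDD"),
                    plate = "D01", row = "A", col = 1:4,
                    adjK2 = c(-5, -5, -9, 2), stringsAsFactors = FALSE)
  r <- rank_outliers(tab, "K", 2, "lowest", n = 3)
  expect_equal(r$strain, c("CCC", "AAA", "BBB"))  # tie AAA before BBB
  expect_warning(r2 <- rank_outliers(tab, "K", 2, "lowest", n = 10),
                 "only 4")
  expect_equal(nrow(r2), 4)
  r3 <- rank_outliers(tab, "K", 2, "highest", n = 1)
  expect_equal(r3$strain, "DDD")
})

test_that("a screened suppressor and enhancer are recovered end to end", {
  sim <- small_screen(seed = 51, n_genes = 150, frac_enhancer = 0.04,
                      frac_suppressor = 0.04)
  it <- score_sim(sim)
  m <- merge(it, sim$truth$genes, by.x = "strain", by.y = "gene")
  sup <- m$class == "suppressor"
  enh <- m$class == "enhancer"
  expect_true(mean(m$class_20ugml[sup] == "suppressor") >= 0.9)
  expect_true(mean(m$class_20ugml[enh] == "enhancer") >= 0.9)
  # the most extreme planted enhancer ranks first for highest adjL3
  top <- rank_outliers(it, "L", 3, "highest", n = 1)$strain
  expect_equal(m$class[match(top, m$strain)], "enhancer")
  # interactions at 10 ug/mL carry half the planted effect by default
  pl <- sup | enh
  expect_gt(cor(m$effect_sd_units[pl] * 0.5, m$adjL2[pl],
                use = "complete.obs"), 0.9)
})

test_that("fitness defects alone do not systematically masquerade as interactions", {
  # Any single screen shares one 384-spot reference array per condition, so
  # the sampling error of that array's SD couples (with random sign) to
  # every gene's fitness z-score. The systematic component -- what would
  # bias the biology -- is the seed-averaged location difference between
  # defect-carrying and defect-free null genes, and that stays small.
  cols <- c("adjK2", "adjK3", "adjL2", "adjL3")
  diffs <- matrix(NA_real_, 5, length(cols), dimnames = list(NULL, cols))
  for (i in 1:5) {
    sim <- small_screen(seed = 60 + i, n_genes = 200, frac_enhancer = 0,
                        frac_suppressor = 0)
    it <- score_sim(sim)
    m <- merge(it, sim$truth$genes, by.x = "strain", by.y = "gene")
    defect <- m$delta_K < 0
    for (col in cols) {
      diffs[i, col] <- median(m[[col]][defect], na.rm = TRUE) -
        median(m[[col]][!defect], na.rm = TRUE)
    }
  }
  expect_lt(max(abs(colMeans(diffs))), 0.2)
})
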