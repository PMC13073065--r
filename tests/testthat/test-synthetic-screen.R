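test_that("the generator is fully deterministic under its seed", {
  s1 <- small_screen(seed = 90, n_genes = 25)
  s2 <- small_screen(seed = 90, n_genes = 25)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_screen(seed = 91, n_genes = 25)
  expect_false(identical(s1$series$intensity, s3$series$intensity))

  a1 <- simulate_annotations(s1$truth, seed = 5)
  a2 <- simulate_annotations(s1$truth, seed = 5)
  expect_identical(a1, a2)

  m1 <- simulate_dose_matrix(list(top = 1, hill = 1, ec50 = 8),
                             list(top = 1, hill = 1, ec50 = 4),
                             noise_sd = 2, seed = 7)
  m2 <- simulate_dose_matrix(list(top = 1, hill = 1, ec50 = 8),
                             list(top = 1, hill = 1, ec50 = 4),
                             noise_sd = 2, seed = 7)
  expect_identical(m1, m2)
})

test_that("a degenerate config collapses every spot onto the reference curve", {
  sim <- simulate_screen(screen_sim_config(
    n_genes = 10, seed = 1, frac_defect = 0, frac_enhancer = 0,
    frac_suppressor = 0, batch_K_sd = 0, batch_L_sd = 0,
    noise_mult_sd = 0, noise_add_sd = 0, spot_K_sd = 0, spot_L_sd = 0,
    ref_spot_K_sd = 0, ref_spot_L_sd = 0,
    drug_K = c(1, 1, 1), drug_L = c(0, 0, 0)))
  ref_curve <- logistic_eval(seq(0, 120, by = 3.5), K = 100, r = 0.2, L = 48) + 2
  one_spot <- sim$series[sim$series$plate == "D01" & sim$series$row == "A" &
                           sim$series$col == 2 & sim$series$condition_ugml == 20, ]
  expect_equal(one_spot$intensity, ref_curve, tolerance = 1e-12)
})

test_that("config invariants are enforced with the offending key named", {
  expect_error(screen_sim_config(n_genes = 10, seed = 1, frac_defect = 1.5),
               "frac_defect")
  expect_error(screen_sim_config(n_genes = 10, seed = 1, frac_enhancer = 0.7,
                                 frac_suppressor = 0.6), "sum above 1")
  expect_error(screen_sim_config(n_genes = 10, seed = 1,
                                 concentrations = c(5, 10)), "must be 0")
  expect_error(screen_sim_config(n_genes = 10, seed = 1, drug_K = c(1, 1)),
               "drug_K")
  expect_error(screen_sim_config(n_genes = 10), "seed is mandatory")
})

test_that("the z-score denominator is calibrated against the reference array", {
  # matched spot-level noise: per-condition z-scores of null genes are close
  # to unit scale, and adjusted z-scores inflate by about sqrt(2)
  sim <- simulate_screen(screen_sim_config(
    n_genes = 200, seed = 95, frac_defect = 0, frac_enhancer = 0,
    frac_suppressor = 0, spot_K_sd = 0.012, spot_L_sd = 0.8,
    ref_spot_K_sd = 0.012, ref_spot_L_sd = 0.8))
  it <- score_sim(sim)
  for (col in c("z_K1", "z_L1", "z_K2", "z_L2")) {
    expect_gt(sd(it[[col]], na.rm = TRUE), 0.8)
    expect_lt(sd(it[[col]], na.rm = TRUE), 1.3)
  }
  ratio <- sd(it$adjL3, na.rm = TRUE) / sd(it$z_L1, na.rm = TRUE)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.6)
})

test_that("planted suppressors survive the full pipeline", {
  hits <- 0
  total <- 0
  for (seed in 96:97) {
    sim <- small_screen(seed = seed, n_genes = 150, frac_enhancer = 0,
                        frac_suppressor = 0.06)
    it <- score_sim(sim)
    m <- merge(it, sim$truth$genes, by.x = "strain", by.y = "gene")
    sup <- m$class == "suppressor"
    hits <- hits + sum(m$class_20ugml[sup] == "suppressor", na.rm = TRUE)
    total <- total + sum(sup)
  }
  expect_gte(hits / total, 19 / 20)
})

test_that("duplicate spots are planted and scored as separate entries", {
  sim <- small_screen(seed = 98, n_genes = 100, frac_duplicate = 0.1)
  lay <- sim$layouts[sim$layouts$role == "deletion", ]
  expect_equal(nrow(lay), 110)
  expect_equal(sum(duplicated(lay$strain)), 10)
  it <- score_sim(sim)
  expect_equal(nrow(it), 110)
  pm <- build_profile_matrix(it)
  expect_equal(length(unique(pm$gene)), 100)
  expect_equal(length(build_background(pm$gene)), 100)
})

test_that("simplex benchmark clusters sit exactly at the requested separation", {
  g <- simulate_cluster_profiles(n = 50, k = 5, d = 4, separation = 6,
                                 seed = 11)
  pd <- as.vector(dist(g$centers))
  expect_equal(pd, rep(6, 10), tolerance = 1e-9)
  expect_equal(sort(unique(g$labels)), 1:5)
  expect_equal(dim(g$x), c(50, 4))
  expect_error(simulate_cluster_profiles(n = 50, k = 7, d = 4, seed = 1),
               "simplex")
})

test_that("annotation generation covers planted classes and respects n_terms", {
  sim <- small_screen(seed = 99, n_genes = 100)
  ann <- simulate_annotations(sim$truth, n_terms = 12, coverage = 0.8,
                              seed = 3)
  expect_true(all(c("PLANTED_ENHANCER", "PLANTED_SUPPRESSOR") %in% names(ann)))
  expect_equal(sum(grepl("^RAND", names(ann))), 12)
  sup <- toupper(sim$truth$genes$gene[sim$truth$genes$class == "suppressor"])
  covered <- mean(sup %in% ann$PLANTED_SUPPRESSOR)
  expect_equal(covered, 0.8, tolerance = 0.15)

  none <- simulate_annotations(sim$truth, n_terms = 0, coverage = 0,
                               base_rate = 0, seed = 3)
  expect_equal(length(none), 0)
})
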