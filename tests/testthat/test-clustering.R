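make_interactions <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(strain = sprintf("G%03d", seq_len(n)), plate = "D01",
             row = "A", col = seq_len(n),
             z_K1 = rnorm(n), z_L1 = rnorm(n),
             adjK2 = rnorm(n), adjK3 = rnorm(n),
             adjL2 = rnorm(n), adjL3 = rnorm(n), stringsAsFactors = FALSE)
}

test_that("profile matrix applies the missingness and imputation rules", {
  it <- make_interactions(50)
  pm <- build_profile_matrix(it)
  expect_equal(dim(pm$x), c(50, 4))
  expect_equal(colnames(pm$x), c("adjK2", "adjK3", "adjL2", "adjL3"))

  # 3 of 4 features missing -> dropped and logged
  it2 <- it
  it2[1, c("adjK2", "adjK3", "adjL2")] <- NA
  expect_message(pm2 <- build_profile_matrix(it2), "dropping 1")
  expect_equal(nrow(pm2$x), 49)
  expect_equal(pm2$dropped, "G001")

  # 1 of 4 missing -> retained, median-imputed
  it3 <- it
  it3$adjK2[5] <- NA
  pm3 <- build_profile_matrix(it3)
  expect_equal(nrow(pm3$x), 50)
  expect_equal(pm3$x["G005", "adjK2"], median(it3$adjK2, na.rm = TRUE))
  expect_equal(pm3$imputed$entry, "G005")

  expect_error(build_profile_matrix(it[0, ]), "empty")
})

test_that("hierarchical clustering is deterministic and order-invariant", {
  it <- make_interactions(30, seed = 2)
  it$adjK2[2] <- it$adjK2[1]; it$adjK3[2] <- it$adjK3[1]
  it$adjL2[2] <- it$adjL2[1]; it$adjL3[2] <- it$adjL3[1]
  pm <- build_profile_matrix(it)
  tree <- hierarchical_cluster(pm)
  expect_equal(min(tree$height), 0)      # identical rows merge first
  first <- sort(rownames(pm$x)[-tree$merge[1, ]])
  expect_equal(first, c("G001", "G002"))

  set.seed(3)
  perm <- sample(nrow(it))
  pm2 <- build_profile_matrix(it[perm, ])
  tree2 <- hierarchical_cluster(pm2)
  for (k in c(2, 5, 10)) {
    a <- cutree(tree, k)
    b <- cutree(tree2, k)[names(a)]
    # same partition up to label permutation
    expect_equal(length(unique(paste(a, b))), k)
  }

  bad <- pm
  bad$x[3, 2] <- Inf
  expect_error(hierarchical_cluster(bad), "non-finite")
})

test_that("BIC selects one cluster for a single Gaussian cloud", {
  set.seed(301)
  x <- matrix(rnorm(300 * 4), 300, 4)
  rownames(x) <- sprintf("R%03d", 1:300)
  a <- bic_cut(hierarchical_cluster(x), x, k_max = 15)
  expect_equal(a$k, 1)
  expect_true(all(is.finite(a$bic_curve$bic)))
  expect_equal(a$bic_curve$k[which.min(a$bic_curve$bic)], a$k)
})

test_that("BIC recovers well-separated planted clusters", {
  for (seed in 71:73) {
    g <- simulate_cluster_profiles(n = 400, k = 5, d = 4, separation = 6,
                                   seed = seed)
    a <- bic_cut(hierarchical_cluster(g$x), g$x, k_max = 20)
    expect_equal(a$k, 5)
    expect_gte(mclust::adjustedRandIndex(a$labels, g$labels), 0.9)
  }
  # with three well-separated groups, the first two cuts recover them
  for (seed in 74:76) {
    g3 <- simulate_cluster_profiles(n = 150, k = 3, d = 4, separation = 8,
                                    seed = seed)
    cut3 <- cutree(hierarchical_cluster(g3$x), 3)
    expect_gte(mclust::adjustedRandIndex(cut3, g3$labels), 0.95)
  }
})

test_that("duplicating every row leaves the selected k unchanged", {
  g <- simulate_cluster_profiles(n = 60, k = 3, d = 4, separation = 8,
                                 seed = 99)
  k1 <- bic_cut(hierarchical_cluster(g$x), g$x, k_max = 10)$k
  x2 <- rbind(g$x, g$x)
  rownames(x2) <- make.unique(rownames(x2))
  k2 <- bic_cut(hierarchical_cluster(x2), x2, k_max = 10)$k
  expect_equal(k1, 3)
  expect_equal(k2, k1)
})

test_that("cluster report summarizes members, means, and tendency", {
  it <- make_interactions(40, seed = 5)
  it$adjL3[1:20] <- it$adjL3[1:20] - 8   # planted suppressor block
  it$adjL3[21:40] <- it$adjL3[21:40] + 8
  pm <- build_profile_matrix(it)
  tree <- hierarchical_cluster(pm)
  a <- bic_cut(tree, pm, k_max = 10)
  rep <- cluster_report(a, pm)
  expect_equal(sum(rep$size), 40)  # partition property
  sup_cl <- rep$cluster[rep$tendency == "suppressor"]
  expect_true(length(sup_cl) >= 1)
  expect_true(all(rep$mean_adjL3[rep$cluster %in% sup_cl] < 0))

  # singleton cluster summary equals the row
  one <- bic_cut(tree, pm, k_max = nrow(pm$x))
  labs <- one$labels
  sizes <- table(labs)
  if (any(sizes == 1)) {
    cl <- names(sizes)[sizes == 1][1]
    entry <- names(labs)[labs == as.integer(cl)]
    r <- cluster_report(one, pm)
    expect_equal(r$mean_adjK2[r$cluster == as.integer(cl)],
                 unname(pm$x[entry, "adjK2"]))
  }
})
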