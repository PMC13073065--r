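test_that("background collapses duplicate ORFs", {
  expect_setequal(build_background(c("RAD9", "RAD9", "XRS2")),
                  c("RAD9", "XRS2"))
  expect_equal(length(build_background(c("rad9", "RAD9"))), 1)
  expect_equal(length(build_background(character())), 0)
})

test_that("cluster member resolution follows the duplicate rules", {
  labels <- c(e1 = 3L, e2 = 3L, e3 = 7L, e4 = 7L, e5 = 3L)
  gene_map <- c(e1 = "RAD9", e2 = "XRS2", e3 = "RAD9", e4 = "MRE11",
                e5 = "XRS2")
  members <- resolve_cluster_members(labels, gene_map)
  # duplicated across clusters: RAD9 contributes to both 3 and 7
  expect_true("RAD9" %in% members[["3"]] && "RAD9" %in% members[["7"]])
  # duplicated within cluster 3: XRS2 counted once
  expect_equal(sum(members[["3"]] == "XRS2"), 1)
  # a duplicate entry outside any cluster is simply absent
  expect_false("SGS1" %in% unlist(members))
})

test_that("Fisher p-values match the brute-force hypergeometric oracle", {
  ann <- list(T1 = sprintf("G%04d", 1:20))
  bg <- sprintf("G%04d", 1:1000)
  clu <- sprintf("G%04d", c(1:5, 501:505))      # a = 5, cluster = 10
  res <- fisher_enrichment(clu, bg, ann)
  expect_equal(res$p, hyper_tail_oracle(5, 20, 1000, 10), tolerance = 1e-12)

  # systematic sweep over table shapes, background up to 2000
  set.seed(812)
  for (i in 1:60) {
    N <- sample(20:2000, 1)
    m <- sample(2:min(N - 2, 150), 1)
    k <- sample(1:min(N - m, 80), 1)
    a <- sample(0:min(m, k), 1)
    genes <- sprintf("G%04d", seq_len(N))
    term <- genes[seq_len(m)]
    clu <- c(genes[seq_len(a)], genes[m + seq_len(k - a)])
    p_pkg <- fisher_enrichment(clu, genes, list(T = term))$p
    expect_equal(p_pkg, hyper_tail_oracle(a, m, N, k), tolerance = 1e-10)
  }

  # a = 0 -> p = 1; cluster = background -> p = 1 for every term
  res0 <- fisher_enrichment(sprintf("G%04d", 900:909), bg, ann)
  expect_equal(res0$p, 1)
  resall <- fisher_enrichment(bg, bg, ann)
  expect_equal(resall$p, 1)

  expect_error(fisher_enrichment(c("NOTBG"), bg, ann), "outside background")
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_identical(bh_correct(p), bh_oracle(p))
  }
})

test_that("reporting picks the lowest-q representative per cluster", {
  res <- data.frame(
    cluster = c("1", "1", "1", "2", "3"),
    term_id = c("B", "A", "C", "D", "E"),
    a = 1, cluster_size = 10, term_size = 5, background_size = 100,
    odds_ratio = 1,
    p = c(0.001, 0.001, 0.5, 0.002, 0.9),
    q = c(0.003, 0.003, 0.5, 0.004, 0.9),
    reported = c(TRUE, TRUE, FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  rep <- report_enrichment(res, q_threshold = 0.005)
  # cluster 3 has nothing below threshold -> absent
  expect_false("3" %in% rep$cluster)
  # q tie in cluster 1 -> alphabetical term wins representative
  expect_equal(rep$term_id[rep$representative & rep$cluster == "1"], "A")
  # threshold 1 reports everything tested
  expect_equal(nrow(report_enrichment(res, q_threshold = 1.01)), 5)
})

test_that("planted enrichment is detected and random annotations are not", {
  sim <- small_screen(seed = 81, n_genes = 200)
  ann <- simulate_annotations(sim$truth, n_terms = 30, coverage = 0.8,
                              seed = 82)
  truth <- sim$truth$genes
  members <- split(toupper(truth$gene), truth$class)
  members <- members[names(members) != "none"]
  bg <- build_background(truth$gene)
  enr <- enrich_clusters(members, bg, ann)
  rep <- report_enrichment(enr)
  for (cl in names(members)) {
    top <- rep$term_id[rep$cluster == cl & rep$representative]
    expect_equal(top, paste0("PLANTED_", toupper(cl)))
  }
  # zero planted coverage: planted terms vanish, nothing should be reported
  ann0 <- simulate_annotations(sim$truth, n_terms = 30, coverage = 0,
                               base_rate = 0, seed = 83)
  expect_false(any(grepl("PLANTED", names(ann0))) &&
                 any(report_enrichment(
                   enrich_clusters(members, bg, ann0))$reported))
})

test_that("annotation propagation adds genes to ancestors", {
  ann <- list(child = c("A", "B"), mid = "C")
  edges <- data.frame(child = c("child", "mid"), parent = c("mid", "root"),
                      stringsAsFactors = FALSE)
  out <- propagate_annotations(ann, edges)
  expect_setequal(out$mid, c("A", "B", "C"))
  expect_setequal(out$root, c("A", "B", "C"))
})
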