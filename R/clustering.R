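#' Build the interaction profile matrix for clustering
#'
#' Assembles one feature row per gene-deletion entry from the interaction
#' table. Clustering features are the adjusted z-scores (adjK and adjL at
#' each drug concentration); the unperturbed z_K1 and z_L1 columns are
#' carried along for display only and never enter the distance computation.
#' Entries missing more than half of the clustering features are dropped
#' (and logged); remaining missing features are imputed with the feature
#' median.
#'
#' @param interactions interaction table from [score_screen()].
#' @param max_missing maximum tolerated fraction of missing features
#'   (default 0.5; strictly more is dropped).
#' @return an object of class `profile_matrix`: a list with `x` (numeric
#'   feature matrix, entries x features), `display` (matrix of z_K1/z_L1),
#'   `gene` (character vector mapping entry to gene symbol), `dropped`
#'   (character vector of dropped entries), `imputed` (data.frame log of
#'   imputations).
#' @export
build_profile_matrix <- function(interactions, max_missing = 0.5) {
  feat_cols <- grep("^adj[KL][0-9]+$", names(interactions), value = TRUE)
  if (length(feat_cols) == 0 || nrow(interactions) == 0) {
    stop("empty screen: no adjusted z-score columns or no rows")
  }
  # order features adjK2, adjK3, ..., adjL2, adjL3, ...
  feat_cols <- feat_cols[order(substr(feat_cols, 4, 4), as.integer(substring(feat_cols, 5)))]
  entry <- make.unique(toupper(interactions$strain), sep = "#")
  x <- as.matrix(interactions[, feat_cols, drop = FALSE])
  rownames(x) <- entry

  miss_frac <- rowMeans(is.na(x))
  drop <- miss_frac > max_missing
  dropped <- entry[drop]
  if (any(drop)) {
    message("build_profile_matrix: dropping ", sum(drop),
            " entr", if (sum(drop) == 1) "y" else "ies",
            " with > ", max_missing * 100, "% missing features")
  }
  x <- x[!drop, , drop = FALSE]
  if (nrow(x) == 0) stop("empty matrix after missingness filtering")

  imputed <- NULL
  for (j in seq_len(ncol(x))) {
    nas <- which(is.na(x[, j]))
    if (length(nas) > 0) {
      med <- stats::median(x[, j], na.rm = TRUE)
      x[nas, j] <- med
      imputed <- rbind(imputed, data.frame(entry = rownames(x)[nas],
                                           feature = colnames(x)[j],
                                           value = med,
                                           stringsAsFactors = FALSE))
    }
  }

  disp_cols <- intersect(c("z_K1", "z_L1"), names(interactions))
  display <- as.matrix(interactions[!drop, disp_cols, drop = FALSE])
  rownames(display) <- rownames(x)

  structure(list(x = x, display = display,
                 gene = stats::setNames(toupper(interactions$strain)[!drop], rownames(x)),
                 dropped = dropped,
                 imputed = if (is.null(imputed)) {
                   data.frame(entry = character(), feature = character(),
                              value = numeric(), stringsAsFactors = FALSE)
                 } else imputed),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$x), "entries x", ncol(x$x), "features (",
      paste(colnames(x$x), collapse = ", "), ")\n")
  invisible(x)
}

#' Hierarchically cluster interaction profiles
#'
#' Agglomerative clustering of the profile matrix. Default is Ward linkage
#' on Euclidean distance, which pairs naturally with the Gaussian model used
#' by [bic_cut()]; average and complete linkage and correlation distance are
#' available. The result is deterministic: no randomized steps.
#'
#' @param pm a [build_profile_matrix()] object (or a bare numeric matrix).
#' @param linkage one of `"ward.D2"`, `"average"`, `"complete"`.
#' @param metric `"euclidean"`, `"manhattan"`, or `"correlation"`
#'   (1 - Pearson correlation between rows).
#' @return an `hclust` tree with attributes `linkage` and `metric` recorded.
#' @export
hierarchical_cluster <- function(pm, linkage = c("ward.D2", "average", "complete"),
                                 metric = c("euclidean", "manhattan", "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  x <- if (inherits(pm, "profile_matrix")) pm$x else as.matrix(pm)
  if (nrow(x) < 2) stop("need at least 2 rows to cluster")
  if (!all(is.finite(x))) {
    bad <- rownames(x)[!stats::complete.cases(x) | rowSums(!is.finite(x)) > 0][1]
    stop("non-finite feature after imputation for entry '", bad, "'")
  }
  d <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(t(x)))
  } else {
    stats::dist(x, method = metric)
  }
  tree <- stats::hclust(d, method = linkage)
  attr(tree, "linkage") <- linkage
  attr(tree, "metric") <- metric
  tree
}

# Gaussian BIC of a k-group partition. The cut parameterizes a spherical
# Gaussian mixture: component weights and mean vectors from the hard
# assignment, one pooled spherical variance; the data are scored under the
# mixture log-likelihood so that cuts of an unclustered cloud gain almost
# nothing over k = 1 (a hard-assignment likelihood would reward any split
# of a Gaussian and never stop). p = k*d + 1 free parameters.
.partition_bic <- function(x, labels) {
  n <- nrow(x)
  d <- ncol(x)
  cls <- sort(unique(labels))
  k <- length(cls)
  mus <- matrix(0, k, d)
  wts <- numeric(k)
  rss <- 0
  for (i in seq_len(k)) {
    sub <- x[labels == cls[i], , drop = FALSE]
    mus[i, ] <- colMeans(sub)
    wts[i] <- nrow(sub) / n
    rss <- rss + sum(sweep(sub, 2, mus[i, ])^2)
  }
  sigma2 <- max(rss / (n * d), 1e-12 * max(stats::var(as.vector(x)), 1e-300))
  # log-sum-exp over components for each row
  comp <- matrix(0, n, k)
  for (i in seq_len(k)) {
    dev <- sweep(x, 2, mus[i, ])
    comp[, i] <- log(wts[i]) - 0.5 * d * log(2 * pi * sigma2) -
      rowSums(dev^2) / (2 * sigma2)
  }
  m <- apply(comp, 1, max)
  loglik <- sum(m + log(rowSums(exp(comp - m))))
  -2 * loglik + (k * d + 1) * log(n * d)
}

# Variant with one spherical variance per mixture component;
# p = k*d + k parameters.
.partition_bic_free <- function(x, labels) {
  n <- nrow(x)
  d <- ncol(x)
  cls <- sort(unique(labels))
  k <- length(cls)
  mus <- matrix(0, k, d)
  wts <- numeric(k)
  s2s <- numeric(k)
  floor_s2 <- 1e-12 * max(stats::var(as.vector(x)), 1e-300)
  for (i in seq_len(k)) {
    sub <- x[labels == cls[i], , drop = FALSE]
    mus[i, ] <- colMeans(sub)
    wts[i] <- nrow(sub) / n
    s2s[i] <- max(sum(sweep(sub, 2, mus[i, ])^2) / (nrow(sub) * d), floor_s2)
  }
  comp <- matrix(0, n, k)
  for (i in seq_len(k)) {
    dev <- sweep(x, 2, mus[i, ])
    comp[, i] <- log(wts[i]) - 0.5 * d * log(2 * pi * s2s[i]) -
      rowSums(dev^2) / (2 * s2s[i])
  }
  m <- apply(comp, 1, max)
  loglik <- sum(m + log(rowSums(exp(comp - m))))
  -2 * loglik + (k * d + k) * log(n * d)
}

#' Cut the cluster tree at the BIC-optimal number of clusters
#'
#' For each candidate k the tree is cut into k groups and scored with the
#' Bayesian information criterion of the spherical Gaussian mixture that
#' the cut parameterizes: component weights and per-cluster mean vectors
#' from the hard assignment, a single pooled spherical variance, and the
#' mixture log-likelihood, so BIC(k) = -2 lnL + (k d + 1) ln(n d) for n
#' entries and d features. The reported k minimizes BIC; ties go to the
#' smallest k. One spherical variance per cluster is available behind
#' `pooled = FALSE`.
#'
#' @param tree an `hclust` tree from [hierarchical_cluster()].
#' @param pm the matching [build_profile_matrix()] object or matrix.
#' @param k_max largest candidate cluster count (default 60).
#' @param pooled use one pooled spherical variance (default TRUE) or one
#'   spherical variance per cluster.
#' @return an object of class `cluster_assignment`: list with `labels`
#'   (named integer vector, entry -> cluster in 1..k), `k`, `bic_curve`
#'   (data.frame of k, bic), `tree`.
#' @export
bic_cut <- function(tree, pm, k_max = 60L, pooled = TRUE) {
  x <- if (inherits(pm, "profile_matrix")) pm$x else as.matrix(pm)
  if (k_max < 1) stop("k_max must be >= 1")
  k_max <- min(as.integer(k_max), nrow(x))
  n <- nrow(x)
  d <- ncol(x)
  bics <- numeric(k_max)
  cuts <- stats::cutree(tree, k = seq_len(k_max))
  if (k_max == 1L) cuts <- matrix(cuts, ncol = 1L)
  for (k in seq_len(k_max)) {
    labels <- cuts[, k]
    bics[k] <- if (pooled) .partition_bic(x, labels)
               else .partition_bic_free(x, labels)
  }
  k_best <- which.min(bics)  # first minimum = smallest k on ties
  labels <- cuts[, k_best]
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = k_best,
                 bic_curve = data.frame(k = seq_len(k_max), bic = bics),
                 tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: k =", x$k, "clusters over", length(x$labels),
      "entries\n")
  invisible(x)
}

#' Summarize clusters
#'
#' Per-cluster membership, mean adjusted z-score per feature, and a
#' tendency label from the sign of the mean adjusted L z-score at the
#' highest drug concentration: negative means the cluster's deletions
#' suppress drug activity (they reach half carrying capacity relatively
#' sooner under drug than their untreated fitness predicts), positive means
#' they enhance it.
#'
#' @param assignment a [bic_cut()] result.
#' @param pm the matching [build_profile_matrix()] object.
#' @return a data.frame with one row per cluster: `cluster`, `size`,
#'   `members` (comma-joined entries), mean feature columns, `tendency`.
#' @export
cluster_report <- function(assignment, pm) {
  x <- pm$x
  labels <- assignment$labels
  stopifnot(identical(names(labels), rownames(x)))
  feat_cols <- colnames(x)
  lcols <- grep("^adjL", feat_cols, value = TRUE)
  top_l <- if (length(lcols) > 0) lcols[which.max(as.integer(substring(lcols, 5)))] else NA
  out <- lapply(sort(unique(labels)), function(cl) {
    sub <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(sub)
    tendency <- if (is.na(top_l) || mu[[top_l]] == 0) "neutral"
                else if (mu[[top_l]] < 0) "suppressor" else "enhancer"
    row <- data.frame(cluster = cl, size = nrow(sub),
                      members = paste(rownames(sub), collapse = ","),
                      stringsAsFactors = FALSE)
    for (f in feat_cols) row[[paste0("mean_", f)]] <- mu[[f]]
    row$tendency <- tendency
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
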