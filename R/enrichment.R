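#' Read a flat gene-annotation table
#'
#' Annotations are a flat two-column table, one `term_id` / `gene` pair per
#' line (TSV by default). Gene symbols are uppercased; terms with no genes
#' are dropped. No ontology-graph propagation is applied: annotations are
#' taken as given. An optional child/parent edge list can be supplied to
#' [propagate_annotations()] when propagated counts are wanted.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return a named list mapping `term_id` to a character vector of unique
#'   gene symbols (an annotation set).
#' @export
read_annotations <- function(path, dialect = "tsv") {
  df <- .read_table(path, dialect, c("term_id", "gene"), numeric_cols = character())
  annotation_set(df$term_id, df$gene)
}

#' @rdname read_annotations
#' @param term_id,gene parallel character vectors of term/gene pairs.
#' @export
annotation_set <- function(term_id, gene) {
  gene <- toupper(gene)
  keep <- nzchar(gene) & !is.na(gene)
  sets <- lapply(split(gene[keep], term_id[keep]), unique)
  sets[lengths(sets) > 0]
}

#' Propagate annotations up a term-parent edge list
#'
#' Adds each term's genes to all of its ancestors, given a flat child ->
#' parent edge table, iterating to a fixed point (cycles saturate rather
#' than loop).
#'
#' @param annotations a named list as from [read_annotations()].
#' @param edges data.frame with columns `child`, `parent`.
#' @return the propagated annotation set.
#' @export
propagate_annotations <- function(annotations, edges) {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  terms <- union(names(annotations), union(edges$child, edges$parent))
  out <- annotations[terms]
  names(out) <- terms
  out[vapply(out, is.null, TRUE)] <- list(character())
  # iterate to a fixed point; union growth is bounded so this terminates
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      ch <- edges$child[i]; pa <- edges$parent[i]
      merged <- union(out[[pa]], out[[ch]])
      if (length(merged) > length(out[[pa]])) {
        out[[pa]] <- merged
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out[lengths(out) > 0]
}

#' Build the enrichment background gene set
#'
#' The background comprises the unique gene symbols with high-quality data
#' in the screen; duplicate ORF entries (the same deletion present at more
#' than one array position) collapse to a single background member.
#'
#' @param genes character vector of gene symbols, one per screened entry
#'   (duplicates allowed).
#' @return character vector of unique uppercase gene symbols.
#' @export
build_background <- function(genes) {
  g <- unique(toupper(genes))
  g[nzchar(g) & !is.na(g)]
}

#' Resolve cluster members for enrichment testing
#'
#' Maps clustered entries back to gene symbols under the duplicate-ORF
#' rules: a gene duplicated across clusters contributes to each of its
#' clusters' test lists; within one cluster a duplicated gene counts once;
#' duplicates that fall outside any cluster are simply absent.
#'
#' @param assignment a [bic_cut()] result (or a named vector of cluster
#'   labels).
#' @param gene_map named character vector mapping entry -> gene symbol
#'   (e.g. the `gene` element of a [build_profile_matrix()]).
#' @return a named list: cluster label -> character vector of unique gene
#'   symbols.
#' @export
resolve_cluster_members <- function(assignment, gene_map) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else assignment
  genes <- toupper(unname(gene_map[names(labels)]))
  lapply(split(genes, labels), unique)
}

#' Fisher's exact over-representation test for one cluster
#'
#' For each annotation term with at least `min_term_size` members in the
#' background, tests over-representation of the term in the cluster with a
#' one-sided Fisher's exact test on the 2x2 table (cluster/term membership),
#' i.e. the hypergeometric upper tail P(X >= a). Terms never annotated in
#' the background are skipped.
#'
#' @param cluster_genes character vector of the cluster's (unique) genes;
#'   must be a subset of `background`.
#' @param background character vector of unique background genes.
#' @param annotations annotation set (named list term -> genes).
#' @param min_term_size minimum background members of a term for testing
#'   (default 2; singletons are uninformative and inflate the family).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return a data.frame with one row per tested term: `term_id`, `a`
#'   (cluster-and-term count), `cluster_size`, `term_size` (in background),
#'   `background_size`, `odds_ratio` (sample odds ratio), `p`.
#' @export
fisher_enrichment <- function(cluster_genes, background, annotations,
                              min_term_size = 2L,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(toupper(background))
  cluster_genes <- unique(toupper(cluster_genes))
  outside <- setdiff(cluster_genes, background)
  if (length(outside) > 0) {
    stop("cluster gene(s) outside background: ", paste(outside, collapse = ", "))
  }
  N <- length(background)
  n_clu <- length(cluster_genes)
  rows <- lapply(names(annotations), function(tid) {
    term_bg <- intersect(annotations[[tid]], background)
    m <- length(term_bg)
    if (m < min_term_size) return(NULL)
    a <- length(intersect(cluster_genes, term_bg))
    b <- n_clu - a
    cc <- m - a
    d <- N - m - b
    p <- if (alternative == "greater") {
      stats::phyper(a - 1L, m, N - m, n_clu, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(a, b, cc, d), 2L), alternative = "two.sided")$p.value
    }
    orat <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    if (a == 0) orat <- 0
    data.frame(term_id = tid, a = a, cluster_size = n_clu, term_size = m,
               background_size = N, odds_ratio = orat, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), a = integer(),
                      cluster_size = integer(), term_size = integer(),
                      background_size = integer(), odds_ratio = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values for false discovery by the BH step-up procedure
#' (q_i = min_{j >= i} p_(j) m / j over the sorted p-values). Output is
#' monotone non-decreasing in p-rank and bounded by \[0, 1\].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values aligned with `p`.
#' @export
bh_correct <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must all lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-cluster enrichment over a whole assignment
#'
#' Runs [fisher_enrichment()] for every cluster and applies BH correction.
#' By default the correction family is each cluster's own set of tested
#' terms (matching per-cluster reporting); `scope = "global"` pools all
#' (cluster, term) tests into one family.
#'
#' @param members list from [resolve_cluster_members()].
#' @param background background gene set from [build_background()].
#' @param annotations annotation set.
#' @param scope `"per_cluster"` (default) or `"global"` BH family.
#' @param q_threshold reporting threshold on q (default 0.005).
#' @inheritParams fisher_enrichment
#' @return data.frame with columns `cluster`, `term_id`, `a`,
#'   `cluster_size`, `term_size`, `background_size`, `odds_ratio`, `p`,
#'   `q`, `reported`.
#' @export
enrich_clusters <- function(members, background, annotations,
                            scope = c("per_cluster", "global"),
                            q_threshold = 0.005, min_term_size = 2L,
                            alternative = c("greater", "two.sided")) {
  scope <- match.arg(scope)
  alternative <- match.arg(alternative)
  if (length(background) == 0) stop("empty background gene set")
  tabs <- lapply(names(members), function(cl) {
    tab <- fisher_enrichment(members[[cl]], background, annotations,
                             min_term_size = min_term_size,
                             alternative = alternative)
    if (nrow(tab) == 0) return(NULL)
    cbind(data.frame(cluster = cl, stringsAsFactors = FALSE), tab)
  })
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  if (length(tabs) == 0) {
    return(data.frame(cluster = character(), term_id = character(),
                      a = integer(), cluster_size = integer(),
                      term_size = integer(), background_size = integer(),
                      odds_ratio = numeric(), p = numeric(), q = numeric(),
                      reported = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, tabs)
  if (scope == "global") {
    out$q <- bh_correct(out$p)
  } else {
    out$q <- NA_real_
    for (cl in unique(out$cluster)) {
      sel <- out$cluster == cl
      out$q[sel] <- bh_correct(out$p[sel])
    }
  }
  out$reported <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Reported enrichment table with representative terms
#'
#' Filters to terms below the q threshold and flags, per cluster, the single
#' lowest-q term as that cluster's representative (ties broken
#' alphabetically by term id). Clusters with no term below threshold are
#' absent from the output.
#'
#' @param results table from [enrich_clusters()].
#' @param q_threshold reporting threshold (default 0.005).
#' @return the filtered table with an added logical `representative` column.
#' @export
report_enrichment <- function(results, q_threshold = 0.005) {
  out <- results[results$q < q_threshold, , drop = FALSE]
  out$representative <- FALSE
  for (cl in unique(out$cluster)) {
    sel <- which(out$cluster == cl)
    best <- sel[order(out$q[sel], out$term_id[sel])][1]
    out$representative[best] <- TRUE
  }
  rownames(out) <- NULL
  out
}
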