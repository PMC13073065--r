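#' Run the full screen analysis pipeline
#'
#' Orchestrates fit -> QC -> score -> cluster -> enrich over an in-memory
#' screen. Deletion arrays flagged incomplete by [validate_design()] are
#' refused (excluded from scoring); if annotations are NULL the enrichment
#' stage is skipped.
#'
#' @param series long time-series data.frame.
#' @param layouts layout data.frame.
#' @param design a [screen_design()].
#' @param annotations optional annotation set for enrichment.
#' @param settings a [fit_settings()] list.
#' @param qc_frac,qc_block,qc_block_count QC thresholds (see [qc_arrays()]).
#' @param threshold interaction-calling threshold.
#' @param k_max BIC search upper bound.
#' @param linkage,metric clustering choices (see [hierarchical_cluster()]).
#' @param scope,q_threshold enrichment BH family and reporting threshold.
#' @return a list of stage outputs: `issues`, `fits`, `qc`, `interactions`,
#'   `profile` (profile_matrix), `tree`, `assignment`, `clusters`,
#'   `enrichment` (or NULL), and `log` (named counts).
#' @export
run_screen_pipeline <- function(series, layouts, design, annotations = NULL,
                                settings = fit_settings(),
                                qc_frac = 0.10, qc_block = 4L,
                                qc_block_count = 8L,
                                threshold = 2.0, k_max = 60L,
                                linkage = "ward.D2", metric = "euclidean",
                                scope = "per_cluster", q_threshold = 0.005) {
  issues <- validate_design(design, layouts, series)
  bad_plates <- unique(issues$plate[!is.na(issues$plate)])
  man <- design$manifest
  usable <- setdiff(unique(man$deletion_plate), bad_plates)
  if (length(usable) == 0) {
    stop("stage error [validate]: no complete deletion arrays to score")
  }
  if (length(bad_plates) > 0) {
    design <- screen_design(design$concentrations,
                            man[man$deletion_plate %in% usable, , drop = FALSE])
  }

  fits <- fit_screen(series, settings)
  qc <- qc_arrays(fits, frac_threshold = qc_frac, block = qc_block,
                  block_count = qc_block_count)
  if (!any(qc$passed)) stop("stage error [qc]: every array failed QC")

  interactions <- score_screen(fits, design, qc = qc, threshold = threshold)
  pm <- build_profile_matrix(interactions)
  tree <- hierarchical_cluster(pm, linkage = linkage, metric = metric)
  assignment <- bic_cut(tree, pm, k_max = k_max)
  clusters <- cluster_report(assignment, pm)

  enrichment <- NULL
  if (!is.null(annotations)) {
    background <- build_background(pm$gene)
    members <- resolve_cluster_members(assignment, pm$gene)
    enrichment <- enrich_clusters(members, background, annotations,
                                  scope = scope, q_threshold = q_threshold)
  }

  log <- c(spots_fitted = nrow(fits),
           arrays_failed_qc = sum(!qc$passed),
           genes_retained = nrow(pm$x),
           clusters = assignment$k,
           terms_tested = if (is.null(enrichment)) 0L else nrow(enrichment))

  list(issues = issues, fits = fits, qc = qc, interactions = interactions,
       profile = pm, tree = tree, assignment = assignment,
       clusters = clusters, enrichment = enrichment, log = log)
}

# flat key=value config files ------------------------------------------------

#' Read and write flat key-value pipeline configs
#'
#' Pipeline configs are flat `key = value` text files; `#` starts a comment.
#' Values are parsed as numeric where possible, comma-separated values
#' become vectors.
#'
#' @param path file path.
#' @param config a named list.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("config error: cannot parse line: ", ln)
    val <- trimws(strsplit(kv[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[kv[2]]] <- if (!anyNA(num)) num else val
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", paste(v, collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.sim_config_from_list <- function(lst) {
  known <- names(formals(screen_sim_config))
  extra <- setdiff(names(lst), known)
  if (length(extra) > 0) {
    stop("config error: unknown key(s): ", paste(extra, collapse = ", "))
  }
  do.call(screen_sim_config, lst)
}

#' Pipeline subcommands
#'
#' Thin command-style wrappers used by the `qhtcp` command-line script
#' (installed under `exec/`): `cmd_simulate()` writes a synthetic screen to
#' disk, `cmd_run_all()` runs the full analysis over screen files and
#' writes every result table, `cmd_synergy()` scores a dose matrix, and
#' `cmd_ic50()` fits a dose series. Config and schema problems raise
#' conditions of class `qhtcp_config_error`; mid-pipeline failures raise
#' `qhtcp_stage_error` (the CLI maps these to exit codes 2 and 3).
#'
#' @param config_path path to a flat key-value config file.
#' @param out_dir output directory (created if needed).
#' @return `cmd_run_all()` and `cmd_simulate()` return the written file
#'   paths invisibly.
#' @export
cmd_simulate <- function(config_path, out_dir) {
  lst <- read_config(config_path)
  cfg <- .with_error_class(.sim_config_from_list(lst), "qhtcp_config_error")
  sim <- simulate_screen(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  paths <- c(
    series = file.path(out_dir, "series.tsv"),
    layouts = file.path(out_dir, "layouts.tsv"),
    manifest = file.path(out_dir, "manifest.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    truth_interactions = file.path(out_dir, "truth_interactions.tsv"),
    truth_plates = file.path(out_dir, "truth_plates.tsv"),
    config = file.path(out_dir, "config.used"))
  write_timeseries(sim$series, paths["series"], seed = seed)
  write_layout(sim$layouts, paths["layouts"], seed = seed)
  write_result_table(sim$design$manifest, paths["manifest"], seed = seed)
  write_result_table(sim$truth$genes, paths["truth_genes"], seed = seed)
  write_result_table(sim$truth$interactions, paths["truth_interactions"],
                     seed = seed)
  write_result_table(sim$truth$plates, paths["truth_plates"], seed = seed)
  flat <- cfg
  class(flat) <- NULL
  write_config(flat, paths["config"])
  invisible(paths)
}

.with_error_class <- function(expr, cls) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c(cls, "error", "condition"),
                   list(message = conditionMessage(e), call = NULL)))
  })
}

#' @rdname cmd_simulate
#' @details `cmd_run_all()` expects config keys `series`, `layouts`,
#'   `manifest`, `out_dir`, optional `annotations`, `seed`, and any of
#'   `threshold`, `k_max`, `q_threshold`, `qc_frac`, `linkage`, `metric`,
#'   `scope`.
#' @export
cmd_run_all <- function(config_path) {
  cfg <- read_config(config_path)
  for (key in c("series", "layouts", "manifest", "out_dir")) {
    if (is.null(cfg[[key]])) {
      stop(structure(class = c("qhtcp_config_error", "error", "condition"),
                     list(message = paste0("config error: missing key '", key, "'"),
                          call = NULL)))
    }
  }
  series <- .with_error_class(read_timeseries(cfg$series), "qhtcp_config_error")
  layouts <- .with_error_class(read_layout(cfg$layouts), "qhtcp_config_error")
  manifest <- .with_error_class(
    read_result_table(cfg$manifest,
                      numeric_cols = "condition_ugml"), "qhtcp_config_error")
  concs <- sort(unique(manifest$condition_ugml))
  design <- .with_error_class(screen_design(concs, manifest),
                              "qhtcp_config_error")
  annotations <- NULL
  if (!is.null(cfg$annotations)) {
    annotations <- .with_error_class(read_annotations(cfg$annotations),
                                     "qhtcp_config_error")
  }
  arg <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  res <- .with_error_class(
    run_screen_pipeline(series, layouts, design, annotations = annotations,
                        qc_frac = arg("qc_frac", 0.10),
                        threshold = arg("threshold", 2.0),
                        k_max = arg("k_max", 60L),
                        linkage = arg("linkage", "ward.D2"),
                        metric = arg("metric", "euclidean"),
                        scope = arg("scope", "per_cluster"),
                        q_threshold = arg("q_threshold", 0.005)),
    "qhtcp_stage_error")

  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- arg("seed", NULL)
  paths <- c(cpp = file.path(out_dir, "cpp.tsv"),
             qc = file.path(out_dir, "qc.tsv"),
             interactions = file.path(out_dir, "interactions.tsv"),
             clusters = file.path(out_dir, "clusters.tsv"),
             bic = file.path(out_dir, "bic_curve.tsv"),
             log = file.path(out_dir, "run_log.txt"))
  write_result_table(res$fits, paths["cpp"], seed = seed)
  write_result_table(res$qc, paths["qc"], seed = seed)
  write_result_table(res$interactions, paths["interactions"], seed = seed)
  assign_tab <- data.frame(entry = names(res$assignment$labels),
                           gene = unname(res$profile$gene),
                           cluster = unname(res$assignment$labels),
                           stringsAsFactors = FALSE)
  write_result_table(assign_tab, paths["clusters"], seed = seed)
  write_result_table(res$assignment$bic_curve, paths["bic"], seed = seed)
  if (!is.null(res$enrichment)) {
    paths["enrichment"] <- file.path(out_dir, "enrichment.tsv")
    write_result_table(res$enrichment, paths["enrichment"], seed = seed)
  }
  log_lines <- c(paste0("# ", .pkg_stamp(seed)),
                 paste0("config: ", normalizePath(config_path)),
                 paste(names(res$log), res$log, sep = " = "))
  writeLines(log_lines, paths["log"])
  invisible(paths)
}

#' @rdname cmd_simulate
#' @param matrix_path path to a dose-matrix TSV.
#' @param window synergy window size, `c(rows, cols)`.
#' @export
cmd_synergy <- function(matrix_path, out_dir, window = c(3L, 3L)) {
  mat <- .with_error_class(read_dose_matrix(matrix_path), "qhtcp_config_error")
  surf <- .with_error_class(zip_surface(mat), "qhtcp_stage_error")
  win <- window_summary(surf, window)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  delta_path <- file.path(out_dir, "delta_surface.tsv")
  write_dose_matrix(surf$delta, delta_path)
  summary_path <- file.path(out_dir, "synergy_summary.txt")
  writeLines(sprintf(
    "mean_delta = %.4f ; best_%dx%d_window mean = %.4f at rows [%s] x cols [%s]",
    surf$summary, window[1], window[2], win$mean_delta,
    paste(win$rows, collapse = ","), paste(win$cols, collapse = ",")),
    summary_path)
  invisible(list(surface = surf, window = win,
                 paths = c(delta = delta_path, summary = summary_path)))
}

#' @rdname cmd_simulate
#' @param series_path path to a dose-series TSV with columns
#'   `concentration`, `replicate`, `response`.
#' @export
cmd_ic50 <- function(series_path, out_dir) {
  df <- .with_error_class(
    .read_table(series_path, "tsv", c("concentration", "replicate", "response"),
                numeric_cols = c("concentration", "response")),
    "qhtcp_config_error")
  fit <- .with_error_class(fit_4pl(df$concentration, df$response),
                           "qhtcp_stage_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- data.frame(bottom = fit$bottom, top = fit$top, hill = fit$hill,
                    ec50 = fit$ec50, ic50 = fit$ic50, rss = fit$rss)
  path <- file.path(out_dir, "ic50.tsv")
  write_result_table(out, path)
  invisible(fit)
}
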