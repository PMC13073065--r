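#' Configuration of a synthetic phenomic screen
#'
#' Defines the generative model for a complete synthetic screen with known
#' ground truth: deletion arrays and matched reference-strain arrays imaged
#' on a fixed cadence at each drug concentration. Per-spot true logistic
#' parameters compose as
#' \deqn{K = K0 (1 + \Delta K_g) drugK(c) (1 + batch)}
#' \deqn{L = L0 + \Delta L_g + drugL(c) + interaction_{g,c} + batch_L}
#' where gene effects are zero on reference arrays. Gene-drug interactions
#' are planted on L (the screen's kinetic phenotype) in reference-SD units:
#' one unit equals the standard deviation of fitted L over a reference
#' array under the default noise model (`sd_unit_L`), so a planted effect
#' of -6 targets an adjusted L z-score near -6.
#'
#' @param n_genes number of gene deletion strains.
#' @param concentrations drug concentrations in ug/mL, untreated first.
#' @param frac_defect fraction of genes with a baseline fitness defect.
#' @param defect_K_range multiplicative K shift range for defective genes
#'   (negative = smaller colonies).
#' @param defect_L_range additive L shift range in hours for defective
#'   genes.
#' @param frac_enhancer,frac_suppressor fractions of genes planted as
#'   drug-enhancing / drug-suppressing interactions (disjoint sets; the sum
#'   of all effect-class fractions must be <= 1).
#' @param effect_range interaction magnitude range, in reference-SD units.
#' @param interaction_weight per-concentration-index multiplier on the
#'   interaction effect (default ramps 0, 0.5, 1 so the top dose carries
#'   the full effect).
#' @param drug_K multiplicative drug effect on K per concentration index.
#' @param drug_L additive drug effect on L (hours) per concentration index.
#' @param batch_K_sd,batch_L_sd SDs of the per-array batch effects
#'   (multiplicative on K, additive hours on L).
#' @param noise_mult_sd,noise_add_sd observation noise: lognormal
#'   multiplicative sigma and additive Gaussian sigma (intensity units).
#' @param spot_K_sd,spot_L_sd spot-level culture variability on deletion
#'   arrays (multiplicative fraction of K; additive hours on L): replica
#'   pinning carries over fairly uniform inocula, so these are small.
#' @param ref_spot_K_sd,ref_spot_L_sd spot-level culture variability on
#'   reference arrays. Reference arrays are grown from independent
#'   inoculations across all 384 positions so that their CPP standard
#'   deviation captures the full assay variation; defaults exceed the
#'   deletion-array spot variability, which keeps null adjusted z-scores
#'   comfortably inside the calling threshold.
#' @param cadence_h,horizon_h imaging cadence and horizon in hours.
#' @param ref_K,ref_r,ref_L reference strain logistic parameters.
#' @param sd_unit_K,sd_unit_L calibration constants: the fitted-CPP
#'   standard deviation over a reference array under the default noise
#'   model, used to convert planted effect sizes from SD units to CPP
#'   units.
#' @param baseline_intensity constant background added to every image.
#' @param frac_duplicate fraction of genes also planted at a second array
#'   position (exercises duplicate-ORF handling).
#' @param seed integer seed; mandatory, every generator draw depends on it.
#' @return a list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 500L,
                              concentrations = c(0, 10, 20),
                              frac_defect = 0.3,
                              defect_K_range = c(-0.08, -0.02),
                              defect_L_range = c(0.5, 4),
                              frac_enhancer = 0.05,
                              frac_suppressor = 0.05,
                              effect_range = c(4, 12),
                              interaction_weight = NULL,
                              drug_K = c(1, 0.9, 0.8),
                              drug_L = c(0, 5, 10),
                              batch_K_sd = 0.01,
                              batch_L_sd = 1,
                              noise_mult_sd = 0.02,
                              noise_add_sd = 0.2,
                              spot_K_sd = 0.0015,
                              spot_L_sd = 0.1,
                              ref_spot_K_sd = 0.012,
                              ref_spot_L_sd = 0.8,
                              cadence_h = 3.5,
                              horizon_h = 120,
                              ref_K = 100, ref_r = 0.2, ref_L = 48,
                              sd_unit_K = 1.2, sd_unit_L = 0.8,
                              baseline_intensity = 2,
                              frac_duplicate = 0,
                              seed) {
  if (missing(seed)) stop("config error: seed is mandatory")
  nc <- length(concentrations)
  if (is.null(interaction_weight)) {
    interaction_weight <- if (nc == 1) 0 else c(0, seq_len(nc - 1) / (nc - 1))
  }
  cfg <- list(n_genes = as.integer(n_genes), concentrations = concentrations,
              frac_defect = frac_defect, defect_K_range = defect_K_range,
              defect_L_range = defect_L_range, frac_enhancer = frac_enhancer,
              frac_suppressor = frac_suppressor, effect_range = effect_range,
              interaction_weight = interaction_weight, drug_K = drug_K,
              drug_L = drug_L, batch_K_sd = batch_K_sd, batch_L_sd = batch_L_sd,
              noise_mult_sd = noise_mult_sd, noise_add_sd = noise_add_sd,
              spot_K_sd = spot_K_sd, spot_L_sd = spot_L_sd,
              ref_spot_K_sd = ref_spot_K_sd, ref_spot_L_sd = ref_spot_L_sd,
              cadence_h = cadence_h, horizon_h = horizon_h,
              ref_K = ref_K, ref_r = ref_r, ref_L = ref_L,
              sd_unit_K = sd_unit_K, sd_unit_L = sd_unit_L,
              baseline_intensity = baseline_intensity,
              frac_duplicate = frac_duplicate, seed = as.integer(seed))
  class(cfg) <- "screen_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname screen_sim_config
#' @param config a `screen_sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  chk_frac <- function(key) {
    v <- config[[key]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("config error: '", key, "' must lie in [0, 1] (got ", v, ")")
    }
  }
  for (key in c("frac_defect", "frac_enhancer", "frac_suppressor",
                "frac_duplicate")) chk_frac(key)
  if (config$frac_enhancer + config$frac_suppressor > 1) {
    stop("config error: effect-class fractions sum above 1")
  }
  if (config$concentrations[1] != 0) {
    stop("config error: first concentration must be 0")
  }
  nc <- length(config$concentrations)
  for (key in c("interaction_weight", "drug_K", "drug_L")) {
    if (length(config[[key]]) != nc) {
      stop("config error: '", key, "' must have one value per concentration")
    }
  }
  if (config$n_genes < 1) stop("config error: n_genes must be >= 1")
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  invisible(config)
}

# deterministic spot-intensity sampler for one array
.sim_array <- function(plate, conc, spots, t, Ktrue, rtrue, Ltrue, cfg) {
  nspot <- nrow(spots)
  nt <- length(t)
  mu <- matrix(0, nspot, nt)
  for (i in seq_len(nspot)) {
    mu[i, ] <- Ktrue[i] / (1 + exp(-rtrue[i] * (t - Ltrue[i]))) +
      cfg$baseline_intensity
  }
  noise_m <- exp(matrix(stats::rnorm(nspot * nt, 0, cfg$noise_mult_sd), nspot, nt))
  noise_a <- matrix(stats::rnorm(nspot * nt, 0, cfg$noise_add_sd), nspot, nt)
  obs <- pmax(mu * noise_m + noise_a, 0)
  data.frame(
    plate = plate,
    row = rep(spots$row, each = nt),
    col = rep(spots$col, each = nt),
    strain = rep(spots$strain, each = nt),
    condition_ugml = conc,
    time_h = rep(t, times = nspot),
    intensity = as.vector(t(obs)),
    stringsAsFactors = FALSE)
}

#' Simulate a complete phenomic screen with known ground truth
#'
#' Generates deletion-array and matched reference-array time series, plate
#' layouts, a screen design manifest, and the planted ground truth, all
#' deterministically from the config seed (identical config and seed give
#' bit-identical output).
#'
#' @param config a [screen_sim_config()].
#' @return a list: `series` (long time-series data.frame), `layouts`,
#'   `design` (a [screen_design()]), `truth` (list with `genes`,
#'   `interactions`, `plates` data.frames), `config`.
#' @export
simulate_screen <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n))

  # effect classes: disjoint enhancer/suppressor sets
  n_enh <- round(cfg$frac_enhancer * n)
  n_sup <- round(cfg$frac_suppressor * n)
  perm <- sample(n)
  cls <- rep("none", n)
  if (n_enh > 0) cls[perm[seq_len(n_enh)]] <- "enhancer"
  if (n_sup > 0) cls[perm[n_enh + seq_len(n_sup)]] <- "suppressor"

  has_defect <- stats::runif(n) < cfg$frac_defect
  dK <- ifelse(has_defect,
               stats::runif(n, cfg$defect_K_range[1], cfg$defect_K_range[2]), 0)
  dL <- ifelse(has_defect,
               stats::runif(n, cfg$defect_L_range[1], cfg$defect_L_range[2]), 0)
  eff <- stats::runif(n, cfg$effect_range[1], cfg$effect_range[2])
  eff[cls == "none"] <- 0
  eff_signed <- ifelse(cls == "enhancer", eff, ifelse(cls == "suppressor", -eff, 0))

  truth_genes <- data.frame(gene = genes, class = cls, delta_K = dK,
                            delta_L = dL, effect_sd_units = eff_signed,
                            stringsAsFactors = FALSE)

  concs <- cfg$concentrations
  nc <- length(concs)
  truth_int <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    data.frame(gene = genes, condition_ugml = concs[ci],
               interaction_L_sd_units = eff_signed * cfg$interaction_weight[ci],
               stringsAsFactors = FALSE)
  }))

  # entries: genes plus optional duplicate spots, chunked into 384-plates
  n_dup <- round(cfg$frac_duplicate * n)
  dup_genes <- if (n_dup > 0) sample(genes, n_dup) else character()
  entries <- c(genes, dup_genes)
  per_plate <- .PLATE_ROWS * .PLATE_COLS
  n_plates <- ceiling(length(entries) / per_plate)
  plate_ids <- sprintf("D%02d", seq_len(n_plates))
  ref_plate <- "R01"

  grid <- expand.grid(col = seq_len(.PLATE_COLS), row = LETTERS[seq_len(.PLATE_ROWS)],
                      stringsAsFactors = FALSE)
  grid <- grid[, c("row", "col")]

  layouts <- list()
  spot_tabs <- list()
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1) * per_plate + 1):min(p * per_plate, length(entries))
    strains <- rep("", per_plate)
    strains[seq_along(idx)] <- entries[idx]
    role <- ifelse(nzchar(strains), "deletion", "empty")
    layouts[[p]] <- data.frame(plate = plate_ids[p], row = grid$row,
                               col = grid$col, strain = strains, role = role,
                               stringsAsFactors = FALSE)
    keep <- nzchar(strains)
    spot_tabs[[p]] <- data.frame(plate = plate_ids[p], row = grid$row[keep],
                                 col = grid$col[keep], strain = strains[keep],
                                 stringsAsFactors = FALSE)
  }
  layouts[[n_plates + 1L]] <- data.frame(plate = ref_plate, row = grid$row,
                                         col = grid$col, strain = "REF",
                                         role = "reference",
                                         stringsAsFactors = FALSE)
  layouts <- do.call(rbind, layouts)

  manifest <- expand.grid(deletion_plate = plate_ids, condition_ugml = concs,
                          stringsAsFactors = FALSE)
  manifest$reference_plate <- ref_plate
  design <- screen_design(concs, manifest)

  t <- seq(0, cfg$horizon_h, by = cfg$cadence_h)
  all_plates <- c(plate_ids, ref_plate)
  batch <- expand.grid(plate = all_plates, condition_ugml = concs,
                       stringsAsFactors = FALSE)
  batch$batch_K <- stats::rnorm(nrow(batch), 0, cfg$batch_K_sd)
  batch$batch_L <- stats::rnorm(nrow(batch), 0, cfg$batch_L_sd)

  gidx <- stats::setNames(seq_len(n), genes)
  series <- list()
  for (ci in seq_len(nc)) {
    conc <- concs[ci]
    for (p in seq_len(n_plates)) {
      spots <- spot_tabs[[p]]
      b <- batch[batch$plate == plate_ids[p] & batch$condition_ugml == conc, ]
      gi <- gidx[spots$strain]
      ns <- nrow(spots)
      Ktrue <- cfg$ref_K * (1 + dK[gi]) * cfg$drug_K[ci] * (1 + b$batch_K) *
        (1 + stats::rnorm(ns, 0, cfg$spot_K_sd))
      Ltrue <- pmax(cfg$ref_L + dL[gi] + cfg$drug_L[ci] +
                      eff_signed[gi] * cfg$interaction_weight[ci] * cfg$sd_unit_L +
                      b$batch_L + stats::rnorm(ns, 0, cfg$spot_L_sd), 1)
      rtrue <- rep(cfg$ref_r, nrow(spots))
      series[[length(series) + 1L]] <-
        .sim_array(plate_ids[p], conc, spots, t, Ktrue, rtrue, Ltrue, cfg)
    }
    # reference array: gene effects zeroed
    b <- batch[batch$plate == ref_plate & batch$condition_ugml == conc, ]
    rspots <- data.frame(plate = ref_plate, row = grid$row, col = grid$col,
                         strain = "REF", stringsAsFactors = FALSE)
    Ktrue <- cfg$ref_K * cfg$drug_K[ci] * (1 + b$batch_K) *
      (1 + stats::rnorm(per_plate, 0, cfg$ref_spot_K_sd))
    Ltrue <- pmax(cfg$ref_L + cfg$drug_L[ci] + b$batch_L +
                    stats::rnorm(per_plate, 0, cfg$ref_spot_L_sd), 1)
    rtrue <- rep(cfg$ref_r, per_plate)
    series[[length(series) + 1L]] <-
      .sim_array(ref_plate, conc, rspots, t, Ktrue, rtrue, Ltrue, cfg)
  }
  series <- do.call(rbind, series)
  rownames(series) <- NULL

  list(series = series, layouts = layouts, design = design,
       truth = list(genes = truth_genes, interactions = truth_int,
                    plates = batch),
       config = cfg)
}

#' Simulate annotation sets with planted enrichment
#'
#' Builds a flat annotation set over the simulated genes: each planted
#' effect class (enhancers, suppressors) receives one term covering
#' `coverage` of its members plus unrelated genes at `base_rate`, and
#' `n_terms` further terms are assigned uniformly at random. With
#' `coverage = 0` no term is genuinely enriched.
#'
#' @param truth the `truth` element of a [simulate_screen()] result.
#' @param n_terms number of random (non-planted) terms.
#' @param coverage fraction of each planted class covered by its planted
#'   term (default 0.8).
#' @param base_rate probability that a gene outside the class is annotated
#'   to a planted term.
#' @param term_size_range size range of random terms.
#' @param seed integer seed.
#' @return an annotation set (named list term -> genes).
#' @export
simulate_annotations <- function(truth, n_terms = 40L, coverage = 0.8,
                                 base_rate = 0.02,
                                 term_size_range = c(10L, 60L), seed) {
  if (missing(seed)) stop("config error: seed is mandatory")
  set.seed(seed)
  genes <- toupper(truth$genes$gene)
  cls <- truth$genes$class
  ann <- list()
  for (cl in setdiff(unique(cls), "none")) {
    members <- genes[cls == cl]
    if (length(members) == 0) next
    n_in <- round(coverage * length(members))
    core <- if (n_in > 0) sample(members, n_in) else character()
    others <- genes[cls != cl]
    extra <- others[stats::runif(length(others)) < base_rate]
    set <- unique(c(core, extra))
    if (length(set) > 0) ann[[paste0("PLANTED_", toupper(cl))]] <- set
  }
  if (n_terms > 0) {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                    replace = TRUE)
    for (i in seq_len(n_terms)) {
      ann[[sprintf("RAND%03d", i)]] <- sample(genes, min(sizes[i], length(genes)))
    }
  }
  ann
}

#' Simulate a planted-partition profile matrix
#'
#' Generates a feature matrix of k spherical Gaussian clusters whose
#' centroids sit at the vertices of a randomly rotated regular simplex, so
#' every pair of centroids is exactly `separation` x `within_sd` apart.
#' Used to benchmark [hierarchical_cluster()] + [bic_cut()] recovery.
#'
#' @param n number of rows (entries).
#' @param k number of planted clusters (requires `k <= d + 1`).
#' @param d number of features (default 4, matching the adjusted z-score
#'   profile adjK2, adjK3, adjL2, adjL3).
#' @param separation pairwise centroid distance in units of `within_sd`.
#' @param within_sd within-cluster standard deviation per feature.
#' @param seed integer seed.
#' @return a list: `x` (n x d matrix with row names), `labels` (true
#'   cluster of each row), `centers` (k x d matrix).
#' @export
simulate_cluster_profiles <- function(n = 400L, k = 5L, d = 4L,
                                      separation = 6, within_sd = 1, seed) {
  if (missing(seed)) stop("config error: seed is mandatory")
  if (k > d + 1) stop("a regular simplex needs k <= d + 1")
  set.seed(seed)
  # regular simplex: e_1..e_k projected off the all-ones direction,
  # edge length sqrt(2), then scaled and randomly rotated into d dims
  v <- diag(k) - 1 / k
  basis <- svd(v)$u[, seq_len(k - 1), drop = FALSE]
  simplex <- v %*% basis            # k vertices in k-1 dims, edge sqrt(2)
  simplex <- simplex / sqrt(2) * separation * within_sd
  centers <- matrix(0, k, d)
  centers[, seq_len(k - 1)] <- simplex
  rot <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  centers <- centers %*% rot
  labels <- sample(rep(seq_len(k), length.out = n))
  x <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * d, 0, within_sd), n, d)
  rownames(x) <- sprintf("G%04d", seq_len(n))
  list(x = x, labels = labels, centers = centers)
}

#' Simulate a two-drug dose-combination matrix
#'
#' Builds a percent-inhibition matrix from two monotherapy inhibition
#' curves under Bliss independence, plus an optional planted interaction
#' surface and Gaussian noise:
#' cell = 100 (yA + yB - yA yB) + delta + noise. Monotherapy curves are
#' y(x) = top / (1 + (ec50 / x)^hill) on the fraction scale.
#'
#' @param params_a,params_b lists with `top`, `hill`, `ec50` for each drug.
#' @param doses_a,doses_b dose ladders (two-fold by default conventions);
#'   0 is prepended automatically if absent.
#' @param delta planted interaction, percentage points: a scalar or a
#'   matrix over the combination cells (rows = positive A doses).
#' @param noise_sd Gaussian noise SD in percentage points.
#' @param seed integer seed (mandatory when `noise_sd > 0`).
#' @return a percent-inhibition dose matrix with dose dimnames.
#' @export
simulate_dose_matrix <- function(params_a, params_b,
                                 doses_a = c(0, 2^(0:6)),
                                 doses_b = c(0, 2^(0:6)),
                                 delta = 0, noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed)) stop("config error: seed is mandatory")
  if (!is.null(seed)) set.seed(seed)
  if (!any(doses_a == 0)) doses_a <- c(0, doses_a)
  if (!any(doses_b == 0)) doses_b <- c(0, doses_b)
  doses_a <- sort(doses_a)
  doses_b <- sort(doses_b)
  yfun <- function(p, x) ifelse(x == 0, 0, p$top / (1 + (p$ec50 / x)^p$hill))
  yA <- yfun(params_a, doses_a)
  yB <- yfun(params_b, doses_b)
  mat <- outer(yA, yB, function(a, b) 100 * (a + b - a * b))
  dimnames(mat) <- list(as.character(doses_a), as.character(doses_b))
  comb <- outer(doses_a > 0, doses_b > 0, `&`)
  if (is.matrix(delta)) {
    mat[comb] <- mat[comb] + as.vector(delta)
  } else {
    mat[comb] <- mat[comb] + delta
  }
  if (noise_sd > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), 0, noise_sd), nrow(mat))
  }
  mat
}
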