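#' Standardize cell proliferation parameters to plate z-scores
#'
#' Each strain's CPP on a deletion array is centered on the median of that
#' array's valid CPPs and divided by the standard deviation of the same CPP
#' over the matched 384-spot reference-strain array:
#' z = (CPP_strain - median(deletion array)) / sd(reference array).
#' Median subtraction removes plate-level shifts; the reference-array sd
#' calibrates assay variation so that z-scores are comparable across plates
#' and conditions.
#'
#' @param cpp numeric vector of one CPP (K or L) for the strains of one
#'   deletion array at one condition; NA for invalid fits.
#' @param reference_sd standard deviation of the same CPP over the matched
#'   reference array; must be > 0.
#' @return numeric vector of z-scores (NA where `cpp` is NA).
#' @examples
#' standardize_plate(c(100, 110, 90), reference_sd = 5)
#' @export
standardize_plate <- function(cpp, reference_sd) {
  if (!is.finite(reference_sd) || reference_sd <= 0) {
    stop("degenerate reference: reference_sd must be a positive finite number")
  }
  if (all(is.na(cpp))) return(cpp)
  if (mean(!is.na(cpp)) < 0.5) {
    stop("fewer than 50% of array strains have valid CPPs; array should fail QC")
  }
  (cpp - stats::median(cpp, na.rm = TRUE)) / reference_sd
}

#' Adjusted z-scores: the gene-drug interaction statistic
#'
#' Under the proportional-response interaction model, a strain's z-score in
#' the presence of the drug equals its untreated z-score plus the gene-drug
#' interaction. The interaction is therefore estimated by subtraction:
#' adjusted z = z(drug) - z(untreated). A strain whose drug response simply
#' scales with the plate has adjusted z near 0; deviations identify
#' deletions that enhance or suppress drug activity.
#'
#' @param z numeric vector (or matrix with concentrations in columns) of
#'   z-scores at a drug concentration.
#' @param z_untreated z-scores of the same strains at concentration index 1
#'   (untreated).
#' @return adjusted z-scores; NA wherever either operand is missing.
#' @export
adjust_zscores <- function(z, z_untreated) {
  z - z_untreated
}

#' Classify gene-drug interactions
#'
#' Drug-suppressing interactions have positive adjusted K z-scores, negative
#' adjusted L z-scores, or both (the deletion grows relatively better under
#' drug); drug-enhancing interactions have negative adjusted K z-scores,
#' positive adjusted L z-scores, or both. A rule only fires beyond
#' `threshold` in absolute value. If both rules fire, the label follows the
#' larger |adjusted z|; an exact tie is neutral.
#'
#' @param adjK,adjL numeric vectors of adjusted K and L z-scores (either may
#'   be NA where unavailable).
#' @param threshold calling threshold on |adjusted z| (default 2, the
#'   conventional two-sigma screen heuristic; raw values are always reported
#'   alongside so users can re-threshold).
#' @return character vector: `"enhancer"`, `"suppressor"`, or `"neutral"`
#'   (NA when both inputs are NA).
#' @examples
#' classify_interaction(adjK = 4.0, adjL = -6.6)   # suppressor
#' classify_interaction(adjK = -10.4, adjL = NA)   # enhancer
#' @export
classify_interaction <- function(adjK, adjL, threshold = 2.0) {
  n <- max(length(adjK), length(adjL))
  adjK <- rep_len(adjK, n)
  adjL <- rep_len(adjL, n)
  out <- character(n)
  for (i in seq_len(n)) {
    k <- adjK[i]; l <- adjL[i]
    if (is.na(k) && is.na(l)) {
      out[i] <- NA_character_
      next
    }
    s_mag <- suppressWarnings(max(c(if (!is.na(k) && k >= threshold) k,
                                    if (!is.na(l) && l <= -threshold) -l), -Inf))
    e_mag <- suppressWarnings(max(c(if (!is.na(k) && k <= -threshold) -k,
                                    if (!is.na(l) && l >= threshold) l), -Inf))
    out[i] <- if (s_mag > e_mag) "suppressor"
              else if (e_mag > s_mag) "enhancer"
              else "neutral"  # neither fired, or exact tie
  }
  out
}

#' Score a fitted screen: z-scores, adjusted z-scores, interaction classes
#'
#' Orchestrates plate standardization across a whole screen. For each
#' QC-passing deletion array and condition, K and L are standardized with
#' [standardize_plate()] against the manifest-matched reference array; the
#' plate median uses only converged, unflagged fits. Adjusted z-scores are
#' then formed per strain (z at each drug concentration minus z untreated)
#' and classified. Strains are keyed by physical spot (plate, row, col), so
#' duplicate ORF strains are scored independently; collapsing happens only
#' in the enrichment background, where the analysis requires it.
#'
#' @param fits fit table from [fit_screen()].
#' @param design a [screen_design()].
#' @param qc QC table from [qc_arrays()]; arrays with `passed = FALSE` are
#'   excluded. Pass NULL to skip QC-based exclusion.
#' @param threshold classification threshold (see [classify_interaction()]).
#' @return a data.frame with one row per deletion-array spot: `strain`,
#'   `plate`, `row`, `col`, z-score columns `z_K1..z_K<n>`, `z_L1..z_L<n>`,
#'   adjusted columns `adjK2..`, `adjL2..`, and one class column per drug
#'   concentration, named `class_<conc>ugml`.
#' @export
score_screen <- function(fits, design, qc = NULL, threshold = 2.0) {
  stopifnot(inherits(design, "screen_design"))
  concs <- design$concentrations
  man <- design$manifest
  valid <- fits$converged & !nzchar(fits$flags)

  if (!is.null(qc)) {
    qc_pass <- qc$passed
    names(qc_pass) <- paste(qc$plate, qc$condition_ugml, sep = "\r")
  }

  array_ok <- function(plate, conc) {
    if (is.null(qc)) return(TRUE)
    isTRUE(qc_pass[[paste(plate, conc, sep = "\r")]])
  }

  # reference sd per (reference plate, condition, parameter)
  ref_sd <- function(rp, conc, param) {
    sel <- fits$plate == rp & fits$condition_ugml == conc & valid
    if (!array_ok(rp, conc)) return(NA_real_)
    v <- fits[[param]][sel]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v)
  }

  dplates <- unique(man$deletion_plate)
  out <- vector("list", length(dplates))
  for (pi in seq_along(dplates)) {
    dp <- dplates[pi]
    base <- fits[fits$plate == dp & fits$condition_ugml == concs[1], , drop = FALSE]
    base <- base[order(base$row, base$col), , drop = FALSE]
    if (nrow(base) == 0) next
    tab <- base[, c("strain", "plate", "row", "col"), drop = FALSE]
    spot_key <- paste(tab$row, tab$col, sep = "\r")

    for (ci in seq_along(concs)) {
      conc <- concs[ci]
      zK <- rep(NA_real_, nrow(tab))
      zL <- rep(NA_real_, nrow(tab))
      mrow <- man[man$deletion_plate == dp & man$condition_ugml == conc, , drop = FALSE]
      if (nrow(mrow) == 1 && array_ok(dp, conc)) {
        sub <- fits[fits$plate == dp & fits$condition_ugml == conc, , drop = FALSE]
        sub_valid <- sub$converged & !nzchar(sub$flags)
        idx <- match(paste(sub$row, sub$col, sep = "\r"), spot_key)
        for (param in c("K", "L")) {
          rsd <- ref_sd(mrow$reference_plate[1], conc, param)
          if (is.na(rsd) || rsd <= 0) next
          cpp <- ifelse(sub_valid, sub[[param]], NA_real_)
          if (all(is.na(cpp)) || mean(!is.na(cpp)) < 0.5) next
          z <- standardize_plate(cpp, rsd)
          if (param == "K") zK[idx[!is.na(idx)]] <- z[!is.na(idx)]
          else zL[idx[!is.na(idx)]] <- z[!is.na(idx)]
        }
      }
      tab[[paste0("z_K", ci)]] <- zK
      tab[[paste0("z_L", ci)]] <- zL
    }
    out[[pi]] <- tab
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) stop("no scorable deletion arrays")

  for (ci in seq_along(concs)[-1]) {
    out[[paste0("adjK", ci)]] <- adjust_zscores(out[[paste0("z_K", ci)]], out$z_K1)
    out[[paste0("adjL", ci)]] <- adjust_zscores(out[[paste0("z_L", ci)]], out$z_L1)
  }
  for (ci in seq_along(concs)[-1]) {
    out[[sprintf("class_%sugml", format(concs[ci]))]] <-
      classify_interaction(out[[paste0("adjK", ci)]], out[[paste0("adjL", ci)]],
                           threshold = threshold)
  }
  rownames(out) <- NULL
  out
}

#' Rank the strongest interaction outliers
#'
#' Returns the `n` strains with the most extreme adjusted z-score for the
#' requested parameter and concentration index, emulating outlier tables
#' such as "the 10 lowest adjusted K z-scores at 10 ug/mL". Ties are broken
#' alphabetically by strain.
#'
#' @param interactions interaction table from [score_screen()].
#' @param param `"K"` or `"L"`.
#' @param conc_index concentration index (2 = first drug concentration, ...).
#' @param direction `"lowest"` (default) or `"highest"`.
#' @param n number of strains to return (default 10).
#' @return a data.frame of `strain`, `plate`, `row`, `col`, and the ranked
#'   adjusted z-score column, sorted. If fewer than `n` strains are scored,
#'   all are returned with a warning.
#' @export
rank_outliers <- function(interactions, param = c("K", "L"), conc_index = 2L,
                          direction = c("lowest", "highest"), n = 10L) {
  param <- match.arg(param)
  direction <- match.arg(direction)
  colname <- paste0("adj", param, conc_index)
  if (!colname %in% names(interactions)) {
    stop("no column '", colname, "' in interaction table")
  }
  v <- interactions[[colname]]
  keep <- !is.na(v)
  sub <- interactions[keep, c("strain", "plate", "row", "col", colname)]
  v <- v[keep]
  ord <- if (direction == "lowest") order(v, sub$strain) else order(-v, sub$strain)
  sub <- sub[ord, , drop = FALSE]
  if (n > nrow(sub)) {
    warning("requested n = ", n, " but only ", nrow(sub), " strains scored")
    n <- nrow(sub)
  }
  out <- utils::head(sub, n)
  rownames(out) <- NULL
  out
}
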