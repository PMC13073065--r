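# Constrained logistic fit of fractional inhibition against dose, used for
# ZIP monotherapy margins and conditional (potency-shift) refits.
#
# Model: y = b + (top - b) / (1 + (ec50 / x)^h)  (increasing in x),
# with baseline b fixed (0 for monotherapy; the conditioning drug's effect
# for conditional fits), top free in [b, top_max]. If the responses are flat
# or the logistic does not beat a constant, the fit degrades to the constant
# mean, which keeps the surface well defined for inert margins.
.fit_inhibition <- function(dose, y, baseline = 0, top_max = 1) {
  stopifnot(length(dose) == length(y), all(dose > 0))
  const_mean <- mean(y)
  const_rss <- sum((y - const_mean)^2)
  pred_const <- function(x) rep(const_mean, length(x))
  if (diff(range(y)) < 1e-9 || length(y) < 3) {
    return(list(fitted = pred_const, model = "constant", rss = const_rss))
  }
  lx <- log10(dose)
  top0 <- min(max(max(y), baseline + 1e-3), top_max)
  mid <- (baseline + top0) / 2
  le0 <- lx[which.min(abs(y - mid))]
  b <- baseline
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + (top - b) / (1 + 10^(h * (le - lx))),
      start = list(top = top0, h = 1, le = le0),
      lower = c(top = baseline, h = 1e-2, le = min(lx) - 3),
      upper = c(top = top_max, h = 20, le = max(lx) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(fitted = pred_const, model = "constant", rss = const_rss))
  }
  rss <- sum(stats::resid(fit)^2)
  if (const_rss <= rss) {
    return(list(fitted = pred_const, model = "constant", rss = const_rss))
  }
  cf <- stats::coef(fit)
  top <- unname(cf["top"]); h <- unname(cf["h"]); ec50 <- 10^unname(cf["le"])
  list(fitted = function(x) b + (top - b) / (1 + (ec50 / x)^h),
       model = "logistic", top = top, hill = h, ec50 = ec50, rss = rss)
}

#' Zero interaction potency (ZIP) synergy surface
#'
#' Computes the ZIP delta landscape of a two-drug percent-inhibition matrix.
#' The model scores each dose combination against the expectation that the
#' two drugs act independently (Bliss) while allowing each drug to shift the
#' apparent potency of the other:
#' \enumerate{
#'   \item each monotherapy margin is fitted with a constrained logistic on
#'     fractional inhibition (baseline 0, maximum bounded by 1);
#'   \item the zero-interaction expectation at combination (x1, x2) is
#'     y1 + y2 - y1 y2 from the fitted monotherapy values;
#'   \item the observed response is taken from potency-shifted refits: each
#'     row (conditioning on drug B) and each column (conditioning on drug A)
#'     is refitted with the baseline fixed to the conditioning drug's fitted
#'     monotherapy effect, and the two directions are averaged;
#'   \item delta = observed - expected, in percentage points of inhibition.
#' }
#' Delta is defined only at combination cells (both doses > 0). The summary
#' score is the mean delta over all combination cells; windowed scores are
#' means over every contiguous window of combination cells (see
#' [window_summary()]).
#'
#' @param mat percent-inhibition dose matrix (see [read_dose_matrix()]):
#'   drug A doses in rows, drug B doses in columns, 0-dose margins present.
#' @return an object of class `synergy_surface`: list with `delta` (matrix
#'   aligned to `mat`, NA on margins), `observed` and `expected` (same
#'   shape, percent scale), `summary` (mean delta), `margin_fits`.
#' @export
zip_surface <- function(mat) {
  .check_dose_matrix(mat)
  dA <- as.numeric(rownames(mat))
  dB <- as.numeric(colnames(mat))
  iA <- which(dA > 0)
  iB <- which(dB > 0)
  if (length(iA) < 2 || length(iB) < 2) {
    stop("need at least 2 positive doses per drug")
  }
  f <- mat / 100

  # margins: column at dB == 0 is drug A monotherapy, row at dA == 0 drug B
  colB0 <- which(dB == 0)[1]
  rowA0 <- which(dA == 0)[1]
  fitA <- .fit_inhibition(dA[iA], f[iA, colB0], baseline = 0)
  fitB <- .fit_inhibition(dB[iB], f[rowA0, iB], baseline = 0)
  y1 <- fitA$fitted(dA[iA])   # monotherapy effect of A at each row dose
  y2 <- fitB$fitted(dB[iB])   # monotherapy effect of B at each column dose

  expected <- outer(y1, y2, function(a, b) a + b - a * b)

  obs_row <- matrix(NA_real_, length(iA), length(iB))
  for (r in seq_along(iA)) {
    fr <- .fit_inhibition(dB[iB], f[iA[r], iB], baseline = min(max(y1[r], 0), 1))
    obs_row[r, ] <- fr$fitted(dB[iB])
  }
  obs_col <- matrix(NA_real_, length(iA), length(iB))
  for (cc in seq_along(iB)) {
    fc <- .fit_inhibition(dA[iA], f[iA, iB[cc]], baseline = min(max(y2[cc], 0), 1))
    obs_col[, cc] <- fc$fitted(dA[iA])
  }
  observed <- (obs_row + obs_col) / 2

  delta <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  delta[iA, iB] <- 100 * (observed - expected)
  obs_full <- exp_full <- delta
  obs_full[iA, iB] <- 100 * observed
  exp_full[iA, iB] <- 100 * expected

  structure(list(delta = delta, observed = obs_full, expected = exp_full,
                 summary = mean(delta[iA, iB]),
                 margin_fits = list(A = fitA, B = fitB)),
            class = "synergy_surface")
}

#' @export
print.synergy_surface <- function(x, ...) {
  comb <- x$delta[!is.na(x$delta)]
  cat(sprintf("synergy_surface: %d combination cells, mean delta = %.2f\n",
              length(comb), x$summary))
  invisible(x)
}

#' Most synergistic dose window
#'
#' Slides a contiguous window (default 3 x 3) over the combination cells of
#' a ZIP delta surface and returns the window with the largest mean delta.
#' Ties resolve to the lowest dose indices (row first).
#'
#' @param surface a [zip_surface()] result (or a bare delta matrix with NA
#'   margins).
#' @param window integer vector `c(rows, cols)` (default `c(3, 3)`).
#' @return a list: `mean_delta`, `rows` and `cols` (dose labels of the
#'   window), `row_index`, `col_index` (indices into the combination grid).
#' @export
window_summary <- function(surface, window = c(3L, 3L)) {
  delta <- if (inherits(surface, "synergy_surface")) surface$delta else surface
  comb_rows <- which(rowSums(!is.na(delta)) > 0)
  comb_cols <- which(colSums(!is.na(delta)) > 0)
  d <- delta[comb_rows, comb_cols, drop = FALSE]
  wr <- window[1]; wc <- window[2]
  if (wr > nrow(d) || wc > ncol(d)) {
    stop("window ", wr, "x", wc, " larger than the ", nrow(d), "x", ncol(d),
         " combination surface")
  }
  best <- NULL
  for (i in seq_len(nrow(d) - wr + 1L)) {
    for (j in seq_len(ncol(d) - wc + 1L)) {
      m <- mean(d[i:(i + wr - 1L), j:(j + wc - 1L)])
      if (is.null(best) || m > best$mean_delta) {
        best <- list(mean_delta = m, row_index = i, col_index = j)
      }
    }
  }
  best$rows <- rownames(d)[best$row_index:(best$row_index + wr - 1L)]
  best$cols <- colnames(d)[best$col_index:(best$col_index + wc - 1L)]
  best
}
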