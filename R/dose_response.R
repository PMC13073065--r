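#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model
#' y(x) = bottom + (top - bottom) / (1 + (x / ec50)^hill)
#' to endpoint responses over a dose ladder, parameterized on log10 dose.
#' With hill > 0 and top > bottom the curve falls from `top` (no drug) to
#' `bottom` (full inhibition), matching endpoint-absorbance assays. The
#' zero-dose wells are used only to anchor the untreated response scale,
#' not in the logistic fit (log dose is undefined at 0). The IC50 is
#' reported as the concentration at which the fitted response equals 50% of
#' the fitted untreated response (= `top`); it coincides with `ec50` when
#' `bottom` is 0.
#'
#' @param conc numeric vector of concentrations (>= 0; at least 4 distinct
#'   values including 0).
#' @param response numeric vector of endpoint responses (absorbance or
#'   fraction of control), same length.
#' @return a list of class `fourpl_fit`: `bottom`, `top`, `hill`, `ec50`,
#'   `ic50`, `rss`, `converged`, and `fitted(x)` closure.
#' @examples
#' x <- c(0, 2^(-2:6))
#' y <- 1 / (1 + (x / 5))
#' fit_4pl(x, y)$ec50
#' @export
fit_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response), all(conc >= 0))
  if (length(unique(conc)) < 4 || !any(conc == 0)) {
    stop("need >= 4 distinct concentrations including 0")
  }
  rng <- diff(range(response))
  if (rng <= 0.1 * max(abs(response), .Machine$double.eps)) {
    stop("flat response: no inhibition detected")
  }
  pos <- conc > 0
  x <- conc[pos]
  y <- response[pos]
  y0 <- mean(response[!pos])

  top0 <- max(c(y, y0))
  bot0 <- min(y)
  mid <- (top0 + bot0) / 2
  le0 <- log10(x[which.min(abs(y - mid))])
  lx <- log10(x)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - le))),
      start = list(bottom = bot0, top = top0, hill = 1, le = le0),
      lower = c(bottom = min(y) - rng, top = min(y), hill = 1e-3,
                le = min(lx) - 3),
      upper = c(bottom = max(c(y, y0)), top = max(c(y, y0)) + rng, hill = 50,
                le = max(lx) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop("dose-response fit did not converge (", length(x), " doses, range ",
         signif(rng, 3), ")")
  }
  cf <- stats::coef(fit)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"]); ec50 <- 10^unname(cf["le"])
  if (top <= bottom) stop("degenerate fit: top <= bottom")

  ic50 <- if (top / 2 > bottom) {
    ec50 * ((top / 2) / (top / 2 - bottom))^(1 / hill)
  } else {
    NA_real_  # fitted floor above half the untreated response
  }
  structure(list(bottom = bottom, top = top, hill = hill, ec50 = ec50,
                 ic50 = ic50, rss = sum(stats::resid(fit)^2), converged = TRUE,
                 fitted = function(xx) {
                   bottom + (top - bottom) / (1 + (xx / ec50)^hill)
                 }),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: bottom=%.4g top=%.4g hill=%.4g ec50=%.4g ic50=%.4g\n",
              x$bottom, x$top, x$hill, x$ec50, x$ic50))
  invisible(x)
}

#' Lag time and maximum growth rate of a liquid growth curve
#'
#' Smooths the absorbance curve with a centered moving average and takes
#' finite-difference slopes between consecutive smoothed points. The lag is
#' the time of maximum slope (midpoint of the steepest segment, hours); the
#' maximum growth rate is that slope rescaled to absorbance x 1000 per
#' minute, the plate-reader convention. A curve that never rises gets
#' `max_rate = 0` and an undefined lag.
#'
#' @param time_h times in hours (>= 10 points at a fixed cadence; 30-minute
#'   reads are typical).
#' @param absorbance matched absorbance readings.
#' @param window moving-average window in points (odd; default 3).
#' @return a list: `lag_h`, `max_rate` (absorbance x 1000 / min),
#'   `max_slope_h` (absorbance per hour), `flags`.
#' @export
growth_metrics <- function(time_h, absorbance, window = 3L) {
  stopifnot(length(time_h) == length(absorbance))
  if (length(time_h) < 10) stop("need >= 10 observations")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > 1L) {
    sm <- stats::filter(absorbance, rep(1 / window, window), sides = 2)
    keep <- !is.na(sm)
    s <- as.numeric(sm[keep])
    tt <- time_h[keep]
  } else {
    s <- absorbance
    tt <- time_h
  }
  slopes <- diff(s) / diff(tt)
  i <- which.max(slopes)
  if (slopes[i] <= 0) {
    return(list(lag_h = NA_real_, max_rate = 0, max_slope_h = 0,
                flags = "no_growth"))
  }
  list(lag_h = (tt[i] + tt[i + 1]) / 2,
       max_rate = slopes[i] * 1000 / 60,
       max_slope_h = slopes[i],
       flags = character())
}

#' Percent inhibition relative to untreated controls
#'
#' 100 x (1 - treated / mean(control)).
#'
#' @param treated numeric vector (or matrix) of treated endpoint responses.
#' @param control numeric vector of untreated control responses; mean must
#'   be positive.
#' @return percent inhibition, same shape as `treated`.
#' @export
percent_inhibition <- function(treated, control) {
  cm <- mean(control)
  if (!is.finite(cm) || cm <= 0) {
    stop("degenerate control: mean control response must be > 0")
  }
  100 * (1 - treated / cm)
}

#' Read and write dose-combination matrices
#'
#' A dose matrix stores percent inhibition over a two-drug concentration
#' grid. On disk the first column holds drug A concentrations, the header
#' row drug B concentrations, and the body percent inhibition; the (0, 0)
#' cell must be present.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param mat a numeric matrix with numeric rownames (drug A doses) and
#'   colnames (drug B doses).
#' @param seed optional integer for the provenance header.
#' @return `read_dose_matrix()` returns the numeric matrix with dose
#'   dimnames.
#' @export
read_dose_matrix <- function(path, dialect = "tsv") {
  sep <- .delim(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(as.numeric(rn))
  colnames(mat) <- as.character(as.numeric(colnames(df)[-1]))
  if (anyNA(suppressWarnings(as.numeric(rownames(mat)))) ||
      anyNA(suppressWarnings(as.numeric(colnames(mat))))) {
    stop("schema error: dose matrix margins must be numeric concentrations")
  }
  storage.mode(mat) <- "double"
  .check_dose_matrix(mat)
  mat
}

#' @rdname read_dose_matrix
#' @export
write_dose_matrix <- function(mat, path, dialect = "tsv", seed = NULL) {
  df <- data.frame(ugml = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_table(df, path, dialect, comment = .pkg_stamp(seed))
}

.check_dose_matrix <- function(mat) {
  dA <- as.numeric(rownames(mat))
  dB <- as.numeric(colnames(mat))
  if (anyNA(dA) || anyNA(dB)) stop("dose matrix must have numeric dose dimnames")
  if (!any(dA == 0) || !any(dB == 0)) {
    stop("schema error: dose matrix must include the 0-dose margin row and column")
  }
  if (is.unsorted(dA) || is.unsorted(dB)) {
    stop("dose ladders must be sorted increasing")
  }
  invisible(mat)
}
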