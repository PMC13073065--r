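#' Logistic growth model
#'
#' The symmetric logistic growth equation G(t) = K / (1 + exp(-r (t - L)))
#' used to summarize each spot culture's imaging time course. K is the
#' carrying capacity (the plateau, in intensity units), r the maximum
#' specific growth rate (per hour), and L the time at which G reaches K/2
#' (hours). The curve's slope is maximal at t = L with value r K / 4.
#'
#' @param t time in hours (vectorized).
#' @param K carrying capacity, > 0.
#' @param r maximum specific growth rate per hour, > 0.
#' @param L time to half carrying capacity in hours, >= 0.
#' @return intensity G(t), strictly increasing in t and bounded by (0, K).
#' @examples
#' logistic_eval(50, K = 100, r = 0.1, L = 50)  # K/2 = 50 at t = L
#' @export
logistic_eval <- function(t, K, r, L) {
  stopifnot(K > 0, r > 0, L >= 0)
  K / (1 + exp(-r * (t - L)))
}

#' Fit settings for growth-curve estimation
#'
#' @param min_points minimum number of observations required for fitting.
#' @param non_grower_range absolute dynamic-range threshold: a series whose
#'   baseline-subtracted range is at or below this value is flagged
#'   `non_grower` and not fitted. [fit_screen()] replaces this with a
#'   plate-relative threshold (see `non_grower_rel`).
#' @param non_grower_rel relative threshold used by [fit_screen()]: fraction
#'   of the plate's median dynamic range below which a series is a
#'   non-grower.
#' @param r_max upper bound on r (per hour).
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return a list of settings.
#' @export
fit_settings <- function(min_points = 5L, non_grower_range = 1e-8,
                         non_grower_rel = 0.10, r_max = 5, maxiter = 100L) {
  list(min_points = as.integer(min_points),
       non_grower_range = non_grower_range,
       non_grower_rel = non_grower_rel,
       r_max = r_max, maxiter = as.integer(maxiter))
}

#' Fit one spot culture's growth curve
#'
#' Nonlinear least squares of the logistic growth model plus a constant
#' background, y = b + K / (1 + exp(-r (t - L))), against a single
#' (time, intensity) series. The free baseline b absorbs imaging background
#' without biasing K when a culture is already part-grown at the first
#' image; K is reported on the background-subtracted scale. Starting values
#' are derived from the data (b0 = series minimum, K0 = observed range,
#' L0 = time nearest the half-range crossing, r0 = 4 x max
#' finite-difference slope / K0) and the optimizer is bounded to the
#' physical range b in [0, min intensity], K in (0, 2 max], r in (0,
#' r_max], L in [0, 2 max time].
#'
#' @param time_h numeric vector of times in hours, strictly increasing.
#' @param intensity numeric vector of spot intensities, same length.
#' @param settings a [fit_settings()] list.
#' @return a list of class `growth_fit` with elements `params` (named vector
#'   K, r, L, or NULL), `rss`, `converged`, and `flags` (character vector;
#'   any of `"non_grower"`, `"poor_fit"`, `"insufficient_data"`). `params`
#'   is present exactly when the fit converged and the series grew.
#' @examples
#' t <- seq(0, 120, by = 3.5)
#' y <- logistic_eval(t, K = 120, r = 0.08, L = 40)
#' fit <- fit_growth_curve(t, y)
#' fit$params
#' @export
fit_growth_curve <- function(time_h, intensity, settings = fit_settings()) {
  stopifnot(length(time_h) == length(intensity))
  out <- list(params = NULL, rss = NA_real_, converged = FALSE,
              flags = character())
  class(out) <- "growth_fit"
  if (length(time_h) < settings$min_points) {
    out$flags <- "insufficient_data"
    return(out)
  }
  if (any(diff(time_h) <= 0)) stop("time_h must be strictly increasing")

  b0 <- min(intensity)
  y <- intensity
  rng <- max(y) - b0
  if (rng <= settings$non_grower_range) {
    out$flags <- "non_grower"
    return(out)
  }

  # data-driven starts, safe for monotone curves
  K0 <- rng
  L0 <- time_h[which.min(abs(y - b0 - rng / 2))]
  slopes <- diff(y) / diff(time_h)
  smax <- max(slopes)
  r0 <- if (smax > 0) 4 * smax / K0 else 0.1
  r0 <- min(max(r0, 1e-3), settings$r_max)
  t_max <- max(time_h)

  # Levenberg-Marquardt on the residuals directly: the baseline and K
  # gradients are nearly collinear for saturated curves, which the damped
  # solver handles without trouble
  fn <- function(p) y - (p[1] + p[2] / (1 + exp(-p[3] * (time_h - p[4]))))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(b = b0, K = K0, r = r0, L = max(L0, 0)), fn = fn,
      lower = c(b = 0, K = K0 * 1e-6, r = 1e-6, L = 0),
      upper = c(b = b0 + 1e-9 + 0.05 * rng, K = 2 * (rng + b0),
                r = settings$r_max, L = 2 * t_max),
      control = minpack.lm::nls.lm.control(maxiter = settings$maxiter)),
    error = function(e) NULL)

  if (is.null(fit) || !(fit$info %in% 1:3)) {
    out$flags <- "poor_fit"
    return(out)
  }
  cf <- fit$par
  out$params <- c(K = unname(cf["K"]), r = unname(cf["r"]), L = unname(cf["L"]))
  out$baseline <- unname(cf["b"])
  out$rss <- fit$deviance
  out$converged <- TRUE
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!is.null(x$params)) {
    cat(sprintf("growth_fit: K=%.4g r=%.4g L=%.4g (rss=%.4g)\n",
                x$params["K"], x$params["r"], x$params["L"], x$rss))
  } else {
    cat("growth_fit: no parameters; flags:",
        paste(x$flags, collapse = ","), "\n")
  }
  invisible(x)
}

#' Fit every spot of a screen
#'
#' Applies [fit_growth_curve()] to every (plate, position, condition) group
#' of a long time-series table. The non-grower threshold is relative: a spot
#' is a non-grower if its dynamic range is below `non_grower_rel` (default
#' 10%) of the median dynamic range on its (plate, condition) array, so the
#' rule adapts to imaging gain. Per-spot failures become flags; the screen
#' never aborts on a bad spot. Output order and values are deterministic
#' given identical inputs and settings, independent of input row order.
#'
#' @param series long time-series data.frame (see [read_timeseries()]).
#' @param settings a [fit_settings()] list.
#' @return a data.frame with one row per spot: `strain`, `plate`, `row`,
#'   `col`, `condition_ugml`, `K`, `r`, `L`, `rss`, `converged`, `flags`
#'   (`;`-joined, empty when clean).
#' @export
fit_screen <- function(series, settings = fit_settings()) {
  stopifnot(all(.TS_COLS %in% names(series)))
  key <- paste(series$plate, series$condition_ugml, series$row, series$col,
               sep = "\r")
  groups <- split(seq_len(nrow(series)), key)
  # deterministic order: plate, condition, row, col
  info <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  ord <- order(info[, 1], as.numeric(info[, 2]), info[, 3], as.numeric(info[, 4]))
  groups <- groups[ord]

  n <- length(groups)
  res <- vector("list", n)
  ranges <- numeric(n)
  plates <- character(n)
  for (i in seq_len(n)) {
    idx <- groups[[i]]
    sub <- series[idx, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    res[[i]] <- sub
    ranges[i] <- diff(range(sub$intensity))
    plates[i] <- paste(sub$plate[1], sub$condition_ugml[1], sep = "\r")
  }
  med_range <- tapply(ranges, plates, stats::median)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- res[[i]]
    st <- settings
    st$non_grower_range <- max(settings$non_grower_range,
                               settings$non_grower_rel * med_range[[plates[i]]])
    f <- fit_growth_curve(sub$time_h, sub$intensity, st)
    p <- if (is.null(f$params)) c(K = NA_real_, r = NA_real_, L = NA_real_) else f$params
    rows[[i]] <- data.frame(
      strain = sub$strain[1], plate = sub$plate[1], row = sub$row[1],
      col = sub$col[1], condition_ugml = sub$condition_ugml[1],
      K = p[["K"]], r = p[["r"]], L = p[["L"]], rss = f$rss,
      converged = f$converged, flags = paste(f$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Array-level quality control
#'
#' Flags problematic arrays, emulating manual filtering of imaging artifacts:
#' an array fails when too many of its spots failed to fit (fraction above
#' `frac_threshold`), or when failures are spatially clustered (any
#' contiguous `block` x `block` window of the 16 x 24 grid contains at least
#' `block_count` failures), a signature of smears and pinning artifacts
#' rather than biology. Failed arrays are excluded downstream.
#'
#' @param fits fit table from [fit_screen()].
#' @param frac_threshold maximum tolerated failed fraction (default 0.10).
#' @param block spatial window size in wells (default 4).
#' @param block_count failures within one window that trigger the spatial
#'   flag (default 8).
#' @return a data.frame with one row per (plate, condition):
#'   `fraction_failed`, `spatial_flag`, `passed`.
#' @export
qc_arrays <- function(fits, frac_threshold = 0.10, block = 4L, block_count = 8L) {
  failed <- !fits$converged | nzchar(fits$flags)
  key <- paste(fits$plate, fits$condition_ugml, sep = "\r")
  out <- lapply(split(seq_len(nrow(fits)), key), function(idx) {
    sub <- fits[idx, , drop = FALSE]
    fail <- failed[idx]
    frac <- mean(fail)
    grid <- matrix(0L, .PLATE_ROWS, .PLATE_COLS)
    rr <- match(sub$row, LETTERS)
    cc <- as.integer(sub$col)
    grid[cbind(rr[fail], cc[fail])] <- 1L
    spatial <- FALSE
    if (sum(grid) >= block_count) {
      for (i in seq_len(.PLATE_ROWS - block + 1L)) {
        for (j in seq_len(.PLATE_COLS - block + 1L)) {
          if (sum(grid[i:(i + block - 1L), j:(j + block - 1L)]) >= block_count) {
            spatial <- TRUE
            break
          }
        }
        if (spatial) break
      }
    }
    data.frame(plate = sub$plate[1], condition_ugml = sub$condition_ugml[1],
               fraction_failed = frac, spatial_flag = spatial,
               passed = frac <= frac_threshold && !spatial,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$plate, out$condition_ugml), , drop = FALSE]
  rownames(out) <- NULL
  out
}
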