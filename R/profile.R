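#' Sample image intensity along a traced polyline
#'
#' Samples the image at unit-pixel arclength spacing along a manually traced
#' polyline (the collar-to-collar trace around the cell body), using
#' bilinear interpolation at sub-pixel coordinates. Endpoint order is
#' preserved and both endpoints are always sampled.
#'
#' Coordinates are 0-based pixel centers: `x` is the column, `y` the row
#' (y increases downward), matching how traces are exported from image
#' viewers.
#'
#' @param img numeric matrix (grayscale image).
#' @param trace data.frame or matrix with columns `x`, `y`; at least two
#'   distinct points with positive total arclength, all within the image.
#' @return numeric vector of intensities along the trace.
#' @export
sample_intensity <- function(img, trace) {
  trace <- as.matrix(trace[, c("x", "y")])
  if (nrow(trace) < 2L) stop("trace needs at least 2 points")
  if (any(trace[, "x"] < 0 | trace[, "x"] > ncol(img) - 1L |
          trace[, "y"] < 0 | trace[, "y"] > nrow(img) - 1L))
    stop("trace extends outside the image")
  seg <- sqrt(diff(trace[, "x"])^2 + diff(trace[, "y"])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("trace has zero arclength")
  at <- unique(c(seq(0, total, by = 1), total))
  x <- approx(s, trace[, "x"], xout = at, ties = "ordered")$y
  y <- approx(s, trace[, "y"], xout = at, ties = "ordered")$y
  bilinear_at(img, x, y)
}

# Bilinear interpolation at 0-based (x = col, y = row) coordinates.
bilinear_at <- function(img, x, y) {
  x0 <- pmin(floor(x), ncol(img) - 2L); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), nrow(img) - 2L); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1L, x0 + 1L)]
  i01 <- img[cbind(y0 + 1L, x0 + 2L)]
  i10 <- img[cbind(y0 + 2L, x0 + 1L)]
  i11 <- img[cbind(y0 + 2L, x0 + 2L)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

#' Normalize a raw intensity profile to the image maximum
#'
#' Divides every sample by the maximum fluorescence intensity of the cropped
#' image it came from, so profiles from different cells share a common 0-1
#' scale.
#'
#' @param profile numeric vector of raw intensities.
#' @param image_max positive maximum intensity of the source (cropped)
#'   image.
#' @return the normalized profile.
#' @export
normalize_intensity <- function(profile, image_max) {
  if (image_max <= 0) stop("image_max must be positive")
  profile / image_max
}

#' Resample a profile to 150 points over normalized arclength
#'
#' Linear interpolation of the profile onto `n_points` (default 150) equally
#' spaced abscissae over normalized arclength `[0, 1]`; the first and last
#' output values equal the input endpoints.
#'
#' @param profile numeric vector of length `>= 2`.
#' @param n_points number of output points, default 150.
#' @return numeric vector of length `n_points`.
#' @export
resample_150 <- function(profile, n_points = 150L) {
  if (length(profile) < 2L) stop("profile must have at least 2 samples")
  approx(seq(0, 1, length.out = length(profile)), profile,
         xout = seq(0, 1, length.out = n_points))$y
}

#' Pointwise ensemble mean and 95% confidence band
#'
#' Averages a set of per-cell normalized 150-point profiles and attaches the
#' pointwise 95% t-interval `mean +/- t(0.975, n-1) * SEM` at each abscissa
#' (the gray band drawn around published ensemble traces). With a single
#' member the mean is returned and the band is flagged empty.
#'
#' @param profiles list of equal-length numeric profiles, or a matrix with
#'   one profile per row; `n >= 1`.
#' @param conf_level confidence level, default 0.95.
#' @return list of class `profile_ensemble` with `n`, `arclength`, `mean`,
#'   `lower`, `upper` and the member `profiles` matrix.
#' @export
ensemble_stats <- function(profiles, conf_level = 0.95) {
  m <- if (is.matrix(profiles)) profiles else do.call(rbind, profiles)
  if (is.null(m) || nrow(m) == 0L) stop("no profiles supplied")
  if (anyNA(m)) stop("profiles contain missing values")
  n <- nrow(m)
  mu <- colMeans(m)
  if (n >= 2L) {
    sem <- apply(m, 2L, sd) / sqrt(n)
    tq <- qt(1 - (1 - conf_level) / 2, df = n - 1L)
    lower <- mu - tq * sem
    upper <- mu + tq * sem
  } else {
    warning("single profile: confidence band undefined")
    lower <- upper <- rep(NA_real_, ncol(m))
  }
  structure(list(n = n, arclength = seq(0, 1, length.out = ncol(m)),
                 mean = mu, lower = lower, upper = upper, profiles = m),
            class = "profile_ensemble")
}

#' @export
print.profile_ensemble <- function(x, ...) {
  cat("Profile ensemble:", x$n, "cells,", length(x$mean),
      "points over normalized arclength\n")
  invisible(x)
}

#' Plot an ensemble mean profile with its confidence band
#'
#' @param x a `profile_ensemble`.
#' @param ... passed to [plot()].
#' @export
plot.profile_ensemble <- function(x, ...) {
  plot(x$arclength, x$mean, type = "n",
       ylim = range(c(x$lower, x$upper, x$mean), na.rm = TRUE),
       xlab = "normalized arclength around cell body",
       ylab = "normalized fluorescence intensity", ...)
  if (!anyNA(x$lower))
    graphics::polygon(c(x$arclength, rev(x$arclength)),
                      c(x$lower, rev(x$upper)),
                      col = gray(0.8), border = NA)
  graphics::lines(x$arclength, x$mean, lwd = 2)
  invisible(x)
}

#' Compare basal-pole fluorescence between two ensembles
#'
#' The basal pole sits at the trace midpoint by construction, so basal
#' signal is summarized as each cell's mean over a central window of the
#' normalized arclength (default the central 20%). The two ensembles'
#' member-level window means are compared with a Welch t-interval for the
#' difference (a minus b).
#'
#' @param ensemble_a,ensemble_b `profile_ensemble` objects.
#' @param basal_window central fraction of arclength to average, in (0, 1].
#' @param conf_level confidence level, default 0.95.
#' @return list with `difference`, `conf_int`, `p_value`, and the two
#'   window-mean vectors.
#' @export
compare_basal_signal <- function(ensemble_a, ensemble_b, basal_window = 0.2,
                                 conf_level = 0.95) {
  win_means <- function(e) {
    k <- ncol(e$profiles)
    idx <- which(abs(e$arclength - 0.5) <= basal_window / 2)
    if (length(idx) == 0L) stop("empty basal window")
    rowMeans(e$profiles[, idx, drop = FALSE])
  }
  a <- win_means(ensemble_a); b <- win_means(ensemble_b)
  ht <- t.test(a, b, conf.level = conf_level)
  list(difference = unname(mean(a) - mean(b)),
       conf_int = unname(ht$conf.int), p_value = unname(ht$p.value),
       window_means_a = a, window_means_b = b)
}
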