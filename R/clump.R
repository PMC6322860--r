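#' Measure particles in a binary mask
#'
#' Connected components (8-connectivity, as in ImageJ Analyze Particles)
#' converted to physical areas; only particles with area strictly greater
#' than `min_area_um2` (default 20 um^2, the published cutoff that removes
#' residual bacterial signal) are kept. Labels follow raster-scan order.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param pixel_size_um microns per pixel side, `> 0`.
#' @param min_area_um2 strict lower area cutoff in um^2.
#' @return data.frame with `label`, `n_pixels`, `area_um2`.
#' @export
analyze_particles <- function(mask, pixel_size_um, min_area_um2 = 20) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  lab <- label_components(mask)
  if (max(lab) == 0L)
    return(data.frame(label = integer(), n_pixels = integer(),
                      area_um2 = numeric()))
  npx <- tabulate(lab[lab > 0L], nbins = max(lab))
  rec <- data.frame(label = seq_along(npx), n_pixels = npx,
                    area_um2 = npx * pixel_size_um^2)
  rec <- rec[rec$area_um2 > min_area_um2, , drop = FALSE]
  rec$label <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  rec
}

#' Convert particle area to cell equivalents
#'
#' Clump size in units of cells: the particle area divided by the area of a
#' representative single cell (in the published analysis, the average
#' measured wild-type cell area — a required input, not a built-in constant).
#'
#' @param area_um2 particle area(s) in um^2.
#' @param ref_cell_area_um2 reference single-cell area in um^2, `> 0`.
#' @return dimensionless cell-equivalent count(s), unrounded.
#' @examples
#' cell_equivalents(750, 10)  # 75-cell clump
#' @export
cell_equivalents <- function(area_um2, ref_cell_area_um2) {
  if (ref_cell_area_um2 <= 0) stop("ref_cell_area_um2 must be > 0")
  area_um2 / ref_cell_area_um2
}

#' Quantify cell clumps in a micrograph
#'
#' The full ImageJ-style chain applied with its default settings, in order:
#' smooth (3x3 mean), find edges (Sobel), despeckle (3x3 median), make
#' binary (IsoData threshold), dilate, erode, fill holes, analyze particles
#' (8-connected, area > `min_area_um2`), then conversion to cell
#' equivalents.
#'
#' @param img numeric matrix (grayscale DIC image).
#' @param pixel_size_um microns per pixel side.
#' @param ref_cell_area_um2 representative single-cell area (um^2).
#' @param min_area_um2 strict particle area cutoff (um^2), default 20.
#' @return data.frame of clump records: `label`, `n_pixels`, `area_um2`,
#'   `cell_equivalents`.
#' @examples
#' spec <- synthetic_image_spec(clump_composition = c(1, 5), seed = 1)
#' gen <- generate_dic_image(spec)
#' quantify_image(gen$image, spec$pixel_size_um,
#'                ref_cell_area_um2 = pi * spec$cell_radius_um^2)
#' @export
quantify_image <- function(img, pixel_size_um, ref_cell_area_um2,
                           min_area_um2 = 20) {
  mask <- ij_make_binary(ij_despeckle(ij_find_edges(ij_smooth(img))))
  mask <- ij_fill_holes(ij_erode(ij_dilate(mask)))
  rec <- analyze_particles(mask, pixel_size_um, min_area_um2)
  rec$cell_equivalents <- cell_equivalents(rec$area_um2, ref_cell_area_um2)
  rec
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two clump-size distributions (cell equivalents per clump) with
#' the two-sample K-S statistic `D = sup |ECDF_x - ECDF_y|` and its
#' asymptotic p-value.
#'
#' @param x,y nonempty numeric samples.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be nonempty")
  ht <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Summarize a set of clump records
#'
#' The quantities drawn in violin boxplots of clump size: median,
#' interquartile range (linear-interpolation quantiles) and the range
#' excluding outliers (values within the 1.5 x IQR fences).
#'
#' @param records data.frame with a `cell_equivalents` column, or a numeric
#'   vector of cell equivalents; at least one value.
#' @return list with `n_clumps`, `median`, `q1`, `q3` and `range_lo` /
#'   `range_hi` (non-outlier range).
#' @export
summarize_clumps <- function(records) {
  x <- if (is.data.frame(records)) records$cell_equivalents else records
  if (length(x) == 0L) stop("no clump records to summarize")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  inliers <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
  list(n_clumps = length(x), median = q[2], q1 = q[1], q3 = q[3],
       range_lo = min(inliers), range_hi = max(inliers))
}
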