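#' Specification of a synthetic DIC-like micrograph
#'
#' Parameters for rendering a synthetic field of cell clumps with known
#' ground truth: bright filled disks (cells, drawn in overlapping groups to
#' form clumps) on a mid-gray background, small dark speckles (bacteria) and
#' additive Gaussian noise. Defaults render a *S. rosetta*-scale cell
#' (radius 2.6 um) at 0.05 um/pixel, a resolution at which the systematic
#' half-edge-width widening of the segmentation chain stays small relative
#' to cell area.
#'
#' @param image_shape integer `(rows, cols)` in pixels.
#' @param pixel_size_um microns per pixel side, `> 0`.
#' @param cell_radius_um representative cell radius (um).
#' @param clump_composition integer vector: cells per clump to draw (all
#'   `>= 1`); may be empty for a pure-background field.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; images use a 0-1 scale).
#' @param bacteria_density dark speckles per pixel.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(image_shape = c(1024L, 1024L),
                                 pixel_size_um = 0.05,
                                 cell_radius_um = 2.6,
                                 clump_composition = c(1L, 5L, 20L),
                                 noise_sd = 0.02,
                                 bacteria_density = 2e-4,
                                 seed = 1L) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (length(clump_composition) && any(clump_composition < 1))
    stop("all clump sizes must be >= 1")
  if (cell_radius_um <= 0) stop("cell_radius_um must be > 0")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 cell_radius_um = cell_radius_um,
                 clump_composition = as.integer(clump_composition),
                 noise_sd = noise_sd,
                 bacteria_density = bacteria_density,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Sunflower-spiral cell centers for an n-cell clump. The scale 0.85 r gives
# a typical nearest-neighbor spacing of ~1.6 r, so adjacent disks overlap
# and the clump rasterizes to one connected blob (cells in real clumps
# overlap in 2-D projection the same way).
clump_cell_centers <- function(n, r) {
  if (n == 1L) return(cbind(0, 0))
  k <- seq_len(n)
  phi <- pi * (3 - sqrt(5))
  rad <- 0.85 * r * sqrt(k - 1)
  cbind(rad * cos(k * phi), rad * sin(k * phi))
}

#' Render a synthetic DIC-like micrograph with ground truth
#'
#' Draws each requested clump as an overlapping group of bright disks at a
#' random location (clumps never touch one another; an error is raised if
#' the field is too small to place them all), scatters dark bacterial
#' speckles, and adds Gaussian noise last. Ground truth records the exact
#' rasterized pixel area of every clump.
#'
#' @param spec a [synthetic_image_spec()].
#' @return list with `image` (numeric matrix, 0-1 scale) and `ground_truth`,
#'   a data.frame with `label`, `n_cells`, `n_pixels`, `area_um2` per clump
#'   (empty for an empty composition).
#' @export
generate_dic_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  r_px <- spec$cell_radius_um / spec$pixel_size_um
  with_seed(spec$seed, {
    img <- matrix(0.5, nr, nc)
    gt <- data.frame(label = integer(), n_cells = integer(),
                     n_pixels = integer(), area_um2 = numeric())
    comp <- spec$clump_composition
    if (length(comp)) {
      centers <- lapply(comp, clump_cell_centers, r = r_px)
      bound <- vapply(centers, function(cc)
        max(sqrt(rowSums(cc^2))) + r_px, 0)
      sep <- 8  # px gap so closing/dilation never bridges clumps
      placed <- matrix(numeric(), 0L, 2L)
      placed_bound <- numeric()
      for (i in order(bound, decreasing = TRUE)) {
        if (2 * (bound[i] + 2) >= min(nr, nc))
          stop("image too small to place requested clumps without overlap")
        ok <- FALSE
        for (try in 1:500) {
          cand <- c(runif(1, bound[i] + 2, nr - bound[i] - 2),
                    runif(1, bound[i] + 2, nc - bound[i] - 2))
          if (nrow(placed) == 0L ||
              all(sqrt(rowSums(sweep(placed, 2, cand)^2)) >
                  placed_bound + bound[i] + sep)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("image too small to place requested clumps without overlap")
        placed <- rbind(placed, cand)
        placed_bound <- c(placed_bound, bound[i])
        cc <- sweep(centers[[i]], 2, cand, `+`)
        # rasterize the union of this clump's disks inside its bounding box
        r0 <- max(1L, floor(cand[1] - bound[i] - 1))
        r1 <- min(nr, ceiling(cand[1] + bound[i] + 1))
        c0 <- max(1L, floor(cand[2] - bound[i] - 1))
        c1 <- min(nc, ceiling(cand[2] + bound[i] + 1))
        rows <- r0:r1; cols <- c0:c1
        inside <- matrix(FALSE, length(rows), length(cols))
        for (j in seq_len(nrow(cc))) {
          d2 <- outer((rows - cc[j, 1])^2, (cols - cc[j, 2])^2, `+`)
          inside <- inside | (d2 <= r_px^2)
        }
        img[rows, cols][inside] <- 0.9
        gt <- rbind(gt, data.frame(label = i, n_cells = comp[i],
                                   n_pixels = sum(inside),
                                   area_um2 = sum(inside) *
                                     spec$pixel_size_um^2))
      }
      gt <- gt[order(gt$label), , drop = FALSE]
      rownames(gt) <- NULL
    }
    n_bact <- rpois(1L, spec$bacteria_density * nr * nc)
    if (n_bact > 0L) {
      # bacteria: dark disks ~0.3 um radius, far below the 20 um^2 cutoff
      b_r <- max(1, 0.3 / spec$pixel_size_um)
      br <- sample.int(nr, n_bact, replace = TRUE)
      bc <- sample.int(nc, n_bact, replace = TRUE)
      off <- expand.grid(dr = -ceiling(b_r):ceiling(b_r),
                         dc = -ceiling(b_r):ceiling(b_r))
      off <- off[off$dr^2 + off$dc^2 <= b_r^2, , drop = FALSE]
      for (k in seq_len(n_bact)) {
        rr <- br[k] + off$dr; cc <- bc[k] + off$dc
        okp <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        idx <- cbind(rr[okp], cc[okp])
        bg <- img[idx] == 0.5  # only on background
        img[idx[bg, , drop = FALSE]] <- 0.2
      }
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    list(image = img, ground_truth = gt)
  })
}

#' Generate synthetic fluorescence cell images with boundary traces
#'
#' Each synthetic cell is a disk with bright apical fluorescence at both
#' collar-body junctions (the two trace endpoints) and, when `basal_signal`
#' is set, an additional basal patch at the middle of the trace. The trace
#' polyline runs along the cell-body boundary from one junction, around the
#' basal pole, to the other junction — so the basal pole is the trace
#' midpoint by construction. Coordinates are 0-based pixel centers,
#' `x` = column, `y` = row (y down).
#'
#' @param n_cells number of cells to generate, `>= 1`.
#' @param basal_signal draw the basal fluorescence patch?
#' @param seed integer RNG seed.
#' @param image_size side of the square image in pixels.
#' @return list of length `n_cells`; each element has `image` (numeric
#'   matrix) and `trace` (data.frame `x`, `y`).
#' @export
generate_profile_set <- function(n_cells, basal_signal = TRUE, seed = 1L,
                                 image_size = 101L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      n <- image_size
      ctr <- (n - 1) / 2
      r <- 0.3 * n * runif(1, 0.9, 1.1)
      rot <- runif(1, 0, 2 * pi)
      # collar junctions 55 deg either side of the apical pole (angle 0
      # before rotation); trace sweeps the remaining 250 deg through the
      # basal pole (angle pi).
      half <- 55 * pi / 180
      theta <- seq(half, 2 * pi - half, length.out = 121L) + rot
      tx <- ctr + r * sin(theta)
      ty <- ctr - r * cos(theta)
      xg <- matrix(rep(0:(n - 1), each = n), n, n)   # column index = x
      yg <- matrix(rep(0:(n - 1), times = n), n, n)  # row index = y
      bump <- function(px, py, amp, sd)
        amp * exp(-((xg - px)^2 + (yg - py)^2) / (2 * sd^2))
      img <- matrix(0.05, n, n)
      img <- img + bump(tx[1L], ty[1L], 0.9, r / 5) +
        bump(tx[length(tx)], ty[length(ty)], 0.9, r / 5)
      if (basal_signal) {
        bx <- ctr + r * sin(pi + rot); by <- ctr - r * cos(pi + rot)
        img <- img + bump(bx, by, 0.7 * runif(1, 0.85, 1.15), r / 4)
      }
      img <- img + matrix(rnorm(n * n, 0, 0.005), n, n)
      img <- pmin(pmax(img, 0), 1)
      list(image = img, trace = data.frame(x = tx, y = ty))
    })
  })
}
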