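# ImageJ-compatible 3x3 neighborhood primitives. Images are numeric matrices
# (row = y, column = x); borders are handled by edge replication, the ImageJ
# convention, so results are bit-stable.

pad_replicate <- function(m) {
  m <- rbind(m[1L, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1L, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

# List of the 9 neighbor matrices for offsets (dr, dc) in {-1,0,1}^2.
neighborhood3 <- function(m) {
  p <- pad_replicate(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    out[[k]] <- p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc),
                  drop = FALSE]
  }
  out
}

check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be a numeric matrix of at least 3x3 pixels")
  img
}

#' Smooth an image (3x3 mean filter)
#'
#' The ImageJ 'Smooth' command: each pixel is replaced by the mean of its
#' 3x3 neighborhood (edge replication at borders). Used to suppress
#' background bacterial signal before edge detection.
#'
#' @param img numeric matrix (grayscale image).
#' @return smoothed matrix of the same shape.
#' @export
ij_smooth <- function(img) {
  check_image(img)
  Reduce(`+`, neighborhood3(img)) / 9
}

#' Edge magnitude (3x3 Sobel)
#'
#' The ImageJ 'Find Edges' command: Sobel gradient magnitude
#' `sqrt(Gx^2 + Gy^2)` with the standard 3x3 kernels, highlighting the
#' phase-bright cell outlines.
#'
#' @inheritParams ij_smooth
#' @return edge-magnitude matrix of the same shape.
#' @export
ij_find_edges <- function(img) {
  check_image(img)
  n <- neighborhood3(img)
  # n indexed by (dr, dc): 1:(-1,-1) 2:(-1,0) 3:(-1,1) 4:(0,-1) 5:(0,0)
  # 6:(0,1) 7:(1,-1) 8:(1,0) 9:(1,1)
  gx <- n[[1]] + 2 * n[[4]] + n[[7]] - n[[3]] - 2 * n[[6]] - n[[9]]
  gy <- n[[1]] + 2 * n[[2]] + n[[3]] - n[[7]] - 2 * n[[8]] - n[[9]]
  sqrt(gx^2 + gy^2)
}

#' Despeckle an image (3x3 median filter)
#'
#' The ImageJ 'Despeckle' command: each pixel is replaced by the median of
#' its 3x3 neighborhood (edge replication), removing isolated noise pixels.
#' Implemented with a 19-exchange median-of-9 selection network so the whole
#' image is processed vectorised.
#'
#' @inheritParams ij_smooth
#' @return median-filtered matrix of the same shape.
#' @export
ij_despeckle <- function(img) {
  check_image(img)
  p <- neighborhood3(img)
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Devillard's optimal median-of-9 network (indices shifted to 1-based).
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}

#' IsoData (iterative intermeans) threshold
#'
#' Computes the ImageJ default global threshold: starting from the image
#' mean, iterate `t <- (mean(below t) + mean(above t)) / 2` to its fixed
#' point.
#'
#' @inheritParams ij_smooth
#' @param tol convergence tolerance on the threshold.
#' @return the threshold value.
#' @export
isodata_threshold <- function(img, tol = 1e-8) {
  check_image(img)
  t <- mean(img)
  for (i in 1:1000) {
    lo <- img[img <= t]; hi <- img[img > t]
    if (length(lo) == 0L || length(hi) == 0L) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

#' Binarize an image (ImageJ 'Make Binary')
#'
#' Thresholds globally at the IsoData iterative-intermeans threshold; pixels
#' strictly above the threshold become foreground. A constant image yields an
#' empty mask with a warning.
#'
#' @inheritParams ij_smooth
#' @return logical matrix (TRUE = foreground).
#' @export
ij_make_binary <- function(img) {
  check_image(img)
  if (diff(range(img)) == 0) {
    warning("constant image: no foreground")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  img > isodata_threshold(img)
}

#' Binary dilation, erosion and hole filling
#'
#' One iteration of binary dilation/erosion with a 3x3 square structuring
#' element (edge replication at borders), and flood-fill hole filling:
#' background not reachable from the image border becomes foreground.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @return logical matrix of the same shape.
#' @export
ij_dilate <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  Reduce(`|`, neighborhood3(mask))
}

#' @rdname ij_dilate
#' @export
ij_erode <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  Reduce(`&`, neighborhood3(mask))
}

#' @rdname ij_dilate
#' @export
ij_fill_holes <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  filled <- EBImage::fillHull(mask * 1L)
  matrix(filled > 0L, nrow(mask), ncol(mask))
}

#' Label connected foreground components (8-connectivity)
#'
#' Connected-component labelling with ImageJ's Analyze Particles
#' connectivity: pixels touching edge- or corner-wise belong to one
#' particle. Labels are assigned in raster-scan (row-major) order of each
#' component's first pixel.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1L)       # 4-connected pass (C speed)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1L) {
    # Merge labels touching diagonally to get 8-connectivity: union-find
    # over the (few) label pairs adjacent along the two diagonals.
    parent <- seq_len(nlab)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    union2 <- function(a, b) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]    # offset (1, 1)
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]    # offset (1, -1)
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- unique(pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                          pairs[, 1L] != pairs[, 2L], , drop = FALSE])
    for (i in seq_len(nrow(pairs))) union2(pairs[i, 1L], pairs[i, 2L])
    roots <- vapply(seq_len(nlab), find, 1L)
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  # Relabel in raster-scan (row-major) order of first occurrence.
  if (max(lab) > 0L) {
    nr <- nrow(lab); nc <- ncol(lab)
    raster_idx <- (row(lab) - 1L) * nc + col(lab)
    first <- tapply(raster_idx[lab > 0L], lab[lab > 0L], min)
    old <- as.integer(names(first))[order(first)]
    remap <- integer(max(lab)); remap[old] <- seq_along(old)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}
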