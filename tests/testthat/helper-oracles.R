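# Independent brute-force oracles, kept deliberately naive (per-element
# loops, set comprehensions) so they share no code path with the package.

random_pool <- function(n, n_contigs = 3) {
  ref <- sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                prob = c(rep(0.23, 4), 0.08))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  dp <- rpois(n, 15)
  pooled_calls(contig = as.character(sample.int(n_contigs, n, replace = TRUE)),
               pos = sample.int(5000, n), ref = ref, alt = alt,
               qual = round(runif(n, 0, 60), 1),
               total_depth = dp,
               alt_depth = rbinom(n, dp, runif(n)))
}

random_strain_set <- function(pool, frac, name = "s") {
  take <- runif(nrow(pool)) < frac
  extra <- variant_sites(contig = "9", pos = sample.int(5000, 5),
                         ref = "A", alt = "T")
  sites <- rbind(pool[take, c("contig", "pos", "ref", "alt", "type")], extra)
  sites <- sites[!duplicated(paste(sites$contig, sites$pos, sites$ref,
                                   sites$alt)), ]
  strain_variant_set(name, sites)
}

# Brute-force cascade: per-row predicate evaluation and membership checks.
brute_cascade <- function(pool, parent, controls, min_depth = 2,
                          min_qual = 10, seg_frac = 0.99, ratio = 0.25,
                          mean_depth) {
  key <- function(r) paste(r$contig, r$pos, r$ref, r$alt)
  pk <- vapply(seq_len(nrow(parent)), function(i) key(parent[i, ]), "")
  ck <- unlist(lapply(controls, function(s)
    vapply(seq_len(nrow(s)), function(i) key(s[i, ]), "")))
  keep <- logical(nrow(pool))
  seg <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    r <- pool[i, ]
    if (!(key(r) %in% pk)) next
    if (key(r) %in% ck) next
    if (!(r$total_depth > min_depth)) next
    if (!(r$qual > min_qual)) next
    if (grepl("N", r$ref)) next
    if (!(r$alt_depth / r$total_depth > seg_frac)) next
    seg[i] <- TRUE
    if (r$total_depth >= ratio * mean_depth) keep[i] <- TRUE
  }
  list(robust = pool[keep, , drop = FALSE],
       segregating = pool[seg, , drop = FALSE])
}

# Brute-force 3x3 median with replicated borders.
brute_median3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(9); k <- 0
    for (di in -1:1) for (dj in -1:1) {
      k <- k + 1
      vals[k] <- img[min(max(i + di, 1), nr), min(max(j + dj, 1), nc)]
    }
    out[i, j] <- median(vals)
  }
  out
}

# Brute-force bilinear interpolation at one 0-based (x, y) point.
brute_bilinear <- function(img, x, y) {
  x0 <- min(max(floor(x), 0), ncol(img) - 2)
  y0 <- min(max(floor(y), 0), nrow(img) - 2)
  fx <- x - x0; fy <- y - y0
  img[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
    img[y0 + 1, x0 + 2] * fx * (1 - fy) +
    img[y0 + 2, x0 + 1] * (1 - fx) * fy +
    img[y0 + 2, x0 + 2] * fx * fy
}

# Brute-force two-sample KS statistic: max ECDF gap over pooled points.
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
}

sorted_keys <- function(df) sort(paste(df$contig, df$pos, df$ref, df$alt))
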