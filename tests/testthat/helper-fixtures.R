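# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the full suite runs in minutes.

small_extent <- function(km = 10) {
  c(xmin = 0, xmax = km * 1000, ymin = 0, ymax = km * 1000)
}

# A three-class landscape with fine patches relative to the 5 km home-range
# kernel, used by the selection-recovery checks.
three_class_landscape <- function(seed = 11, km = 40, patch = 4000) {
  generate_landscape(seed = seed, extent = small_extent(km), n_classes = 3,
                     patch_scale = patch, cell = 100, n_ecoregions = 3)
}

# Two Gaussian clusters separated by `sep` with within-cluster SD `sd`;
# the canonical fragmented / bimodal point pattern.
bimodal_points <- function(n = 60, sep = 6000, sd = 400) {
  half <- n %/% 2
  tibble::tibble(
    x_m = c(stats::rnorm(half, 0, sd), stats::rnorm(n - half, sep, sd)),
    y_m = stats::rnorm(n, 0, sd)
  )
}

# Independent brute-force KDE: per-cell double loop over points, no
# separability trick. Evaluates on the same grid geometry as `ud`.
oracle_kde <- function(points, ud) {
  r <- ud$raster
  ctr <- raster_centers(r)
  h <- ud$h
  m <- matrix(0, nrow(r$values), ncol(r$values))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      d2 <- (points$x_m - ctr$x[j])^2 + (points$y_m - ctr$y[i])^2
      m[i, j] <- sum(exp(-d2 / (2 * h^2)))
    }
  }
  m / sum(m)
}

# Independent connected-component count by iterative label propagation over
# the 8 neighbourhood (no graph library).
oracle_components <- function(cells) {
  lab <- matrix(0L, nrow(cells), ncol(cells))
  lab[cells] <- seq_len(sum(cells))
  repeat {
    old <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- shift_matrix(lab, dr, dc)
      upd <- cells & sh > 0 & (sh < lab | lab == 0)
      lab[upd] <- sh[upd]
    }
    if (identical(old, lab)) break
  }
  length(unique(lab[cells]))
}

shift_matrix <- function(m, dr, dc) {
  out <- matrix(0L, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rsrc <- rs - dr; csrc <- cs - dc
  okr <- rsrc >= 1 & rsrc <= nrow(m); okc <- csrc >= 1 & csrc <= ncol(m)
  out[rs[okr], cs[okc]] <- m[rsrc[okr], csrc[okc]]
  out
}

# Independent exhaustive ad-hoc bandwidth scan: own h_ref arithmetic, own
# sort-and-accumulate isopleth, own component count; only the kernel-sum
# grid is shared (verified separately against oracle_kde).
oracle_adhoc <- function(points, level = 0.99, multipliers = seq(0.1, 1, by = 0.1),
                         cell = 100, escalate_cap = 2) {
  n <- nrow(points)
  h_ref <- sqrt((stats::sd(points$x_m)^2 + stats::sd(points$y_m)^2) / 2) * n^(-1 / 6)
  contiguous_at <- function(m) {
    ud <- kernel_ud(points, h = m * h_ref, cell = cell)
    v <- as.vector(ud$raster$values)
    ord <- order(v, decreasing = TRUE)
    k <- which(cumsum(v[ord]) >= level)[1]
    sel <- logical(length(v)); sel[ord[seq_len(k)]] <- TRUE
    oracle_components(matrix(sel, nrow = nrow(ud$raster$values))) == 1
  }
  ok <- multipliers[vapply(multipliers, contiguous_at, logical(1))]
  if (length(ok)) return(min(ok))
  up <- seq(max(multipliers) + 0.1, escalate_cap, by = 0.1)
  ok <- up[vapply(up, contiguous_at, logical(1))]
  if (length(ok)) min(ok) else NA_real_
}
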