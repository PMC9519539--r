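# Independent brute-force oracles. These deliberately avoid the package's
# code paths: winding-number point-in-polygon, pair-counting U statistics,
# definitional BH, naive complete linkage.

# Winding-number point-in-polygon (single ring, single point).
bf_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  total <- 0
  for (k in seq_len(n)) {
    a <- ring[k, ]; b <- ring[k %% n + 1, ]
    a1 <- atan2(a[2] - py, a[1] - px)
    a2 <- atan2(b[2] - py, b[1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi  # ~2*pi inside, ~0 outside
}

bf_label_point <- function(px, py, geometry) {
  for (cmp in c("epithelium", "debris", "stroma")) {
    for (p in geometry$polygons[[cmp]] %||% list()) {
      inside <- bf_point_in_ring(px, py, p$outer)
      for (h in p$holes) if (bf_point_in_ring(px, py, h)) inside <- FALSE
      if (inside) return(cmp)
    }
  }
  "background"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) proximity count: immune cells with any DCIS cell within r.
bf_proximity_count <- function(ix, iy, dx, dy, r) {
  cnt <- 0L
  for (i in seq_along(ix)) {
    if (length(dx) &&
        any(sqrt((dx - ix[i])^2 + (dy - iy[i])^2) <= r)) cnt <- cnt + 1L
  }
  cnt
}

# Definitional BH: q_i = min_{j: p_j >= p_i} min(1, m * p_j / rank_j).
bf_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- which(p >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[cand] / r[cand]))
  }
  q
}

# Spearman rho by explicit sums over average ranks.
bf_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Naive complete linkage on a raw matrix (rows = items): returns the sorted
# merge heights.
bf_complete_linkage_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Exact two-sided two-group permutation p for the MW effect, with U computed
# by pair counting (not ranks).
bf_pair_u <- function(a, b) {
  u <- 0
  for (x in a) u <- u + sum(x > b) + 0.5 * sum(x == b)
  u
}

bf_exact_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a); n <- length(pooled)
  obs <- abs(bf_pair_u(a, b) - n_a * length(b) / 2)
  splits <- utils::combn(n, n_a)
  effs <- apply(splits, 2, function(idx)
    abs(bf_pair_u(pooled[idx], pooled[-idx]) -
        n_a * (n - n_a) / 2))
  mean(effs >= obs - 1e-12)
}

# Small fast slide spec shared by tests.
tiny_slide_spec <- function(seed = 1L, ...) {
  args <- list(slide_width_um = 3000, slide_height_um = 3000, n_ducts = 3,
               duct_radius_um = c(120, 180), stroma_band_um = 120,
               epithelial_cell_density = 600, n_tls = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(slide_spec, args)
}

# Cell table with explicit marker flags for hand-built fixtures.
make_cells <- function(x, y, assay = "mif", compartment = "stroma", ...) {
  n <- length(x)
  flags <- list(...)
  df <- data.frame(cell_id = sprintf("c%04d", seq_len(n)), x_um = x,
                   y_um = y, assay = assay, stringsAsFactors = FALSE)
  for (m in c("panCK", "CD3", "CD8", "CD20", "FOXP3", "CD68", "Ki67"))
    df[[m]] <- if (!is.null(flags[[m]])) as.integer(flags[[m]])
               else NA_integer_
  df$compartment <- compartment
  df
}

# Minimal rectangular geometry: one epithelium square and one stroma square.
rect_ring <- function(x0, y0, x1, y1)
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

square_geometry <- function(epi = c(0, 0, 1000, 1000),
                            str = c(1000, 0, 2000, 1000)) {
  compartment_geometry(list(
    epithelium = list(new_polygon(rect_ring(epi[1], epi[2], epi[3], epi[4]))),
    stroma = list(new_polygon(rect_ring(str[1], str[2], str[3], str[4])))),
    3000, 3000)
}
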