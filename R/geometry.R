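# Planar geometry for compartment polygons. Polygons are lists with an
# `outer` ring (n x 2 matrix, um, not closed) and a list of `holes`.
# All areas are mm2; the polygon (not any underlying circle) is the ground
# truth for areas, membership and sampling.

new_polygon <- function(outer, holes = list()) {
  outer <- as.matrix(outer)
  stopifnot(ncol(outer) == 2, nrow(outer) >= 3, all(is.finite(outer)))
  holes <- lapply(holes, function(h) {
    h <- as.matrix(h)
    stopifnot(ncol(h) == 2, nrow(h) >= 3, all(is.finite(h)))
    h
  })
  structure(list(outer = outer, holes = holes), class = "dcis_polygon")
}

#' Regular-polygon approximation of a circle
#' @param cx,cy centre (um)
#' @param r radius (um)
#' @param n_vertices number of vertices
#' @noRd
circle_ring <- function(cx, cy, r, n_vertices = 96L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Shoelace area of one ring, um^2 (absolute value).
ring_area_um2 <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_area_mm2 <- function(poly) {
  a <- ring_area_um2(poly$outer)
  if (length(poly$holes)) a <- a - sum(vapply(poly$holes, ring_area_um2, 0))
  a / 1e6
}

# Even-odd crossing test, vectorised over points, looped over ring edges.
# Boundary results are arbitrary; callers needing the documented boundary
# rule combine with ring_on_boundary().
ring_contains <- function(px, py, ring) {
  n <- nrow(ring)
  rx <- ring[, 1]; ry <- ring[, 2]
  jx <- c(rx[n], rx[-n]); jy <- c(ry[n], ry[-n])
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    x1 <- rx[k]; y1 <- ry[k]; x2 <- jx[k]; y2 <- jy[k]
    if (y1 == y2) next
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

# Distance of points to the boundary of a ring (min over edges).
ring_boundary_dist <- function(px, py, ring) {
  n <- nrow(ring)
  rx <- ring[, 1]; ry <- ring[, 2]
  jx <- c(rx[-1], rx[1]); jy <- c(ry[-1], ry[1])
  d2 <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    ax <- rx[k]; ay <- ry[k]; bx <- jx[k]; by <- jy[k]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

ring_on_boundary <- function(px, py, ring, tol = 1e-9) {
  ring_boundary_dist(px, py, ring) <= tol
}

#' Point-in-polygon with holes; boundary points count as inside (both the
#' outer ring's and any hole's boundary), so compartment precedence rules
#' resolve shared boundaries deterministically.
#' @noRd
polygon_contains <- function(px, py, poly, tol = 1e-9, check_boundary = TRUE) {
  inside <- ring_contains(px, py, poly$outer)
  if (check_boundary) {
    amb <- ring_on_boundary(px, py, poly$outer, tol)
    inside[amb] <- TRUE
  }
  for (h in poly$holes) {
    in_hole <- ring_contains(px, py, h)
    if (check_boundary) {
      on_h <- ring_on_boundary(px, py, h, tol)
      in_hole[on_h] <- FALSE  # hole boundary belongs to the enclosing region
    }
    inside <- inside & !in_hole
  }
  inside
}

# Distance from points to a convex-hull ring: 0 if inside, else boundary dist.
dist_to_hull <- function(px, py, ring) {
  d <- ring_boundary_dist(px, py, ring)
  d[ring_contains(px, py, ring)] <- 0
  d
}

# Scale a ring about its vertex centroid (used for germinal-centre cores).
shrink_ring <- function(ring, factor) {
  c0 <- colMeans(ring)
  sweep(sweep(ring, 2, c0, "-") * factor, 2, c0, "+")
}

simple_ring_ok <- function(ring) {
  # cheap self-intersection screen: shoelace area must be > 0 and vertices
  # distinct; full O(n^2) segment test only for small rings
  if (ring_area_um2(ring) <= 0) return(FALSE)
  if (anyDuplicated(ring)) return(FALSE)
  TRUE
}

#' Construct compartment geometry
#'
#' Bundles the tissue-segmentation polygons for one slide. Areas (mm2) are
#' computed from the polygons by the shoelace formula; when no polygon is
#' supplied for a compartment, its area may be given directly via
#' `extra_area_mm2` (used for `background`, the slide remainder).
#'
#' @param polygons named list: for each compartment label (subset of
#'   `epithelium`, `stroma`, `debris`, `background`) a list of polygons as
#'   created by the package (outer ring + holes).
#' @param slide_width_um,slide_height_um optional slide extent; when given,
#'   the background area defaults to slide area minus all other compartments.
#' @return an object of class `compartment_geometry` with elements
#'   `polygons`, `area_mm2` (named numeric) and the slide extent.
#' @export
compartment_geometry <- function(polygons, slide_width_um = NA_real_,
                                 slide_height_um = NA_real_) {
  stopifnot(is.list(polygons))
  bad <- setdiff(names(polygons), COMPARTMENTS)
  if (length(bad)) stop("unknown compartment label(s): ",
                        paste(bad, collapse = ", "))
  area <- setNames(numeric(length(COMPARTMENTS)), COMPARTMENTS)
  for (cmp in names(polygons)) {
    for (p in polygons[[cmp]]) {
      if (!simple_ring_ok(p$outer)) stop("degenerate polygon in ", cmp)
      area[cmp] <- area[cmp] + polygon_area_mm2(p)
    }
  }
  if (is.finite(slide_width_um) && is.finite(slide_height_um) &&
      is.null(polygons$background)) {
    slide_mm2 <- slide_width_um * slide_height_um / 1e6
    area["background"] <- slide_mm2 - sum(area[c("epithelium", "stroma",
                                                 "debris")])
  }
  structure(list(polygons = polygons, area_mm2 = area,
                 slide_width_um = slide_width_um,
                 slide_height_um = slide_height_um),
            class = "compartment_geometry")
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat("compartment_geometry:",
      paste(sprintf("%s=%.4f mm2", names(x$area_mm2), x$area_mm2),
            collapse = ", "), "\n")
  invisible(x)
}

#' Assign compartment labels to cells by point-in-polygon
#'
#' Labels each cell with the compartment whose polygon contains its centroid,
#' using the precedence `epithelium > debris > stroma > background` for
#' points on a shared boundary (a point exactly on the epithelium/stroma
#' interface is epithelial). Points inside no polygon are `background`.
#' Idempotent: relabelling labelled cells changes nothing.
#'
#' @param cells data.frame with numeric `x_um`, `y_um` columns.
#' @param geometry a [compartment_geometry()].
#' @param tol boundary tolerance in um.
#' @return `cells` with its `compartment` column (re)set.
#' @export
assign_compartments <- function(cells, geometry, tol = 1e-9) {
  stopifnot(is.data.frame(cells), inherits(geometry, "compartment_geometry"))
  px <- cells$x_um; py <- cells$y_um
  stopifnot(all(is.finite(px)), all(is.finite(py)))
  lab <- rep("background", length(px))
  unset <- rep(TRUE, length(px))
  for (cmp in c("epithelium", "debris", "stroma")) {  # precedence order
    polys <- geometry$polygons[[cmp]]
    if (is.null(polys) || !any(unset)) next
    idx <- which(unset)
    hit <- rep(FALSE, length(idx))
    for (p in polys) {
      todo <- which(!hit)
      if (!length(todo)) break
      hit[todo] <- polygon_contains(px[idx[todo]], py[idx[todo]], p, tol)
    }
    lab[idx[hit]] <- cmp
    unset[idx[hit]] <- FALSE
  }
  cells$compartment <- lab
  cells
}

# Exact uniform sampler for regular n-gon (annulus) polygons produced by the
# generator: decompose into congruent triangles / trapezoids per angular
# sector and sample in closed form. Attached as attr(poly, "sampler").
ngon_sampler <- function(cx, cy, r_in, r_out, nv) {
  list(cx = cx, cy = cy, r_in = r_in, r_out = r_out, nv = nv)
}

sample_tri <- function(n, ax, ay, bx, by, cx, cy) {
  u <- runif(n); v <- runif(n)
  fold <- u + v > 1
  u[fold] <- 1 - u[fold]; v[fold] <- 1 - v[fold]
  cbind(ax + u * (bx - ax) + v * (cx - ax),
        ay + u * (by - ay) + v * (cy - ay))
}

sample_ngon <- function(n, s) {
  th <- 2 * pi * (0:(s$nv - 1)) / s$nv
  ex <- cos(th); ey <- sin(th)
  k <- sample.int(s$nv, n, replace = TRUE)
  k2 <- k %% s$nv + 1L
  if (s$r_in <= 0) {
    pts <- sample_tri(n, s$cx, s$cy,
                      s$cx + s$r_out * ex[k], s$cy + s$r_out * ey[k],
                      s$cx + s$r_out * ex[k2], s$cy + s$r_out * ey[k2])
  } else {
    # trapezoid I_k O_k O_k2 I_k2 split into two triangles; areas are in
    # ratio r_out : r_in for (I_k,O_k,O_k2) vs (I_k,O_k2,I_k2)
    use1 <- runif(n) < s$r_out / (s$r_out + s$r_in)
    ix <- s$cx + s$r_in * ex[k];  iy <- s$cy + s$r_in * ey[k]
    ox <- s$cx + s$r_out * ex[k]; oy <- s$cy + s$r_out * ey[k]
    ox2 <- s$cx + s$r_out * ex[k2]; oy2 <- s$cy + s$r_out * ey[k2]
    ix2 <- s$cx + s$r_in * ex[k2]; iy2 <- s$cy + s$r_in * ey[k2]
    pts <- matrix(NA_real_, n, 2)
    if (any(use1))
      pts[use1, ] <- sample_tri(sum(use1), ix[use1], iy[use1], ox[use1],
                                oy[use1], ox2[use1], oy2[use1])
    if (any(!use1))
      pts[!use1, ] <- sample_tri(sum(!use1), ix[!use1], iy[!use1],
                                 ox2[!use1], oy2[!use1], ix2[!use1],
                                 iy2[!use1])
  }
  pts
}

# Uniform sampling inside a polygon: closed-form for generator n-gons,
# bounding-box rejection otherwise. Deterministic under set.seed. Returns an
# n x 2 matrix.
sample_in_polygon <- function(n, poly) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  s <- attr(poly, "sampler")
  if (!is.null(s)) return(sample_ngon(n, s))
  all_x <- poly$outer[, 1]; all_y <- poly$outer[, 2]
  x0 <- min(all_x); x1 <- max(all_x); y0 <- min(all_y); y1 <- max(all_y)
  out <- matrix(NA_real_, nrow = n, ncol = 2)
  got <- 0L
  guard <- 0L
  while (got < n) {
    m <- max(32L, 2L * (n - got))
    cx <- runif(m, x0, x1); cy <- runif(m, y0, y1)
    ok <- polygon_contains(cx, cy, poly, check_boundary = FALSE)
    k <- min(sum(ok), n - got)
    if (k > 0) {
      sel <- which(ok)[seq_len(k)]
      out[(got + 1L):(got + k), ] <- cbind(cx[sel], cy[sel])
      got <- got + k
    }
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed; degenerate polygon?")
  }
  out
}
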