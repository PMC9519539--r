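# Tertiary lymphoid structure (TLS) detection from cell point patterns.
# zone-TLS: a CD20+ B-cell follicle (dense cluster) with an adjacent CD3+
# T-cell zone. GC-TLS: a lymphoid aggregate whose core is Ki67+ (germinal
# centre), assessed on the CD8/Ki67 double-stain. The study's TLS were
# counted by pathologists; these detectors are algorithmic stand-ins whose
# defaults call seeded synthetic follicles and nothing on homogeneous
# Poisson background.

# Connected components at distance eps (single-link chaining), grid-bucketed.
# Returns an integer component id per point.
eps_components <- function(x, y, eps) {
  n <- length(x)
  if (n == 0) return(integer(0))
  cell <- eps
  gx <- floor(x / cell); gy <- floor(y / cell)
  buckets <- split(seq_len(n), paste(gx, gy))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  eps2 <- eps * eps
  for (i in seq_len(n)) {
    for (dx in 0:1) for (dy in -1:1) {
      if (dx == 0 && dy < 0) next  # scan half-neighbourhood, links symmetric
      b <- buckets[[paste(gx[i] + dx, gy[i] + dy)]]
      if (is.null(b)) next
      for (j in b) {
        if (j <= i && dx == 0 && dy == 0) next
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= eps2) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, sort(unique(roots)))
}

hull_ring <- function(x, y) {
  h <- chull(x, y)
  cbind(x[h], y[h])
}

tls_record <- function(id, type, x, y, n_b, n_t, n_core, hull) {
  data.frame(tls_id = id, tls_type = type,
             centroid_x_um = mean(x), centroid_y_um = mean(y),
             n_b_cells = n_b, n_t_zone_cells = n_t, n_core_cells = n_core,
             hull_area_mm2 = if (nrow(hull) >= 3) ring_area_um2(hull) / 1e6
                             else 0,
             stringsAsFactors = FALSE)
}

empty_tls_table <- function() {
  data.frame(tls_id = character(0), tls_type = character(0),
             centroid_x_um = numeric(0), centroid_y_um = numeric(0),
             n_b_cells = integer(0), n_t_zone_cells = integer(0),
             n_core_cells = integer(0), hull_area_mm2 = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect zone-TLS (B-cell follicle + adjacent T-cell zone)
#'
#' Clusters B cells (mIF `b_cell` label) into candidate follicles as
#' connected components at distance `eps_um`; follicles with at least
#' `min_follicle` members are kept if at least `min_t_zone` CD3+ T cells lie
#' within `t_zone_um` of the follicle convex hull (distance 0 inside the
#' hull). Deterministic given the parameters; invariant under rigid motions
#' of the coordinates.
#'
#' @param slide a [slide_cell_map()].
#' @param eps_um B-cell neighbourhood radius (um).
#' @param min_follicle minimum B cells per follicle.
#' @param t_zone_um T-zone search distance from the follicle hull (um).
#' @param min_t_zone minimum T cells in the zone.
#' @return data.frame of TLS records (0 rows when none found).
#' @export
detect_zone_tls <- function(slide, eps_um = 30, min_follicle = 20,
                            t_zone_um = 50, min_t_zone = 30) {
  stopifnot(inherits(slide, "slide_cell_map"))
  cells <- slide$cells
  mif <- cells[cells$assay != "cd8ki67" &
               cells$compartment %in% ANALYSIS_COMPARTMENTS, ]
  lab <- gate_cells(mif)
  b <- mif[lab == "b_cell", ]
  t_ <- mif[lab %in% c("t_helper", "t_cytotoxic", "t_reg"), ]
  empty <- empty_tls_table()
  if (nrow(b) == 0) return(empty)
  comp <- eps_components(b$x_um, b$y_um, eps_um)
  recs <- list()
  for (cid in sort(unique(comp))) {
    idx <- comp == cid
    if (sum(idx) < min_follicle) next
    bx <- b$x_um[idx]; by <- b$y_um[idx]
    hull <- hull_ring(bx, by)
    n_t <- if (nrow(t_) == 0) 0L else
      sum(dist_to_hull(t_$x_um, t_$y_um, hull) <= t_zone_um)
    if (n_t < min_t_zone) next
    recs[[length(recs) + 1L]] <- tls_record(
      sprintf("%s_zone_%02d", slide$patient_id, length(recs) + 1L),
      "zone", bx, by, sum(idx), n_t, NA_integer_, hull)
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Detect GC-TLS (aggregates with a Ki67+ germinal centre)
#'
#' Clusters lymphoid-candidate cells — on the CD8/Ki67 double-stain, cells
#' positive for CD8 or Ki67; on mIF (with Ki67 enabled), CD3+ or CD20+
#' cells — into aggregates at `eps_um` with at least `min_aggregate`
#' members. An aggregate is a GC-TLS when the fraction of Ki67+ cells inside
#' its core (the hull shrunk about its centroid to `gc_core_frac` of the
#' hull area) is at least `gc_threshold`. With `gc_threshold = 0` every
#' candidate aggregate is returned.
#'
#' @param slide a [slide_cell_map()].
#' @param eps_um,min_aggregate clustering parameters.
#' @param gc_core_frac core area as a fraction of hull area (default 0.5).
#' @param gc_threshold minimum Ki67+ fraction in the core (default 0.3).
#' @param assay `"cd8ki67"` (default) or `"mif"`.
#' @return data.frame of TLS records (`tls_type = "gc"`).
#' @export
detect_gc_tls <- function(slide, eps_um = 30, min_aggregate = 20,
                          gc_core_frac = 0.5, gc_threshold = 0.3,
                          assay = c("cd8ki67", "mif")) {
  stopifnot(inherits(slide, "slide_cell_map"))
  assay <- match.arg(assay)
  cells <- slide$cells
  cells <- cells[cells$compartment %in% ANALYSIS_COMPARTMENTS, ]
  pos <- function(m) !is.na(cells[[m]]) & cells[[m]] == 1
  cand <- if (assay == "cd8ki67")
    cells[cells$assay == "cd8ki67" & (pos("CD8") | pos("Ki67")), ]
  else
    cells[cells$assay != "cd8ki67" & (pos("CD3") | pos("CD20")), ]
  empty <- empty_tls_table()
  if (nrow(cand) == 0) return(empty)
  ki <- !is.na(cand$Ki67) & cand$Ki67 == 1
  comp <- eps_components(cand$x_um, cand$y_um, eps_um)
  recs <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) < min_aggregate) next
    cx <- cand$x_um[idx]; cy <- cand$y_um[idx]
    hull <- hull_ring(cx, cy)
    if (nrow(hull) < 3) next
    core <- shrink_ring(hull, sqrt(gc_core_frac))
    in_core <- polygon_contains(cx, cy, new_polygon(core))
    n_core <- sum(in_core)
    frac <- if (n_core == 0) 0 else sum(ki[idx][in_core]) / n_core
    if (frac < gc_threshold) next
    recs[[length(recs) + 1L]] <- tls_record(
      sprintf("%s_gc_%02d", slide$patient_id, length(recs) + 1L),
      "gc", cx, cy, NA_integer_, NA_integer_, n_core, hull)
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' TLS density (structures per mm2)
#'
#' @param records TLS record table from the detectors (possibly 0 rows).
#' @param analysed_area_mm2 analysed tissue area (> 0), typically stroma +
#'   epithelium.
#' @param patient_id identifier for the output row(s).
#' @return data.frame `(patient_id, tls_type, n_tls, analysed_area_mm2,
#'   density_per_mm2)`, one row per TLS type (zone, gc).
#' @export
tls_density <- function(records, analysed_area_mm2, patient_id = NA) {
  if (!is.numeric(analysed_area_mm2) || analysed_area_mm2 <= 0)
    stop("analysed_area_mm2 must be positive")
  types <- c("zone", "gc")
  n <- vapply(types, function(tt)
    if (nrow(records) == 0) 0L else sum(records$tls_type == tt), 0L)
  data.frame(patient_id = patient_id, tls_type = types, n_tls = unname(n),
             analysed_area_mm2 = analysed_area_mm2,
             density_per_mm2 = unname(n) / analysed_area_mm2,
             stringsAsFactors = FALSE)
}
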