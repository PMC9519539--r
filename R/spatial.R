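# Spatial summaries: compartment densities (cells/mm2), composition ratios,
# and the DCIS proximity index (immune cells within a radius of any DCIS
# cell, per DCIS cell).

#' Compartment-resolved immune-cell densities
#'
#' One row per subset x compartment (stroma, epithelium):
#' `density = count / area_mm2`. Subsets whose defining markers are not
#' assessable on this slide are emitted with NA count/density (missing, not
#' zero) — e.g. a failed FOXP3 stain blanks `t_reg`, `t_helper`,
#' `t_cytotoxic` and `lymphocytes`.
#'
#' @param slide a [slide_cell_map()].
#' @param subsets subset ids (default all 8).
#' @param formula_mode lymphocyte formula mode, see [count_subsets()].
#' @param unassessable_markers character vector of markers that failed on
#'   this slide (e.g. `"FOXP3"`).
#' @return data.frame `(patient_id, subset_id, compartment, count,
#'   area_mm2, density_cells_per_mm2)`.
#' @export
compute_densities <- function(slide, subsets = SUBSETS,
                              formula_mode = c("strict", "inclusive"),
                              unassessable_markers = character(0)) {
  formula_mode <- match.arg(formula_mode)
  counts <- count_subsets(slide, subsets, formula_mode)
  area <- slide$geometry$area_mm2[counts$compartment]
  if (any(area == 0 & counts$count > 0))
    stop("zero compartment area with non-zero cell count: inconsistent slide")
  drop <- area == 0 & counts$count == 0
  if (any(drop)) {
    warning(sprintf("omitting %d rows with zero area and zero count",
                    sum(drop)))
    counts <- counts[!drop, , drop = FALSE]
    area <- area[!drop]
  }
  out <- data.frame(patient_id = slide$patient_id,
                    subset_id = counts$subset_id,
                    compartment = counts$compartment,
                    count = counts$count, area_mm2 = unname(area),
                    stringsAsFactors = FALSE)
  if (length(unassessable_markers)) {
    blank <- vapply(out$subset_id, function(s)
      any(SUBSET_MARKER_DEPS[[s]] %in% unassessable_markers), TRUE)
    out$count[blank] <- NA_integer_
  }
  out$density_cells_per_mm2 <- out$count / out$area_mm2
  rownames(out) <- NULL
  out
}

#' Immune composition ratios (all unordered subset pairs)
#'
#' All C(8,2) = 28 unordered pairs of the immune subsets, per patient and
#' compartment, in the canonical subset order (numerator precedes
#' denominator). `0/0` is NA (undefined); `x/0` with `x > 0` is `Inf`,
#' flagged for downstream exclusion; pairs involving a missing (NA) density
#' are NA.
#'
#' @param density_table output of [compute_densities()] (one patient).
#' @param subsets subsets to pair (default all 8).
#' @return data.frame `(patient_id, compartment, numerator_subset,
#'   denominator_subset, ratio)`.
#' @export
compute_ratios <- function(density_table, subsets = SUBSETS) {
  stopifnot(all(subsets %in% SUBSETS))
  bad <- setdiff(unique(density_table$subset_id), SUBSETS)
  if (length(bad)) stop("unknown subset id: ", paste(bad, collapse = ", "))
  pairs <- combn(subsets, 2)
  out <- list()
  for (pid in unique(density_table$patient_id)) {
    for (cmp in unique(density_table$compartment)) {
      d <- density_table[density_table$patient_id == pid &
                         density_table$compartment == cmp, ]
      dens <- setNames(d$density_cells_per_mm2, d$subset_id)
      num <- dens[pairs[1, ]]; den <- dens[pairs[2, ]]
      ratio <- ifelse(is.na(num) | is.na(den), NA_real_,
               ifelse(den == 0 & num == 0, NA_real_, num / den))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, compartment = cmp,
        numerator_subset = pairs[1, ], denominator_subset = pairs[2, ],
        ratio = unname(ratio), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# For each query point, is any reference point within r (closed boundary by
# default)? Grid-bucketed; equals brute force exactly.
any_within_radius <- function(qx, qy, rx, ry, r, closed = TRUE) {
  nq <- length(qx)
  if (nq == 0) return(logical(0))
  if (length(rx) == 0) return(rep(FALSE, nq))
  cell <- r
  gx <- floor(rx / cell); gy <- floor(ry / cell)
  key <- paste(gx, gy)
  buckets <- split(seq_along(rx), key)
  qgx <- floor(qx / cell); qgy <- floor(qy / cell)
  r2 <- r * r
  hit <- rep(FALSE, nq)
  cmp <- if (closed) `<=` else `<`
  qkey <- paste(qgx, qgy)
  for (grp in split(seq_len(nq), qkey)) {
    cgx <- qgx[grp[1]]; cgy <- qgy[grp[1]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cgx + dx, cgy + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    if (!length(cand)) next
    for (qi in grp) {
      d2 <- (rx[cand] - qx[qi])^2 + (ry[cand] - qy[qi])^2
      hit[qi] <- any(cmp(d2, r2))
    }
  }
  hit
}

#' DCIS proximity index
#'
#' For each requested immune subset: the number of immune cells whose
#' nearest DCIS (panCK+) cell centroid lies within `radius_um` (Euclidean;
#' closed boundary, so a cell at exactly `radius_um` counts), divided by the
#' total number of DCIS cells on the slide. Each immune cell counts at most
#' once however many DCIS cells surround it. Only mIF-assay cells in the
#' analysis compartments participate.
#'
#' @param slide a [slide_cell_map()].
#' @param subsets immune subset ids (default: all mIF subsets, i.e.
#'   everything but `activated_cytotoxic`).
#' @param radius_um neighbourhood radius in um (default 25, the approximate
#'   diameter of a DCIS cell).
#' @param boundary `"closed"` (`<=`, default) or `"open"` (`<`).
#' @param formula_mode lymphocyte formula mode.
#' @return data.frame `(patient_id, subset_id, n_immune_within_radius,
#'   n_dcis_cells, proximity_index, radius_um)`.
#' @export
proximity_index <- function(slide, subsets = setdiff(SUBSETS,
                                                     "activated_cytotoxic"),
                            radius_um = 25,
                            boundary = c("closed", "open"),
                            formula_mode = c("strict", "inclusive")) {
  boundary <- match.arg(boundary)
  formula_mode <- match.arg(formula_mode)
  stopifnot(inherits(slide, "slide_cell_map"), radius_um > 0)
  cells <- slide$cells
  mif <- cells[cells$assay != "cd8ki67" &
               cells$compartment %in% ANALYSIS_COMPARTMENTS, ]
  lab <- gate_cells(mif)
  dcis <- mif[lab == "dcis_cell", ]
  if (nrow(dcis) == 0)
    stop("proximity index undefined: no DCIS cells on slide ",
         slide$patient_id)
  out <- data.frame(patient_id = slide$patient_id, subset_id = subsets,
                    n_immune_within_radius = NA_integer_,
                    n_dcis_cells = nrow(dcis), proximity_index = NA_real_,
                    radius_um = radius_um, stringsAsFactors = FALSE)
  for (i in seq_along(subsets)) {
    memb <- subset_membership(mif, subsets[i], formula_mode)
    imm <- mif[memb, ]
    nw <- sum(any_within_radius(imm$x_um, imm$y_um, dcis$x_um, dcis$y_um,
                                radius_um, closed = boundary == "closed"))
    out$n_immune_within_radius[i] <- nw
    out$proximity_index[i] <- nw / nrow(dcis)
  }
  out
}
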