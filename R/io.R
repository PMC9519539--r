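# Cell-table and geometry I/O. Cell tables are plain CSV (UTF-8, comma,
# header, '.' decimal): cell_id, x_um, y_um, assay, one 0/1 column per
# marker, compartment. Geometry travels as GeoJSON polygons with a
# "compartment" property; coordinates stay in micrometres.

#' Construct a slide cell map
#'
#' The central per-patient container: all cells of one slide (both assays)
#' plus the compartment geometry. Validates the schema: unique cell ids,
#' finite coordinates, marker flags in {0, 1, NA}, compartment labels from
#' the fixed vocabulary, Ki67 only flagged on the `cd8ki67` assay unless
#' `allow_mif_ki67`.
#'
#' @param patient_id identifier.
#' @param cells data.frame with columns `cell_id`, `x_um`, `y_um`, `assay`,
#'   the marker columns `panCK`, `CD3`, `CD8`, `CD20`, `FOXP3`, `CD68`,
#'   `Ki67`, and `compartment`. Extra columns are preserved.
#' @param geometry a [compartment_geometry()].
#' @param allow_mif_ki67 permit Ki67 flags on mIF rows.
#' @return object of class `slide_cell_map`.
#' @export
slide_cell_map <- function(patient_id, cells, geometry,
                           allow_mif_ki67 = FALSE) {
  stopifnot(is.data.frame(cells), inherits(geometry, "compartment_geometry"))
  needed <- c("cell_id", "x_um", "y_um", "assay", ALL_MARKERS, "compartment")
  miss <- setdiff(needed, names(cells))
  if (length(miss)) stop("cell table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cells$cell_id)) {
    dup <- cells$cell_id[duplicated(cells$cell_id)][1]
    stop("duplicate cell_id: ", dup)
  }
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)))
    stop("non-finite coordinates in cell table")
  bad_cmp <- setdiff(unique(cells$compartment), COMPARTMENTS)
  if (length(bad_cmp)) stop("unknown compartment label(s): ",
                            paste(bad_cmp, collapse = ", "))
  for (m in ALL_MARKERS) {
    v <- cells[[m]]
    bad <- which(!(is.na(v) | v %in% c(0L, 1L)))
    if (length(bad))
      stop(sprintf("non-binary value for marker %s in row %d", m, bad[1]))
    cells[[m]] <- as.integer(v)
  }
  if (!allow_mif_ki67) {
    bad <- which(cells$assay != "cd8ki67" & !is.na(cells$Ki67) &
                 cells$Ki67 == 1L)
    if (length(bad))
      stop(sprintf("Ki67 flag on non-cd8ki67 assay row %d", bad[1]))
  }
  structure(list(patient_id = patient_id, cells = cells,
                 geometry = geometry,
                 assay_set = sort(unique(cells$assay))),
            class = "slide_cell_map")
}

#' @export
print.slide_cell_map <- function(x, ...) {
  cat(sprintf("slide_cell_map %s: %d cells (%s); areas: %s\n",
              x$patient_id, nrow(x$cells),
              paste(x$assay_set, collapse = "+"),
              paste(sprintf("%s %.3f mm2",
                            names(x$geometry$area_mm2), x$geometry$area_mm2),
                    collapse = ", ")))
  invisible(x)
}

#' Patient clinicopathological metadata record
#'
#' @param patient_id identifier.
#' @param outcome `"case"` (subsequent ipsilateral invasive breast cancer)
#'   or `"control"`.
#' @param grade DCIS nuclear grade 1/2/3 or NA.
#' @param er,pr,her2 `"negative"`/`"positive"`/NA.
#' @param cox2 `"low"`/`"high"`/NA.
#' @param ki67_category `"<14%"`/`">=14%"`/NA.
#' @param fibrosis,comedonecrosis `"absent"`/`"present"`/NA.
#' @param foxp3_assessable was FOXP3 staining assessable on the mIF slide?
#' @return one-row data.frame with a derived `subtype` (HR/HER2) column.
#' @export
patient_metadata <- function(patient_id, outcome, grade = NA, er = NA,
                             pr = NA, her2 = NA, cox2 = NA,
                             ki67_category = NA, fibrosis = NA,
                             comedonecrosis = NA, foxp3_assessable = TRUE) {
  stopifnot(outcome %in% c("case", "control"))
  chk <- function(x, lv) { stopifnot(is.na(x) || x %in% lv); x }
  er <- chk(er, c("negative", "positive"))
  pr <- chk(pr, c("negative", "positive"))
  her2 <- chk(her2, c("negative", "positive"))
  cox2 <- chk(cox2, c("low", "high"))
  ki67_category <- chk(ki67_category, c("<14%", ">=14%"))
  fibrosis <- chk(fibrosis, c("absent", "present"))
  comedonecrosis <- chk(comedonecrosis, c("absent", "present"))
  stopifnot(is.na(grade) || grade %in% 1:3)
  subtype <- NA_character_
  if (!is.na(er) && !is.na(pr) && !is.na(her2)) {
    hr <- if (er == "positive" || pr == "positive") "HR+" else "HR-"
    subtype <- paste0(hr, if (her2 == "positive") "HER2+" else "HER2-")
  }
  data.frame(patient_id = patient_id, outcome = outcome,
             grade = as.integer(grade), er = er, pr = pr, her2 = her2,
             cox2 = cox2, ki67_category = ki67_category,
             fibrosis = fibrosis, comedonecrosis = comedonecrosis,
             subtype = subtype, foxp3_assessable = foxp3_assessable,
             stringsAsFactors = FALSE)
}

ring_to_coords <- function(ring) {
  ring <- rbind(ring, ring[1, , drop = FALSE])  # GeoJSON rings are closed
  unname(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
}

coords_to_ring <- function(cc) {
  m <- do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  m[-nrow(m), , drop = FALSE]
}

#' Write compartment geometry as GeoJSON
#'
#' One Feature per polygon, with property `compartment`; coordinates in um.
#' @param geometry a [compartment_geometry()].
#' @param path output file.
#' @export
write_geometry <- function(geometry, path) {
  feats <- list()
  for (cmp in names(geometry$polygons)) {
    for (p in geometry$polygons[[cmp]]) {
      coords <- c(list(ring_to_coords(p$outer)),
                  lapply(p$holes, ring_to_coords))
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(compartment = cmp),
        geometry = list(type = "Polygon", coordinates = coords))
    }
  }
  gj <- list(type = "FeatureCollection",
             properties = list(slide_width_um = geometry$slide_width_um,
                               slide_height_um = geometry$slide_height_um),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read compartment geometry from GeoJSON
#' @param path GeoJSON file written by [write_geometry()] (or equivalent).
#' @return a [compartment_geometry()].
#' @export
read_geometry <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- list()
  for (f in gj$features) {
    cmp <- f$properties$compartment
    if (is.null(cmp)) stop("geometry feature without 'compartment' property")
    coords <- f$geometry$coordinates
    p <- new_polygon(coords_to_ring(coords[[1]]),
                     lapply(coords[-1], coords_to_ring))
    polys[[cmp]] <- c(polys[[cmp]], list(p))
  }
  w <- gj$properties$slide_width_um %||% NA_real_
  h <- gj$properties$slide_height_um %||% NA_real_
  compartment_geometry(polys, as.numeric(w), as.numeric(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a slide's cell table (CSV) and geometry (GeoJSON)
#'
#' @param slide a [slide_cell_map()].
#' @param cell_csv_path,geometry_path output paths (geometry optional).
#' @export
write_slide <- function(slide, cell_csv_path, geometry_path = NULL) {
  stopifnot(inherits(slide, "slide_cell_map"))
  write.csv(slide$cells, cell_csv_path, row.names = FALSE, quote = FALSE,
            na = "")
  if (!is.null(geometry_path)) write_geometry(slide$geometry, geometry_path)
  invisible(cell_csv_path)
}

#' Read a slide from a cell-table CSV and GeoJSON geometry
#'
#' Validates the schema (duplicate ids, non-binary marker values, unknown
#' compartments are errors naming the offending row/column). A `compartment`
#' column in the file wins over geometry assignment unless
#' `reassign = TRUE`; absent the column, labels come from point-in-polygon
#' against the geometry.
#'
#' @param cell_csv_path CSV path.
#' @param geometry_path GeoJSON path.
#' @param patient_id id to stamp; defaults to the file name stem.
#' @param reassign force re-assignment of compartments from geometry.
#' @return a [slide_cell_map()].
#' @export
read_slide <- function(cell_csv_path, geometry_path, patient_id = NULL,
                       reassign = FALSE) {
  if (!file.exists(cell_csv_path)) stop("no such file: ", cell_csv_path)
  cells <- read.csv(cell_csv_path, stringsAsFactors = FALSE)
  geometry <- read_geometry(geometry_path)
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(cell_csv_path))
  needed <- c("cell_id", "x_um", "y_um", "assay")
  miss <- setdiff(needed, names(cells))
  if (length(miss)) stop("cell table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (m in ALL_MARKERS) if (is.null(cells[[m]])) cells[[m]] <- NA_integer_
  if (is.null(cells$compartment) || reassign)
    cells <- assign_compartments(cells, geometry)
  slide_cell_map(patient_id, cells, geometry)
}

#' Write cohort metadata to CSV
#' @param metadata data.frame of row-bound [patient_metadata()] records.
#' @param path CSV path.
#' @export
write_metadata <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read cohort metadata from CSV
#' @param path CSV path.
#' @return data.frame with one row per patient.
#' @export
read_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  stopifnot(all(c("patient_id", "outcome") %in% names(md)))
  stopifnot(all(md$outcome %in% c("case", "control")))
  md
}
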