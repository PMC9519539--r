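# Synthetic-slide generator. Compartments are polygonal (regular-polygon
# circles); immune cells are homogeneous Poisson per compartment with known
# intensities, so every downstream estimate has an exact ground truth.

place_ducts <- function(spec, max_attempts = 10000L) {
  n <- spec$n_ducts
  if (n == 0) return(data.frame(cx = numeric(0), cy = numeric(0),
                                r = numeric(0), r_outer = numeric(0)))
  rmin <- spec$duct_radius_um[1]; rmax <- spec$duct_radius_um[2]
  band <- spec$stroma_band_um
  cx <- cy <- r <- numeric(n)
  for (i in seq_len(n)) {
    ri <- runif(1, rmin, rmax)
    ro <- ri + band
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- runif(1, ro, spec$slide_width_um - ro)
      y <- runif(1, ro, spec$slide_height_um - ro)
      if (i == 1L || all(sqrt((x - cx[seq_len(i - 1)])^2 +
                              (y - cy[seq_len(i - 1)])^2) >=
                         ro + r[seq_len(i - 1)] + band)) {
        cx[i] <- x; cy[i] <- y; r[i] <- ri
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "failed to place duct %d of %d without overlap after %d attempts",
        i, n, max_attempts))
  }
  data.frame(cx = cx, cy = cy, r = r, r_outer = r + band)
}

duct_geometry <- function(spec, ducts) {
  nv <- spec$n_vertices
  epi <- list(); str_ <- list(); deb <- list()
  for (i in seq_len(nrow(ducts))) {
    d <- ducts[i, ]
    lumen_r <- spec$lumen_radius_frac * d$r
    epi_holes <- if (lumen_r > 0)
      list(circle_ring(d$cx, d$cy, lumen_r, nv)) else list()
    epi[[i]] <- new_polygon(circle_ring(d$cx, d$cy, d$r, nv), epi_holes)
    attr(epi[[i]], "sampler") <- ngon_sampler(d$cx, d$cy, lumen_r, d$r, nv)
    str_[[i]] <- new_polygon(circle_ring(d$cx, d$cy, d$r_outer, nv),
                             list(circle_ring(d$cx, d$cy, d$r, nv)))
    attr(str_[[i]], "sampler") <- ngon_sampler(d$cx, d$cy, d$r, d$r_outer, nv)
    if (lumen_r > 0) {
      deb[[length(deb) + 1L]] <- new_polygon(
        circle_ring(d$cx, d$cy, lumen_r, nv))
      attr(deb[[length(deb)]], "sampler") <-
        ngon_sampler(d$cx, d$cy, 0, lumen_r, nv)
    }
  }
  polys <- list(epithelium = epi, stroma = str_)
  if (length(deb)) polys$debris <- deb
  compartment_geometry(polys, spec$slide_width_um, spec$slide_height_um)
}

# One marker-flag row per generative phenotype (mIF panel).
phenotype_flags <- function(phen, treg_cd8_fraction) {
  n <- length(phen)
  f <- matrix(0L, n, length(MIF_MARKERS),
              dimnames = list(NULL, MIF_MARKERS))
  f[phen == "b_cell", "CD20"] <- 1L
  t_lineage <- phen %in% c("t_helper", "t_cytotoxic", "t_reg")
  f[t_lineage, "CD3"] <- 1L
  f[phen == "t_cytotoxic", "CD8"] <- 1L
  f[phen == "t_reg", "FOXP3"] <- 1L
  if (treg_cd8_fraction > 0) {
    tr <- which(phen == "t_reg")
    f[tr, "CD8"] <- rbinom(length(tr), 1L, treg_cd8_fraction)
  }
  f[phen == "macrophage", "CD68"] <- 1L
  f
}

# Poisson-place immune cells of every generative phenotype in a polygon list.
poisson_immune <- function(polys, intensity, decay = NULL, ducts = NULL) {
  xs <- ys <- numeric(0); ph <- character(0)
  for (p in polys) {
    a_mm2 <- polygon_area_mm2(p)
    for (k in GEN_PHENOTYPES) {
      lam <- intensity[[k]]
      if (lam <= 0) next
      nk <- rpois(1, lam * a_mm2)
      if (nk == 0) next
      pts <- sample_in_polygon(nk, p)
      xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
      ph <- c(ph, rep(k, nk))
    }
  }
  if (!is.null(decay) && length(xs) && !is.null(ducts) && nrow(ducts)) {
    d <- rep(Inf, length(xs))
    for (i in seq_len(nrow(ducts)))
      d <- pmin(d, abs(sqrt((xs - ducts$cx[i])^2 + (ys - ducts$cy[i])^2) -
                       ducts$r[i]))
    keep <- runif(length(xs)) <= exp(-d / decay)
    xs <- xs[keep]; ys <- ys[keep]; ph <- ph[keep]
  }
  list(x = xs, y = ys, phenotype = ph)
}

# Classify points against the slide geometry (same precedence as
# assign_compartments), used for seeded structures that may straddle
# compartment boundaries.
classify_points <- function(x, y, geometry) {
  if (!length(x)) return(character(0))
  df <- assign_compartments(data.frame(x_um = x, y_um = y), geometry)
  df$compartment
}

place_follicle_centres <- function(n, ducts, spec) {
  if (n == 0 || nrow(ducts) == 0) return(NULL)
  idx <- sample.int(nrow(ducts), n, replace = TRUE)
  blob_r <- spec$tls_b_radius_um
  cx <- cy <- numeric(n)
  for (j in seq_len(n)) {
    d <- ducts[idx[j], ]
    lo <- d$r + blob_r
    hi <- max(lo, d$r_outer - blob_r)
    rad <- runif(1, lo, hi)
    th <- runif(1, 0, 2 * pi)
    cx[j] <- d$cx + rad * cos(th); cy[j] <- d$cy + rad * sin(th)
  }
  cbind(cx, cy)
}

#' Generate one synthetic DCIS slide
#'
#' Produces a [slide_cell_map()] with exact polygonal compartment geometry,
#' panCK+ epithelial cells filling the ducts, immune cells placed as
#' homogeneous Poisson point processes per compartment at the specified
#' intensities, optional seeded TLS follicles (B-cell blob + T-cell ring) and
#' germinal-centre aggregates, and a second cell table for the CD8/Ki67
#' double-stain assay. Identical `spec` (including `seed`) gives a
#' byte-identical slide. Ground truth (duct table, follicle centres, applied
#' intensities) is attached as attribute `"truth"`.
#'
#' @param spec a [slide_spec()].
#' @return a `slide_cell_map`.
#' @export
generate_slide <- function(spec) {
  validate_slide_spec(spec)
  set.seed(spec$seed)
  ducts <- place_ducts(spec)
  geometry <- duct_geometry(spec, ducts)

  xs <- ys <- numeric(0); ph <- cmp <- character(0)
  # epithelial (DCIS) cells
  for (p in geometry$polygons$epithelium) {
    ne <- rpois(1, spec$epithelial_cell_density * polygon_area_mm2(p))
    if (ne == 0) next
    pts <- sample_in_polygon(ne, p)
    xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
    ph <- c(ph, rep("dcis_cell", ne)); cmp <- c(cmp, rep("epithelium", ne))
  }
  # immune cells per compartment
  imm_s <- poisson_immune(geometry$polygons$stroma, spec$stromal_intensity,
                          spec$boundary_decay_um, ducts)
  imm_e <- poisson_immune(geometry$polygons$epithelium,
                          spec$intraepithelial_intensity)
  xs <- c(xs, imm_s$x, imm_e$x); ys <- c(ys, imm_s$y, imm_e$y)
  ph <- c(ph, imm_s$phenotype, imm_e$phenotype)
  cmp <- c(cmp, rep("stroma", length(imm_s$x)),
           rep("epithelium", length(imm_e$x)))

  # seeded zone-TLS follicles (B blob + T ring), stroma-anchored
  follicles <- place_follicle_centres(spec$n_tls, ducts, spec)
  if (!is.null(follicles)) {
    for (j in seq_len(nrow(follicles))) {
      fb <- spec$tls_b_cells; ft <- spec$tls_t_ring_cells
      if (fb > 0) {
        rr <- spec$tls_b_radius_um * sqrt(runif(fb))
        th <- runif(fb, 0, 2 * pi)
        bx <- follicles[j, 1] + rr * cos(th)
        by <- follicles[j, 2] + rr * sin(th)
        xs <- c(xs, bx); ys <- c(ys, by)
        ph <- c(ph, rep("b_cell", fb))
        cmp <- c(cmp, classify_points(bx, by, geometry))
      }
      if (ft > 0) {
        r0 <- spec$tls_b_radius_um
        rr <- sqrt(runif(ft, r0^2, (r0 + spec$tls_t_ring_um)^2))
        th <- runif(ft, 0, 2 * pi)
        tx <- follicles[j, 1] + rr * cos(th)
        ty <- follicles[j, 2] + rr * sin(th)
        xs <- c(xs, tx); ys <- c(ys, ty)
        ph <- c(ph, sample(c("t_helper", "t_cytotoxic"), ft,
                           replace = TRUE, prob = c(0.6, 0.4)))
        cmp <- c(cmp, classify_points(tx, ty, geometry))
      }
    }
  }

  flags <- phenotype_flags(ph, spec$treg_cd8_fraction)
  flags[ph == "dcis_cell", "panCK"] <- 1L
  if (spec$flip_noise > 0) {
    flip <- matrix(rbinom(length(flags), 1L, spec$flip_noise) == 1L,
                   nrow = nrow(flags))
    flags[flip] <- 1L - flags[flip]
  }
  n_mif <- length(xs)
  mif <- data.frame(x_um = xs, y_um = ys, assay = rep("mif", n_mif),
                    stringsAsFactors = FALSE)
  mif <- cbind(mif, as.data.frame(flags))
  mif$Ki67 <- NA_integer_
  mif$compartment <- cmp
  mif$true_phenotype <- ph

  # CD8/Ki67 double-stain assay: an independent slide realisation that only
  # sees CD8 and Ki67.
  dxs <- dys <- numeric(0); dk <- integer(0); dcd8 <- integer(0)
  dcmp <- character(0)
  cd8_int <- setNames(rep(0, length(GEN_PHENOTYPES)), GEN_PHENOTYPES)
  cd8_int["t_cytotoxic"] <- spec$stromal_intensity[["t_cytotoxic"]]
  d_s <- poisson_immune(geometry$polygons$stroma, cd8_int)
  cd8_int["t_cytotoxic"] <- spec$intraepithelial_intensity[["t_cytotoxic"]]
  d_e <- poisson_immune(geometry$polygons$epithelium, cd8_int)
  dxs <- c(d_s$x, d_e$x); dys <- c(d_s$y, d_e$y)
  dcmp <- c(rep("stroma", length(d_s$x)), rep("epithelium", length(d_e$x)))
  dcd8 <- rep(1L, length(dxs))
  dk <- rbinom(length(dxs), 1L, spec$ki67_pos_fraction)
  # seeded germinal-centre aggregates: Ki67+ core, CD8+ mantle
  gc_centres <- place_follicle_centres(spec$n_gc_tls, ducts, spec)
  if (!is.null(gc_centres)) {
    for (j in seq_len(nrow(gc_centres))) {
      ng <- spec$gc_cells
      if (ng == 0) next
      rr <- spec$tls_b_radius_um * sqrt(runif(ng))
      th <- runif(ng, 0, 2 * pi)
      gx <- gc_centres[j, 1] + rr * cos(th)
      gy <- gc_centres[j, 2] + rr * sin(th)
      core <- rr <= spec$tls_b_radius_um * sqrt(0.5)
      ki <- integer(ng)
      ki[core] <- rbinom(sum(core), 1L, spec$gc_core_ki67_frac)
      cd8 <- as.integer(!core | ki == 0L)
      dxs <- c(dxs, gx); dys <- c(dys, gy)
      dk <- c(dk, ki); dcd8 <- c(dcd8, cd8)
      dcmp <- c(dcmp, classify_points(gx, gy, geometry))
    }
  }
  dbl <- data.frame(x_um = dxs, y_um = dys,
                    assay = rep("cd8ki67", length(dxs)),
                    stringsAsFactors = FALSE)
  for (m in MIF_MARKERS) dbl[[m]] <- rep(NA_integer_, nrow(dbl))
  dbl$CD8 <- dcd8
  dbl$Ki67 <- dk
  dbl$compartment <- dcmp
  dbl$true_phenotype <- ifelse(dcd8 == 1L & dk == 1L, "activated_cytotoxic",
                               ifelse(dcd8 == 1L, "t_cytotoxic", "other"))

  cells <- rbind(mif, dbl)
  cells$cell_id <- sprintf("c%06d", seq_len(nrow(cells)))
  cells <- cells[, c("cell_id", "x_um", "y_um", "assay", ALL_MARKERS,
                     "compartment", "true_phenotype")]
  rownames(cells) <- NULL
  slide <- slide_cell_map(spec$patient_id, cells, geometry)
  attr(slide, "truth") <- list(
    ducts = ducts, follicles = follicles, gc_centres = gc_centres,
    stromal_intensity = spec$stromal_intensity,
    intraepithelial_intensity = spec$intraepithelial_intensity,
    ki67_pos_fraction = spec$ki67_pos_fraction,
    spec = spec)
  slide
}

draw_metadata <- function(pid, outcome, model) {
  grade <- sample(as.integer(names(model$grade)), 1, prob = model$grade)
  er <- if (runif(1) < model$er_pos) "positive" else "negative"
  pr <- if (runif(1) < model$pr_pos) "positive" else "negative"
  her2 <- if (runif(1) < model$her2_pos) "positive" else "negative"
  cox2 <- if (runif(1) < model$cox2_high) "high" else "low"
  fib <- if (runif(1) < model$fibrosis_present) "present" else "absent"
  com <- if (runif(1) < model$comedonecrosis_present) "present" else "absent"
  ki <- if (runif(1) < model$ki67_high) ">=14%" else "<14%"
  patient_metadata(pid, outcome, grade = grade, er = er, pr = pr,
                   her2 = her2, cox2 = cox2, ki67_category = ki,
                   fibrosis = fib, comedonecrosis = com)
}

#' Generate a synthetic case-control cohort
#'
#' Draws per-patient metadata and lognormal intensity multipliers under the
#' root seed, then generates each slide under its derived child seed (see
#' [cohort_spec()]). Cases get stromal intensities multiplied by
#' `case_effect`; with `case_effect` all 1 the case and control generative
#' laws are identical.
#'
#' @param spec a [cohort_spec()].
#' @return list with one element per patient: `list(slide, metadata)`;
#'   cases first.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  set.seed(spec$seed)
  mult <- exp(rnorm(n, 0, spec$patient_sd_log))
  outcomes <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  meta <- vector("list", n)
  for (i in seq_len(n))
    meta[[i]] <- draw_metadata(sprintf("P%03d", i), outcomes[i],
                               spec$metadata_model)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ss <- spec$slide_spec
    ss$patient_id <- sprintf("P%03d", i)
    ss$seed <- child_seed(spec$seed, i)
    ss$stromal_intensity <- ss$stromal_intensity * mult[i]
    ss$intraepithelial_intensity <- ss$intraepithelial_intensity * mult[i]
    if (outcomes[i] == "case")
      ss$stromal_intensity <- ss$stromal_intensity * spec$case_effect
    out[[i]] <- list(slide = generate_slide(ss), metadata = meta[[i]])
  }
  out
}

#' Simulate rater score matrices
#'
#' Draws an `n_subjects` x `n_raters` matrix from the two-way random-effects
#' model `y_ij = mu + s_i + r_j + e_ij` of a [rater_sim_spec()].
#'
#' @param spec a [rater_sim_spec()].
#' @return numeric matrix (subjects x raters) with dimnames.
#' @export
simulate_rater_scores <- function(spec) {
  stopifnot(inherits(spec, "rater_sim_spec"))
  set.seed(spec$seed)
  s <- rnorm(spec$n_subjects, 0, spec$subject_sd)
  r <- rnorm(spec$n_raters, 0, spec$rater_sd)
  e <- matrix(rnorm(spec$n_subjects * spec$n_raters, 0, spec$error_sd),
              spec$n_subjects, spec$n_raters)
  m <- spec$mu + outer(s, r, "+") + e
  dimnames(m) <- list(sprintf("subj%03d", seq_len(spec$n_subjects)),
                      sprintf("rater%d", seq_len(spec$n_raters)))
  m
}
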