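# Specification objects for the synthetic-slide generator. Defaults encode
# the stated world the pipeline targets: whole-slide DCIS mIF with a median
# stromal lymphocyte density of ~370 cells/mm2 split over subsets, sparse
# intraepithelial infiltration, and a 77-case / 64-control cohort design.

DEFAULT_STROMAL_INTENSITY <- c(
  b_cell = 120, t_helper = 140, t_cytotoxic = 80, t_reg = 30, macrophage = 80
)
DEFAULT_INTRAEPITHELIAL_INTENSITY <- c(
  b_cell = 2, t_helper = 8, t_cytotoxic = 6, t_reg = 2, macrophage = 5
)

#' Slide specification for the synthetic generator
#'
#' Describes one synthetic DCIS slide: rectangular slide of
#' `slide_width_um` x `slide_height_um`, `n_ducts` circular ducts (DCIS
#' epithelium) with radii drawn uniformly from `duct_radius_um`, each
#' surrounded by a periductal-stroma annulus of width `stroma_band_um`.
#' Immune cells are homogeneous Poisson within each compartment with
#' per-subset intensities (cells/mm2); epithelial (panCK+) cells fill the
#' ducts at `epithelial_cell_density`. Optional seeded tertiary lymphoid
#' structures: `n_tls` B-cell follicles (blobs of `tls_b_cells` B cells of
#' radius `tls_b_radius_um`) each wrapped in a T-cell ring of
#' `tls_t_ring_cells` cells, placed in the stroma; `n_gc_tls` germinal-centre
#' aggregates on the CD8/Ki67 double-stain assay. A second cell table for the
#' CD8/Ki67 assay is generated with CD8+ T cells at the `t_cytotoxic`
#' intensity, a fraction `ki67_pos_fraction` of them Ki67+.
#'
#' @param slide_width_um,slide_height_um slide extent (um).
#' @param n_ducts number of ducts.
#' @param duct_radius_um length-2 numeric `(min, max)` duct radius (um).
#' @param stroma_band_um periductal stroma annulus width (um).
#' @param lumen_radius_frac fraction of the duct radius occupied by an
#'   intraluminal-debris core (0 disables debris).
#' @param epithelial_cell_density DCIS cells/mm2 inside ducts.
#' @param stromal_intensity,intraepithelial_intensity named cells/mm2 over
#'   the generative phenotypes `b_cell`, `t_helper`, `t_cytotoxic`, `t_reg`,
#'   `macrophage`.
#' @param boundary_decay_um optional length scale; when set, stromal immune
#'   cells are thinned with probability `exp(-d/boundary_decay_um)` where `d`
#'   is distance to the nearest duct boundary, concentrating immune cells
#'   near ducts (proximity-index structure). `NULL` = homogeneous.
#' @param n_tls,tls_b_cells,tls_b_radius_um,tls_t_ring_cells,tls_t_ring_um
#'   seeded zone-TLS follicle parameters.
#' @param n_gc_tls,gc_cells,gc_core_ki67_frac seeded germinal-centre
#'   aggregates on the double-stain assay: `gc_cells` cells per aggregate,
#'   the inner core Ki67+ with probability `gc_core_ki67_frac`.
#' @param ki67_pos_fraction fraction of double-stain CD8+ T cells Ki67+.
#' @param treg_cd8_fraction fraction of regulatory T cells also CD8+.
#' @param flip_noise probability that each marker flag is flipped
#'   independently (0 = clean flags).
#' @param n_vertices vertices of the regular polygon approximating each
#'   circle; the polygon is the exact geometric truth.
#' @param patient_id identifier stamped on generated cells.
#' @param seed integer seed fixing the slide byte-for-byte.
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(slide_width_um = 6000, slide_height_um = 6000,
                       n_ducts = 6, duct_radius_um = c(150, 300),
                       stroma_band_um = 150, lumen_radius_frac = 0,
                       epithelial_cell_density = 4000,
                       stromal_intensity = DEFAULT_STROMAL_INTENSITY,
                       intraepithelial_intensity =
                         DEFAULT_INTRAEPITHELIAL_INTENSITY,
                       boundary_decay_um = NULL,
                       n_tls = 1, tls_b_cells = 60, tls_b_radius_um = 40,
                       tls_t_ring_cells = 80, tls_t_ring_um = 50,
                       n_gc_tls = 0, gc_cells = 60, gc_core_ki67_frac = 0.7,
                       ki67_pos_fraction = 0.1, treg_cd8_fraction = 0,
                       flip_noise = 0, n_vertices = 96L,
                       patient_id = "S1", seed = 1L) {
  stromal_intensity <- fill_intensity(stromal_intensity)
  intraepithelial_intensity <- fill_intensity(intraepithelial_intensity)
  spec <- structure(mget(names(formals())), class = "slide_spec")
  validate_slide_spec(spec)
  spec
}

fill_intensity <- function(x) {
  out <- setNames(numeric(length(GEN_PHENOTYPES)), GEN_PHENOTYPES)
  if (length(x)) {
    bad <- setdiff(names(x), GEN_PHENOTYPES)
    if (length(bad)) stop("unknown generative phenotype(s): ",
                          paste(bad, collapse = ", "))
    out[names(x)] <- as.numeric(x)
  }
  out
}

validate_slide_spec <- function(spec) {
  with(spec, {
    stopifnot(slide_width_um > 0, slide_height_um > 0, n_ducts >= 0,
              length(duct_radius_um) == 2, duct_radius_um[1] > 0,
              duct_radius_um[1] <= duct_radius_um[2], stroma_band_um > 0,
              lumen_radius_frac >= 0, lumen_radius_frac < 1,
              epithelial_cell_density >= 0,
              all(stromal_intensity >= 0),
              all(intraepithelial_intensity >= 0),
              is.null(boundary_decay_um) || boundary_decay_um > 0,
              n_tls >= 0, tls_b_cells >= 0, tls_b_radius_um > 0,
              tls_t_ring_cells >= 0, tls_t_ring_um > 0, n_gc_tls >= 0,
              gc_cells >= 0, gc_core_ki67_frac >= 0, gc_core_ki67_frac <= 1,
              ki67_pos_fraction >= 0, ki67_pos_fraction <= 1,
              treg_cd8_fraction >= 0, treg_cd8_fraction <= 1,
              flip_noise >= 0, flip_noise <= 1, n_vertices >= 12,
              length(seed) == 1, is.finite(seed))
  })
  invisible(spec)
}

# Default label frequencies follow the pooled case+control margins of the
# study design this generator emulates (grade 1/2/3 ~ 12/64/24%, ER+ ~80%,
# PR+ ~62%, HER2+ ~28%, COX-2 high ~91%, fibrosis ~30%, comedonecrosis ~79%,
# Ki67>=14% ~13%).
DEFAULT_METADATA_MODEL <- list(
  grade = c(`1` = 0.12, `2` = 0.64, `3` = 0.24),
  er_pos = 0.80, pr_pos = 0.62, her2_pos = 0.28, cox2_high = 0.91,
  fibrosis_present = 0.30, comedonecrosis_present = 0.79,
  ki67_high = 0.13
)

#' Cohort specification
#'
#' A case-control cohort of synthetic slides. Each patient gets a lognormal
#' multiplier `exp(N(0, patient_sd_log^2))` applied to every immune intensity
#' in both compartments (patient-level heterogeneity); case slides
#' additionally have their *stromal* intensities multiplied per-subset by
#' `case_effect` (all 1 = null, the default). Per-slide seeds are derived
#' from `seed` by the documented splitting scheme
#' `(seed + 1000003 * patient_index) mod 2147483647`, so slides are
#' reproducible regardless of generation order.
#'
#' @param n_cases,n_controls group sizes (>= 1).
#' @param slide_spec template [slide_spec()] shared by all patients.
#' @param patient_sd_log SD of the per-patient log-intensity multiplier.
#'   Default 1.0, consistent with a ~4x interquartile ratio in stromal
#'   lymphocyte density across patients.
#' @param case_effect named multiplicative factors (> 0) on stromal
#'   intensities for cases, keyed by generative phenotype; unnamed scalar
#'   applies to all.
#' @param metadata_model list of label frequencies for clinicopathological
#'   metadata; see `DEFAULT_METADATA_MODEL` defaults in the source.
#' @param seed root seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 77, n_controls = 64,
                        slide_spec = dcisime::slide_spec(),
                        patient_sd_log = 1.0, case_effect = 1,
                        metadata_model = DEFAULT_METADATA_MODEL,
                        seed = 1L) {
  if (length(case_effect) == 1 && is.null(names(case_effect))) {
    case_effect <- setNames(rep(as.numeric(case_effect),
                                length(GEN_PHENOTYPES)), GEN_PHENOTYPES)
  } else {
    full <- setNames(rep(1, length(GEN_PHENOTYPES)), GEN_PHENOTYPES)
    bad <- setdiff(names(case_effect), GEN_PHENOTYPES)
    if (length(bad)) stop("unknown case_effect phenotype(s): ",
                          paste(bad, collapse = ", "))
    full[names(case_effect)] <- as.numeric(case_effect)
    case_effect <- full
  }
  stopifnot(n_cases >= 1, n_controls >= 1, patient_sd_log >= 0,
            all(case_effect > 0), inherits(slide_spec, "slide_spec"))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 slide_spec = slide_spec, patient_sd_log = patient_sd_log,
                 case_effect = case_effect, metadata_model = metadata_model,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Documented seed-splitting scheme: child seed for patient i.
child_seed <- function(root, i) {
  as.integer((as.numeric(root) + 1000003 * i) %% 2147483647)
}

#' Rater-simulation specification
#'
#' Two-way random-effects score model `y_ij = mu + s_i + r_j + e_ij` with
#' subject, rater and error SDs. `true_icc` is the population mean-rating
#' absolute-agreement ICC, ICC(A,k) with `k = n_raters`:
#' `sigma_s^2 / (sigma_s^2 + (sigma_r^2 + sigma_e^2)/k)`.
#' Either give the three SDs (then `true_icc` is derived, or checked against
#' a supplied value to 1e-9), or give `true_icc` alone and the SDs are solved
#' with `subject_sd = 1` and a 20/80 rater/error split of the noise
#' variance (`true_icc = 0` forces `subject_sd = 0`).
#'
#' @param n_subjects,n_raters matrix dimensions (>= 2 for downstream ICC).
#' @param true_icc population ICC(A,k) in `[0, 1)`.
#' @param subject_sd,rater_sd,error_sd variance components (SDs).
#' @param mu grand mean.
#' @param seed integer seed.
#' @return object of class `rater_sim_spec`.
#' @export
rater_sim_spec <- function(n_subjects, n_raters, true_icc = NULL,
                           subject_sd = NULL, rater_sd = NULL,
                           error_sd = NULL, mu = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, n_raters >= 1)
  k <- n_raters
  have_sds <- !is.null(subject_sd) && !is.null(rater_sd) && !is.null(error_sd)
  if (have_sds) {
    stopifnot(subject_sd >= 0, rater_sd >= 0, error_sd >= 0)
    noise <- rater_sd^2 + error_sd^2
    denom <- subject_sd^2 + noise / k
    implied <- if (denom == 0) 0 else subject_sd^2 / denom
    if (!is.null(true_icc) && abs(implied - true_icc) > 1e-9)
      stop(sprintf(
        "variance components imply ICC(A,k) = %.12f, not the requested %.12f",
        implied, true_icc))
    true_icc <- implied
  } else {
    if (is.null(true_icc)) stop("give true_icc or all three SDs")
    stopifnot(true_icc >= 0, true_icc < 1)
    if (true_icc == 0) {
      subject_sd <- 0; noise <- 1
    } else {
      subject_sd <- 1
      noise <- k * (1 - true_icc) / true_icc  # sigma_r^2 + sigma_e^2
    }
    rater_sd <- sqrt(0.2 * noise); error_sd <- sqrt(0.8 * noise)
  }
  structure(list(n_subjects = n_subjects, n_raters = n_raters,
                 true_icc = true_icc, subject_sd = subject_sd,
                 rater_sd = rater_sd, error_sd = error_sd, mu = mu,
                 seed = as.integer(seed)),
            class = "rater_sim_spec")
}
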