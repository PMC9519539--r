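# Densities, ratios and the DCIS proximity index.

test_that("density arithmetic: count / area, zero counts give zero density", {
  set.seed(4)
  cells <- make_cells(runif(10, 1000, 2000), runif(10, 0, 1000),
                      compartment = "stroma", CD20 = rep(1, 10))
  geom <- square_geometry(str = c(1000, 0, 3000, 1000))  # 2.0 mm2 stroma
  sl <- slide_cell_map("t", cells, geom)
  d <- compute_densities(sl)
  pick <- function(s, cmp)
    d[d$subset_id == s & d$compartment == cmp, ]
  expect_equal(pick("b_cell", "stroma")$density_cells_per_mm2, 5.0)
  expect_equal(pick("b_cell", "stroma")$area_mm2, 2.0, tolerance = 1e-12)
  expect_equal(pick("t_all", "stroma")$density_cells_per_mm2, 0)
  expect_equal(pick("b_cell", "epithelium")$density_cells_per_mm2, 0)
})

test_that("density recovery: lambda = 370/mm2 over a large stroma area", {
  # one big slide, >= 50 mm2 of stroma, estimate within 3 Poisson SEs
  sp <- slide_spec(slide_width_um = 20000, slide_height_um = 20000,
                   n_ducts = 24, duct_radius_um = c(500, 500),
                   stroma_band_um = 500, epithelial_cell_density = 200,
                   stromal_intensity = c(b_cell = 90, t_helper = 140,
                                         t_cytotoxic = 80, t_reg = 30,
                                         macrophage = 60),
                   intraepithelial_intensity =
                     setNames(rep(0, 5), GEN_PHENOTYPES),
                   n_tls = 0, seed = 31)
  sl <- generate_slide(sp)
  a <- sl$geometry$area_mm2[["stroma"]]
  expect_gt(a, 50)
  d <- compute_densities(sl)
  est <- d$density_cells_per_mm2[d$subset_id == "lymphocytes" &
                                 d$compartment == "stroma"]
  lam <- 90 + 140 + 80 + 30  # 340 lymphocyte intensity
  se <- sqrt(lam / a)
  expect_lt(abs(est - lam), 3 * se)
})

test_that("unassessable markers blank dependent subsets (missing, not zero)", {
  sl <- generate_slide(tiny_slide_spec(seed = 37))
  d <- compute_densities(sl, unassessable_markers = "FOXP3")
  na_subsets <- unique(d$subset_id[is.na(d$density_cells_per_mm2)])
  expect_setequal(na_subsets,
                  c("lymphocytes", "t_helper", "t_cytotoxic", "t_reg"))
  expect_false(anyNA(d$density_cells_per_mm2[d$subset_id == "t_all"]))
})

test_that("ratios: 28 unordered pairs, scale invariance, brute force", {
  sl <- generate_slide(tiny_slide_spec(seed = 41))
  d <- compute_densities(sl)
  r <- compute_ratios(d)
  expect_identical(nrow(r), 2L * 28L)  # per compartment
  expect_identical(nrow(unique(r[, c("numerator_subset",
                                     "denominator_subset")])), 28L)
  # brute-force double loop
  for (cmp in c("stroma", "epithelium")) {
    dens <- d[d$compartment == cmp, ]
    v <- setNames(dens$density_cells_per_mm2, dens$subset_id)
    rr <- r[r$compartment == cmp, ]
    for (i in seq_len(nrow(rr))) {
      num <- v[[rr$numerator_subset[i]]]; den <- v[[rr$denominator_subset[i]]]
      want <- if (num == 0 && den == 0) NA_real_ else num / den
      expect_equal(rr$ratio[i], want, tolerance = 1e-12)
    }
  }
  # scale invariance
  d2 <- d; d2$density_cells_per_mm2 <- d2$density_cells_per_mm2 * 17.3
  r2 <- compute_ratios(d2)
  expect_equal(r2$ratio, r$ratio, tolerance = 1e-12)
  # identical densities -> ratio 1, 0/0 -> NA, x/0 -> Inf
  dd <- data.frame(patient_id = "p", subset_id = c("b_cell", "t_all",
                                                   "t_reg", "macrophage"),
                   compartment = "stroma",
                   count = c(5L, 5L, 0L, 3L), area_mm2 = 1,
                   density_cells_per_mm2 = c(5, 5, 0, 3))
  rr <- compute_ratios(dd, subsets = c("b_cell", "t_all", "t_reg",
                                       "macrophage"))
  g <- function(n, dn) rr$ratio[rr$numerator_subset == n &
                                rr$denominator_subset == dn]
  expect_equal(g("b_cell", "t_all"), 1.0)
  expect_equal(g("b_cell", "t_reg"), Inf)   # x/0 flagged as Inf
  expect_equal(g("t_reg", "macrophage"), 0)
  expect_error(compute_ratios(data.frame(patient_id = "p",
                                         subset_id = "nk_cell",
                                         compartment = "stroma", count = 1L,
                                         area_mm2 = 1,
                                         density_cells_per_mm2 = 1)),
               "unknown subset")
})

test_that("proximity index: hand-checked boundary case", {
  # 1 DCIS cell at the origin corner; immune cells at 10, 25, 26 um
  cells <- make_cells(c(100, 110, 125, 126), rep(100, 4),
                      compartment = "epithelium",
                      panCK = c(1, 0, 0, 0), CD20 = c(0, 1, 1, 1))
  sl <- slide_cell_map("t", cells, square_geometry())
  r <- proximity_index(sl, subsets = "b_cell")
  expect_equal(r$proximity_index, 2 / 1)  # 25 um is inclusive
  expect_identical(r$n_dcis_cells, 1L)
  ro <- proximity_index(sl, subsets = "b_cell", boundary = "open")
  expect_equal(ro$proximity_index, 1.0)
  # no immune cell in range
  far <- make_cells(c(100, 900), c(100, 900), compartment = "epithelium",
                    panCK = c(1, 0), CD20 = c(0, 1))
  sl2 <- slide_cell_map("t", far, square_geometry())
  expect_equal(proximity_index(sl2, subsets = "b_cell")$proximity_index, 0)
  # zero DCIS cells is an error
  none <- make_cells(100, 100, compartment = "stroma", CD20 = 1)
  expect_error(proximity_index(slide_cell_map("t", none, square_geometry()),
                               subsets = "b_cell"), "no DCIS cells")
})

test_that("proximity: indexed search equals O(n^2) brute force; monotone in r", {
  sl <- generate_slide(tiny_slide_spec(seed = 43, epithelial_cell_density =
                                         300))
  mif <- sl$cells[sl$cells$assay == "mif" &
                  sl$cells$compartment %in% c("stroma", "epithelium"), ]
  lab <- gate_cells(mif)
  dcis <- mif[lab == "dcis_cell", ]
  prev <- -1
  for (r_um in c(10, 25, 60)) {
    res <- proximity_index(sl, subsets = "lymphocytes", radius_um = r_um)
    memb <- subset_membership(mif, "lymphocytes", "strict")
    want <- bf_proximity_count(mif$x_um[memb], mif$y_um[memb],
                               dcis$x_um, dcis$y_um, r_um)
    expect_identical(res$n_immune_within_radius, want)
    expect_gte(res$n_immune_within_radius, prev)
    prev <- res$n_immune_within_radius
  }
})

test_that("lymphocyte density equals the sum of its four components", {
  sl <- generate_slide(tiny_slide_spec(seed = 47))
  d <- compute_densities(sl)
  for (cmp in c("stroma", "epithelium")) {
    v <- setNames(d$density_cells_per_mm2[d$compartment == cmp],
                  d$subset_id[d$compartment == cmp])
    expect_equal(v[["lymphocytes"]],
                 v[["b_cell"]] + v[["t_helper"]] + v[["t_cytotoxic"]] +
                   v[["t_reg"]],
                 tolerance = 1e-12)
  }
})

test_that("estimated densities track true intensities across a cohort", {
  lams <- c(50, 120, 370, 800, 1500)
  est <- vapply(seq_along(lams), function(i) {
    sp <- tiny_slide_spec(seed = 50 + i,
                          stromal_intensity = c(b_cell = lams[i]))
    d <- compute_densities(generate_slide(sp))
    d$density_cells_per_mm2[d$subset_id == "b_cell" &
                            d$compartment == "stroma"]
  }, 0)
  expect_gt(suppressWarnings(cor(lams, est, method = "spearman")), 0.95)
})
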