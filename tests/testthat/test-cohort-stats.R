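# Permutation tests, BH, ICC, Spearman, TIL bins, clustering, contrasts.

test_that("permutation MW test: degenerate and hand-enumerated cases", {
  expect_equal(perm_rank_test(c(3, 3, 3), c(3, 3, 3))$p_nominal, 1)
  # full separation of 3 vs 3: 2 of the 20 label splits are as extreme
  r <- perm_rank_test(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$p_nominal, 0.1)
  expect_identical(r$mode, "exact")
  # symmetric in group order
  r2 <- perm_rank_test(c(4, 5, 6), c(1, 2, 3), mode = "exact")
  expect_equal(r2$p_nominal, 0.1)
  expect_error(perm_rank_test(numeric(0), 1:3), "at least one finite")
})

test_that("exact permutation p matches the pair-counting oracle", {
  set.seed(11)
  for (i in 1:100) {
    n_a <- sample(3:5, 1); n_b <- sample(3:5, 1)
    a <- round(rnorm(n_a), 2); b <- round(rnorm(n_b, sample(0:1, 1)), 2)
    mine <- perm_rank_test(a, b, mode = "exact")$p_nominal
    expect_equal(mine, bf_exact_perm_p(a, b), tolerance = 1e-9)
  }
})

test_that("Monte-Carlo p agrees with exact p within 3 MC standard errors", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5, 1)
    pe <- perm_rank_test(a, b, mode = "exact")$p_nominal
    pm <- perm_rank_test(a, b, mode = "montecarlo", n_perm = 20000,
                         seed = i)$p_nominal
    se <- sqrt(pe * (1 - pe) / 20000)
    expect_lt(abs(pm - pe), 3 * se + 2 / 20000)
  }
})

test_that("permutation Kruskal-Wallis: degenerate, two-group, power", {
  expect_warning(r <- perm_kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2))),
                 "distinct")
  expect_equal(r$p_nominal, 1)
  set.seed(17)
  a <- rnorm(8); b <- rnorm(8, 1.2)
  p_kw <- perm_kruskal_wallis(list(a, b), n_perm = 20000, seed = 5)$p_nominal
  p_mw <- perm_rank_test(a, b, n_perm = 20000, seed = 6,
                         mode = "montecarlo")$p_nominal
  expect_lt(abs(p_kw - p_mw), 3 * sqrt(p_mw * (1 - p_mw) / 20000) + 0.005)
  # rejection becomes easier as the shift grows
  ps <- vapply(c(0, 1, 2.5), function(sh) {
    set.seed(23)
    g <- list(rnorm(10), rnorm(10, sh), rnorm(10, 2 * sh))
    perm_kruskal_wallis(g, n_perm = 2000, seed = 7)$p_nominal
  }, 0)
  expect_true(all(diff(ps) <= 0))
  expect_error(perm_kruskal_wallis(list(1:3)), "2 non-empty groups")
})

test_that("BH q-values: worked example, oracle, FDR control", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # NAs pass through
  expect_equal(bh_fdr(c(0.1, NA, 0.2)), c(0.2, NA, 0.2))
  set.seed(29)
  for (i in 1:100) {
    p <- runif(sample(2:30, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bf_bh(p), tolerance = 1e-9)
  }
  # empirical FDR under independent nulls with planted effects
  set.seed(31)
  fdr <- replicate(300, {
    m0 <- 40; m1 <- 10
    p <- c(runif(m0), rbeta(m1, 0.05, 1))
    null_flag <- rep(c(TRUE, FALSE), c(m0, m1))
    rej <- bh_fdr(p) < 0.05
    if (any(rej)) sum(rej & null_flag) / sum(rej) else 0
  })
  expect_lte(mean(fdr), 0.05 + 0.02)
})

test_that("ICC: worked fixture equals the ANOVA-decomposition oracle", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  # independent oracle: mean squares via aov()
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:6, 4)),
                   rater = factor(rep(1:4, each = 6)))
  ms <- anova(stats::aov(y ~ subj + rater, df))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]; n <- 6; k <- 4
  want_a1 <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  want_c1 <- (msr - mse) / (msr + (k - 1) * mse)
  want_ak <- (msr - mse) / (msr + (msc - mse) / n)
  expect_equal(icc(m, form = "absolute", unit = "single")$estimate, want_a1,
               tolerance = 1e-12)
  expect_equal(icc(m, form = "consistency", unit = "single")$estimate,
               want_c1, tolerance = 1e-12)
  expect_equal(icc(m, form = "absolute", unit = "mean")$estimate, want_ak,
               tolerance = 1e-12)
  # shift invariance and the Spearman-Brown direction
  expect_equal(icc(m + 100, form = "absolute", unit = "single")$estimate,
               want_a1, tolerance = 1e-9)
  expect_gte(icc(m, unit = "mean")$estimate, icc(m, unit = "single")$estimate)
  # CI brackets the estimate
  r <- icc(m, form = "absolute", unit = "mean")
  expect_lt(r$lower, r$estimate); expect_gt(r$upper, r$estimate)
  expect_error(icc(m[1, , drop = FALSE]), ">= 2 subjects")
})

test_that("ICC recovery at the agreement levels seen for TLS/TIL scoring", {
  for (true in c(0.72, 0.89, 0.97)) {
    sp <- rater_sim_spec(500, 3, true_icc = true,
                         seed = round(1000 * true))
    m <- simulate_rater_scores(sp)
    est <- icc(m, model = "random", form = "absolute", unit = "mean")$estimate
    expect_lt(abs(est - true), 0.05)
  }
})

test_that("Spearman: monotone pairs, reversal, oracle, degenerate input", {
  x <- c(1, 2, 5, 7); y <- c(10, 20, 21, 40)
  expect_equal(spearman_cor(x, y)$rho, 1)
  expect_equal(spearman_cor(x, rev(y))$rho, -1)
  set.seed(37)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    a <- sample(rnorm(n)); b <- rnorm(n) + a
    if (i %% 3 == 0) { a <- round(a); b <- round(b) }  # force ties
    expect_equal(spearman_cor(a, b)$rho, bf_spearman_rho(a, b),
                 tolerance = 1e-9)
  }
  expect_warning(r <- spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r$rho))
  expect_error(spearman_cor(1:2, 1:2), "3 complete pairs")
})

test_that("TIL binning uses the predefined cutoffs", {
  expect_identical(bin_tils(c(0, 0.5, 0.99, 1, 7.5, 49.9, 50, 100)),
                   c("<1%", "<1%", "<1%", "1-49%", "1-49%", "1-49%",
                     ">=50%", ">=50%"))
  expect_error(bin_tils(101), "outside")
  expect_true(is.na(bin_tils(NA_real_)))
})

test_that("complete-linkage clustering matches the naive oracle", {
  set.seed(41)
  m <- matrix(rexp(5 * 4, 1 / 200), nrow = 5)
  rownames(m) <- letters[1:5]
  cl <- cluster_densities(m)
  expect_equal(sort(cl$height), bf_complete_linkage_heights(log1p(m)),
               tolerance = 1e-9)
  # identical profiles merge at height 0
  m2 <- rbind(m, m[3, , drop = FALSE])
  rownames(m2) <- letters[1:6]
  expect_equal(min(cluster_densities(m2)$height), 0, tolerance = 1e-12)
  # permutation of rows gives the same tree up to relabelling
  set.seed(43)
  perm <- sample(1:5)
  cl2 <- cluster_densities(m[perm, ])
  expect_equal(sort(cl2$height), sort(cl$height), tolerance = 1e-12)
  expect_setequal(cl2$labels, cl$labels)
  # same partition (up to cluster relabelling) at every cut height
  for (k in 2:4) {
    c1 <- cutree(cl$hclust, k)[sort(rownames(m))]
    c2 <- cutree(cl2$hclust, k)[sort(rownames(m))]
    expect_identical(outer(c1, c1, `==`), outer(c2, c2, `==`),
                     ignore_attr = TRUE)
  }
  expect_error(cluster_densities(m[1, , drop = FALSE]), "at least 2")
  # newick string parses in ape and reproduces the topology
  tr <- ape::read.tree(text = cl$newick)
  expect_setequal(tr$tip.label, rownames(m))
})

test_that("contrast_suite: ratio family width, BH within family, strata", {
  set.seed(47)
  co <- generate_cohort(cohort_spec(8, 8, slide_spec = tiny_slide_spec(),
                                    seed = 53, patient_sd_log = 0.5))
  dens <- do.call(rbind, lapply(co, function(p) compute_densities(p$slide)))
  ratios <- compute_ratios(dens)
  meta <- do.call(rbind, lapply(co, `[[`, "metadata"))
  feats <- build_feature_table(densities = dens, ratios = ratios)
  res <- contrast_suite(feats, meta, n_perm = 200, seed = 3,
                        contrasts = c("grade", "er"))
  cc <- res[res$contrast == "case_vs_control", ]
  expect_identical(sum(cc$family == "ratio_stroma"), 28L)
  expect_identical(sum(cc$family == "ratio_epithelium"), 28L)
  expect_true(all(!is.na(cc$q_bh[is.finite(cc$p_nominal)])))
  # q >= p within each family (BH can only inflate)
  expect_true(all(cc$q_bh >= cc$p_nominal - 1e-12, na.rm = TRUE))
  # clinicopathological rows are flagged uncorrected
  cp <- res[res$contrast != "case_vs_control", ]
  expect_gt(nrow(cp), 0)
  expect_true(all(!cp$corrected))
  expect_true(all(is.na(cp$q_bh)))
  # stratum filter restricts the cohort
  res_er <- contrast_suite(feats, meta, n_perm = 200, seed = 3,
                           contrasts = character(0),
                           stratum = list(er = "positive"))
  expect_true(all(res_er$stratum == "er=positive"))
  n_er <- sum(meta$er == "positive" & meta$outcome == "case")
  expect_identical(res_er$n_a[1], n_er)
})

test_that("an injected stromal Treg effect surfaces with small q-values", {
  co <- generate_cohort(cohort_spec(
    15, 15, slide_spec = tiny_slide_spec(),
    case_effect = c(t_reg = 4), patient_sd_log = 0.3, seed = 59))
  dens <- do.call(rbind, lapply(co, function(p) compute_densities(p$slide)))
  meta <- do.call(rbind, lapply(co, `[[`, "metadata"))
  feats <- build_feature_table(densities = dens)
  res <- contrast_suite(feats, meta, n_perm = 2000, seed = 5,
                        contrasts = character(0))
  st <- res[res$family == "density_stroma", ]
  treg_q <- st$q_bh[st$feature_id == "density_t_reg_stroma"]
  expect_lte(treg_q, sort(st$q_bh)[2])  # among the two smallest q
  expect_lt(treg_q, 0.05)
})
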