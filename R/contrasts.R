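# Case-control and clinicopathological contrasts over feature tables, with
# BH FDR applied within declared feature families.

#' Run the cohort contrast suite
#'
#' Takes a long feature table (one value per patient per feature) joined to
#' patient metadata and runs:
#' \itemize{
#'   \item case vs control permutation Mann-Whitney tests on every feature,
#'     with BH q-values computed *within each feature family* (e.g. stromal
#'     densities, intraepithelial densities, stromal ratios, ...);
#'   \item clinicopathological contrasts — grade (3 groups, permutation
#'     Kruskal-Wallis) and the binary variables ER, PR, HER2, COX-2,
#'     fibrosis, comedonecrosis, Ki67 category (permutation Mann-Whitney) —
#'     left uncorrected (`q_bh = NA`, `corrected = FALSE`), since these
#'     validate expected associations.
#' }
#' Non-finite feature values (missing or infinite ratios) are dropped per
#' test (complete-case); the dropped count lands in `notes`. An optional
#' `stratum` filter (named list of metadata column = value) restricts the
#' cohort first.
#'
#' @param features data.frame with columns `patient_id`, `feature_id`,
#'   `family`, `value`.
#' @param metadata data.frame with `patient_id`, `outcome` and the
#'   clinicopathological columns.
#' @param n_perm permutations per test.
#' @param seed base seed; each test uses a seed derived from it and the
#'   feature's position, so results do not depend on iteration order.
#' @param contrasts which clinicopathological variables to test (default
#'   all available); `character(0)` for case-control only.
#' @param clinpath_families families on which clinicopathological contrasts
#'   run (default the density and TLS families present).
#' @param stratum optional named list filter, e.g.
#'   `list(er = "positive", her2 = "negative")`.
#' @return data.frame of [perm_rank_test()]/[perm_kruskal_wallis()] results
#'   with columns `feature_id, family, contrast, stratum, test, statistic,
#'   p_nominal, q_bh, corrected, n_a, n_b, notes`.
#' @export
contrast_suite <- function(features, metadata, n_perm = 10000, seed = 1L,
                           contrasts = c("grade", "er", "pr", "her2", "cox2",
                                         "fibrosis", "comedonecrosis",
                                         "ki67_category"),
                           clinpath_families = NULL, stratum = NULL) {
  stopifnot(all(c("patient_id", "feature_id", "family", "value") %in%
                names(features)),
            all(c("patient_id", "outcome") %in% names(metadata)))
  stratum_label <- "all"
  if (!is.null(stratum) && length(stratum)) {
    for (v in names(stratum))
      metadata <- metadata[!is.na(metadata[[v]]) &
                           metadata[[v]] == stratum[[v]], ]
    stratum_label <- paste(sprintf("%s=%s", names(stratum),
                                   unlist(stratum)), collapse = ",")
  }
  features <- features[features$patient_id %in% metadata$patient_id, ]
  feat_ids <- unique(features[, c("feature_id", "family")])
  if (is.null(clinpath_families))
    clinpath_families <- intersect(unique(feat_ids$family),
                                   c("density_stroma", "density_epithelium",
                                     "tls"))
  rows <- list()
  run_two_group <- function(va, vb, test_seed) {
    ok_a <- sum(is.finite(va)); ok_b <- sum(is.finite(vb))
    if (ok_a < 1 || ok_b < 1)
      return(data.frame(test = "perm_mann_whitney", statistic = NA_real_,
                        effect = NA_real_, p_nominal = NA_real_,
                        mode = "not_computable", n_a = ok_a, n_b = ok_b,
                        notes = "empty group", stringsAsFactors = FALSE))
    perm_rank_test(va, vb, n_perm = n_perm, seed = test_seed)
  }
  # --- case vs control on every feature
  for (i in seq_len(nrow(feat_ids))) {
    fid <- feat_ids$feature_id[i]; fam <- feat_ids$family[i]
    f <- features[features$feature_id == fid, ]
    v <- setNames(f$value, f$patient_id)
    grp <- split(unname(v[metadata$patient_id]), metadata$outcome)
    res <- run_two_group(grp$case, grp$control, child_seed(seed, i))
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = fid, family = fam, contrast = "case_vs_control",
      stratum = stratum_label, test = res$test, statistic = res$statistic,
      p_nominal = res$p_nominal, q_bh = NA_real_, corrected = TRUE,
      n_a = res$n_a, n_b = res$n_b, notes = res$notes,
      stringsAsFactors = FALSE)
  }
  # --- clinicopathological contrasts, uncorrected
  cp_feat <- feat_ids[feat_ids$family %in% clinpath_families, ]
  contrasts <- intersect(contrasts, names(metadata))
  for (v_name in contrasts) {
    for (i in seq_len(nrow(cp_feat))) {
      fid <- cp_feat$feature_id[i]
      f <- features[features$feature_id == fid, ]
      vals <- setNames(f$value, f$patient_id)
      lab <- metadata[[v_name]]
      keep <- !is.na(lab)
      groups <- split(unname(vals[metadata$patient_id[keep]]), lab[keep])
      groups <- lapply(groups, function(g) g[is.finite(g)])
      groups <- groups[vapply(groups, length, 0L) > 0]
      ts <- child_seed(seed, 100000 + i * 31 + match(v_name, contrasts))
      if (length(groups) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = fid, family = cp_feat$family[i], contrast = v_name,
          stratum = stratum_label, test = "perm_mann_whitney",
          statistic = NA_real_, p_nominal = NA_real_, q_bh = NA_real_,
          corrected = FALSE, n_a = NA_integer_, n_b = NA_integer_,
          notes = "not computable: <2 non-empty groups",
          stringsAsFactors = FALSE)
        next
      }
      if (length(groups) == 2) {
        res <- perm_rank_test(groups[[1]], groups[[2]], n_perm = n_perm,
                              seed = ts)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = fid, family = cp_feat$family[i], contrast = v_name,
          stratum = stratum_label, test = res$test,
          statistic = res$statistic, p_nominal = res$p_nominal,
          q_bh = NA_real_, corrected = FALSE, n_a = res$n_a, n_b = res$n_b,
          notes = res$notes, stringsAsFactors = FALSE)
      } else {
        res <- perm_kruskal_wallis(groups, n_perm = n_perm, seed = ts)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = fid, family = cp_feat$family[i], contrast = v_name,
          stratum = stratum_label, test = res$test,
          statistic = res$statistic, p_nominal = res$p_nominal,
          q_bh = NA_real_, corrected = FALSE, n_a = res$n,
          n_b = NA_integer_, notes = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  # BH within family, case-control rows only
  cc <- out$contrast == "case_vs_control"
  for (fam in unique(out$family[cc])) {
    sel <- cc & out$family == fam
    out$q_bh[sel] <- bh_fdr(out$p_nominal[sel])
  }
  rownames(out) <- NULL
  out
}

#' Build a long feature table from per-patient summary tables
#'
#' Reshapes density / ratio / proximity / TLS tables into the
#' `(patient_id, feature_id, family, value)` format [contrast_suite()]
#' consumes. Infinite ratios are kept (and excluded per-test downstream).
#'
#' @param densities output of [compute_densities()] row-bound over patients
#'   (or NULL).
#' @param ratios output of [compute_ratios()] likewise.
#' @param proximity output of [proximity_index()] likewise.
#' @param tls output of [tls_density()] likewise.
#' @return long data.frame.
#' @export
build_feature_table <- function(densities = NULL, ratios = NULL,
                                proximity = NULL, tls = NULL) {
  out <- list()
  if (!is.null(densities) && nrow(densities))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = densities$patient_id,
      feature_id = paste0("density_", densities$subset_id, "_",
                          densities$compartment),
      family = paste0("density_", densities$compartment),
      value = densities$density_cells_per_mm2, stringsAsFactors = FALSE)
  if (!is.null(ratios) && nrow(ratios))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = ratios$patient_id,
      feature_id = paste0("ratio_", ratios$numerator_subset, "_over_",
                          ratios$denominator_subset, "_", ratios$compartment),
      family = paste0("ratio_", ratios$compartment),
      value = ratios$ratio, stringsAsFactors = FALSE)
  if (!is.null(proximity) && nrow(proximity))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = proximity$patient_id,
      feature_id = paste0("proximity_", proximity$subset_id),
      family = "proximity",
      value = proximity$proximity_index, stringsAsFactors = FALSE)
  if (!is.null(tls) && nrow(tls))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = tls$patient_id,
      feature_id = paste0("tls_", tls$tls_type, "_density"),
      family = "tls",
      value = tls$density_per_mm2, stringsAsFactors = FALSE)
  if (!length(out)) return(data.frame(patient_id = character(0),
                                      feature_id = character(0),
                                      family = character(0),
                                      value = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
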