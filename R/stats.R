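# Cohort inference: permutation Mann-Whitney and Kruskal-Wallis tests,
# Benjamini-Hochberg FDR, McGraw-Wong ICC, Spearman correlation, TIL
# binning, and complete-linkage clustering of log densities.

# Mann-Whitney U for group a vs pooled ranks (average ranks for ties).
mw_u_from_ranks <- function(r_a, n_a) sum(r_a) - n_a * (n_a + 1) / 2

#' Two-group permutation Mann-Whitney test
#'
#' Two-sided test of a location difference using the Mann-Whitney U
#' statistic with average ranks for ties. The permutation effect is
#' `|U - n_a * n_b / 2|`. With `mode = "exact"` (or `"auto"` when the number
#' of group-label splits is at most `exact_limit`) all splits are
#' enumerated: `p = #{splits with effect >= observed} / #splits`. Otherwise
#' `n_perm` Monte-Carlo permutations are drawn and the add-one estimator
#' `p = (1 + #{effect >= observed}) / (1 + n_perm)` avoids zero p-values.
#' Non-finite values are removed (count reported in `notes`).
#'
#' @param values_a,values_b numeric vectors.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed integer seed for the Monte-Carlo path.
#' @param mode `"auto"`, `"exact"` or `"montecarlo"`.
#' @param exact_limit maximum number of splits enumerated under `"auto"`.
#' @return one-row data.frame: `test, statistic, effect, p_nominal, mode,
#'   n_a, n_b, notes`.
#' @export
perm_rank_test <- function(values_a, values_b, n_perm = 10000, seed = 1L,
                           mode = c("auto", "exact", "montecarlo"),
                           exact_limit = 50000) {
  mode <- match.arg(mode)
  drop_a <- sum(!is.finite(values_a)); drop_b <- sum(!is.finite(values_b))
  a <- values_a[is.finite(values_a)]; b <- values_b[is.finite(values_b)]
  if (length(a) < 1 || length(b) < 1)
    stop("each group needs at least one finite value")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- mw_u_from_ranks(r[seq_len(n_a)], n_a)
  eff_obs <- abs(u_obs - n_a * n_b / 2)
  n_splits <- choose(n, n_a)
  use_exact <- mode == "exact" || (mode == "auto" && n_splits <= exact_limit)
  if (use_exact) {
    if (n_splits > 5e6) stop("exact enumeration infeasible: ", n_splits,
                             " splits")
    splits <- combn(n, n_a)
    effs <- abs(colSums(matrix(r[splits], nrow = n_a)) -
                n_a * (n_a + 1) / 2 - n_a * n_b / 2)
    p <- sum(effs >= eff_obs - 1e-12) / n_splits
    used <- "exact"
  } else {
    set.seed(seed)
    effs <- vapply(seq_len(n_perm), function(i) {
      ra <- r[sample.int(n, n_a)]
      abs(sum(ra) - n_a * (n_a + 1) / 2 - n_a * n_b / 2)
    }, 0)
    p <- (1 + sum(effs >= eff_obs - 1e-12)) / (1 + n_perm)
    used <- "montecarlo"
  }
  data.frame(test = "perm_mann_whitney", statistic = u_obs,
             effect = eff_obs, p_nominal = p, mode = used,
             n_a = n_a, n_b = n_b,
             notes = if (drop_a + drop_b > 0)
               sprintf("dropped %d non-finite", drop_a + drop_b) else "",
             stringsAsFactors = FALSE)
}

kw_h <- function(values, g, n_groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  # tie correction
  ties <- table(values)
  ct <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (ct > 0) h / ct else 0
}

#' Permutation Kruskal-Wallis test
#'
#' Tie-corrected H statistic; p-value by Monte-Carlo permutation of group
#' labels with the add-one estimator. When fewer than 2 distinct values are
#' present, p = 1 with a warning.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @param n_perm,seed Monte-Carlo controls.
#' @return one-row data.frame `test, statistic, p_nominal, n_groups, n`.
#' @export
perm_kruskal_wallis <- function(groups, n_perm = 10000, seed = 1L) {
  groups <- lapply(groups, function(v) v[is.finite(v)])
  groups <- groups[vapply(groups, length, 0L) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  if (length(unique(values)) < 2) {
    warning("fewer than 2 distinct values; p = 1")
    return(data.frame(test = "perm_kruskal_wallis", statistic = 0,
                      p_nominal = 1, n_groups = length(groups),
                      n = length(values)))
  }
  h_obs <- kw_h(values, g, length(groups))
  set.seed(seed)
  hs <- vapply(seq_len(n_perm), function(i)
    kw_h(values, g[sample.int(length(g))], length(groups)), 0)
  p <- (1 + sum(hs >= h_obs - 1e-12)) / (1 + n_perm)
  data.frame(test = "perm_kruskal_wallis", statistic = h_obs, p_nominal = p,
             n_groups = length(groups), n = length(values))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min_{j: p_(j) >= p_(i)} min(1, m * p_(j) / j)` over the `m`
#' non-missing p-values; NAs pass through.
#'
#' @param p_values numeric in `[0, 1]`, NAs allowed.
#' @return q-values aligned with the input.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  if (m) {
    o <- order(p)
    adj <- pmin(1, p[o] * m / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    qi <- numeric(m)
    qi[o] <- adj
    q[ok] <- qi
  }
  q
}

icc_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation coefficient (McGraw-Wong)
#'
#' Two-way ANOVA-based ICC with 95% confidence interval. Models: two-way
#' `random` (raters a random sample; absolute agreement meaningful) or
#' two-way `mixed` (same estimator; interpretation differs). Forms:
#' `absolute` agreement or `consistency`; unit `single` (one rater's score)
#' or `mean` (mean of the k raters). Rows with missing values are dropped
#' (complete-case).
#'
#' @param mat subjects x raters numeric matrix.
#' @param model `"random"` or `"mixed"`.
#' @param form `"absolute"` or `"consistency"`.
#' @param unit `"single"` or `"mean"`.
#' @param conf_level confidence level (default 0.95).
#' @return list `estimate`, `lower`, `upper`, `model`, `form`, `unit`,
#'   `n_subjects`, `n_raters`.
#' @export
icc <- function(mat, model = c("random", "mixed"),
                form = c("absolute", "consistency"),
                unit = c("single", "mean"), conf_level = 0.95) {
  model <- match.arg(model); form <- match.arg(form)
  unit <- match.arg(unit)
  mat <- as.matrix(mat)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("ICC needs >= 2 subjects and >= 2 raters after NA removal")
  a <- icc_anova(mat)
  msr <- a$msr; msc <- a$msc; mse <- a$mse; n <- a$n; k <- a$k
  alpha <- 1 - conf_level
  if (form == "consistency") {
    est1 <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo1 <- (fl - 1) / (fl + k - 1); up1 <- (fu - 1) / (fu + k - 1)
  } else {
    est1 <- (msr - mse) /
      (msr + (k - 1) * mse + k / n * (msc - mse))
    aa <- k * est1 / (n * (1 - est1))
    bb <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  sb <- function(r) k * r / (1 + (k - 1) * r)  # Spearman-Brown to mean-of-k
  if (unit == "mean") {
    est <- sb(est1); lo <- sb(lo1); up <- sb(up1)
  } else {
    est <- est1; lo <- lo1; up <- up1
  }
  list(estimate = est, lower = lo, upper = up, model = model, form = form,
       unit = unit, n_subjects = n, n_raters = k)
}

#' Spearman rank correlation with two-sided p-value
#'
#' Pearson correlation of average ranks; p-value from the t approximation
#' (two-sided). A constant vector yields NA rho (undefined) with a warning.
#'
#' @param x,y paired numeric vectors, n >= 3 after removing incomplete
#'   pairs.
#' @return list `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (!is.finite(tt)) 0 else 2 * pt(-abs(tt), n - 2)
  list(rho = rho, p = p, n = n)
}

#' Bin a stromal TIL percentage into the predefined categories
#'
#' `<1%`, `1-49%` and `>=50%` of stromal area occupied by tumour-
#' infiltrating lymphocytes.
#'
#' @param percent numeric in `[0, 100]` (vectorised).
#' @return character category.
#' @examples
#' bin_tils(c(0.5, 7.5, 50))
#' @export
bin_tils <- function(percent) {
  stopifnot(is.numeric(percent))
  if (any(!is.na(percent) & (percent < 0 | percent > 100)))
    stop("TIL percentage outside [0, 100]")
  ifelse(is.na(percent), NA_character_,
         ifelse(percent < 1, "<1%",
                ifelse(percent < 50, "1-49%", ">=50%")))
}

#' Cluster patients on log-transformed densities
#'
#' Transforms the patients x features density matrix with `log(1 + x)`,
#' computes Euclidean distances and agglomerates with complete linkage.
#' Rows with any missing feature are dropped (`na_action = "drop"`) or NAs
#' are mean-imputed per feature (`"impute"`).
#'
#' @param density_matrix numeric matrix, patients in rows.
#' @param k optional number of clusters for `cutree` labels.
#' @param na_action `"drop"` or `"impute"`.
#' @return list `hclust`, `order` (leaf order), `height` (merge heights),
#'   `labels`, `clusters` (if `k` given), `newick` (dendrogram as a
#'   Newick string with merge heights as branch lengths).
#' @export
cluster_densities <- function(density_matrix, k = NULL,
                              na_action = c("drop", "impute")) {
  na_action <- match.arg(na_action)
  m <- as.matrix(density_matrix)
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  if (na_action == "drop") {
    m <- m[complete.cases(m), , drop = FALSE]
  } else {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
  }
  if (nrow(m) < 2) stop("need at least 2 complete patient rows")
  lm_ <- log1p(m)
  hc <- hclust(stats::dist(lm_), method = "complete")
  nw <- hclust_to_newick(hc)
  out <- list(hclust = hc, order = hc$order, height = hc$height,
              labels = hc$labels, newick = nw)
  if (!is.null(k)) out$clusters <- cutree(hc, k = k)
  out
}

hclust_to_newick <- function(hc) {
  lab <- hc$labels
  node <- function(i, h_parent) {
    if (i < 0) {
      sprintf("%s:%.10g", lab[-i], h_parent)
    } else {
      l <- node(hc$merge[i, 1], hc$height[i])
      r <- node(hc$merge[i, 2], hc$height[i])
      sprintf("(%s,%s):%.10g", l, r, h_parent - hc$height[i])
    }
  }
  top <- nrow(hc$merge)
  l <- node(hc$merge[top, 1], hc$height[top])
  r <- node(hc$merge[top, 2], hc$height[top])
  paste0("(", l, ",", r, ");")
}
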