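# Phenotype gating: marker-flag vectors -> mutually exclusive phenotype
# labels, and subset counting per tissue compartment.
#
# mIF gating precedence: panCK > CD3-lineage > CD20 > CD68 > other; inside
# the CD3 lineage FOXP3+ -> t_reg, else CD8+ -> t_cytotoxic, else t_helper
# (CD4 is not in the panel, so helper T cells are CD3+CD8-FOXP3-).
# The double-stain assay only sees CD8/Ki67: CD8+Ki67+ -> activated
# cytotoxic, CD8+Ki67- -> t_cytotoxic, anything else -> other.

#' Gate one cell
#'
#' @param markers named flags (0/1/NA, NA = not measured) over the marker
#'   vocabulary `panCK, CD3, CD8, CD20, FOXP3, CD68, Ki67`.
#' @param assay `"mif"` or `"cd8ki67"`.
#' @return a phenotype label (character scalar).
#' @examples
#' gate_cell(c(CD3 = 1, CD8 = 0, FOXP3 = 1))            # "t_reg"
#' gate_cell(c(panCK = 1, CD3 = 1))                      # "dcis_cell"
#' gate_cell(c(CD8 = 1, Ki67 = 1), assay = "cd8ki67")    # "activated_cytotoxic"
#' @export
gate_cell <- function(markers, assay = "mif") {
  bad <- setdiff(names(markers), ALL_MARKERS)
  if (length(bad)) stop("unknown marker key(s): ", paste(bad, collapse = ", "))
  if (is.null(names(markers))) stop("markers must be named")
  df <- as.data.frame(as.list(markers))
  for (m in setdiff(ALL_MARKERS, names(df))) df[[m]] <- NA_integer_
  gate_cells(df, assay = assay)
}

#' Gate a cell table (vectorised)
#'
#' @param cells data.frame with the marker columns; NA flags count as
#'   negative (marker not measured).
#' @param assay single assay tag, or `NULL` to use `cells$assay` per row.
#' @return character vector of phenotype labels, one per row.
#' @export
gate_cells <- function(cells, assay = NULL) {
  f <- function(m) {
    v <- cells[[m]]
    if (is.null(v)) v <- rep(NA_integer_, nrow(cells))
    !is.na(v) & v == 1
  }
  assay_v <- if (is.null(assay)) cells$assay else rep(assay, nrow(cells))
  stopifnot(!is.null(assay_v))
  lab <- rep("other", nrow(cells))
  mif <- assay_v != "cd8ki67"
  panck <- f("panCK"); cd3 <- f("CD3"); cd8 <- f("CD8"); cd20 <- f("CD20")
  foxp3 <- f("FOXP3"); cd68 <- f("CD68"); ki67 <- f("Ki67")
  lab[mif & cd68] <- "macrophage"
  lab[mif & cd20] <- "b_cell"
  lab[mif & cd3 & !cd8 & !foxp3] <- "t_helper"
  lab[mif & cd3 & cd8 & !foxp3] <- "t_cytotoxic"
  lab[mif & cd3 & foxp3] <- "t_reg"
  lab[mif & panck] <- "dcis_cell"
  lab[!mif] <- "other"
  lab[!mif & cd8 & !ki67] <- "t_cytotoxic"
  lab[!mif & cd8 & ki67] <- "activated_cytotoxic"
  lab
}

subset_membership <- function(cells, subset_id, formula_mode = "strict") {
  f <- function(m) { v <- cells[[m]]; !is.na(v) & v == 1 }
  assay <- cells$assay
  mif <- assay != "cd8ki67"
  panck <- f("panCK"); cd3 <- f("CD3"); cd8 <- f("CD8"); cd20 <- f("CD20")
  foxp3 <- f("FOXP3"); cd68 <- f("CD68"); ki67 <- f("Ki67")
  imm <- mif & !panck  # panCK wins any conflict; DCIS cells are not immune
  switch(subset_id,
    t_all = imm & cd3,
    b_cell = imm & !cd3 & cd20,
    t_helper = imm & cd3 & !cd8 & !foxp3,
    t_cytotoxic = imm & cd3 & cd8 & !foxp3,
    t_reg = imm & cd3 & foxp3,
    macrophage = imm & !cd3 & !cd20 & cd68,
    lymphocytes = {
      base <- (imm & cd3 & !cd8 & !foxp3) |   # helper T
              (imm & cd3 & cd8 & !foxp3)  |   # cytotoxic T
              (imm & cd3 & !cd8 & foxp3)  |   # regulatory T (CD8-)
              (imm & !cd3 & cd20)             # B cells
      if (formula_mode == "inclusive") base | (imm & cd3 & cd8 & foxp3)
      else base
    },
    activated_cytotoxic = !mif & cd8 & ki67,
    stop("unknown subset id: ", subset_id))
}

#' Count immune subsets per compartment
#'
#' Counts each of the 8 immune subsets in the two analysis compartments
#' (periductal stroma, DCIS epithelium); debris/background cells never
#' count. `t_all` is all CD3+ cells regardless of CD8/FOXP3. `lymphocytes`
#' follows the four-term panel formula helper T + cytotoxic T + (CD8-)
#' regulatory T + B cells; `formula_mode = "inclusive"` additionally counts
#' CD3+CD8+FOXP3+ cells, a combination the literal formula omits while the
#' Treg definition includes it. `activated_cytotoxic` (CD8+Ki67+) comes from
#' the double-stain assay; everything else from the mIF assay.
#'
#' @param slide a [slide_cell_map()] (cells carry marker flags and
#'   compartment labels).
#' @param subsets subset ids to count (default all 8).
#' @param formula_mode `"strict"` (printed formula, default) or
#'   `"inclusive"`.
#' @return data.frame `(subset_id, compartment, count)` with one row per
#'   subset x compartment.
#' @export
count_subsets <- function(slide, subsets = SUBSETS,
                          formula_mode = c("strict", "inclusive")) {
  formula_mode <- match.arg(formula_mode)
  stopifnot(inherits(slide, "slide_cell_map"),
            all(subsets %in% SUBSETS))
  cells <- slide$cells
  out <- expand.grid(subset_id = subsets,
                     compartment = ANALYSIS_COMPARTMENTS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- NA_integer_
  for (s in subsets) {
    memb <- subset_membership(cells, s, formula_mode)
    for (cmp in ANALYSIS_COMPARTMENTS)
      out$count[out$subset_id == s & out$compartment == cmp] <-
        sum(memb & cells$compartment == cmp)
  }
  out
}
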