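# Group-wise differential testing: Wilcoxon rank-sum, fold changes, BH-FDR,
# and the named significance presets.

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with mid-ranks for ties. The default mode uses the
#' normal approximation with tie correction and continuity correction; for
#' small samples (`n_x + n_y <= 12` when `exact = NULL`) an exact enumeration
#' over all rank assignments is used: the p-value is the fraction of
#' assignments whose rank sum deviates from its expectation at least as much
#' as observed. If every value is identical across both groups, `p = 1` by
#' convention.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` decides by total sample size.
#' @return A list with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop_input("both samples must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  w <- sum(r[seq_len(nx)])
  if (length(unique(all_v)) == 1L) {
    return(list(statistic = w, p.value = 1, method = "degenerate"))
  }
  use_exact <- exact %||% (nx + ny <= 12L)
  if (use_exact) {
    combs <- combn(nx + ny, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    e <- nx * (nx + ny + 1) / 2
    p <- mean(abs(sums - e) >= abs(w - e) - 1e-12)
    return(list(statistic = w, p.value = p, method = "exact"))
  }
  n <- nx + ny
  e <- nx * (n + 1) / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties)
  v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(statistic = w, p.value = 1, method = "normal"))
  z <- (abs(w - e) - 0.5) / sqrt(v)   # continuity correction
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(statistic = w, p.value = p, method = "normal")
}

#' log2 fold change with pseudocount
#'
#' `log2((mean(a) + pc) / (mean(b) + pc))`; antisymmetric under group swap.
#'
#' @param group_a,group_b Non-negative values on a common normalized scale
#'   (scalars are treated as precomputed means).
#' @param pseudocount Stabilizing constant.
#' @return A single numeric value.
#' @export
log2_fold_change <- function(group_a, group_b, pseudocount = 0.01) {
  if (any(group_a < 0) || any(group_b < 0)) stop_input("negative inputs")
  log2((mean(group_a) + pseudocount) / (mean(group_b) + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure with monotonicity enforcement:
#' `q_(i) = min_(j >= i) (m * p_(j) / j)`.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed, passed through).
#' @return Adjusted q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop_input("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m) {
    o <- order(p)
    q <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
    out[ok][o] <- q
  }
  out
}

#' Registered significance presets
#'
#' Named threshold sets used for calling differential features. `fc` values
#' are linear-scale fold-change bounds (`fdr0.01_fc1.25` calls a feature when
#' `q < 0.01` and `|log2FC| > log2(1.25)`); `lfc` presets bound `|log2FC|`
#' directly. All presets require both compared groups to have at least
#' `min_cells` cells (50).
#'
#' @return A tibble: `preset`, `use` (`"q"` or `"p"`), `max_p`, `min_lfc`,
#'   `min_cells`.
#' @export
threshold_presets <- function() {
  tibble(
    preset = c("fdr0.01_fc1.25", "fdr0.1_lfc0.25", "p0.001_lfc0.25",
               "padj0.01_lfc0.5"),
    use = c("q", "q", "p", "q"),
    max_p = c(0.01, 0.1, 0.001, 0.01),
    min_lfc = c(log2(1.25), 0.25, 0.25, 0.5),
    min_cells = 50L
  )
}

get_preset <- function(preset) {
  reg <- threshold_presets()
  row <- reg[reg$preset == preset, ]
  if (!nrow(row)) {
    stop_config("unknown preset '%s'; available: %s", preset,
                paste(reg$preset, collapse = ", "))
  }
  row
}

# vectorized tie-corrected normal-approximation rank-sum test over matrix rows
wilcoxon_matrix <- function(mat, in_a) {
  nx <- sum(in_a); ny <- sum(!in_a)
  n <- nx + ny
  res <- apply(mat, 1, function(v) {
    r <- rank(v)
    w <- sum(r[in_a])
    ties <- table(v)
    c(w, sum(ties^3 - ties), length(ties))
  })
  w <- res[1, ]; tie_term <- res[2, ]; n_distinct <- res[3, ]
  e <- nx * (n + 1) / 2
  v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (abs(w - e) - 0.5) / sqrt(pmax(v, .Machine$double.eps))
  p <- pmin(1, 2 * pnorm(-pmax(z, 0)))
  p[n_distinct == 1] <- 1
  list(statistic = w, p.value = p)
}

#' Differential features between a group and its complement (or another group)
#'
#' Per-feature Wilcoxon rank-sum test plus log2 fold change of the
#' (de-logged) group means, BH-FDR over the tested features, and a
#' significance call under a named preset. Features detected in fewer than
#' `min_frac` of the cells of both groups are not tested.
#'
#' @param mat Normalized matrix (features x cells), e.g. [normalize_rna()].
#' @param cells_a Cells of the target group (names or logical over columns).
#' @param cells_b Cells of the comparison group; `NULL` uses all other cells.
#' @param preset Name from [threshold_presets()].
#' @param min_frac Detection-fraction pre-filter (default 10%).
#' @param pseudocount Passed to [log2_fold_change()].
#' @return A tibble: `feature`, `n_a`, `n_b`, `mean_a`, `mean_b`, `pct_a`,
#'   `pct_b`, `log2fc`, `statistic`, `p_value`, `q_value`, `significant`.
#' @export
find_markers <- function(mat, cells_a, cells_b = NULL,
                         preset = "fdr0.01_fc1.25", min_frac = 0.1,
                         pseudocount = 0.01) {
  pr <- get_preset(preset)
  cells <- colnames(mat)
  a <- if (is.logical(cells_a)) cells[cells_a] else intersect(cells_a, cells)
  b <- if (is.null(cells_b)) setdiff(cells, a)
  else if (is.logical(cells_b)) cells[cells_b] else intersect(cells_b, cells)
  if (length(intersect(a, b))) stop_input("groups overlap")
  if (length(a) < pr$min_cells || length(b) < pr$min_cells) {
    stop_input("group below the minimum size of %d cells (sizes %d and %d)",
               pr$min_cells, length(a), length(b))
  }
  ma <- mat[, a, drop = FALSE]; mb <- mat[, b, drop = FALSE]
  pct_a <- rowMeans(ma > 0); pct_b <- rowMeans(mb > 0)
  tested <- pct_a >= min_frac | pct_b >= min_frac
  x <- as.matrix(cbind(ma, mb))[tested, , drop = FALSE]
  in_a <- c(rep(TRUE, length(a)), rep(FALSE, length(b)))
  wt <- wilcoxon_matrix(x, in_a)
  # means on the de-logged normalized scale
  mean_a <- rowMeans(expm1(x[, in_a, drop = FALSE]))
  mean_b <- rowMeans(expm1(x[, !in_a, drop = FALSE]))
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  q <- bh_fdr(wt$p.value)
  crit <- if (pr$use == "q") q else wt$p.value
  tibble(
    feature = rownames(mat)[tested],
    n_a = length(a), n_b = length(b),
    mean_a = mean_a, mean_b = mean_b,
    pct_a = pct_a[tested], pct_b = pct_b[tested],
    log2fc = lfc, statistic = wt$statistic,
    p_value = wt$p.value, q_value = q,
    significant = crit < pr$max_p & abs(lfc) > pr$min_lfc
  )
}

#' Differential 5-kb bins between conditions, per cell type
#'
#' Runs [find_markers()] on the (normalized) bin matrix within each cell
#' type, exposed vs control. Cell types where either condition has fewer than
#' the preset's minimum cells are skipped with a message.
#'
#' @param bin_norm Normalized bin matrix (bins x cells).
#' @param condition Named character vector (cell -> `"control"`/`"exposed"`),
#'   or a vector aligned with the columns.
#' @param cell_type Optional named vector of cell-type labels; `NULL` tests
#'   all cells as one group.
#' @inheritParams find_markers
#' @return A tibble as [find_markers()] with an extra `cell_type` column.
#' @export
differential_bins <- function(bin_norm, condition, cell_type = NULL,
                              preset = "fdr0.01_fc1.25", min_frac = 0.1) {
  cells <- colnames(bin_norm)
  condition <- align_labels(condition, cells, "condition")
  cell_type <- if (is.null(cell_type)) setNames(rep("all", length(cells)), cells)
  else align_labels(cell_type, cells, "cell_type")
  out <- list()
  for (ct in unique(cell_type)) {
    sel <- cells[cell_type == ct]
    a <- sel[condition[sel] == "exposed"]
    b <- sel[condition[sel] == "control"]
    res <- tryCatch(
      find_markers(bin_norm[, sel, drop = FALSE], a, b, preset = preset,
                   min_frac = min_frac),
      pairedtag_input_error = function(e) {
        inform(sprintf("skipping cell type '%s': %s", ct, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) out[[ct]] <- mutate(res, cell_type = ct)
  }
  bind_rows(out)
}

align_labels <- function(x, cells, what) {
  if (!is.null(names(x))) {
    if (!all(cells %in% names(x))) stop_input("%s labels missing for some cells", what)
    x[cells]
  } else {
    if (length(x) != length(cells)) stop_input("%s labels wrong length", what)
    setNames(x, cells)
  }
}
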