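# Ground-truth cells and RNA counts.

#' Simulate ground-truth nuclei and their RNA counts
#'
#' Assigns every nucleus a cell type, capture group, barcode triple and PCR
#' sub-library, and draws its RNA profile from a negative-binomial model:
#' gene abundances come from a seeded gamma baseline, marker genes are
#' up-weighted `marker_upweight`-fold in their own type, genes whose current
#' promoter state carries H3K27me3 are down-weighted by
#' `2^-k27_expression_coupling`, and exposure applies the planted expression
#' log2 fold changes.
#'
#' @param config A [sim_config()].
#' @return A `pt_sim` list with elements `cells` (one row per nucleus:
#'   `cell_id`, `cell_barcode`, `bc1`/`bc2`/`bc3`, `pcr_index`, `cell_type`,
#'   `condition`, `sex`, `mark`, `group`), `gene_plan` (planted truth per
#'   gene), `rna_counts` (sparse genes x cells), `whitelists`, and `config`.
#' @export
simulate_cells <- function(config) {
  stopifnot(is(config, "sim_config"))
  plan <- sim_gene_plan(config)
  whitelists <- sim_whitelists(bc_len = config$layout$bc_len[1],
                               seed = config$whitelist_seed)
  groups <- config$groups

  cells <- withr::with_seed(config$seed + 200L, {
    per_group <- purrr::map(seq_len(nrow(groups)), function(gi) {
      g <- groups[gi, ]
      type <- sample(config$cell_types$name, config$n_cells_per_group,
                     replace = TRUE, prob = config$cell_types$fraction)
      tibble(cell_type = type, condition = g$condition, sex = g$sex,
             mark = g$mark, group = g$group)
    })
    cells <- bind_rows(per_group)
    cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
    # BC1 wells encode the sample of origin: the 12 wells are split evenly
    # over the sample groups of a capture
    sample_groups <- unique(groups$group)
    n_wells <- length(whitelists[[1]])
    well_sets <- split(seq_len(n_wells),
                       rep(seq_along(sample_groups), length.out = n_wells))
    names(well_sets) <- sample_groups
    # unique barcode triples within each capture (mark): sample without
    # replacement from the group's BC1 wells crossed with all BC2 x BC3 combos
    n2 <- length(whitelists[[2]])
    n3 <- length(whitelists[[3]])
    cells$bc1_idx <- cells$bc2_idx <- cells$bc3_idx <- NA_integer_
    for (idx in split(seq_len(nrow(cells)), list(cells$mark, cells$group), drop = TRUE)) {
      ws <- well_sets[[cells$group[idx[1]]]]
      total <- length(ws) * n2 * n3
      if (length(idx) > total) {
        stop_config("more cells per group (%d) than available barcode combinations (%d)",
                    length(idx), total)
      }
      combo <- sample.int(total, length(idx), replace = FALSE) - 1L
      cells$bc1_idx[idx] <- ws[(combo %/% (n2 * n3)) + 1L]
      rem <- combo %% (n2 * n3)
      cells$bc2_idx[idx] <- (rem %/% n3) + 1L
      cells$bc3_idx[idx] <- (rem %% n3) + 1L
    }
    cells$bc1 <- whitelists[[1]][cells$bc1_idx]
    cells$bc2 <- whitelists[[2]][cells$bc2_idx]
    cells$bc3 <- whitelists[[3]][cells$bc3_idx]
    cells$cell_barcode <- paste(cells$bc1, cells$bc2, cells$bc3, sep = "-")
    cells$pcr_index <- sample.int(config$n_pcr_indices, nrow(cells),
                                  replace = TRUE)
    cells$combo <- NULL
    cells
  })

  rna_counts <- withr::with_seed(config$seed + 250L, {
    draw_rna_counts(cells, plan, config)
  })

  structure(list(cells = cells, gene_plan = plan, rna_counts = rna_counts,
                 whitelists = whitelists, config = config),
            class = "pt_sim")
}

# expected relative expression of every gene for one (type, condition) block
expression_profile <- function(plan, type, condition, config) {
  state <- if (condition == "control") plan$state_control else plan$state_exposed
  rate <- plan$base_rate
  rate <- rate * ifelse(!is.na(plan$marker_of) & plan$marker_of == type,
                        config$marker_upweight, 1)
  k27 <- !is.na(state) & state %in% c("bivalent", "K27-only")
  rate <- rate * 2^(-config$k27_expression_coupling * k27)
  if (condition == "exposed") rate <- rate * 2^plan$expression_lfc
  rate / sum(rate)
}

draw_rna_counts <- function(cells, plan, config) {
  n_genes <- nrow(plan)
  n_cells <- nrow(cells)
  libsize <- exp(rnorm(n_cells, log(config$reads_per_cell_rna) -
                         config$rna_library_sd^2 / 2, config$rna_library_sd))
  counts <- matrix(0L, n_genes, n_cells)
  blocks <- split(seq_len(n_cells),
                  list(cells$cell_type, cells$condition), drop = TRUE)
  for (b in names(blocks)) {
    idx <- blocks[[b]]
    type <- cells$cell_type[idx[1]]
    condition <- cells$condition[idx[1]]
    p <- expression_profile(plan, type, condition, config)
    mu <- outer(p, libsize[idx])
    counts[, idx] <- rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
  m <- as(as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(plan$gene_id, cells$cell_id)
  m
}
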