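# Synthetic experiment configuration.
#
# The generator emulates the structure of a two-capture Paired-Tag study:
# two histone marks (H3K4me1, H3K27me3) x four sample groups (F_Ctr, F_Ecig,
# M_Ctr, M_Ecig), every nucleus carrying a matched DNA (histone) and RNA
# profile, with cell-type-specific marker genes and planted promoter
# bivalency states that differ between conditions.

SIM_MARKS <- c("H3K4me1", "H3K27me3")
BIVALENCY_STATES <- c("bivalent", "K4-only", "K27-only", "unmarked")

#' Default sample groups
#'
#' Condition x sex x histone mark, eight capture groups in total.
#' @return A tibble with columns `condition`, `sex`, `mark`, `group`.
#' @export
default_groups <- function() {
  g <- expand_grid(mark = SIM_MARKS, sex = c("F", "M"),
                   condition = c("control", "exposed"))
  g$group <- paste0(g$sex, "_", ifelse(g$condition == "control", "Ctr", "Ecig"))
  g[, c("condition", "sex", "mark", "group")]
}

#' Default cell types and marker genes
#'
#' Four cortical cell types with realistic neonatal-cortex fractions and
#' canonical marker genes (excitatory/inhibitory neurons, astrocytes, OPCs).
#' @return A tibble with columns `name`, `fraction`, `markers` (list column).
#' @export
default_cell_types <- function() {
  tibble(
    name = c("excitatory", "inhibitory", "astrocyte", "opc"),
    fraction = c(0.55, 0.20, 0.15, 0.10),
    markers = list(
      c("Arpp21", "Slc17a7", "Satb2", "Fezf2", "Tbr1", "Neurod6", "Fibcd1", "Cux2"),
      c("Gad1", "Gad2", "Erbb4", "Slc32a1", "Dlx1", "Dlx2", "Pvalb", "Sst"),
      c("Slc1a2", "Aqp4", "Gja1", "Slc1a3", "Fgfr3", "Sox9", "Aldh1l1", "Gfap"),
      c("Pdgfra", "Cspg4", "Olig1", "Olig2", "Sox10", "Gpr17", "Lhfpl3", "Ptprz1")
    )
  )
}

#' Synthetic experiment configuration
#'
#' All randomness in the generator is driven by `seed`: two runs with an
#' identical configuration produce byte-identical outputs.
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_chromosomes,chromosome_length Toy genome dimensions (bp).
#' @param n_genes Number of genes laid out on the genome.
#' @param gene_length Gene span in bp.
#' @param n_cells_per_group Nuclei per capture group (8 groups by default).
#' @param groups Tibble as [default_groups()].
#' @param cell_types Tibble as [default_cell_types()]; fractions must sum to 1.
#' @param reads_per_cell_rna Expected RNA molecules (UMIs) per nucleus.
#' @param fragments_per_cell_dna DNA fragments per nucleus.
#' @param rna_library_sd Log-normal sd of per-cell RNA library size.
#' @param nb_dispersion Negative-binomial dispersion of RNA counts.
#' @param marker_upweight Fold up-weighting of a marker gene in its own type.
#' @param barcode_error_rate Per-barcode (per round) probability that exactly
#'   one base of the barcode is substituted.
#' @param duplicate_rate PCR duplication rate: every unique molecule gains
#'   `k ~ Geometric(1 / (1 + duplicate_rate))` extra copies, so the expected
#'   read count is `(1 + duplicate_rate) x` the unique-molecule count.
#' @param adapter_contamination_rate Fraction of Read 1 with 3' adapter
#'   read-through.
#' @param polydt_rate Fraction of RNA Read 1 carrying a 3' poly-dT tail.
#' @param n_bivalent,n_k4_only,n_k27_only,n_unmarked_eval Sizes of the planted
#'   promoter-state blocks (control condition); `n_unmarked_eval` genes are
#'   explicitly planted "unmarked" and included in recovery evaluation.
#' @param n_transitions Number of bivalent genes switching to K4-only under
#'   exposure (loss of H3K27me3).
#' @param k27_type_genes Type-specific H3K27me3 promoter genes per cell type
#'   (disjoint across types: localized, identity-linked repression).
#' @param k4_pool_genes Size of each of the two shared H3K4me1 pools
#'   (excitatory vs all other types: widespread shared enhancer-like signal).
#' @param n_effect_genes,effect_lfc Exposure expression effect: the
#'   `n_effect_genes` most abundant evaluation genes get `+effect_lfc` (half)
#'   or `-effect_lfc` (half) log2 fold change in exposed cells.
#' @param k27_expression_coupling log2 expression reduction applied to genes
#'   whose current promoter state contains H3K27me3.
#' @param background_fraction Fraction of DNA fragments placed uniformly on
#'   the genome.
#' @param type_signal_fraction Named fraction (per mark) of DNA fragments
#'   placed in the cell type's own type-specific promoters.
#' @param planted_bivalency Optional explicit plan: tibble with `gene_index`,
#'   `control`, `exposed` states overriding the block defaults.
#' @param read_length,fragment_length Read / DNA fragment lengths (bp).
#' @param n_pcr_indices Number of PCR sub-libraries; each nucleus belongs to
#'   one, and the index rides in the read header.
#' @param layout A [barcode_layout()].
#' @param whitelist_seed Seed for [sim_whitelists()] (kept separate so the
#'   same whitelists can be shared across configurations).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chromosome_length = 2.5e6,
                       n_genes = 500L,
                       gene_length = 2000L,
                       n_cells_per_group = 250L,
                       groups = default_groups(),
                       cell_types = default_cell_types(),
                       reads_per_cell_rna = 400L,
                       fragments_per_cell_dna = 800L,
                       rna_library_sd = 0.3,
                       nb_dispersion = 0.3,
                       marker_upweight = 8,
                       barcode_error_rate = 0.01,
                       duplicate_rate = 0.3,
                       adapter_contamination_rate = 0.1,
                       polydt_rate = 0.5,
                       n_bivalent = 60L,
                       n_k4_only = 60L,
                       n_k27_only = 60L,
                       n_unmarked_eval = 100L,
                       n_transitions = 20L,
                       k27_type_genes = 25L,
                       k4_pool_genes = 12L,
                       n_effect_genes = 40L,
                       effect_lfc = 1,
                       k27_expression_coupling = 1,
                       background_fraction = 0.4,
                       type_signal_fraction = c(H3K4me1 = 0.1, H3K27me3 = 0.3),
                       planted_bivalency = NULL,
                       read_length = 150L,
                       fragment_length = 100L,
                       n_pcr_indices = 4L,
                       layout = barcode_layout(),
                       whitelist_seed = 42L) {
  if (n_chromosomes < 1L || chromosome_length < 1 || n_genes < 1L) {
    stop_config("genome dimensions must be positive")
  }
  if (abs(sum(cell_types$fraction) - 1) > 1e-8) {
    stop_config("cell type fractions must sum to 1")
  }
  if (!all(groups$mark %in% SIM_MARKS)) {
    stop_config("mark must be one of %s", paste(SIM_MARKS, collapse = ", "))
  }
  if (duplicate_rate < 0 || barcode_error_rate < 0 || barcode_error_rate > 1) {
    stop_config("rates must be valid probabilities")
  }
  n_markers <- length(unique(unlist(cell_types$markers)))
  n_special <- n_markers + n_bivalent + n_k4_only + n_k27_only + n_unmarked_eval +
    k27_type_genes * nrow(cell_types) + 2L * k4_pool_genes
  if (n_special > n_genes) {
    stop_config("n_genes = %d is too small for the planted blocks (need >= %d)",
                n_genes, n_special)
  }
  if (n_transitions > n_bivalent) stop_config("n_transitions cannot exceed n_bivalent")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    n_cells_per_group = as.integer(n_cells_per_group),
    groups = groups, cell_types = cell_types,
    reads_per_cell_rna = as.integer(reads_per_cell_rna),
    fragments_per_cell_dna = as.integer(fragments_per_cell_dna),
    rna_library_sd = rna_library_sd, nb_dispersion = nb_dispersion,
    marker_upweight = marker_upweight,
    barcode_error_rate = barcode_error_rate, duplicate_rate = duplicate_rate,
    adapter_contamination_rate = adapter_contamination_rate,
    polydt_rate = polydt_rate,
    n_bivalent = as.integer(n_bivalent), n_k4_only = as.integer(n_k4_only),
    n_k27_only = as.integer(n_k27_only),
    n_unmarked_eval = as.integer(n_unmarked_eval),
    n_transitions = as.integer(n_transitions),
    k27_type_genes = as.integer(k27_type_genes),
    k4_pool_genes = as.integer(k4_pool_genes),
    n_effect_genes = as.integer(n_effect_genes), effect_lfc = effect_lfc,
    k27_expression_coupling = k27_expression_coupling,
    background_fraction = background_fraction,
    type_signal_fraction = type_signal_fraction,
    planted_bivalency = planted_bivalency,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    n_pcr_indices = as.integer(n_pcr_indices),
    layout = layout, whitelist_seed = as.integer(whitelist_seed)
  ), class = "sim_config")
}

#' Zero-noise variant of a configuration
#'
#' Switches off barcode errors, PCR duplication, adapter contamination and
#' shrinks count dispersion; used by recovery tests that assert exact
#' reconstruction of the planted truth.
#'
#' @param config A [sim_config()].
#' @return The modified configuration.
#' @export
sim_config_zero_noise <- function(config) {
  config$barcode_error_rate <- 0
  config$duplicate_rate <- 0
  config$adapter_contamination_rate <- 0
  config$nb_dispersion <- 0.05
  config
}

# Deterministic gene role plan: which genes are markers, carry planted
# promoter states, belong to type-specific mark sets, or carry an expression
# effect. Roles are assigned to consecutive gene indices; base abundances are
# drawn from a seeded gamma so relative expression is fixed by the seed.
sim_gene_plan <- function(config) {
  n <- config$n_genes
  types <- config$cell_types$name
  markers <- config$cell_types$markers

  gene_id <- sprintf("gene%04d", seq_len(n))
  marker_of <- rep(NA_character_, n)
  i <- 1L
  for (t in seq_along(types)) {
    ids <- markers[[t]]
    idx <- i:(i + length(ids) - 1L)
    gene_id[idx] <- ids
    marker_of[idx] <- types[t]
    i <- i + length(ids)
  }

  state_control <- rep(NA_character_, n)
  state_exposed <- rep(NA_character_, n)
  take <- function(k) { idx <- i:(i + k - 1L); i <<- i + k; idx }
  biv <- take(config$n_bivalent)
  k4 <- take(config$n_k4_only)
  k27 <- take(config$n_k27_only)
  unm <- take(config$n_unmarked_eval)
  state_control[biv] <- "bivalent"; state_exposed[biv] <- "bivalent"
  if (config$n_transitions > 0L) {
    state_exposed[biv[seq_len(config$n_transitions)]] <- "K4-only"
  }
  state_control[k4] <- "K4-only"; state_exposed[k4] <- "K4-only"
  state_control[k27] <- "K27-only"; state_exposed[k27] <- "K27-only"
  state_control[unm] <- "unmarked"; state_exposed[unm] <- "unmarked"

  type_k27 <- rep(NA_character_, n)
  for (t in types) type_k27[take(config$k27_type_genes)] <- t
  # H3K4me1 signal is largely shared across types: one excitatory pool and one
  # pool shared by every other type
  k4_pool <- rep(NA_character_, n)
  k4_pool[take(config$k4_pool_genes)] <- "excitatory"
  k4_pool[take(config$k4_pool_genes)] <- "other"

  if (!is.null(config$planted_bivalency)) {
    pb <- config$planted_bivalency
    state_control[pb$gene_index] <- pb$control
    state_exposed[pb$gene_index] <- pb$exposed
  }

  base_rate <- withr::with_seed(config$seed + 101L, {
    pmax(stats::rgamma(n, shape = 0.5, rate = 1), 0.05)
  })

  expression_lfc <- rep(0, n)
  if (config$n_effect_genes > 0L) {
    cand <- unm[order(base_rate[unm], decreasing = TRUE)]
    if (length(cand) < config$n_effect_genes) {
      stop_config("not enough evaluation genes for n_effect_genes")
    }
    eff <- cand[seq_len(config$n_effect_genes)]
    half <- ceiling(length(eff) / 2)
    expression_lfc[eff[seq_len(half)]] <- config$effect_lfc
    expression_lfc[eff[-seq_len(half)]] <- -config$effect_lfc
  }

  tibble(
    gene_index = seq_len(n), gene_id = gene_id, marker_of = marker_of,
    state_control = state_control, state_exposed = state_exposed,
    type_k27 = type_k27, k4_pool = k4_pool,
    base_rate = base_rate, expression_lfc = expression_lfc
  )
}

state_has_mark <- function(state, mark) {
  if (mark == "H3K4me1") state %in% c("bivalent", "K4-only")
  else state %in% c("bivalent", "K27-only")
}
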