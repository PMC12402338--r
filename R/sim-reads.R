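# Fragment and read emission.
#
# DNA fragments mix three components: a uniform genomic background, promoter
# signal at genes whose planted state carries the simulated mark (shared
# across cell types), and type-specific promoter signal (disjoint gene sets
# per type for H3K27me3; two shared pools - excitatory vs the rest - for
# H3K4me1, emulating its widespread shared-enhancer distribution). RNA
# "fragments" are one record per transcript UMI, placed uniformly inside the
# gene span.

#' Emit deduplicated ground-truth fragments
#'
#' Produces the BED-like fragment records that the alignment stage of a real
#' pipeline would yield, bypassing demultiplexing and mapping. With
#' `with_duplicates = TRUE` each unique molecule gains
#' `k ~ Geometric(1/(1+duplicate_rate))` extra copies.
#'
#' @param sim A `pt_sim` from [simulate_cells()].
#' @param genes Gene models from [sim_genes()].
#' @param modality `"DNA"` or `"RNA"`.
#' @param with_duplicates Inject PCR duplicates at the configured rate.
#' @return A tibble sorted by coordinate with columns `chrom`, `start`, `end`,
#'   `strand`, `mapq`, `cell`, `umi`, `pcr_index`, `modality`, plus truth
#'   columns `cell_id`, `cell_type`, `condition`, `sex`, `mark`, `group`.
#' @export
emit_fragments <- function(sim, genes, modality = c("DNA", "RNA"),
                           with_duplicates = FALSE) {
  modality <- match.arg(modality)
  config <- sim$config
  seed_off <- if (modality == "DNA") 300L else 350L
  frags <- withr::with_seed(config$seed + seed_off, {
    if (modality == "DNA") dna_fragments(sim, genes, config)
    else rna_fragments(sim, genes, config)
  })
  if (with_duplicates && config$duplicate_rate > 0 && nrow(frags)) {
    frags <- withr::with_seed(config$seed + seed_off + 5L, {
      extra <- rgeom(nrow(frags), prob = 1 / (1 + config$duplicate_rate))
      frags[rep(seq_len(nrow(frags)), extra + 1L), ]
    })
  }
  arrange(frags, .data$chrom, .data$start, .data$end)
}

dna_fragments <- function(sim, genes, config) {
  cells <- sim$cells
  plan <- sim$gene_plan
  sizes_all <- config$chromosome_length  # all chromosomes share one length
  fpc <- config$fragments_per_cell_dna
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))

  blocks <- split(seq_len(nrow(cells)),
                  list(cells$mark, cells$condition, cells$cell_type), drop = TRUE)
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    mark <- cells$mark[idx[1]]
    condition <- cells$condition[idx[1]]
    type <- cells$cell_type[idx[1]]
    state <- if (condition == "control") plan$state_control else plan$state_exposed
    shared_set <- which(!is.na(state) & state_has_mark(state, mark))
    type_set <- if (mark == "H3K27me3") {
      which(!is.na(plan$type_k27) & plan$type_k27 == type)
    } else {
      pool <- if (type == "excitatory") "excitatory" else "other"
      which(!is.na(plan$k4_pool) & plan$k4_pool == pool)
    }
    p_bg <- config$background_fraction
    p_type <- unname(config$type_signal_fraction[mark])
    if (!length(type_set)) p_type <- 0
    p_shared <- 1 - p_bg - p_type
    if (!length(shared_set)) { p_bg <- p_bg + p_shared; p_shared <- 0 }

    n <- length(idx) * fpc
    comp <- sample.int(3L, n, replace = TRUE, prob = c(p_bg, p_shared, p_type))
    chrom <- character(n); start <- integer(n)
    is_bg <- comp == 1L
    if (any(is_bg)) {
      chrom[is_bg] <- chrom_names[sample.int(config$n_chromosomes, sum(is_bg),
                                             replace = TRUE)]
      start[is_bg] <- floor(runif(sum(is_bg)) *
                              (sizes_all - config$fragment_length))
    }
    for (ci in 2:3) {
      sel <- comp == ci
      if (!any(sel)) next
      set <- if (ci == 2L) shared_set else type_set
      g <- set[sample.int(length(set), sum(sel), replace = TRUE)]
      tss <- genes$tss[g]
      pos <- tss - 1000L + floor(runif(sum(sel)) * 2000L)
      pos <- pmax(0L, pmin(pos, sizes_all - config$fragment_length))
      chrom[sel] <- genes$chrom[g]
      start[sel] <- pos
    }
    ci_rep <- rep(idx, each = fpc)
    out[[bi]] <- tibble(
      chrom = chrom, start = as.integer(start),
      end = as.integer(start + config$fragment_length),
      strand = "+", mapq = 42L,
      cell = cells$cell_barcode[ci_rep],
      umi = rand_dna(n, config$layout$umi_len),
      pcr_index = cells$pcr_index[ci_rep],
      modality = "DNA",
      cell_id = cells$cell_id[ci_rep], cell_type = cells$cell_type[ci_rep],
      condition = cells$condition[ci_rep], sex = cells$sex[ci_rep],
      mark = cells$mark[ci_rep], group = cells$group[ci_rep]
    )
  }
  bind_rows(out)
}

rna_fragments <- function(sim, genes, config) {
  cells <- sim$cells
  trip <- Matrix::summary(sim$rna_counts)  # i = gene, j = cell, x = count
  trip <- trip[trip$x > 0, , drop = FALSE]
  gi <- rep(trip$i, trip$x)
  ci <- rep(trip$j, trip$x)
  n <- length(gi)
  span <- pmax(genes$end[gi] - genes$start[gi] - config$read_length, 1L)
  start <- genes$start[gi] + floor(runif(n) * span)
  tibble(
    chrom = genes$chrom[gi], start = as.integer(start),
    end = as.integer(start + config$read_length),
    strand = "+", mapq = 42L,
    cell = cells$cell_barcode[ci],
    umi = rand_dna(n, config$layout$umi_len),
    pcr_index = cells$pcr_index[ci],
    modality = "RNA",
    gene_id = genes$gene_id[gi],
    cell_id = cells$cell_id[ci], cell_type = cells$cell_type[ci],
    condition = cells$condition[ci], sex = cells$sex[ci],
    mark = cells$mark[ci], group = cells$group[ci]
  )
}

#' Emit paired FASTQ reads per capture and modality
#'
#' Builds Read 1 (the genomic/cDNA insert, with optional 3' poly-dT tail for
#' RNA and optional adapter read-through) and Read 2 (the barcode cassette
#' with per-read start jitter and per-round barcode substitution errors), and
#' records the exact read-to-cell truth. The PCR sub-library index travels in
#' the read-name comment (`PI:<n>`). PCR duplicates are injected at the
#' configured rate.
#'
#' @param sim A `pt_sim` from [simulate_cells()].
#' @param genes Gene models from [sim_genes()].
#' @param genome The [sim_genome()] the fragments were placed on.
#' @param fragments Optional precomputed fragment tibbles (list with `DNA`,
#'   `RNA`); when `NULL` they are generated, reproducibly, from `sim`.
#' @return A list of runs (one per mark x modality), each with `mark`,
#'   `modality`, `reads` (tibble `name`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   `pcr_index`) and `truth` (read-to-cell map).
#' @export
emit_reads <- function(sim, genes, genome, fragments = NULL) {
  config <- sim$config
  if (is.null(fragments)) {
    fragments <- list(DNA = emit_fragments(sim, genes, "DNA"),
                      RNA = emit_fragments(sim, genes, "RNA"))
  }
  chrom_chars <- lapply(as.character(genome), identity)
  runs <- list()
  for (mark in unique(sim$cells$mark)) {
    for (modality in c("DNA", "RNA")) {
      frags <- fragments[[modality]][fragments[[modality]]$mark == mark, ]
      runs[[paste(mark, modality, sep = "_")]] <-
        withr::with_seed(config$seed + 400L +
                           10L * match(mark, SIM_MARKS) +
                           match(modality, c("DNA", "RNA")), {
          emit_run(frags, mark, modality, chrom_chars, sim, config)
        })
    }
  }
  runs
}

emit_run <- function(frags, mark, modality, chrom_chars, sim, config) {
  # PCR duplication: geometric extra copies per unique molecule
  n0 <- nrow(frags)
  if (config$duplicate_rate > 0 && n0) {
    extra <- rgeom(n0, prob = 1 / (1 + config$duplicate_rate))
    frags <- frags[rep(seq_len(n0), extra + 1L), ]
  }
  n <- nrow(frags)
  insert_len <- if (modality == "DNA") config$fragment_length else config$read_length
  seq1 <- character(n)
  for (ch in unique(frags$chrom)) {
    sel <- frags$chrom == ch
    seq1[sel] <- substr(rep(chrom_chars[[ch]], sum(sel)),
                        frags$start[sel] + 1L, frags$start[sel] + insert_len)
  }
  # poly-dT read-through on RNA
  if (modality == "RNA" && config$polydt_rate > 0) {
    hit <- runif(n) < config$polydt_rate
    if (any(hit)) {
      tl <- sample(10:30, sum(hit), replace = TRUE)
      keep <- nchar(seq1[hit]) - tl
      seq1[hit] <- paste0(substr(seq1[hit], 1L, keep),
                          strrep("T", tl))
    }
  }
  # adapter read-through
  if (config$adapter_contamination_rate > 0) {
    hit <- runif(n) < config$adapter_contamination_rate
    if (any(hit)) {
      len <- nchar(seq1[hit])
      keep <- 40L + floor(runif(sum(hit)) * pmax(len - 60L, 1L))
      pad <- rand_dna_var(pmax(len - keep - nchar(NEXTERA_ADAPTER), 0L))
      seq1[hit] <- substr(paste0(substr(seq1[hit], 1L, keep),
                                 NEXTERA_ADAPTER, pad), 1L, len)
    }
  }
  qual1 <- strrep("F", nchar(seq1))

  # Read 2: [pad][BC3][linker2][BC2][linker1][UMI][BC1][pad]
  lay <- config$layout
  jitter <- sample.int(lay$jitter_max + 1L, n, replace = TRUE) - 1L
  l1 <- lay$bc_len[1]; l2 <- lay$bc_len[2]; l3 <- lay$bc_len[3]
  bc1 <- substr(frags$cell, 1L, l1)
  bc2 <- substr(frags$cell, l1 + 2L, l1 + 1L + l2)
  bc3 <- substr(frags$cell, l1 + l2 + 3L, l1 + l2 + 2L + l3)
  err <- config$barcode_error_rate
  if (err > 0) {
    for (r in 1:3) {
      hit <- runif(n) < err
      if (!any(hit)) next
      v <- list(bc1, bc2, bc3)[[r]]
      v[hit] <- substitute_one_base(v[hit])
      if (r == 1L) bc1 <- v else if (r == 2L) bc2 <- v else bc3 <- v
    }
  }
  pad5 <- rand_dna_var(lay$bc3_window[1] - 1L + jitter)
  core <- paste0(pad5, bc3, lay$linker2, bc2, lay$linker1, frags$umi, bc1)
  pad3 <- rand_dna_var(pmax(lay$read_length - nchar(core), 0L))
  seq2 <- substr(paste0(core, pad3), 1L, lay$read_length)
  qual2 <- strrep("F", nchar(seq2))

  id <- sprintf("%s_%s_rd%07d", mark, modality, seq_len(n))
  tibble_reads <- tibble(
    name = paste0(id, " PI:", frags$pcr_index),
    seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
    pcr_index = frags$pcr_index
  )
  truth <- tibble(read_id = id, cell_id = frags$cell_id,
                  cell_barcode = frags$cell, umi = frags$umi,
                  chrom = frags$chrom, start = frags$start,
                  jitter = jitter)
  list(mark = mark, modality = modality, reads = tibble_reads, truth = truth)
}

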