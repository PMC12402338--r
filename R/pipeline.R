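# End-to-end orchestration on synthetic data: simulate -> emit reads ->
# demultiplex -> locate -> quantify (-> cluster), with an exact per-stage
# count ledger and reproducible outputs.

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a full Paired-Tag experiment from `config`, emits paired FASTQ
#' reads, demultiplexes them, places Read 1 by exact matching on the toy
#' genome, builds and QC-filters the cell-by-gene and cell-by-bin matrices,
#' and (optionally) clusters the joint modalities. Every read is accounted
#' for in the returned ledger: for each capture and modality,
#' `reads_in = linker_not_found + out_of_window + no_match + ambiguous +
#' dropped_length + unaligned + mapq_removed + duplicates_collapsed +
#' pileup_removed + unassigned + in_matrix` exactly, and the matrix totals
#' decompose further into kept counts plus the cell-filter and top-bin-filter
#' losses.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory; when given, fragments, matrices,
#'   reports and the effective configuration (JSON manifest) are written.
#' @param stages Character vector of stages to run after quantification:
#'   any of `"cluster"`.
#' @param qc A [qc_params()].
#' @param bin_size,pileup_cutoff,min_rna,min_dna,top_bin_fraction Quantify
#'   parameters (defaults: 5-kb bins, pileup cutoff 10, cell filters 200/500
#'   nonzero features, top 2% bins removed).
#' @param k,resolution,weight_rna,min_cluster_cells Clustering parameters.
#' @return A list with `sim`, `genes`, `genome`, `matrices` (per mark:
#'   raw/filtered RNA and DNA), `clusters` (per mark, when run), `ledger`
#'   (tibble) and `reports`.
#' @export
run_pipeline <- function(config, outdir = NULL, stages = "cluster",
                         qc = qc_params(), bin_size = 5000L,
                         pileup_cutoff = 10L, min_rna = 200L, min_dna = 500L,
                         top_bin_fraction = 0.02, k = 20L, resolution = 1,
                         weight_rna = 0.5, min_cluster_cells = 50L) {
  genome <- sim_genome(config)
  genes <- sim_genes(genome, config)
  sizes <- genome_sizes(genome)
  sim <- simulate_cells(config)
  runs <- emit_reads(sim, genes, genome)
  reference <- build_barcode_reference(sim$whitelists)

  ledger_rows <- list()
  frag_store <- list()
  reports <- list()
  for (rn in names(runs)) {
    this_run <- runs[[rn]]
    dm <- demux_reads(this_run$reads, reference, config$layout, this_run$modality, qc)
    loc <- locate_reads(dm$reads$seq, genome)
    n_unaligned <- sum(!loc$aligned)
    frags <- bind_cols(
      loc[loc$aligned, c("chrom", "start", "end", "strand", "mapq")],
      dm$reads[loc$aligned, c("cell_barcode", "umi", "pcr_index")]
    ) |> rename(cell = "cell_barcode") |>
      mutate(modality = this_run$modality)
    frag_store[[rn]] <- frags
    st <- setNames(dm$report$reads, dm$report$status)
    ledger_rows[[rn]] <- tibble(
      run = rn, mark = this_run$mark, modality = this_run$modality,
      reads_in = nrow(this_run$reads),
      linker_not_found = unname(st["linker_not_found"] %|0|% 0L),
      out_of_window = unname(st["out_of_window"] %|0|% 0L),
      no_match = unname(st["no_match"] %|0|% 0L),
      ambiguous = unname(st["ambiguous"] %|0|% 0L),
      assigned = unname(st["assigned"] %|0|% 0L),
      dropped_length = unname(st["assigned"] %|0|% 0L) - nrow(dm$reads),
      unaligned = n_unaligned,
      aligned = nrow(frags)
    )
    reports[[rn]] <- dm$report
  }

  matrices <- list()
  clusters <- list()
  extra_rows <- list()
  for (mark in unique(sim$cells$mark)) {
    dna_run <- paste0(mark, "_DNA"); rna_run <- paste0(mark, "_RNA")
    dna <- frag_store[[dna_run]]
    rna <- frag_store[[rna_run]]

    dna1 <- filter_mapq(dna, qc$mapq)
    dna2 <- deduplicate_fragments(dna1)
    dna3 <- remove_high_pileup(dna2, pileup_cutoff)
    rna1 <- deduplicate_fragments(rna)
    cells_union <- sort(union(dna3$cell, rna1$cell))
    bin_m <- build_bin_matrix(dna3, sizes, bin_size, cells = cells_union)
    gene_m <- build_gene_matrix(rna1, genes, cells = cells_union)
    filt <- filter_low_coverage_cells(gene_m, bin_m, min_rna, min_dna)
    dna_f <- filter_top_bins(filt$dna, top_bin_fraction)

    extra_rows[[mark]] <- tibble(
      run = c(dna_run, rna_run), mark = mark, modality = c("DNA", "RNA"),
      mapq_removed = c(nrow(dna) - nrow(dna1), 0L),
      duplicates_collapsed = c(nrow(dna1) - nrow(dna2), nrow(rna) - nrow(rna1)),
      pileup_removed = c(nrow(dna2) - nrow(dna3), 0L),
      unassigned = c(0L, attr(gene_m, "n_unassigned")),
      in_matrix = c(sum(bin_m), sum(gene_m)),
      cell_filtered = c(sum(bin_m) - sum(filt$dna), sum(gene_m) - sum(filt$rna)),
      top_bin_filtered = c(sum(filt$dna) - sum(dna_f), 0),
      final_counts = c(sum(dna_f), sum(filt$rna))
    )
    matrices[[mark]] <- list(
      rna_raw = gene_m, dna_raw = bin_m,
      rna = filt$rna, dna = dna_f,
      removed_cells = filt$removed
    )

    if ("cluster" %in% stages && ncol(filt$rna) > k) {
      rna_norm <- normalize_rna(filt$rna)
      hvg <- select_variable_genes(rna_norm, min(2000L, nrow(rna_norm)))
      emb_rna <- reduce_dims(rna_norm[hvg, , drop = FALSE], "pca",
                             min(30L, ncol(rna_norm) - 1L, length(hvg) - 1L))
      dna_bin <- binarize(dna_f)
      keep_bins <- rowSums(dna_bin) > 0
      emb_dna <- reduce_dims(tfidf(dna_bin[keep_bins, , drop = FALSE]), "lsi",
                             min(30L, ncol(dna_bin) - 1L))
      g_rna <- knn_graph(emb_rna, k = k)
      g_dna <- knn_graph(emb_dna, k = k)
      g <- joint_graph(g_rna, g_dna, weight_rna)
      clusters[[mark]] <- cluster_graph(g, resolution = resolution,
                                        seed = config$seed,
                                        min_cells = min_cluster_cells)
    }
  }

  ledger <- bind_rows(ledger_rows) |>
    left_join(bind_rows(extra_rows),
              by = c("run", "mark", "modality"))

  out <- list(sim = sim, genes = genes, genome = genome, matrices = matrices,
              clusters = clusters, ledger = ledger, reports = reports,
              fragments = frag_store)
  if (!is.null(outdir)) write_pipeline_outputs(out, config, outdir)
  out
}

`%|0|%` <- function(x, default) if (is.na(x)) default else x

#' Check the pipeline count ledger balances exactly
#'
#' @param ledger Ledger tibble from [run_pipeline()].
#' @return `TRUE` invisibly; errors when any run does not balance.
#' @export
check_ledger <- function(ledger) {
  losses <- ledger$linker_not_found + ledger$out_of_window + ledger$no_match +
    ledger$ambiguous + ledger$dropped_length + ledger$unaligned +
    ledger$mapq_removed + ledger$duplicates_collapsed + ledger$pileup_removed +
    ledger$unassigned + ledger$in_matrix
  bad <- which(losses != ledger$reads_in)
  if (length(bad)) {
    stop_input("count ledger does not balance for run(s): %s",
               paste(ledger$run[bad], collapse = ", "))
  }
  bad2 <- which(ledger$in_matrix !=
                  ledger$final_counts + ledger$cell_filtered + ledger$top_bin_filtered)
  if (length(bad2)) {
    stop_input("matrix-filter ledger does not balance for run(s): %s",
               paste(ledger$run[bad2], collapse = ", "))
  }
  invisible(TRUE)
}

write_pipeline_outputs <- function(result, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (rn in names(result$fragments)) {
    write_fragments(result$fragments[[rn]],
                    file.path(outdir, paste0("fragments_", rn, ".tsv.gz")))
  }
  for (mark in names(result$matrices)) {
    m <- result$matrices[[mark]]
    write_count_matrix(m$rna, file.path(outdir, mark), "rna")
    write_count_matrix(m$dna, file.path(outdir, mark), "dna")
    readr::write_tsv(m$removed_cells,
                     file.path(outdir, mark, "removed_cells.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(result$ledger, file.path(outdir, "ledger.tsv"),
                   progress = FALSE)
  for (mark in names(result$clusters)) {
    readr::write_tsv(result$clusters[[mark]],
                     file.path(outdir, paste0("clusters_", mark, ".tsv")),
                     progress = FALSE)
  }
  write_config(config, file.path(outdir, "config.json"))
  manifest <- list(
    package = "pairedtag",
    version = as.character(utils::packageVersion("pairedtag")),
    seed = config$seed,
    runs = result$ledger$run,
    reads_in = result$ledger$reads_in
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}
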