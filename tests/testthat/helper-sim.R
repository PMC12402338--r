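# Shared miniature configurations and brute-force oracles.

# Small but complete experiment: 2 chromosomes x 400 kb, 80 genes, 8 groups x
# 12 cells. Override any sim_config() argument by name.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed, n_chromosomes = 2L, chromosome_length = 400000L,
    n_genes = 80L, n_cells_per_group = 12L,
    n_bivalent = 4L, n_k4_only = 3L, n_k27_only = 3L, n_unmarked_eval = 6L,
    n_transitions = 2L, k27_type_genes = 2L, k4_pool_genes = 2L,
    n_effect_genes = 4L, reads_per_cell_rna = 60L,
    fragments_per_cell_dna = 100L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# larger mid-scale config used by recovery-style tests
recovery_config <- function(seed = 7L, ...) {
  defaults <- list(
    seed = seed, n_chromosomes = 4L, chromosome_length = 2500000L,
    n_genes = 500L, n_cells_per_group = 60L,
    reads_per_cell_rna = 150L, fragments_per_cell_dna = 400L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# brute-force minimum-Hamming assignment of one barcode against a whitelist:
# returns index, 0 (ambiguous at minimal distance <= 1), or NA (no entry
# within distance 1)
brute_resolve <- function(query, whitelist) {
  d <- vapply(whitelist, function(w) {
    sum(strsplit(query, "")[[1]] != strsplit(w, "")[[1]])
  }, 1L)
  dmin <- min(d)
  if (dmin > 1L) return(NA_integer_)
  hits <- which(d == dmin)
  if (length(hits) > 1L) 0L else hits
}

brute_assign_status <- function(bc1, bc2, bc3, whitelists) {
  r <- c(brute_resolve(bc1, whitelists[[1]]),
         brute_resolve(bc2, whitelists[[2]]),
         brute_resolve(bc3, whitelists[[3]]))
  if (anyNA(r)) "no_match" else if (any(r == 0L)) "ambiguous" else "assigned"
}

# dense TF-IDF: feature x cell, entry log(1 + 1e4 * tf * idf)
brute_tfidf <- function(m) {
  m <- as.matrix(m)
  tf <- sweep(m, 2, colSums(m), "/")
  idf <- ncol(m) / rowSums(m > 0)
  log1p(1e4 * tf * idf)
}

# literal BH definition: q_i = min_{j >= i} m p_(j) / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q
}

# random mini fragment tibble
make_frags <- function(n, chrom = "chr1", max_pos = 1000L, cells = c("A", "B"),
                       seed = 1L) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE)
    tibble::tibble(
      chrom = chrom, start = start, end = start + 50L, strand = "+",
      mapq = 42L, cell = sample(cells, n, replace = TRUE),
      umi = pairedtag:::rand_dna(n, 6L),
      pcr_index = sample.int(2L, n, replace = TRUE), modality = "DNA"
    )
  })
}
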