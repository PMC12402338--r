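# From assigned, aligned records to QC-filtered count matrices.
#
# Conventions (documented, configurable where noted):
# * "position" for deduplication and pileup is (chromosome, 5' start, strand);
# * the pileup cutoff is strict-greater: pooled depth > cutoff removes the
#   position;
# * a fragment is assigned to the 5-kb bin containing its 5' start;
# * gene-overlap ties count the record once for each overlapping gene
#   (`ties = "all"`), or drop ambiguous records (`ties = "drop"`).

#' Filter DNA fragments on mapping quality
#'
#' Keeps fragments with `MAPQ > threshold` (strictly greater; the default 10
#' removes MAPQ 10 and keeps MAPQ 11).
#'
#' @param frags Fragment tibble with a `mapq` column.
#' @param threshold Integer threshold.
#' @return The filtered tibble.
#' @export
filter_mapq <- function(frags, threshold = 10L) {
  assert_fragments(frags, c("chrom", "start", "mapq"))
  frags[frags$mapq > threshold, , drop = FALSE]
}

#' Remove PCR duplicates
#'
#' Keeps exactly one representative per (chromosome, 5' start, strand, cell
#' barcode, PCR index, UMI) tuple. Order-independent and idempotent: the
#' representative is the first record in coordinate-then-key order.
#'
#' @param frags Fragment tibble.
#' @return Deduplicated tibble.
#' @export
deduplicate_fragments <- function(frags) {
  assert_fragments(frags)
  if (!"strand" %in% names(frags)) frags$strand <- "+"
  key <- c("chrom", "start", "strand", "cell", "pcr_index", "umi")
  if (anyNA(frags[key])) stop_input("dedup key fields contain missing values")
  frags <- arrange(frags, across(dplyr::all_of(key)))
  frags[!duplicated(frags[key]), , drop = FALSE]
}

#' Remove high-pileup positions
#'
#' Pools fragments over all cells, UMIs and PCR indices per (chromosome,
#' 5' start, strand) position and removes every fragment at positions whose
#' pooled count exceeds `cutoff` (strictly greater: depth 11 is removed at
#' the default cutoff 10, depth 10 is kept).
#'
#' @param frags Fragment tibble (normally already deduplicated).
#' @param cutoff Integer depth cutoff; `Inf` disables the filter.
#' @return The filtered tibble.
#' @export
remove_high_pileup <- function(frags, cutoff = 10L) {
  assert_fragments(frags, c("chrom", "start"))
  if (!nrow(frags) || is.infinite(cutoff)) return(frags)
  if (!"strand" %in% names(frags)) frags$strand <- "+"
  pos <- paste(frags$chrom, frags$start, frags$strand)
  depth <- table(pos)
  bad <- names(depth)[depth > cutoff]
  frags[!(pos %in% bad), , drop = FALSE]
}

bin_labels <- function(chrom, index, bin_size) {
  sprintf("%s:%d-%d", chrom, index * bin_size, (index + 1L) * bin_size)
}

#' Build the cell-by-bin chromatin matrix
#'
#' Tiles every chromosome with fixed non-overlapping bins (5 kb by default)
#' and counts each fragment in the single bin containing its 5' start. The
#' matrix total equals the number of fragments.
#'
#' @param frags Deduplicated, pileup-filtered DNA fragment tibble.
#' @param sizes Chromosome sizes tibble (`chrom`, `length`), e.g. from
#'   [genome_sizes()].
#' @param bin_size Bin width in bp.
#' @param cells Optional character vector fixing the column (cell) universe.
#' @return A sparse `dgCMatrix`, bins x cells, with `feature_kind = "bin"`
#'   attribute.
#' @export
build_bin_matrix <- function(frags, sizes, bin_size = 5000L, cells = NULL) {
  assert_fragments(frags, c("chrom", "start", "cell"))
  if (!all(frags$chrom %in% sizes$chrom)) {
    stop_input("fragments on chromosomes absent from the sizes table")
  }
  len <- setNames(sizes$length, sizes$chrom)
  if (any(frags$start >= len[frags$chrom]) || any(frags$start < 0)) {
    stop_input("fragment start beyond chromosome end")
  }
  n_bins_per <- as.integer(ceiling(sizes$length / bin_size))
  offsets <- setNames(c(0L, cumsum(n_bins_per))[seq_len(nrow(sizes))], sizes$chrom)
  all_bins <- unlist(lapply(seq_len(nrow(sizes)), function(i) {
    bin_labels(sizes$chrom[i], seq_len(n_bins_per[i]) - 1L, bin_size)
  }))
  cells <- cells %||% sort(unique(frags$cell))
  bi <- offsets[frags$chrom] + (frags$start %/% bin_size) + 1L
  ci <- match(frags$cell, cells)
  if (anyNA(ci)) stop_input("fragments from cells outside the given cell universe")
  m <- sparseMatrix(i = bi, j = ci, x = 1,
                    dims = c(length(all_bins), length(cells)),
                    dimnames = list(all_bins, cells))
  attr(m, "feature_kind") <- "bin"
  m
}

#' Build the cell-by-gene RNA matrix
#'
#' A record increments a gene when its interval overlaps the gene span
#' (one UMI = one count). Records overlapping no gene are dropped and counted
#' in the `n_unassigned` attribute. Records overlapping several genes are
#' counted once per overlapping gene (`ties = "all"`, naive union counting)
#' or dropped and counted in `n_ambiguous` (`ties = "drop"`).
#'
#' @param frags Deduplicated RNA record tibble.
#' @param genes Gene models tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param ties Tie rule for multi-gene overlaps.
#' @param cells Optional fixed cell universe.
#' @return A sparse `dgCMatrix`, genes x cells, with attributes
#'   `feature_kind = "gene"`, `n_unassigned` and `n_ambiguous`.
#' @export
build_gene_matrix <- function(frags, genes, ties = c("all", "drop"),
                              cells = NULL) {
  ties <- match.arg(ties)
  assert_fragments(frags, c("chrom", "start", "end", "cell"))
  cells <- cells %||% sort(unique(frags$cell))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L, genes$end))
  gr_frags <- GenomicRanges::GRanges(frags$chrom,
                                     IRanges::IRanges(frags$start + 1L, frags$end))
  hits <- GenomicRanges::findOverlaps(gr_frags, gr_genes, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n_per_frag <- tabulate(qh, nbins = nrow(frags))
  n_unassigned <- sum(n_per_frag == 0L)
  n_ambiguous <- sum(n_per_frag > 1L)
  if (ties == "drop") {
    keep <- n_per_frag[qh] == 1L
    qh <- qh[keep]; sh <- sh[keep]
  }
  ci <- match(frags$cell[qh], cells)
  m <- sparseMatrix(i = sh, j = ci, x = 1,
                    dims = c(nrow(genes), length(cells)),
                    dimnames = list(genes$gene_id, cells))
  attr(m, "feature_kind") <- "gene"
  attr(m, "n_unassigned") <- n_unassigned
  attr(m, "n_ambiguous") <- n_ambiguous
  m
}

#' Remove low-coverage nuclei, keeping matched DNA and RNA profiles
#'
#' A nucleus is kept only if it has at least `min_rna` nonzero RNA features
#' AND at least `min_dna` nonzero DNA bins (the defaults mirror the <200 /
#' <500 removal rule: 199 RNA features is removed, 200 kept). Both matrices
#' are restricted to the surviving, shared cells.
#'
#' @param rna,dna Count matrices (features x cells) sharing a cell identifier
#'   space.
#' @param min_rna,min_dna Minimum nonzero-feature counts.
#' @param what Count `"features"` (nonzero features, default) or `"counts"`
#'   (total molecules) against the thresholds.
#' @return A list `rna`, `dna` (filtered matrices) and `removed` (tibble of
#'   dropped cells with their feature counts).
#' @export
filter_low_coverage_cells <- function(rna, dna, min_rna = 200L, min_dna = 500L,
                                      what = c("features", "counts")) {
  what <- match.arg(what)
  shared <- intersect(colnames(rna), colnames(dna))
  if (!length(shared)) stop_input("RNA and DNA matrices share no cells")
  rna <- rna[, shared, drop = FALSE]
  dna <- dna[, shared, drop = FALSE]
  stat <- function(m) if (what == "features") colSums(m > 0) else colSums(m)
  n_rna <- stat(rna); n_dna <- stat(dna)
  keep <- n_rna >= min_rna & n_dna >= min_dna
  list(
    rna = rna[, keep, drop = FALSE],
    dna = dna[, keep, drop = FALSE],
    removed = tibble(cell = shared[!keep], rna = n_rna[!keep], dna = n_dna[!keep])
  )
}

#' Remove the highest-covered bins
#'
#' Ranks bins by total coverage and removes the top `ceiling(fraction x
#' n_bins)` bins; ties at the boundary are broken by genomic coordinate
#' (earlier bins kept).
#'
#' @param dna Bin matrix (bins x cells).
#' @param fraction Fraction of bins to remove, in `[0, 1)`.
#' @return The matrix without the removed bins.
#' @export
filter_top_bins <- function(dna, fraction = 0.02) {
  if (fraction < 0 || fraction >= 1) stop_config("fraction must be in [0, 1)")
  if (fraction == 0) return(dna)
  totals <- rowSums(dna)
  k <- ceiling(fraction * nrow(dna))
  # order by coverage descending, then by coordinate descending, so that among
  # tied bins the later ones (by row order = genomic coordinate) are removed
  ord <- order(-totals, -seq_along(totals))
  drop_idx <- ord[seq_len(k)]
  dna[-drop_idx, , drop = FALSE]
}

#' Binarize a count matrix
#'
#' @param m A sparse count matrix.
#' @return The same matrix with entries in `{0, 1}`; idempotent.
#' @export
binarize <- function(m) {
  out <- m
  out@x <- as.numeric(out@x > 0)
  out <- drop0(out)
  attr(out, "feature_kind") <- attr(m, "feature_kind")
  out
}
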