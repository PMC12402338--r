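# Gene models and genomic annotation of peaks/bins.
#
# Coordinates are 0-based half-open internally; GTF (1-based closed) is
# converted at the boundary. The promoter is TSS +/- 1 kb; annotation
# precedence is Promoter > 5'UTR > 3'UTR > Exon > Intron > Downstream >
# DistalIntergenic, decided by any-overlap of the peak with the region.

ANNOTATION_CATEGORIES <- c("Promoter", "FivePrimeUTR", "ThreePrimeUTR",
                           "Exon", "Intron", "Downstream", "DistalIntergenic")

#' Read gene models from a GTF file
#'
#' Parses `gene` features (and `exon`/UTR features when present) and converts
#' to 0-based half-open coordinates with a strand-aware TSS (`start` on `+`,
#' `end - 1` on `-`).
#'
#' @param path GTF file path.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, and
#'   a list-column `exons` (tibbles of 0-based exon intervals) when exon
#'   features are present.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop_input("no gene features in %s", path)
  if (any(GenomicRanges::strand(genes) == "*")) {
    stop_input("gene feature(s) without strand in %s", path)
  }
  out <- tibble(
    gene_id = genes$gene_id,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes))
  )
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  exons <- gr[gr$type == "exon"]
  if (length(exons)) {
    ex <- tibble(gene_id = exons$gene_id,
                 start = GenomicRanges::start(exons) - 1L,
                 end = GenomicRanges::end(exons))
    out$exons <- purrr::map(out$gene_id, function(g) {
      ex[ex$gene_id == g, c("start", "end")]
    })
  }
  out
}

#' Write gene models to GTF
#'
#' Emits one `gene` feature per row (1-based closed coordinates).
#'
#' @param genes Gene models tibble.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "pairedtag"
  gr$gene_id <- genes$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Promoter windows around each TSS
#'
#' `[TSS - up, TSS + down)` in 0-based half-open coordinates (strand-agnostic
#' arithmetic on the TSS position), clipped at chromosome bounds when sizes
#' are given.
#'
#' @param genes Gene models tibble.
#' @param up,down Extension upstream/downstream of the TSS coordinate in bp.
#' @param sizes Optional chromosome sizes tibble for clipping.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_windows <- function(genes, up = 1000L, down = 1000L, sizes = NULL) {
  out <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                start = genes$tss - up, end = genes$tss + down)
  out$start <- pmax(out$start, 0L)
  if (!is.null(sizes)) {
    len <- setNames(sizes$length, sizes$chrom)
    out$end <- pmin(out$end, unname(len[out$chrom]))
  }
  out
}

#' Annotate peaks with genic categories
#'
#' Each peak gets exactly one category by precedence (Promoter > 5'UTR >
#' 3'UTR > Exon > Intron > Downstream > DistalIntergenic), where membership
#' means any overlap of the peak with the corresponding region of any gene:
#' Promoter is TSS +/- the given window; Exon/Intron come from the gene span
#' (and exon models when available); Downstream extends `downstream_limit` bp
#' past the gene 3' end. The nearest gene (by TSS) and the signed
#' center-to-TSS distance (positive downstream of the TSS in gene
#' orientation) are attached; nearest-gene ties break by gene id.
#'
#' @param peaks Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param genes Gene models tibble (optionally with an `exons` list-column).
#' @param promoter_up,promoter_down Promoter window around the TSS in bp.
#' @param downstream_limit Downstream region size in bp.
#' @return `peaks` with `category`, `nearest_gene`, `dist_to_tss` columns.
#' @export
annotate_peaks <- function(peaks, genes, promoter_up = 1000L,
                           promoter_down = 1000L, downstream_limit = 3000L) {
  if (!all(peaks$chrom %in% genes$chrom)) {
    stop_input("peak(s) on chromosome(s) with no gene model: %s",
               paste(setdiff(peaks$chrom, genes$chrom), collapse = ", "))
  }
  gp <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  overlaps_any <- function(region_start, region_end, region_chrom) {
    keep <- region_end > region_start
    gr <- GenomicRanges::GRanges(region_chrom[keep],
                                 IRanges::IRanges(region_start[keep] + 1L,
                                                  region_end[keep]))
    GenomicRanges::countOverlaps(gp, gr, ignore.strand = TRUE) > 0
  }
  # inclusive TSS +/- window (2001 bp at the defaults): symmetric around the
  # TSS base, so annotation is invariant under coordinate reflection
  prom <- overlaps_any(genes$tss - promoter_up, genes$tss + promoter_down + 1L,
                       genes$chrom)
  has_exons <- "exons" %in% names(genes)
  if (has_exons) {
    ex <- bind_rows(purrr::map2(genes$exons, genes$chrom, function(e, ch) {
      if (is.null(e) || !nrow(e)) return(NULL)
      tibble(chrom = ch, start = e$start, end = e$end)
    }))
    exon <- if (nrow(ex)) overlaps_any(ex$start, ex$end, ex$chrom)
    else rep(FALSE, nrow(peaks))
  } else {
    # without exon models the whole gene span counts as exonic
    exon <- overlaps_any(genes$start, genes$end, genes$chrom)
  }
  genic <- overlaps_any(genes$start, genes$end, genes$chrom)
  intron <- genic & !exon
  down_start <- ifelse(genes$strand == "+", genes$end, genes$start - downstream_limit)
  down_end <- ifelse(genes$strand == "+", genes$end + downstream_limit, genes$start)
  downstream <- overlaps_any(pmax(down_start, 0L), down_end, genes$chrom)

  category <- rep("DistalIntergenic", nrow(peaks))
  category[downstream] <- "Downstream"
  category[intron] <- "Intron"
  category[exon & genic] <- "Exon"
  category[prom] <- "Promoter"

  # nearest gene by |center - TSS|, ties by gene id
  center <- (peaks$start + peaks$end) / 2
  ord <- order(genes$gene_id)
  nearest_gene <- character(nrow(peaks))
  dist_to_tss <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    gi <- ord[genes$chrom[ord] == ch]
    pi <- which(peaks$chrom == ch)
    d <- abs(outer(center[pi], genes$tss[gi], "-"))
    best <- apply(d, 1, which.min)
    nearest_gene[pi] <- genes$gene_id[gi][best]
    signed <- center[pi] - genes$tss[gi][best]
    flip <- genes$strand[gi][best] == "-"
    dist_to_tss[pi] <- ifelse(flip, -signed, signed)
  }
  mutate(peaks, category = factor(category, ANNOTATION_CATEGORIES),
         nearest_gene = nearest_gene, dist_to_tss = dist_to_tss)
}

#' Summarize annotation categories
#'
#' @param annotated Tibble from [annotate_peaks()].
#' @return A tibble `category`, `n`, `fraction` (fractions sum to 1).
#' @export
summarize_annotation <- function(annotated) {
  if (!nrow(annotated)) stop_input("no annotated peaks")
  annotated |>
    count(.data$category, name = "n", .drop = FALSE) |>
    mutate(fraction = .data$n / sum(.data$n))
}

#' Convert significant differential bins to peak intervals
#'
#' Parses `chrom:start-end` bin labels back into a peaks tibble.
#'
#' @param features Character vector of bin labels.
#' @return A tibble `chrom`, `start`, `end`.
#' @export
bins_to_peaks <- function(features) {
  m <- stringr::str_match(features, "^(.+):(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) stop_input("feature labels are not bin intervals")
  tibble(chrom = m[, 2], start = as.integer(m[, 3]), end = as.integer(m[, 4]))
}
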