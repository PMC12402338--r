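# Fragment filtering, deduplication and matrix construction.

test_that("MAPQ filter is strict-greater and commutes with deduplication", {
  fr <- make_frags(200L)
  fr$mapq <- rep(c(9L, 10L, 11L, 42L), 50L)
  kept <- filter_mapq(fr, 10L)
  expect_setequal(unique(kept$mapq), c(11L, 42L))
  expect_equal(nrow(filter_mapq(fr, 0L)), 200L)
  expect_equal(nrow(filter_mapq(fr[0, ], 10L)), 0L)
  # commutation with dedup
  a <- deduplicate_fragments(filter_mapq(fr, 10L))
  b <- filter_mapq(deduplicate_fragments(fr), 10L)
  expect_identical(dplyr::arrange(a, dplyr::across(dplyr::everything())),
                   dplyr::arrange(b, dplyr::across(dplyr::everything())))
})

test_that("deduplication keys on position+barcode+PCR index+UMI and is idempotent", {
  one <- tibble::tibble(chrom = "chr1", start = 100L, end = 150L, strand = "+",
                        mapq = 42L, cell = "A", umi = "ACGTAC", pcr_index = 1L,
                        modality = "DNA")
  five <- one[rep(1, 5), ]
  expect_equal(nrow(deduplicate_fragments(five)), 1L)
  # different UMI at the same position/cell/index -> both kept
  two <- dplyr::bind_rows(one, dplyr::mutate(one, umi = "TTTTTT"))
  expect_equal(nrow(deduplicate_fragments(two)), 2L)
  # order invariance and idempotence
  fr <- make_frags(500L, max_pos = 50L, seed = 4L)
  d1 <- deduplicate_fragments(fr)
  d2 <- deduplicate_fragments(fr[sample.int(nrow(fr)), ])
  expect_identical(d1, d2)
  expect_identical(deduplicate_fragments(d1), d1)
  expect_error(deduplicate_fragments(dplyr::mutate(fr, umi = NA_character_)),
               class = "pairedtag_input_error")
})

test_that("high-pileup removal pools over cells and is strict-greater", {
  base <- tibble::tibble(chrom = "chr1", start = 0L, end = 50L, strand = "+",
                         mapq = 42L, cell = "A", umi = "AAAAAA", pcr_index = 1L,
                         modality = "DNA")
  mk <- function(pos, n) {
    out <- base[rep(1, n), ]
    out$start <- pos
    out$umi <- pairedtag:::rand_dna(n, 6L)
    out$cell <- sample(c("A", "B"), n, replace = TRUE)
    out
  }
  withr::with_seed(1L, {
    fr <- dplyr::bind_rows(mk(100L, 11L), mk(200L, 10L), mk(300L, 1L))
  })
  out <- remove_high_pileup(fr, 10L)
  expect_setequal(unique(out$start), c(200L, 300L))
  expect_equal(nrow(out), 11L)
  expect_identical(remove_high_pileup(fr, Inf), fr)
  expect_equal(nrow(remove_high_pileup(mk(1L, 1L), 10L)), 1L)
})

test_that("bin matrix assigns by 5' start with half-open boundaries", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(20000L, 10000L))
  fr <- make_frags(1L)[0, ]
  mk <- function(chrom, start, cell) tibble::tibble(
    chrom = chrom, start = start, end = start + 50L, strand = "+", mapq = 42L,
    cell = cell, umi = "AAAAAA", pcr_index = 1L, modality = "DNA")
  fr <- dplyr::bind_rows(mk("chr1", 4999L, "A"), mk("chr1", 5000L, "A"),
                         mk("chr2", 1L, "B"))
  m <- build_bin_matrix(fr, sizes, 5000L)
  expect_equal(sum(m), nrow(fr))
  expect_equal(unname(m["chr1:0-5000", "A"]), 1)
  expect_equal(unname(m["chr1:5000-10000", "A"]), 1)
  expect_equal(unname(m["chr2:0-5000", "B"]), 1)
  # bins tile without gaps: total bins = ceiling(length / bin)
  expect_equal(nrow(m), 4L + 2L)
  expect_error(build_bin_matrix(mk("chr1", 20001L, "A"), sizes, 5000L),
               class = "pairedtag_input_error")
  # conservation per cell
  fr2 <- make_frags(300L, max_pos = 19000L, seed = 9L)
  m2 <- build_bin_matrix(fr2, sizes, 5000L)
  expect_equal(unname(Matrix::colSums(m2)[sort(unique(fr2$cell))]),
               as.numeric(table(fr2$cell)))
})

test_that("gene matrix counts overlaps and matches a brute-force interval scan", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = c("chr1", "chr1", "chr1"),
    start = c(1000L, 1400L, 5000L), end = c(1500L, 2000L, 6000L),
    strand = "+", tss = c(1000L, 1400L, 5000L))
  withr::with_seed(21L, {
    n <- 400L
    start <- sample.int(8000L, n, replace = TRUE)
    fr <- tibble::tibble(chrom = "chr1", start = start, end = start + 100L,
                         strand = "+", mapq = 42L,
                         cell = sample(c("A", "B"), n, TRUE),
                         umi = pairedtag:::rand_dna(n, 6L), pcr_index = 1L,
                         modality = "RNA")
  })
  m <- build_gene_matrix(fr, genes, ties = "all")
  # brute force: count each (fragment, gene) overlap
  brute <- matrix(0, 3, 2, dimnames = list(genes$gene_id, c("A", "B")))
  for (i in seq_len(nrow(fr))) {
    for (g in seq_len(3)) {
      if (fr$start[i] < genes$end[g] && fr$end[i] > genes$start[g]) {
        brute[g, fr$cell[i]] <- brute[g, fr$cell[i]] + 1
      }
    }
  }
  expect_equal(as.matrix(m), brute)
  # unassigned records are counted
  in_any <- vapply(seq_len(nrow(fr)), function(i) {
    any(fr$start[i] < genes$end & fr$end[i] > genes$start)
  }, TRUE)
  expect_equal(attr(m, "n_unassigned"), sum(!in_any))
  # ties = "drop" removes multi-gene records
  md <- build_gene_matrix(fr, genes, ties = "drop")
  multi <- vapply(seq_len(nrow(fr)), function(i) {
    sum(fr$start[i] < genes$end & fr$end[i] > genes$start) > 1L
  }, TRUE)
  expect_equal(sum(m) - sum(md), sum(multi) * 2L)
})

test_that("low-coverage cell filter keeps matched profiles at exact boundaries", {
  mk <- function(nfeat, total_feat, cell) {
    Matrix::sparseMatrix(i = seq_len(nfeat), j = rep(1L, nfeat), x = 1,
                         dims = c(total_feat, 1L),
                         dimnames = list(NULL, cell))
  }
  rna <- cbind(mk(199L, 600L, "c1"), mk(200L, 600L, "c2"), mk(300L, 600L, "c3"))
  dna <- cbind(mk(500L, 600L, "c1"), mk(500L, 600L, "c2"), mk(499L, 600L, "c3"))
  out <- filter_low_coverage_cells(rna, dna)
  expect_equal(colnames(out$rna), "c2")   # c1 fails RNA 199<200, c3 fails DNA 499<500
  expect_equal(colnames(out$dna), "c2")
  expect_setequal(out$removed$cell, c("c1", "c3"))
  # all-pass identity
  out2 <- filter_low_coverage_cells(rna, dna, min_rna = 1L, min_dna = 1L)
  expect_equal(ncol(out2$rna), 3L)
  expect_error(filter_low_coverage_cells(rna,
                                         `colnames<-`(dna, c("x", "y", "z"))),
               class = "pairedtag_input_error")
})

test_that("top-bin filter matches a brute-force sort with coordinate tie-break", {
  withr::with_seed(31L, {
    m <- Matrix::rsparsematrix(100, 8, density = 0.4,
                               rand.x = function(n) rpois(n, 4) + 1)
    rownames(m) <- sprintf("chr1:%d-%d", (0:99) * 5000L, (1:100) * 5000L)
    colnames(m) <- paste0("c", 1:8)
  })
  out <- filter_top_bins(m, 0.02)
  expect_equal(nrow(out), 98L)
  tot <- Matrix::rowSums(m)
  worst2 <- order(-tot, -seq_along(tot))[1:2]
  expect_setequal(setdiff(rownames(m), rownames(out)), rownames(m)[worst2])
  expect_identical(filter_top_bins(m, 0), m)
  # all-equal coverage: the last ceil(f n) bins by coordinate are removed
  eq <- m; eq@x <- rep(1, length(eq@x))
  eq <- eq * 0 + 1  # dense ones -> make every bin total equal
  eq <- as(eq, "CsparseMatrix")
  oute <- filter_top_bins(eq, 0.02)
  expect_equal(setdiff(rownames(eq), rownames(oute)),
               rownames(eq)[99:100])
  expect_error(filter_top_bins(m, 1), class = "pairedtag_config_error")
})

test_that("binarize is idempotent and preserves structure", {
  withr::with_seed(5L, m <- Matrix::rsparsematrix(30, 5, density = 0.3,
                                                  rand.x = function(n) rpois(n, 3)))
  b <- binarize(m)
  expect_true(all(b@x == 1))
  expect_identical(as.matrix(binarize(b)), as.matrix(b))
  expect_equal(as.matrix(b), (as.matrix(m) > 0) * 1,
               ignore_attr = TRUE)
})

test_that("zero-noise simulation: per-cell bin totals equal truth totals", {
  cfg <- sim_config_zero_noise(tiny_config())
  genome <- sim_genome(cfg)
  genes <- sim_genes(genome, cfg)
  sim <- simulate_cells(cfg)
  frags <- emit_fragments(sim, genes, "DNA")
  f <- frags[frags$mark == "H3K4me1", ]
  dedup <- deduplicate_fragments(f)
  expect_equal(nrow(dedup), nrow(f))  # no duplicates at zero noise
  m <- build_bin_matrix(f, genome_sizes(genome))
  truth_tot <- table(f$cell)
  expect_equal(unname(Matrix::colSums(m)[names(truth_tot)]),
               as.numeric(truth_tot))
})
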