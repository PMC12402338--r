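# Promoter signal, TSS profiles, bivalency calls, transitions, correlations.

test_that("promoter signal normalizations follow the closed forms", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 10000L,
                          end = 12000L, strand = "+", tss = 10000L)
  mk <- function(starts) tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 50L, strand = "+",
    mapq = 42L, cell = "A", umi = "AAAAAA", pcr_index = 1L, modality = "DNA")
  # 10 promoter fragments among a given total
  withr::with_seed(1L, {
    inside <- sample(9000:10999, 10L)
    outside <- sample(100000:200000, 90L) %% 90000L + 50000L
  })
  frags <- mk(c(inside, outside))
  sig <- promoter_signal(frags, genes)
  expect_equal(sig$count, 10L)
  expect_equal(sig$rpm, 10 / 100 * 1e6)
  # FPKM: count / (window kb x total millions) = 10 / (2 x 1e-4) = 5e4
  expect_equal(sig$fpkm, 10 / (2 * (100 / 1e6)))
  # boundary: half-open [TSS-1000, TSS+1000)
  expect_equal(promoter_signal(mk(9000L), genes)$count, 1L)
  expect_equal(promoter_signal(mk(8999L), genes)$count, 0L)
  expect_equal(promoter_signal(mk(10999L), genes)$count, 1L)
  expect_equal(promoter_signal(mk(11000L), genes)$count, 0L)
  # uniform duplication leaves RPM unchanged
  sig2 <- promoter_signal(frags[rep(seq_len(nrow(frags)), each = 3), ], genes)
  expect_equal(sig2$rpm, sig$rpm)
  expect_error(promoter_signal(frags[0, ], genes),
               class = "pairedtag_input_error")
})

test_that("TSS profiles conserve counts, flip minus strands, localize spikes", {
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(10000L, 50000L), end = c(12000L, 52000L),
    strand = c("+", "-"), tss = c(10000L, 51999L))
  mk <- function(starts) tibble::tibble(
    chrom = "chr1", start = starts, end = starts + 50L, strand = "+",
    mapq = 42L, cell = "A", umi = "AAAAAA", pcr_index = 1L, modality = "DNA")
  # spike at +500 (+/- 25) downstream of the plus-strand TSS
  withr::with_seed(2L, spike <- 10000L + 500L + sample(-25:24, 200L, TRUE))
  prof <- tss_profile(mk(spike), genes)
  expect_s3_class(autoplot(prof), "ggplot")
  expect_equal(sum(prof$matrix["plus", ]), 200L)
  hot <- as.integer(colnames(prof$matrix)[prof$matrix["plus", ] > 0])
  expect_true(all(hot %in% c(450L, 500L)))
  # conservation against promoter_signal for random fragments
  withr::with_seed(3L, rnd <- mk(sample(9000:11050, 500L, TRUE)))
  prof2 <- tss_profile(rnd, genes)
  expect_equal(sum(prof2$matrix["plus", ]),
               promoter_signal(rnd, genes)$count[1])
  # minus-strand gene: fragments genomically LEFT of its TSS are downstream,
  # so a spike at tss - 300 appears at positive grid positions
  withr::with_seed(4L, mspike <- 51999L - 300L + sample(-10:9, 100L, TRUE))
  prof3 <- tss_profile(mk(mspike), genes)
  hot3 <- as.integer(colnames(prof3$matrix)[prof3$matrix["minus", ] > 0])
  expect_true(all(hot3 >= 250L & hot3 <= 300L))
  # uniform placement gives a flat profile
  withr::with_seed(5L, unif <- mk(sample(9000:10999, 10000L, TRUE)))
  prof4 <- tss_profile(unif, genes)
  m <- prof4$matrix["plus", ]
  expect_lt(max(m) / min(m), 1.5)
  expect_error(tss_profile(rnd, genes, step = 33L),
               class = "pairedtag_config_error")
})

test_that("bivalency states and transitions recover the planted truth", {
  cfg <- sim_config_zero_noise(tiny_config(n_cells_per_group = 40L))
  genome <- sim_genome(cfg); genes <- sim_genes(genome, cfg)
  sizes <- genome_sizes(genome)
  sim <- simulate_cells(cfg)
  frags <- emit_fragments(sim, genes, "DNA")
  bg <- background_windows(genes, sizes, n = 100L, seed = 17L)
  plan <- sim$gene_plan
  eval_genes <- genes[genes$gene_id %in%
                        plan$gene_id[!is.na(plan$state_control)], ]
  calls <- list()
  for (cond in c("control", "exposed")) {
    sg <- function(mk) frags[frags$mark == mk & frags$condition == cond, ]
    k4 <- promoter_signal(sg("H3K4me1"), eval_genes)
    k27 <- promoter_signal(sg("H3K27me3"), eval_genes)
    calls[[cond]] <- call_bivalency(k4, k27,
                                    promoter_signal(sg("H3K4me1"), bg),
                                    promoter_signal(sg("H3K27me3"), bg))
  }
  truth_col <- function(cond) {
    s <- if (cond == "control") plan$state_control else plan$state_exposed
    s[match(eval_genes$gene_id, plan$gene_id)]
  }
  # exact recovery at zero noise
  expect_identical(as.character(calls$control$state), truth_col("control"))
  expect_identical(as.character(calls$exposed$state), truth_col("exposed"))
  # transitions: planted bivalent -> K4-only genes labelled "K27 resolved"
  tr <- call_transitions(calls$control, calls$exposed)
  planted <- plan$gene_id[!is.na(plan$state_control) &
                            plan$state_control == "bivalent" &
                            plan$state_exposed == "K4-only"]
  expect_true(all(tr$transition[tr$gene_id %in% planted] == "K27 resolved"))
  expect_true(all(tr$transition[!(tr$gene_id %in% planted)] == "stable"))
  # recorded thresholds make calls recomputable
  thr <- attr(calls$control, "thresholds")
  expect_identical(calls$control$state,
                   factor(dplyr::case_when(
                     calls$control$k4_rpm >= thr["k4"] &
                       calls$control$k27_rpm >= thr["k27"] ~ "bivalent",
                     calls$control$k4_rpm >= thr["k4"] ~ "K4-only",
                     calls$control$k27_rpm >= thr["k27"] ~ "K27-only",
                     .default = "unmarked"),
                     levels(calls$control$state)))
})

test_that("transition labels are a pure function of the state pair", {
  mk_calls <- function(states) {
    tibble::tibble(gene_id = paste0("g", seq_along(states)),
                   k4_rpm = 0, k27_rpm = 0,
                   state = factor(states, c("bivalent", "K4-only",
                                            "K27-only", "unmarked")))
  }
  tr <- call_transitions(
    mk_calls(c("bivalent", "bivalent", "K4-only", "unmarked")),
    mk_calls(c("K4-only", "bivalent", "bivalent", "K27-only")))
  expect_equal(tr$transition,
               c("K27 resolved", "stable", "K27 gained", "unmarked->K27-only"))
  expect_error(call_transitions(mk_calls("bivalent"),
                                mk_calls(c("bivalent", "unmarked"))),
               class = "pairedtag_input_error")
})

test_that("Pearson correlation matches cor.test to 1e-12", {
  withr::with_seed(29L, {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  })
  got <- correlate_signal_expression(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(got$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(correlate_signal_expression(x, -x)$estimate, -1)
  expect_error(correlate_signal_expression(x, rep(1, 50)),
               class = "pairedtag_input_error")
  expect_error(correlate_signal_expression(1:2, 2:1),
               class = "pairedtag_input_error")
})

test_that("null correlation p-values are uniform (KS check)", {
  withr::with_seed(31L, {
    ps <- replicate(400, {
      correlate_signal_expression(rnorm(40), rnorm(40))$p_value
    })
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("group signal comparison is symmetric with correct conventions", {
  expect_equal(compare_group_signal(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  withr::with_seed(37L, {
    up <- rnorm(30, 5); down <- rnorm(30, 0)   # 5 SD apart
  })
  res <- compare_group_signal(up, down)
  expect_lt(res$p_value, 0.001)
  expect_equal(compare_group_signal(down, up)$p_value, res$p_value)
  rest <- compare_group_signal(up, down, method = "t")
  expect_lt(rest$p_value, 0.001)
  expect_error(compare_group_signal(1, 1:5), class = "pairedtag_input_error")
})
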