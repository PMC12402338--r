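# Promoter signal quantification, metagene TSS profiles, bivalency states,
# transitions, and signal-expression correlation.
#
# A fragment belongs to a promoter when its 5' start lies in
# [TSS - window, TSS + window) (half-open, so the 50-bp profile grid tiles the
# window exactly and profile totals equal the promoter counts). RPM =
# count / total mapped fragments x 1e6; FPKM additionally divides by the
# window length in kb.

#' Promoter signal per gene
#'
#' Counts fragments whose 5' start falls in the promoter window of each gene
#' and attaches RPM and FPKM normalizations computed against the group's
#' total fragment count.
#'
#' @param frags Deduplicated fragment tibble for one group/mark (the group
#'   total is `nrow(frags)`).
#' @param genes Gene models tibble.
#' @param window Promoter half-width in bp (default 1000).
#' @return A tibble `gene_id`, `count`, `rpm`, `fpkm` (one row per gene).
#' @export
promoter_signal <- function(frags, genes, window = 1000L) {
  total <- nrow(frags)
  if (!total) stop_input("group has zero total fragments")
  counts <- count_in_windows(frags, genes$chrom, genes$tss - window,
                             genes$tss + window)
  tibble(
    gene_id = genes$gene_id,
    count = counts,
    rpm = counts / total * 1e6,
    fpkm = counts / ((2 * window / 1000) * (total / 1e6))
  )
}

count_in_windows <- function(frags, chrom, start, end) {
  n <- length(chrom)
  counts <- integer(n)
  for (ch in unique(chrom)) {
    wi <- which(chrom == ch)
    fs <- sort(frags$start[frags$chrom == ch])
    if (!length(fs)) next
    # half-open [start, end): starts strictly below `end`, at or above `start`
    counts[wi] <- findInterval(end[wi] - 1L, fs) -
      findInterval(start[wi] - 1L, fs)
  }
  counts
}

#' Metagene profile around the TSS
#'
#' Bins fragment 5' starts into a fixed grid over `[TSS - window,
#' TSS + window)`; minus-strand genes are flipped so positive grid positions
#' are downstream of the TSS in gene orientation. The aggregate curve is the
#' unweighted per-position mean over genes; each gene's profile sums to its
#' [promoter_signal()] count.
#'
#' @param frags Fragment tibble.
#' @param genes Gene models tibble.
#' @param window Half-width in bp.
#' @param step Grid step in bp; must divide `2 * window`.
#' @return A `tss_profile`: list with `matrix` (genes x positions), `position`
#'   (bin left edges relative to the TSS), `mean` curve.
#' @export
tss_profile <- function(frags, genes, window = 1000L, step = 50L) {
  if ((2L * window) %% step != 0L) {
    stop_config("step (%d) must divide the window width (%d)", step, 2L * window)
  }
  n_bins <- (2L * window) %/% step
  pos <- seq(-window, window - step, by = step)
  mat <- matrix(0L, nrow(genes), n_bins,
                dimnames = list(genes$gene_id, pos))
  by_chrom <- split(frags$start, frags$chrom)
  by_chrom <- lapply(by_chrom, sort)
  for (gi in seq_len(nrow(genes))) {
    fs <- by_chrom[[genes$chrom[gi]]]
    if (is.null(fs)) next
    edges <- genes$tss[gi] - window + step * (0:n_bins)
    binned <- diff(findInterval(edges - 1L, fs))
    if (genes$strand[gi] == "-") binned <- rev(binned)
    mat[gi, ] <- binned
  }
  structure(list(matrix = mat, position = pos, mean = colMeans(mat)),
            class = "tss_profile")
}

#' Sample background windows away from promoters
#'
#' Draws random fixed-width intervals that do not intersect any promoter
#' window; used to set the mark-presence threshold for bivalency calls.
#'
#' @param genes Gene models tibble.
#' @param sizes Chromosome sizes tibble.
#' @param n Number of windows.
#' @param width Window width in bp (default the 2-kb promoter width).
#' @param seed Integer seed.
#' @param exclusion Half-width around each TSS to avoid (default 2000 bp).
#' @return A tibble `gene_id` (synthetic window ids), `chrom`, `start`,
#'   `end`, `strand`, `tss` - shaped like gene models so the signal machinery
#'   applies unchanged.
#' @export
background_windows <- function(genes, sizes, n = 200L, width = 2000L,
                               seed = 1L, exclusion = 2000L) {
  withr::with_seed(seed, {
    out <- vector("list", 0)
    got <- 0L
    while (got < n) {
      k <- (n - got) * 2L
      ci <- sample.int(nrow(sizes), k, replace = TRUE,
                       prob = sizes$length)
      start <- floor(runif(k) * (sizes$length[ci] - width))
      cand <- tibble(chrom = sizes$chrom[ci], start = as.integer(start),
                     end = as.integer(start + width))
      bad <- purrr::map_lgl(seq_len(k), function(i) {
        any(genes$chrom == cand$chrom[i] &
              abs(genes$tss - (cand$start[i] + width / 2)) <
                (exclusion + width / 2))
      })
      cand <- cand[!bad, ]
      out[[length(out) + 1L]] <- cand
      got <- got + nrow(cand)
    }
    win <- head(bind_rows(out), n)
    win$gene_id <- sprintf("bg%04d", seq_len(n))
    win$strand <- "+"
    win$tss <- as.integer(win$start + width / 2)
    win[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
  })
}

#' Call per-gene promoter bivalency states
#'
#' A mark is "present" at a promoter when its RPM is at least
#' `min_fold x quantile(background RPM, bg_quantile)`. States:
#' both marks present = `bivalent`, H3K4me1 only = `K4-only`, H3K27me3 only =
#' `K27-only`, neither = `unmarked`. The thresholds used are recorded in the
#' `thresholds` attribute so calls are recomputable.
#'
#' @param k4,k27 [promoter_signal()] tibbles for the two marks over the same
#'   genes.
#' @param k4_background,k27_background [promoter_signal()] tibbles evaluated
#'   on [background_windows()].
#' @param bg_quantile Background quantile anchoring the threshold.
#' @param min_fold Multiplicative margin above the background quantile
#'   (default 2; 1 reduces to the plain background percentile).
#' @return A tibble `gene_id`, `k4_rpm`, `k27_rpm`, `state`.
#' @export
call_bivalency <- function(k4, k27, k4_background, k27_background,
                           bg_quantile = 0.95, min_fold = 2) {
  if (!identical(k4$gene_id, k27$gene_id)) {
    stop_input("the two marks cover different gene sets")
  }
  thr_k4 <- min_fold * quantile(k4_background$rpm, bg_quantile, names = FALSE)
  thr_k27 <- min_fold * quantile(k27_background$rpm, bg_quantile, names = FALSE)
  has_k4 <- k4$rpm >= thr_k4
  has_k27 <- k27$rpm >= thr_k27
  state <- dplyr::case_when(
    has_k4 & has_k27 ~ "bivalent",
    has_k4 ~ "K4-only",
    has_k27 ~ "K27-only",
    .default = "unmarked"
  )
  out <- tibble(gene_id = k4$gene_id, k4_rpm = k4$rpm, k27_rpm = k27$rpm,
                state = factor(state, BIVALENCY_STATES))
  attr(out, "thresholds") <- c(k4 = thr_k4, k27 = thr_k27)
  out
}

TRANSITION_LABELS <- c(
  "bivalent->K4-only" = "K27 resolved",
  "bivalent->K27-only" = "K4 lost",
  "bivalent->unmarked" = "both lost",
  "K4-only->bivalent" = "K27 gained",
  "K27-only->bivalent" = "K4 gained",
  "unmarked->bivalent" = "both gained"
)

#' Label promoter state transitions between conditions
#'
#' Pure state-pair labelling; unchanged states are `stable`, the named
#' transitions get descriptive labels (e.g. bivalent to K4-only is
#' "K27 resolved"), all others are `from->to`.
#'
#' @param control_calls,exposed_calls [call_bivalency()] tibbles over the
#'   same genes.
#' @return A tibble `gene_id`, `control`, `exposed`, `transition`.
#' @export
call_transitions <- function(control_calls, exposed_calls) {
  if (!identical(control_calls$gene_id, exposed_calls$gene_id)) {
    stop_input("condition calls cover different gene sets")
  }
  from <- as.character(control_calls$state)
  to <- as.character(exposed_calls$state)
  key <- paste0(from, "->", to)
  label <- if_else(from == to, "stable",
                   dplyr::coalesce(unname(TRANSITION_LABELS[key]), key))
  tibble(gene_id = control_calls$gene_id, control = control_calls$state,
         exposed = exposed_calls$state, transition = label)
}

#' Pearson correlation between promoter signal and expression
#'
#' Closed-form Pearson r with the t-based two-sided p-value.
#'
#' @param signal,expression Paired numeric vectors (n >= 3).
#' @return A tibble with `estimate`, `statistic`, `p_value`, `n`.
#' @export
correlate_signal_expression <- function(signal, expression) {
  ok <- complete.cases(signal, expression)
  x <- signal[ok]; y <- expression[ok]
  n <- length(x)
  if (n < 3) stop_input("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop_input("zero variance in input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble(estimate = r, statistic = tstat,
         p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Compare promoter signal between two gene sets
#'
#' Two-sided two-sample test (Wilcoxon rank-sum by default, Welch t-test as
#' alternative) of, e.g., up- versus down-regulated DEG promoter signal.
#'
#' @param signals_up,signals_down Numeric signal vectors.
#' @param method `"wilcoxon"` or `"t"`.
#' @return A tibble `method`, `statistic`, `p_value`, `n_up`, `n_down`.
#' @export
compare_group_signal <- function(signals_up, signals_down,
                                 method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(signals_up) < 2 || length(signals_down) < 2) {
    stop_input("both groups need at least 2 values")
  }
  if (method == "wilcoxon") {
    res <- wilcoxon_rank_sum(signals_up, signals_down)
    tibble(method = "wilcoxon", statistic = res$statistic,
           p_value = res$p.value,
           n_up = length(signals_up), n_down = length(signals_down))
  } else {
    res <- stats::t.test(signals_up, signals_down)
    tibble(method = "t", statistic = unname(res$statistic),
           p_value = res$p.value,
           n_up = length(signals_up), n_down = length(signals_down))
  }
}
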