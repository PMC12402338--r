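# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# n random DNA strings of fixed length `len`, drawn from the current RNG stream
rand_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# random DNA strings of per-element lengths `lens` (max reasonably small)
rand_dna_var <- function(lens) {
  n <- length(lens)
  if (n == 0L) return(character())
  mx <- max(lens, 0L)
  if (mx == 0L) return(rep("", n))
  str_sub(rand_dna(n, mx), 1L, lens)
}

# Hamming distance between equal-length strings; `a` vector vs scalar or vector `b`
hamming <- function(a, b) {
  if (length(b) == 1L) b <- rep(b, length(a))
  stopifnot(all(nchar(a) == nchar(b)))
  if (!length(a)) return(integer())
  am <- matrix(unlist(strsplit(a, "")), ncol = length(a))
  bm <- matrix(unlist(strsplit(b, "")), ncol = length(b))
  as.integer(Matrix::colSums(am != bm))
}

# substitute one random base (position and replacement from current RNG) in
# each string of `x`; replacement differs from the original base
substitute_one_base <- function(x) {
  if (!length(x)) return(x)
  len <- nchar(x)
  pos <- floor(runif(length(x)) * len) + 1L
  old <- substr(x, pos, pos)
  pick <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L), "", USE.NAMES = FALSE)
  substr(x, pos, pos) <- pick
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells; 1 means
#' identical partitions, 0 is the expectation under independent labelings.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

stop_config <- function(msg, ...) abort(sprintf(msg, ...), class = "pairedtag_config_error")
stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "pairedtag_input_error")

assert_fragments <- function(frags, need = c("chrom", "start", "end", "cell", "umi", "pcr_index")) {
  missing <- setdiff(need, names(frags))
  if (length(missing)) {
    stop_input("fragment table is missing required column(s): %s",
               paste(missing, collapse = ", "))
  }
  invisible(frags)
}
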