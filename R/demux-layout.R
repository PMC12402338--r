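# Read 2 layout of the split-pool barcode read.
#
# Read 2 carries, 5' to 3': a pad, the round-3 barcode, a fixed linker, the
# round-2 barcode, a second fixed linker, the UMI, and the round-1 barcode
# (which also encodes the sample of origin). A per-read start jitter of 0-3 bp
# shifts the whole cassette, so the first base of BC1/BC2/BC3 falls in the
# 1-based windows 84-87, 47-50 and 10-13 respectively.

LINKER1_DEFAULT <- "CGAATGCTCTGGCCTCTCAAG"          # 21 bp, between BC2 and UMI/BC1
LINKER2_DEFAULT <- "ATCCACGTGCTTGAGAGGCCAGAGCATTC"  # 29 bp, between BC3 and BC2
NEXTERA_ADAPTER <- "CTGTCTCTTATACACATCT"

#' Barcode read layout
#'
#' Describes where the three barcode rounds, the linkers and the UMI sit on
#' Read 2. The defaults use 8-bp barcodes, an 8-bp UMI and 21/29-bp linkers
#' chosen so that at zero jitter the first bases of BC1, BC2 and BC3 sit at
#' positions 84, 47 and 10 (1-based); the allowed windows are 84-87, 47-50 and
#' 10-13 (jitter 0-3).
#'
#' @param bc_len Integer vector of barcode lengths for rounds 1-3.
#' @param umi_len UMI length in bp.
#' @param linker1,linker2 Fixed linker sequences: `linker2` sits between BC3
#'   and BC2, `linker1` between BC2 and the UMI.
#' @param bc1_window,bc2_window,bc3_window 1-based inclusive windows for the
#'   first base of each barcode round.
#' @param read_length Length of Read 2 in bp.
#' @return A `barcode_layout` object (a validated list).
#' @export
barcode_layout <- function(bc_len = c(8L, 8L, 8L),
                           umi_len = 8L,
                           linker1 = LINKER1_DEFAULT,
                           linker2 = LINKER2_DEFAULT,
                           bc1_window = c(84L, 87L),
                           bc2_window = c(47L, 50L),
                           bc3_window = c(10L, 13L),
                           read_length = 150L) {
  bc_len <- as.integer(bc_len)
  if (length(bc_len) != 3L || any(bc_len < 1L)) {
    stop_config("bc_len must give three positive barcode lengths")
  }
  w <- list(bc1 = as.integer(bc1_window), bc2 = as.integer(bc2_window),
            bc3 = as.integer(bc3_window))
  widths <- vapply(w, function(x) diff(x) + 1L, 1L)
  if (length(unique(widths)) != 1L) {
    stop_config("all barcode windows must have the same width (common jitter)")
  }
  if (!(w$bc3[1] < w$bc2[1] && w$bc2[1] < w$bc1[1])) {
    stop_config("windows must be ordered BC3 < BC2 < BC1 along Read 2")
  }
  # zero-jitter anchoring: each element must connect exactly to the next
  if (w$bc3[1] + bc_len[3] + nchar(linker2) != w$bc2[1]) {
    stop_config("layout incompatible: BC3 start + BC3 length + linker2 length must equal BC2 start")
  }
  if (w$bc2[1] + bc_len[2] + nchar(linker1) + umi_len != w$bc1[1]) {
    stop_config("layout incompatible: BC2 start + BC2 length + linker1 + UMI must equal BC1 start")
  }
  if (w$bc1[2] + bc_len[1] - 1L > read_length) {
    stop_config("read_length too short for the BC1 window")
  }
  structure(list(
    bc_len = bc_len, umi_len = as.integer(umi_len),
    linker1 = linker1, linker2 = linker2,
    bc1_window = w$bc1, bc2_window = w$bc2, bc3_window = w$bc3,
    jitter_max = widths[[1]] - 1L,
    read_length = as.integer(read_length)
  ), class = "barcode_layout")
}

#' Simulate barcode whitelists
#'
#' Draws random whitelists for the three barcode rounds with a guaranteed
#' minimum pairwise Hamming distance within each round. Real split-pool
#' whitelists are designed error-correcting; with `min_dist = 3` a single
#' substitution is always either corrected to the true barcode or discarded,
#' never mis-assigned.
#'
#' @param sizes Whitelist sizes for rounds 1-3 (default 96, 96, 12).
#' @param bc_len Barcode length in bp (same for all rounds here).
#' @param min_dist Minimum pairwise Hamming distance within a round.
#' @param seed Integer seed; the draw is fully deterministic.
#' @return A list of three character vectors.
#' @export
sim_whitelists <- function(sizes = c(96L, 96L, 12L), bc_len = 8L,
                           min_dist = 3L, seed = 1L) {
  withr::with_seed(seed, {
    lapply(sizes, function(k) {
      chosen <- character(0)
      tries <- 0L
      while (length(chosen) < k) {
        cand <- rand_dna(1L, bc_len)
        tries <- tries + 1L
        if (tries > 200000L) {
          stop_config("could not place %d barcodes of length %d at distance >= %d",
                      k, bc_len, min_dist)
        }
        if (!length(chosen) || all(hamming(chosen, cand) >= min_dist)) {
          chosen <- c(chosen, cand)
        }
      }
      chosen
    })
  })
}

#' Read barcode whitelists from files
#'
#' One barcode per line, one file per round.
#'
#' @param paths Character vector of three file paths (rounds 1-3).
#' @return A list of three character vectors.
#' @export
read_whitelists <- function(paths) {
  stopifnot(length(paths) == 3L)
  lapply(paths, function(p) readr::read_lines(p, progress = FALSE))
}

#' @rdname read_whitelists
#' @param whitelists List of three character vectors.
#' @export
write_whitelists <- function(whitelists, paths) {
  stopifnot(length(paths) == 3L, length(whitelists) == 3L)
  purrr::walk2(whitelists, paths, readr::write_lines)
  invisible(paths)
}
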