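# Barcode identification and cell assignment.
#
# The three-round cellular barcode is located on Read 2 by matching the fixed
# linker sequences flanking each barcode (exact match first, then a <= 1
# mismatch fallback), then each raw barcode is resolved against its round's
# whitelist with a <= 1 Hamming mismatch, unique-hit rule: zero whitelist
# entries at the minimal distance discards the read as `no_match`, two or more
# as `ambiguous`. `N` bases count as mismatches. Reverse-strand matching is
# never attempted.

#' Build a combinatorial barcode reference
#'
#' Pre-computes exact and Hamming-distance-1 lookup tables for each barcode
#' round. The reference represents all `|W1| x |W2| x |W3|` barcode
#' combinations (110,592 for the default 96 x 96 x 12 whitelists).
#'
#' @param whitelists List of three character vectors (rounds 1-3). Entries
#'   within a round must be unique and of one common length.
#' @return A `barcode_reference` object with element `n_combinations`.
#' @export
build_barcode_reference <- function(whitelists) {
  if (length(whitelists) != 3L) stop_config("need exactly three whitelists")
  rounds <- lapply(seq_along(whitelists), function(i) {
    wl <- whitelists[[i]]
    if (!length(wl)) stop_config("whitelist %d is empty", i)
    if (anyDuplicated(wl)) stop_config("whitelist %d contains duplicate entries", i)
    if (length(unique(nchar(wl))) != 1L) {
      stop_config("whitelist %d mixes barcode lengths", i)
    }
    list(barcodes = wl, len = nchar(wl[1]), neighbors = hamming1_index(wl))
  })
  structure(list(
    rounds = rounds,
    n_combinations = prod(vapply(rounds, function(r) length(r$barcodes), 1L))
  ), class = "barcode_reference")
}

# Named integer vector mapping every string at Hamming distance exactly 1 from
# a whitelist entry (substitutions over A/C/G/T/N) to that entry's index, or 0
# when two different entries generate the same variant (ambiguous). Variants
# that are themselves whitelist members are omitted: exact lookup wins.
hamming1_index <- function(wl) {
  len <- nchar(wl[1])
  variants <- character(0)
  owner <- integer(0)
  for (pos in seq_len(len)) {
    for (ch in c(DNA_BASES, "N")) {
      v <- wl
      substr(v, pos, pos) <- ch
      changed <- v != wl
      variants <- c(variants, v[changed])
      owner <- c(owner, which(changed))
    }
  }
  keep <- !(variants %in% wl)
  variants <- variants[keep]
  owner <- owner[keep]
  first <- !duplicated(variants)
  map <- setNames(owner[first], variants[first])
  # any variant reachable from two different entries is ambiguous
  amb <- unique(variants[duplicated(variants)])
  if (length(amb)) {
    amb_real <- vapply(amb, function(v) length(unique(owner[variants == v])) > 1L, TRUE)
    map[amb[amb_real]] <- 0L
  }
  map
}

# resolve one round: index > 0 assigned, 0 ambiguous, NA no_match
resolve_round <- function(query, round) {
  idx <- match(query, round$barcodes)
  todo <- is.na(idx)
  if (any(todo)) {
    nb <- unname(round$neighbors[match(query[todo], names(round$neighbors))])
    idx[todo] <- nb
  }
  idx
}

# leftmost best-scoring linker start among candidate positions; exact pass
# first, then a mismatch-tolerant pass over reads with no exact hit
find_linker <- function(reads, linker, cand_starts, max_mismatch = 1L) {
  n <- length(reads)
  L <- nchar(linker)
  best <- rep(NA_integer_, n)
  cand_starts <- cand_starts[cand_starts >= 1L]
  for (s in cand_starts) {
    hit <- is.na(best) & substr(reads, s, s + L - 1L) == linker
    best[hit] <- s
  }
  if (max_mismatch > 0L && anyNA(best)) {
    todo <- which(is.na(best))
    sub <- reads[todo]
    lchars <- strsplit(linker, "")[[1]]
    best_mm <- rep(Inf, length(sub))
    for (s in cand_starts) {
      mm <- integer(length(sub))
      for (i in seq_len(L)) {
        p <- s + i - 1L
        mm <- mm + (substr(sub, p, p) != lchars[i])
      }
      better <- mm <= max_mismatch & mm < best_mm
      best[todo[better]] <- s
      best_mm[better] <- mm[better]
    }
  }
  best
}

#' Locate barcodes, UMI and status on Read 2
#'
#' Anchors the barcode cassette by matching the two linker sequences (exact
#' first, then up to `max_linker_mismatch` substitutions) at candidate
#' positions around the allowed windows, and extracts the raw barcode triple
#' and UMI. A read whose linkers cannot be found gets status
#' `linker_not_found`; a read whose barcode first base falls outside its
#' 1-based window (BC1 84-87, BC2 47-50, BC3 10-13 by default) gets
#' `out_of_window`; otherwise `ok`.
#'
#' @param read2 Character vector of Read 2 sequences.
#' @param layout A [barcode_layout()].
#' @param max_linker_mismatch Substitution tolerance for linker matching.
#' @param window_slack How many bp beyond each window linkers are still
#'   searched (so out-of-window reads are recognised as such rather than
#'   `linker_not_found`).
#' @return A tibble with columns `bc1`, `bc2`, `bc3`, `umi`, `bc1_start`,
#'   `bc2_start`, `bc3_start` and `status`.
#' @export
locate_barcodes <- function(read2, layout, max_linker_mismatch = 1L,
                            window_slack = 4L) {
  stopifnot(is(layout, "barcode_layout"))
  n <- length(read2)
  bc1_len <- layout$bc_len[1]; bc2_len <- layout$bc_len[2]; bc3_len <- layout$bc_len[3]

  bc3_cand <- (layout$bc3_window[1] - window_slack):(layout$bc3_window[2] + window_slack)
  l2_start <- find_linker(read2, layout$linker2, bc3_cand + bc3_len, max_linker_mismatch)
  bc2_cand <- (layout$bc2_window[1] - window_slack):(layout$bc2_window[2] + window_slack)
  l1_start <- find_linker(read2, layout$linker1, bc2_cand + bc2_len, max_linker_mismatch)

  bc3_start <- l2_start - bc3_len
  bc2_start <- l1_start - bc2_len
  umi_start <- l1_start + nchar(layout$linker1)
  bc1_start <- umi_start + layout$umi_len

  in_win <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  status <- rep("ok", n)
  fits <- !is.na(bc1_start) & (bc1_start + bc1_len - 1L) <= nchar(read2)
  status[!(in_win(bc1_start, layout$bc1_window) &
             in_win(bc2_start, layout$bc2_window) &
             in_win(bc3_start, layout$bc3_window) & fits)] <- "out_of_window"
  status[is.na(l2_start) | is.na(l1_start)] <- "linker_not_found"

  ok <- status == "ok"
  out <- tibble(
    bc1 = NA_character_, bc2 = NA_character_, bc3 = NA_character_,
    umi = NA_character_,
    bc1_start = bc1_start, bc2_start = bc2_start, bc3_start = bc3_start,
    status = status
  )
  out$bc1[ok] <- substr(read2[ok], bc1_start[ok], bc1_start[ok] + bc1_len - 1L)
  out$bc2[ok] <- substr(read2[ok], bc2_start[ok], bc2_start[ok] + bc2_len - 1L)
  out$bc3[ok] <- substr(read2[ok], bc3_start[ok], bc3_start[ok] + bc3_len - 1L)
  out$umi[ok] <- substr(read2[ok], umi_start[ok], umi_start[ok] + layout$umi_len - 1L)
  out
}

#' Assign located barcodes to cells
#'
#' Resolves each barcode round against the reference with the one-mismatch
#' unique rule. Any round with no whitelist entry within Hamming distance 1
#' discards the read (`no_match`); any round whose minimal-distance hit is not
#' unique discards it (`ambiguous`). `no_match` takes precedence over
#' `ambiguous` when both occur.
#'
#' @param located Tibble from [locate_barcodes()] (or any tibble with `bc1`,
#'   `bc2`, `bc3`, `status` columns).
#' @param reference A [build_barcode_reference()] object.
#' @return `located` with added columns `bc1_id`, `bc2_id`, `bc3_id` (resolved
#'   whitelist barcodes), `cell_barcode`, `sample_index` (BC1 well, the sample
#'   of origin) and updated `status` (`assigned` / `no_match` / `ambiguous` /
#'   pass-through locate failures).
#' @export
assign_cells <- function(located, reference) {
  stopifnot(is(reference, "barcode_reference"))
  ok <- located$status == "ok"
  rlens <- vapply(reference$rounds, function(r) r$len[[1]], 1L)
  bad_len <- vapply(1:3, function(i) {
    any(nchar(located[[paste0("bc", i)]][ok]) != rlens[i])
  }, TRUE)
  if (any(ok) && any(bad_len)) {
    stop_input("raw barcode length does not match the reference round length")
  }
  idx <- lapply(1:3, function(i) {
    v <- rep(NA_integer_, nrow(located))
    v[ok] <- resolve_round(located[[paste0("bc", i)]][ok], reference$rounds[[i]])
    v
  })
  status <- located$status
  no_match <- ok & (is.na(idx[[1]]) | is.na(idx[[2]]) | is.na(idx[[3]]))
  ambiguous <- ok & !no_match &
    (idx[[1]] == 0L | idx[[2]] == 0L | idx[[3]] == 0L)
  assigned <- ok & !no_match & !ambiguous
  status[no_match] <- "no_match"
  status[ambiguous] <- "ambiguous"
  status[assigned] <- "assigned"

  out <- located
  out$bc1_id <- out$bc2_id <- out$bc3_id <- NA_character_
  out$bc1_id[assigned] <- reference$rounds[[1]]$barcodes[idx[[1]][assigned]]
  out$bc2_id[assigned] <- reference$rounds[[2]]$barcodes[idx[[2]][assigned]]
  out$bc3_id[assigned] <- reference$rounds[[3]]$barcodes[idx[[3]][assigned]]
  out$cell_barcode <- NA_character_
  out$cell_barcode[assigned] <- paste(out$bc1_id[assigned], out$bc2_id[assigned],
                                      out$bc3_id[assigned], sep = "-")
  out$sample_index <- idx[[1]]
  out$sample_index[!assigned] <- NA_integer_
  out$status <- status
  out
}

#' Demultiplex a batch of read pairs
#'
#' Runs [locate_barcodes()], [assign_cells()] and [trim_reads()] on paired
#' reads held in memory, and produces the per-status demultiplexing report.
#' The report counts satisfy `reads_in = assigned + no_match + ambiguous +
#' linker_not_found + out_of_window` exactly; trimming drops are reported
#' separately (they apply to already-assigned reads).
#'
#' @param reads Tibble with columns `name`, `seq1`, `qual1`, `seq2`, `qual2`
#'   and optionally `pcr_index` (otherwise parsed from a `PI:<n>` token in
#'   `name`).
#' @param reference A [build_barcode_reference()].
#' @param layout A [barcode_layout()].
#' @param modality `"DNA"` or `"RNA"` (controls poly-dT trimming).
#' @param qc A [qc_params()].
#' @return A list with `reads` (assigned, trimmed reads: `name` rewritten to
#'   `orig|CB:...|UMI:...|PI:...`, `seq`, `qual`, `cell_barcode`, `umi`,
#'   `pcr_index`, `sample_index`), `report` (status counts) and
#'   `trim_report`.
#' @export
demux_reads <- function(reads, reference, layout, modality = c("DNA", "RNA"),
                        qc = qc_params()) {
  modality <- match.arg(modality)
  loc <- locate_barcodes(reads$seq2, layout)
  asg <- assign_cells(loc, reference)
  report <- asg |>
    count(.data$status, name = "reads") |>
    arrange(.data$status)

  pcr_index <- reads$pcr_index %||% parse_pcr_index(reads$name)
  keep <- asg$status == "assigned"
  trimmed <- trim_reads(reads$seq1[keep], reads$qual1[keep], modality, qc)
  trim_report <- trimmed |> count(.data$drop_reason, name = "reads")

  kept <- trimmed$kept
  base <- sub("\\s.*$", "", reads$name[keep])
  out <- tibble(
    name = paste0(base[kept], "|CB:", asg$cell_barcode[keep][kept],
                  "|UMI:", asg$umi[keep][kept],
                  "|PI:", pcr_index[keep][kept]),
    seq = trimmed$seq[kept],
    qual = trimmed$qual[kept],
    cell_barcode = asg$cell_barcode[keep][kept],
    umi = asg$umi[keep][kept],
    pcr_index = pcr_index[keep][kept],
    sample_index = asg$sample_index[keep][kept]
  )
  list(reads = out, report = report, trim_report = trim_report)
}

parse_pcr_index <- function(names) {
  pi <- stringr::str_match(names, "PI:(\\d+)")[, 2]
  as.integer(pi)
}
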