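# Readers/writers for the standard formats. Coordinate conventions are
# converted at the boundary (GTF 1-based closed <-> internal 0-based
# half-open; BED-like fragments native 0-based). gzip is handled by the
# underlying readers (magic-byte detection) and by file extension on write.

#' Write paired reads as FASTQ
#'
#' @param reads Tibble with `name`, `seq1`, `qual1`, `seq2`, `qual2` (as from
#'   [emit_reads()]); or `seq`/`qual` for single-end output.
#' @param r1_path,r2_path Output paths (`.gz` for compressed output).
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  write_fastq_one(reads$name, reads$seq1, reads$qual1, r1_path)
  write_fastq_one(reads$name, reads$seq2, reads$qual2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq_pair
#' @param name,seq,qual Read names, sequences, quality strings.
#' @param path Output path.
#' @export
write_fastq_one <- function(name, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- name
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return A tibble `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(name = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

FRAGMENT_COLS <- c("chrom", "start", "end", "cell", "umi", "pcr_index")

#' Write a BED-like fragments file
#'
#' Tab-separated `chrom start end cell umi pcr_index`, coordinate-sorted,
#' 0-based half-open; no header line (BED convention). `.gz` paths are
#' compressed.
#'
#' @param frags Fragment tibble (extra columns are dropped).
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  assert_fragments(frags)
  out <- frags[, FRAGMENT_COLS]
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED-like fragments file
#'
#' @param path Fragments file path.
#' @param modality Modality tag to attach (`"DNA"` or `"RNA"`).
#' @return A fragment tibble with `strand = "+"` and `mapq = 42` defaults.
#' @export
read_fragments <- function(path, modality = "DNA") {
  out <- readr::read_tsv(path, col_names = FRAGMENT_COLS,
                         col_types = "ciicci", progress = FALSE)
  mutate(out, strand = "+", mapq = 42L, modality = modality)
}

#' Write a sparse count matrix as MatrixMarket + feature/barcode TSVs
#'
#' @param m Sparse matrix (features x cells).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_count_matrix <- function(m, dir, prefix = "matrix") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m, file.path(dir, paste0(prefix, ".mtx")))
  readr::write_lines(rownames(m), file.path(dir, paste0(prefix, ".features.tsv")))
  readr::write_lines(colnames(m), file.path(dir, paste0(prefix, ".barcodes.tsv")))
  invisible(dir)
}

#' Read a sparse count matrix written by [write_count_matrix()]
#'
#' @param dir Directory holding the files.
#' @param prefix File-name prefix.
#' @return A sparse `dgCMatrix` with dimnames restored.
#' @export
read_count_matrix <- function(dir, prefix = "matrix") {
  m <- as(Matrix::readMM(file.path(dir, paste0(prefix, ".mtx"))), "CsparseMatrix")
  rownames(m) <- readr::read_lines(file.path(dir, paste0(prefix, ".features.tsv")),
                                   progress = FALSE)
  colnames(m) <- readr::read_lines(file.path(dir, paste0(prefix, ".barcodes.tsv")),
                                   progress = FALSE)
  m
}

#' Serialize / restore a pipeline or simulation configuration
#'
#' JSON round-trip of the plain-list parts of a configuration (tibbles are
#' stored as data frame records). The effective configuration of every run is
#' written alongside its outputs.
#'
#' @param config A `sim_config` or plain list.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  ser <- config
  class(ser) <- NULL
  ser$layout <- unclass(ser$layout)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @return `read_config()` returns the configuration list (class restored for
#'   `sim_config` payloads).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$layout)) {
    raw$layout <- do.call(barcode_layout, raw$layout[c(
      "bc_len", "umi_len", "linker1", "linker2",
      "bc1_window", "bc2_window", "bc3_window", "read_length")])
  }
  for (nm in c("groups", "cell_types")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as_tibble(raw[[nm]])
  }
  if (!is.null(raw$type_signal_fraction)) {
    raw$type_signal_fraction <- unlist(raw$type_signal_fraction)
  }
  if (all(c("seed", "n_genes", "groups") %in% names(raw))) {
    class(raw) <- "sim_config"
  }
  raw
}

#' Write a bedGraph coverage track of fragment 5' starts
#'
#' @param frags Fragment tibble.
#' @param path Output path.
#' @param bin Bin width in bp for the track.
#' @export
write_bedgraph <- function(frags, path, bin = 50L) {
  cov <- frags |>
    mutate(bin_start = (.data$start %/% bin) * bin) |>
    count(.data$chrom, .data$bin_start, name = "score") |>
    mutate(bin_end = .data$bin_start + bin) |>
    select("chrom", "bin_start", "bin_end", "score") |>
    arrange(.data$chrom, .data$bin_start)
  readr::write_tsv(cov, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
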