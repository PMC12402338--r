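# Exact-match read locator for toy genomes.
#
# Stands in for the alignment stage on synthetic data: reads are placed on the
# forward strand by exact matching of a 30-bp seed (Aho-Corasick via
# Biostrings::matchPDict) followed by full-length verification. Reads with no
# verified hit, or with more than one, are reported unaligned. Real-data
# alignment is out of scope.

#' Locate reads by exact matching on a toy genome
#'
#' @param seqs Character vector of read sequences (post-trimming).
#' @param genome A [Biostrings::DNAStringSet].
#' @param seed_length Seed prefix length (reads shorter than this are
#'   unaligned; the default matches the minimum kept read length).
#' @return A tibble with one row per read: `chrom`, `start` (0-based), `end`
#'   (half-open), `strand`, `mapq` (42 for a unique verified hit) and
#'   `aligned`.
#' @export
locate_reads <- function(seqs, genome, seed_length = 30L) {
  n <- length(seqs)
  out <- tibble(chrom = NA_character_, start = NA_integer_, end = NA_integer_,
                strand = "+", mapq = NA_integer_,
                aligned = rep(FALSE, n))
  eligible <- which(nchar(seqs) >= seed_length & !grepl("[^ACGT]", seqs))
  if (!length(eligible)) return(out)
  seeds <- Biostrings::DNAStringSet(substr(seqs[eligible], 1L, seed_length))
  pd <- Biostrings::PDict(seeds)
  chrom_chars <- as.character(genome)
  hit_count <- integer(length(eligible))
  hit_chrom <- character(length(eligible))
  hit_start <- integer(length(eligible))
  for (ci in seq_along(genome)) {
    mi <- Biostrings::matchPDict(pd, genome[[ci]])
    st <- IRanges::start(mi)
    counts <- lengths(st)
    if (!sum(counts)) next
    ul_start <- unlist(st, use.names = FALSE)
    ul_read <- rep.int(seq_along(counts), counts)
    # verify the full read against the genome at each seed hit
    full <- seqs[eligible[ul_read]]
    ok <- substr(rep(chrom_chars[ci], length(ul_start)),
                 ul_start, ul_start + nchar(full) - 1L) == full
    ul_start <- ul_start[ok]; ul_read <- ul_read[ok]
    if (!length(ul_read)) next
    add <- tabulate(ul_read, nbins = length(counts))
    hit_count <- hit_count + add
    firsts <- !duplicated(ul_read)
    hit_chrom[ul_read[firsts]] <- names(genome)[ci]
    hit_start[ul_read[firsts]] <- ul_start[firsts]
  }
  unique_hit <- hit_count == 1L
  idx <- eligible[unique_hit]
  out$chrom[idx] <- hit_chrom[unique_hit]
  out$start[idx] <- hit_start[unique_hit] - 1L
  out$end[idx] <- out$start[idx] + nchar(seqs[idx])
  out$mapq[idx] <- 42L
  out$aligned[idx] <- TRUE
  out
}
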