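# Toy genome and gene models.

#' Generate a toy genome
#'
#' Uniform-random DNA, deterministic given the configuration seed; chromosomes
#' are named `chr1..chrN`.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet].
#' @export
sim_genome <- function(config) {
  if (config$n_chromosomes < 1L || config$chromosome_length < 1L) {
    stop_config("genome dimensions must be positive")
  }
  seqs <- withr::with_seed(config$seed + 100L, {
    vapply(seq_len(config$n_chromosomes), function(i) {
      paste(sample(DNA_BASES, config$chromosome_length, replace = TRUE),
            collapse = "")
    }, "")
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))
  genome
}

#' Chromosome sizes of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] (or a named numeric vector).
#' @return A tibble with columns `chrom`, `length`.
#' @export
genome_sizes <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    tibble(chrom = names(genome), length = Biostrings::width(genome))
  } else {
    tibble(chrom = names(genome), length = as.integer(genome))
  }
}

#' Generate non-overlapping gene models on a toy genome
#'
#' Genes are laid out in evenly spaced slots so that promoter windows
#' (TSS +/- 1 kb) never overlap; strand alternates along each chromosome and
#' the exact start position jitters deterministically inside its slot.
#' Coordinates are 0-based half-open; the TSS is `start` for `+` genes and
#' `end - 1` for `-` genes.
#'
#' @param genome A [Biostrings::DNAStringSet] from [sim_genome()].
#' @param config A [sim_config()].
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
sim_genes <- function(genome, config) {
  sizes <- genome_sizes(genome)
  n <- config$n_genes
  plan <- sim_gene_plan(config)
  # contiguous blocks of genes per chromosome, proportional to length
  cuts <- floor(seq(0, n, length.out = nrow(sizes) + 1L))
  per_chrom <- diff(cuts)
  margin <- 2000L   # promoter half-width on either flank
  rows <- withr::with_seed(config$seed + 150L, {
    purrr::map2(seq_len(nrow(sizes)), per_chrom, function(ci, k) {
      if (k == 0L) return(NULL)
      slot <- floor(sizes$length[ci] / k)
      if (slot < config$gene_length + 2L * margin) {
        stop_config(paste0("chromosome %s too short for %d genes: slot %d < ",
                           "gene length + 2 x 2kb promoter margin"),
                    sizes$chrom[ci], k, slot)
      }
      jitter_room <- slot - config$gene_length - 2L * margin
      offs <- margin + floor(runif(k) * (jitter_room + 1L))
      start <- (seq_len(k) - 1L) * slot + offs
      tibble(chrom = sizes$chrom[ci], start = as.integer(start),
             end = as.integer(start + config$gene_length),
             strand = rep_len(c("+", "-"), k))
    })
  })
  genes <- bind_rows(rows)
  genes$gene_id <- plan$gene_id
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
}
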