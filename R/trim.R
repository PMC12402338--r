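# Read 1 trimming and quality filtering.
#
# 3' adapter removal (>= 10 bp overlap, <= 10% mismatches), then for RNA a
# terminal poly-dT/poly-dA run of >= 6 bases is removed, then 3' bases below
# the quality cutoff are trimmed, and the read is kept only if at least
# `min_length` bases remain (defaults L = 30, Q = 30).

#' Quality-control parameters
#'
#' @param min_length Minimum read length after trimming (L, default 30).
#' @param min_quality Minimum Phred base quality for 3' trimming (Q, default 30).
#' @param mapq Minimum mapping quality used downstream (reads kept iff
#'   `MAPQ > mapq`, default 10).
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_length = 30L, min_quality = 30L, mapq = 10L) {
  if (min_length < 1L) stop_config("min_length must be >= 1")
  if (min_quality < 0L || min_quality > 41L) stop_config("min_quality must be in [0, 41]")
  structure(list(min_length = as.integer(min_length),
                 min_quality = as.integer(min_quality),
                 mapq = as.integer(mapq)),
            class = "qc_params")
}

# first position (1-based) at which `adapter` starts in each read, allowing
# <= 10% mismatches over the overlap and requiring >= min_overlap bases;
# NA when no acceptable hit. Exact seed search first; mismatch-tolerant scan
# only for reads without an exact seed hit.
find_adapter <- function(seq, adapter, min_overlap = 10L, max_mismatch_frac = 0.1) {
  n <- length(seq)
  hit <- rep(NA_integer_, n)
  if (!n) return(hit)
  seed <- substr(adapter, 1L, min_overlap)
  pos <- as.integer(regexpr(seed, seq, fixed = TRUE))
  found <- pos > 0L
  hit[found] <- pos[found]
  # mismatch-tolerant pass for the rest: scan all starts leaving >= min_overlap
  todo <- which(!found)
  if (length(todo)) {
    achars <- strsplit(adapter, "")[[1]]
    alen <- length(achars)
    sub <- seq[todo]
    lens <- nchar(sub)
    maxlen <- max(lens)
    for (s in seq_len(max(maxlen - min_overlap + 1L, 0L))) {
      open <- is.na(hit[todo]) & (lens - s + 1L) >= min_overlap
      if (!any(open)) next
      ov <- pmin(alen, lens - s + 1L)
      mm <- integer(length(sub))
      for (i in seq_len(alen)) {
        p <- s + i - 1L
        active <- i <= ov
        mm <- mm + (active & substr(sub, p, p) != achars[i])
      }
      good <- open & mm <= floor(max_mismatch_frac * ov)
      hit[todo[good]] <- s
    }
  }
  hit
}

#' Trim and quality-filter Read 1
#'
#' @param seq,qual Character vectors of sequences and Phred+33 quality strings.
#' @param modality `"DNA"` or `"RNA"`; poly-dT/dA tail removal applies to RNA
#'   only.
#' @param qc A [qc_params()].
#' @param adapter 3' adapter sequence (Nextera by default).
#' @return A tibble with `seq`, `qual`, `kept` and `drop_reason`
#'   (`"kept"`/`"length"`).
#' @export
trim_reads <- function(seq, qual, modality = c("DNA", "RNA"), qc = qc_params(),
                       adapter = NEXTERA_ADAPTER) {
  modality <- match.arg(modality)
  stopifnot(length(seq) == length(qual))
  pos <- find_adapter(seq, adapter)
  newlen <- ifelse(is.na(pos), nchar(seq), pos - 1L)
  seq <- substr(seq, 1L, newlen)
  qual <- substr(qual, 1L, newlen)

  if (modality == "RNA") {
    tail_len <- attr(regexpr("(T{6,}|A{6,})$", seq), "match.length")
    tail_len[tail_len < 0L] <- 0L
    newlen <- nchar(seq) - tail_len
    seq <- substr(seq, 1L, newlen)
    qual <- substr(qual, 1L, newlen)
  }

  if (qc$min_quality > 0L) {
    # Phred+33: bases with quality < Q are chars \x21 .. \x21+Q-1
    low_class <- sprintf("[\\x21-\\x%02X]+$", 0x20L + qc$min_quality)
    lowrun <- attr(regexpr(low_class, qual, perl = TRUE), "match.length")
    lowrun[lowrun < 0L] <- 0L
    newlen <- nchar(qual) - lowrun
    seq <- substr(seq, 1L, newlen)
    qual <- substr(qual, 1L, newlen)
  }

  kept <- nchar(seq) >= qc$min_length
  tibble(seq = seq, qual = qual, kept = kept,
         drop_reason = if_else(kept, "kept", "length"))
}
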