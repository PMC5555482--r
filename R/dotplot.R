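# Shared-motif dotplot core: maximal exact matches of length >= k between
# two intergenic-region sequences. Matching is k-mer seeded: every shared
# k-mer hit is assigned to its diagonal (q_start - s_start), and maximal
# runs of consecutive hits on one diagonal are merged into a single span
# (the dotplot's "contiguous lines"). Runs of k-mer starts are maximal in
# the character sense by construction, so no extension step is needed.
# k-mers containing N never match (ambiguity is not identity).

#' Construct an intergenic-region sequence
#'
#' @param gene Gene identifier the IGR is upstream of.
#' @param chrom Chromosome/contig name.
#' @param start,end 1-based inclusive genomic coordinates;
#'   `end - start + 1` must equal the sequence length.
#' @param strand `"+"` or `"-"`.
#' @param seq Nucleotide string over A/C/G/T/N; lower case is normalized to
#'   upper case.
#' @return An object of class `igr_sequence`.
#' @export
igr_sequence <- function(gene, chrom, start, end, strand, seq) {
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]+$", seq)) {
    stop_param("`seq` must be a non-empty string over A/C/G/T/N")
  }
  if (!strand %in% c("+", "-")) stop_param("`strand` must be '+' or '-'")
  if (end - start + 1 != nchar(seq)) {
    stop_param("end - start + 1 must equal the sequence length")
  }
  structure(list(gene = gene, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, seq = seq),
            class = "igr_sequence")
}

#' @export
print.igr_sequence <- function(x, ...) {
  cat(sprintf("<igr_sequence> %s | %s:%d-%d(%s) | %d bp\n", x$gene, x$chrom,
              x$start, x$end, x$strand, nchar(x$seq)))
  invisible(x)
}

as_igr <- function(x, gene = "seq") {
  if (inherits(x, "igr_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(igr_sequence(gene, ".", 1L, nchar(x), "+", x))
  }
  stop_param("sequence must be an igr_sequence or a single string")
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# forward-strand maximal spans between two plain uppercase strings
kmer_spans <- function(a, b, k) {
  empty <- tibble(q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  length = integer(), motif = character())
  na_ <- nchar(a); nb_ <- nchar(b)
  if (na_ < k || nb_ < k) return(empty)
  sa <- seq_len(na_ - k + 1L)
  sb <- seq_len(nb_ - k + 1L)
  ka <- substring(a, sa, sa + k - 1L)
  kb <- substring(b, sb, sb + k - 1L)
  ok_a <- !grepl("N", ka, fixed = TRUE)
  ok_b <- !grepl("N", kb, fixed = TRUE)
  pos_b <- split(which(ok_b) - 1L, kb[ok_b])  # 0-based starts per k-mer
  ia <- which(ok_a)
  hits <- pos_b[ka[ia]]
  nh <- lengths(hits)
  if (sum(nh) == 0L) return(empty)
  i0 <- rep(ia - 1L, nh)
  j0 <- unlist(hits, use.names = FALSE)
  d <- i0 - j0
  o <- order(d, i0)
  i0 <- i0[o]; j0 <- j0[o]; d <- d[o]
  m <- length(i0)
  new_run <- c(TRUE, d[-1] != d[-m] | i0[-1] != i0[-m] + 1L)
  q_start <- i0[new_run]
  q_last <- i0[c(new_run[-1], TRUE)]
  s_start <- j0[new_run]
  q_end <- q_last + k
  len <- q_end - q_start
  tibble(q_start = as.integer(q_start), q_end = as.integer(q_end),
         s_start = as.integer(s_start),
         s_end = as.integer(s_start + len), length = as.integer(len),
         motif = substring(a, q_start + 1L, q_end))
}

#' Find maximal shared matches between two sequences
#'
#' Reports every maximal exact match of length at least `k` between the
#' two sequences' forward strands (and, optionally, between the first
#' sequence and the reverse complement of the second). Each match carries
#' 0-based half-open offsets into both sequences, the matched motif, and —
#' when conservation tracks are given — the mean per-base conservation over
#' each side's span.
#'
#' @param seq_a,seq_b [igr_sequence()] objects (or plain strings).
#' @param k Minimum match length; at least 2 (default 8, the standard
#'   base-pair filter).
#' @param revcomp Also report matches against the reverse complement of
#'   `seq_b` (strand `"-"`; `s_start`/`s_end` remain coordinates in
#'   `seq_b`'s own forward frame).
#' @param track_a,track_b Optional per-base conservation vectors aligned to
#'   the sequences (scores in `[0, 1]`).
#' @return A tibble sorted by `q_start` then `s_start` with columns
#'   `q_start`, `q_end`, `s_start`, `s_end`, `length`, `motif`, `strand`,
#'   `mean_cons_q`, `mean_cons_s`.
#' @examples
#' m <- find_shared_matches("TTTTACGTACGTTT", "GGGACGTACGGG", k = 6)
#' m[, c("q_start", "s_start", "length", "motif")]
#' @export
find_shared_matches <- function(seq_a, seq_b, k = 8L, revcomp = FALSE,
                                track_a = NULL, track_b = NULL) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2) {
    stop_param("`k` must be a single integer >= 2")
  }
  k <- as.integer(k)
  seq_a <- as_igr(seq_a, "seqA")
  seq_b <- as_igr(seq_b, "seqB")
  a <- seq_a$seq; b <- seq_b$seq
  res <- kmer_spans(a, b, k)
  res$strand <- rep("+", nrow(res))
  if (revcomp) {
    nb_ <- nchar(b)
    rc <- kmer_spans(a, revcomp_chr(b), k)
    if (nrow(rc) > 0) {
      rc <- mutate(rc,
                   s_start_new = nb_ - .data$s_end,
                   s_end = nb_ - .data$s_start,
                   s_start = .data$s_start_new) |>
        select(-"s_start_new")
      rc$strand <- "-"
      res <- bind_rows(res, rc)
    }
  }
  span_mean <- function(track, s, e, len) {
    if (is.null(track)) return(rep(NA_real_, length(s)))
    if (length(track) != len) {
      stop_consistency("conservation track length must equal sequence length")
    }
    map_dbl(seq_along(s), ~ mean_conservation(track, s[.x], e[.x]))
  }
  res$mean_cons_q <- span_mean(track_a, res$q_start, res$q_end, nchar(a))
  res$mean_cons_s <- span_mean(track_b, res$s_start, res$s_end, nchar(b))
  arrange(res, .data$q_start, .data$s_start)
}

#' List distinct shared motifs
#'
#' The "Shared Motifs" dropdown: unique motif strings across a match table,
#' longest first, ties broken lexicographically.
#'
#' @param matches A match tibble from [find_shared_matches()].
#' @return Character vector of distinct motifs.
#' @export
list_shared_motifs <- function(matches) {
  u <- unique(matches$motif)
  u[order(-nchar(u), u)]
}

#' Select the matches of one shared motif
#'
#' Exact string equality with the listed motif (the dropdown selection is
#' unambiguous); an empty result is allowed.
#'
#' @param matches A match tibble.
#' @param motif Non-empty motif string.
#' @return The subset of `matches` whose motif equals `motif`.
#' @export
highlight_motif <- function(matches, motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L) {
    stop_param("`motif` must be a non-empty string")
  }
  matches[matches$motif == toupper(motif), ]
}

CONS_BINS <- c("white", "light_gray", "dark_gray", "black")

#' Bin a conservation score into the grey-scale classes
#'
#' Scores in `[0, 0.25]` are white, `(0.25, 0.5]` light gray,
#' `(0.5, 0.75]` dark gray and `(0.75, 1]` black. Vectorized.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @return Factor with levels `white`, `light_gray`, `dark_gray`, `black`.
#' @export
conservation_bin <- function(score) {
  if (!is.numeric(score) || anyNA(score) || any(score < 0 | score > 1)) {
    abort("conservation scores must lie in [0, 1]",
          class = "embryogem_domain_error")
  }
  cut(score, breaks = c(0, 0.25, 0.5, 0.75, 1), labels = CONS_BINS,
      include.lowest = TRUE, right = TRUE)
}

#' Mean conservation over a span
#'
#' Arithmetic mean of per-base scores over the 0-based half-open span
#' `[start, end)`.
#'
#' @param track Numeric per-base conservation vector.
#' @param start,end Span offsets, `0 <= start < end <= length(track)`.
#' @return The mean score.
#' @export
mean_conservation <- function(track, start, end) {
  if (!is.numeric(track) || length(track) == 0L) {
    stop_param("`track` must be a non-empty numeric vector")
  }
  if (start < 0 || end > length(track) || start >= end) {
    abort("span must satisfy 0 <= start < end <= track length",
          class = "embryogem_range_error")
  }
  mean(track[(start + 1):end])
}
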