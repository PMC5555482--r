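# Sequence and conservation-track readers. FASTA record ids encode the
# genomic provenance as gene|chrom:start-end(strand); bedGraph intervals
# (0-based half-open) are expanded to per-base scores over the IGR, with
# uncovered bases defaulting to 0 (the PhastCons convention for unaligned
# bases).

#' Read intergenic-region sequences from FASTA
#'
#' Record ids of the form `gene|chrom:start-end(strand)` are parsed into
#' genomic coordinates; ids in any other form yield a sequence with
#' placeholder coordinates (`chrom = "."`, `start = 1`).
#'
#' @param path FASTA file path.
#' @return A named list of [igr_sequence()] objects (named by gene).
#' @export
read_igr_fasta <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("FASTA not found: '%s'", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop_format(sprintf("no records in '%s'", path))
  out <- lapply(seq_along(set), function(i) {
    id <- names(set)[i]
    s <- as.character(set[[i]])
    m <- regmatches(id, regexec(
      "^([^|]+)\\|([^:]+):([0-9]+)-([0-9]+)\\(([+-])\\)", id))[[1]]
    if (length(m) == 6L) {
      igr_sequence(m[2], m[3], as.integer(m[4]), as.integer(m[5]), m[6], s)
    } else {
      igr_sequence(strsplit(id, "\\s+")[[1]][1], ".", 1L, nchar(s), "+", s)
    }
  })
  names(out) <- map_chr(out, "gene")
  out
}

#' Read a per-base conservation track from bedGraph
#'
#' Expands bedGraph intervals onto the bases of an IGR. Bases not covered
#' by any interval take the documented default score 0. Scores outside
#' `[0, 1]` are a validation error naming the offending interval.
#'
#' @param path bedGraph file path (columns chrom, start, end, score;
#'   0-based half-open coordinates).
#' @param igr The [igr_sequence()] the track aligns to; only intervals on
#'   its chromosome contribute.
#' @return Numeric vector with one score per IGR base.
#' @export
read_bedgraph_track <- function(path, igr) {
  if (!file.exists(path)) stop_format(sprintf("bedGraph not found: '%s'", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  sc <- gr$score
  bad <- which(is.na(sc) | sc < 0 | sc > 1)
  if (length(bad) > 0) {
    stop_format(sprintf("bedGraph row %d: score %s outside [0, 1]",
                        bad[1], format(sc[bad[1]])))
  }
  len <- nchar(igr$seq)
  track <- rep(0, len)
  keep <- as.character(GenomicRanges::seqnames(gr)) == igr$chrom
  gr <- gr[keep]
  if (length(gr) > 0) {
    # GRanges from bedGraph import are already 1-based inclusive
    s <- pmax(GenomicRanges::start(gr), igr$start) - igr$start + 1L
    e <- pmin(GenomicRanges::end(gr), igr$end) - igr$start + 1L
    ok <- s <= e
    for (i in which(ok)) track[s[i]:e[i]] <- gr$score[i]
  }
  track
}
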