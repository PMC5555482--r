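# Synthetic intergenic-region pairs with planted shared motifs and piecewise
# conservation tracks. Backgrounds are rejection-sampled so the planted
# motifs are the ONLY shared maximal matches at the guard k-mer length;
# silent acceptance of accidental collisions would corrupt ground truth, so
# exhausting the attempt budget is an error.

#' Specify a planted-motif sequence pair
#'
#' @param len_a,len_b Sequence lengths in bp.
#' @param gc GC content of the random backgrounds, in (0, 1).
#' @param motifs List of planted shared motifs, each a
#'   `list(motif = "ACGT...", offset_a = <0-based>, offset_b = <0-based>)`.
#'   Every motif must be ACGT-only, at least `guard_k` long, and fit inside
#'   both sequences.
#' @param plateaus_a,plateaus_b Conservation plateaus, each a
#'   `list(start, end, level)` with 0-based half-open span and level in
#'   `[0, 1]`, painted over a flat `base_cons` background.
#' @param base_cons Baseline conservation score.
#' @param guard_k Backgrounds are resampled until the two sequences share no
#'   maximal match of length >= `guard_k` other than the planted motifs, so
#'   ground truth is exact for any dotplot `k >= guard_k`.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget before erroring.
#' @return An object of class `motif_pair_spec`.
#' @export
motif_pair_spec <- function(len_a, len_b = len_a, gc = 0.4, motifs = list(),
                            plateaus_a = list(), plateaus_b = list(),
                            base_cons = 0.05, guard_k = 6L, seed = 1L,
                            max_attempts = 50L) {
  assert_scalar_number(len_a, "len_a", 10, 1e6)
  assert_scalar_number(len_b, "len_b", 10, 1e6)
  assert_scalar_number(gc, "gc", 0.05, 0.95)
  assert_scalar_number(base_cons, "base_cons", 0, 1)
  if (guard_k < 2) stop_param("`guard_k` must be >= 2")
  for (m in motifs) {
    if (!grepl("^[ACGT]+$", m$motif)) stop_param("planted motifs must be ACGT-only")
    if (nchar(m$motif) < guard_k) {
      stop_param("planted motifs must be at least `guard_k` long")
    }
    if (m$offset_a < 0 || m$offset_a + nchar(m$motif) > len_a ||
        m$offset_b < 0 || m$offset_b + nchar(m$motif) > len_b) {
      abort("planted motif does not fit inside both sequences",
            class = "embryogem_spec_error")
    }
  }
  check_plateaus <- function(pl, len, side) {
    for (p in pl) {
      if (p$start < 0 || p$end > len || p$start >= p$end ||
          p$level < 0 || p$level > 1) {
        stop_param(sprintf("invalid conservation plateau on side %s", side))
      }
    }
  }
  check_plateaus(plateaus_a, len_a, "a")
  check_plateaus(plateaus_b, len_b, "b")
  structure(
    list(len_a = as.integer(len_a), len_b = as.integer(len_b), gc = gc,
         motifs = motifs, plateaus_a = plateaus_a, plateaus_b = plateaus_b,
         base_cons = base_cons, guard_k = as.integer(guard_k),
         seed = as.integer(seed), max_attempts = as.integer(max_attempts)),
    class = "motif_pair_spec"
  )
}

random_dna <- function(len, gc) {
  sample(c("A", "C", "G", "T"), len, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Maximal exact matches by diagonal run scanning on the full position-pair
# equality matrix (N never matches anything, including N). Quadratic in
# sequence length; used to validate rejection-sampled backgrounds, and kept
# algorithmically disjoint from the k-mer-seeded matcher in
# find_shared_matches().
scan_matches_diagonal <- function(a, b, k) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  na_ <- length(ca); nb_ <- length(cb)
  code <- function(x, n_code) {
    i <- match(x, c("A", "C", "G", "T"))
    i[is.na(i)] <- n_code
    i
  }
  ia <- code(ca, -1L)  # N on the two sides gets distinct codes,
  ib <- code(cb, -2L)  # so N never equals N
  E <- outer(ia, ib, "==")
  prev <- matrix(FALSE, na_, nb_)
  if (na_ > 1 && nb_ > 1) prev[-1, -1] <- E[-na_, -nb_]
  nxt <- matrix(FALSE, na_, nb_)
  if (na_ > 1 && nb_ > 1) nxt[-na_, -nb_] <- E[-1, -1]
  starts <- which(E & !prev, arr.ind = TRUE)
  ends <- which(E & !nxt, arr.ind = TRUE)
  ds <- starts[, 1] - starts[, 2]
  de <- ends[, 1] - ends[, 2]
  os <- order(ds, starts[, 1])
  oe <- order(de, ends[, 1])
  s <- starts[os, , drop = FALSE]
  e <- ends[oe, , drop = FALSE]
  len <- e[, 1] - s[, 1] + 1L
  keep <- len >= k
  res <- tibble(
    q_start = as.integer(s[keep, 1] - 1L),
    q_end = as.integer(e[keep, 1]),
    s_start = as.integer(s[keep, 2] - 1L),
    s_end = as.integer(e[keep, 2]),
    length = as.integer(len[keep])
  )
  res$motif <- if (nrow(res) > 0) {
    substring(toupper(a), res$q_start + 1L, res$q_end)
  } else {
    character(0)
  }
  arrange(res, .data$q_start, .data$s_start)
}

#' Generate a planted-motif sequence pair with conservation tracks
#'
#' Draws two random backgrounds, plants the shared motifs at their stated
#' offsets, and verifies by a full maximal-match scan that the planted
#' motifs are the only shared matches of length >= `guard_k`; otherwise the
#' backgrounds are redrawn, up to `max_attempts` times.
#'
#' @param spec A [motif_pair_spec()].
#' @return A list with `seq_a`, `seq_b` ([igr_sequence()] objects), `track_a`,
#'   `track_b` (per-base conservation vectors) and `truth` (tibble of the
#'   planted matches with columns q_start, q_end, s_start, s_end, length,
#'   motif; 0-based half-open offsets).
#' @examples
#' sp <- motif_pair_spec(200, 200, motifs = list(
#'   list(motif = "ACGTACGTAC", offset_a = 20, offset_b = 100)), seed = 4)
#' pair <- make_igr_pair(sp)
#' pair$truth
#' @export
make_igr_pair <- function(spec) {
  if (!inherits(spec, "motif_pair_spec")) stop_param("`spec` must be a motif_pair_spec")
  truth <- tibble(
    q_start = map_int(spec$motifs, ~ as.integer(.x$offset_a)),
    s_start = map_int(spec$motifs, ~ as.integer(.x$offset_b)),
    length = map_int(spec$motifs, ~ nchar(.x$motif)),
    motif = map_chr(spec$motifs, ~ toupper(.x$motif))
  ) |>
    mutate(q_end = .data$q_start + .data$length,
           s_end = .data$s_start + .data$length) |>
    select("q_start", "q_end", "s_start", "s_end", "length", "motif") |>
    arrange(.data$q_start, .data$s_start)

  in_spans <- function(pos0, starts0, ends0) {
    # pos0 0-based scalar-or-vector; spans 0-based half-open
    out <- rep(FALSE, length(pos0))
    for (i in seq_along(starts0)) {
      out <- out | (pos0 >= starts0[i] & pos0 < ends0[i])
    }
    out
  }
  seqs <- with_seed(spec$seed, {
    ca <- random_dna(spec$len_a, spec$gc)
    cb <- random_dna(spec$len_b, spec$gc)
    for (m in spec$motifs) {
      mm <- strsplit(toupper(m$motif), "")[[1]]
      ca[(m$offset_a + 1):(m$offset_a + length(mm))] <- mm
      cb[(m$offset_b + 1):(m$offset_b + length(mm))] <- mm
    }
    done <- FALSE
    # Repair pass: any shared maximal match other than a planted motif gets
    # one of its background bases mutated (on the B side where possible,
    # else on A); rescan until only the planted set remains.
    for (attempt in seq_len(spec$max_attempts)) {
      a <- paste(ca, collapse = "")
      b <- paste(cb, collapse = "")
      found <- scan_matches_diagonal(a, b, spec$guard_k)
      extra <- dplyr::anti_join(found, truth,
                                by = c("q_start", "s_start", "length"))
      missing_planted <- dplyr::anti_join(truth, found,
                                          by = c("q_start", "s_start", "length"))
      if (nrow(extra) == 0L && nrow(missing_planted) == 0L) {
        done <- TRUE
        break
      }
      # A planted motif missing from the scan is either destroyed (defensive;
      # repairs never touch planted spans) or accidentally extended -- the
      # extended match shows up in `extra`, and mutating its background
      # flanks below restores the planted coordinates.
      for (i in seq_len(nrow(missing_planted))) {
        mm <- strsplit(missing_planted$motif[i], "")[[1]]
        qa <- (missing_planted$q_start[i] + 1):(missing_planted$q_end[i])
        sb <- (missing_planted$s_start[i] + 1):(missing_planted$s_end[i])
        ca[qa] <- mm
        cb[sb] <- mm
      }
      for (i in seq_len(nrow(extra))) {
        cand_b <- extra$s_start[i]:(extra$s_end[i] - 1L)
        cand_b <- cand_b[!in_spans(cand_b, truth$s_start, truth$s_end)]
        if (length(cand_b) > 0L) {
          p <- cand_b[ceiling(length(cand_b) / 2)]
          cb[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), cb[p + 1L]), 1)
        } else {
          cand_a <- extra$q_start[i]:(extra$q_end[i] - 1L)
          cand_a <- cand_a[!in_spans(cand_a, truth$q_start, truth$q_end)]
          if (length(cand_a) == 0L) {
            abort("planted motifs themselves share k-mers; ground truth is infeasible",
                  class = "embryogem_spec_error")
          }
          p <- cand_a[ceiling(length(cand_a) / 2)]
          ca[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), ca[p + 1L]), 1)
        }
      }
    }
    if (!done) {
      abort(sprintf(
        "could not rid backgrounds of accidental shared %d-mers in %d repair passes",
        spec$guard_k, spec$max_attempts), class = "embryogem_spec_error")
    }
    list(a = paste(ca, collapse = ""), b = paste(cb, collapse = ""))
  })

  make_track <- function(len, plateaus) {
    tr <- rep(spec$base_cons, len)
    for (p in plateaus) tr[(p$start + 1):p$end] <- p$level
    tr
  }
  list(
    seq_a = igr_sequence("geneA", "2L", 100001L,
                         100000L + spec$len_a, "+", seqs$a),
    seq_b = igr_sequence("geneB", "3R", 250001L,
                         250000L + spec$len_b, "+", seqs$b),
    track_a = make_track(spec$len_a, spec$plateaus_a),
    track_b = make_track(spec$len_b, spec$plateaus_b),
    truth = truth
  )
}

#' Write a synthetic sequence pair to disk
#'
#' Emits the formats the dotplot pipeline consumes: one FASTA per sequence
#' (record id `gene|chrom:start-end(strand)`), one bedGraph conservation
#' track per sequence (run-length condensed), and the ground-truth match
#' table as TSV.
#'
#' @param pair A [make_igr_pair()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_igr_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(s, track, stem) {
    atomic_write(file.path(dir, paste0(stem, ".fasta")), function(p) {
      writeLines(c(sprintf(">%s|%s:%d-%d(%s)", s$gene, s$chrom, s$start,
                           s$end, s$strand),
                   s$seq), p)
    })
    r <- rle(track)
    stops <- cumsum(r$lengths)
    starts0 <- c(0L, head(stops, -1))  # bedGraph is 0-based half-open
    atomic_write(file.path(dir, paste0(stem, ".bedgraph")), function(p) {
      writeLines(sprintf("%s\t%d\t%d\t%g", s$chrom,
                         s$start - 1L + starts0, s$start - 1L + stops,
                         r$values), p)
    })
  }
  write_one(pair$seq_a, pair$track_a, "a")
  write_one(pair$seq_b, pair$track_b, "b")
  atomic_write(file.path(dir, "truth_matches.tsv"), function(p) {
    readr::write_tsv(pair$truth, p)
  })
  invisible(dir)
}
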