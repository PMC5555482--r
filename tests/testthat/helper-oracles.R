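# Independent brute-force oracles. Deliberately written with the most
# direct algorithm available (per-pixel / per-diagonal loops), sharing no
# code with the package implementations they check.

# All-start-pairs maximal-match oracle: walk every diagonal of the
# comparison, extend runs of equal characters, keep runs >= k. N matches
# nothing (not even N).
oracle_matches <- function(a, b, k) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  na_ <- length(ca); nb_ <- length(cb)
  out <- list()
  for (d in (-(nb_ - 1)):(na_ - 1)) {
    i0 <- max(1, 1 + d)            # a-index where diagonal enters
    j0 <- i0 - d
    len_d <- min(na_ - i0, nb_ - j0) + 1
    if (len_d < k) next
    ai <- ca[i0:(i0 + len_d - 1)]
    bj <- cb[j0:(j0 + len_d - 1)]
    eq <- ai == bj & ai != "N" & bj != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (t in which(r$values & r$lengths >= k)) {
      qs <- i0 + starts[t] - 2     # 0-based
      ss <- j0 + starts[t] - 2
      out[[length(out) + 1]] <- c(qs, qs + r$lengths[t], ss, ss + r$lengths[t],
                                  r$lengths[t])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          length = integer(), motif = character()))
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(q_start = as.integer(m[, 1]), q_end = as.integer(m[, 2]),
                        s_start = as.integer(m[, 3]), s_end = as.integer(m[, 4]),
                        length = as.integer(m[, 5]))
  res$motif <- substring(toupper(a), res$q_start + 1, res$q_end)
  res[order(res$q_start, res$s_start), ]
}

# Per-gene search oracle: intersect the query coordinates with each gene's
# mask independently, one pixel at a time.
oracle_gem_search <- function(masks, query_pixels, min_score) {
  t_q <- nrow(query_pixels)
  genes <- names(masks)
  n <- integer(length(genes))
  for (gi in seq_along(genes)) {
    m <- masks[[gi]]
    cnt <- 0L
    for (r in seq_len(t_q)) {
      if (m[query_pixels$y[r] + 1, query_pixels$x[r] + 1]) cnt <- cnt + 1L
    }
    n[gi] <- cnt
  }
  res <- tibble::tibble(gene = genes, score = n / t_q, n = n, t = t_q)
  res <- res[res$n / res$t >= min_score - 1e-12, ]
  res <- res[order(-res$score, res$gene), ]
  res$rank <- seq_len(nrow(res))
  res
}

# Pairwise Jaccard oracle, plain double loop over pixels.
oracle_jaccard <- function(a, b) {
  inter <- 0L; un <- 0L
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1L
    if (a[i] || b[i]) un <- un + 1L
  }
  if (un == 0L) NA_real_ else inter / un
}

random_mask <- function(h, w, p = 0.2) {
  matrix(runif(h * w) < p, nrow = h, ncol = w)
}

random_seq <- function(len, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small profile tibble straight from masks
profiles_from_masks <- function(masks, key = gem_key("BDGP", "4-6", "lateral")) {
  tibble::tibble(
    gene = names(masks), source = key$source, stage_bin = key$stage_bin,
    orientation = key$orientation, n_source_images = 1L,
    mask = unname(masks)
  )
}
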