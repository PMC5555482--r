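# Coexpression search. Two scores:
#   GEM n/t: n = search pixels expressed in the candidate gene's profile,
#            t = total search pixels;
#   Jaccard: |intersection| / |union| of two profiles' black pixels (the
#            legacy pairwise search).
# Threshold filtering is decided on exact integer (n, t) cross-products, so
# printed thresholds like "at least 25% similarity" never misclassify at
# the boundary.

new_hitlist <- function(hits, method, key, threshold, query_description) {
  structure(hits,
            class = c("embryogem_hitlist", class(tibble())),
            method = method, key = key, threshold = threshold,
            query_description = query_description)
}

rank_hits <- function(hits) {
  hits <- hits |> arrange(desc(.data$score), .data$gene)
  hits$rank <- seq_len(nrow(hits))
  hits
}

#' Search a GEM with a pixel query (n/t score)
#'
#' For every gene in the GEM, counts the search pixels at which that gene is
#' expressed (`n`), scores it `n / t` with `t` the total number of search
#' pixels, and returns the genes passing `min_score`, ranked by score
#' (ties broken by gene identifier). Genes scoring 0 appear (at the tail)
#' only when `min_score = 0`.
#'
#' @param gem A [build_gem()] result.
#' @param query A `pixel_query`; every pixel must lie inside the GEM frame.
#' @param min_score Minimum n/t score to report, in `[0, 1]`; compared with
#'   `>=` using exact rational arithmetic on `(n, t)`.
#' @return A hitlist tibble with columns `gene`, `score`, `n`, `t`, `rank`,
#'   sorted by descending score.
#' @examples
#' lib <- make_library(library_spec(5, frame = c(64, 32), seed = 3))
#' gem <- build_gem(truth_profiles(lib))
#' q <- query_from_profile(truth_profiles(lib)[1, ])
#' gem_search(gem, q, min_score = 0.25)
#' @export
gem_search <- function(gem, query, min_score = 0) {
  if (!inherits(gem, "gem")) stop_param("`gem` must be a gem")
  if (!inherits(query, "pixel_query")) stop_param("`query` must be a pixel_query")
  assert_scalar_number(min_score, "min_score", 0, 1)
  w <- gem$frame[1]; h <- gem$frame[2]
  px <- query$pixels
  if (any(px$x < 0 | px$x >= w | px$y < 0 | px$y >= h)) {
    abort("query pixel outside the GEM frame",
          class = "embryogem_coordinate_error")
  }
  idx <- px$x * h + px$y + 1L
  t_q <- length(idx)
  n_vec <- as.integer(colSums(gem$masks[idx, , drop = FALSE]))
  hits <- tibble(gene = gem$genes, score = n_vec / t_q, n = n_vec, t = t_q)
  hits <- hits[score_passes(hits$n, hits$t, min_score), ]
  new_hitlist(rank_hits(hits), method = "gem", key = gem$key,
              threshold = min_score,
              query_description = sprintf("%s query, t=%d, coverage %.3g",
                                          query$origin, t_q, query$coverage))
}

#' Jaccard similarity of two binary masks
#'
#' Intersection of black pixels divided by their union. Symmetric, in
#' `[0, 1]`, and 1 exactly for identical non-empty masks. When both masks
#' are empty the similarity is undefined and `NA` is returned (never 0).
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return A fraction in `[0, 1]`, or `NA` if both masks are empty.
#' @export
jaccard <- function(a, b) {
  assert_binary_mask(a, "a")
  assert_binary_mask(b, "b")
  if (!identical(dim(a), dim(b))) {
    stop_consistency("masks must share dimensions")
  }
  un <- sum(a | b)
  if (un == 0L) return(NA_real_)
  sum(a & b) / un
}

#' Pairwise (Jaccard) profile search
#'
#' The legacy search: scores every library profile against the query
#' profile by Jaccard similarity of their masks. In the returned hitlist
#' `n` and `t` are the intersection and union pixel counts, so `score =
#' n / t` still holds.
#'
#' @param profiles Profile tibble or list of `expression_profile`s, all
#'   sharing the query's key and frame.
#' @param query_profile The query `expression_profile` (or one-row profile
#'   tibble).
#' @param min_sim Minimum Jaccard similarity to report (exact `>=` on
#'   `(n, t)`).
#' @return A hitlist tibble (`gene`, `score`, `n`, `t`, `rank`).
#' @export
pairwise_search <- function(profiles, query_profile, min_sim = 0) {
  if (is.data.frame(query_profile)) query_profile <- profile_from_row(query_profile)
  if (!inherits(query_profile, "expression_profile")) {
    stop_param("`query_profile` must be an expression profile")
  }
  assert_scalar_number(min_sim, "min_sim", 0, 1)
  if (is.data.frame(profiles)) {
    plist <- lapply(seq_len(nrow(profiles)), function(i) profile_from_row(profiles[i, ]))
  } else {
    plist <- profiles
  }
  dims <- unique(map(plist, ~ dim(.x$mask)))
  if (length(dims) != 1L || !identical(dims[[1]], dim(query_profile$mask))) {
    stop_consistency("library and query profiles must share frame dimensions")
  }
  if (any(map_chr(plist, ~ format(.x$key)) != format(query_profile$key))) {
    stop_consistency("library profiles must share the query's key")
  }
  qv <- as.numeric(query_profile$mask)
  tq <- sum(qv)
  M <- vapply(plist, function(p) as.numeric(p$mask), numeric(length(qv)))
  inter <- as.integer(crossprod(M, qv))
  un <- as.integer(colSums(M) + tq - inter)
  hits <- tibble(gene = map_chr(plist, "gene"),
                 score = ifelse(un > 0L, inter / un, NA_real_),
                 n = inter, t = un)
  defined <- un > 0L
  keep <- defined & score_passes(hits$n, pmax(hits$t, 1L), min_sim)
  hits <- hits[keep, ]
  new_hitlist(rank_hits(hits), method = "pairwise", key = query_profile$key,
              threshold = min_sim,
              query_description = sprintf("pairwise vs %s", query_profile$gene))
}

#' @export
print.embryogem_hitlist <- function(x, ...) {
  cat(sprintf("<hitlist> %s search, %s, threshold %.3g: %d hit(s)\n",
              attr(x, "method"), attr(x, "query_description"),
              attr(x, "threshold"), nrow(x)))
  NextMethod()
}

#' Export / import a hitlist as CSV
#'
#' The downloadable gene-list format: comma-separated with header
#' `gene,score,n,t,rank`. [write_gene_list()] writes the bare ranked gene
#' identifiers, one per line, suitable for pasting into batch query pages
#' of gene-annotation databases.
#'
#' @param hits A hitlist tibble.
#' @param path Output file path.
#' @return `path`, invisibly; `read_hitlist()` returns the hit tibble.
#' @export
write_hitlist <- function(hits, path) {
  out <- as_tibble(hits)[, c("gene", "score", "n", "t", "rank")]
  atomic_write(path, function(p) readr::write_csv(out, p))
}

#' @rdname write_hitlist
#' @export
read_hitlist <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    score = readr::col_double(),
                    n = readr::col_integer(),
                    t = readr::col_integer(),
                    rank = readr::col_integer()))
}

#' @rdname write_hitlist
#' @export
write_gene_list <- function(hits, path) {
  atomic_write(path, function(p) writeLines(hits$gene, p))
}
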