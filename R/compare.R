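# Formal comparison of the two searches. For a full-coverage query built
# from profile A, jaccard(A, B) = |A&B| / |A|B-union| <= |A&B| / |A| =
# n/t = gem score, so at any common threshold the pairwise result set is a
# subset of the GEM result set. compare_methods() computes both scores per
# gene, the per-threshold result-set sizes, and checks that subset relation.

#' Compare GEM-based and pairwise search on one query
#'
#' Runs both searches for a query profile against the same library, pairs
#' each gene's Jaccard similarity with its GEM n/t score (the scatter view
#' of the comparison), tabulates result-set sizes at the given thresholds,
#' and, for full-coverage queries, checks that every pairwise hit is also a
#' GEM hit at each threshold.
#'
#' @param gem The [build_gem()] result built from `profiles`.
#' @param profiles The profile tibble (or list) the GEM was built from.
#' @param query_profile The query `expression_profile` (or one-row profile
#'   tibble).
#' @param coverage Pixel coverage of the GEM query in (0, 1]; fractions
#'   below 1 subsample the query's search pixels (see [subsample_query()]).
#'   The pairwise side always uses the full profile masks.
#' @param seed Seed for the coverage subsample.
#' @param thresholds Score thresholds at which to compare result sets.
#' @return An object of class `search_comparison`: list with `scores`
#'   (tibble gene, jaccard, gem_score, n/t counts for both methods),
#'   `thresholds` (tibble threshold, n_pairwise, n_gem, subset_ok),
#'   `coverage`, `seed` and `query_gene`. `subset_ok` is `NA` when
#'   `coverage < 1`, where the subset relation is not guaranteed.
#' @examples
#' lib <- make_library(library_spec(8, frame = c(64, 32), seed = 5))
#' profs <- truth_profiles(lib)
#' cmp <- compare_methods(build_gem(profs), profs, profs[1, ])
#' cmp$thresholds
#' @export
compare_methods <- function(gem, profiles, query_profile, coverage = 1,
                            seed = 1L, thresholds = c(0.25, 0.5)) {
  if (is.data.frame(query_profile)) query_profile <- profile_from_row(query_profile)
  q <- query_from_profile(query_profile)
  if (coverage < 1) q <- subsample_query(q, coverage, seed)
  gem_hits <- gem_search(gem, q, min_score = 0)
  pair_hits <- pairwise_search(profiles, query_profile, min_sim = 0)
  scores <- as_tibble(pair_hits) |>
    select(gene = "gene", jaccard = "score",
           n_pairwise = "n", t_pairwise = "t") |>
    left_join(as_tibble(gem_hits) |>
                select(gene = "gene", gem_score = "score",
                       n_gem = "n", t_gem = "t"),
              by = "gene") |>
    arrange(.data$gene)
  thr_tbl <- purrr::map_dfr(thresholds, function(th) {
    pair_pass <- scores$gene[score_passes(scores$n_pairwise,
                                          scores$t_pairwise, th)]
    gem_pass <- scores$gene[score_passes(scores$n_gem, scores$t_gem, th)]
    tibble(threshold = th,
           n_pairwise = length(pair_pass),
           n_gem = length(gem_pass),
           subset_ok = if (coverage == 1) all(pair_pass %in% gem_pass) else NA)
  })
  structure(list(scores = scores, thresholds = thr_tbl,
                 coverage = coverage, seed = seed,
                 query_gene = query_profile$gene),
            class = "search_comparison")
}

#' @export
print.search_comparison <- function(x, ...) {
  cat(sprintf("<search_comparison> query %s, coverage %.3g, %d genes\n",
              x$query_gene, x$coverage, nrow(x$scores)))
  print(x$thresholds)
  invisible(x)
}

#' @describeIn compare_methods Per-gene (jaccard, gem_score) pairs.
#' @param x,object A `search_comparison`.
#' @param ... Unused.
#' @export
tidy.search_comparison <- function(x, ...) x$scores

#' @describeIn compare_methods One-row summary including whether the
#'   pairwise-subset relation held at every threshold checked.
#' @export
glance.search_comparison <- function(x, ...) {
  tibble(query_gene = x$query_gene,
         n_genes = nrow(x$scores),
         coverage = x$coverage,
         all_subset_ok = all(x$thresholds$subset_ok))
}

#' @describeIn compare_methods Scatter of GEM n/t score against Jaccard
#'   similarity, one point per gene, with the identity line; points below
#'   the line are impossible for full-coverage queries.
#' @export
autoplot.search_comparison <- function(object, ...) {
  object$scores |>
    ggplot(aes(x = .data$jaccard, y = .data$gem_score)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Jaccard pairwise similarity", y = "GEM n/t coexpression",
         title = sprintf("Pairwise vs GEM search (query %s, coverage %.0f%%)",
                         object$query_gene, 100 * object$coverage)) +
    theme_minimal()
}

#' Export the comparison scatter as CSV
#'
#' Columns `gene,jaccard,gem_score`.
#'
#' @param cmp A `search_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  out <- cmp$scores |> select("gene", "jaccard", "gem_score")
  atomic_write(path, function(p) readr::write_csv(out, p))
}
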