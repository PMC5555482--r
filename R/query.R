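# Pixel queries: the "search pixels" a GEM is interrogated with. A query is
# an ordered set of distinct in-frame coordinates; t (the n/t denominator)
# is the number of search pixels.

new_pixel_query <- function(pixels, origin, coverage = 1, seed = NULL) {
  structure(list(pixels = pixels, origin = origin,
                 coverage = coverage, seed = seed),
            class = "pixel_query")
}

#' @export
print.pixel_query <- function(x, ...) {
  cat(sprintf("<pixel_query> %d search pixels (origin: %s, coverage %.3g)\n",
              nrow(x$pixels), x$origin, x$coverage))
  invisible(x)
}

mask_to_coords <- function(mask) {
  h <- nrow(mask)
  idx0 <- which(as.vector(mask)) - 1L
  tibble(x = idx0 %/% h, y = idx0 %% h)
}

#' Build a pixel query from a profile
#'
#' Takes the collection of expressed (black) pixels of a binary expression
#' profile as the search pixels.
#'
#' @param profile An `expression_profile` (see [composite_profile()]) or a
#'   single-row profile tibble.
#' @return An object of class `pixel_query` with `coverage = 1`.
#' @export
query_from_profile <- function(profile) {
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1L) stop_param("pass exactly one profile row")
    profile <- profile_from_row(profile)
  }
  if (!inherits(profile, "expression_profile")) {
    stop_param("`profile` must be an expression profile")
  }
  if (!any(profile$mask)) {
    abort("empty query: profile has no expressed pixels",
          class = "embryogem_empty_query_error")
  }
  new_pixel_query(mask_to_coords(profile$mask), origin = "profile")
}

#' Build a pixel query from a painted mask
#'
#' The painting entry point: regions of interest highlighted directly onto
#' a GEM frame become search pixels.
#'
#' @param painted Frame-sized logical matrix with at least one `TRUE` pixel.
#' @return A `pixel_query` with origin `"painted_mask"`.
#' @export
query_from_mask <- function(painted) {
  assert_binary_mask(painted, "painted")
  if (!any(painted)) {
    abort("empty query: painted mask has no pixels",
          class = "embryogem_empty_query_error")
  }
  new_pixel_query(mask_to_coords(painted), origin = "painted_mask")
}

#' Build a pixel query from point coordinates
#'
#' The point-and-click entry point; a single pixel is a valid query.
#'
#' @param x,y Equal-length integer vectors of 0-based pixel coordinates
#'   (`x` = column from left, `y` = row from top), no duplicates.
#' @return A `pixel_query` with origin `"points"`.
#' @export
query_from_points <- function(x, y) {
  if (length(x) != length(y) || length(x) == 0L) {
    stop_param("`x` and `y` must be non-empty and of equal length")
  }
  if (any(x < 0) || any(y < 0)) stop_param("coordinates must be non-negative")
  pix <- tibble(x = as.integer(x), y = as.integer(y))
  if (anyDuplicated(pix)) stop_param("duplicate query pixels are not allowed")
  new_pixel_query(pix, origin = "points")
}

#' Subsample a query to a pixel coverage
#'
#' Retains `round(coverage * t)` search pixels (round half up, minimum 1),
#' drawn uniformly without replacement under `seed`. The implementation
#' permutes the pixel order once per seed and takes a prefix, so for a
#' fixed seed, subsets at decreasing coverage are nested.
#'
#' @param query A `pixel_query`.
#' @param coverage Fraction in (0, 1] of pixels to retain.
#' @param seed Integer seed making the draw reproducible.
#' @return A `pixel_query` with its `coverage` field scaled accordingly.
#' @export
subsample_query <- function(query, coverage, seed = 1L) {
  if (!inherits(query, "pixel_query")) stop_param("`query` must be a pixel_query")
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
      coverage <= 0 || coverage > 1) {
    stop_param("`coverage` must be in (0, 1]")
  }
  if (coverage == 1) return(query)
  t_full <- nrow(query$pixels)
  m <- max(1L, round_half_up(coverage * t_full))
  perm <- with_seed(seed, sample.int(t_full))
  new_pixel_query(query$pixels[perm[seq_len(m)], ],
                  origin = query$origin,
                  coverage = query$coverage * coverage, seed = seed)
}
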