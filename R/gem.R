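# The Genomewide Expression Map (GEM): per-key aggregate of all composite
# binary profiles. Conceptually an inverted index pixel -> set of expressed
# genes plus a per-pixel expression-count map; stored as a pixels x genes
# logical matrix (column subsetting turns a pixel-set query into one
# vectorized count per gene), from which the pixel-major view is derivable.

#' Build a Genomewide Expression Map
#'
#' Aggregates the composite profiles that share one (source, stage range,
#' orientation) key into a GEM: for every pixel, the set of genes expressed
#' there, plus the per-pixel count of expressed genes. Genes with all-empty
#' masks are retained in the gene set (they are legitimate "no expression
#' detected" records and rank with score 0), but index no pixel.
#'
#' @param profiles A profile tibble (see [build_profiles()],
#'   [truth_profiles()]) or a list of `expression_profile` objects; exactly
#'   one profile per gene.
#' @param key Optional [gem_key()]; defaults to the common key of the
#'   profiles. A profile with a different key is a consistency error.
#' @return An object of class `gem`: list with `key`, `frame`
#'   (`c(width, height)`), `genes`, `masks` (pixels x genes logical matrix,
#'   column-major pixel order) and `counts` (height x width integer matrix).
#' @examples
#' lib <- make_library(library_spec(5, frame = c(64, 32), seed = 3))
#' gem <- build_gem(truth_profiles(lib))
#' glance(gem)
#' @export
build_gem <- function(profiles, key = NULL) {
  if (is.data.frame(profiles)) {
    profiles <- lapply(seq_len(nrow(profiles)), function(i) {
      profile_from_row(profiles[i, ])
    })
  }
  if (length(profiles) < 1L) stop_param("at least one profile is required")
  if (!all(map_lgl(profiles, inherits, "expression_profile"))) {
    stop_param("`profiles` must be expression profiles or a profile tibble")
  }
  keys <- map_chr(profiles, ~ format(.x$key))
  if (is.null(key)) {
    if (length(unique(keys)) != 1L) {
      stop_consistency("profiles carry different keys; pass one key per GEM")
    }
    key <- profiles[[1]]$key
  }
  if (!inherits(key, "gem_key")) stop_param("`key` must be a gem_key")
  if (any(keys != format(key))) {
    stop_consistency("profile key does not match the GEM key")
  }
  genes <- map_chr(profiles, "gene")
  if (anyDuplicated(genes)) {
    stop_consistency(sprintf("duplicate gene for the same key: %s",
                             genes[duplicated(genes)][1]))
  }
  dims <- unique(map(profiles, ~ dim(.x$mask)))
  if (length(dims) != 1L) {
    stop_consistency("profiles must share frame dimensions")
  }
  h <- dims[[1]][1]; w <- dims[[1]][2]
  ord <- order(genes)
  profiles <- profiles[ord]
  genes <- genes[ord]
  M <- vapply(profiles, function(p) as.vector(p$mask), logical(h * w))
  colnames(M) <- genes
  counts <- matrix(as.integer(rowSums(M)), nrow = h, ncol = w)
  structure(list(key = key, frame = c(w, h), genes = genes,
                 masks = M, counts = counts),
            class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %s: %d genes on %dx%d frame, max %d genes/pixel\n",
              format(x$key), length(x$genes), x$frame[1], x$frame[2],
              max(x$counts)))
  invisible(x)
}

#' Per-pixel gene-count map of a GEM
#'
#' Global expression in the embryo at a glance: each pixel's value is the
#' number of genes expressed there.
#'
#' @param gem A [build_gem()] result.
#' @return Integer matrix (height x width).
#' @export
gem_heatmap <- function(gem) {
  if (!inherits(gem, "gem")) stop_param("`gem` must be a gem")
  gem$counts
}

#' Genes expressed at one pixel
#'
#' The pixel-major (inverted-index) view of the GEM.
#'
#' @param gem A `gem`.
#' @param x,y Pixel coordinate: `x` = column from left, `y` = row from top,
#'   both 0-based.
#' @return Character vector of gene identifiers (possibly empty).
#' @export
gem_genes_at <- function(gem, x, y) {
  h <- gem$frame[2]
  if (x < 0 || x >= gem$frame[1] || y < 0 || y >= h) {
    abort("pixel coordinate outside the GEM frame",
          class = "embryogem_coordinate_error")
  }
  idx <- x * h + y + 1
  gem$genes[gem$masks[idx, ]]
}

#' @describeIn build_gem Long tibble of the count map: one row per pixel
#'   with columns `x`, `y`, `count`.
#' @param x A `gem` (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.gem <- function(x, ...) {
  h <- x$frame[2]; w <- x$frame[1]
  cnt <- as.integer(x$counts)
  tibble(
    x = rep(0:(w - 1L), each = h),
    y = rep(0:(h - 1L), times = w),
    count = cnt
  )
}

#' @describeIn build_gem One-row summary: gene count, frame, occupied
#'   pixels, maximum per-pixel multiplicity.
#' @export
glance.gem <- function(x, ...) {
  tibble(
    n_genes = length(x$genes),
    width = x$frame[1],
    height = x$frame[2],
    occupied_pixels = sum(x$counts > 0L),
    max_count = max(x$counts)
  )
}

#' @describeIn build_gem Heatmap of the per-pixel gene counts.
#' @param object A `gem`.
#' @export
autoplot.gem <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$x, y = .data$y, fill = .data$count)) +
    geom_raster() +
    scale_fill_viridis_c(name = "genes/pixel") +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(title = paste("GEM", format(object$key)), x = "x (px)", y = "y (px)") +
    theme_minimal()
}
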