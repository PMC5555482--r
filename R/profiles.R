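# Image -> standardized frame -> binary mask -> per-gene composite profile.
# Coordinates follow the pixel convention (x, y) = (column, row), 0-based;
# matrices are stored height x width ([row, col]).

PROFILE_SOURCES <- c("BDGP", "FlyFISH", "PubMed")
PROFILE_ORIENTATIONS <- c("lateral", "dorsal", "ventral")

#' Default developmental stage bins
#'
#' Campos-Ortega stages 1-17 are binned into six ranges (1-3, 4-6, 7-8,
#' 9-10, 11-12, 13-16) for keying profiles and GEMs. An image whose stated
#' stage range straddles two bins is assigned to the bin containing the
#' midpoint of the range; half-integer midpoints on a bin boundary go to the
#' earlier bin, and midpoints above the last bin clamp into it (so stage-17
#' records remain assignable).
#'
#' @return A tibble with columns `lo`, `hi`, `label`.
#' @export
default_stage_bins <- function() {
  tibble(
    lo = c(1L, 4L, 7L, 9L, 11L, 13L),
    hi = c(3L, 6L, 8L, 10L, 12L, 16L),
    label = c("1-3", "4-6", "7-8", "9-10", "11-12", "13-16")
  )
}

#' Assign a stage range to a stage bin
#'
#' @param stage_lo,stage_hi Campos-Ortega stage bounds, integers in 1-17 with
#'   `stage_lo <= stage_hi`. Vectorized.
#' @param bins A bin table as from [default_stage_bins()].
#' @return Character vector of bin labels.
#' @export
stage_bin_label <- function(stage_lo, stage_hi, bins = default_stage_bins()) {
  if (any(stage_lo > stage_hi) || any(stage_lo < 1) || any(stage_hi > 17)) {
    stop_param("stage range must satisfy 1 <= stage_lo <= stage_hi <= 17")
  }
  mid <- (stage_lo + stage_hi) / 2
  vapply(mid, function(m) {
    inside <- which(bins$lo <= m & m <= bins$hi)
    if (length(inside) > 0) return(bins$label[inside[1]])
    # half-integer midpoint between bins, or beyond the bin range
    below <- which(bins$hi <= m)
    if (length(below) > 0) return(bins$label[max(below)])
    bins$label[1]
  }, character(1))
}

#' Construct a GEM key
#'
#' A key names one collection of images: same data source, stage range and
#' anatomical orientation. Profiles and GEMs are built per key, never
#' across keys.
#'
#' @param source One of `"BDGP"`, `"FlyFISH"`, `"PubMed"`.
#' @param stage_bin A stage-bin label, e.g. `"4-6"` (see
#'   [default_stage_bins()]).
#' @param orientation One of `"lateral"`, `"dorsal"`, `"ventral"`.
#' @return An object of class `gem_key`.
#' @export
gem_key <- function(source, stage_bin, orientation) {
  source <- match.arg(source, PROFILE_SOURCES)
  orientation <- match.arg(orientation, PROFILE_ORIENTATIONS)
  if (!is.character(stage_bin) || length(stage_bin) != 1L || is.na(stage_bin)) {
    stop_param("`stage_bin` must be a single bin label string")
  }
  structure(list(source = source, stage_bin = stage_bin,
                 orientation = orientation),
            class = "gem_key")
}

#' @export
format.gem_key <- function(x, ...) {
  sprintf("%s/%s/%s", x$source, x$stage_bin, x$orientation)
}

#' @export
print.gem_key <- function(x, ...) {
  cat("<gem_key>", format(x), "\n")
  invisible(x)
}

#' Standardize an embryo image to the common frame
#'
#' Segments the embryo as the largest connected component of pixels darker
#' than the image background (estimated as the median intensity of the
#' border pixels, minus a fixed offset of 16 intensity units), crops to its
#' bounding box and rescales to the standard frame by bilinear
#' interpolation. Deterministic for a fixed input; if the cropped region
#' already has frame dimensions the image is returned unchanged apart from
#' the crop.
#'
#' @param image Greyscale matrix (height x width, intensities 0-255).
#' @param frame Target `c(width, height)`, both at least 8.
#' @return Numeric matrix of dimensions `frame[2] x frame[1]`.
#' @export
standardize_image <- function(image, frame = c(320L, 160L)) {
  assert_grey_matrix(image)
  if (length(frame) != 2L || any(frame < 8)) {
    stop_param("`frame` must be c(width, height) with both dimensions >= 8")
  }
  h <- nrow(image); w <- ncol(image)
  border <- c(image[1, ], image[h, ], image[, 1], image[, w])
  bg <- median(border)
  fg <- image < bg - 16
  if (!any(fg)) {
    abort("empty image: no foreground component found",
          class = "embryogem_empty_image_error")
  }
  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  rows <- range(which(rowSums(comp) > 0))
  cols <- range(which(colSums(comp) > 0))
  crop <- image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  target <- c(frame[2], frame[1])  # rows, cols
  if (all(dim(crop) == target)) return(crop)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(crop / 255),
                                            w = target[1], h = target[2]))
  pmin(pmax(out * 255, 0), 255)
}

#' Binarize a standardized image into an expression mask
#'
#' Stain is dark on a light background, so a pixel is called expressed when
#' its intensity is at or below the threshold. `method = "otsu"` picks the
#' threshold by Otsu's criterion on the image histogram (256 levels);
#' `method = "fixed"` uses the given threshold.
#'
#' @param image Greyscale matrix, intensities 0-255.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required for `method = "fixed"`; in 0-255.
#' @return Logical matrix of the same dimensions; `TRUE` = expression.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  assert_grey_matrix(image)
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop_param("method = \"fixed\" requires `threshold`")
    assert_scalar_number(threshold, "threshold", 0, 255)
    threshold
  } else {
    EBImage::otsu(EBImage::Image(image / 255), range = c(0, 1), levels = 256) * 255
  }
  structure(image <= thr, dim = dim(image))
}

#' Combine per-image masks into a gene's composite profile
#'
#' The composite spatial expression of a gene under one key is the
#' pixel-wise union of its per-image masks: a pixel is part of the
#' composite if any curated image shows expression there.
#'
#' @param masks A logical mask matrix or list of them, all frame-sized.
#' @param gene Gene identifier.
#' @param key A [gem_key()].
#' @return An object of class `expression_profile`: list with `gene`, `key`,
#'   `mask`, `n_source_images`.
#' @export
composite_profile <- function(masks, gene, key) {
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) == 0L) stop_param("at least one mask is required")
  lapply(masks, assert_binary_mask)
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) {
    stop_consistency("masks for one composite must share frame dimensions")
  }
  if (!inherits(key, "gem_key")) stop_param("`key` must be a gem_key")
  mask <- Reduce(`|`, masks)
  structure(list(gene = gene, key = key, mask = mask,
                 n_source_images = length(masks)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s [%s] %dx%d, %d expressed px, %d image(s)\n",
              x$gene, format(x$key), ncol(x$mask), nrow(x$mask),
              sum(x$mask), x$n_source_images))
  invisible(x)
}

#' Build composite profiles from an annotation table
#'
#' The pipeline entry point: standardizes and binarizes every annotated
#' image, then unions masks per (gene, source, stage bin, orientation) into
#' composite profiles. Images can be supplied in memory (named list by
#' `image_id`) or read from the PNG paths in the annotation table.
#'
#' @param annotations Annotation tibble with columns `image_id`, `gene`,
#'   `source`, `stage_lo`, `stage_hi`, `orientation`, `genotype`, `path`
#'   (see [read_annotations()]).
#' @param images Optional named list of greyscale matrices keyed by
#'   `image_id`; when `NULL`, PNGs are read from `path` relative to
#'   `image_dir`.
#' @param image_dir Base directory for relative `path`s.
#' @param frame Standard frame `c(width, height)`.
#' @param method,threshold Binarization settings, see [binarize()].
#' @param bins Stage-bin table, see [default_stage_bins()].
#' @return A tibble with one row per (gene, key): columns `gene`, `source`,
#'   `stage_bin`, `orientation`, `n_source_images` and a `mask` list-column
#'   of frame-sized logical matrices.
#' @examples
#' lib <- make_library(library_spec(3, n_blocks = 1, block_size = 2,
#'                                  frame = c(64, 32), seed = 2))
#' profs <- build_profiles(lib$annotations, images = lib$images,
#'                         frame = c(64, 32))
#' profs[, c("gene", "stage_bin", "n_source_images")]
#' @export
build_profiles <- function(annotations, images = NULL, image_dir = ".",
                           frame = c(320L, 160L),
                           method = c("otsu", "fixed"), threshold = NULL,
                           bins = default_stage_bins()) {
  method <- match.arg(method)
  ann <- validate_annotations(annotations)
  ann$stage_bin <- stage_bin_label(ann$stage_lo, ann$stage_hi, bins)
  masks <- lapply(seq_len(nrow(ann)), function(i) {
    img <- if (!is.null(images)) {
      img <- images[[ann$image_id[i]]]
      if (is.null(img)) {
        stop_consistency(sprintf("no image supplied for image_id '%s'",
                                 ann$image_id[i]))
      }
      img
    } else {
      read_image_png(file.path(image_dir, ann$path[i]))
    }
    binarize(standardize_image(img, frame = frame),
             method = method, threshold = threshold)
  })
  ann$mask <- masks
  ann |>
    group_by(.data$gene, .data$source, .data$stage_bin, .data$orientation) |>
    summarise(n_source_images = dplyr::n(),
              mask = list(Reduce(`|`, .data$mask)),
              .groups = "drop") |>
    arrange(.data$gene)
}

# one expression_profile from a profile-tibble row
profile_from_row <- function(row) {
  structure(list(
    gene = row$gene,
    key = gem_key(row$source, row$stage_bin, row$orientation),
    mask = row$mask[[1]],
    n_source_images = row$n_source_images
  ), class = "expression_profile")
}
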