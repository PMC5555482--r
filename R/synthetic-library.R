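# Seeded synthetic image libraries with controlled coexpression structure.
# Blocks of genes share a domain template (optionally jittered), so the
# ground-truth Jaccard matrix has known high-similarity cells; remaining
# genes get independent random domains.

#' Specify a synthetic expression-image library
#'
#' A library is a set of genes, each with one rendered embryo image under a
#' shared (source, stage range, orientation) key. `n_blocks` blocks of
#' `block_size` genes share a domain template; with `jitter = 0` the members
#' of a block have identical masks (ground-truth Jaccard 1 between them).
#' The remaining genes receive independent random domains, every gene having
#' at least one stained domain.
#'
#' @param n_genes Number of genes (one composite image each).
#' @param n_blocks,block_size Coexpression blocks sharing a domain template.
#' @param jitter Spatial jitter of block-member domains, in pixels.
#' @param noise Additive uniform intensity noise amplitude for the images.
#' @param frame Frame dimensions `c(width, height)`.
#' @param source,stage_lo,stage_hi,orientation Annotation key fields shared
#'   by the whole library.
#' @param seed Integer seed; the whole library is reproducible from it.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_genes, n_blocks = 2, block_size = 3, jitter = 0,
                         noise = 0, frame = c(320L, 160L), source = "BDGP",
                         stage_lo = 4, stage_hi = 6, orientation = "lateral",
                         seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", 1, 1e5)
  assert_scalar_number(jitter, "jitter", 0, 100)
  if (n_blocks * block_size > n_genes) {
    stop_param("n_blocks * block_size must not exceed n_genes")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_blocks = as.integer(n_blocks),
         block_size = as.integer(block_size), jitter = jitter, noise = noise,
         frame = as.integer(frame), source = source, stage_lo = stage_lo,
         stage_hi = stage_hi, orientation = orientation,
         seed = as.integer(seed)),
    class = "library_spec"
  )
}

random_domain <- function(frame, jitter_px = 0, base = NULL) {
  if (is.null(base)) {
    if (runif(1) < 0.6) {
      base <- list(kind = "stripe",
                   axis = if (runif(1) < 0.8) "x" else "y",
                   position = runif(1, 0.2, 0.8),
                   width = runif(1, 0.09, 0.18),
                   intensity = 40)
    } else {
      base <- list(kind = "patch", cx = runif(1, 0.3, 0.7),
                   cy = runif(1, 0.4, 0.6), r = runif(1, 0.06, 0.09),
                   intensity = 40)
    }
  }
  d <- base
  if (jitter_px > 0) {
    if (d$kind == "stripe") {
      dim_len <- if (d$axis == "x") frame[1] else frame[2]
      d$position <- min(0.85, max(0.15, d$position + runif(1, -jitter_px, jitter_px) / dim_len))
    } else if (d$kind == "patch") {
      d$cx <- min(0.7, max(0.3, d$cx + runif(1, -jitter_px, jitter_px) / frame[1]))
      d$cy <- min(0.6, max(0.4, d$cy + runif(1, -jitter_px, jitter_px) / frame[2]))
    }
  }
  structure(d, class = "embryo_domain")
}

#' Generate a synthetic library
#'
#' Renders every gene's image, builds the annotation table the image pipeline
#' consumes, and computes the ground-truth composite masks and the
#' ground-truth pairwise Jaccard matrix directly from the planted masks.
#'
#' @param spec A [library_spec()].
#' @return An object of class `embryo_library`: a list with `spec`, `key`
#'   (the [gem_key()] of the library), `genes`, `annotations` (tibble with
#'   columns image_id, gene, source, stage_lo, stage_hi, orientation,
#'   genotype, path), `images` (named list of greyscale matrices, by
#'   image_id), `masks` (named list of ground-truth logical masks, by gene)
#'   and `jaccard_truth` (genes x genes matrix).
#' @examples
#' lib <- make_library(library_spec(6, frame = c(80, 40), seed = 7))
#' lib$jaccard_truth[1:3, 1:3]
#' @export
make_library <- function(spec) {
  if (!inherits(spec, "library_spec")) stop_param("`spec` must be a library_spec")
  frame <- spec$frame
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  out <- with_seed(spec$seed, {
    dom_sets <- vector("list", spec$n_genes)
    idx <- 1L
    for (b in seq_len(spec$n_blocks)) {
      n_dom <- sample(1:2, 1)
      template <- lapply(seq_len(n_dom), function(i) random_domain(frame))
      for (m in seq_len(spec$block_size)) {
        dom_sets[[idx]] <- lapply(template, function(d) {
          random_domain(frame, jitter_px = spec$jitter, base = d)
        })
        idx <- idx + 1L
      }
    }
    while (idx <= spec$n_genes) {
      n_dom <- sample(1:2, 1)
      dom_sets[[idx]] <- lapply(seq_len(n_dom), function(i) random_domain(frame))
      idx <- idx + 1L
    }
    rendered <- lapply(dom_sets, function(doms) {
      make_embryo_image(embryo_spec(frame = frame, domains = doms,
                                    noise = spec$noise, seed = NULL))
    })
    rendered
  })
  masks <- lapply(out, `[[`, "mask")
  names(masks) <- genes
  image_ids <- paste0(genes, "_im1")
  images <- lapply(out, `[[`, "image")
  names(images) <- image_ids

  ann <- tibble(
    image_id = image_ids, gene = genes, source = spec$source,
    stage_lo = spec$stage_lo, stage_hi = spec$stage_hi,
    orientation = spec$orientation, genotype = "wild type",
    path = file.path("images", paste0(image_ids, ".png"))
  )

  M <- vapply(masks, as.numeric, numeric(prod(frame)))
  inter <- crossprod(M)
  sizes <- colSums(M)
  un <- outer(sizes, sizes, "+") - inter
  jac <- ifelse(un > 0, inter / un, NA_real_)
  dimnames(jac) <- list(genes, genes)

  structure(
    list(spec = spec, key = gem_key(spec$source,
                                    stage_bin_label(spec$stage_lo, spec$stage_hi),
                                    spec$orientation),
         genes = genes, annotations = ann, images = images, masks = masks,
         jaccard_truth = jac),
    class = "embryo_library"
  )
}

#' @export
print.embryo_library <- function(x, ...) {
  cat(sprintf("<embryo_library> %d genes, frame %dx%d, key %s\n",
              length(x$genes), x$spec$frame[1], x$spec$frame[2],
              format(x$key)))
  invisible(x)
}

#' Ground-truth profiles of a synthetic library
#'
#' Builds the binary expression profiles of a library directly from its
#' planted ground-truth masks, bypassing image rendering and thresholding.
#' Useful when the object under test is the search layer, not the image
#' pipeline.
#'
#' @param lib An [make_library()] result.
#' @return A profile tibble as returned by [build_profiles()].
#' @export
truth_profiles <- function(lib) {
  if (!inherits(lib, "embryo_library")) stop_param("`lib` must be an embryo_library")
  tibble(
    gene = lib$genes,
    source = lib$key$source,
    stage_bin = lib$key$stage_bin,
    orientation = lib$key$orientation,
    n_source_images = 1L,
    mask = unname(lib$masks)
  )
}

#' Write a synthetic library to disk
#'
#' Emits exactly the artifacts the image pipeline consumes: one 8-bit
#' greyscale PNG per image under `images/`, the annotation TSV, plus the
#' ground-truth masks (as 0/255 PNGs under `truth_masks/`) and the
#' ground-truth Jaccard matrix as TSV.
#'
#' @param lib An `embryo_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(lib, dir) {
  if (!inherits(lib, "embryo_library")) stop_param("`lib` must be an embryo_library")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth_masks"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(lib$images)) {
    img <- lib$images[[id]]
    atomic_write(file.path(dir, "images", paste0(id, ".png")), function(p) {
      png::writePNG(img / 255, p)
    })
  }
  for (g in names(lib$masks)) {
    m <- lib$masks[[g]]
    atomic_write(file.path(dir, "truth_masks", paste0(g, ".png")), function(p) {
      png::writePNG(1 - m * 1, p)  # black = expressed
    })
  }
  atomic_write(file.path(dir, "annotations.tsv"), function(p) {
    readr::write_tsv(lib$annotations, p)
  })
  jt <- as.data.frame(lib$jaccard_truth)
  jt <- cbind(gene = rownames(lib$jaccard_truth), jt)
  atomic_write(file.path(dir, "truth_jaccard.tsv"), function(p) {
    readr::write_tsv(jt, p)
  })
  invisible(dir)
}
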