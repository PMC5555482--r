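# Parametric synthetic embryo images with planted expression domains.
# The generator is the ground-truth side of every image-pipeline test: it
# returns both the greyscale image and the exact binary mask it painted.

#' Specify a synthetic embryo image
#'
#' Describes a parametric in situ embryo image: an elliptical embryo on a
#' light background, with zero or more stained expression domains painted at
#' a dark intensity, plus optional additive uniform intensity noise. The
#' default ellipse is inscribed in the frame (it touches all four borders),
#' so standardization of a native-frame image is an exact no-op and
#' ground-truth masks live in frame coordinates.
#'
#' @param frame Integer pair `c(width, height)` in pixels.
#' @param domains List of expression domains created by [domain_stripe()],
#'   [domain_patch()] or [domain_ellipse()].
#' @param background Background intensity (0-255; light).
#' @param tissue Unstained embryo tissue intensity (0-255; must sit between
#'   stain and background).
#' @param noise Amplitude of additive uniform noise, in intensity units;
#'   each pixel gets `U(-noise, noise)` added, then clipping to 0-255.
#' @param seed Optional integer seed; fixed seeds give bit-identical images.
#' @return An object of class `embryo_spec`.
#' @seealso [make_embryo_image()]
#' @export
embryo_spec <- function(frame = c(320L, 160L), domains = list(),
                        background = 245, tissue = 200, noise = 0,
                        seed = NULL) {
  if (length(frame) != 2L || any(frame < 8)) {
    stop_param("`frame` must be c(width, height) with both dimensions >= 8")
  }
  assert_scalar_number(background, "background", 0, 255)
  assert_scalar_number(tissue, "tissue", 0, 255)
  assert_scalar_number(noise, "noise", 0, 128)
  if (!is.list(domains)) stop_param("`domains` must be a list of domain objects")
  structure(
    list(frame = as.integer(frame), domains = domains,
         background = background, tissue = tissue, noise = noise,
         seed = seed),
    class = "embryo_spec"
  )
}

#' Expression-domain primitives
#'
#' Domains are regions of the embryo ellipse painted at a stain intensity
#' (dark on light tissue). Positions and sizes are fractions of the frame so
#' that specs are frame-independent. `domain_stripe()` is a band across the
#' embryo (anterior-posterior when `axis = "x"`, dorsal-ventral when
#' `axis = "y"`), clipped to the ellipse; `domain_patch()` is a filled circle
#' that must lie entirely inside the embryo; `domain_ellipse()` stains the
#' whole embryo.
#'
#' @param position Centre of the stripe along `axis`, fraction of that frame
#'   dimension in (0, 1).
#' @param width Stripe width as a fraction of the same dimension.
#' @param cx,cy Patch centre, fractions of frame width / height.
#' @param r Patch radius as a fraction of frame width.
#' @param intensity Stain intensity (0-255; dark).
#' @param axis `"x"` or `"y"` for stripes.
#' @return A domain object usable in [embryo_spec()].
#' @export
domain_stripe <- function(position, width, intensity = 40, axis = c("x", "y")) {
  axis <- match.arg(axis)
  assert_scalar_number(position, "position", 0, 1)
  assert_scalar_number(width, "width", 1e-6, 1)
  assert_scalar_number(intensity, "intensity", 0, 255)
  structure(list(kind = "stripe", axis = axis, position = position,
                 width = width, intensity = intensity),
            class = "embryo_domain")
}

#' @rdname domain_stripe
#' @export
domain_patch <- function(cx, cy, r, intensity = 40) {
  assert_scalar_number(cx, "cx", 0, 1)
  assert_scalar_number(cy, "cy", 0, 1)
  assert_scalar_number(r, "r", 1e-6, 0.5)
  assert_scalar_number(intensity, "intensity", 0, 255)
  structure(list(kind = "patch", cx = cx, cy = cy, r = r,
                 intensity = intensity),
            class = "embryo_domain")
}

#' @rdname domain_stripe
#' @export
domain_ellipse <- function(intensity = 40) {
  assert_scalar_number(intensity, "intensity", 0, 255)
  structure(list(kind = "ellipse", intensity = intensity),
            class = "embryo_domain")
}

# Pixel-centre coordinate grids for a frame; x = column, y = row, 0-based.
frame_grid <- function(frame) {
  w <- frame[1]; h <- frame[2]
  list(
    x = matrix(rep(0:(w - 1L), each = h), nrow = h),
    y = matrix(rep(0:(h - 1L), times = w), nrow = h)
  )
}

# Embryo ellipse inscribed in the frame. The rasterization includes a thin
# boundary band (half-pixel tolerance on the implicit equation, so the axis
# tips between lattice rows/columns still raster) which guarantees the
# ellipse touches all four frame borders: the bounding box of a
# native-frame embryo is then the full frame and standardization is an
# exact no-op.
embryo_ellipse_mask <- function(frame) {
  g <- frame_grid(frame)
  cx <- (frame[1] - 1) / 2; cy <- (frame[2] - 1) / 2
  tol <- max((0.5 / cx)^2, (0.5 / cy)^2) + 1e-9
  ((g$x - cx) / cx)^2 + ((g$y - cy) / cy)^2 <= 1 + tol
}

domain_raster <- function(domain, frame, ellipse) {
  g <- frame_grid(frame)
  w <- frame[1]; h <- frame[2]
  m <- switch(domain$kind,
    stripe = {
      if (domain$axis == "x") {
        c0 <- domain$position * (w - 1)
        abs(g$x - c0) <= domain$width * w / 2
      } else {
        c0 <- domain$position * (h - 1)
        abs(g$y - c0) <= domain$width * h / 2
      }
    },
    patch = {
      c0x <- domain$cx * (w - 1); c0y <- domain$cy * (h - 1)
      (g$x - c0x)^2 + (g$y - c0y)^2 <= (domain$r * w)^2
    },
    ellipse = ellipse,
    stop_param(sprintf("unknown domain kind '%s'", domain$kind))
  )
  if (domain$kind == "patch") {
    if (!any(m)) abort("patch domain rasterizes to zero pixels",
                       class = "embryogem_spec_error")
    if (any(m & !ellipse)) {
      abort("expression domain falls outside the embryo ellipse",
            class = "embryogem_spec_error")
    }
  }
  m & ellipse
}

#' Render a synthetic embryo image and its ground-truth mask
#'
#' Paints the spec's embryo ellipse and expression domains onto a greyscale
#' frame and returns both the image and the exact binary mask of painted
#' stain. Same spec and seed give bit-identical output.
#'
#' @param spec An [embryo_spec()].
#' @return A list with `image` (numeric height x width matrix, intensities
#'   0-255) and `mask` (logical matrix, `TRUE` where stain was painted).
#' @examples
#' sp <- embryo_spec(frame = c(80, 40),
#'                   domains = list(domain_stripe(0.3, 0.15)))
#' out <- make_embryo_image(sp)
#' sum(out$mask)
#' @export
make_embryo_image <- function(spec) {
  if (!inherits(spec, "embryo_spec")) stop_param("`spec` must be an embryo_spec")
  frame <- spec$frame
  ellipse <- embryo_ellipse_mask(frame)
  img <- matrix(spec$background, nrow = frame[2], ncol = frame[1])
  img[ellipse] <- spec$tissue
  mask <- matrix(FALSE, nrow = frame[2], ncol = frame[1])
  for (d in spec$domains) {
    r <- domain_raster(d, frame, ellipse)
    img[r] <- d$intensity
    mask <- mask | r
  }
  if (spec$noise > 0) {
    img <- with_seed(spec$seed, {
      img + runif(length(img), -spec$noise, spec$noise)
    })
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = round(img), mask = mask)
}
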