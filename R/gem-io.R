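# GEM persistence: a counts PNG, a TSV of (x, y, gene) triples (the index
# itself) and a JSON key descriptor carrying the key, frame and full gene
# set (so genes with empty masks survive the round trip). The 16-bit
# per-pixel counts are packed big-endian across the red (high byte) and
# green (low byte) channels of an 8-bit RGB PNG, keeping the file lossless
# with a plain 8-bit PNG codec: counts = 256 * R + G. Loading reconstructs
# the GEM losslessly from triples + descriptor.

#' Persist / load a GEM
#'
#' @param gem A [build_gem()] result.
#' @param dir Directory to write to / read from.
#' @return `write_gem()` returns `dir` invisibly; `read_gem()` returns a
#'   `gem` identical to the one written.
#' @export
write_gem <- function(gem, dir) {
  if (!inherits(gem, "gem")) stop_param("`gem` must be a gem")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (max(gem$counts) > 65535) stop_param("counts exceed the 16-bit range")
  atomic_write(file.path(dir, "counts.png"), function(p) {
    arr <- array(0, dim = c(dim(gem$counts), 3))
    arr[, , 1] <- (gem$counts %/% 256L) / 255
    arr[, , 2] <- (gem$counts %% 256L) / 255
    png::writePNG(arr, p)
  })
  h <- gem$frame[2]
  idx <- which(gem$masks, arr.ind = TRUE)
  triples <- tibble(
    x = as.integer((idx[, 1] - 1L) %/% h),
    y = as.integer((idx[, 1] - 1L) %% h),
    gene = gem$genes[idx[, 2]]
  ) |> arrange(.data$gene, .data$x, .data$y)
  atomic_write(file.path(dir, "index.tsv"), function(p) {
    readr::write_tsv(triples, p)
  })
  atomic_write(file.path(dir, "key.json"), function(p) {
    jsonlite::write_json(
      list(source = gem$key$source, stage_bin = gem$key$stage_bin,
           orientation = gem$key$orientation,
           frame = gem$frame, genes = gem$genes),
      p, auto_unbox = TRUE, digits = NA)
  })
  invisible(dir)
}

#' @rdname write_gem
#' @export
read_gem <- function(dir) {
  kpath <- file.path(dir, "key.json")
  if (!file.exists(kpath)) stop_format(sprintf("no key.json in '%s'", dir))
  meta <- jsonlite::read_json(kpath, simplifyVector = TRUE)
  triples <- readr::read_tsv(file.path(dir, "index.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(
                               x = readr::col_integer(),
                               y = readr::col_integer(),
                               gene = readr::col_character()))
  w <- meta$frame[1]; h <- meta$frame[2]
  genes <- sort(meta$genes)
  M <- matrix(FALSE, nrow = w * h, ncol = length(genes),
              dimnames = list(NULL, genes))
  if (nrow(triples) > 0) {
    bad <- triples$x < 0 | triples$x >= w | triples$y < 0 | triples$y >= h
    if (any(bad)) {
      stop_format(sprintf("index.tsv row %d: pixel outside frame", which(bad)[1]))
    }
    M[cbind(triples$x * h + triples$y + 1L, match(triples$gene, genes))] <- TRUE
  }
  counts <- matrix(as.integer(rowSums(M)), nrow = h, ncol = w)
  structure(list(
    key = gem_key(meta$source, meta$stage_bin, meta$orientation),
    frame = c(w, h), genes = genes, masks = M, counts = counts
  ), class = "gem")
}
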