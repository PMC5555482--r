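# Readers and writers for annotation tables, greyscale PNGs and persisted
# binary profiles (0/255 PNG + TSV manifest sidecar).

ANNOTATION_COLS <- c("image_id", "gene", "source", "stage_lo", "stage_hi",
                     "orientation", "genotype", "path")

validate_annotations <- function(ann) {
  if (!is.data.frame(ann)) stop_format("annotations must be a data frame")
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("annotation table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  ann <- as_tibble(ann)
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0) {
      stop_format(sprintf("annotation row %d: %s", i[1], what))
    }
  }
  bad_row(!ann$source %in% PROFILE_SOURCES,
          sprintf("source must be one of %s",
                  paste(PROFILE_SOURCES, collapse = "/")))
  bad_row(!ann$orientation %in% PROFILE_ORIENTATIONS,
          sprintf("orientation must be one of %s",
                  paste(PROFILE_ORIENTATIONS, collapse = "/")))
  bad_row(is.na(ann$stage_lo) | is.na(ann$stage_hi) |
            ann$stage_lo < 1 | ann$stage_hi > 17 | ann$stage_lo > ann$stage_hi,
          "stage range must satisfy 1 <= stage_lo <= stage_hi <= 17")
  bad_row(is.na(ann$gene) | ann$gene == "", "gene identifier is empty")
  ann
}

#' Read an image annotation table
#'
#' Reads a TSV with header columns `image_id`, `gene`, `source`,
#' `stage_lo`, `stage_hi`, `orientation`, `genotype`, `path` and validates
#' every row (known source and orientation enums, stage range inside 1-17),
#' reporting the first offending row by number.
#'
#' @param path Path to the TSV file.
#' @return A validated annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("annotation file not found: '%s'", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           stage_lo = readr::col_integer(),
                           stage_hi = readr::col_integer(),
                           .default = readr::col_character()))
  validate_annotations(ann)
}

#' Read a greyscale PNG as a 0-255 intensity matrix
#'
#' RGB images are converted to luminance (Rec. 709 weights); an alpha
#' channel, if present, is ignored.
#'
#' @param path PNG file path.
#' @return Numeric matrix (height x width), intensities in 0-255.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("image not found: '%s'", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img * 255
}

#' Persist / load composite profiles
#'
#' Profiles are stored as one 0/255 PNG per (gene, key) — black pixels mark
#' expression presence — plus a `manifest.tsv` sidecar with the gene, key
#' fields, image count and file name. `read_profiles()` inverts the writer
#' losslessly.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param dir Directory to write to / read from.
#' @return `write_profiles()` returns `dir` invisibly; `read_profiles()`
#'   returns a profile tibble.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- profiles |>
    mutate(file = sprintf("%s__%s_%s_%s.png", .data$gene, .data$source,
                          .data$stage_bin, .data$orientation)) |>
    select("gene", "source", "stage_bin", "orientation",
           "n_source_images", "file")
  for (i in seq_len(nrow(profiles))) {
    m <- profiles$mask[[i]]
    atomic_write(file.path(dir, manifest$file[i]), function(p) {
      png::writePNG(1 - m * 1, p)
    })
  }
  atomic_write(file.path(dir, "manifest.tsv"), function(p) {
    readr::write_tsv(manifest, p)
  })
  invisible(dir)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop_format(sprintf("no manifest.tsv in '%s'", dir))
  manifest <- readr::read_tsv(mpath, show_col_types = FALSE,
                              col_types = readr::cols(
                                n_source_images = readr::col_integer(),
                                .default = readr::col_character()))
  manifest$mask <- lapply(manifest$file, function(f) {
    read_image_png(file.path(dir, f)) < 128
  })
  manifest |> select(-"file")
}
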