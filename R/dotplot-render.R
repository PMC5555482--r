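# SVG rendering of the dotplot and motif export. The SVG is self-contained
# (no external references); genome-browser links are carried only as inert
# URL strings in <metadata>.

CONS_COLORS <- c(white = "#FFFFFF", light_gray = "#C0C0C0",
                 dark_gray = "#606060", black = "#000000")

darker_bin <- function(bin_q, bin_s) {
  lv <- CONS_BINS
  iq <- match(as.character(bin_q), lv)
  is_ <- match(as.character(bin_s), lv)
  lv[pmax(iq, is_, na.rm = TRUE)]
}

igr_axis_label <- function(s) {
  sprintf("%s | %s:%d-%d(%s) | %d bp", s$gene, s$chrom, s$start, s$end,
          s$strand, nchar(s$seq))
}

#' Render a dotplot as SVG
#'
#' Draws one line element per match at scaled coordinates: the first
#' sequence runs along the x axis, the second down the y axis, forward
#' matches as main-diagonal segments and reverse-complement matches as
#' anti-diagonal segments. When conservation tracks were used, each span is
#' colored by the grey-scale bin of its own mean conservation (where the
#' two axes disagree, the darker bin); matches of the highlighted motif are
#' styled red. Axis labels carry the gene name, genomic coordinates and IGR
#' length; each line carries a `<title>` with the 1-based inclusive match
#' coordinates and the matching sequence.
#'
#' @param seq_a,seq_b The [igr_sequence()]s the matches were computed from.
#' @param matches Match tibble from [find_shared_matches()].
#' @param highlight Optional motif string to paint red.
#' @param file Optional path; the SVG is written atomically when given.
#' @param size Plot-area edge length in SVG units.
#' @return The SVG as an `xml2` document, invisibly when `file` is given.
#' @export
render_dotplot <- function(seq_a, seq_b, matches, highlight = NULL,
                           file = NULL, size = 500) {
  seq_a <- as_igr(seq_a, "seqA")
  seq_b <- as_igr(seq_b, "seqB")
  margin <- 60
  la <- nchar(seq_a$seq); lb <- nchar(seq_b$seq)
  sx <- size / la; sy <- size / lb
  width <- margin + size + 20
  height <- margin + size + 20
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg",
    width = as.character(width), height = as.character(height),
    viewBox = sprintf("0 0 %d %d", width, height))
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "browser", name = "FlyBase",
                      url = sprintf("https://flybase.org/jbrowse/?loc=%s:%d..%d",
                                    seq_a$chrom, seq_a$start, seq_a$end))
  xml2::xml_add_child(meta, "browser", name = "modENCODE",
                      url = "http://www.modencode.org/")
  xml2::xml_add_child(doc, "rect", x = as.character(margin),
                      y = as.character(margin),
                      width = as.character(size), height = as.character(size),
                      fill = "none", stroke = "#333333", class = "frame")
  xml2::xml_add_child(doc, "text", igr_axis_label(seq_a),
                      x = as.character(margin + size / 2),
                      y = as.character(margin - 15),
                      `text-anchor` = "middle", `font-size` = "12",
                      class = "axis-label-q")
  xml2::xml_add_child(doc, "text", igr_axis_label(seq_b),
                      x = as.character(margin - 15),
                      y = as.character(margin + size / 2),
                      transform = sprintf("rotate(-90 %d %d)", margin - 15L,
                                          as.integer(margin + size / 2)),
                      `text-anchor` = "middle", `font-size` = "12",
                      class = "axis-label-s")
  has_cons <- nrow(matches) > 0 && !all(is.na(matches$mean_cons_q) &
                                          is.na(matches$mean_cons_s))
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    red <- !is.null(highlight) && m$motif == toupper(highlight)
    bin <- NA_character_
    if (!red && has_cons) {
      bq <- if (!is.na(m$mean_cons_q)) conservation_bin(m$mean_cons_q) else NA
      bs <- if (!is.na(m$mean_cons_s)) conservation_bin(m$mean_cons_s) else NA
      bin <- darker_bin(bq, bs)
    }
    col <- if (red) "red" else if (!is.na(bin)) CONS_COLORS[[bin]] else "#000000"
    minus <- !is.null(m$strand) && identical(m$strand, "-")
    y1 <- if (minus) m$s_end else m$s_start
    y2 <- if (minus) m$s_start else m$s_end
    ln <- xml2::xml_add_child(
      doc, "line",
      x1 = format(margin + m$q_start * sx), y1 = format(margin + y1 * sy),
      x2 = format(margin + m$q_end * sx), y2 = format(margin + y2 * sy),
      stroke = col, `stroke-width` = "1.5", class = "match",
      `data-motif` = m$motif)
    if (!is.na(bin)) xml2::xml_set_attr(ln, "data-bin", bin)
    xml2::xml_add_child(ln, "title", sprintf(
      "%s:%d-%d / %s:%d-%d %s",
      seq_a$gene, seq_a$start + m$q_start, seq_a$start + m$q_end - 1L,
      seq_b$gene, seq_b$start + m$s_start, seq_b$start + m$s_end - 1L,
      m$motif))
  }
  if (!is.null(file)) {
    atomic_write(file, function(p) xml2::write_xml(doc, p))
    return(invisible(doc))
  }
  doc
}

#' Export a motif for downstream analysis
#'
#' `"fasta"` writes a single-record FASTA; `"meme_minimal"` writes the MEME
#' minimal motif format with a position matrix putting frequency 1 on each
#' motif base, suitable for motif-comparison tools.
#'
#' @param motif Motif string over A/C/G/T.
#' @param out_format `"fasta"` or `"meme_minimal"`.
#' @param name Record/motif name.
#' @param path Optional path to write atomically.
#' @return Character vector of output lines (invisibly when `path` given).
#' @export
export_motif <- function(motif, out_format = c("fasta", "meme_minimal"),
                         name = "motif", path = NULL) {
  out_format <- match.arg(out_format)
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) {
    abort("motif must be a non-empty string over A/C/G/T",
          class = "embryogem_content_error")
  }
  lines <- if (out_format == "fasta") {
    c(paste0(">", name), motif)
  } else {
    chars <- strsplit(motif, "")[[1]]
    rows <- vapply(chars, function(ch) {
      paste(sprintf("%.6f", as.numeric(c("A", "C", "G", "T") == ch)),
            collapse = " ")
    }, character(1))
    c("MEME version 4", "",
      "ALPHABET= ACGT", "",
      "strands: + -", "",
      "Background letter frequencies",
      "A 0.25 C 0.25 G 0.25 T 0.25", "",
      paste("MOTIF", name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0",
              length(chars)),
      rows)
  }
  if (!is.null(path)) {
    atomic_write(path, function(p) writeLines(lines, p))
    return(invisible(lines))
  }
  lines
}

#' Segment plot of a match table
#'
#' A ggplot view of the dotplot (the SVG renderer is the canonical output;
#' this is for interactive inspection).
#'
#' @param matches Match tibble from [find_shared_matches()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(matches, ...) {
  matches |>
    ggplot(aes(x = .data$q_start, xend = .data$q_end,
               y = .data$s_start, yend = .data$s_end)) +
    geom_segment(linewidth = 0.8) +
    ggplot2::scale_y_reverse() +
    labs(x = "sequence A offset (bp)", y = "sequence B offset (bp)") +
    theme_minimal()
}
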