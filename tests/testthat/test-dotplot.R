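test_that("maximal matches include self-identity and respect planted fixtures", {
  s <- random_seq(60)
  self <- find_shared_matches(s, s, k = 8)
  expect_true(any(self$q_start == 0 & self$q_end == 60 &
                    self$s_start == 0 & self$s_end == 60))

  pair <- make_igr_pair(motif_pair_spec(200, 200, guard_k = 8, seed = 41))
  expect_equal(nrow(find_shared_matches(pair$seq_a, pair$seq_b, k = 8)), 0)
  expect_equal(nrow(oracle_matches(pair$seq_a$seq, pair$seq_b$seq, 8)), 0)

  planted <- make_igr_pair(motif_pair_spec(
    300, 300, motifs = list(list(motif = "ACGTGACCTT", offset_a = 10,
                                 offset_b = 50)),
    guard_k = 8, seed = 6))
  m <- find_shared_matches(planted$seq_a, planted$seq_b, k = 8)
  expect_equal(nrow(m), 1)
  expect_equal(m$q_start, 10L); expect_equal(m$s_start, 50L)
  expect_equal(m$length, 10L)
  expect_equal(m$motif, "ACGTGACCTT")
})

test_that("the k-mer matcher equals the all-start-pairs oracle exactly", {
  set.seed(19)
  for (rep in 1:6) {
    a <- random_seq(sample(150:400, 1))
    b <- random_seq(sample(150:400, 1))
    for (k in c(4, 6, 8)) {
      got <- find_shared_matches(a, b, k = k)
      want <- oracle_matches(a, b, k)
      expect_equal(as.data.frame(got[, names(want)]), as.data.frame(want),
                   label = sprintf("rep %d k %d", rep, k))
      # every reported match's two substrings are character-identical
      for (i in seq_len(nrow(got))) {
        expect_identical(substr(a, got$q_start[i] + 1, got$q_end[i]),
                         got$motif[i])
        expect_identical(substr(b, got$s_start[i] + 1, got$s_end[i]),
                         got$motif[i])
      }
      # transpose symmetry
      sw <- find_shared_matches(b, a, k = k)
      expect_equal(
        as.data.frame(sw[order(sw$s_start, sw$q_start),
                         c("s_start", "s_end", "q_start", "q_end", "length")]),
        as.data.frame(got[, c("q_start", "q_end", "s_start", "s_end", "length")]),
        ignore_attr = TRUE)
    }
    # monotonicity in k: the k+1 set is the k set minus short matches
    g6 <- find_shared_matches(a, b, k = 6)
    g7 <- find_shared_matches(a, b, k = 7)
    expect_equal(as.data.frame(g7), as.data.frame(g6[g6$length >= 7, ]),
                 ignore_attr = TRUE)
  }
})

test_that("N is never part of a match", {
  a <- "AAAAANAAAAA"
  b <- "AAAAANAAAAA"
  m <- find_shared_matches(a, b, k = 3)
  expect_true(all(!grepl("N", m$motif)))
  expect_true(all(m$length <= 5))
  expect_error(find_shared_matches(a, b, k = 1),
               class = "embryogem_parameter_error")
})

test_that("motif listing and highlighting behave like the viewer controls", {
  expect_length(list_shared_motifs(tibble::tibble(motif = character())), 0)
  m <- tibble::tibble(
    q_start = c(0L, 20L, 40L, 60L), q_end = c(12L, 29L, 52L, 72L),
    s_start = c(5L, 50L, 80L, 90L), s_end = c(17L, 59L, 92L, 102L),
    length = c(12L, 9L, 12L, 12L),
    motif = c("ACGTACGTACGT", "TTTTTTTTT", "ACGTACGTACGT", "ACGTACGTACGT"))
  expect_equal(list_shared_motifs(m), c("ACGTACGTACGT", "TTTTTTTTT"))
  expect_equal(nrow(highlight_motif(m, "ACGTACGTACGT")), 3)
  expect_equal(nrow(highlight_motif(m, "TTTTTTTTT")), 1)
  expect_equal(nrow(highlight_motif(m, "GGGGGGGG")), 0)
  # exact equality, not substring
  expect_equal(nrow(highlight_motif(m, "ACGTACGT")), 0)
  expect_error(highlight_motif(m, ""), class = "embryogem_parameter_error")
})

test_that("conservation binning follows the half-open grey-scale intervals", {
  expect_equal(as.character(conservation_bin(0.25)), "white")
  expect_equal(as.character(conservation_bin(0.8)), "black")
  expect_equal(as.character(conservation_bin(0)), "white")
  expect_equal(as.character(conservation_bin(1)), "black")
  expect_equal(as.character(conservation_bin(0.5)), "light_gray")
  expect_equal(as.character(conservation_bin(0.75)), "dark_gray")
  expect_equal(as.character(conservation_bin(c(0.1, 0.3, 0.6, 0.9))),
               c("white", "light_gray", "dark_gray", "black"))
  expect_error(conservation_bin(1.2), class = "embryogem_domain_error")
  expect_error(conservation_bin(-0.1), class = "embryogem_domain_error")
})

test_that("span means equal an independent loop mean", {
  expect_equal(mean_conservation(rep(0.6, 50), 5, 20), 0.6)
  expect_equal(mean_conservation(c(0, 1), 0, 2), 0.5)
  set.seed(23)
  tr <- runif(100)
  s <- 0
  for (i in 11:30) s <- s + tr[i]
  expect_equal(mean_conservation(tr, 10, 30), s / 20)
  expect_error(mean_conservation(tr, 20, 20), class = "embryogem_range_error")
  expect_error(mean_conservation(tr, -1, 5), class = "embryogem_range_error")
  expect_error(mean_conservation(tr, 90, 101), class = "embryogem_range_error")
})

test_that("SVG rendering draws one styled line per match", {
  pair <- make_igr_pair(motif_pair_spec(
    250, 250, motifs = list(list(motif = "ACGTGACCTTGA", offset_a = 30,
                                 offset_b = 120)),
    plateaus_a = list(list(start = 30, end = 42, level = 0.9)),
    plateaus_b = list(list(start = 120, end = 132, level = 0.9)),
    guard_k = 8, seed = 33))
  # axes only for an empty match table
  empty <- find_shared_matches(pair$seq_a, pair$seq_b, k = 40)
  svg0 <- render_dotplot(pair$seq_a, pair$seq_b, empty)
  expect_length(xml2::xml_find_all(svg0, "//*[local-name() = 'line']"), 0)
  labs <- xml2::xml_text(xml2::xml_find_all(svg0, "//*[local-name() = 'text']"))
  expect_true(any(grepl("geneA \\| 2L:100001-100250\\(\\+\\) \\| 250 bp", labs)))

  m <- find_shared_matches(pair$seq_a, pair$seq_b, k = 8,
                           track_a = pair$track_a, track_b = pair$track_b)
  svg1 <- render_dotplot(pair$seq_a, pair$seq_b, m)
  lines <- xml2::xml_find_all(svg1, "//*[local-name() = 'line']")
  expect_length(lines, 1)
  # mean conservation 0.9 -> black bin styling
  expect_equal(xml2::xml_attr(lines[[1]], "data-bin"), "black")
  expect_equal(xml2::xml_attr(lines[[1]], "stroke"), "#000000")
  expect_equal(xml2::xml_attr(lines[[1]], "data-motif"), "ACGTGACCTTGA")
  # match context: 1-based inclusive genomic coordinates plus the sequence
  title <- xml2::xml_text(xml2::xml_find_first(svg1, "//*[local-name() = 'title']"))
  expect_match(title, "geneA:100031-100042")
  expect_match(title, "geneB:250121-250132")
  expect_match(title, "ACGTGACCTTGA")

  # highlighting wins over conservation styling
  svg2 <- render_dotplot(pair$seq_a, pair$seq_b, m, highlight = "ACGTGACCTTGA")
  l2 <- xml2::xml_find_first(svg2, "//*[local-name() = 'line']")
  expect_equal(xml2::xml_attr(l2, "stroke"), "red")

  # atomic write to disk produces a parseable, self-contained document
  f <- withr::local_tempfile(fileext = ".svg")
  render_dotplot(pair$seq_a, pair$seq_b, m, file = f)
  expect_true(file.exists(f))
  expect_s3_class(xml2::read_xml(f), "xml_document")
})

test_that("reverse-complement matches render as anti-diagonals", {
  set.seed(27)
  a <- paste0(random_seq(40), "ACGTGACCTTGA", random_seq(40))
  b_fwd <- paste0(random_seq(30), "TCAAGGTCACGT", random_seq(30))
  m <- find_shared_matches(a, b_fwd, k = 10, revcomp = TRUE)
  mm <- m[m$strand == "-", ]
  expect_gte(nrow(mm), 1)
  # the reported span in B forward coordinates reverse-complements to the motif
  i <- which(mm$length >= 12)[1]
  sub_b <- substr(b_fwd, mm$s_start[i] + 1, mm$s_end[i])
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(sub_b, "")[[1]]), collapse = ""))
  expect_equal(rc, mm$motif[i])
  svg <- render_dotplot(a, b_fwd, mm)
  ln <- xml2::xml_find_first(svg, "//*[local-name() = 'line']")
  expect_gt(as.numeric(xml2::xml_attr(ln, "y1")),
            as.numeric(xml2::xml_attr(ln, "y2")))
})

test_that("motif export round-trips and encodes the MEME matrix", {
  fa <- export_motif("ACGT", "fasta", name = "m1")
  expect_equal(fa, c(">m1", "ACGT"))
  f <- withr::local_tempfile(fileext = ".fa")
  export_motif("ACGTTGCA", "fasta", path = f)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(as.character(back[[1]]), "ACGTTGCA")

  meme <- export_motif("ACGT", "meme_minimal")
  expect_true("MEME version 4" %in% meme)
  rows <- meme[(which(grepl("^letter-probability", meme)) + 1):length(meme)]
  expect_length(rows, 4)
  mat <- do.call(rbind, lapply(strsplit(rows, " "), as.numeric))
  expect_equal(mat, diag(4), ignore_attr = TRUE)  # one 1.0 per row, in order
  expect_error(export_motif("ACGTN", "fasta"),
               class = "embryogem_content_error")
})
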