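key <- gem_key("BDGP", "4-6", "lateral")

test_that("queries enumerate exactly the expressed pixels", {
  m <- matrix(FALSE, 6, 10)
  m[cbind(c(1, 2, 3, 4, 5), c(1, 3, 5, 7, 9))] <- TRUE
  q <- query_from_profile(composite_profile(m, "gA", key))
  expect_equal(nrow(q$pixels), 5)
  expect_equal(q$coverage, 1)

  all_true <- matrix(TRUE, 160, 320)
  q_all <- query_from_mask(all_true)
  expect_equal(nrow(q_all$pixels), 51200)

  # random mask: pixel set equals an independent scan
  set.seed(13)
  rm <- random_mask(6, 10, 0.4)
  q_r <- query_from_mask(rm)
  found <- NULL
  for (col in 1:10) for (row in 1:6) {
    if (rm[row, col]) found <- rbind(found, c(col - 1, row - 1))
  }
  expect_equal(as.matrix(q_r$pixels), found, ignore_attr = TRUE)

  # painting a profile's own mask gives the same query as the profile
  expect_equal(query_from_mask(m)$pixels,
               query_from_profile(composite_profile(m, "gA", key))$pixels)
  # single pixel is a valid query
  expect_equal(nrow(query_from_points(5, 3)$pixels), 1)
  expect_error(query_from_mask(matrix(FALSE, 4, 4)),
               class = "embryogem_empty_query_error")
})

test_that("subsampling retains round(coverage * t) pixels, reproducibly and nested", {
  set.seed(14)
  m <- random_mask(10, 20, 0.6)
  q <- query_from_mask(m)
  t_full <- nrow(q$pixels)

  expect_identical(subsample_query(q, 1, seed = 5), q)

  q100 <- query_from_points(rep(0:9, 10), rep(0:9, each = 10))
  q40 <- subsample_query(q100, 0.4, seed = 2)
  expect_equal(nrow(q40$pixels), 40)
  expect_true(all(paste(q40$pixels$x, q40$pixels$y) %in%
                    paste(q100$pixels$x, q100$pixels$y)))

  expect_identical(subsample_query(q, 0.3, seed = 7),
                   subsample_query(q, 0.3, seed = 7))
  expect_equal(nrow(subsample_query(q, 0.3, seed = 8)$pixels),
               nrow(subsample_query(q, 0.3, seed = 7)$pixels))
  # round-half-up with minimum 1
  q3 <- query_from_points(0:2, 0:2)
  expect_equal(nrow(subsample_query(q3, 0.5, seed = 1)$pixels), 2)  # 1.5 -> 2
  expect_equal(nrow(subsample_query(q3, 0.1, seed = 1)$pixels), 1)
  expect_error(subsample_query(q, 0, seed = 1),
               class = "embryogem_parameter_error")
  expect_error(subsample_query(q, 1.2, seed = 1),
               class = "embryogem_parameter_error")

  # same seed: subsets nested across coverages, so n is monotone in coverage
  for (cov in list(c(1, 0.8), c(0.8, 0.4), c(0.4, 0.2))) {
    hi <- subsample_query(q, cov[1], seed = 3)
    lo <- subsample_query(q, cov[2], seed = 3)
    expect_true(all(paste(lo$pixels$x, lo$pixels$y) %in%
                      paste(hi$pixels$x, hi$pixels$y)))
  }
})

test_that("gem_search equals the per-gene brute-force oracle", {
  set.seed(15)
  masks <- replicate(50, random_mask(16, 32, 0.25), simplify = FALSE)
  names(masks) <- sprintf("g%03d", 1:50)
  profs <- profiles_from_masks(masks, key)
  gem <- build_gem(profs)

  # self query: perfect score at the top
  q_self <- query_from_profile(profs[profs$gene == "g001", ])
  hits <- gem_search(gem, q_self, 0)
  self <- hits[hits$gene == "g001", ]
  expect_equal(self$score, 1)
  expect_equal(self$n, self$t)
  expect_equal(hits$score[1], 1)

  # gene disjoint from the query: present with score 0 only at min_score 0
  left <- matrix(FALSE, 16, 32); left[, 1:16] <- TRUE
  right <- matrix(FALSE, 16, 32); right[, 17:32] <- TRUE
  gem2 <- build_gem(profiles_from_masks(list(gL = left, gR = right), key))
  q_left <- query_from_mask(left)
  h0 <- gem_search(gem2, q_left, 0)
  expect_equal(h0$score[h0$gene == "gR"], 0)
  h25 <- gem_search(gem2, q_left, 0.25)
  expect_false("gR" %in% h25$gene)

  # seeded 40%-coverage query at min score 0.25: identical to the oracle
  q <- subsample_query(query_from_profile(profs[3, ]), 0.4, seed = 77)
  got <- gem_search(gem, q, 0.25)
  want <- oracle_gem_search(masks, q$pixels, 0.25)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)

  expect_error(gem_search(gem, query_from_points(100, 0), 0),
               class = "embryogem_coordinate_error")
})

test_that("jaccard matches hand-enumerated pixel sets and signals the empty case", {
  m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE
  expect_equal(jaccard(m, m), 1)
  d <- matrix(FALSE, 5, 5); d[4:5, 4:5] <- TRUE
  expect_equal(jaccard(m, d), 0)
  # intersection 4, union 12
  a <- matrix(FALSE, 4, 4); a[1:2, 1:4] <- TRUE          # 8 pixels
  b <- matrix(FALSE, 4, 4); b[2:3, 1:4] <- TRUE          # 8 pixels, overlap 4
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_true(is.na(jaccard(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))))
  expect_error(jaccard(a, matrix(FALSE, 5, 5)),
               class = "embryogem_consistency_error")
})

test_that("pairwise search equals a naive double-loop recomputation", {
  set.seed(16)
  masks <- replicate(50, random_mask(12, 24, 0.3), simplify = FALSE)
  names(masks) <- sprintf("g%03d", 1:50)
  profs <- profiles_from_masks(masks, key)
  qp <- profile_row <- profs[profs$gene == "g010", ]

  hits <- pairwise_search(profs, qp, min_sim = 0.2)
  # oracle
  sims <- vapply(names(masks), function(g) {
    oracle_jaccard(as.vector(masks[[g]]), as.vector(masks$g010))
  }, numeric(1))
  want <- sims[sims >= 0.2 - 1e-12]
  want <- want[order(-want, names(want))]
  expect_equal(hits$gene, names(want))
  expect_equal(hits$score, unname(want))
  expect_equal(hits$score, hits$n / hits$t)

  # self-hit at 1.0; fully disjoint library yields nothing above 0
  expect_equal(hits$score[hits$gene == "g010"], 1)
  left <- matrix(FALSE, 6, 6); left[, 1:2] <- TRUE
  right <- matrix(FALSE, 6, 6); right[, 5:6] <- TRUE
  dj <- pairwise_search(profiles_from_masks(list(gL = left), key),
                        composite_profile(right, "gR", key), min_sim = 0.01)
  expect_equal(nrow(dj), 0)
})

test_that("threshold filtering is exact at printed boundaries", {
  # n/t exactly on the threshold must pass the >= rule even when the
  # threshold has no finite binary representation
  masks <- list(
    gA = matrix(c(rep(TRUE, 10), rep(FALSE, 90)), 10, 10),   # n = 10 of t = 100
    gB = matrix(c(rep(TRUE, 9), rep(FALSE, 91)), 10, 10))    # n = 9
  q <- query_from_mask(matrix(TRUE, 10, 10))
  gem <- build_gem(profiles_from_masks(masks, key))
  h <- gem_search(gem, q, min_score = 0.1)
  expect_true("gA" %in% h$gene)     # 10/100 == 0.1 exactly
  expect_false("gB" %in% h$gene)    # 9/100 < 0.1
  # a third: 1/3 against threshold 1/3
  m3 <- list(gC = matrix(c(TRUE, FALSE, FALSE), 3, 1))
  g3 <- build_gem(profiles_from_masks(m3, key))
  h3 <- gem_search(g3, query_from_points(c(0, 0, 0), 0:2), min_score = 1 / 3)
  expect_equal(h3$gene, "gC")
})

test_that("hitlists export and re-import as CSV, plus bare gene lists", {
  set.seed(17)
  masks <- replicate(5, random_mask(8, 8, 0.4), simplify = FALSE)
  names(masks) <- sprintf("g%d", 1:5)
  profs <- profiles_from_masks(masks, key)
  hits <- gem_search(build_gem(profs), query_from_profile(profs[1, ]), 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_hitlist(hits, f)
  expect_equal(readLines(f)[1], "gene,score,n,t,rank")
  back <- read_hitlist(f)
  expect_equal(as.data.frame(back), as.data.frame(tibble::as_tibble(hits)),
               ignore_attr = TRUE)
  g <- withr::local_tempfile(fileext = ".txt")
  write_gene_list(hits, g)
  expect_equal(readLines(g), hits$gene)
})
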