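test_that("embryo images are painted exactly where the spec says", {
  # zero domains -> all-false mask
  out0 <- make_embryo_image(embryo_spec(frame = c(40, 20)))
  expect_false(any(out0$mask))
  expect_equal(dim(out0$image), c(20, 40))

  # full-ellipse domain: mask equals an independent per-pixel ellipse test
  out1 <- make_embryo_image(embryo_spec(frame = c(40, 20),
                                        domains = list(domain_ellipse())))
  cx <- 39 / 2; cy <- 19 / 2
  tol <- max((0.5 / cx)^2, (0.5 / cy)^2) + 1e-9  # half-pixel boundary band
  oracle <- matrix(FALSE, 20, 40)
  for (row in 1:20) {
    for (col in 1:40) {
      x <- col - 1; y <- row - 1
      oracle[row, col] <-
        ((x - cx) / cx)^2 + ((y - cy) / cy)^2 <= 1 + tol
    }
  }
  expect_identical(out1$mask, oracle)
  expect_true(all(out1$image[out1$mask] == 40))

  # stain is painted only inside the embryo
  outs <- make_embryo_image(embryo_spec(frame = c(40, 20),
                                        domains = list(domain_stripe(0.5, 0.3))))
  expect_true(all(outs$mask | !outs$mask))  # logical
  expect_true(all(out1$mask[outs$mask]))    # stripe subset of ellipse

  # patch escaping the embryo is a spec error
  expect_error(
    make_embryo_image(embryo_spec(frame = c(40, 20),
                                  domains = list(domain_patch(0.02, 0.02, 0.05)))),
    class = "embryogem_spec_error")
})

test_that("image generation is bit-identical under a fixed seed", {
  sp <- embryo_spec(frame = c(60, 30), domains = list(domain_stripe(0.4, 0.2)),
                    noise = 25, seed = 42L)
  a <- make_embryo_image(sp)
  b <- make_embryo_image(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- make_embryo_image(embryo_spec(frame = c(60, 30),
                                     domains = list(domain_stripe(0.4, 0.2)),
                                     noise = 25, seed = 43L))
  expect_false(identical(a$image, c$image))
  expect_identical(a$mask, c$mask)  # noise never changes ground truth
})

test_that("library generation matches its own ground truth", {
  lib1 <- make_library(library_spec(1, n_blocks = 0, block_size = 0,
                                    frame = c(40, 20), seed = 2))
  expect_length(lib1$images, 1)
  expect_equal(nrow(lib1$annotations), 1)

  lib <- make_library(library_spec(8, n_blocks = 2, block_size = 2,
                                   jitter = 0, frame = c(64, 32), seed = 5))
  # zero-jitter blocks: identical masks, truth Jaccard exactly 1
  expect_identical(lib$masks$g001, lib$masks$g002)
  expect_equal(lib$jaccard_truth["g001", "g002"], 1)
  expect_equal(lib$jaccard_truth["g003", "g004"], 1)
  # symmetry + unit diagonal
  expect_equal(lib$jaccard_truth, t(lib$jaccard_truth))
  expect_equal(unname(diag(lib$jaccard_truth)), rep(1, 8))
  # truth matrix agrees with a double-loop Jaccard on the masks
  for (i in c(1, 4, 7)) {
    for (j in c(2, 8)) {
      expect_equal(lib$jaccard_truth[i, j],
                   oracle_jaccard(as.vector(lib$masks[[i]]),
                                  as.vector(lib$masks[[j]])))
    }
  }
  # annotations pass the pipeline's validator
  expect_s3_class(build_profiles(lib$annotations, images = lib$images,
                                 frame = c(64, 32)), "tbl_df")
  # determinism
  lib2 <- make_library(library_spec(8, n_blocks = 2, block_size = 2,
                                    jitter = 0, frame = c(64, 32), seed = 5))
  expect_identical(lib$masks, lib2$masks)
  expect_identical(lib$images, lib2$images)
})

test_that("planted-motif pairs carry exact ground truth", {
  sp <- motif_pair_spec(300, 300,
                        motifs = list(list(motif = "ACGTGACCTT",
                                           offset_a = 40, offset_b = 220)),
                        plateaus_a = list(list(start = 40, end = 50, level = 0.9)),
                        guard_k = 6, seed = 11)
  pair <- make_igr_pair(sp)
  expect_equal(nrow(pair$truth), 1)
  expect_equal(pair$truth$length, 10L)
  expect_equal(substr(pair$seq_a$seq, 41, 50), "ACGTGACCTT")
  expect_equal(substr(pair$seq_b$seq, 221, 230), "ACGTGACCTT")
  # plateau under the planted motif
  expect_equal(mean_conservation(pair$track_a, 40, 50), 0.9)
  # the planted motif is the only shared maximal match at guard k
  expect_identical(oracle_matches(pair$seq_a$seq, pair$seq_b$seq, 6),
                   pair$truth)
  # determinism
  pair2 <- make_igr_pair(sp)
  expect_identical(pair$seq_a$seq, pair2$seq_a$seq)
  expect_identical(pair$seq_b$seq, pair2$seq_b$seq)
})

test_that("motif-free pairs share nothing at the guard length", {
  pair <- make_igr_pair(motif_pair_spec(200, 200, guard_k = 6, seed = 3))
  expect_equal(nrow(pair$truth), 0)
  expect_equal(nrow(oracle_matches(pair$seq_a$seq, pair$seq_b$seq, 6)), 0)
  expect_equal(nrow(find_shared_matches(pair$seq_a, pair$seq_b, k = 6)), 0)
})

test_that("infeasible rejection sampling errors instead of lying", {
  # 2 kb backgrounds cannot avoid shared 4-mers; the generator must say so
  expect_error(
    make_igr_pair(motif_pair_spec(2000, 2000, guard_k = 4, seed = 1,
                                  max_attempts = 3)),
    class = "embryogem_spec_error")
  # motif placement outside the sequence is rejected up front
  expect_error(
    motif_pair_spec(50, 50, motifs = list(list(motif = "ACGTACGTA",
                                               offset_a = 45, offset_b = 0))),
    class = "embryogem_spec_error")
})
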