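toy_rois <- function(mem, tot, bg) roi_set(mem, tot, bg)

test_that("membrane/total ratio matches a hand-computed toy image", {
  # 10x10 image: cell occupies columns 1:8; membrane = column 1; background
  # = columns 9:10. Cytosol 50, membrane 100, background 0.
  img <- matrix(0, 10, 10)
  img[, 1] <- 100
  img[, 2:8] <- 50
  mem <- matrix(FALSE, 10, 10); mem[, 1] <- TRUE
  tot <- matrix(FALSE, 10, 10); tot[, 1:8] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[, 9:10] <- TRUE
  res <- membrane_total_ratio(img, toy_rois(mem, tot, bg))
  # hand-computed: mem mean 100; total mean (10*100 + 70*50)/80 = 56.25
  expect_equal(res$membrane_mean, 100)
  expect_equal(res$total_mean, 56.25)
  expect_equal(res$background_mean, 0)
  expect_equal(res$ratio, 100 / 56.25)
  expect_gt(res$ratio, 1)
})

test_that("ratio is invariant under a shared constant offset", {
  set.seed(2)
  img <- matrix(runif(400, 10, 50), 20, 20)
  mem <- matrix(FALSE, 20, 20); mem[1:3, ] <- TRUE
  tot <- matrix(FALSE, 20, 20); tot[1:15, ] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[18:20, ] <- TRUE
  r0 <- membrane_total_ratio(img, toy_rois(mem, tot, bg))$ratio
  r1 <- membrane_total_ratio(img + 123.4, toy_rois(mem, tot, bg))$ratio
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("uniform image gives ratio one; inverted background errors", {
  img <- matrix(7, 10, 10)
  mem <- matrix(FALSE, 10, 10); mem[1, ] <- TRUE
  tot <- matrix(FALSE, 10, 10); tot[1:8, ] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[10, ] <- TRUE
  # uniform: total mean equals background mean -> undefined
  expect_error(membrane_total_ratio(img, toy_rois(mem, tot, bg)),
               "does not exceed background")
  img2 <- img
  img2[10, ] <- 0
  expect_equal(membrane_total_ratio(img2, toy_rois(mem, tot, bg))$ratio, 1)
  img3 <- img
  img3[10, ] <- 50  # background above cell
  expect_error(membrane_total_ratio(img3, toy_rois(mem, tot, bg)),
               "does not exceed background")
})

test_that("roi_set validates masks", {
  tot <- matrix(TRUE, 5, 5)
  bg <- matrix(FALSE, 5, 5)
  expect_error(roi_set(matrix(TRUE, 5, 5), tot, bg), "empty")
  bg[1, 1] <- TRUE
  expect_error(roi_set(matrix(TRUE, 5, 5), tot, bg), "disjoint")
})

test_that("Pearson colocalization is exact on affine and inverted channels", {
  set.seed(6)
  ch1 <- matrix(runif(900, 0, 100), 30, 30)
  affine <- 3.2 * ch1 + 11
  res <- pearson_colocalization(ch1, affine)
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  res_neg <- pearson_colocalization(ch1, -ch1)
  expect_equal(res_neg$pearson_r, -1, tolerance = 1e-12)
})

test_that("Pearson matches the textbook covariance formula on toy arrays", {
  ch1 <- matrix(c(1, 2, 3, 4, 5,
                  2, 4, 1, 3, 5,
                  0, 1, 0, 2, 1,
                  7, 3, 2, 8, 1,
                  4, 4, 2, 1, 0), 5, 5, byrow = TRUE)
  ch2 <- matrix(c(2, 1, 4, 4, 6,
                  1, 5, 2, 2, 4,
                  1, 0, 1, 3, 2,
                  6, 2, 3, 9, 0,
                  5, 3, 1, 2, 1), 5, 5, byrow = TRUE)
  res <- pearson_colocalization(ch1, ch2)
  expect_equal(res$pearson_r, direct_pearson(as.vector(ch1), as.vector(ch2)),
               tolerance = 1e-12)
  expect_equal(res$n_pixels, 25L)
})

test_that("auto-threshold mode reduces to plain when thresholds reach zero", {
  set.seed(9)
  ch1 <- matrix(runif(2500, 0, 10), 50, 50)
  ch2 <- 2 * ch1 + matrix(rnorm(2500, 0, 0.5), 50, 50)
  # perfectly coupled channels never decorrelate below threshold ->
  # threshold walks to the minimum and all pixels are used
  plain <- pearson_colocalization(ch1, ch1 * 2)
  auto <- pearson_colocalization(ch1, ch1 * 2, mode = "auto_threshold")
  expect_equal(auto$pearson_r, plain$pearson_r, tolerance = 1e-12)
  expect_equal(auto$n_pixels, plain$n_pixels)
  # with uncorrelated background + correlated signal, auto mode keeps the
  # signal pixels and reports a positive r
  sig <- matrix(0, 50, 50); sig[20:30, 20:30] <- 50
  n1 <- matrix(runif(2500, 0, 5), 50, 50)
  n2 <- matrix(runif(2500, 0, 5), 50, 50)
  auto2 <- pearson_colocalization(sig + n1, sig + n2, mode = "auto_threshold")
  expect_gt(auto2$pearson_r, 0.9)
  expect_lt(auto2$n_pixels, 2500)
})

test_that("constant channels are rejected", {
  ch <- matrix(1, 10, 10)
  expect_error(pearson_colocalization(ch, matrix(runif(100), 10, 10)),
               "constant")
})
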