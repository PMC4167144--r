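test_that("LoG candidates find planted blobs and nothing on flat frames", {
  p <- spot_params(60)
  img <- matrix(0.02, 60, 60) + gaussian_blob(60, 60, 30, 30, 2.2, 0.7)
  cand <- log_candidates(img, p$log_sigma)
  lab <- EBImage::bwlabel(cand * 1)
  expect_equal(max(lab), 1)
  expect_true(cand[30, 30])
  expect_false(any(log_candidates(matrix(0.3, 40, 40), p$log_sigma)))
  # grid of 9 planted spots -> 9 candidate regions
  grid <- matrix(0.02, 100, 100)
  for (r in c(20, 50, 80)) for (c in c(20, 50, 80))
    grid <- grid + gaussian_blob(100, 100, r, c, 2.2, 0.65)
  expect_equal(max(EBImage::bwlabel(log_candidates(grid, p$log_sigma) * 1)), 9)
})

test_that("gradient-maxima confirmation drops smooth mounds", {
  p <- spot_params(60)
  img <- matrix(0.02, 80, 120)
  img <- img + gaussian_blob(80, 120, 40, 30, 2.2, 0.7)    # sharp spot
  img <- img + gaussian_blob(80, 120, 40, 90, 12, 0.5)     # broad mound
  cand <- log_candidates(img, p$log_sigma, rel_threshold = 0.05)
  expect_true(cand[40, 30])
  conf <- confirm_gradient_maxima(cand, img)
  expect_true(conf[40, 30])
  expect_false(any(conf[, 70:120]))
  empty <- matrix(FALSE, 80, 120)
  expect_identical(confirm_gradient_maxima(empty, img), empty)
})

test_that("spot filtering applies thresholds and is monotone", {
  spots <- data.frame(label = 1:4, area = c(14, 15, 40, 8),
                      mean_intensity = c(0.9, 0.2, 0.5, 0.95))
  p <- spot_params(60, min_spot_size = 15, intensity_threshold = 0.3)
  kept <- filter_spots(spots, p)
  expect_identical(kept$label, 3L)
  # identity with trivial thresholds
  p0 <- spot_params(60, min_spot_size = 1, intensity_threshold = 0)
  expect_identical(filter_spots(spots, p0), spots)
  # brute-force predicate count on random sets + monotonicity
  set.seed(51)
  for (rep in 1:5) {
    s <- data.frame(label = 1:50, area = sample(1:60, 50, TRUE),
                    mean_intensity = runif(50))
    pa <- spot_params(60, min_spot_size = 12, intensity_threshold = 0.4)
    expect_identical(nrow(filter_spots(s, pa)),
                     sum(s$area >= 12 & s$mean_intensity >= 0.4))
    pb <- spot_params(60, min_spot_size = 20, intensity_threshold = 0.6)
    expect_true(all(filter_spots(s, pb)$label %in% filter_spots(s, pa)$label))
  }
})

test_that("spot morphology classifier separates specks, spots and smears", {
  p <- spot_params(60)
  mk <- function(mask, img) {
    spots <- measure_spots(mask, img)
    classify_spots(spots, mask, p)
  }
  img <- matrix(0.05, 120, 120)
  mask <- matrix(FALSE, 120, 120)
  # round spot of ~20 px
  spot_m <- draw_disk(matrix(0L, 120, 120), 30, 30, 2.5, 1L) > 0
  img[spot_m] <- 0.7
  # 2 px speck
  img[90, 30] <- 0.6; img[90, 31] <- 0.6
  speck_m <- matrix(FALSE, 120, 120); speck_m[90, 30:31] <- TRUE
  # elongated ~300 px smear
  smear_m <- matrix(FALSE, 120, 120); smear_m[55:64, 60:89] <- TRUE
  img[smear_m] <- 0.35
  res <- mk(spot_m | speck_m | smear_m, img)
  res <- res[order(res$centroid_row), ]
  expect_identical(as.character(res$class), c("optimal", "too_large", "too_small"))
})

test_that("copy number estimation follows the 20 px/copy law with saturation", {
  p <- spot_params(60)
  expect_identical(estimate_copies(0, p), 0L)
  expect_identical(estimate_copies(40, p), 2L)
  expect_identical(estimate_copies(450, p), 22L)   # above the ~400 px plateau
  expect_identical(estimate_copies(395, p), 20L)
  expect_identical(estimate_copies(20 * 21, p), 22L)  # >= saturation area
  expect_identical(estimate_copies(c(0, 40, 450), p), c(0L, 2L, 22L))
})

test_that("detection is translation-equivariant", {
  p <- spot_params(60)
  base <- matrix(0.02, 90, 90)
  for (ctr in list(c(25, 25), c(30, 60), c(60, 40)))
    base <- base + gaussian_blob(90, 90, ctr[1], ctr[2], 2.2, 0.65)
  shifted <- matrix(0.02, 90, 90)
  shifted[6:90, 8:90] <- base[1:85, 1:83]
  a <- detect_spots(base, params = p)
  b <- detect_spots(shifted, params = p)
  a <- a[order(a$centroid_row), ]; b <- b[order(b$centroid_row), ]
  expect_identical(nrow(a), 3L)
  expect_identical(nrow(b), 3L)
  expect_equal(b$centroid_row, a$centroid_row + 5, tolerance = 0.1)
  expect_equal(b$centroid_col, a$centroid_col + 7, tolerance = 0.1)
})
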