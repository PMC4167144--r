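test_that("Voronoi partition assigns pixels to the nearest region", {
  one <- draw_disk(matrix(0L, 30, 30), 15, 15, 4, 1L)
  v1 <- voronoi_partition(one)
  expect_true(all(v1 == 1L))
  # two point-like nuclei: the boundary is the perpendicular bisector
  two <- matrix(0L, 21, 40)
  two[11, 10] <- 1L; two[11, 30] <- 2L
  v2 <- voronoi_partition(two)
  expect_true(all(v2[, 1:19] == 1L))
  expect_true(all(v2[, 22:40] == 2L))
  expect_error(voronoi_partition(matrix(0L, 5, 5)), "empty")
})

test_that("Voronoi equals brute-force distance-to-region argmin", {
  set.seed(41)
  lab <- matrix(0L, 20, 24)
  lab <- draw_disk(lab, 5, 5, 2, 1L)
  lab <- draw_disk(lab, 14, 18, 3, 2L)
  lab[18, 3] <- 3L
  v <- voronoi_partition(lab)
  px <- lapply(1:3, function(l) {
    p <- which(lab == l)
    cbind((p - 1) %% 20 + 1, (p - 1) %/% 20 + 1)
  })
  for (r in seq_len(20)) for (c in seq_len(24)) {
    d <- vapply(px, function(m)
      sqrt(min((m[, 1] - r)^2 + (m[, 2] - c)^2)), numeric(1))
    best <- which(d <= min(d) + 1e-9)[1]   # ties -> lowest label
    expect_identical(v[r, c], best)
  }
})

test_that("flat membrane channel reduces to the Voronoi partition", {
  nuc <- draw_disk(matrix(0L, 40, 40), 12, 12, 5, 1L)
  nuc <- draw_disk(nuc, 28, 28, 5, 2L)
  mm <- membrane_segment(matrix(0.3, 40, 40), nuc)
  expect_identical(mm$labels, voronoi_partition(nuc))
  expect_identical(unname(mm$owner), c(1L, 2L))
})

test_that("membrane boundary locks onto a bright ring", {
  nr <- 80
  img <- matrix(0.02, nr, nr)
  nuc <- draw_disk(matrix(0L, nr, nr), 40, 40, 8, 1L)
  ring_r <- 20
  for (r in 1:nr) for (c in 1:nr) {
    d <- sqrt((r - 40)^2 + (c - 40)^2)
    if (abs(d - ring_r) <= 1.5) img[r, c] <- 0.8
  }
  mm <- membrane_segment(img, nuc)
  region <- mm$labels == 1L
  # the region fills the ring interior and stops at the ring
  dists <- sqrt((row(img) - 40)^2 + (col(img) - 40)^2)
  expect_true(all(region[dists <= ring_r - 2]))
  expect_true(all(!region[dists >= ring_r + 4]))
  # boundary recall: region boundary pixels sit within 2 px of the ring
  b <- region & !EBImage::erode(region * 1, EBImage::makeBrush(3, "box"))
  recall <- mean(abs(dists[b] - ring_r) <= 2.5)
  expect_gte(recall, 0.9)
})

test_that("two nuclei sharing one ring split its interior completely", {
  nr <- 90
  img <- matrix(0.02, nr, nr)
  for (r in 1:nr) for (c in 1:nr) {
    d <- sqrt((r - 45)^2 + (c - 45)^2)
    if (abs(d - 30) <= 1.5) img[r, c] <- 0.9
  }
  nuc <- draw_disk(matrix(0L, nr, nr), 45, 35, 6, 1L)
  nuc <- draw_disk(nuc, 45, 55, 6, 2L)
  mm <- membrane_segment(img, nuc)
  dists <- sqrt((row(img) - 45)^2 + (col(img) - 45)^2)
  interior <- dists <= 27
  expect_true(all(mm$labels[interior] > 0L))
  expect_setequal(unique(mm$labels[interior]), c(1L, 2L))
})

test_that("ownership is equivariant under nucleus relabeling", {
  sc <- generate_scene(scene_spec(n_cells = 5, magnification = 20, seed = 44))
  her2 <- sc$stack$channels$HER2
  nuc <- sc$nuclei
  mm1 <- membrane_segment(her2, nuc)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  nuc2 <- nuc
  nuc2[nuc > 0] <- perm[nuc[nuc > 0]]
  mm2 <- membrane_segment(her2, nuc2)
  relab <- mm1$labels
  relab[relab > 0] <- perm[relab[relab > 0]]
  expect_identical(relab, mm2$labels)
})

test_that("membrane regions partition ownership of nucleus pixels", {
  sc <- generate_scene(scene_spec(n_cells = 6, magnification = 20, seed = 45))
  mm <- membrane_segment(sc$stack$channels$HER2, sc$nuclei)
  nuc <- sc$nuclei
  expect_true(all(mm$labels[nuc > 0] == nuc[nuc > 0]))
})

test_that("contour refinement is identity at 0 iterations and improves fit", {
  nr <- 70
  set.seed(46)
  truth_r <- 18
  img <- matrix(0.1, nr, nr)
  img <- draw_disk(img, 35, 35, truth_r, 0.8)
  img <- img + matrix(rnorm(nr * nr, 0, 0.03), nr, nr)
  nuc <- draw_disk(matrix(0L, nr, nr), 35, 35, 6, 1L)
  # deliberately poor initialization: an oversized square territory
  init <- matrix(0L, nr, nr); init[8:62, 8:62] <- 1L
  mm <- structure(list(labels = init, owner = c("1" = 1L)),
                  class = "MembraneMap")
  expect_identical(refine_contours(mm, img, nuc, iterations = 0), mm)
  ref <- refine_contours(mm, img, nuc, method = "chan_vese",
                         iterations = 40)
  dists <- sqrt((row(img) - 35)^2 + (col(img) - 35)^2)
  bdist <- function(m) {
    reg <- matrix(FALSE, nr + 2, nr + 2)
    reg[2:(nr + 1), 2:(nr + 1)] <- m$labels == 1L
    b <- reg & !EBImage::erode(reg * 1, EBImage::makeBrush(3, "box"))
    dpad <- matrix(Inf, nr + 2, nr + 2)
    dpad[2:(nr + 1), 2:(nr + 1)] <- dists
    mean(abs(dpad[b & is.finite(dpad)] - truth_r))
  }
  expect_lt(bdist(ref), bdist(mm))
  expect_error(refine_contours(mm, img, nuc, method = "nope",
                               iterations = 3))
})
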