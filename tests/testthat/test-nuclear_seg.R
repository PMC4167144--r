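test_that("foreground mask separates bright disks from dark background", {
  img <- matrix(0.02, 80, 80)
  img <- draw_disk(img, 25, 25, 10, 0.8)
  img <- draw_disk(img, 55, 55, 10, 0.8)
  mask <- foreground_mask(img)
  disks <- draw_disk(draw_disk(matrix(0L, 80, 80), 25, 25, 9, 1L),
                     55, 55, 9, 1L) > 0
  expect_true(all(mask[disks]))
  far <- matrix(TRUE, 80, 80)
  far[10:70, 10:70] <- FALSE
  expect_false(any(mask[far]))
  expect_warning(m0 <- foreground_mask(matrix(0, 20, 20)), "constant")
  expect_false(any(m0))
})

test_that("Otsu threshold maximizes between-class variance", {
  set.seed(5)
  x <- c(rnorm(400, 0.25, 0.04), rnorm(300, 0.75, 0.05))
  x <- matrix(pmin(pmax(x, 0), 1), 70, 10)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
  # brute force over all 256 candidate levels
  breaks <- seq(0, 1, length.out = 257)
  h <- hist(x, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-257]) / 2
  bcv <- vapply(1:255, function(k) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) return(0)
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    w0 * w1 * (m0 - m1)^2
  }, numeric(1))
  # the threshold must lie on the argmax plateau of between-class variance
  k_th <- which.min(abs(mids - th))
  expect_equal(bcv[min(k_th, 255)], max(bcv), tolerance = 1e-8)
})

test_that("H-minima depth controls blob merging at the saddle", {
  img <- gaussian_blob(60, 60, 30, 20, 6, 1) + gaussian_blob(60, 60, 30, 40, 6, 1)
  mask <- img > 0.05
  # saddle height between the two peaks along the connecting line
  saddle <- img[30, 30]
  peak <- max(img)
  expect_identical(max(hminima_watershed(img, mask, depth = (peak - saddle) / 2)), 2L)
  expect_identical(max(hminima_watershed(img, mask, depth = (peak - saddle) * 1.5)), 1L)
  empty <- hminima_watershed(img, matrix(FALSE, 60, 60), 0.1)
  expect_identical(max(empty), 0L)
})

test_that("fragment triage separates optimal, fused and sliver shapes", {
  th <- theoretical_shape(60)
  mk_feat <- function(mask) {
    normalize_features(region_features(mask, th$area, th$perimeter),
                       th$area, th$perimeter)
  }
  r_opt <- sqrt(th$area / pi)
  opt <- draw_disk(matrix(0L, 200, 200), 100, 100, r_opt, 1L)
  expect_identical(as.character(classify_fragment(mk_feat(opt))), "optimal")
  # fused pair at ~2.2x theoretical area, waisted outline
  fused <- draw_disk(matrix(0L, 300, 300), 150, 110, r_opt * 1.06, 1L)
  fused <- draw_disk(fused, 150, 195, r_opt * 1.06, 1L)
  expect_identical(as.character(classify_fragment(mk_feat(fused))),
                   "undersegmented")
  sliver <- draw_disk(matrix(0L, 100, 100), 50, 50, r_opt * 0.35, 1L)
  expect_identical(as.character(classify_fragment(mk_feat(sliver))),
                   "oversegmented")
  bad <- mk_feat(opt); bad$solidity <- NaN
  expect_error(classify_fragment(bad), "non-finite")
})

test_that("iterative segmentation recovers planted nuclei", {
  sc <- generate_scene(scene_spec(n_cells = 15, magnification = 20,
                                  touching_prob = 0, seed = 21))
  lab <- iterative_segment(sc$stack$channels$DAPI, seg_params(20))
  f <- precision_recall_f(match_segments(lab, sc$nuclei))[["F"]]
  expect_gte(f, 0.95)
  # touching pairs must be split, not returned as one label per pair
  sct <- generate_scene(scene_spec(n_cells = 12, magnification = 20,
                                   touching_prob = 0.5, seed = 22))
  labt <- iterative_segment(sct$stack$channels$DAPI, seg_params(20))
  mct <- match_segments(labt, sct$nuclei)
  expect_lte(mct$Nunder, 2L)
  expect_gte(precision_recall_f(mct)[["F"]], 0.75)
  # blank image -> no labels
  expect_identical(max(iterative_segment(matrix(0, 50, 50), seg_params(20))), 0L)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  sc <- generate_scene(scene_spec(n_cells = 6, magnification = 20, seed = 23))
  d <- sc$stack$channels$DAPI
  a <- iterative_segment(d, seg_params(20))
  b <- iterative_segment(0.37 * d + 0.11, seg_params(20))
  expect_identical(a, b)
})

test_that("labels are consecutive positive integers with background 0", {
  sc <- generate_scene(scene_spec(n_cells = 8, magnification = 20, seed = 24))
  lab <- iterative_segment(sc$stack$channels$DAPI, seg_params(20))
  u <- sort(unique(as.vector(lab)))
  expect_identical(u, c(0L, seq_len(max(lab))))
})

test_that("oversegmentation merging joins split halves and respects c*=f", {
  # a disk split into two half-disks, each with depressed solidity
  half1 <- matrix(0L, 60, 60); half2 <- matrix(0L, 60, 60)
  full <- draw_disk(matrix(0L, 60, 60), 30, 30, 14, 1L)
  rows <- row(full)
  lab <- full
  lab[full > 0 & rows > 30] <- 2L
  a_star <- sum(full > 0)
  merged <- merge_oversegmented(lab, c("oversegmented", "oversegmented"),
                                r = 5, theoretical_area = a_star)
  expect_identical(length(unique(merged[merged > 0])), 1L)
  # isolated fragment with no neighbours is untouched
  iso <- draw_disk(matrix(0L, 40, 40), 20, 20, 6, 1L)
  out <- merge_oversegmented(iso, "oversegmented", r = 5,
                             theoretical_area = 400)
  expect_identical(out, iso)
})

test_that("powerset subset choice matches exhaustive scoring with 4 neighbours", {
  set.seed(31)
  for (rep in 1:10) {
    canvas <- matrix(0L, 90, 90)
    canvas <- place_blob(canvas, 45, 45, 250, 1L)
    angles <- runif(4, 0, 2 * pi)
    for (k in 1:4)
      canvas <- place_blob(canvas, 45 + 22 * cos(angles[k]),
                           45 + 22 * sin(angles[k]), runif(1, 120, 320),
                           k + 1L)
    present <- sort(unique(canvas[canvas > 0]))
    if (!all(1:5 %in% present)) next
    a_star <- 900
    merged <- merge_oversegmented(
      canvas, c("oversegmented", rep("optimal", 4)), r = 8,
      theoretical_area = a_star)
    nr <- nrow(canvas)
    px_of <- function(l) {
      p <- which(canvas == l)
      cbind((p - 1) %% nr + 1, (p - 1) %/% nr + 1)
    }
    nbrs <- ifishquant:::find_neighbors(canvas, 1L, 8)
    choice <- oracle_merge_choice(px_of(1L), lapply(nbrs, px_of), a_star)
    expect_setequal(unique(merged[canvas == 1L]), 1L)
    merged_into_f <- nbrs[vapply(nbrs, function(l)
      all(merged[canvas == l] == 1L), logical(1))]
    expect_setequal(merged_into_f, nbrs[choice])
  }
})

test_that("seeded watershed honours seeds", {
  img <- gaussian_blob(60, 60, 20, 20, 7) + gaussian_blob(60, 60, 42, 42, 7)
  seeds <- rbind(c(20, 20), c(42, 42))
  lab <- seeded_watershed(img, seeds)
  expect_identical(max(lab), 2L)
  expect_identical(lab[20, 20], 1L)
  expect_identical(lab[42, 42], 2L)
  one <- seeded_watershed(matrix(0.5, 30, 30), rbind(c(15, 15)))
  expect_identical(sort(unique(as.vector(one))), 1L)
  expect_warning(dup <- seeded_watershed(img, rbind(c(20, 20), c(20, 20))),
                 "duplicate")
  expect_identical(max(dup), 1L)
  # property: n distinct seeds -> n labels, each containing its seed
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    pts <- cbind(sample(5:55, n), sample(5:55, n))
    pts <- unique(pts)
    lab <- seeded_watershed(img, pts)
    expect_identical(max(lab), nrow(pts))
    expect_identical(lab[pts], seq_len(nrow(pts)))
  }
})
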