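make_linked_fixture <- function() {
  nuc <- matrix(0L, 60, 90)
  nuc <- draw_disk(nuc, 15, 15, 6, 1L)
  nuc <- draw_disk(nuc, 15, 45, 6, 2L)
  nuc <- draw_disk(nuc, 15, 75, 6, 3L)
  mm <- membrane_segment(matrix(0.2, 60, 90), nuc)
  spots <- data.frame(label = 1:6,
                      area = rep(20, 6),
                      centroid_row = rep(15, 6),
                      centroid_col = c(14, 16, 44, 46, 74, 76),
                      mean_intensity = 0.7, min_intensity = 0.4,
                      nucleus = c(1L, 1L, 2L, 2L, 3L, 3L))
  list(nuc = nuc, mm = mm, spots = spots)
}

test_that("segments map one nucleus per membrane with its spots", {
  fx <- make_linked_fixture()
  rec <- map_segments(fx$nuc, fx$mm, fx$spots)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$n_spots, c(2L, 2L, 2L))
  expect_identical(rec$membrane, rec$nucleus)
  # no spots at all -> zero spot area and count
  rec0 <- map_segments(fx$nuc, fx$mm, NULL)
  expect_true(all(rec0$n_spots == 0L))
  expect_true(all(rec0$spot_area == 0))
})

test_that("a membrane containing two nuclei raises a mapping error naming both", {
  nuc <- matrix(0L, 40, 40)
  nuc <- draw_disk(nuc, 15, 20, 4, 1L)
  nuc <- draw_disk(nuc, 28, 20, 4, 2L)
  mem <- structure(list(labels = matrix(1L, 40, 40),
                        owner = c("1" = 1L)), class = "MembraneMap")
  expect_error(map_segments(nuc, mem, NULL), "1, 2")
})

test_that("cell measurement recovers planted intensities and morphology", {
  fx <- make_linked_fixture()
  # constant channel with zero background: raw == adjusted == v
  v <- 0.42
  chans <- list(DAPI = matrix(0.5, 60, 90), ER = matrix(v, 60, 90))
  st <- image_stack(chans, c("DAPI", "nuclear-protein"), 60,
                    names = c("DAPI", "ER"))
  rec <- map_segments(fx$nuc, NULL, NULL)
  out <- measure_cells(rec, st, backgrounds = list(ER = 0))
  expect_equal(out$ER_raw, rep(v, 3))
  expect_equal(out$ER_adj, rep(v, 3))
  expect_true(all(c("area", "perimeter", "solidity") %in% colnames(out)))
})

test_that("planted per-class intensity contrast is recovered", {
  sc <- generate_scene(scene_spec(n_cells = 12, magnification = 20,
                                  two_populations = TRUE, seed = 61))
  rec <- map_segments(sc$nuclei, NULL, NULL)
  bg <- ring_background(sc$stack$channels$ER, sc$nuclei)
  out <- measure_cells(rec, sc$stack, backgrounds = list(ER = bg))
  truth <- sc$cells
  for (cl in c("A", "B")) {
    planted <- mean(truth$er_amp[truth$class == cl])
    got <- mean(out$ER_ring_adj[truth$class == cl])
    expect_lt(abs(got - planted) / planted, 0.05)
  }
})

test_that("label edits: glue, trash, cut, paint, erase", {
  lab <- matrix(0L, 50, 50)
  lab <- draw_disk(lab, 15, 15, 6, 1L)
  lab <- draw_disk(lab, 35, 35, 6, 2L)
  a1 <- sum(lab == 1L); a2 <- sum(lab == 2L)
  glued <- edit_labels(lab, list(list(op = "glue", a = 1L, b = 2L)))
  expect_identical(sum(glued == 1L), a1 + a2)
  trashed <- edit_labels(lab, list(list(op = "trash", label = 2L)))
  expect_identical(sum(trashed > 0), a1)
  expect_identical(sum(trashed == 1L), a1)
  # cut a disk along its diameter: two labels of near-equal area
  disk <- draw_disk(matrix(0L, 41, 41), 21, 21, 10, 1L)
  total <- sum(disk > 0)
  cut <- edit_labels(disk, list(list(
    op = "cut", label = 1L, polyline = rbind(c(21, 5), c(21, 37)))))
  expect_identical(max(cut), 2L)
  areas <- table(cut[cut > 0])
  expect_identical(sum(areas), as.integer(total))     # area conserved
  expect_lt(abs(areas[[1]] - areas[[2]]), 25)
  # cut that misses the region: warning, no-op
  expect_warning(
    miss <- edit_labels(disk, list(list(
      op = "cut", label = 1L, polyline = rbind(c(2, 2), c(2, 40))))),
    "no-op")
  expect_identical(miss, disk)
  painted <- edit_labels(lab, list(list(
    op = "paint", pixels = cbind(45:47, 45:47))))
  expect_identical(max(painted), 3L)
  erased <- edit_labels(lab, list(list(
    op = "erase", pixels = which(lab == 1L, arr.ind = TRUE))))
  expect_identical(max(erased), 1L)   # relabeled survivor
  expect_error(edit_labels(lab, list(list(op = "glue", a = 1L, b = 9L))),
               "does not exist")
})

test_that("cell classifier separates planted phenotypes", {
  sc <- generate_scene(scene_spec(n_cells = 20, magnification = 20,
                                  two_populations = TRUE, seed = 62))
  rec <- map_segments(sc$nuclei, NULL, NULL)
  out <- measure_cells(rec, sc$stack,
                       backgrounds = list(ER = 0, HER2 = 0))
  truth <- sc$cells$class
  tr_idx <- c(1:4, 17:20)
  training <- data.frame(cell_id = out$cell_id[tr_idx],
                         class = truth[tr_idx])
  res <- classify_cells(out, training)
  expect_gte(mean(res$class == truth), 0.95)
  # invariant to record order and training duplication
  shuf <- sample(nrow(out))
  res2 <- classify_cells(out[shuf, ], rbind(training, training))
  expect_identical(res2$class[order(res2$cell_id)],
                   res$class[order(res$cell_id)])
  # minimal training: one cell per class is accepted
  res3 <- classify_cells(out, training[c(1, 8), ])
  expect_identical(length(res3$class), nrow(out))
  # degenerate training rejected (two labels of the same class)
  same_class <- training[training$class == training$class[1], ][1:2, ]
  expect_error(classify_cells(out, same_class), "2 classes")
  too_many <- data.frame(cell_id = out$cell_id[1:5],
                         class = letters[1:5])
  expect_error(classify_cells(out, too_many), "classes")
})

test_that("permuted training labels collapse accuracy to chance", {
  sc <- generate_scene(scene_spec(n_cells = 20, magnification = 20,
                                  two_populations = TRUE, seed = 63))
  rec <- map_segments(sc$nuclei, NULL, NULL)
  out <- measure_cells(rec, sc$stack, backgrounds = list())
  truth <- sc$cells$class
  set.seed(9)
  accs <- replicate(20, {
    tr_idx <- sample(nrow(out), 10)
    training <- data.frame(cell_id = out$cell_id[tr_idx],
                           class = sample(truth[tr_idx]))
    if (length(unique(training$class)) < 2) return(NA_real_)
    mean(classify_cells(out, training)$class == truth)
  })
  expect_lt(mean(accs, na.rm = TRUE), 0.75)
})

test_that("threshold rules produce the four product categories", {
  rec <- data.frame(cell_id = 1:4,
                    ER_ring_adj = c(60, 0, 60, 0),
                    HER2_adj = c(350, 0, 0, 350))
  rules <- rbind(threshold_rule("ER", 50, "ring"),
                 threshold_rule("HER2", 300, "global"))
  out <- apply_thresholds(rec, rules)
  expect_identical(out$category,
                   c("ER+/HER2+", "ER-/HER2-", "ER+/HER2-", "ER-/HER2+"))
  # boundary value equal to the cutoff counts positive
  b <- apply_thresholds(data.frame(cell_id = 1, ER_ring_adj = 50,
                                   HER2_adj = 0), rules)
  expect_true(b$ER_positive)
  expect_error(apply_thresholds(data.frame(cell_id = 1, X_adj = 1), rules),
               "absent")
})

test_that("topology ratios are bounded, symmetric and spatially faithful", {
  lab <- matrix(0L, 30, 120)
  rec <- data.frame(cell_id = 1:10,
                    centroid_row = rep(15, 10),
                    centroid_col = seq(10, 110, length.out = 10))
  for (i in 1:10) lab <- draw_disk(lab, 15, rec$centroid_col[i], 4, i)
  rec$A_adj <- seq(0.1, 1, length.out = 10)   # planted gradient
  rec$B_adj <- 0.5
  tm <- topology_map(rec, "A", "B", lab)
  expect_gte(cor(tm$table$ratio, rec$centroid_col, method = "spearman"), 0.99)
  even <- topology_map(data.frame(cell_id = 1, centroid_row = 15,
                                  centroid_col = 10, A_adj = 2, B_adj = 2),
                       "A", "B", draw_disk(matrix(0L, 30, 30), 15, 10, 4, 1L))
  expect_equal(even$table$ratio, 0.5)
  one <- topology_map(data.frame(cell_id = 1, centroid_row = 15,
                                 centroid_col = 10, A_adj = 2, B_adj = 0),
                      "A", "B", draw_disk(matrix(0L, 30, 30), 15, 10, 4, 1L))
  expect_equal(one$table$ratio, 1)
  none <- topology_map(data.frame(cell_id = 1, centroid_row = 15,
                                  centroid_col = 10, A_adj = 0, B_adj = 0),
                       "A", "B", draw_disk(matrix(0L, 30, 30), 15, 10, 4, 1L))
  expect_true(is.na(none$table$ratio))
  expect_equal(none$rgb[15, 10, ], c(0.5, 0.5, 0.5))
})

test_that("cell records round-trip through CSV exactly", {
  sc <- generate_scene(scene_spec(n_cells = 5, magnification = 20, seed = 64))
  rec <- map_segments(sc$nuclei, NULL, NULL)
  out <- measure_cells(rec, sc$stack, backgrounds = list())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cells(out, path)
  back <- read_cells(path)
  attr(out, "nuclei") <- NULL
  expect_identical(colnames(back), colnames(out))
  for (cn in colnames(out)) expect_identical(back[[cn]], out[[cn]], label = cn)
})
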