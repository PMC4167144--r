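#' Link nuclei, membranes and spots into per-cell records
#'
#' Builds one record per nucleus, carrying its owned membrane territory
#' and the spots whose centroids it contains. An inconsistent editing
#' state in which one membrane region contains pixels of two or more
#' nuclei is an error naming the offending labels (it is never silently
#' resolved); membranes owning no nucleus are dropped with a warning.
#'
#' @param nuclei integer nucleus label matrix.
#' @param membranes a `MembraneMap` (or `NULL` for nuclei-only data).
#' @param spots data.frame from [detect_spots()] (or `NULL`).
#' @return data.frame skeleton of `CellRecord`s: cell_id, nucleus,
#'   membrane, centroid, spot count and total spot area per cell.
#' @export
map_segments <- function(nuclei, membranes = NULL, spots = NULL) {
  nuclei <- as_label_matrix(nuclei)
  labs <- sort(unique(nuclei[nuclei > 0L]))
  if (length(labs) == 0L)
    return(data.frame(cell_id = integer(), nucleus = integer(),
                      membrane = integer()))
  if (!is.null(membranes)) {
    stopifnot(inherits(membranes, "MembraneMap"))
    ml <- membranes$labels
    # consistency: a membrane region may contain at most one nucleus
    both <- ml > 0L & nuclei > 0L
    pairs <- unique(cbind(ml[both], nuclei[both]))
    counts <- table(pairs[, 1])
    bad <- names(counts)[counts > 1]
    if (length(bad)) {
      culprits <- vapply(bad, function(m)
        paste0("membrane ", m, " <- nuclei {",
               paste(sort(pairs[pairs[, 1] == as.integer(m), 2]),
                     collapse = ", "), "}"), character(1))
      stop("mapping error: two nuclei mapping to one membrane: ",
           paste(culprits, collapse = "; "))
    }
    nuc_of_mem <- setNames(pairs[, 2], pairs[, 1])
    orphan <- setdiff(unique(ml[ml > 0L]), as.integer(names(nuc_of_mem)))
    if (length(orphan))
      warning("membrane region(s) without nucleus dropped: ",
              paste(orphan, collapse = ", "))
    mem_of_nuc <- setNames(as.integer(names(nuc_of_mem)), nuc_of_mem)
  }
  feats <- region_features(nuclei)
  rec <- data.frame(cell_id = labs, nucleus = labs,
                    membrane = if (!is.null(membranes))
                      as.integer(mem_of_nuc[as.character(labs)])
                    else NA_integer_,
                    centroid_row = feats$centroid_row[match(labs, feats$label)],
                    centroid_col = feats$centroid_col[match(labs, feats$label)])
  if (!is.null(spots) && nrow(spots) > 0L) {
    agg_n <- tapply(spots$label, spots$nucleus, length)
    agg_a <- tapply(spots$area, spots$nucleus, sum)
    rec$n_spots <- as.integer(agg_n[as.character(labs)])
    rec$spot_area <- as.numeric(agg_a[as.character(labs)])
    rec$n_spots[is.na(rec$n_spots)] <- 0L
    rec$spot_area[is.na(rec$spot_area)] <- 0
  } else {
    rec$n_spots <- 0L
    rec$spot_area <- 0
  }
  attr(rec, "nuclei") <- nuclei
  rec
}

#' Measure per-cell intensities and morphology
#'
#' Fills a record skeleton from [map_segments()] with, per stain: the raw
#' mean intensity over the stain's compartment (nucleus for DAPI and
#' nuclear proteins, the 2 px membrane band of the cell territory for
#' membrane proteins, the nucleus for FISH channels), the globally
#' background-adjusted intensity (raw minus global mean, clamped at 0)
#' and, for nuclear stains, the per-nucleus ring-adjusted intensity.
#' Nuclear morphology, the membrane-band coefficient of variation (a
#' completeness proxy: broken rings vary more) and FISH copy numbers are
#' appended.
#'
#' @param records data.frame from [map_segments()].
#' @param stack an [image_stack()].
#' @param membranes `MembraneMap` used for the membrane band (or `NULL`).
#' @param backgrounds named list: per channel name, either a scalar global
#'   background or a `BackgroundEstimate` from [ring_background()].
#'   Missing entries default to 0.
#' @param spot_params a [spot_params()] for copy-number conversion.
#' @param band_width membrane band width in px (default 2).
#' @return completed records data.frame.
#' @export
measure_cells <- function(records, stack, membranes = NULL,
                          backgrounds = list(),
                          spot_params = NULL, band_width = 2) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.null(spot_params)) spot_params <- spot_params(stack$magnification)
  nuclei_idx <- NULL
  nr <- dim(stack$channels[[1]])[1]
  feats <- NULL
  labs <- records$nucleus
  # nucleus pixel sets keyed by label
  nuc_map <- matrix(0L, nr, dim(stack$channels[[1]])[2])
  # reconstruct nucleus map from records is impossible; caller passes via attr
  nuc_map <- attr(records, "nuclei")
  if (is.null(nuc_map))
    stop("records must carry the nucleus label map as attr(records, 'nuclei')")
  nuc_map <- as_label_matrix(nuc_map)
  idx_n <- label_indices(nuc_map)
  band_idx <- NULL
  if (!is.null(membranes)) {
    band <- membrane_band(membranes$labels, band_width)
    idx_b <- label_indices(band)
  }
  th <- theoretical_shape(stack$magnification)
  morph <- region_features(nuc_map, th$area, th$perimeter)
  m <- morph[match(labs, morph$label), ]
  records$area <- m$area
  records$perimeter <- m$perimeter
  records$major_axis <- m$major_axis
  records$minor_axis <- m$minor_axis
  records$solidity <- m$solidity
  records$eccentricity <- m$eccentricity
  for (i in seq_along(stack$channels)) {
    nm <- names(stack$channels)[i]
    stain <- stack$stains[i]
    ch <- stack$channels[[i]]
    bg <- backgrounds[[nm]]
    gbg <- 0; ring <- NULL
    if (inherits(bg, "BackgroundEstimate")) {
      gbg <- bg$global_mean; ring <- bg$per_label
    } else if (is.numeric(bg)) gbg <- bg
    compartment <- if (stain == "membrane-protein" && !is.null(membranes))
      "band" else "nucleus"
    raw <- vapply(as.character(labs), function(lb) {
      px <- if (compartment == "band") idx_b[[lb]] else idx_n[[lb]]
      if (is.null(px) || length(px) == 0L) px <- idx_n[[lb]]
      mean(ch[px])
    }, numeric(1))
    records[[paste0(nm, "_raw")]] <- unname(raw)
    records[[paste0(nm, "_adj")]] <- pmax(raw - gbg, 0)
    if (stain %in% c("DAPI", "nuclear-protein")) {
      rb <- if (!is.null(ring)) ring[as.character(labs)] else gbg
      records[[paste0(nm, "_ring_adj")]] <- unname(pmax(raw - rb, 0))
    }
    if (stain == "membrane-protein" && !is.null(membranes)) {
      cv <- vapply(as.character(labs), function(lb) {
        px <- idx_b[[lb]]
        if (is.null(px) || length(px) < 2L) return(NA_real_)
        v <- ch[px]
        if (mean(v) <= 0) return(NA_real_)
        sd(v) / mean(v)
      }, numeric(1))
      records[[paste0(nm, "_band_cv")]] <- unname(cv)
    }
    if (stain == "FISH-spot") {
      records[[paste0(nm, "_copies")]] <-
        estimate_copies(records$spot_area, spot_params)
    }
  }
  records
}

#' Programmatic label-map editing
#'
#' Applies an ordered edit script to a label map, mirroring interactive
#' correction tools: `cut` splits a label along a rasterized polyline,
#' `glue` merges two labels, `trash` deletes one, `paint` adds a new
#' labeled region, `erase` clears pixels. Each edit is a list with an
#' `op` field: \describe{
#'   \item{cut}{`list(op="cut", label=, polyline=matrix (row,col))`}
#'   \item{glue}{`list(op="glue", a=, b=)` -- b is absorbed into a}
#'   \item{trash}{`list(op="trash", label=)`}
#'   \item{paint}{`list(op="paint", pixels=matrix (row,col))`}
#'   \item{erase}{`list(op="erase", pixels=matrix (row,col))`}
#' }
#' Edit scripts may also be read from JSON (arrays of such objects).
#'
#' @param labels integer label matrix.
#' @param edits list of edit objects, applied in order.
#' @return edited label matrix (relabeled consecutively).
#' @export
edit_labels <- function(labels, edits) {
  labels <- as_label_matrix(labels)
  for (e in edits) {
    op <- e$op
    if (op == "glue") {
      for (lb in c(e$a, e$b))
        if (!any(labels == lb)) stop("glue: label ", lb, " does not exist")
      labels[labels == e$b] <- as.integer(e$a)
    } else if (op == "trash") {
      labels[labels == e$label] <- 0L
    } else if (op == "cut") {
      labels <- cut_label(labels, e$label, e$polyline)
    } else if (op == "paint") {
      px <- as.matrix(e$pixels)
      new_lab <- max(labels) + 1L
      labels[px] <- new_lab
    } else if (op == "erase") {
      labels[as.matrix(e$pixels)] <- 0L
    } else stop("unknown edit op: ", op)
  }
  relabel(labels)
}

# Bresenham rasterization of a polyline
rasterize_polyline <- function(polyline) {
  polyline <- round(as.matrix(polyline))
  pts <- NULL
  for (i in seq_len(nrow(polyline) - 1L)) {
    p0 <- polyline[i, ]; p1 <- polyline[i + 1L, ]
    n <- max(abs(p1 - p0)) + 1L
    pts <- rbind(pts, cbind(round(seq(p0[1], p1[1], length.out = n)),
                            round(seq(p0[2], p1[2], length.out = n))))
  }
  unique(pts)
}

cut_label <- function(labels, lb, polyline) {
  if (!any(labels == lb)) stop("cut: label ", lb, " does not exist")
  pts <- rasterize_polyline(polyline)
  inside <- pts[, 1] >= 1 & pts[, 1] <= nrow(labels) &
    pts[, 2] >= 1 & pts[, 2] <= ncol(labels)
  pts <- pts[inside, , drop = FALSE]
  on_label <- labels[pts] == lb
  if (!any(on_label)) {
    warning("cut polyline does not cross label ", lb, "; no-op")
    return(labels)
  }
  work <- labels
  work[pts[on_label, , drop = FALSE]] <- 0L
  # 4-connected relabel of the remaining pieces of lb (the 1 px cut line
  # separates pieces only under 4-connectivity)
  piece <- as_label_matrix(EBImage::bwlabel((work == lb) * 1))
  npiece <- max(piece)
  if (npiece >= 2L) {
    base <- max(labels)
    for (k in 2:npiece) work[piece == k] <- base + k - 1L
    # reattach the cut line pixels to the nearest piece
    cutpx <- pts[on_label, , drop = FALSE]
    for (i in seq_len(nrow(cutpx))) {
      r <- cutpx[i, 1]; c <- cutpx[i, 2]
      nb <- work[max(1, r - 1):min(nrow(work), r + 1),
                 max(1, c - 1):min(ncol(work), c + 1)]
      nb <- nb[nb > 0L]
      work[r, c] <- if (length(nb)) min(nb) else 0L
    }
  } else {
    warning("cut polyline does not split label ", lb, "; no-op")
    return(labels)
  }
  work
}

# one-vs-all linear SVM: one binary margin per class, argmax of decision
# values
ova_svm_fit <- function(x, y, cost = 1) {
  classes <- sort(unique(as.character(y)))
  mu <- colMeans(x); sdev <- apply(x, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  xs <- scale(x, mu, sdev)
  fits <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, cl, "rest"), levels = c(cl, "rest"))
    e1071::svm(xs, yy, kernel = "linear", cost = cost, scale = FALSE)
  })
  list(classes = classes, fits = fits, mu = mu, sd = sdev)
}

ova_svm_predict <- function(model, x) {
  xs <- scale(x, model$mu, model$sd)
  dec <- vapply(seq_along(model$classes), function(i) {
    p <- predict(model$fits[[i]], xs, decision.values = TRUE)
    d <- attr(p, "decision.values")[, 1]
    # orient: positive = the class (e1071 signs follow factor level order)
    if (startsWith(colnames(attr(p, "decision.values"))[1],
                   paste0(model$classes[i], "/"))) d else -d
  }, numeric(nrow(xs)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  model$classes[max.col(dec, ties.method = "first")]
}

cell_feature_matrix <- function(records, feature_set) {
  morph_cols <- c("area", "perimeter", "solidity", "major_axis",
                  "minor_axis", "eccentricity")
  cols <- intersect(morph_cols, colnames(records))
  if (feature_set == "morphology_plus_intensity") {
    int_cols <- grep("_adj$|_ring_adj$", colnames(records), value = TRUE)
    cols <- c(cols, int_cols, intersect("spot_area", colnames(records)))
  }
  as.matrix(records[, cols, drop = FALSE])
}

#' Classify cells with a one-vs-all linear SVM
#'
#' Trains on a user-labeled subset of the records (at least one example
#' per class, 2--4 classes) and assigns every record the argmax class.
#' Features: nuclear morphology (area, perimeter, solidity, axis lengths,
#' eccentricity), optionally extended by per-stain adjusted intensities
#' and spot area. Features are standardized on the training subset;
#' regularization cost 1.
#'
#' @param records measured records from [measure_cells()].
#' @param training data.frame with columns `cell_id` and `class` (the
#'   labeled subset).
#' @param feature_set `"morphology_only"` or
#'   `"morphology_plus_intensity"`.
#' @param max_classes class-count limit (4, matching interactive use;
#'   raise in batch mode).
#' @return records with a `class` column (training labels preserved).
#' @export
classify_cells <- function(records, training,
                           feature_set = c("morphology_plus_intensity",
                                           "morphology_only"),
                           max_classes = 4) {
  feature_set <- match.arg(feature_set)
  stopifnot(all(c("cell_id", "class") %in% colnames(training)))
  classes <- unique(as.character(training$class))
  if (length(classes) < 2) stop("training must contain at least 2 classes")
  if (length(classes) > max_classes)
    stop("more than ", max_classes, " classes")
  x <- cell_feature_matrix(records, feature_set)
  tr_idx <- match(training$cell_id, records$cell_id)
  if (any(is.na(tr_idx))) stop("training cell_id not found in records")
  model <- ova_svm_fit(x[tr_idx, , drop = FALSE],
                       as.character(training$class))
  records$class <- ova_svm_predict(model, x)
  records$class[tr_idx] <- as.character(training$class)
  records
}

#' Global intensity threshold rules
#'
#' @param stain channel name the rule reads.
#' @param cutoff non-negative intensity cutoff; comparisons are inclusive
#'   (value >= cutoff is positive).
#' @param mode which adjusted intensity the rule applies to: `"raw"`,
#'   `"global"` (background-adjusted) or `"ring"` (per-nucleus adjusted).
#' @return data.frame row usable in a rule table.
#' @export
threshold_rule <- function(stain, cutoff, mode = c("global", "ring", "raw")) {
  mode <- match.arg(mode)
  stopifnot(cutoff >= 0)
  data.frame(stain = stain, cutoff = cutoff, mode = mode)
}

#' Apply global threshold rules to cell records
#'
#' Each rule marks cells positive/negative for one stain at a global
#' cutoff (e.g. ER at 50 on ring-adjusted intensity and HER2 at 300 on
#' background-adjusted intensity, yielding four combined classes). The
#' product category string joins the per-rule signs, e.g. `"ER+/HER2-"`.
#'
#' @param records measured records.
#' @param rules data.frame of [threshold_rule()] rows.
#' @return records with logical columns `<stain>_positive` and a combined
#'   `category` column.
#' @export
apply_thresholds <- function(records, rules) {
  parts <- character(nrow(records))
  for (i in seq_len(nrow(rules))) {
    col <- switch(rules$mode[i],
                  raw = paste0(rules$stain[i], "_raw"),
                  global = paste0(rules$stain[i], "_adj"),
                  ring = paste0(rules$stain[i], "_ring_adj"))
    if (!col %in% colnames(records))
      stop("rule references absent measurement: ", col)
    pos <- records[[col]] >= rules$cutoff[i]
    records[[paste0(rules$stain[i], "_positive")]] <- pos
    parts <- paste0(parts, ifelse(i > 1, "/", ""),
                    rules$stain[i], ifelse(pos, "+", "-"))
  }
  records$category <- parts
  records
}

#' Topology map of the relative ratio of two stains
#'
#' Per cell, the relative ratio `a / (a + b)` of two adjusted intensities
#' (0.5 = balanced, 1 = all `a`); cells are painted at their segmented
#' footprint with a blue-white-red map preserving tissue context. Also
#' supports protein-vs-spot-area maps by passing `"spot_area"` as
#' `stain_b`. Cells with `a + b = 0` have undefined ratio and render
#' neutral grey.
#'
#' @param records measured records.
#' @param stain_a,stain_b measurement columns (an `_adj` suffix is added
#'   when the bare stain name is given), or `"spot_area"`.
#' @param labels label matrix of cell footprints (nuclei or membrane
#'   territories), labels matching `records$cell_id`.
#' @param png_file optional path; when given the map is written as PNG.
#' @return list with `table` (cell_id, centroid, ratio) and `rgb` (array
#'   h x w x 3).
#' @export
topology_map <- function(records, stain_a, stain_b, labels,
                         png_file = NULL) {
  col_of <- function(s) {
    if (s %in% colnames(records)) return(s)
    sa <- paste0(s, "_adj")
    if (sa %in% colnames(records)) return(sa)
    stop("stain not measured: ", s)
  }
  a <- records[[col_of(stain_a)]]
  b <- records[[col_of(stain_b)]]
  ratio <- ifelse(a + b > 0, a / (a + b), NA_real_)
  tab <- data.frame(cell_id = records$cell_id,
                    centroid_row = records$centroid_row,
                    centroid_col = records$centroid_col, ratio = ratio)
  labels <- as_label_matrix(labels)
  pal <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  rgb_arr <- array(0, c(nrow(labels), ncol(labels), 3))
  lut <- matrix(NA_real_, max(c(labels, 1L)), 3)
  for (i in seq_len(nrow(tab))) {
    lb <- tab$cell_id[i]
    lut[lb, ] <- if (is.na(ratio[i])) c(0.5, 0.5, 0.5)
                 else pal(ratio[i]) / 255
  }
  pos <- labels > 0L & labels <= nrow(lut)
  for (k in 1:3) {
    plane <- rgb_arr[, , k]
    v <- lut[labels[pos], k]
    v[is.na(v)] <- 0
    plane[pos] <- v
    rgb_arr[, , k] <- plane
  }
  if (!is.null(png_file)) png::writePNG(rgb_arr, png_file)
  list(table = tab, rgb = rgb_arr)
}

#' Write and read per-cell records as CSV
#'
#' Numeric columns are serialized at 17 significant digits, so a write
#' followed by a read reproduces every value exactly.
#'
#' @param records data.frame of cell records.
#' @param path CSV file.
#' @export
write_cells <- function(records, path) {
  write_exact_csv(records, path)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    # an integer column that was entirely NA reads back as logical
    if (is.logical(df[[j]]) && all(is.na(df[[j]])))
      df[[j]] <- as.integer(df[[j]])
  }
  df
}
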