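#' Nuclear segmentation parameters
#'
#' Defaults follow the pipeline's standard settings: intensity suppression
#' depths swept from 30% down to 10% of the foreground dynamic range over 5
#' rungs, fragments below 500 px (at 60x; scaled with magnification
#' squared) discarded, and theoretical nucleus shape from
#' [theoretical_shape()].
#'
#' @param magnification 20, 40 or 60.
#' @param h_min_fraction,h_max_fraction relative H-minima suppression
#'   depths (fractions of the foreground dynamic range).
#' @param n_depth_steps rungs of the depth ladder.
#' @param min_fragment_area discard threshold (px); default 500 at 60x,
#'   scaled by `(magnification/60)^2`.
#' @param theoretical_area,theoretical_perimeter reference nucleus shape.
#' @param merge_radius neighbour search radius for the oversegmentation
#'   merger (px between fragment boundaries).
#' @param max_neighbors cap on exhaustively enumerated neighbours (beyond
#'   it, greedy pairwise merging with the same score).
#' @return object of class `SegParams`.
#' @export
seg_params <- function(magnification = 60, h_min_fraction = 0.10,
                       h_max_fraction = 0.30, n_depth_steps = 5,
                       min_fragment_area = NULL, theoretical_area = NULL,
                       theoretical_perimeter = NULL, merge_radius = 5,
                       max_neighbors = 8) {
  stopifnot(h_min_fraction > 0, h_min_fraction < h_max_fraction,
            h_max_fraction < 1, n_depth_steps >= 1)
  magnification <- as.numeric(match.arg(as.character(magnification),
                                        c("20", "40", "60")))
  th <- theoretical_shape(magnification)
  if (is.null(min_fragment_area))
    min_fragment_area <- 500 * (magnification / 60)^2
  if (is.null(theoretical_area)) theoretical_area <- th$area
  if (is.null(theoretical_perimeter)) theoretical_perimeter <- th$perimeter
  stopifnot(min_fragment_area > 0)
  structure(list(magnification = magnification,
                 h_min_fraction = h_min_fraction,
                 h_max_fraction = h_max_fraction,
                 n_depth_steps = n_depth_steps,
                 min_fragment_area = min_fragment_area,
                 theoretical_area = theoretical_area,
                 theoretical_perimeter = theoretical_perimeter,
                 merge_radius = merge_radius,
                 max_neighbors = max_neighbors),
            class = "SegParams")
}

# local entropy of the intensity distribution in a disk window, computed by
# binned indicator convolutions (exact for the window, cyclic at borders)
local_entropy <- function(x, radius = 4, bins = 16) {
  rng <- range(x)
  if (diff(rng) == 0) return(matrix(0, nrow(x), ncol(x)))
  q <- pmin(floor((x - rng[1]) / diff(rng) * bins) + 1L, bins)
  w <- disk_brush(radius)
  w <- w / sum(w)
  ent <- matrix(0, nrow(x), ncol(x))
  for (b in seq_len(bins)) {
    p <- EBImage::filter2((q == b) * 1, w)
    p[p < 1e-12] <- 1      # 0 log 0 = 0
    ent <- ent - p * log(p)
  }
  ent
}

#' Cellular foreground mask from the DAPI channel
#'
#' Min-max-normalizes a local-entropy image and the intensity image,
#' sums them, and applies Otsu thresholding; holes in the resulting mask
#' are filled.
#'
#' @param dapi numeric matrix.
#' @param entropy_radius disk radius of the entropy window (default 4,
#'   i.e. a 9x9 disk).
#' @return logical matrix; constant input yields an empty mask with a
#'   warning.
#' @export
foreground_mask <- function(dapi, entropy_radius = 4) {
  if (diff(range(dapi)) == 0) {
    warning("constant image: empty foreground mask")
    return(matrix(FALSE, nrow(dapi), ncol(dapi)))
  }
  norm01 <- function(m) (m - min(m)) / diff(range(m))
  comb <- norm01(local_entropy(dapi, entropy_radius)) + norm01(dapi)
  th <- EBImage::otsu(EBImage::Image(comb / 2), range = c(0, 1)) * 2
  mask <- comb > th
  mask <- EBImage::fillHull(mask * 1) > 0
  matrix(as.logical(mask), nrow(dapi), ncol(dapi))
}

#' H-minima watershed of a nuclear intensity image
#'
#' Watershed of the complemented intensity after suppression of minima
#' shallower than `depth`: basins whose peak-to-saddle height is below
#' `depth` are absorbed into their neighbours. Restricted to `mask`;
#' label 0 outside.
#'
#' @param dapi numeric matrix (bright nuclei).
#' @param mask logical foreground mask.
#' @param depth suppression depth, in intensity units of `dapi` (> 0).
#' @return integer label matrix.
#' @export
hminima_watershed <- function(dapi, mask, depth) {
  stopifnot(depth > 0, all(dim(dapi) == dim(mask)))
  x <- dapi
  x[!mask] <- 0
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  # guard: watershed treats exact 0 as background; keep masked-in pixels > 0
  x[mask & x <= 0] <- 1e-9
  w <- EBImage::watershed(EBImage::Image(x), tolerance = depth, ext = 1)
  relabel(as_label_matrix(w))
}

#' Linear discriminant triage of segmentation fragments
#'
#' Classifies a fragment's 10-feature shape vector as `optimal`,
#' `undersegmented` or `oversegmented` with a linear discriminant model.
#' The default model is trained (deterministically) on the synthetic
#' fragment set from [generate_fragments()]; pass `training` to retrain.
#'
#' @param features data.frame (or coercible row) with the normalized
#'   feature columns produced by [normalize_features()].
#' @param model a model from [fragment_classifier()]; default model used
#'   when `NULL`.
#' @return factor of classes, one per row.
#' @export
classify_fragment <- function(features, model = NULL) {
  if (is.null(model)) model <- fragment_classifier()
  features <- as.data.frame(features)[, model$feature_names, drop = FALSE]
  if (any(!is.finite(as.matrix(features))))
    stop("non-finite fragment features")
  predict(model$lda, features)$class
}

.ifq_cache <- new.env(parent = emptyenv())

#' Fragment and spot triage models
#'
#' Trains (and caches) the linear discriminant models used to triage
#' nucleus fragments and FISH spot candidates. With `training = NULL` a
#' default synthetic training set of 300 fragments is generated under a
#' fixed seed, so the default models are deterministic and identical in
#' every session.
#'
#' @param training optional data.frame with a `class` column and feature
#'   columns (as from [generate_fragments()]).
#' @param type `"nucleus"` or `"spot"`.
#' @return list with elements `lda`, `type`, `feature_names`.
#' @export
fragment_classifier <- function(training = NULL, type = c("nucleus", "spot")) {
  type <- match.arg(type)
  key <- paste0("model_", type)
  default <- is.null(training)
  if (default) {
    if (!is.null(.ifq_cache[[key]])) return(.ifq_cache[[key]])
    training <- generate_fragments(300, type = type, seed = 442L)
  }
  feature_names <- setdiff(colnames(training), "class")
  fit <- suppressWarnings(
    MASS::lda(stats::as.formula("class ~ ."), data = training))
  model <- list(lda = fit, type = type, feature_names = feature_names)
  if (default) .ifq_cache[[key]] <- model
  model
}

#' Iterative H-minima watershed nuclear segmentation
#'
#' Sweeps the suppression depth down a linear ladder from
#' `h_max_fraction` to `h_min_fraction` of the foreground dynamic range.
#' At each rung, fragments triaged `optimal` by the linear discriminant
#' are frozen into the output and removed from the working mask; the
#' remainder is re-segmented at the next (shallower) depth. After the
#' ladder, remaining fragments are admitted and fragments triaged
#' `oversegmented` are merged by [merge_oversegmented()]; fragments below
#' `min_fragment_area` are discarded. The result is invariant to affine
#' rescaling of image intensities.
#'
#' @param dapi numeric matrix (DAPI channel).
#' @param params a [seg_params()].
#' @param model optional triage model ([fragment_classifier()]).
#' @return integer nucleus label matrix with consecutive labels.
#' @export
iterative_segment <- function(dapi, params = seg_params(), model = NULL) {
  stopifnot(inherits(params, "SegParams"))
  if (is.null(model)) model <- fragment_classifier()
  rng <- range(dapi)
  if (diff(rng) == 0) return(matrix(0L, nrow(dapi), ncol(dapi)))
  x <- (dapi - rng[1]) / diff(rng)
  fg <- foreground_mask(x)
  if (!any(fg)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  drange <- diff(range(x[fg]))
  depths <- seq(params$h_max_fraction, params$h_min_fraction,
                length.out = params$n_depth_steps) * drange
  out <- matrix(0L, nrow(x), ncol(x))
  quality <- character(0)
  work <- fg
  next_label <- 1L
  for (step in seq_along(depths)) {
    if (!any(work)) break
    w <- hminima_watershed(x, work, depths[step])
    if (max(w) == 0L) break
    feats <- region_features(w, params$theoretical_area,
                             params$theoretical_perimeter)
    cls <- as.character(classify_fragment(
      normalize_features(feats, params$theoretical_area,
                         params$theoretical_perimeter), model))
    last <- step == length(depths)
    for (i in seq_len(nrow(feats))) {
      accept <- cls[i] == "optimal" || last
      if (!accept) next
      px <- which(w == feats$label[i])
      out[px] <- next_label
      quality[next_label] <- cls[i]
      next_label <- next_label + 1L
      work[px] <- FALSE
    }
  }
  if (next_label == 1L) return(out)
  merged <- merge_oversegmented(out, quality,
                                r = params$merge_radius,
                                theoretical_area = params$theoretical_area,
                                max_neighbors = params$max_neighbors)
  areas <- tabulate(merged[merged > 0L], nbins = max(merged))
  drop <- which(areas > 0 & areas < params$min_fragment_area)
  if (length(drop)) merged[merged %in% drop] <- 0L
  relabel(merged)
}

# features used by the merge score: solidity and negated relative deviation
# from the theoretical area, computed on a raw pixel set
merge_score_features <- function(rows, cols, theoretical_area) {
  a <- length(rows)
  c(solidity = min(a / hull_area(rows, cols), 1),
    neg_dev_area = -abs(a - theoretical_area) / theoretical_area)
}

#' Merge oversegmented fragments by morphological scoring
#'
#' For every fragment `f` triaged as oversegmented, all neighbouring
#' fragments within `r` pixels of its boundary are listed and every union
#' of `f` with a subset of neighbours is scored by
#' `S(c) = sum_F [ F(c) - mean_i F(c_i) ]` over the features solidity and
#' negated relative deviation from the theoretical area, where `c_i` are
#' the member fragments of the union. The union with the highest positive
#' score replaces its members; with no neighbours or no positive maximum
#' the fragment is kept unchanged. Ties break toward fewer members, then
#' lower enumeration index. Beyond `max_neighbors` neighbours the powerset
#' is not enumerated; greedy pairwise merging with the same score is used.
#'
#' @param labels integer label matrix.
#' @param quality character vector: class per label
#'   (`"optimal"`/`"undersegmented"`/`"oversegmented"`), indexed by label.
#' @param r neighbour radius in pixels between fragment boundaries.
#' @param theoretical_area reference nucleus area (px).
#' @param max_neighbors powerset enumeration cap.
#' @return integer label matrix (labels of absorbed fragments vanish).
#' @export
merge_oversegmented <- function(labels, quality, r = 5,
                                theoretical_area = theoretical_shape(60)$area,
                                max_neighbors = 8) {
  labels <- as_label_matrix(labels)
  labs <- sort(unique(labels[labels > 0L]))
  if (length(labs) == 0L) return(labels)
  if (length(quality) < max(labs))
    stop("quality must be available for every label")
  nr <- nrow(labels)
  consumed <- logical(max(labs))
  for (f in labs) {
    if (consumed[f] || !identical(quality[f], "oversegmented")) next
    idx <- label_indices(labels)
    if (is.null(idx[[as.character(f)]])) next
    g <- find_neighbors(labels, f, r)
    g <- g[!consumed[g]]
    if (length(g) == 0L) next
    pix <- function(lb) {
      px <- idx[[as.character(lb)]]
      cbind(((px - 1L) %% nr) + 1L, ((px - 1L) %/% nr) + 1L)
    }
    f_px <- pix(f)
    g_px <- lapply(g, pix)
    if (length(g) <= max_neighbors) {
      best <- best_subset_score(f_px, g_px, theoretical_area)
      chosen <- g[best$subset]
    } else {
      chosen <- integer(0)
      cur_px <- f_px
      cur_members <- list(f_px)
      avail <- seq_along(g)
      repeat {
        scores <- vapply(avail, function(k) {
          union_score(c(cur_members, g_px[k]), theoretical_area)
        }, numeric(1))
        if (length(scores) == 0L || max(scores) <= 0) break
        k <- avail[which.max(scores)]
        chosen <- c(chosen, g[k])
        cur_members <- c(cur_members, g_px[match(g[k], g)])
        avail <- setdiff(avail, match(g[k], g))
      }
    }
    if (length(chosen)) {
      labels[labels %in% chosen] <- f
      consumed[chosen] <- TRUE
      quality[f] <- "optimal"
    }
  }
  labels
}

# union score of a list of member pixel matrices (Eq.-style contrast of the
# union's features against the mean of its members')
union_score <- function(members, theoretical_area) {
  u <- do.call(rbind, members)
  fu <- merge_score_features(u[, 1], u[, 2], theoretical_area)
  fm <- vapply(members, function(m)
    merge_score_features(m[, 1], m[, 2], theoretical_area), numeric(2))
  sum(fu - rowMeans(fm))
}

# exhaustive powerset scoring; returns the winning subset (possibly empty)
best_subset_score <- function(f_px, g_px, theoretical_area) {
  n <- length(g_px)
  best <- list(score = 0, subset = integer(0), n_j = 1L, j = -1L)
  for (j in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(j, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    s <- union_score(c(list(f_px), g_px[sel]), theoretical_area)
    nj <- 1L + length(sel)
    better <- s > best$score + 1e-12 ||
      (abs(s - best$score) <= 1e-12 && best$j >= 0L &&
         (nj < best$n_j || (nj == best$n_j && j < best$j)))
    if (better && s > 1e-12) best <- list(score = s, subset = sel,
                                          n_j = nj, j = j)
  }
  best
}

# labels of fragments whose pixels lie within r px of fragment f's boundary
find_neighbors <- function(labels, f, r) {
  nr <- nrow(labels); nc <- ncol(labels)
  px <- which(labels == f)
  rows <- ((px - 1L) %% nr) + 1L
  cols <- ((px - 1L) %/% nr) + 1L
  r0 <- max(1L, min(rows) - r - 1L); r1 <- min(nr, max(rows) + r + 1L)
  c0 <- max(1L, min(cols) - r - 1L); c1 <- min(nc, max(cols) + r + 1L)
  sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1
  dil <- EBImage::dilate(sub, disk_brush(r)) > 0
  nb <- labels[r0:r1, c0:c1][dil]
  sort(setdiff(unique(nb[nb > 0L]), f))
}

#' Marker-controlled (seeded) watershed
#'
#' Grows one region per user-supplied seed point over the nuclear
#' intensity landscape (seeded region growing with the image-gradient
#' metric), for fields with few cells or poor contrast where automatic
#' seeding fails.
#'
#' @param dapi numeric matrix.
#' @param seeds two-column matrix or data.frame of (row, col) seed
#'   coordinates (e.g. read from a CSV).
#' @param mask optional logical mask restricting growth; default: whole
#'   frame.
#' @return integer label matrix with one label per distinct seed; every
#'   seed lies inside its own label.
#' @export
seeded_watershed <- function(dapi, seeds, mask = NULL) {
  seeds <- as.matrix(seeds)[, 1:2, drop = FALSE]
  storage.mode(seeds) <- "integer"
  nr <- nrow(dapi); nc <- ncol(dapi)
  inside <- seeds[, 1] >= 1 & seeds[, 1] <= nr & seeds[, 2] >= 1 &
    seeds[, 2] <= nc
  if (!any(inside)) stop("no seed inside the image")
  seeds <- seeds[inside, , drop = FALSE]
  dup <- duplicated(seeds)
  if (any(dup)) {
    warning(sum(dup), " duplicate seed(s) merged")
    seeds <- seeds[!dup, , drop = FALSE]
  }
  seed_map <- matrix(0L, nr, nc)
  seed_map[seeds] <- seq_len(nrow(seeds))
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  mask <- mask | seed_map > 0L
  rng <- range(dapi)
  x <- if (diff(rng) > 0) (dapi - rng[1]) / diff(rng) else
    matrix(0.5, nr, nc)
  w <- EBImage::propagate(EBImage::Image(x), EBImage::Image(seed_map),
                          mask = mask)
  as_label_matrix(w)
}
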