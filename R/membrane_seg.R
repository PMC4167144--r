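#' Voronoi partition of the frame by nucleus regions
#'
#' Assigns every pixel the label of the nearest nucleus region (Euclidean
#' distance to the region, not to its centroid), computed from per-label
#' distance transforms. Ties break toward the lowest label.
#'
#' @param nuclei integer nucleus label matrix (>= 1 nucleus).
#' @param shape optional c(rows, cols) of the output; defaults to
#'   `dim(nuclei)` (must match it).
#' @return integer label matrix covering the full frame.
#' @export
voronoi_partition <- function(nuclei, shape = dim(nuclei)) {
  nuclei <- as_label_matrix(nuclei)
  stopifnot(all(shape == dim(nuclei)))
  labs <- sort(unique(nuclei[nuclei > 0L]))
  if (length(labs) == 0L) stop("empty nucleus label map")
  best_d <- matrix(Inf, nrow(nuclei), ncol(nuclei))
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  for (lb in labs) {
    # distmap gives the distance of each background pixel to the region
    d <- EBImage::distmap(EBImage::Image((nuclei != lb) * 1))
    d <- matrix(as.numeric(d), nrow(nuclei), ncol(nuclei))
    upd <- d < best_d           # strict: first (lowest) label wins ties
    out[upd] <- lb
    best_d[upd] <- d[upd]
  }
  out
}

#' Membrane/cytoplasm territory segmentation
#'
#' Combines the Voronoi partition of the nuclei with the membrane-channel
#' intensity: regions are grown from the nuclei by seeded region growing
#' over the intensity landscape, with pixels above the `barrier_quantile`
#' intensity acting as watershed barriers so boundaries lock onto bright
#' membrane ridges; the barrier (ridge) pixels themselves are then
#' attached to their nearest region so the ring is part of its cell.
#' Pixels separated from every nucleus by a closed ridge stay background.
#' A flat (constant) channel degenerates to the pure Voronoi partition.
#'
#' @param channel numeric matrix (membrane stain), co-registered with
#'   `nuclei`.
#' @param nuclei integer nucleus label matrix.
#' @param barrier_quantile intensity quantile above which pixels are
#'   treated as ridges (default 0.95).
#' @param lambda regularization of the seeded growth (see
#'   [EBImage::propagate()]).
#' @return object of class `MembraneMap`: list with `labels` (integer
#'   matrix) and `owner` (named integer: membrane label -> nucleus label;
#'   here the identity by construction).
#' @export
membrane_segment <- function(channel, nuclei, barrier_quantile = 0.95,
                             lambda = 1e-4) {
  nuclei <- as_label_matrix(nuclei)
  stopifnot(all(dim(channel) == dim(nuclei)))
  if (max(nuclei) == 0L) stop("empty nucleus label map")
  rng <- range(channel)
  if (diff(rng) == 0) {
    labels <- voronoi_partition(nuclei)
  } else {
    x <- (channel - rng[1]) / diff(rng)
    thr <- quantile(x, barrier_quantile, names = FALSE)
    barrier <- x >= thr & x > median(x)
    barrier[nuclei > 0L] <- FALSE
    grow_mask <- !barrier
    labels <- as_label_matrix(EBImage::propagate(
      EBImage::Image(x), EBImage::Image(nuclei), mask = grow_mask,
      lambda = lambda))
    if (any(barrier)) {
      # attach ridge pixels to the adjacent region (the ring band belongs
      # to the cell it bounds)
      labels <- as_label_matrix(EBImage::propagate(
        EBImage::Image(x), EBImage::Image(labels),
        mask = (labels > 0L) | barrier, lambda = lambda))
    }
  }
  owners <- sort(unique(labels[labels > 0L]))
  # degenerate nuclei that received no territory keep themselves
  missing <- setdiff(sort(unique(nuclei[nuclei > 0L])), owners)
  if (length(missing)) {
    warning("nucleus label(s) ", paste(missing, collapse = ", "),
            " received no territory; using the nucleus itself")
    for (lb in missing) labels[nuclei == lb] <- lb
    owners <- sort(unique(labels[labels > 0L]))
  }
  structure(list(labels = labels,
                 owner = setNames(as.integer(owners), owners)),
            class = "MembraneMap")
}

#' @export
print.MembraneMap <- function(x, ...) {
  cat("MembraneMap:", length(x$owner), "cell territories,",
      paste(dim(x$labels), collapse = " x "), "px\n")
  invisible(x)
}

# membrane measurement band: pixels of the region within `width` px of its
# boundary (inner band), where ring-phenotype intensity lives
membrane_band <- function(labels, width = 2) {
  labels <- as_label_matrix(labels)
  er <- labels
  for (k in seq_len(width)) {
    # peel one 4-connected layer per iteration
    nr <- nrow(er); nc <- ncol(er)
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- er
    ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
    keep <- ctr > 0L
    for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nb <- pad[(2L + sh[1]):(nr + 1L + sh[1]),
                (2L + sh[2]):(nc + 1L + sh[2])]
      keep <- keep & nb == ctr
    }
    er[!keep] <- 0L
  }
  band <- labels
  band[er > 0L] <- 0L
  band
}

#' Active-contour refinement of membrane territories
#'
#' Per-region morphological active contours: `chan_vese` evolves each
#' region toward the two-phase piecewise-constant model (inside/outside
#' means over a local shell), `localized` uses Gaussian-windowed local
#' means. Refinements that would evict the owning nucleus from its region
#' are rejected and the region reverts. `iterations = 0` is the identity.
#'
#' @param membranes a `MembraneMap` from [membrane_segment()].
#' @param channel numeric matrix the contours follow.
#' @param nuclei nucleus label matrix (ownership constraint).
#' @param method `"chan_vese"` or `"localized"`.
#' @param iterations evolution steps (default 0: disabled).
#' @param window Gaussian window sigma for the localized method (px).
#' @return refined `MembraneMap`.
#' @export
refine_contours <- function(membranes, channel, nuclei,
                            method = c("chan_vese", "localized"),
                            iterations = 0, window = 15) {
  method <- match.arg(method)
  stopifnot(inherits(membranes, "MembraneMap"), iterations >= 0)
  if (iterations == 0) return(membranes)
  labels <- membranes$labels
  nuclei <- as_label_matrix(nuclei)
  out <- labels
  for (lb in as.integer(names(membranes$owner))) {
    u <- out == lb
    if (!any(u)) next
    cand <- evolve_region(u, channel, method, iterations, window,
                          frozen = out > 0L & !u)
    nuc_px <- nuclei == membranes$owner[[as.character(lb)]]
    if (!all(cand[nuc_px])) next     # eviction: revert
    out[u & !cand] <- 0L
    out[cand & out == 0L] <- lb
  }
  structure(list(labels = out, owner = membranes$owner),
            class = "MembraneMap")
}

evolve_region <- function(u, channel, method, iterations, window, frozen) {
  b3 <- disk_brush(1)
  for (it in seq_len(iterations)) {
    um <- u * 1
    dil <- EBImage::dilate(um, b3) > 0
    ero <- EBImage::erode(um, b3) > 0
    shell <- dil & !u & !frozen         # candidate accretion pixels
    rim <- u & !ero                      # candidate shedding pixels
    if (method == "chan_vese") {
      outside <- !u & !frozen
      c1 <- mean(channel[u])
      c2 <- if (any(outside)) mean(channel[outside]) else c1
      if (abs(c1 - c2) < 1e-9) break      # no contrast to follow
      take <- (channel - c1)^2 < (channel - c2)^2
    } else {
      w <- um
      num1 <- EBImage::gblur(channel * w, sigma = window)
      den1 <- EBImage::gblur(w, sigma = window)
      num2 <- EBImage::gblur(channel * (1 - w), sigma = window)
      den2 <- EBImage::gblur(1 - w, sigma = window)
      c1 <- num1 / pmax(den1, 1e-9)
      c2 <- num2 / pmax(den2, 1e-9)
      if (max(abs(c1 - c2)) < 1e-9) break # no contrast to follow
      take <- (channel - c1)^2 < (channel - c2)^2
    }
    new_u <- u
    new_u[shell & take] <- TRUE
    new_u[rim & !take] <- FALSE
    # curvature regularization: binary median smoothing
    new_u <- EBImage::medianFilter(new_u * 1, size = 1) > 0.5
    if (identical(new_u, u)) break
    u <- new_u
  }
  u
}
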