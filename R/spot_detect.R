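#' FISH spot detection parameters
#'
#' Defaults are the 60x reference values: minimum spot size 15 px, about
#' 20 px of signal area per copy, saturation of the area--copy-number
#' relation near 400 px, a countable maximum of 21 copies with amplified
#' cells coded 22. Pixel sizes scale with `(magnification/60)^2`.
#'
#' @param magnification 20, 40 or 60.
#' @param min_spot_size minimum area (px) of a retained spot.
#' @param intensity_threshold minimum mean intensity of a retained spot, or
#'   `"auto"` (Otsu over candidate mean intensities).
#' @param log_sigma Laplacian-of-Gaussian scale; default matched to
#'   `min_spot_size` (`sqrt(min_spot_size/pi)/sqrt(2)`).
#' @param area_per_spot signal area of one copy (px).
#' @param saturation_area area at which counting saturates (px).
#' @param max_countable largest countable copy number (saturated cells get
#'   `max_countable + 1`).
#' @return object of class `SpotParams`.
#' @export
spot_params <- function(magnification = 60, min_spot_size = NULL,
                        intensity_threshold = 0, log_sigma = NULL,
                        area_per_spot = NULL, saturation_area = NULL,
                        max_countable = 21) {
  magnification <- as.numeric(match.arg(as.character(magnification),
                                        c("20", "40", "60")))
  s <- (magnification / 60)^2
  if (is.null(min_spot_size)) min_spot_size <- max(15 * s, 2)
  if (is.null(area_per_spot)) area_per_spot <- 20 * s
  if (is.null(saturation_area)) saturation_area <- 400 * s
  if (is.null(log_sigma)) log_sigma <- sqrt(min_spot_size / pi) / sqrt(2)
  stopifnot(min_spot_size > 0, area_per_spot > 0, log_sigma > 0)
  structure(list(magnification = magnification,
                 min_spot_size = min_spot_size,
                 intensity_threshold = intensity_threshold,
                 log_sigma = log_sigma, area_per_spot = area_per_spot,
                 saturation_area = saturation_area,
                 max_countable = max_countable),
            class = "SpotParams")
}

log_kernel <- function(sigma) {
  half <- max(ceiling(4 * sigma), 2)
  g <- outer(-half:half, -half:half, function(r, c)
    exp(-(r^2 + c^2) / (2 * sigma^2)))
  g <- g / sum(g)
  rc2 <- outer(-half:half, -half:half, function(r, c) r^2 + c^2)
  k <- g * (rc2 - 2 * sigma^2) / sigma^4
  k - mean(k)    # zero-sum: flat response on constant images
}

#' Laplacian-of-Gaussian candidate spot mask
#'
#' Convolves the channel with a LoG kernel at scale `sigma` and returns
#' the mask of connected regions where the (sign-inverted) response
#' indicates a bright blob at that scale. The response threshold is
#' relative to the strongest blob in the frame.
#'
#' @param channel numeric matrix.
#' @param sigma LoG scale (px).
#' @param rel_threshold fraction of the peak response required (default
#'   0.15).
#' @return logical candidate mask (empty on a flat image).
#' @export
log_candidates <- function(channel, sigma, rel_threshold = 0.15) {
  stopifnot(sigma > 0)
  resp <- -EBImage::filter2(channel, log_kernel(sigma))
  resp <- matrix(as.numeric(resp), nrow(channel), ncol(channel))
  mx <- max(resp)
  if (mx <= 1e-9) return(matrix(FALSE, nrow(channel), ncol(channel)))
  resp > rel_threshold * mx
}

#' Confirm LoG candidates by gradient maxima
#'
#' Retains only candidate regions that coincide with strong local maxima
#' of the Sobel gradient magnitude (a sharp spot raises a steep rim; a
#' smooth broad mound does not), within a 2 px tolerance of the region.
#'
#' @param candidates logical candidate mask from [log_candidates()].
#' @param channel numeric matrix.
#' @param strength_fraction a gradient maximum must reach this fraction of
#'   the frame's strongest gradient (default 0.25).
#' @return filtered logical mask.
#' @export
confirm_gradient_maxima <- function(candidates, channel,
                                    strength_fraction = 0.25) {
  stopifnot(all(dim(candidates) == dim(channel)))
  if (!any(candidates)) return(candidates)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(channel, sx)
  gy <- EBImage::filter2(channel, t(sx))
  mag <- sqrt(as.numeric(gx)^2 + as.numeric(gy)^2)
  mag <- matrix(mag, nrow(channel), ncol(channel))
  mmax <- max(mag)
  if (mmax <= 1e-12) return(candidates & FALSE)
  # 3x3 regional maxima of the gradient magnitude
  dil <- EBImage::dilate(mag / mmax, matrix(1, 3, 3))
  is_max <- mag / mmax >= as.numeric(dil) - 1e-12 &
    mag >= strength_fraction * mmax
  lab <- EBImage::bwlabel(candidates * 1)
  lab <- as_label_matrix(lab)
  near <- EBImage::dilate((is_max) * 1, disk_brush(2)) > 0
  keep <- sort(unique(lab[lab > 0L & near]))
  matrix(lab %in% keep, nrow(lab), ncol(lab)) & candidates
}

#' Measure detected spots
#'
#' Labels confirmed candidate regions and measures each spot. The spot
#' area is the half-maximum area: pixels of the (slightly dilated)
#' candidate region whose intensity exceeds the midpoint between the
#' region's peak and the background floor (frame median). This makes the
#' area of a diffraction-limited spot independent of the LoG threshold and
#' supports the linear area-per-copy relation.
#'
#' @param mask confirmed candidate mask.
#' @param channel numeric matrix.
#' @param nuclei optional nucleus label matrix; spots are assigned to the
#'   nucleus containing their centroid (NA when outside all nuclei).
#' @return data.frame of spots: label, area, centroid_row, centroid_col,
#'   mean_intensity, min_intensity, nucleus, plus the shape feature
#'   columns used by the spot classifier.
#' @export
measure_spots <- function(mask, channel, nuclei = NULL) {
  lab <- as_label_matrix(EBImage::bwlabel(mask * 1))
  floor_int <- median(channel)
  nr <- nrow(channel)
  idx <- label_indices(lab)
  out <- lapply(names(idx), function(lb) {
    px <- idx[[lb]]
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    r0 <- max(1L, min(rows) - 2L); r1 <- min(nr, max(rows) + 2L)
    c0 <- max(1L, min(cols) - 2L); c1 <- min(ncol(channel), max(cols) + 2L)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    sub <- EBImage::dilate(sub * 1, disk_brush(2)) > 0
    ch <- channel[r0:r1, c0:c1]
    peak <- max(ch[sub])
    half <- sub & ch >= (peak + floor_int) / 2
    hpx <- which(half)
    hrows <- ((hpx - 1L) %% nrow(half)) + 1L + r0 - 1L
    hcols <- ((hpx - 1L) %/% nrow(half)) + 1L + c0 - 1L
    cr <- mean(hrows); cc <- mean(hcols)
    nuc <- NA_integer_
    if (!is.null(nuclei)) {
      v <- nuclei[round(cr), round(cc)]
      if (v > 0L) nuc <- as.integer(v)
    }
    data.frame(label = as.integer(lb), area = length(hpx),
               centroid_row = cr, centroid_col = cc,
               mean_intensity = mean(ch[half]),
               min_intensity = min(ch[half]), nucleus = nuc)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(label = integer(), area = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      mean_intensity = numeric(), min_intensity = numeric(),
                      nucleus = integer())
  out
}

#' Size and intensity filtering of spots
#'
#' Keeps spots with `area >= min_spot_size` and
#' `mean_intensity >= intensity_threshold`. Monotone: raising either
#' threshold never admits a spot.
#'
#' @param spots data.frame from [measure_spots()].
#' @param params a [spot_params()].
#' @return filtered data.frame.
#' @export
filter_spots <- function(spots, params = spot_params()) {
  thr <- params$intensity_threshold
  if (identical(thr, "auto")) {
    thr <- if (nrow(spots) >= 2 && diff(range(spots$mean_intensity)) > 0)
      as.numeric(EBImage::otsu(EBImage::Image(
        matrix(spots$mean_intensity, ncol = 1)), range = range(spots$mean_intensity)))
    else 0
  }
  spots[spots$area >= params$min_spot_size &
          spots$mean_intensity >= thr, , drop = FALSE]
}

#' Morphology classification of spot candidates
#'
#' Assigns each spot `optimal`, `too_small` or `too_large` with the linear
#' discriminant spot model (useful for low-contrast probes such as
#' centromere 17, where autofluorescent artefacts confound detection).
#' Downstream counting keeps only `optimal` spots when the classifier is
#' enabled.
#'
#' @param spots data.frame from [measure_spots()] (for shape features the
#'   spot mask is re-derived from area/perimeter proxies; see Details).
#' @param mask the confirmed candidate mask the spots were measured from.
#' @param params a [spot_params()].
#' @param model optional model from
#'   `fragment_classifier(type = "spot")`.
#' @return `spots` with a `class` factor column.
#' @export
classify_spots <- function(spots, mask, params = spot_params(),
                           model = NULL) {
  if (is.null(model)) model <- fragment_classifier(type = "spot")
  if (nrow(spots) == 0L) {
    spots$class <- factor(character(), levels = model$lda$lev)
    return(spots)
  }
  aps <- params$area_per_spot
  p_ref <- 2 * pi * sqrt(aps / pi)
  lab <- as_label_matrix(EBImage::bwlabel(mask * 1))
  feat <- region_features(lab, aps, p_ref)
  feat <- feat[match(spots$label, feat$label), , drop = FALSE]
  nf <- normalize_features(feat, aps, p_ref)
  nf$mean_intensity <- spots$mean_intensity
  nf$min_intensity <- spots$min_intensity
  if (any(!is.finite(as.matrix(nf)))) stop("non-finite spot features")
  spots$class <- predict(model$lda, nf[, model$feature_names])$class
  spots
}

#' Copy number from total spot area
#'
#' Linear area-to-copies conversion, `round(area / area_per_spot)`,
#' saturating at the amplified code: totals at or above the saturation
#' area, or estimates beyond the countable maximum (21), return 22.
#'
#' @param total_spot_area summed spot area of one cell (px, >= 0).
#' @param params a [spot_params()].
#' @return integer copy number in 0..21, or 22 (amplified).
#' @export
estimate_copies <- function(total_spot_area, params = spot_params()) {
  stopifnot(all(total_spot_area >= 0))
  est <- round(total_spot_area / params$area_per_spot)
  amplified <- total_spot_area >= params$saturation_area |
    est > params$max_countable
  out <- ifelse(amplified, params$max_countable + 1L, est)
  as.integer(out)
}

#' End-to-end FISH spot detection for one channel
#'
#' LoG candidates, gradient-maxima confirmation, measurement,
#' size/intensity filtering and (optionally) morphology classification.
#'
#' @param channel numeric matrix (FISH channel).
#' @param nuclei optional nucleus label matrix for spot assignment.
#' @param params a [spot_params()].
#' @param classify apply the spot morphology classifier and keep only
#'   `optimal` spots.
#' @return data.frame of retained spots.
#' @export
detect_spots <- function(channel, nuclei = NULL, params = spot_params(),
                         classify = FALSE) {
  cand <- log_candidates(channel, params$log_sigma)
  conf <- confirm_gradient_maxima(cand, channel)
  spots <- measure_spots(conf, channel, nuclei)
  spots <- filter_spots(spots, params)
  if (classify && nrow(spots) > 0L) {
    spots <- classify_spots(spots, conf, params)
    spots <- spots[spots$class == "optimal", , drop = FALSE]
  }
  spots
}
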