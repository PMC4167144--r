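#' @import EBImage
#' @importFrom stats quantile sd predict rnorm runif rpois median setNames
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# circular structuring element of the given pixel radius
disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

as_label_matrix <- function(x) {
  m <- x
  if (inherits(m, "Image")) m <- EBImage::imageData(m)
  storage.mode(m) <- "integer"
  m
}

#' Relabel a label map to consecutive positive integers
#'
#' Background (0) is preserved; positive labels are renumbered 1..k in
#' increasing order of their original value.
#'
#' @param labels integer matrix, 0 = background.
#' @return integer matrix with labels 1..k.
#' @export
relabel <- function(labels) {
  labels <- as_label_matrix(labels)
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  pos <- labels > 0L
  out[pos] <- lut[labels[pos]]
  out
}

label_indices <- function(labels) {
  labels <- as_label_matrix(labels)
  pos <- which(labels > 0L)
  split(pos, labels[pos])
}

# Perimeter as exposed pixel-face count (crack length): for every region
# pixel, count the 4-neighbour faces adjacent to a different label or the
# image border. Additive under integer scaling (P of an n x n square is 4n).
face_perimeter <- function(labels) {
  labels <- as_label_matrix(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  per <- numeric(max(labels, 0L))
  if (length(per) == 0L) return(per)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- pad[(2L + sh[1]):(nr + 1L + sh[1]), (2L + sh[2]):(nc + 1L + sh[2])]
    exposed <- ctr > 0L & nb != ctr
    t <- tabulate(ctr[exposed], nbins = length(per))
    per <- per + t
  }
  per
}

# Convex hull area of a pixel region, using the 4 corners of every pixel so
# the hull covers full pixel extents (shoelace on the hull polygon).
hull_area <- function(rows, cols) {
  px <- cbind(rep(rows, 4L) + rep(c(-0.5, -0.5, 0.5, 0.5), each = length(rows)),
              rep(cols, 4L) + rep(c(-0.5, 0.5, -0.5, 0.5), each = length(cols)))
  h <- grDevices::chull(px)
  p <- px[h, , drop = FALSE]
  n <- nrow(p)
  if (n < 3L) return(length(rows))
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Theoretical nucleus area and perimeter for a magnification
#'
#' Reference values for shape triage: at 60x the expected nucleus covers
#' 2500--10000 px, summarized by the geometric mean (5000 px); areas scale
#' with the square of magnification, perimeter with its square root via the
#' equivalent circle.
#'
#' @param magnification one of 20, 40, 60.
#' @return list with `area` and `perimeter` in pixels.
#' @export
theoretical_shape <- function(magnification = 60) {
  magnification <- match.arg(as.character(magnification), c("20", "40", "60"))
  scale <- (as.numeric(magnification) / 60)^2
  area <- sqrt(2500 * 10000) * scale
  list(area = area, perimeter = 2 * pi * sqrt(area / pi))
}

#' Morphological feature vectors for labeled regions
#'
#' Computes, per label, the 10 shape descriptors used for fragment triage:
#' solidity, area, perimeter, major and minor axis lengths, axis ratio,
#' circularity (4*pi*A/P^2), area--perimeter ratio, and relative deviation
#' from the theoretical area and perimeter. Size features are reported in
#' pixels; `dev_area`/`dev_perimeter` are dimensionless.
#'
#' @param labels integer label matrix (0 = background).
#' @param theoretical_area,theoretical_perimeter reference nucleus shape
#'   (defaults: 60x values from [theoretical_shape()]).
#' @return data.frame with one row per label.
#' @export
region_features <- function(labels,
                            theoretical_area = theoretical_shape(60)$area,
                            theoretical_perimeter = theoretical_shape(60)$perimeter) {
  labels <- as_label_matrix(labels)
  idx <- label_indices(labels)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), solidity = numeric(),
                      area = numeric(), perimeter = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      axis_ratio = numeric(), circularity = numeric(),
                      area_perimeter_ratio = numeric(), dev_area = numeric(),
                      dev_perimeter = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), eccentricity = numeric()))
  }
  per <- face_perimeter(labels)
  nr <- nrow(labels)
  out <- lapply(names(idx), function(lb) {
    px <- idx[[lb]]
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    a <- length(px)
    p <- per[as.integer(lb)]
    mu_r <- mean(rows); mu_c <- mean(cols)
    # central second moments; +1/12 is the per-pixel variance correction
    v_rr <- mean((rows - mu_r)^2) + 1 / 12
    v_cc <- mean((cols - mu_c)^2) + 1 / 12
    v_rc <- mean((rows - mu_r) * (cols - mu_c))
    tr <- v_rr + v_cc
    det <- v_rr * v_cc - v_rc^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-9)
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
    data.frame(
      label = as.integer(lb),
      solidity = min(a / hull_area(rows, cols), 1),
      area = a,
      perimeter = p,
      major_axis = major,
      minor_axis = minor,
      axis_ratio = major / minor,
      circularity = 4 * pi * a / p^2,
      area_perimeter_ratio = a / p,
      dev_area = (a - theoretical_area) / theoretical_area,
      dev_perimeter = (p - theoretical_perimeter) / theoretical_perimeter,
      centroid_row = mu_r,
      centroid_col = mu_c,
      eccentricity = sqrt(max(1 - (minor / major)^2, 0))
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

feature_columns <- c("solidity", "area", "perimeter", "major_axis",
                     "minor_axis", "axis_ratio", "circularity",
                     "area_perimeter_ratio", "dev_area", "dev_perimeter")

#' Dimensionless triage features
#'
#' Normalizes the pixel-sized shape features of [region_features()] by
#' their theoretical counterparts (area by the theoretical area, lengths
#' by the equivalent diameter), so one trained triage model spans
#' magnifications.
#'
#' @param feat data.frame from [region_features()].
#' @param theoretical_area,theoretical_perimeter reference shape (px).
#' @return data.frame with the 10 dimensionless feature columns.
#' @export
normalize_features <- function(feat, theoretical_area, theoretical_perimeter) {
  d_eq <- 2 * sqrt(theoretical_area / pi)
  data.frame(
    solidity = feat$solidity,
    area = feat$area / theoretical_area,
    perimeter = feat$perimeter / theoretical_perimeter,
    major_axis = feat$major_axis / d_eq,
    minor_axis = feat$minor_axis / d_eq,
    axis_ratio = feat$axis_ratio,
    circularity = feat$circularity,
    area_perimeter_ratio = feat$area_perimeter_ratio / (theoretical_area / theoretical_perimeter),
    dev_area = feat$dev_area,
    dev_perimeter = feat$dev_perimeter
  )
}

# write a data.frame to CSV with numeric columns formatted at 17 significant
# digits so that read-back is bit-exact for doubles
write_exact_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- vapply(out[[j]], function(x)
        if (is.na(x)) NA_character_ else sprintf("%.17g", x), character(1))
      # keep a decimal marker so whole numbers read back as doubles
      plain <- !is.na(v) & !grepl("[.eE]", v)
      v[plain] <- paste0(v[plain], ".0")
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}
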