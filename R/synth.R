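#' Specification of a synthetic IFISH scene
#'
#' Describes a rendered tissue field: densely packed elliptical nuclei
#' (optionally touching), ring-like membrane staining with controllable
#' completeness, FISH spots (isolated, and amplified clusters), a spatially
#' varying background and Poisson--Gaussian sensor noise. Generation is
#' deterministic given `seed`.
#'
#' Defaults emulate a 60x FFPE field: nuclei at the theoretical area for the
#' magnification, an 80:20 chance of any nucleus being placed touching a
#' neighbour, complete membranes, 4 expected FISH signals per cell, a 5%
#' constant autofluorescence floor and Gaussian read noise of 0.01 on a unit
#' intensity scale.
#'
#' @param n_cells number of cells to place.
#' @param magnification 20, 40 or 60; sets nucleus and spot scale.
#' @param image_size optional c(rows, cols); default sized so territories
#'   fill about half the frame.
#' @param radius_mean,radius_sd nucleus equivalent radius (px); default
#'   from the theoretical nucleus area at this magnification.
#' @param touching_prob probability a cell is planted adjacent to an
#'   existing cell (centres at 88--98% of the radius sum).
#' @param membrane_completeness scalar or range c(lo,hi): fraction of each
#'   membrane ring rendered (a single contiguous arc is deleted).
#' @param spots_lambda Poisson mean of FISH signals per cell.
#' @param spots_fixed optional integer vector recycled over cells,
#'   overriding `spots_lambda` (use for exact planted counts).
#' @param amplified_prob probability a cell carries an amplified cluster
#'   (true copy number coded 22, rendered area above the saturation area).
#' @param background list(type = "constant"|"gradient"|"field", level).
#' @param noise_sd Gaussian noise sd (unit intensity scale).
#' @param poisson add Poisson photon noise (1000 photons at intensity 1).
#' @param two_populations if `TRUE`, half the cells form a second
#'   morphologically smaller, dimmer population (truth class "B").
#' @param seed RNG seed.
#' @return object of class `SceneSpec`.
#' @export
scene_spec <- function(n_cells = 30, magnification = 60, image_size = NULL,
                       radius_mean = NULL, radius_sd = NULL,
                       touching_prob = 0.2, membrane_completeness = 1,
                       spots_lambda = 4, spots_fixed = NULL,
                       amplified_prob = 0, background = list(type = "constant", level = 0.05),
                       noise_sd = 0.01, poisson = FALSE,
                       two_populations = FALSE, seed = 1) {
  stopifnot(n_cells >= 0, touching_prob >= 0, touching_prob <= 1,
            all(membrane_completeness >= 0), all(membrane_completeness <= 1))
  magnification <- as.numeric(match.arg(as.character(magnification),
                                        c("20", "40", "60")))
  th <- theoretical_shape(magnification)
  if (is.null(radius_mean)) radius_mean <- sqrt(th$area / pi)
  if (is.null(radius_sd)) radius_sd <- 0.08 * radius_mean
  if (is.null(image_size)) {
    side <- ceiling(sqrt(max(n_cells, 1) * pi * (1.6 * radius_mean)^2 / 0.5)) +
      ceiling(4 * radius_mean)
    image_size <- c(side, side)
  }
  structure(list(n_cells = n_cells, magnification = magnification,
                 image_size = image_size, radius_mean = radius_mean,
                 radius_sd = radius_sd, touching_prob = touching_prob,
                 membrane_completeness = membrane_completeness,
                 spots_lambda = spots_lambda, spots_fixed = spots_fixed,
                 amplified_prob = amplified_prob, background = background,
                 noise_sd = noise_sd, poisson = poisson,
                 two_populations = two_populations, seed = seed),
            class = "SceneSpec")
}

# squared elliptical metric of pixel grid (rows x cols) w.r.t. an ellipse
ellipse_d2 <- function(rows, cols, cr, cc, a, b, theta) {
  dr <- rows - cr; dc <- cols - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2
}

background_field <- function(type, level, nr, nc) {
  switch(type,
    constant = matrix(level, nr, nc),
    gradient = level * (0.5 + outer(rep(0, nr), seq(0, 1, length.out = nc), `+`) +
                          0.3 * outer(seq(0, 1, length.out = nr), rep(0, nc), `+`)),
    field = {
      f <- EBImage::gblur(matrix(runif(nr * nc), nr, nc),
                          sigma = max(nr, nc) / 20)
      f <- (f - min(f)) / max(diff(range(f)), 1e-12)
      level * (0.5 + f)
    },
    stop("unknown background type: ", type)
  )
}

#' Render a synthetic IFISH scene with ground truth
#'
#' Produces a four-channel [image_stack()] (DAPI, a nuclear protein stain
#' such as ER, a membrane protein stain such as HER2, and a FISH spot
#' channel) together with aligned ground truth: the nucleus and membrane
#' territory label maps, a spot table, and per-cell truth records.
#'
#' Nuclei are rendered as ellipses with a parabolic intensity profile
#' (bright centre, dimmer rim) so that touching nuclei present a watershed
#' saddle; membranes as rings at the cell-territory border with an optional
#' deleted arc; FISH signals as Gaussian blobs whose half-maximum area is
#' the per-spot reference area (20 px at 60x), amplified cells as one large
#' contiguous cluster above the saturation area.
#'
#' @param spec a [scene_spec()].
#' @return list of class `IfishScene`: `stack`, `nuclei`, `membranes`,
#'   `spots` (data.frame: cell, spot, row, col, area, amplified),
#'   `cells` (per-cell truth records), `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  mag_scale <- (spec$magnification / 60)^2
  area_per_spot <- 20 * mag_scale
  saturation_area <- 400 * mag_scale
  sigma_spot <- sqrt(area_per_spot / (2 * pi * log(2)))
  empty <- function() matrix(0, nr, nc)
  bg <- background_field(spec$background$type, spec$background$level, nr, nc)

  n <- spec$n_cells
  cells <- NULL
  if (n > 0) {
    # --- placement: dart throwing with optional adjacency ----------------
    r <- pmax(rnorm(n, spec$radius_mean, spec$radius_sd),
              0.6 * spec$radius_mean)
    cls <- rep("A", n)
    if (spec$two_populations) cls[seq_len(n) %% 2 == 0L] <- "B"
    r[cls == "B"] <- r[cls == "B"] * 0.65
    ratio <- ifelse(cls == "A", runif(n, 1.0, 1.5), runif(n, 1.8, 2.6))
    a <- r * sqrt(ratio); b <- r / sqrt(ratio)
    theta <- runif(n, 0, pi)
    margin <- 1.4 * max(a)
    if (2 * margin >= nr || 2 * margin >= nc)
      stop("infeasible packing: placed 0 of ", n, " cells")
    cr <- numeric(n); cc <- numeric(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      touch <- placed > 0L && runif(1) < spec$touching_prob
      for (try in seq_len(3000L)) {
        if (touch) {
          j <- sample.int(placed, 1L)
          ang <- runif(1, 0, 2 * pi)
          d <- (r[i] + r[j]) * runif(1, 0.88, 0.98)
          pr <- cr[j] + d * cos(ang); pc <- cc[j] + d * sin(ang)
        } else {
          pr <- runif(1, margin, nr - margin)
          pc <- runif(1, margin, nc - margin)
        }
        if (pr < margin || pr > nr - margin || pc < margin || pc > nc - margin)
          next
        if (placed > 0L) {
          dd <- sqrt((cr[seq_len(placed)] - pr)^2 + (cc[seq_len(placed)] - pc)^2)
          lim <- (r[seq_len(placed)] + r[i]) * if (touch) 0.85 else 1.25
          if (touch) {
            # adjacent to j but not overlapping anyone else too deeply
            if (any(dd < lim)) next
          } else {
            if (any(dd < lim)) next
          }
        }
        cr[i] <- pr; cc[i] <- pc; ok <- TRUE; break
      }
      if (!ok)
        stop("infeasible packing: placed ", placed, " of ", n, " cells")
      placed <- placed + 1L
    }
    cells <- data.frame(cell = seq_len(n), centroid_row = cr, centroid_col = cc,
                        radius = r, semi_major = a, semi_minor = b,
                        orientation = theta, class = cls)
  }

  nuclei <- matrix(0L, nr, nc)
  territories <- matrix(0L, nr, nc)
  dapi <- empty(); er <- empty(); her2 <- empty(); fish <- empty()
  spot_tab <- data.frame(cell = integer(), spot = integer(), row = numeric(),
                         col = numeric(), area = numeric(),
                         amplified = logical())

  if (n > 0) {
    comp <- spec$membrane_completeness
    comp_i <- if (length(comp) == 2L) runif(n, comp[1], comp[2])
              else rep(comp[1], n)
    dapi_amp <- runif(n, 0.75, 0.95)
    er_amp <- ifelse(cells$class == "A", runif(n, 0.35, 0.6),
                     runif(n, 0.02, 0.08))
    her2_amp <- ifelse(cells$class == "A", runif(n, 0.5, 0.7),
                       runif(n, 0.08, 0.15))
    cells$dapi_amp <- dapi_amp; cells$er_amp <- er_amp
    cells$her2_amp <- her2_amp; cells$membrane_completeness <- comp_i

    d2n_min <- matrix(Inf, nr, nc)   # nucleus assignment metric
    d2t_min <- matrix(Inf, nr, nc)   # territory assignment metric
    tscale <- 1.55
    for (i in seq_len(n)) {
      ao <- tscale * cells$semi_major[i]; bo <- tscale * cells$semi_minor[i]
      r0 <- max(1L, floor(cells$centroid_row[i] - ao - 2))
      r1 <- min(nr, ceiling(cells$centroid_row[i] + ao + 2))
      c0 <- max(1L, floor(cells$centroid_col[i] - ao - 2))
      c1 <- min(nc, ceiling(cells$centroid_col[i] + ao + 2))
      rows <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
      cols <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
      d2 <- ellipse_d2(rows, cols, cells$centroid_row[i], cells$centroid_col[i],
                       cells$semi_major[i], cells$semi_minor[i],
                       cells$orientation[i])
      blk <- nuclei[r0:r1, c0:c1]; dblk <- d2n_min[r0:r1, c0:c1]
      upd <- d2 <= 1 & d2 < dblk
      blk[upd] <- i; dblk[upd] <- d2[upd]
      nuclei[r0:r1, c0:c1] <- blk; d2n_min[r0:r1, c0:c1] <- dblk
      # DAPI parabolic profile, combined with max for touching pairs
      dapi_blk <- dapi[r0:r1, c0:c1]
      prof <- dapi_amp[i] * (1 - 0.5 * d2)
      sel <- d2 <= 1 & prof > dapi_blk
      dapi_blk[sel] <- prof[sel]
      dapi[r0:r1, c0:c1] <- dapi_blk
      # territory
      d2t <- ellipse_d2(rows, cols, cells$centroid_row[i], cells$centroid_col[i],
                        ao, bo, cells$orientation[i])
      tblk <- territories[r0:r1, c0:c1]; dtblk <- d2t_min[r0:r1, c0:c1]
      updt <- d2t <= 1 & d2t < dtblk
      tblk[updt] <- i; dtblk[updt] <- d2t[updt]
      territories[r0:r1, c0:c1] <- tblk; d2t_min[r0:r1, c0:c1] <- dtblk
      # membrane ring with deleted arc
      gap_start <- runif(1, 0, 2 * pi)
      gap_len <- (1 - comp_i[i]) * 2 * pi
      dr <- rows - cells$centroid_row[i]; dc <- cols - cells$centroid_col[i]
      u <- dr * cos(cells$orientation[i]) + dc * sin(cells$orientation[i])
      v <- -dr * sin(cells$orientation[i]) + dc * cos(cells$orientation[i])
      ang <- atan2(v / bo, u / ao) %% (2 * pi)
      in_gap <- ((ang - gap_start) %% (2 * pi)) < gap_len
      band <- d2t >= 0.82 & d2t <= 1 & tblk == i & !in_gap
      hblk <- her2[r0:r1, c0:c1]
      hblk[band] <- pmax(hblk[band], her2_amp[i])
      her2[r0:r1, c0:c1] <- hblk
    }
    # nuclear protein stain over nucleus footprints
    for (i in seq_len(n)) {
      px <- nuclei == i
      er[px] <- er_amp[i]
    }

    # --- FISH spots -------------------------------------------------------
    k <- if (!is.null(spec$spots_fixed))
      rep_len(as.integer(spec$spots_fixed), n) else rpois(n, spec$spots_lambda)
    amp_cell <- runif(n) < spec$amplified_prob
    copies_true <- ifelse(amp_cell, 22L, pmin(k, 21L))
    cells$copies_true <- copies_true
    half_r <- sigma_spot * sqrt(2 * log(2))
    for (i in seq_len(n)) {
      if (amp_cell[i]) {
        sig_c <- sqrt(1.15 * saturation_area / (2 * pi * log(2)))
        srow <- cells$centroid_row[i]; scol <- cells$centroid_col[i]
        fish <- add_gaussian(fish, srow, scol, sig_c, 0.6)
        spot_tab <- rbind(spot_tab, data.frame(
          cell = i, spot = 1L, row = srow, col = scol,
          area = 2 * pi * log(2) * sig_c^2, amplified = TRUE))
        next
      }
      if (k[i] == 0L) next
      pts <- matrix(NA_real_, 0, 2)
      for (s in seq_len(k[i])) {
        for (try in seq_len(600L)) {
          rho <- sqrt(runif(1)) * 0.72
          ang <- runif(1, 0, 2 * pi)
          u <- rho * cos(ang) * cells$semi_major[i]
          v <- rho * sin(ang) * cells$semi_minor[i]
          srow <- cells$centroid_row[i] + u * cos(cells$orientation[i]) -
            v * sin(cells$orientation[i])
          scol <- cells$centroid_col[i] + u * sin(cells$orientation[i]) +
            v * cos(cells$orientation[i])
          if (nrow(pts) == 0L ||
              all(sqrt((pts[, 1] - srow)^2 + (pts[, 2] - scol)^2) >
                  2 * half_r + 2)) {
            pts <- rbind(pts, c(srow, scol))
            break
          }
        }
      }
      for (s in seq_len(nrow(pts))) {
        fish <- add_gaussian(fish, pts[s, 1], pts[s, 2], sigma_spot,
                             runif(1, 0.55, 0.7))
        spot_tab <- rbind(spot_tab, data.frame(
          cell = i, spot = s, row = pts[s, 1], col = pts[s, 2],
          area = 2 * pi * log(2) * sigma_spot^2, amplified = FALSE))
      }
    }
  }

  finish <- function(signal) {
    x <- signal + bg
    if (spec$poisson) x <- rpois(length(x), pmax(x, 0) * 1000) / 1000
    x <- x + rnorm(length(signal), 0, spec$noise_sd)
    matrix(pmin(pmax(x, 0), 1), nr, nc)
  }
  stack <- image_stack(
    list(DAPI = finish(dapi), ER = finish(er), HER2 = finish(her2),
         HER2_FISH = finish(fish)),
    stains = c("DAPI", "nuclear-protein", "membrane-protein", "FISH-spot"),
    magnification = spec$magnification,
    names = c("DAPI", "ER", "HER2", "HER2_FISH"))

  structure(list(stack = stack, nuclei = nuclei, membranes = territories,
                 spots = spot_tab, cells = cells, background = bg,
                 spec = spec),
            class = "IfishScene")
}

# add an isotropic Gaussian blob by maximum composition
add_gaussian <- function(canvas, cr, cc, sigma, amp) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  ext <- ceiling(3.5 * sigma)
  r0 <- max(1L, floor(cr - ext)); r1 <- min(nr, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(nc, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cols <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  g <- amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sigma^2))
  canvas[r0:r1, c0:c1] <- pmax(canvas[r0:r1, c0:c1], g)
  canvas
}

#' Generate a labeled synthetic fragment training set
#'
#' Builds fragments of known segmentation quality for training the linear
#' triage classifiers: nucleus fragments labeled
#' `optimal` / `undersegmented` / `oversegmented`, or FISH spot candidates
#' labeled `optimal` / `too_small` / `too_large`. Classes are balanced
#' (n split as evenly as possible).
#'
#' Optimal nucleus fragments are ellipses near the theoretical area;
#' undersegmented ones are fused ellipse pairs (about twice the area, lower
#' solidity); oversegmented ones are elliptical caps and slivers well below
#' the theoretical area.
#'
#' @param n total number of fragments (>= number of classes).
#' @param type `"nucleus"` or `"spot"`.
#' @param magnification reference magnification for theoretical sizes.
#' @param seed RNG seed.
#' @return data.frame with a `class` column and one column per feature
#'   (normalized, dimensionless shape features; spots also carry
#'   `mean_intensity` and `min_intensity`).
#' @export
generate_fragments <- function(n, type = c("nucleus", "spot"),
                               magnification = 60, seed = 1) {
  type <- match.arg(type)
  classes <- if (type == "nucleus") c("optimal", "undersegmented", "oversegmented")
             else c("optimal", "too_small", "too_large")
  stopifnot(n >= length(classes))
  counts <- diff(floor(seq(0, n, length.out = length(classes) + 1)))
  with_seed(seed, {
    rows <- mapply(function(cl, k) {
      do.call(rbind, lapply(seq_len(k), function(i)
        render_training_fragment(cl, type, magnification)))
    }, classes, counts, SIMPLIFY = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

render_training_fragment <- function(cl, type, magnification) {
  th <- theoretical_shape(magnification)
  mag_scale <- (magnification / 60)^2
  if (type == "nucleus") {
    a_ref <- th$area
    geom <- switch(cl,
      optimal = list(kind = "ellipse", area = runif(1, 0.7, 1.35) * a_ref,
                     ratio = runif(1, 1, 1.7)),
      undersegmented = list(kind = "fused", area = runif(1, 1.7, 2.8) * a_ref,
                            ratio = runif(1, 1, 1.4)),
      oversegmented = list(kind = if (runif(1) < 0.5) "cap" else "ellipse",
                           area = runif(1, 0.06, 0.45) * a_ref,
                           ratio = runif(1, 1.2, 3)))
    m <- render_fragment_mask(geom)
    feat <- region_features(m, th$area, th$perimeter)
    out <- normalize_features(feat, th$area, th$perimeter)
  } else {
    aps <- 20 * mag_scale
    p_ref <- 2 * pi * sqrt(aps / pi)
    geom <- switch(cl,
      optimal = list(kind = "ellipse", area = runif(1, 0.6, 1.6) * aps,
                     ratio = runif(1, 1, 1.4)),
      too_small = list(kind = "ellipse", area = runif(1, 1, 6),
                       ratio = runif(1, 1, 2)),
      too_large = list(kind = if (runif(1) < 0.5) "ellipse" else "fused",
                       area = runif(1, 6, 30) * aps,
                       ratio = runif(1, 1.5, 5)))
    m <- render_fragment_mask(geom)
    feat <- region_features(m, aps, p_ref)
    out <- normalize_features(feat, aps, p_ref)
    out$mean_intensity <- switch(cl, optimal = runif(1, 0.45, 0.85),
                                 too_small = runif(1, 0.3, 0.8),
                                 too_large = runif(1, 0.15, 0.55))
    out$min_intensity <- out$mean_intensity * runif(1, 0.4, 0.8)
  }
  cbind(data.frame(class = cl), out)
}

# rasterize a single training fragment on its own canvas, return label mask
render_fragment_mask <- function(geom) {
  r_eq <- sqrt(geom$area / pi)
  a <- r_eq * sqrt(geom$ratio); b <- r_eq / sqrt(geom$ratio)
  theta <- runif(1, 0, pi)
  if (geom$kind == "fused") {
    # two overlapping ellipses along a shared axis
    a1 <- a / sqrt(2) * runif(1, 0.95, 1.15); b1 <- b / sqrt(2)
    sep <- a1 * runif(1, 1.1, 1.5)
    side <- ceiling(2 * (a1 + sep) + 8)
    rows <- matrix(seq_len(side), side, side)
    cols <- matrix(seq_len(side), side, side, byrow = TRUE)
    ctr <- (side + 1) / 2
    d1 <- ellipse_d2(rows, cols, ctr - sep / 2 * cos(theta),
                     ctr - sep / 2 * sin(theta), a1, b1, theta)
    d2 <- ellipse_d2(rows, cols, ctr + sep / 2 * cos(theta),
                     ctr + sep / 2 * sin(theta), a1, b1, theta)
    m <- (d1 <= 1 | d2 <= 1) * 1L
  } else {
    side <- ceiling(2 * a + 8)
    rows <- matrix(seq_len(side), side, side)
    cols <- matrix(seq_len(side), side, side, byrow = TRUE)
    ctr <- (side + 1) / 2
    d2 <- ellipse_d2(rows, cols, ctr, ctr, a, b, theta)
    m <- (d2 <= 1) * 1L
    if (geom$kind == "cap") {
      # keep one side of a chord through the ellipse
      frac <- runif(1, 0.25, 0.5)
      u <- (rows - ctr) * cos(theta) + (cols - ctr) * sin(theta)
      m[u > (2 * frac - 1) * a] <- 0L
    }
  }
  if (sum(m) == 0L) m[ceiling(nrow(m) / 2), ceiling(ncol(m) / 2)] <- 1L
  m
}
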