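#' Read and validate a batch parameter file
#'
#' YAML (or JSON) file with keys: `input` (glob of TIFF files), `stains`
#' (one label per channel), `magnification`, `output` (directory), and
#' optional `saturation_fraction`, `ring_margins` (two ints),
#' `seg` / `spot` parameter overrides (named lists passed to
#' [seg_params()] / [spot_params()]), `membrane_channel`,
#' `background_mask` (TIFF/PNG path), `thresholds` (list of
#' stain/cutoff/mode), `max_pixels` (tiling threshold), `seed`.
#'
#' @param path parameter file.
#' @return validated parameter list of class `ParameterFile`.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  p <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  for (key in c("input", "stains", "magnification", "output"))
    if (is.null(p[[key]])) stop("parameter file missing key: ", key)
  if (sum(p$stains == "DAPI") != 1L)
    stop("stains must include exactly one DAPI channel")
  if (!is.null(p$membrane_channel) &&
      !p$membrane_channel %in% c(p$stains, p$channel_names %||% character()))
    stop("membrane_channel not named in stains")
  p$magnification <- as.numeric(p$magnification)
  p$saturation_fraction <- p$saturation_fraction %||% 0.01
  p$ring_margins <- p$ring_margins %||% c(2, 6)
  p$max_pixels <- p$max_pixels %||% 12e6
  p$seed <- p$seed %||% 1L
  structure(p, class = "ParameterFile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Process one image stack through segmentation and measurement
#'
#' The default pipeline: foreground + iterative nuclear segmentation on
#' DAPI, membrane territories when a membrane stain is present, spot
#' detection on every FISH channel, per-cell background-adjusted
#' measurement.
#'
#' @param stack an [image_stack()].
#' @param seg a [seg_params()] (default from the stack magnification).
#' @param spot a [spot_params()] (default from the stack magnification).
#' @param background_mask optional logical matrix of background pixels
#'   for the global estimate; default: complement of the foreground mask.
#' @param classify_spots run the spot morphology classifier.
#' @return list: `nuclei`, `membranes` (`MembraneMap` or NULL), `spots`
#'   (data.frame, possibly several FISH channels with a `channel`
#'   column), `cells` (measured records), `backgrounds`.
#' @export
process_stack <- function(stack, seg = NULL, spot = NULL,
                          background_mask = NULL, classify_spots = FALSE) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.null(seg)) seg <- seg_params(stack$magnification)
  if (is.null(spot)) spot <- spot_params(stack$magnification)
  dapi <- dapi_channel(stack)
  nuclei <- iterative_segment(dapi, seg)
  if (is.null(background_mask)) {
    fg <- suppressWarnings(foreground_mask(dapi))
    background_mask <- !fg
    if (!any(background_mask)) background_mask <- NULL
  }
  backgrounds <- list()
  for (i in seq_along(stack$channels)) {
    nm <- names(stack$channels)[i]
    ch <- stack$channels[[i]]
    gbg <- if (!is.null(background_mask))
      global_background(ch, background_mask) else 0
    if (stack$stains[i] %in% c("DAPI", "nuclear-protein") &&
        max(nuclei) > 0L) {
      backgrounds[[nm]] <- suppressWarnings(
        ring_background(ch, nuclei, global_mean = gbg))
    } else backgrounds[[nm]] <- gbg
  }
  membranes <- NULL
  mem_i <- which(stack$stains == "membrane-protein")
  if (length(mem_i) && max(nuclei) > 0L)
    membranes <- membrane_segment(stack$channels[[mem_i[1]]], nuclei)
  spots <- NULL
  for (i in which(stack$stains == "FISH-spot")) {
    s <- detect_spots(stack$channels[[i]], nuclei, spot,
                      classify = classify_spots)
    if (nrow(s)) s$channel <- names(stack$channels)[i]
    spots <- if (is.null(spots)) s else rbind(spots, s)
  }
  cells <- map_segments(nuclei, membranes, spots)
  cells <- measure_cells(cells, stack, membranes, backgrounds, spot)
  list(nuclei = nuclei, membranes = membranes, spots = spots,
       cells = cells, backgrounds = backgrounds)
}

#' Split an oversized stack into overlapping tiles
#'
#' Tiles are at most `max_pixels` each, overlapping by 10% of the tile
#' edge; the stitch plan records each tile's placement so duplicate
#' objects in overlaps can be resolved by larger-area precedence.
#'
#' @param stack an [image_stack()].
#' @param max_pixels per-tile pixel budget.
#' @return list of `list(stack =, rows =, cols =)` tiles plus an
#'   attribute `shape` with the full frame dimensions.
#' @export
tile_image <- function(stack, max_pixels) {
  stopifnot(max_pixels > 0)
  d <- dim(stack$channels[[1]])
  if (prod(d) <= max_pixels) {
    out <- list(list(stack = stack, rows = c(1L, d[1]), cols = c(1L, d[2])))
    attr(out, "shape") <- d
    return(out)
  }
  n_tiles <- ceiling(prod(d) / max_pixels)
  n_r <- ceiling(sqrt(n_tiles * d[1] / d[2]))
  n_c <- ceiling(n_tiles / n_r)
  base_r <- ceiling(d[1] / n_r); base_c <- ceiling(d[2] / n_c)
  ov_r <- ceiling(0.1 * base_r); ov_c <- ceiling(0.1 * base_c)
  tiles <- list()
  for (i in seq_len(n_r)) for (j in seq_len(n_c)) {
    r0 <- max(1L, (i - 1L) * base_r + 1L - ov_r)
    r1 <- min(d[1], i * base_r + ov_r)
    c0 <- max(1L, (j - 1L) * base_c + 1L - ov_c)
    c1 <- min(d[2], j * base_c + ov_c)
    sub <- lapply(stack$channels, function(ch) ch[r0:r1, c0:c1])
    tiles[[length(tiles) + 1L]] <- list(
      stack = image_stack(sub, stack$stains, stack$magnification,
                          names = names(stack$channels),
                          gui_parity = FALSE),
      rows = c(r0, r1), cols = c(c0, c1))
  }
  attr(tiles, "shape") <- d
  tiles
}

#' Stitch tiled label maps into one frame
#'
#' Places tile label maps at their offsets; where an incoming object
#' overlaps an already-placed object, the larger object wins and the
#' smaller is dropped entirely.
#'
#' @param tile_labels list of label matrices, one per tile of
#'   [tile_image()].
#' @param tiles the tile list (for offsets).
#' @return stitched integer label matrix over the full frame.
#' @export
stitch_labels <- function(tile_labels, tiles) {
  shape <- attr(tiles, "shape")
  out <- matrix(0L, shape[1], shape[2])
  next_lab <- 1L
  for (k in seq_along(tile_labels)) {
    tl <- relabel(as_label_matrix(tile_labels[[k]]))
    if (max(tl) == 0L) next
    r <- tiles[[k]]$rows; cc <- tiles[[k]]$cols
    window <- out[r[1]:r[2], cc[1]:cc[2]]
    for (lb in seq_len(max(tl))) {
      px <- which(tl == lb)
      if (!length(px)) next
      existing <- unique(window[px])
      existing <- existing[existing > 0L]
      if (length(existing)) {
        ex_area <- sum(out %in% existing)
        if (ex_area >= length(px)) next        # keep placed objects
        out[out %in% existing] <- 0L
        window <- out[r[1]:r[2], cc[1]:cc[2]]
      }
      window[px] <- next_lab
      next_lab <- next_lab + 1L
      out[r[1]:r[2], cc[1]:cc[2]] <- window
    }
  }
  relabel(out)
}

#' Batch-process an image set from a parameter file
#'
#' For every input image: load, segment (nuclei, membranes, spots with
#' the parameter file's settings), measure, and save a result bundle —
#' a directory with `nuclei.tiff`, `membranes.tiff`, `spots.csv`,
#' `cells.csv`, a `manifest.json` recording every parameter actually
#' used, and `run.log`. Existing bundles are skipped unless
#' `force = TRUE` (resumability); any per-image failure is logged and
#' skipped, and reflected in the return value.
#'
#' Images larger than `max_pixels` are segmented in overlapping tiles and
#' stitched by larger-area precedence before measurement.
#'
#' @param params a `ParameterFile` from [read_params()], or a path to
#'   one, or an equivalent list.
#' @param force recompute existing bundles.
#' @return invisibly, data.frame of per-image status (`image`, `bundle`,
#'   `status`, `n_cells`).
#' @export
run_batch <- function(params, force = FALSE) {
  if (is.character(params)) params <- read_params(params)
  files <- Sys.glob(params$input)
  if (length(files) == 0L) stop("no input files match: ", params$input)
  dir.create(params$output, showWarnings = FALSE, recursive = TRUE)
  seg <- do.call(seg_params, c(list(magnification = params$magnification),
                               params$seg %||% list()))
  spot <- do.call(spot_params, c(list(magnification = params$magnification),
                                 params$spot %||% list()))
  bg_mask <- NULL
  if (!is.null(params$background_mask))
    bg_mask <- read_label_map(params$background_mask) > 0L
  status <- data.frame(image = files, bundle = NA_character_,
                       status = NA_character_, n_cells = NA_integer_)
  for (i in seq_along(files)) {
    f <- files[i]
    bundle <- file.path(params$output,
                        sub("\\.[^.]+$", "", basename(f)))
    status$bundle[i] <- bundle
    manifest_file <- file.path(bundle, "manifest.json")
    if (file.exists(manifest_file) && !force) {
      status$status[i] <- "skipped"
      next
    }
    res <- tryCatch({
      stack <- load_stack(f, params$stains, params$magnification,
                          gui_parity = FALSE)
      run_one(stack, seg, spot, bg_mask, params, bundle, f)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      status$status[i] <- paste0("error: ", res)
    } else {
      status$status[i] <- "ok"
      status$n_cells[i] <- res
    }
  }
  failed <- grepl("^error", status$status)
  if (any(failed))
    warning(sum(failed), " image(s) failed; see status")
  invisible(status)
}

run_one <- function(stack, seg, spot, bg_mask, params, bundle, src) {
  dir.create(bundle, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(bundle, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("input: ", src)
  d <- dim(stack$channels[[1]])
  if (prod(d) > params$max_pixels) {
    logline("tiling: frame ", prod(d), " px exceeds ", params$max_pixels)
    tiles <- tile_image(stack, params$max_pixels)
    tl <- lapply(tiles, function(t)
      iterative_segment(dapi_channel(t$stack), seg))
    nuclei <- stitch_labels(tl, tiles)
    res <- process_with_nuclei(stack, nuclei, seg, spot, bg_mask)
  } else {
    res <- process_stack(stack, seg, spot, bg_mask)
  }
  write_label_map(res$nuclei, file.path(bundle, "nuclei.tiff"))
  if (!is.null(res$membranes)) {
    write_label_map(res$membranes$labels, file.path(bundle, "membranes.tiff"))
    write_exact_csv(data.frame(membrane = as.integer(names(res$membranes$owner)),
                               nucleus = as.integer(res$membranes$owner)),
                    file.path(bundle, "owners.csv"))
  }
  spots <- res$spots %||% data.frame()
  write_exact_csv(spots, file.path(bundle, "spots.csv"))
  write_cells(res$cells, file.path(bundle, "cells.csv"))
  manifest <- list(
    input = src, n_cells = nrow(res$cells),
    stains = params$stains, magnification = params$magnification,
    seg = unclass(seg), spot = unclass(spot),
    saturation_fraction = params$saturation_fraction,
    ring_margins = params$ring_margins, seed = params$seed,
    files = c("nuclei.tiff", "cells.csv", "spots.csv"))
  jsonlite::write_json(manifest, file.path(bundle, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logline("parameters: h in [", seg$h_min_fraction, ", ",
          seg$h_max_fraction, "], min fragment ", seg$min_fragment_area,
          " px, min spot ", spot$min_spot_size, " px")
  logline("cells: ", nrow(res$cells))
  nrow(res$cells)
}

# measurement path when nuclei were produced by tiled segmentation
process_with_nuclei <- function(stack, nuclei, seg, spot, bg_mask) {
  dapi <- dapi_channel(stack)
  if (is.null(bg_mask)) {
    fg <- suppressWarnings(foreground_mask(dapi))
    bg_mask <- !fg
    if (!any(bg_mask)) bg_mask <- NULL
  }
  backgrounds <- list()
  for (i in seq_along(stack$channels)) {
    nm <- names(stack$channels)[i]
    ch <- stack$channels[[i]]
    gbg <- if (!is.null(bg_mask)) global_background(ch, bg_mask) else 0
    if (stack$stains[i] %in% c("DAPI", "nuclear-protein") && max(nuclei) > 0L)
      backgrounds[[nm]] <- suppressWarnings(
        ring_background(ch, nuclei, global_mean = gbg))
    else backgrounds[[nm]] <- gbg
  }
  membranes <- NULL
  mem_i <- which(stack$stains == "membrane-protein")
  if (length(mem_i) && max(nuclei) > 0L)
    membranes <- membrane_segment(stack$channels[[mem_i[1]]], nuclei)
  spots <- NULL
  for (i in which(stack$stains == "FISH-spot")) {
    s <- detect_spots(stack$channels[[i]], nuclei, spot)
    if (nrow(s)) s$channel <- names(stack$channels)[i]
    spots <- if (is.null(spots)) s else rbind(spots, s)
  }
  cells <- map_segments(nuclei, membranes, spots)
  cells <- measure_cells(cells, stack, membranes, backgrounds, spot)
  list(nuclei = nuclei, membranes = membranes, spots = spots,
       cells = cells, backgrounds = backgrounds)
}
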