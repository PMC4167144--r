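#' Construct an IFISH image stack
#'
#' An `ImageStack` holds co-registered 2-D channels with their stain labels
#' and the acquisition magnification. Exactly one channel must be labeled
#' `"DAPI"`; valid stain labels are `DAPI`, `nuclear-protein`,
#' `membrane-protein`, `FISH-spot`, `other`.
#'
#' @param channels list of numeric matrices with identical dimensions,
#'   non-negative intensities.
#' @param stains character vector, one stain label per channel.
#' @param magnification one of 20, 40, 60.
#' @param names optional channel names (e.g. `c("DAPI","HER2")`); defaults
#'   to the stain labels made unique.
#' @param gui_parity if `TRUE` (default), enforce the 5-channel limit of the
#'   interactive tool; batch processing may disable it.
#' @return object of class `ImageStack`.
#' @export
image_stack <- function(channels, stains, magnification = 60, names = NULL,
                        gui_parity = TRUE) {
  stain_levels <- c("DAPI", "nuclear-protein", "membrane-protein",
                    "FISH-spot", "other")
  if (!is.list(channels) || length(channels) == 0L)
    stop("channels must be a non-empty list of matrices")
  if (length(stains) != length(channels))
    stop("configuration error: ", length(stains), " stain labels for ",
         length(channels), " channels")
  bad <- setdiff(stains, stain_levels)
  if (length(bad))
    stop("configuration error: unknown stain label(s): ",
         paste(bad, collapse = ", "))
  if (sum(stains == "DAPI") != 1L)
    stop("configuration error: exactly one channel must be labeled DAPI")
  if (gui_parity && length(channels) > 5L)
    stop("configuration error: more than 5 stains (GUI-parity mode)")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all channels must share identical dimensions")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("channel intensities must be non-negative")
  magnification <- as.numeric(match.arg(as.character(magnification),
                                        c("20", "40", "60")))
  if (is.null(names)) names <- make.unique(stains, sep = "_")
  names(channels) <- names
  structure(list(channels = channels, stains = stains,
                 magnification = magnification),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("ImageStack:", length(x$channels), "channel(s),", d[1], "x", d[2],
      "px,", paste0(x$magnification, "x"), "\n")
  for (i in seq_along(x$channels))
    cat(sprintf("  [%d] %-16s (%s)\n", i, names(x$channels)[i], x$stains[i]))
  invisible(x)
}

#' Select a channel from an ImageStack by name or stain label
#'
#' @param stack an [image_stack()].
#' @param what a channel name (e.g. `"HER2"`) or stain label (e.g.
#'   `"membrane-protein"`); the first matching channel is returned.
#' @return numeric matrix.
#' @export
stack_channel <- function(stack, what) {
  if (what %in% names(stack$channels)) return(stack$channels[[what]])
  i <- which(stack$stains == what)
  if (length(i) == 0L) stop("no channel with stain or name '", what, "'")
  stack$channels[[i[1]]]
}

dapi_channel <- function(stack) stack_channel(stack, "DAPI")

#' Load a multi-page TIFF as an ImageStack
#'
#' Pages are read in file order, one channel per page, with intensities
#' preserved bit-exact (integer sample values are not rescaled).
#'
#' @param path TIFF file, one grayscale page per channel (8/16-bit or float).
#' @param stains stain label per page.
#' @inheritParams image_stack
#' @return an [image_stack()].
#' @export
load_stack <- function(path, stains, magnification = 60, gui_parity = TRUE) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse grayscale-as-RGB
    p
  })
  image_stack(pages, stains, magnification, gui_parity = gui_parity)
}

#' Save an ImageStack as a multi-page 16-bit TIFF
#'
#' Integer-valued channels up to 65535 round-trip bit-exact.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @export
save_stack <- function(stack, path) {
  pages <- lapply(stack$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write integer label maps as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background), values < 65536.
#' @param path TIFF file.
#' @export
write_label_map <- function(labels, path) {
  labels <- as_label_matrix(labels)
  if (max(labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  as_label_matrix(m)
}

#' Display-contrast adjustment with quantile saturation
#'
#' Linearly rescales a channel so that the lowest and highest
#' `saturation_fraction` of pixels saturate at the output range limits
#' (default 1%, matching common fluorescence display practice). The mapping
#' is monotone non-decreasing. Quantification should always read the
#' unadjusted copy; this adjustment is for display and for contrast-hungry
#' steps.
#'
#' @param channel numeric matrix.
#' @param saturation_fraction fraction in \[0, 0.5) clipped at each tail.
#' @param out_range length-2 output range; default `c(0,1)` for unit-scale
#'   input, otherwise the matching 8/16-bit range.
#' @return adjusted matrix; a constant channel is returned unchanged with a
#'   warning.
#' @export
autoadjust <- function(channel, saturation_fraction = 0.01, out_range = NULL) {
  stopifnot(length(channel) > 0, saturation_fraction >= 0,
            saturation_fraction < 0.5)
  lo <- quantile(channel, saturation_fraction, names = FALSE, type = 1)
  hi <- quantile(channel, 1 - saturation_fraction, names = FALSE, type = 1)
  if (hi <= lo) {
    warning("constant channel: no contrast adjustment possible")
    return(channel)
  }
  if (is.null(out_range)) {
    mx <- max(channel)
    out_range <- if (mx <= 1) c(0, 1) else if (mx <= 255) c(0, 255)
                 else c(0, 65535)
  }
  y <- (channel - lo) / (hi - lo)
  y[y < 0] <- 0
  y[y > 1] <- 1
  out_range[1] + y * (out_range[2] - out_range[1])
}

#' Mean background intensity over a region mask
#'
#' @param channel numeric matrix.
#' @param region_mask logical matrix of the same shape marking background
#'   pixels (in batch use, a painted/background mask file).
#' @return scalar mean intensity.
#' @export
global_background <- function(channel, region_mask) {
  stopifnot(all(dim(channel) == dim(region_mask)))
  region_mask <- region_mask > 0
  if (!any(region_mask)) stop("empty background mask")
  mean(channel[region_mask])
}

#' Subtract a background value from a channel
#'
#' @param channel numeric matrix.
#' @param value non-negative scalar.
#' @param clamp if `TRUE` (default) negative corrected intensities are set
#'   to 0 (a negative corrected intensity has no physical meaning).
#' @return corrected matrix.
#' @export
subtract_background <- function(channel, value, clamp = TRUE) {
  stopifnot(value >= 0)
  out <- channel - value
  if (clamp) out[out < 0] <- 0
  out
}

#' Per-nucleus ring background estimate
#'
#' For every nucleus, the local background is the mean channel intensity
#' over the annulus between morphological dilations of the nucleus by
#' `inner_margin` and `outer_margin` pixels (default 2--6 px from the
#' nucleus edge), excluding pixels of any nucleus. Nuclei whose annulus is
#' fully occluded by neighbors fall back to the global mean with a warning.
#'
#' @param channel numeric matrix.
#' @param nuclei nucleus label matrix.
#' @param inner_margin,outer_margin annulus margins in pixels.
#' @param global_mean fallback value; default: mean of the channel outside
#'   all nuclei.
#' @return object of class `BackgroundEstimate`: list with `global_mean`,
#'   `per_label` (named numeric, one value per nucleus label) and `mode`.
#' @export
ring_background <- function(channel, nuclei, inner_margin = 2,
                            outer_margin = 6, global_mean = NULL) {
  stopifnot(inner_margin < outer_margin, inner_margin >= 0)
  nuclei <- as_label_matrix(nuclei)
  stopifnot(all(dim(channel) == dim(nuclei)))
  idx <- label_indices(nuclei)
  if (length(idx) == 0L) stop("empty nucleus label map")
  if (is.null(global_mean)) {
    out_px <- nuclei == 0L
    global_mean <- if (any(out_px)) mean(channel[out_px]) else mean(channel)
  }
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  any_nucleus <- nuclei > 0L
  b_in <- disk_brush(inner_margin)
  b_out <- disk_brush(outer_margin)
  per <- setNames(numeric(length(idx)), names(idx))
  fellback <- character(0)
  for (lb in names(idx)) {
    px <- idx[[lb]]
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    r0 <- max(1L, min(rows) - outer_margin - 1L)
    r1 <- min(nr, max(rows) + outer_margin + 1L)
    c0 <- max(1L, min(cols) - outer_margin - 1L)
    c1 <- min(nc, max(cols) + outer_margin + 1L)
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1
    inner <- if (inner_margin > 0) EBImage::dilate(sub, b_in) else sub
    outer <- EBImage::dilate(sub, b_out)
    ann <- outer > 0 & inner == 0 & !any_nucleus[r0:r1, c0:c1]
    if (any(ann)) {
      per[lb] <- mean(channel[r0:r1, c0:c1][ann])
    } else {
      per[lb] <- global_mean
      fellback <- c(fellback, lb)
    }
  }
  if (length(fellback))
    warning("annulus occluded for label(s) ", paste(fellback, collapse = ", "),
            "; falling back to global mean")
  structure(list(global_mean = global_mean, per_label = per,
                 mode = "from_raw"),
            class = "BackgroundEstimate")
}
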