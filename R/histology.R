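#' Multi-channel annotated microscopy image
#'
#' @param channels named list of 2-D non-negative numeric matrices, all the
#'   same dimensions.
#' @param pixel_size_um side of one pixel (um).
#' @param roi_masks integer matrix of the same dimensions; 0 = background,
#'   k = pixels of cell ROI k (labels contiguous from 1).
#' @param roi_meta optional data frame with one row per ROI (e.g.
#'   \code{cell_id}, \code{animal_id}, \code{cell_class}).
#' @return list of class \code{"annotated_image"}.
#' @export
annotated_image <- function(channels, pixel_size_um, roi_masks,
                            roi_meta = NULL) {
  if (!length(channels) || is.null(names(channels))) {
    stop("channels must be a named list")
  }
  dims <- dim(channels[[1]])
  for (ch in channels) {
    if (!identical(dim(ch), dims)) stop("all channels must share dimensions")
    if (any(ch < 0)) stop("channel intensities must be non-negative")
  }
  if (!identical(dim(roi_masks), dims)) {
    stop("roi_masks must match channel dimensions")
  }
  labs <- sort(unique(as.integer(roi_masks[roi_masks > 0])))
  if (length(labs) && !identical(labs, seq_along(labs))) {
    stop("roi labels must be contiguous positive integers")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 roi_masks = roi_masks, roi_meta = roi_meta,
                 n_roi = length(labs)),
            class = "annotated_image")
}

#' Per-ROI mean staining intensity in an equally thresholded image
#'
#' The channel is thresholded once per batch (sub-threshold pixels zeroed)
#' and the mean over all pixels of each ROI is returned; with
#' \code{mode = "suprathreshold"} the mean runs over supra-threshold ROI
#' pixels only.
#'
#' @param img an \code{\link{annotated_image}}.
#' @param channel channel name.
#' @param threshold common batch threshold (>= 0).
#' @param mode \code{"all_pixels"} (default) or \code{"suprathreshold"}.
#' @return data frame: \code{roi}, \code{mean_intensity}, \code{n_pixels};
#'   empty ROIs are flagged with \code{NA} and excluded from downstream
#'   group summaries.
#' @export
roi_mean_intensity <- function(img, channel, threshold = 0,
                               mode = c("all_pixels", "suprathreshold")) {
  stopifnot(inherits(img, "annotated_image"))
  mode <- match.arg(mode)
  ch <- img$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  thr <- ch
  thr[thr < threshold] <- 0
  out <- data.frame(roi = seq_len(img$n_roi), mean_intensity = NA_real_,
                    n_pixels = 0L)
  for (k in seq_len(img$n_roi)) {
    sel <- img$roi_masks == k
    if (mode == "suprathreshold") sel <- sel & ch >= threshold
    n <- sum(sel)
    out$n_pixels[k] <- n
    if (n > 0) out$mean_intensity[k] <- mean(thr[sel])
  }
  out
}

#' Perimetric ring ROI around a cell
#'
#' The ring contains the pixels outside the cell whose Euclidean distance to
#' the cell is below \code{ring_width_um} — the lineal ROI used to quantify
#' perineuronal-net staining around a soma.
#'
#' @param roi_masks labeled integer matrix.
#' @param label cell label (> 0, present in the mask).
#' @param ring_width_um ring width (um).
#' @param pixel_size_um pixel size (um).
#' @return logical matrix of ring pixels (disjoint from the cell) with
#'   attribute \code{"clipped"} set when the ring touches the image border.
#' @export
perimetric_ring <- function(roi_masks, label, ring_width_um = 3.8,
                            pixel_size_um = 1) {
  if (ring_width_um < 0) stop("ring_width_um must be >= 0")
  cell <- roi_masks == label
  if (!any(cell)) stop("label not present in mask")
  if (ring_width_um == 0) {
    ring <- cell & FALSE
    attr(ring, "clipped") <- FALSE
    return(ring)
  }
  # distance of outside pixels to the nearest cell pixel
  d <- EBImage::distmap(1 - cell, metric = "euclidean")
  ring <- !cell & d * pixel_size_um <= ring_width_um
  # clipped if any ring pixel sits on the border, or the ring would extend
  # past it
  border <- matrix(FALSE, nrow(cell), ncol(cell))
  border[c(1, nrow(cell)), ] <- TRUE
  border[, c(1, ncol(cell))] <- TRUE
  attr(ring, "clipped") <- any(ring & border)
  ring
}

#' mRNA dot surface density within an ROI
#'
#' Binarizes the channel at the batch threshold, labels connected components
#' inside the ROI, discards components smaller than \code{dot_min_area_um2},
#' and reports dots per square micron together with the supra-threshold area
#' fraction.
#'
#' @param img an \code{\link{annotated_image}}.
#' @param channel channel name (e.g. the Fast Red mRNA channel).
#' @param roi logical matrix (ROI pixels), or an integer label into
#'   \code{img$roi_masks}.
#' @param threshold binarization threshold.
#' @param dot_min_area_um2 minimum accepted dot area (um^2).
#' @return list: \code{density_per_um2}, \code{n_dots}, \code{roi_area_um2},
#'   \code{area_fraction}.
#' @export
dot_density <- function(img, channel, roi, threshold,
                        dot_min_area_um2 = 0.25) {
  stopifnot(inherits(img, "annotated_image"))
  ch <- img$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  if (is.numeric(roi) && length(roi) == 1) roi <- img$roi_masks == roi
  px_area <- img$pixel_size_um^2
  roi_area <- sum(roi) * px_area
  if (roi_area == 0) stop("ROI has zero area")
  bin <- (ch >= threshold) & roi
  lab <- EBImage::bwlabel(bin)
  n_dots <- 0L
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    n_dots <- sum(sizes * px_area >= dot_min_area_um2)
  }
  list(density_per_um2 = n_dots / roi_area, n_dots = n_dots,
       roi_area_um2 = roi_area, area_fraction = sum(bin) / sum(roi))
}

#' Observed vs chance dot colocalization
#'
#' Chance colocalization re-runs \code{\link{dot_density}} after mirror
#' flipping the signal channel left-right (ROI masks untouched), breaking
#' any spatial relation between dots and cells while preserving the dot
#' statistics. \code{flip = "rotate180"} rotates instead.
#'
#' @inheritParams dot_density
#' @param flip \code{"horizontal"} (default) or \code{"rotate180"}.
#' @return list with \code{observed} and \code{chance}, each a
#'   \code{\link{dot_density}} result.
#' @export
chance_colocalization <- function(img, channel, roi, threshold,
                                  dot_min_area_um2 = 0.25,
                                  flip = c("horizontal", "rotate180")) {
  flip <- match.arg(flip)
  observed <- dot_density(img, channel, roi, threshold, dot_min_area_um2)
  ch <- img$channels[[channel]]
  flipped <- if (flip == "horizontal") ch[nrow(ch):1, , drop = FALSE]
             else ch[nrow(ch):1, ncol(ch):1, drop = FALSE]
  img2 <- img
  img2$channels[[channel]] <- flipped
  chance <- dot_density(img2, channel, roi, threshold, dot_min_area_um2)
  list(observed = observed, chance = chance)
}

#' Per-animal cumulative intensity distributions
#'
#' Builds a common bin-edge grid over the pooled value range, computes each
#' animal's cumulative fraction at every edge, and averages the per-animal
#' curves pointwise — so every animal contributes equally regardless of its
#' cell count.
#'
#' @param values numeric per-cell measurements.
#' @param animal factor/vector of the animal each cell belongs to.
#' @param n_bins number of bins of the common grid (default 18).
#' @return list: \code{edges} (length \code{n_bins + 1}),
#'   \code{per_animal} (matrix, one row per animal), \code{mean},
#'   \code{sem}, \code{animals}.
#' @export
cumulative_curves <- function(values, animal, n_bins = 18) {
  ok <- is.finite(values)
  values <- values[ok]; animal <- animal[ok]
  if (!length(values)) stop("no finite values")
  animals <- unique(animal)
  rng <- range(values)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  per <- t(vapply(animals, function(a) {
    stats::ecdf(values[animal == a])(edges)
  }, numeric(n_bins + 1)))
  rownames(per) <- as.character(animals)
  m <- colMeans(per)
  sem <- if (length(animals) > 1) {
    apply(per, 2, stats::sd) / sqrt(length(animals))
  } else rep(NA_real_, n_bins + 1)
  list(edges = edges, per_animal = per, mean = m, sem = sem,
       animals = animals)
}
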