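#' Configuration for the synthetic staining-image generator
#'
#' Emulates a confocal field of labeled somata: a cell-body channel
#' (\code{"pv"}), a graded somatic staining channel (\code{"arom"}), a
#' perineuronal-ring channel (\code{"wfa"}, present on a stated fraction of
#' cells), and an mRNA dot channel (\code{"dots"}) with programmable dot
#' densities inside and outside cells.
#'
#' @param size_px image side (pixels, square image).
#' @param pixel_size_um pixel size (um).
#' @param n_cells number of somata.
#' @param soma_radius_um soma radius (um).
#' @param pv_intensity,arom_intensity_range soma intensity (constant) and
#'   the range of the graded per-cell staining intensity.
#' @param ring_fraction fraction of cells carrying a perineuronal ring.
#' @param ring_width_um,ring_intensity ring geometry and intensity.
#' @param dot_density_in,dot_density_out mRNA dots per um^2 inside / outside
#'   somata.
#' @param dot_radius_um,dot_intensity dot geometry and intensity.
#' @param background,noise_sd additive background level and Gaussian noise
#'   SD (all channels; intensities are clipped at 0).
#' @param max_place_tries placement retries before giving up on a
#'   non-overlapping layout.
#' @return list of class \code{"stain_sim_config"}.
#' @export
stain_sim_config <- function(size_px = 360, pixel_size_um = 0.5,
                             n_cells = 12, soma_radius_um = 5,
                             pv_intensity = 120,
                             arom_intensity_range = c(40, 160),
                             ring_fraction = 0.83, ring_width_um = 3.8,
                             ring_intensity = 90, dot_density_in = 0.05,
                             dot_density_out = 0.005, dot_radius_um = 0.6,
                             dot_intensity = 150, background = 10,
                             noise_sd = 3, max_place_tries = 2000) {
  if (n_cells < 1) stop("need at least one cell")
  if (ring_fraction < 0 || ring_fraction > 1) {
    stop("ring_fraction must be in [0, 1]")
  }
  if (dot_density_in < 0 || dot_density_out < 0) {
    stop("dot densities must be >= 0")
  }
  structure(list(size_px = size_px, pixel_size_um = pixel_size_um,
                 n_cells = n_cells, soma_radius_um = soma_radius_um,
                 pv_intensity = pv_intensity,
                 arom_intensity_range = arom_intensity_range,
                 ring_fraction = ring_fraction,
                 ring_width_um = ring_width_um,
                 ring_intensity = ring_intensity,
                 dot_density_in = dot_density_in,
                 dot_density_out = dot_density_out,
                 dot_radius_um = dot_radius_um,
                 dot_intensity = dot_intensity, background = background,
                 noise_sd = noise_sd, max_place_tries = max_place_tries),
            class = "stain_sim_config")
}

#' Simulate an annotated staining image with per-cell ground truth
#'
#' Somata are placed without overlap (including their rings) and away from
#' the border; ring carriers are a Bernoulli draw at \code{ring_fraction};
#' dot counts are Poisson at the programmed densities, with dots inside one
#' soma kept apart so each remains one connected component. The ground
#' truth records each cell's programmed intensities, ring status and exact
#' dot count — everything needed to score the histology module with no
#' reference to the rendered pixels.
#'
#' @param cfg a \code{\link{stain_sim_config}}.
#' @param seed integer seed; output is a pure function of (cfg, seed).
#' @return list with \code{image} (an \code{\link{annotated_image}} with
#'   channels \code{pv}, \code{arom}, \code{wfa}, \code{dots}) and
#'   \code{truth} (data frame: \code{cell}, \code{arom_intensity},
#'   \code{has_ring}, \code{n_dots}).
#' @export
simulate_stain_image <- function(cfg = stain_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "stain_sim_config"))
  set.seed(seed)
  npx <- cfg$size_px
  px <- cfg$pixel_size_um
  side_um <- npx * px
  r <- cfg$soma_radius_um
  outer <- r + cfg$ring_width_um
  # pixel-center coordinates (um)
  xs <- (seq_len(npx) - 0.5) * px
  X <- matrix(xs, npx, npx)
  Y <- matrix(xs, npx, npx, byrow = TRUE)
  # place cells: centers at least 2*outer + 1um apart, outer inside image
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < cfg$n_cells) {
    tries <- tries + 1
    if (tries > cfg$max_place_tries) {
      stop("could not place cells without overlap; lower n_cells or radius")
    }
    cand <- stats::runif(2, outer + px, side_um - outer - px)
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - cand[1])^2 +
                 (centers[, 2] - cand[2])^2)) > 2 * outer + 1) {
      centers <- rbind(centers, cand)
    }
  }
  mask <- matrix(0L, npx, npx)
  pv <- arom <- wfa <- dots <- matrix(0, npx, npx)
  has_ring <- stats::runif(cfg$n_cells) < cfg$ring_fraction
  arom_int <- stats::runif(cfg$n_cells, cfg$arom_intensity_range[1],
                           cfg$arom_intensity_range[2])
  cell_area_um2 <- pi * r^2
  n_dots <- integer(cfg$n_cells)
  dot_centers <- matrix(numeric(0), 0, 2)
  min_sep <- 2 * cfg$dot_radius_um + 2 * px
  for (k in seq_len(cfg$n_cells)) {
    d2 <- (X - centers[k, 1])^2 + (Y - centers[k, 2])^2
    inside <- d2 <= r^2
    mask[inside] <- k
    pv[inside] <- cfg$pv_intensity
    arom[inside] <- arom_int[k]
    if (has_ring[k]) {
      ring <- d2 > r^2 & d2 <= (r + cfg$ring_width_um)^2
      wfa[ring] <- cfg$ring_intensity
    }
    want <- stats::rpois(1, cfg$dot_density_in * cell_area_um2)
    placed <- 0
    guard <- 0
    while (placed < want && guard < 200 * max(want, 1)) {
      guard <- guard + 1
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (r - cfg$dot_radius_um - px)
      cand <- centers[k, ] + rad * c(cos(ang), sin(ang))
      if (nrow(dot_centers) == 0 ||
          min(sqrt((dot_centers[, 1] - cand[1])^2 +
                   (dot_centers[, 2] - cand[2])^2)) > min_sep) {
        dot_centers <- rbind(dot_centers, cand)
        placed <- placed + 1
      }
    }
    n_dots[k] <- placed
  }
  # background dots outside any soma (and clear of them)
  out_area <- side_um^2 - cfg$n_cells * cell_area_um2
  want_out <- stats::rpois(1, cfg$dot_density_out * out_area)
  placed <- 0; guard <- 0
  while (placed < want_out && guard < 200 * max(want_out, 1)) {
    guard <- guard + 1
    cand <- stats::runif(2, px, side_um - px)
    dmin <- min(sqrt((centers[, 1] - cand[1])^2 +
                     (centers[, 2] - cand[2])^2))
    if (dmin > r + cfg$dot_radius_um + px &&
        (nrow(dot_centers) == 0 ||
         min(sqrt((dot_centers[, 1] - cand[1])^2 +
                  (dot_centers[, 2] - cand[2])^2)) > min_sep)) {
      dot_centers <- rbind(dot_centers, cand)
      placed <- placed + 1
    }
  }
  for (j in seq_len(nrow(dot_centers))) {
    d2 <- (X - dot_centers[j, 1])^2 + (Y - dot_centers[j, 2])^2
    dots[d2 <= cfg$dot_radius_um^2] <- cfg$dot_intensity
  }
  addnoise <- function(ch) {
    ch <- ch + cfg$background
    if (cfg$noise_sd > 0) {
      ch <- ch + stats::rnorm(length(ch), sd = cfg$noise_sd)
    }
    pmax(matrix(ch, npx, npx), 0)
  }
  img <- annotated_image(
    channels = list(pv = addnoise(pv), arom = addnoise(arom),
                    wfa = addnoise(wfa), dots = addnoise(dots)),
    pixel_size_um = px, roi_masks = mask,
    roi_meta = data.frame(cell = seq_len(cfg$n_cells),
                          cell_class = "PV"))
  list(image = img,
       truth = data.frame(cell = seq_len(cfg$n_cells),
                          arom_intensity = arom_int + cfg$background,
                          has_ring = has_ring, n_dots = n_dots))
}
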