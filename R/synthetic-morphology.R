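#' Parameters for stochastic island growth
#'
#' The simulator mimics the seed-mediated, surface-based growth that produces
#' silver nanostructures on a polystyrene substrate: gold-nanoparticle
#' nucleation sites are laid down at a controllable areal density (the proxy
#' for poly-L-lysine-mediated seeding), and silver then accretes around them
#' until a target surface coverage (the proxy for the silver-precursor
#' budget) is reached.  Varying `seed_density` and `target_coverage` moves
#' the output through the three continuity regimes observed for such
#' substrates: sparsely dispersed particles, semi-continuous nanoislands,
#' and near-continuous films.
#'
#' @param field_size integer c(width, height) of the field in pixels.
#' @param pixel_size nm per pixel.  The default 2 nm/px makes a 1000 x 750 px
#'   field correspond to a 2000 nm x 1500 nm SEM region.
#' @param seed_density nucleation sites per square micrometre.
#' @param seed_radius initial radius of each nucleation disk, px.
#' @param target_coverage silver area fraction at which growth stops, in
#'   \[0, 1\].
#' @param attach_prob per-sweep conversion probability of a gap pixel
#'   touching silver (in (0, 1\]); lower values give rougher growth fronts.
#' @param rng_seed integer seed making the simulation reproducible.
#' @return list of class `growth_params`.
#' @seealso [simulate_seed_field()], [grow_islands()]
#' @export
growth_params <- function(field_size = c(256L, 256L), pixel_size = 2,
                          seed_density = 20, seed_radius = 3L,
                          target_coverage = 0.5, attach_prob = 0.5,
                          rng_seed = NULL) {
  stopifnot(length(field_size) == 2L, all(field_size >= 1L))
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  if (seed_density < 0) stop("'seed_density' must be >= 0")
  if (target_coverage < 0 || target_coverage > 1)
    stop("'target_coverage' must be in [0, 1]")
  if (attach_prob <= 0 || attach_prob > 1)
    stop("'attach_prob' must be in (0, 1]")
  if (seed_radius < 0) stop("'seed_radius' must be >= 0")
  structure(list(field_size = as.integer(field_size), pixel_size = pixel_size,
                 seed_density = seed_density, seed_radius = seed_radius,
                 target_coverage = target_coverage, attach_prob = attach_prob,
                 rng_seed = rng_seed),
            class = "growth_params")
}

#' Simulate a field of nucleation sites
#'
#' Draws a Poisson number of seeds with mean `seed_density` times the field
#' area in square micrometres, placed uniformly over the field.  Seeds
#' falling outside the image cannot occur (the field is the whole world);
#' growth at the border simply truncates.
#'
#' @param params a [growth_params()] object.
#' @return data.frame with columns `x`, `y` (pixel coordinates, continuous,
#'   in \[0, width\] x \[0, height\]).
#' @export
simulate_seed_field <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  w <- params$field_size[1L]; h <- params$field_size[2L]
  area_um2 <- (w * params$pixel_size / 1000) * (h * params$pixel_size / 1000)
  if (area_um2 <= 0) stop("field has zero area")
  with_seed(params$rng_seed, {
    n <- rpois(1L, params$seed_density * area_um2)
    data.frame(x = runif(n, 0, w), y = runif(n, 0, h))
  })
}

#' Grow silver islands from seeds (Eden-type accretion)
#'
#' Initializes silver as disks of `seed_radius` around each seed, then
#' repeatedly lets every gap pixel 4-adjacent to silver convert with
#' probability `attach_prob` per sweep, stopping at the first sweep where
#' coverage reaches `target_coverage`.  Coverage is non-decreasing across
#' sweeps, so for a fixed seed field and `rng_seed` the mask at a lower
#' target is always a sub-mask of the one at a higher target.
#'
#' @param seeds data.frame with `x`, `y` seed positions (px), e.g. from
#'   [simulate_seed_field()].
#' @param params a [growth_params()] object.
#' @return a [binary_mask()].
#' @export
grow_islands <- function(seeds, params) {
  stopifnot(inherits(params, "growth_params"))
  w <- params$field_size[1L]; h <- params$field_size[2L]
  mask <- matrix(0L, nrow = h, ncol = w)
  if (params$target_coverage == 0)
    return(binary_mask(mask, params$pixel_size))
  if (is.null(seeds) || nrow(seeds) == 0L)
    stop("target_coverage > 0 requires at least one seed")
  # stamp nucleation disks (pixel centers at integer coordinates - 0.5)
  r <- params$seed_radius
  px <- col(mask) - 0.5; py <- row(mask) - 0.5
  for (i in seq_len(nrow(seeds))) {
    sel <- (px - seeds$x[i])^2 + (py - seeds$y[i])^2 <= r^2
    mask[sel] <- 1L
  }
  if (!any(mask == 1L)) {
    # radius too small to cover any pixel center: use nearest pixel
    ij <- cbind(pmin(pmax(ceiling(seeds$y), 1L), h),
                pmin(pmax(ceiling(seeds$x), 1L), w))
    mask[ij] <- 1L
  }
  npix <- length(mask)
  with_seed(params$rng_seed, {
    sweeps <- 0L
    while (sum(mask) / npix < params$target_coverage) {
      frontier <- which(mask == 0L & frontier_adjacent(mask))
      if (!length(frontier)) break  # nothing left to grow into
      grow <- frontier[runif(length(frontier)) < params$attach_prob]
      mask[grow] <- 1L
      sweeps <- sweeps + 1L
      if (sweeps > 100000L) stop("growth failed to reach target coverage")
    }
  })
  binary_mask(mask, params$pixel_size)
}

# gap pixels with at least one silver 4-neighbour
frontier_adjacent <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(0L, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask
  adj <- P[1:nr, 2:(nc + 1L)] | P[3:(nr + 2L), 2:(nc + 1L)] |
    P[2:(nr + 1L), 1:nc] | P[2:(nr + 1L), 3:(nc + 2L)]
  adj
}

#' Rendering parameters for synthetic SEM images
#'
#' @param fg_mean,bg_mean mean intensities of the silver and gap phases on
#'   the bit-depth scale (must differ).
#' @param noise_sd additive Gaussian noise s.d., intensity units.
#' @param blur_sigma Gaussian blur s.d. in px (0 = no blur).
#' @param bit_depth 8 or 16.
#' @return list of class `render_params`.
#' @export
render_params <- function(fg_mean = 200, bg_mean = 40, noise_sd = 8,
                          blur_sigma = 1, bit_depth = 8L) {
  if (fg_mean == bg_mean) stop("'fg_mean' and 'bg_mean' must differ")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (blur_sigma < 0) stop("'blur_sigma' must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  structure(list(fg_mean = fg_mean, bg_mean = bg_mean, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, bit_depth = as.integer(bit_depth)),
            class = "render_params")
}

#' Render a binary mask as a synthetic SEM-style grayscale image
#'
#' Silver pixels take `fg_mean`, gaps `bg_mean`; the image is Gaussian
#' blurred, Gaussian noise is added, and intensities are clipped (not
#' rescaled) to the bit-depth range, mimicking detector saturation.
#'
#' @param mask a [binary_mask()].
#' @param params a [render_params()] object.
#' @param rng_seed optional integer seed for the noise draw.
#' @return a [gray_image()].
#' @export
render_sem <- function(mask, params = render_params(), rng_seed = NULL) {
  stopifnot(inherits(params, "render_params"))
  m <- as_mask_matrix(mask)
  img <- params$bg_mean + m * (params$fg_mean - params$bg_mean)
  if (params$blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = params$blur_sigma))
  if (params$noise_sd > 0)
    img <- with_seed(rng_seed,
                     img + rnorm(length(img), sd = params$noise_sd))
  lim <- 2^params$bit_depth - 1
  img <- round(pmin(pmax(img, 0), lim))
  gray_image(img, pixel_size = mask_pixel_size(mask),
             bit_depth = params$bit_depth)
}

#' Simulate a nanoisland substrate end to end
#'
#' Convenience wrapper: seed field, island growth, and (optionally) SEM-style
#' rendering, all driven by one `rng_seed`.
#'
#' @inheritParams simulate_seed_field
#' @param render `NULL` for mask only, or a [render_params()] object.
#' @return list with `seeds`, `mask`, and (if requested) `image`.
#' @export
simulate_substrate <- function(params, render = NULL) {
  seeds <- simulate_seed_field(params)
  mask <- grow_islands(seeds, params)
  out <- list(seeds = seeds, mask = mask)
  if (!is.null(render)) {
    rs <- if (is.null(params$rng_seed)) NULL else params$rng_seed + 1L
    out$image <- render_sem(mask, render, rng_seed = rs)
  }
  out
}
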