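#' Grayscale SEM-style image container
#'
#' @param x numeric matrix of intensities on the bit-depth scale.
#' @param pixel_size nm per pixel (positive).
#' @param bit_depth 8 or 16.
#' @return numeric matrix of class `gray_image` with `pixel_size` and
#'   `bit_depth` attributes.
#' @export
gray_image <- function(x, pixel_size = 1, bit_depth = 8L) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  if (any(x < 0) || any(x > 2^bit_depth - 1))
    stop("intensities outside bit-depth range")
  attr(x, "pixel_size") <- pixel_size
  attr(x, "bit_depth") <- as.integer(bit_depth)
  class(x) <- c("gray_image", class(x))
  x
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %d-bit, pixel size %g nm/px\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "pixel_size")))
  invisible(x)
}

#' Otsu threshold of an integer-valued grayscale image
#'
#' Exhaustively maximizes the between-class variance of the intensity
#' histogram over every candidate threshold; ties are broken toward the
#' lowest maximizing threshold.  Pixels strictly above the returned
#' threshold form the bright class.
#'
#' @param img matrix of integer intensities (a [gray_image()] or plain
#'   matrix).
#' @return the threshold t (intensity value); bright class is `img > t`.
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(round(as.numeric(img)))
  levels <- sort(unique(v))
  if (length(levels) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct intensities")
  lo <- min(levels); hi <- max(levels)
  counts <- tabulate(v - lo + 1L, nbins = hi - lo + 1L)
  vals <- lo:hi
  n <- sum(counts)
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * vals)
  total <- sum0[length(sum0)]
  # candidate thresholds t = vals[i]: class0 = (<= t), class1 = (> t)
  i <- seq_len(length(vals) - 1L)
  w1 <- n - w0[i]
  valid <- w0[i] > 0L & w1 > 0L
  mu0 <- sum0[i] / w0[i]
  mu1 <- (total - sum0[i]) / w1
  bcv <- (w0[i] / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  vals[which.max(bcv)]  # which.max returns the first (lowest) maximizer
}

#' Binarize an SEM image by Otsu's method
#'
#' Classifies each pixel into silver (1) or gap (0) by global Otsu
#' thresholding of the intensity histogram.  The brighter phase is taken as
#' silver (backscatter contrast of metal on polystyrene); use
#' `invert = TRUE` for reversed-contrast images.
#'
#' @param img a [gray_image()] (or integer matrix).
#' @param invert if `TRUE` the darker phase is treated as silver.
#' @return a [binary_mask()].
#' @export
binarize_otsu <- function(img, invert = FALSE) {
  t <- otsu_threshold(img)
  m <- matrix(as.integer(img > t), nrow(img), ncol(img))
  if (invert) m <- 1L - m
  binary_mask(m, pixel_size = attr(img, "pixel_size") %||% 1)
}

#' Morphological cleanup: remove isolated pixels, then majority filter
#'
#' Reproduces the classic `clean` + `majority` post-processing of binarized
#' SEM fields: first, silver pixels with no silver 8-neighbour are removed;
#' then a pixel becomes silver iff at least 5 of the 9 pixels in its 3x3
#' neighbourhood (itself included) are silver.  Pixels beyond the image
#' border count as gap (zero padding).
#'
#' @param mask a [binary_mask()].
#' @return a cleaned [binary_mask()].
#' @export
morphological_clean <- function(mask) {
  m <- as_mask_matrix(mask)
  ns <- neighbor_sum8(m)
  m[m == 1L & ns == 0L] <- 0L  # 'clean'
  ns <- neighbor_sum8(m)
  maj <- matrix(as.integer(ns + m >= 5L), nrow(m), ncol(m))  # 'majority'
  binary_mask(maj, pixel_size = mask_pixel_size(mask))
}

#' Euclidean distance transform to the silver phase
#'
#' Exact Euclidean distance from every pixel center to the nearest silver
#' pixel center (zero on silver).  Computed with [EBImage::distmap()], which
#' agrees exactly with a brute-force nearest-silver search.
#'
#' @param mask a [binary_mask()] containing at least one silver pixel.
#' @return numeric matrix of distances in px with attribute `pixel_size`.
#' @export
distance_transform <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m == 1L)) stop("all-gap mask: no silver phase to measure against")
  d <- as.matrix(EBImage::distmap(1 - m, metric = "euclidean"))
  attr(d, "pixel_size") <- mask_pixel_size(mask)
  d
}

#' Skeletonize the gap phase (topology-preserving, 4-connectivity)
#'
#' Thins the gap phase (the complement of the silver mask) to a unit-width
#' medial representation under 4-connectivity of the gaps, by sequential
#' deletion of simple pixels in order of increasing distance to silver.
#' Deleting only simple pixels guarantees that the Euler number (components
#' minus holes) of the skeleton equals that of the full gap phase; curve
#' end-pixels are retained so medial lines keep their extent.
#'
#' @param mask a [binary_mask()]; the gaps (0 pixels) are skeletonized.
#' @return logical matrix of class `gap_skeleton` (`TRUE` = skeleton pixel),
#'   with attributes `connectivity = 4` and `pixel_size`.
#' @export
skeletonize_gaps <- function(mask) {
  m <- as_mask_matrix(mask)
  gap <- m == 0L
  if (!any(gap)) {
    sk <- matrix(FALSE, nrow(m), ncol(m))
  } else {
    # order deletions from the silver boundary inwards: medial result
    dm <- if (any(m == 1L)) distance_transform(mask) else
      matrix(0, nrow(m), ncol(m))
    sk <- thin4(gap, dm)
  }
  attr(sk, "connectivity") <- 4L
  attr(sk, "pixel_size") <- mask_pixel_size(mask)
  class(sk) <- c("gap_skeleton", class(sk))
  sk
}

# Sequential topology-preserving thinning of `fg` under 4-connectivity of
# the foreground (8-connectivity of the background).  A pixel is deletable
# iff its Yokoi 4-connectivity number is 1 (simple point) and it is not a
# curve end-pixel (> 1 foreground 8-neighbour).  Candidates are processed
# in order of increasing `dmap`, so deletion proceeds from the phase
# boundary toward the medial line.
thin4 <- function(fg, dmap) {
  nr <- nrow(fg); nc <- ncol(fg)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- fg
  D <- matrix(0, nr + 2L, nc + 2L)
  D[2:(nr + 1L), 2:(nc + 1L)] <- dmap
  # neighbour offsets in cyclic order E, NE, N, NW, W, SW, S, SE
  off_r <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  off_c <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  nrp <- nr + 2L
  repeat {
    idx <- which(P)
    if (!length(idx)) break
    rr <- ((idx - 1L) %% nrp) + 1L
    cc <- ((idx - 1L) %/% nrp) + 1L
    interior <- P[cbind(rr, cc + 1L)] & P[cbind(rr - 1L, cc)] &
      P[cbind(rr, cc - 1L)] & P[cbind(rr + 1L, cc)]
    cand <- idx[!interior]
    if (!length(cand)) break
    cand <- cand[order(D[cand], cand)]
    removed <- FALSE
    for (p in cand) {
      r <- ((p - 1L) %% nrp) + 1L
      c2 <- ((p - 1L) %/% nrp) + 1L
      n <- P[cbind(r + off_r, c2 + off_c)]
      if (sum(n) <= 1L) next  # end-pixel (or isolated): keep
      s <- 0L
      for (k in c(1L, 3L, 5L, 7L)) {
        a <- n[k]; b <- n[(k %% 8L) + 1L]; d <- n[((k + 1L) %% 8L) + 1L]
        s <- s + (a - a * b * d)
      }
      if (s == 1L) { P[p] <- FALSE; removed <- TRUE }
    }
    if (!removed) break
  }
  P[2:(nr + 1L), 2:(nc + 1L)]
}

#' Gap distances along the gap skeleton
#'
#' The package's core morphometric statistic: at every gap-skeleton pixel
#' the gap distance is twice the Euclidean distance to the nearest silver
#' pixel, i.e. the local width of the gap read at its medial line.
#' Skeleton pixels in the 1-px border frame are excluded, since gaps cut by
#' the field of view are truncated.  Distances are measured between pixel
#' centers, so on a stripe of geometric width w px the statistic reads
#' w + 1 px; this discretization offset is intrinsic to the convention and
#' covered by the package's phantom tests.
#'
#' @param skeleton a [skeletonize_gaps()] result.
#' @param dmap a [distance_transform()] of the same mask.
#' @param pixel_size nm per px; taken from the inputs when `NULL`.
#' @param units `"px"` or `"nm"`.
#' @return numeric vector of gap distances (one per interior skeleton
#'   pixel), with attribute `units`.
#' @export
gap_distances <- function(skeleton, dmap, pixel_size = NULL,
                          units = c("px", "nm")) {
  units <- match.arg(units)
  if (!all(dim(skeleton) == dim(dmap)))
    stop("skeleton and distance map must share dimensions")
  sk <- unclass(skeleton)
  nr <- nrow(sk); nc <- ncol(sk)
  if (nr > 2L && nc > 2L) {
    border <- matrix(TRUE, nr, nc)
    border[2:(nr - 1L), 2:(nc - 1L)] <- FALSE
    sk <- sk & !border
  } else sk[] <- FALSE
  d <- 2 * dmap[sk]
  if (!length(d)) warning("empty gap skeleton: no gap distances emitted")
  if (units == "nm") {
    ps <- pixel_size %||% attr(skeleton, "pixel_size") %||%
      attr(dmap, "pixel_size") %||% 1
    d <- d * ps
  }
  attr(d, "units") <- units
  d
}

#' Fit a gamma distribution to a gap-distance sample
#'
#' Maximum-likelihood gamma fit (shape k, scale theta) with
#' method-of-moments initialization (k0 = mean^2/var, theta0 = var/mean),
#' the standard parametric summary of gap-width distributions.  Delegates
#' the likelihood optimization to [fitdistrplus::fitdist()].
#'
#' @param sample positive numeric vector (n >= 10, non-zero variance), e.g.
#'   from [gap_distances()].
#' @return list of class `gamma_fit` with `shape`, `scale`, `loglik`, `n`,
#'   and `units`.
#' @export
fit_gamma <- function(sample) {
  x <- as.numeric(sample)
  if (length(x) < 10L) stop("degenerate sample: need at least 10 values")
  if (any(x <= 0)) stop("gap distances must be positive")
  if (var(x) == 0) stop("degenerate sample: zero variance")
  k0 <- mean(x)^2 / var(x)
  theta0 <- var(x) / mean(x)
  fit <- fitdistrplus::fitdist(x, "gamma", method = "mle",
                               start = list(shape = k0, rate = 1 / theta0),
                               keepdata = FALSE)
  est <- coef(fit)
  structure(list(shape = unname(est["shape"]),
                 scale = 1 / unname(est["rate"]),
                 loglik = fit$loglik, n = length(x),
                 units = attr(sample, "units") %||% NA_character_),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "<gamma_fit> shape %.4g, scale %.4g (mean %.4g), n = %d, logLik %.2f\n",
    x$shape, x$scale, x$shape * x$scale, x$n, x$loglik))
  invisible(x)
}

#' Gamma density of a fitted gap-distance distribution
#'
#' @param fit a [fit_gamma()] result.
#' @param x distances at which to evaluate the normalized density.
#' @return numeric density values, for overlay on normalized histograms.
#' @export
gamma_fit_density <- function(fit, x) {
  stopifnot(inherits(fit, "gamma_fit"))
  dgamma(x, shape = fit$shape, scale = fit$scale)
}

#' Silver surface coverage and phase component counts
#'
#' @param mask a [binary_mask()].
#' @return list of class `coverage_result` with `fraction` (silver area
#'   fraction), `silver_components` (8-connectivity), and `gap_components`
#'   (4-connectivity).
#' @export
coverage <- function(mask) {
  m <- as_mask_matrix(mask)
  structure(list(fraction = mean(m == 1L),
                 silver_components = label_components(m == 1L, 8)$n,
                 gap_components = label_components(m == 0L, 4)$n),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "<coverage> silver fraction %.3f; %d silver / %d gap components\n",
    x$fraction, x$silver_components, x$gap_components))
  invisible(x)
}

#' Classify the structural-continuity regime of a substrate
#'
#' Operationalizes the qualitative progression from sparsely dispersed
#' nanoparticles through semi-continuous nanoislands to continuous films:
#' a mask is `"continuous"` when its largest silver component spans both
#' image axes and the gap fraction is below `gap_frac_continuous`;
#' `"discrete"` when no silver component spans either axis and the largest
#' component holds less than `largest_share_discrete` of the silver area;
#' `"semi-continuous"` otherwise.
#'
#' @param cov a [coverage()] result for `mask` (recomputed when `NULL`).
#' @param mask a [binary_mask()].
#' @param gap_frac_continuous gap-fraction threshold for films.
#' @param largest_share_discrete largest-component share threshold below
#'   which unspanning structures count as discrete particles.
#' @return list of class `morph_regime` with `label` and the supporting
#'   metrics.
#' @export
classify_regime <- function(cov = NULL, mask, gap_frac_continuous = 0.05,
                            largest_share_discrete = 0.5) {
  m <- as_mask_matrix(mask)
  if (is.null(cov)) cov <- coverage(mask)
  lab <- label_components(m == 1L, 8)
  if (lab$n == 0L) {
    spans_both <- spans_any <- FALSE
    share <- 0
  } else {
    sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
    big <- which.max(sizes)
    share <- sizes[big] / sum(sizes)
    ij <- which(lab$labels == big, arr.ind = TRUE)
    spans_rows <- min(ij[, 1L]) == 1L && max(ij[, 1L]) == nrow(m)
    spans_cols <- min(ij[, 2L]) == 1L && max(ij[, 2L]) == ncol(m)
    spans_both <- spans_rows && spans_cols
    # does ANY component span either axis?
    spans_any <- FALSE
    for (l in seq_len(lab$n)) {
      ij2 <- which(lab$labels == l, arr.ind = TRUE)
      if ((min(ij2[, 1L]) == 1L && max(ij2[, 1L]) == nrow(m)) ||
          (min(ij2[, 2L]) == 1L && max(ij2[, 2L]) == ncol(m))) {
        spans_any <- TRUE
        break
      }
    }
  }
  gap_frac <- 1 - cov$fraction
  label <- if (spans_both && gap_frac < gap_frac_continuous) "continuous"
  else if (!spans_any && share < largest_share_discrete) "discrete"
  else "semi-continuous"
  structure(list(label = label, coverage = cov$fraction,
                 gap_fraction = gap_frac, spanning = spans_both,
                 largest_component_share = share),
            class = "morph_regime")
}

#' @export
print.morph_regime <- function(x, ...) {
  cat(sprintf(
    "<morph_regime> %s (coverage %.3f, largest-component share %.3f)\n",
    x$label, x$coverage, x$largest_component_share))
  invisible(x)
}

#' Full gap-distance morphometry of one field
#'
#' Runs the whole chain on a grayscale image or a ready mask: Otsu
#' binarization, clean/majority cleanup, gap skeletonization, distance
#' transform, the 2x gap-distance statistic, gamma fit, coverage, and
#' regime classification.  Deterministic: the same image always yields the
#' identical gap-distance sample.
#'
#' @param img a [gray_image()], or `NULL` when `mask` is given.
#' @param mask optionally, a precomputed [binary_mask()] (skips
#'   binarization and cleanup).
#' @param invert passed to [binarize_otsu()].
#' @param units `"px"` or `"nm"` for the gap distances.
#' @param clean apply [morphological_clean()] (default `TRUE`).
#' @return list of class `morphometry_result` with `mask`, `coverage`,
#'   `regime`, `distances`, and `gamma` (`NULL` when the sample is too
#'   small to fit).
#' @export
analyze_gaps <- function(img = NULL, mask = NULL, invert = FALSE,
                         units = c("px", "nm"), clean = TRUE) {
  units <- match.arg(units)
  if (is.null(mask)) {
    if (is.null(img)) stop("provide an image or a mask")
    mask <- binarize_otsu(img, invert = invert)
    if (clean) mask <- morphological_clean(mask)
  }
  cov <- coverage(mask)
  regime <- classify_regime(cov, mask)
  sk <- skeletonize_gaps(mask)
  if (any(as_mask_matrix(mask) == 1L) && any(sk)) {
    dm <- distance_transform(mask)
    d <- gap_distances(sk, dm, units = units)
  } else {
    d <- structure(numeric(0), units = units)
  }
  gam <- if (length(d) >= 10L && var(d) > 0) fit_gamma(d) else NULL
  structure(list(mask = mask, coverage = cov, regime = regime,
                 skeleton = sk, distances = d, gamma = gam),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> %s, coverage %.3f, n(gap) = %d\n",
              x$regime$label, x$coverage$fraction, length(x$distances)))
  if (!is.null(x$gamma)) print(x$gamma)
  invisible(x)
}

#' Pooled gap-distance profiles across labelled conditions
#'
#' Pools per-mask gap-distance samples within each condition label (e.g.
#' precursor concentration), fits a gamma distribution per label, and
#' tabulates normalized histograms for overlay plots.
#'
#' @param masks list of [binary_mask()] objects.
#' @param labels character/factor vector, one label per mask.
#' @param units `"px"` or `"nm"`.
#' @param breaks histogram bin count (passed to [hist()]).
#' @return list of class `gap_profile` with `fits` (named list of
#'   [fit_gamma()] results), `samples` (named list), and `histogram`
#'   (tidy data.frame: label, mid, count, density).
#' @export
gap_profile <- function(masks, labels, units = c("px", "nm"), breaks = 30L) {
  units <- match.arg(units)
  stopifnot(length(masks) == length(labels), length(masks) >= 1L)
  labels <- as.character(labels)
  samples <- list()
  for (i in seq_along(masks)) {
    d <- tryCatch({
      sk <- skeletonize_gaps(masks[[i]])
      dm <- distance_transform(masks[[i]])
      gap_distances(sk, dm, units = units)
    }, error = function(e)
      stop(sprintf("label '%s' (mask %d): %s", labels[i], i,
                   conditionMessage(e)), call. = FALSE))
    samples[[labels[i]]] <- c(samples[[labels[i]]], as.numeric(d))
  }
  fits <- lapply(names(samples), function(l) {
    tryCatch(fit_gamma(structure(samples[[l]], units = units)),
             error = function(e)
               stop(sprintf("label '%s': %s", l, conditionMessage(e)),
                    call. = FALSE))
  })
  names(fits) <- names(samples)
  hist_tab <- do.call(rbind, lapply(names(samples), function(l) {
    h <- graphics::hist(samples[[l]], breaks = breaks, plot = FALSE)
    data.frame(label = l, mid = h$mids, count = h$counts,
               density = h$density)
  }))
  structure(list(fits = fits, samples = samples, histogram = hist_tab,
                 units = units),
            class = "gap_profile")
}
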