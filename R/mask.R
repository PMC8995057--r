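#' Binary silver/gap masks
#'
#' A binary mask encodes the phase classification of an SEM field: silver
#' structures are coded 1 and inter-island gaps 0.  Masks are plain integer
#' matrices (rows = image y, columns = image x) carrying the physical pixel
#' size in nm/px as an attribute, so every downstream statistic can be
#' reported in nanometres.
#'
#' @param x matrix coercible to 0/1 (logical or numeric).
#' @param pixel_size physical pixel size in nm per pixel (positive scalar).
#' @return An integer 0/1 matrix of class `binary_mask` with attribute
#'   `pixel_size`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2), pixel_size = 2)
#' coverage(m)$fraction
#' @export
binary_mask <- function(x, pixel_size = 1) {
  stopifnot(is.matrix(x))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a positive scalar (nm/px)")
  v <- as.integer(round(as.numeric(x)))
  if (!all(v %in% c(0L, 1L))) stop("mask values must be 0 (gap) or 1 (silver)")
  m <- matrix(v, nrow = nrow(x), ncol = ncol(x))
  attr(m, "pixel_size") <- pixel_size
  class(m) <- c("binary_mask", class(m))
  m
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, pixel size %g nm/px, coverage %.3f\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), mean(x == 1L)))
  invisible(x)
}

as_mask_matrix <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}

mask_pixel_size <- function(mask, pixel_size = NULL) {
  ps <- pixel_size %||% attr(mask, "pixel_size") %||% 1
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label connected components of a binary phase
#'
#' Connected-component labelling under the package's digital-topology
#' convention: the silver phase is analysed with 8-connectivity and the gap
#' phase with 4-connectivity (the standard dual pair; see
#' [skeletonize_gaps()]).  4-connectivity labelling is delegated to
#' [EBImage::bwlabel()]; 8-connectivity merges 4-connected labels that touch
#' diagonally, via a union on the label adjacency graph.
#'
#' @param fg logical or 0/1 matrix; `TRUE`/1 marks the phase of interest.
#' @param connectivity 4 or 8.
#' @return list with `n` (component count) and `labels` (integer matrix,
#'   0 = background, 1..n component ids).
#' @export
label_components <- function(fg, connectivity = c(8, 4)) {
  connectivity <- match.arg(as.character(connectivity[1L]), c("8", "4"))
  m <- matrix(as.numeric(fg != 0), nrow(fg), ncol(fg))
  if (!any(m == 1)) return(list(n = 0L, labels = matrix(0L, nrow(m), ncol(m))))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  n4 <- max(lab)
  if (connectivity == "4") return(list(n = n4, labels = lab))
  # merge labels that are diagonal neighbours
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a <- lab[-nr, -nc]; d <- lab[-1, -1]   # NW-SE diagonal
    b <- lab[-nr, -1]; c2 <- lab[-1, -nc]  # NE-SW diagonal
    keep1 <- a > 0L & d > 0L & a != d
    keep2 <- b > 0L & c2 > 0L & b != c2
    pairs <- rbind(cbind(a[keep1], d[keep1]), cbind(b[keep2], c2[keep2]))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(list(n = n4, labels = lab))
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n4 - igraph::vcount(g)))
  comp <- igraph::components(g)
  remap <- comp$membership[seq_len(n4)]
  out <- lab
  out[lab > 0L] <- as.integer(remap[lab[lab > 0L]])
  list(n = as.integer(comp$no), labels = out)
}

#' Euler number of a binary phase
#'
#' Components minus holes, computed from 2x2 quad counts (Gray's formula),
#' under either foreground connectivity.  Used to verify that gap
#' skeletonization preserves the topology of the gap phase.
#'
#' @inheritParams label_components
#' @return integer Euler number.
#' @export
euler_number <- function(fg, connectivity = c(4, 8)) {
  connectivity <- match.arg(as.character(connectivity[1L]), c("4", "8"))
  m <- matrix(as.integer(fg != 0), nrow(fg), ncol(fg))
  P <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  P[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  a <- P[-nrow(P), -ncol(P)]; b <- P[-nrow(P), -1L]
  c2 <- P[-1L, -ncol(P)]; d <- P[-1L, -1L]
  s <- a + b + c2 + d
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a == 1L & d == 1L) | (b == 1L & c2 == 1L)))
  if (connectivity == "4") as.integer((q1 - q3 + 2L * qd) / 4)
  else as.integer((q1 - q3 - 2L * qd) / 4)
}

# 3x3 neighbourhood sum (self excluded), zero padding outside the image.
neighbor_sum8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(0L, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m
  tot <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    tot <- tot + P[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  tot
}
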