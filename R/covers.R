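#' Overlapping interval cover of a real range
#'
#' `n` equal-length closed intervals covering `[lo, hi]`, with consecutive
#' intervals overlapping by a fraction `overlap_g` of their length (the
#' conventional Mapper "percent overlap"). The element length is
#' `(hi - lo) / (1 + (n - 1) (1 - g))` and left endpoints step by
#' `length * (1 - g)`, so the first element starts at `lo` and the last ends
#' at `hi`.
#'
#' Elements are treated as closed: a lens value on an overlap (or shared
#' boundary at `g = 0`) belongs to every covering element, so no node is
#' ever dropped.
#'
#' @param n number of intervals (>= 1).
#' @param overlap_g overlap fraction in `[0, 1)`.
#' @param lo,hi cover range, `lo < hi`.
#' @return an object of class `c("interval_cover", "cover")` with fields
#'   `n`, `overlap_g`, `elements` (n x 2 matrix), `range`.
#' @export
make_interval_cover <- function(n, overlap_g, lo = 0, hi = 1) {
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  if (overlap_g < 0 || overlap_g >= 1) {
    stop("overlap_g must lie in [0, 1): intervals would coincide")
  }
  if (!(lo < hi)) stop("cover range requires lo < hi")
  len <- (hi - lo) / (1 + (n - 1) * (1 - overlap_g))
  left <- lo + (seq_len(n) - 1) * len * (1 - overlap_g)
  elements <- cbind(left, left + len)
  dimnames(elements) <- NULL
  # pin the last endpoint exactly to hi against roundoff
  elements[n, 2] <- hi
  structure(list(n = n, overlap_g = overlap_g, elements = elements,
                 range = c(lo, hi)),
            class = c("interval_cover", "cover"))
}

#' Interval cover from explicit elements
#'
#' Builds an interval cover directly from a matrix of (possibly unbounded)
#' closed intervals. Used for analytic covers such as the two half-lines
#' `(-Inf, eps]`, `[-eps, Inf)` around zero that recover the spectral
#' bipartition from a Fiedler lens. Covers with non-finite endpoints are
#' applied to raw lens values (no rescaling).
#'
#' @param elements k x 2 numeric matrix of interval endpoints (lo, hi).
#' @return an `interval_cover`.
#' @export
interval_cover_from_elements <- function(elements) {
  elements <- matrix(as.numeric(elements), ncol = 2)
  if (any(elements[, 1] > elements[, 2])) stop("interval lo > hi")
  structure(list(n = nrow(elements), overlap_g = NA_real_, elements = elements,
                 range = c(min(elements[, 1]), max(elements[, 2]))),
            class = c("interval_cover", "cover"))
}

#' Overlapping grid cover of a planar bounding box
#'
#' The product of two interval covers: `nx * ny` rectangles in row-major
#' order (y outer, x inner), each axis overlapping by `overlap_g` as in
#' [make_interval_cover()]. A degenerate axis (zero extent) is covered by a
#' single cell, with a warning.
#'
#' @param nx,ny cells per axis.
#' @param overlap_g per-axis overlap fraction in `[0, 1)`.
#' @param bbox 2 x 2 matrix `rbind(xrange, yrange)`.
#' @return an object of class `c("grid_cover", "cover")` with `elements` a
#'   list of `(xlo, xhi, ylo, yhi)` vectors.
#' @export
make_grid_cover <- function(nx, ny, overlap_g, bbox) {
  bbox <- matrix(as.numeric(bbox), nrow = 2, byrow = FALSE)
  axis_cover <- function(n, lo, hi, axis) {
    if (hi <= lo) {
      warning("degenerate bounding box on ", axis,
              " axis; using a single cell")
      return(make_interval_cover(1L, 0, lo, lo + max(1e-12, abs(lo) * 1e-12 + 1e-12)))
    }
    make_interval_cover(n, overlap_g, lo, hi)
  }
  cx <- axis_cover(nx, bbox[1, 1], bbox[1, 2], "x")
  cy <- axis_cover(ny, bbox[2, 1], bbox[2, 2], "y")
  elements <- vector("list", cx$n * cy$n)
  k <- 1L
  for (iy in seq_len(cy$n)) {
    for (ix in seq_len(cx$n)) {
      elements[[k]] <- c(xlo = cx$elements[ix, 1], xhi = cx$elements[ix, 2],
                         ylo = cy$elements[iy, 1], yhi = cy$elements[iy, 2])
      k <- k + 1L
    }
  }
  structure(list(nx = cx$n, ny = cy$n, overlap_g = overlap_g,
                 x_cover = cx, y_cover = cy, elements = elements,
                 bbox = bbox),
            class = c("grid_cover", "cover"))
}

#' RBF-kernel cover of the unit interval
#'
#' `n` radial basis kernels `phi(x, x_i) = exp(-(x - x_i)^2 / delta)` with
#' centers equally spaced on `[0, 1]` (`x_i = (i - 1)/(n - 1)`; a single
#' kernel sits at 0.5). The scale `delta` controls the overlap between cover
#' elements and defaults to `1 / n^2`, so more clusters mean sharper, less
#' overlapping kernels. This soft cover drives the differentiable pooling
#' operator.
#'
#' @param n kernel count (>= 1).
#' @param scale_delta positive kernel scale; default `1 / n^2`.
#' @return an object of class `c("rbf_cover", "cover")` with `centers` and
#'   `scale_delta`.
#' @export
make_rbf_cover <- function(n, scale_delta = NULL) {
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  if (is.null(scale_delta)) scale_delta <- 1 / n^2
  if (scale_delta <= 0) stop("scale_delta must be positive")
  centers <- if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
  structure(list(n = n, centers = centers, scale_delta = scale_delta),
            class = c("rbf_cover", "cover"))
}

#' Evaluate RBF cover kernels
#'
#' @param cover an `rbf_cover`.
#' @param x numeric vector of points in the lens codomain.
#' @return `length(x)` x `n` matrix of kernel values `exp(-(x - x_i)^2 / delta)`.
#' @export
rbf_kernel_values <- function(cover, x) {
  stopifnot(inherits(cover, "rbf_cover"))
  exp(-outer(as.numeric(x), cover$centers, `-`)^2 / cover$scale_delta)
}

# Affine rescale of lens values onto the cover range (per dimension), so that
# the cover is guaranteed to cover all lens values. Skipped when the cover has
# unbounded elements (analytic covers are applied to raw values). A constant
# column maps to the midpoint of the target range.
rescale_lens_to_cover <- function(lens, cover) {
  vals <- lens$values
  if (inherits(cover, "interval_cover")) {
    if (any(!is.finite(cover$elements))) return(vals)
    tgt <- matrix(cover$range, ncol = 1)
  } else if (inherits(cover, "grid_cover")) {
    tgt <- cbind(c(cover$x_cover$range), c(cover$y_cover$range))
  } else {
    stop("hard membership is defined for interval and grid covers only")
  }
  if (ncol(vals) != ncol(tgt)) {
    stop("lens dimension (", ncol(vals), ") does not match cover dimension (",
         ncol(tgt), ")")
  }
  for (j in seq_len(ncol(vals))) {
    r <- range(vals[, j])
    lo <- tgt[1, j]; hi <- tgt[2, j]
    if (r[2] - r[1] <= 0) {
      vals[, j] <- (lo + hi) / 2
    } else {
      vals[, j] <- lo + (vals[, j] - r[1]) / (r[2] - r[1]) * (hi - lo)
    }
  }
  vals
}

#' Hard membership: the pull back sets of a cover
#'
#' Assigns every node to the cover elements whose closed region contains its
#' (rescaled) lens value — the pull back sets `f^-1(U_i)`. Every node belongs
#' to at least one element; nodes on overlaps belong to all covering
#' elements.
#'
#' @param lens a `lens_values`.
#' @param cover an `interval_cover` (d = 1) or `grid_cover` (d = 2).
#' @return list of sorted integer node-id vectors, one per cover element
#'   (empty vectors possible), with attribute `"rescaled_values"`.
#' @export
hard_membership <- function(lens, cover) {
  vals <- rescale_lens_to_cover(lens, cover)
  if (inherits(cover, "interval_cover")) {
    x <- vals[, 1]
    sets <- lapply(seq_len(cover$n), function(i) {
      which(x >= cover$elements[i, 1] & x <= cover$elements[i, 2])
    })
  } else {
    x <- vals[, 1]; y <- vals[, 2]
    sets <- lapply(cover$elements, function(el) {
      which(x >= el["xlo"] & x <= el["xhi"] & y >= el["ylo"] & y <= el["yhi"])
    })
  }
  covered <- sort(unique(unlist(sets)))
  if (length(covered) < nrow(vals)) {
    stop("internal error: cover failed to cover all lens values")
  }
  attr(sets, "rescaled_values") <- vals
  sets
}
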