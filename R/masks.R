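# Low-level binary-mask utilities shared by all stages.
#
# A mask is a plain logical matrix indexed [row, col] with row 1 at the top
# of the image, matching the layout returned by png::readPNG().  Foreground
# connectivity is 8-neighbor throughout unless stated otherwise.

#' Coerce to a binary mask
#'
#' Accepts a logical/numeric matrix or an `EBImage::Image` and returns a
#' logical matrix.  Numeric input on the 8-bit scale uses the > 127
#' foreground threshold; input on the unit scale uses > 0.5.
#'
#' @param x matrix or `Image`.
#' @return logical matrix `[row, col]`.
#' @export
as_mask <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1L]
  if (!is.matrix(x)) stop("mask input must be a matrix or Image")
  if (is.logical(x)) return(x)
  thr <- if (max(x, na.rm = TRUE) > 1) 127 else 0.5
  x > thr
}

#' @keywords internal
mask_area <- function(mask) sum(mask)

#' Bounding box of foreground pixels
#'
#' @param mask logical matrix.
#' @return integer vector `c(row_min, row_max, col_min, col_max)`, or `NULL`
#'   for an empty mask.
#' @keywords internal
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  c(min(w[, 1L]), max(w[, 1L]), min(w[, 2L]), max(w[, 2L]))
}

#' @keywords internal
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("row", "col")
  w
}

#' Disc-shaped structuring element of a given radius
#' @keywords internal
disc_brush <- function(radius) {
  size <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

#' Morphological dilation/erosion with a disc
#'
#' Thin wrappers around [EBImage::dilate()]/[EBImage::erode()] keeping the
#' logical-matrix mask convention.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels; `0` returns the input.
#' @return logical matrix.
#' @export
mask_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  as_mask(EBImage::dilate(EBImage::Image(mask * 1), disc_brush(radius)))
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  as_mask(EBImage::erode(EBImage::Image(mask * 1), disc_brush(radius)))
}

#' Label connected components
#'
#' 4-connected labelling via [EBImage::bwlabel()] followed by an equivalence
#' merge across the two diagonal offsets, which yields 8-connected labels.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer matrix of labels (0 = background), with labels compacted
#'   to `1..n`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  if (connectivity == 4L || max(lab) <= 1L) return(compact_labels(lab))
  nmax <- max(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs: (dr, dc) in {(1,1), (1,-1)} suffice by symmetry
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    r0 <- if (off[2L] == 1L) seq_len(nc - 1L) else 2L:nc
    a <- lab[seq_len(nr - 1L), r0, drop = FALSE]
    b <- lab[2L:nr, r0 + off[2L], drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  compact_labels(lab)
}

#' @keywords internal
compact_labels <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Pad a matrix (or H x W x 3 array) with a constant border
#' @keywords internal
pad_canvas <- function(x, pad, value = 0) {
  pad <- as.integer(pad)
  if (pad <= 0L) return(x)
  if (length(dim(x)) == 3L) {
    out <- array(value, dim(x) + c(2L * pad, 2L * pad, 0L))
    out[pad + seq_len(dim(x)[1L]), pad + seq_len(dim(x)[2L]), ] <- x
  } else {
    out <- matrix(value, nrow(x) + 2L * pad, ncol(x) + 2L * pad)
    out[pad + seq_len(nrow(x)), pad + seq_len(ncol(x))] <- x
  }
  out
}

#' Rotate a mask or RGB array about its center
#'
#' The output canvas is enlarged so no foreground is clipped.  `angle`
#' follows the convention that the petiole-to-apex vector with image angle
#' `atan2(dy, dx)` becomes vertical ("up", decreasing row) after rotating by
#' `atan2(dy, dx) * 180/pi + 90` degrees.
#'
#' @param x logical matrix (mask) or numeric H x W x 3 array (image).
#' @param angle degrees.
#' @param filter `"none"` (nearest neighbor, for masks) or `"bilinear"`.
#' @param bg background fill value.
#' @return same type as `x`.
#' @export
rotate_canvas <- function(x, angle, filter = c("none", "bilinear"), bg = 0) {
  filter <- match.arg(filter)
  angle <- angle %% 360
  if (angle == 0) return(x)
  ismask <- is.logical(x)
  img <- EBImage::Image(if (ismask) x * 1 else x,
                        colormode = if (length(dim(x)) == 3L) "Color" else "Grayscale")
  out <- EBImage::rotate(img, angle, filter = filter, bg.col = bg)
  out <- EBImage::imageData(out)
  if (ismask) out > 0.5 else out
}

#' Uniformly rescale a mask or RGB array
#'
#' @param x logical matrix or H x W x 3 array.
#' @param factor multiplicative size factor (> 0).
#' @param filter `"none"` for masks, `"bilinear"` for images.
#' @return same type as `x`.
#' @export
resize_canvas <- function(x, factor, filter = c("none", "bilinear")) {
  filter <- match.arg(filter)
  stopifnot(factor > 0)
  if (factor == 1) return(x)
  ismask <- is.logical(x)
  d <- dim(x)
  new1 <- max(1L, round(d[1L] * factor))
  new2 <- max(1L, round(d[2L] * factor))
  img <- EBImage::Image(if (ismask) x * 1 else x,
                        colormode = if (length(d) == 3L) "Color" else "Grayscale")
  out <- EBImage::imageData(EBImage::resize(img, w = new1, h = new2, filter = filter))
  if (ismask) out > 0.5 else out
}

#' Mirror about the vertical axis (reverse columns)
#' @keywords internal
mirror_horizontal <- function(x) {
  if (length(dim(x)) == 3L) x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
  else x[, rev(seq_len(ncol(x))), drop = FALSE]
}

#' Trace the outer boundary of one connected foreground region
#'
#' Moore-neighbor tracing with Jacob's stopping criterion; returns the
#' closed boundary as ordered pixel coordinates.  Used for contour
#' perimeters and as input to Douglas-Peucker simplification.
#'
#' @param mask logical matrix containing a single 8-connected region.
#' @return integer matrix with columns `row`, `col` (closed path; first
#'   vertex not repeated).
#' @export
trace_boundary <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask")
  # start at the topmost of the leftmost foreground pixels
  start <- w[order(w[, 2L], w[, 1L])[1L], ]
  if (nrow(w) == 1L) return(matrix(start, 1L, 2L, dimnames = list(NULL, c("row", "col"))))
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  # clockwise Moore neighborhood starting west
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  path <- matrix(0L, 4L * nrow(w) + 8L, 2L)
  path[1L, ] <- start
  np <- 1L
  cur <- start
  back <- 1L       # scan start: one past the backtrack direction (west initially)
  limit <- 8L * nrow(w) + 8L
  steps <- 0L
  repeat {
    found <- FALSE
    for (k in seq_len(8L)) {
      idx <- ((back - 1L + k - 1L) %% 8L) + 1L
      cand <- cur + nb[idx, ]
      if (fg(cand[1L], cand[2L])) {
        # moved in direction idx: the new pixel's backtrack points to the
        # previous pixel at (idx + 4); resume scanning one step past it
        back <- ((idx + 4L) %% 8L) + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cur[1L] == start[1L] && cur[2L] == start[2L]) break
    steps <- steps + 1L
    if (steps > limit) {
      warning("boundary tracing exceeded its step limit; contour truncated")
      break
    }
    np <- np + 1L
    if (np > nrow(path)) path <- rbind(path, matrix(0L, nrow(path), 2L))
    path[np, ] <- cur
  }
  out <- path[seq_len(np), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Arc length of an ordered pixel path
#'
#' Sum of inter-vertex steps; axial steps count 1, diagonal steps
#' `sqrt(2)`.
#'
#' @param path two-column matrix of `row`, `col` coordinates.
#' @param closed add the closing step from last back to first vertex.
#' @return numeric length in pixels.
#' @export
path_length <- function(path, closed = FALSE) {
  if (nrow(path) < 2L) return(0)
  d <- sqrt(rowSums((path[-1L, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
  tot <- sum(d)
  if (closed) tot <- tot + sqrt(sum((path[1L, ] - path[nrow(path), ])^2))
  tot
}

#' Convex hull area of the foreground pixels
#'
#' Shoelace area of the convex hull of pixel centers, corrected to the
#' pixel-count scale by Pick's theorem (`+ perimeter/2 + 1`) so that the
#' hull area of a solid convex region equals its pixel count.
#'
#' @param mask logical matrix.
#' @return numeric area in px^2 (the pixel count for fewer than 3 pixels).
#' @export
hull_area <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 3L) return(nrow(w))
  h <- grDevices::chull(w[, 2L], w[, 1L])
  x <- w[h, 2L]; y <- w[h, 1L]
  shoelace <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
  shoelace + per / 2 + 1
}

#' @keywords internal
pairwise_min_dist <- function(a, b, chunk = 2000L) {
  # for each row of a (n x 2), distance to the nearest row of b, chunked to
  # bound memory
  n <- nrow(a)
  out <- numeric(n)
  idx <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(a[s:e, 1L], b[, 1L], "-")^2 + outer(a[s:e, 2L], b[, 2L], "-")^2
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    out[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
  }
  list(dist = out, index = idx)
}
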