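# Leaf normalization into the "size-free" space: rotate the leaf upright
# (petiole down, apex up) using the petiole->apex centroid line of the
# mid-rib, then scale uniformly so the blade width equals a fixed number of
# pixels (500 by default).  The scaling factor -- original blade width over
# normalized width -- is itself a size trait.

#' Minimum-area oriented bounding box of a mask
#'
#' Rotating-calipers construction over the convex hull: the minimum-area
#' enclosing rectangle has a side collinear with a hull edge, so each hull
#' edge orientation is tried and the smallest-area rectangle kept.
#'
#' @param mask non-empty logical matrix.
#' @return list with `center` (`c(row, col)`), `dir` (unit vector
#'   `c(drow, dcol)` along the long axis), `half_extents`
#'   (`c(long, short)`, in px, using the max-min+1 pixel convention).
#' @export
min_area_obb <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask")
  y <- w[, 1L]; x <- w[, 2L]
  if (nrow(w) == 1L)
    return(list(center = c(y[1L], x[1L]), dir = c(1, 0), half_extents = c(0.5, 0.5)))
  hidx <- grDevices::chull(x, y)
  hx <- x[hidx]; hy <- y[hidx]
  nh <- length(hidx)
  if (nh < 2L) return(list(center = c(mean(y), mean(x)), dir = c(1, 0),
                           half_extents = c(0.5, 0.5)))
  best <- NULL
  edges <- cbind(c(hx[-1L], hx[1L]) - hx, c(hy[-1L], hy[1L]) - hy)
  lens <- sqrt(rowSums(edges^2))
  edges <- edges[lens > 0, , drop = FALSE] / lens[lens > 0]
  if (nrow(edges) == 0L) edges <- matrix(c(1, 0), 1L)
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]                          # (dx, dy) unit
    n <- c(-e[2L], e[1L])
    pe <- hx * e[1L] + hy * e[2L]
    pn <- hx * n[1L] + hy * n[2L]
    ext1 <- max(pe) - min(pe) + 1
    ext2 <- max(pn) - min(pn) + 1
    area <- ext1 * ext2
    if (is.null(best) || area < best$area) {
      cen_e <- (max(pe) + min(pe)) / 2
      cen_n <- (max(pn) + min(pn)) / 2
      cx <- cen_e * e[1L] + cen_n * n[1L]
      cy <- cen_e * e[2L] + cen_n * n[2L]
      if (ext1 >= ext2) {
        best <- list(area = area, center = c(cy, cx),
                     dir = c(e[2L], e[1L]), half_extents = c(ext1, ext2) / 2)
      } else {
        best <- list(area = area, center = c(cy, cx),
                     dir = c(n[2L], n[1L]), half_extents = c(ext2, ext1) / 2)
      }
    }
  }
  best$area <- NULL
  best
}

#' Locate the petiole and apex ends of the mid-rib
#'
#' The mid-rib bounding box is cut across its long axis at the midline; the
#' half carrying the larger mid-rib pixel count is the petiole half (its
#' stroke is markedly wider), and the two halves' mid-rib centroids give the
#' petiole and apex reference points.  Exactly equal counts fall back to the
#' half whose centroid sits lower in the image (larger row), with a warning.
#'
#' @param MR non-empty logical matrix.
#' @param box optional [min_area_obb()] of `MR` (computed if missing).
#' @return list with `petiole` and `apex` centroids (`c(row, col)` each).
#' @export
locate_petiole_apex <- function(MR, box = NULL) {
  w <- which(MR, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mid-rib mask")
  if (is.null(box)) box <- min_area_obb(MR)
  proj <- (w[, 1L] - box$center[1L]) * box$dir[1L] +
          (w[, 2L] - box$center[2L]) * box$dir[2L]
  a <- proj < 0
  na <- sum(a); nb <- nrow(w) - na
  centroid <- function(sel) c(mean(w[sel, 1L]), mean(w[sel, 2L]))
  if (na == 0L || nb == 0L) {
    # degenerate: all pixels in one half; farthest pixel stands in as apex
    pet <- centroid(rep(TRUE, nrow(w)))
    d <- (w[, 1L] - pet[1L])^2 + (w[, 2L] - pet[2L])^2
    return(list(petiole = pet, apex = w[which.max(d), ]))
  }
  if (na == nb) {
    warning("mid-rib halves have equal pixel counts; taking the lower half as petiole")
    pet_is_a <- centroid(a)[1L] >= centroid(!a)[1L]
  } else pet_is_a <- na > nb
  list(petiole = centroid(if (pet_is_a) a else !a),
       apex = centroid(if (pet_is_a) !a else a))
}

#' Normalize a leaf into the fixed-width upright space
#'
#' Rotates the sample so the petiole->apex centroid line points from bottom
#' to top, rescales it uniformly so the blade's horizontal extent equals
#' `width` pixels (masks nearest-neighbor, image bilinear), and crops to the
#' blade bounding box plus a 10 px margin.
#'
#' @param sample a `leaf_sample` with non-empty `BD` and `MR`.
#' @param width target blade width in px (default 500).
#' @return object of class `leaf_normalization`: elements `sample`
#'   (normalized `leaf_sample`), `scaling_factor` (pre-scale blade width /
#'   `width`), `rotation_applied` (degrees), `flipped`, `normalized_width`.
#' @export
normalize_leaf <- function(sample, width = 500L) {
  stopifnot(inherits(sample, "leaf_sample"), width > 0)
  MR <- sample$components$masks$MR
  BD <- sample$components$masks$BD
  if (!any(MR) || !any(BD)) stop("normalization requires non-empty BD and MR masks")
  ends <- locate_petiole_apex(MR)
  vx <- ends$apex[2L] - ends$petiole[2L]
  vy <- ends$apex[1L] - ends$petiole[1L]
  angle <- (atan2(vy, vx) * 180 / pi + 90) %% 360
  rotated <- apply_rigid_transform(sample, angle = angle, scale = 1, flip = FALSE)
  bb <- mask_bbox(rotated$components$masks$BD)
  w0 <- bb[4L] - bb[3L] + 1
  sf <- w0 / width
  scaled <- apply_rigid_transform(rotated, angle = 0, scale = 1 / sf, flip = FALSE)
  scaled <- crop_to_blade(scaled, margin = 10L)
  structure(list(sample = scaled, scaling_factor = sf,
                 rotation_applied = angle, flipped = FALSE,
                 normalized_width = as.integer(width)),
            class = "leaf_normalization")
}

#' @export
print.leaf_normalization <- function(x, ...) {
  cat(sprintf("<leaf_normalization> %s: rotation %.1f deg, scaling factor %.3f%s\n",
              x$sample$id, x$rotation_applied, x$scaling_factor,
              if (x$flipped) ", flipped" else ""))
  invisible(x)
}

#' @keywords internal
crop_to_blade <- function(sample, margin = 10L) {
  bb <- mask_bbox(sample$components$masks$BD)
  d <- dim(sample$image)
  r <- max(1L, bb[1L] - margin):min(d[1L], bb[2L] + margin)
  c <- max(1L, bb[3L] - margin):min(d[2L], bb[4L] + margin)
  masks <- lapply(sample$components$masks, function(m) m[r, c, drop = FALSE])
  img <- sample$image[r, c, , drop = FALSE]
  leaf_sample(sample$id, img, component_set(masks, sample$components$provenance),
              sample$orientation, sample$scale_mm_per_px)
}

#' Mirror back-side leaves into the shared handedness
#'
#' Adaxial ("positive") and abaxial ("back") photographs of the same leaf
#' are mirror images; after normalization the back leaf is flipped about
#' the vertical axis so both orientations share handedness.
#'
#' @param result a [normalize_leaf()] result.
#' @param orientation `"positive"` or `"back"`; defaults to the sample's own.
#' @param policy set `"never"` to disable flipping.
#' @return the (possibly mirrored) `leaf_normalization`.
#' @export
flip_to_canonical <- function(result, orientation = NULL,
                              policy = c("back", "never")) {
  policy <- match.arg(policy)
  stopifnot(inherits(result, "leaf_normalization"))
  if (is.null(orientation)) orientation <- result$sample$orientation
  if (policy == "never" || orientation != "back") return(result)
  s <- result$sample
  masks <- lapply(s$components$masks, mirror_horizontal)
  img <- mirror_horizontal(s$image)
  result$sample <- leaf_sample(s$id, img,
                               component_set(masks, s$components$provenance),
                               s$orientation, s$scale_mm_per_px)
  result$flipped <- !result$flipped
  result
}
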