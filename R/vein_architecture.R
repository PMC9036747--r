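# Lamina-based reconstruction of the petiole and second-order vein
# architecture.  Works in the normalized (upright, fixed-width) space:
# laminas adjacent to the dilated mid-rib are the first-order laminas;
# each lamina contour is simplified to a polygon (Douglas-Peucker), the
# polygon vertex closest to the mid-rib -- ties resolved toward the leaf
# base -- is the vein attachment point, and the interior angle between its
# two incident polygon edges is the vein angle.  The smallest attachment
# arc position splits the mid-rib into petiole and first-order vein.

#' Determine the petiole from the lamina closest to the leaf base
#'
#' The mid-rib is dilated by a disc of radius `r`; laminas overlapping the
#' dilation are adjacent.  Each adjacent lamina projects to the arc
#' position of its nearest mid-rib-axis pixel, and the smallest arc
#' position `s*` splits the mid-rib: petiole pixels lie at arc < `s*`,
#' `PE_L = s*`, `AP_L = MR_L - s*`.
#'
#' @param MR mid-rib mask.
#' @param LM lamina mask.
#' @param axis optional [midrib_axis()] of `MR`.
#' @param r adjacency dilation radius, px (default 5).
#' @param min_area laminas smaller than this many px^2 are ignored.
#' @return list `petiole` (mask), `PE_L`, `AP_L`, `MR_L`, `axis`,
#'   `petiole_area`; with no adjacent lamina `PE_L` is `NA` and the whole
#'   mid-rib is reported as first-order vein (with a warning).
#' @export
determine_petiole <- function(MR, LM, axis = NULL, r = 5L, min_area = 25) {
  if (is.null(axis)) axis <- midrib_axis(MR)
  adj <- mask_dilate(MR, r)
  lab <- label_components(LM, 8L)
  n <- max(lab)
  s_star <- Inf
  for (i in seq_len(n)) {
    w <- which(lab == i, arr.ind = TRUE)
    if (nrow(w) < min_area) next
    if (!any(adj[w])) next
    # the minimum distance to the axis is attained on the boundary
    bd <- trace_boundary(lab == i)
    ap <- arc_position(axis, bd)
    near <- ap$dist <= min(ap$dist) + 1
    s_star <- min(s_star, min(ap$arc[near]))
  }
  if (!is.finite(s_star)) {
    warning("no lamina adjacent to the mid-rib; petiole undefined, whole mid-rib taken as first-order vein")
    return(list(petiole = MR & FALSE, PE_L = NA_real_, AP_L = axis$length,
                MR_L = axis$length, axis = axis, petiole_area = 0))
  }
  mr_px <- mask_coords(MR)
  ap <- arc_position(axis, mr_px)
  pet <- MR & FALSE
  pet[mr_px[ap$arc < s_star, , drop = FALSE]] <- TRUE
  list(petiole = pet, PE_L = s_star, AP_L = axis$length - s_star,
       MR_L = axis$length, axis = axis, petiole_area = sum(pet))
}

#' Extract first-order laminas (those adjacent to the mid-rib)
#'
#' @param LM lamina mask.
#' @param MR mid-rib mask.
#' @param r adjacency dilation radius, px.
#' @param min_area drop laminas below this area, px^2 (small fragments are
#'   the dominant source of count errors).
#' @return list of lamina records: `label`, `area`, `contour` (closed
#'   boundary path), `mask_idx` (pixel coordinates); unordered.
#' @export
extract_first_order_laminas <- function(LM, MR, r = 5L, min_area = 25) {
  adj <- mask_dilate(MR, r)
  lab <- label_components(LM, 8L)
  out <- list()
  for (i in seq_len(max(lab))) {
    w <- which(lab == i, arr.ind = TRUE)
    if (nrow(w) < min_area) next
    if (!any(adj[w])) next
    m <- lab == i
    out[[length(out) + 1L]] <- list(label = i, area = nrow(w),
                                    contour = trace_boundary(m),
                                    mask_idx = w)
  }
  out
}

#' Douglas-Peucker polygon simplification
#'
#' Recursive split at the point of maximum perpendicular deviation until
#' every deviation is within `tolerance`.  For a closed contour the chain
#' is anchored at the two mutually farthest contour points, so the result
#' is a closed polygon whose vertices are a subset of the input points.
#'
#' @param contour n x 2 matrix of ordered boundary coordinates.
#' @param tolerance maximal allowed perpendicular deviation, px (default 5,
#'   appropriate for leaves in the normalized space).
#' @param closed treat the contour as a closed ring (default).
#' @return m x 2 matrix of retained vertices (subset of `contour`, original
#'   order), with attribute `index` giving their positions in the input.
#' @export
simplify_polygon <- function(contour, tolerance = 5, closed = TRUE) {
  contour <- matrix(as.numeric(contour), ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  n <- nrow(contour)
  if (n < 3L) stop("contour must have at least 3 points")
  keep <- logical(n)
  dp <- function(i, j) {
    # mark retained vertices between anchors i < j (indices kept)
    if (j <= i + 1L) return(invisible())
    a <- contour[i, ]; b <- contour[j, ]
    seg <- b - a
    len <- sqrt(sum(seg^2))
    ids <- (i + 1L):(j - 1L)
    if (len == 0) {
      d <- sqrt(rowSums((contour[ids, , drop = FALSE] -
                           matrix(a, length(ids), 2L, byrow = TRUE))^2))
    } else {
      d <- abs(seg[2L] * (contour[ids, 1L] - a[1L]) -
                 seg[1L] * (contour[ids, 2L] - a[2L])) / len
    }
    k <- which.max(d)
    if (d[k] > tolerance) {
      m <- ids[k]
      keep[m] <<- TRUE
      dp(i, m); dp(m, j)
    }
    invisible()
  }
  if (closed) {
    # anchor 1: first point; anchor 2: the point farthest from it
    d0 <- rowSums((contour - matrix(contour[1L, ], n, 2L, byrow = TRUE))^2)
    a2 <- which.max(d0)
    keep[1L] <- TRUE; keep[a2] <- TRUE
    dp(1L, a2)
    # second chain wraps around: rotate so it is contiguous
    idx2 <- c(a2:n, 1L)
    sub <- contour[idx2, , drop = FALSE]
    keep2 <- logical(length(idx2))
    dp2 <- function(i, j, pts, mark) {
      if (j <= i + 1L) return(mark)
      a <- pts[i, ]; b <- pts[j, ]
      seg <- b - a; len <- sqrt(sum(seg^2))
      ids <- (i + 1L):(j - 1L)
      if (len == 0) d <- sqrt(rowSums((pts[ids, , drop = FALSE] -
                                         matrix(a, length(ids), 2L, byrow = TRUE))^2))
      else d <- abs(seg[2L] * (pts[ids, 1L] - a[1L]) -
                      seg[1L] * (pts[ids, 2L] - a[2L])) / len
      k <- which.max(d)
      if (d[k] > tolerance) {
        m <- ids[k]
        mark[m] <- TRUE
        mark <- dp2(i, m, pts, mark)
        mark <- dp2(m, j, pts, mark)
      }
      mark
    }
    keep2 <- dp2(1L, length(idx2), sub, keep2)
    keep[idx2[keep2]] <- TRUE
  } else {
    keep[1L] <- TRUE; keep[n] <- TRUE
    dp(1L, n)
  }
  out <- contour[keep, , drop = FALSE]
  attr(out, "index") <- which(keep)
  out
}

#' Select the vein attachment point on a simplified lamina polygon
#'
#' Lexicographic rule: minimize the distance to the mid-rib axis; among
#' vertices tied within `tie` px, minimize the distance to the leaf base.
#' Simplified-polygon vertices along the lamina's inner edge deviate from
#' the axis-offset curve by up to the simplification tolerance (plus the
#' bow of the mid-rib across the lamina's span), so the tie window must be
#' at least that wide or a mid-edge vertex shadows the true basal corner.
#'
#' @param polygon m x 2 vertex matrix ([simplify_polygon()] output).
#' @param axis a [midrib_axis()].
#' @param base `c(row, col)`; defaults to the axis base.
#' @param tie tie tolerance in px (default 6: the polygon simplification
#'   tolerance plus 1 px quantization).
#' @return the selected vertex `c(row, col)` with attribute `index` (row in
#'   `polygon`).
#' @export
find_attachment_point <- function(polygon, axis, base = axis$base, tie = 6) {
  stopifnot(nrow(polygon) >= 1L)
  nn <- pairwise_min_dist(matrix(polygon, ncol = 2L), axis$path)
  dmin <- min(nn$dist)
  cand <- which(nn$dist <= dmin + tie)
  db <- sqrt((polygon[cand, 1L] - base[1L])^2 + (polygon[cand, 2L] - base[2L])^2)
  sel <- cand[which.min(db)]
  out <- polygon[sel, ]
  attr(out, "index") <- sel
  out
}

#' Vein angle at an attachment vertex
#'
#' Interior angle, in degrees within (0, 180], between the two polygon
#' edges incident to the attachment vertex.  Zero-length edges are skipped
#' by advancing to the next distinct vertex; with `min_edge > 0`, vertices
#' closer than `min_edge` px are skipped as well, so short chamfer edges
#' left by rounded lamina corners do not masquerade as vein edges.
#'
#' @param polygon m x 2 closed-polygon vertex matrix (m >= 3).
#' @param attachment_index row index of the attachment vertex.
#' @param min_edge minimal incident-edge length in px (default 0: any
#'   distinct vertex).
#' @return angle in degrees.
#' @export
compute_vein_angle <- function(polygon, attachment_index, min_edge = 0) {
  m <- nrow(polygon)
  stopifnot(m >= 3L, attachment_index >= 1L, attachment_index <= m)
  a <- polygon[attachment_index, ]
  next_distinct <- function(step, minlen) {
    i <- attachment_index
    best <- NULL; bestlen <- 0
    for (k in seq_len(m - 1L)) {
      i <- ((i - 1L + step) %% m) + 1L
      v <- polygon[i, ] - a
      len <- sqrt(sum(v^2))
      if (len == 0) next
      if (len >= minlen) return(v)
      if (len > bestlen) { best <- v; bestlen <- len }
    }
    if (is.null(best)) stop("degenerate polygon: all vertices coincide")
    best
  }
  v1 <- next_distinct(-1L, min_edge)
  v2 <- next_distinct(+1L, min_edge)
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (ang <= 0) 180 else ang
}

#' Assemble the vein architecture of one leaf
#'
#' Runs the lamina-based algorithm end to end on normalized masks:
#' mid-rib axis, petiole split, first-order lamina extraction, polygon
#' simplification, attachment points, vein angles, left/right assignment
#' (by lamina centroid against the extended mid-rib axis) and ordering by
#' arc position from the base.
#'
#' @param MR,LM,VS component masks of the normalized leaf.
#' @param r adjacency dilation radius, px.
#' @param tolerance Douglas-Peucker tolerance, px.
#' @param min_area minimal lamina area, px^2.
#' @return object of class `vein_architecture`: `laminas` (data frame with
#'   side, order, area, attachment, arc position, vein angle), `records`
#'   (full per-lamina list incl. contours and polygons), petiole fields
#'   (`PE_L`, `AP_L`, `MR_L`, `BD_PE_PX`, `petiole` mask), angle lists and
#'   summaries (`LM_ANG_List_LT/RT`, `LM_Ave_ANG[_LT/_RT]`), counts
#'   (`LM_N[_LT/_RT]`), and the `axis`.
#' @export
assemble_architecture <- function(MR, LM, VS = NULL, r = 5L, tolerance = 5,
                                  min_area = 25) {
  axis <- midrib_axis(MR)
  pet <- determine_petiole(MR, LM, axis = axis, r = r, min_area = min_area)
  recs <- extract_first_order_laminas(LM, MR, r = r, min_area = min_area)
  split <- split_left_right(LM, axis)
  lam <- NULL
  for (rec in recs) {
    poly <- simplify_polygon(rec$contour, tolerance = tolerance)
    att <- find_attachment_point(poly, axis, tie = tolerance + 1)
    ang <- compute_vein_angle(poly, attr(att, "index"), min_edge = 2 * tolerance)
    ap <- arc_position(axis, matrix(att, 1L))
    cen <- colMeans(rec$mask_idx)
    side <- if (cen[2L] < split$divider_col[round(cen[1L])]) "left" else "right"
    rec$polygon <- poly; rec$attachment <- att; rec$vein_angle <- ang
    rec$arc_position <- ap$arc[1L]; rec$side <- side
    lam <- rbind(lam, data.frame(label = rec$label, side = side,
                                 area = rec$area,
                                 att_row = att[1L], att_col = att[2L],
                                 arc = ap$arc[1L], angle = ang,
                                 stringsAsFactors = FALSE))
    recs[[match(rec$label, vapply(recs, `[[`, 0L, "label"))]] <- rec
  }
  if (!is.null(lam)) {
    lam <- lam[order(lam$side, lam$arc), , drop = FALSE]
    lam$order <- stats::ave(lam$arc, lam$side, FUN = seq_along)
    rownames(lam) <- NULL
  } else {
    lam <- data.frame(label = integer(0), side = character(0), area = numeric(0),
                      att_row = numeric(0), att_col = numeric(0),
                      arc = numeric(0), angle = numeric(0), order = numeric(0))
  }
  ang_lt <- lam$angle[lam$side == "left"][order(lam$arc[lam$side == "left"])]
  ang_rt <- lam$angle[lam$side == "right"][order(lam$arc[lam$side == "right"])]
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  structure(list(
    laminas = lam, records = recs,
    petiole = pet$petiole, PE_L = pet$PE_L, AP_L = pet$AP_L, MR_L = pet$MR_L,
    BD_PE_PX = pet$petiole_area,
    LM_ANG_List_LT = ang_lt, LM_ANG_List_RT = ang_rt,
    LM_Ave_ANG = mean_or_na(lam$angle),
    LM_Ave_ANG_LT = mean_or_na(ang_lt), LM_Ave_ANG_RT = mean_or_na(ang_rt),
    LM_ANG_Std_LT = if (length(ang_lt) > 1L) stats::sd(ang_lt) else NA_real_,
    LM_ANG_Std_RT = if (length(ang_rt) > 1L) stats::sd(ang_rt) else NA_real_,
    LM_N = nrow(lam), LM_N_LT = length(ang_lt), LM_N_RT = length(ang_rt),
    axis = axis), class = "vein_architecture")
}

#' @export
print.vein_architecture <- function(x, ...) {
  cat(sprintf("<vein_architecture> %d laminas (%d left, %d right), PE_L %.1f, MR_L %.1f, mean angle %.1f deg\n",
              x$LM_N, x$LM_N_LT, x$LM_N_RT, x$PE_L, x$MR_L, x$LM_Ave_ANG))
  invisible(x)
}

#' Reconstruct the mid-rib from laminas and veins (validation)
#'
#' Left and right laminas plus their veins are morphologically closed into
#' solid side objects, and the mid-rib estimate is the blade band caught
#' between their inner edges.  The per-row inner bounds are filtered with
#' a running median (a vein stroke crossing near the axis perturbs only a
#' few consecutive rows), interpolated across rows without laminas (the
#' petiole and the apex tip), and pulled in by `clearance` -- laminas
#' stand off the mid-rib stroke by about the adjacency clearance.  Used to
#' validate the lamina representation against the segmented mid-rib
#' (IoU), not as a production path.
#'
#' @param arch a [assemble_architecture()] result.
#' @param VS vein mask.
#' @param BD blade mask.
#' @param close_radius closing radius for the side objects, px.
#' @param clearance inward shift of each inner bound, px (default 2).
#' @return logical matrix: the reconstructed mid-rib `MR_by_LM`.
#' @export
reconstruct_midrib_from_laminas <- function(arch, VS, BD, close_radius = 9L,
                                            clearance = 2L) {
  H <- nrow(BD); W <- ncol(BD)
  side_mask <- function(side) {
    m <- matrix(FALSE, H, W)
    for (rec in arch$records) if (identical(rec$side, side)) m[rec$mask_idx] <- TRUE
    m
  }
  div <- split_left_right(BD, arch$axis)$divider_col
  colmat <- matrix(rep(seq_len(W), each = H), H, W)
  L <- side_mask("left") | (VS & colmat < div)
  R <- side_mask("right") | (VS & colmat > div)
  if (!any(L) || !any(R)) stop("mid-rib reconstruction needs laminas on both sides")
  close_m <- function(m) mask_erode(mask_dilate(m, close_radius), close_radius)
  Lc <- close_m(L); Rc <- close_m(R)
  lo <- hi <- rep(NA_real_, H)
  for (rr in seq_len(H)) {
    lc <- which(Lc[rr, ]); rc <- which(Rc[rr, ])
    lc <- lc[lc < div[rr]]; rc <- rc[rc > div[rr]]
    if (length(lc)) lo[rr] <- max(lc)
    if (length(rc)) hi[rr] <- min(rc)
  }
  ok <- which(!is.na(lo) & !is.na(hi))
  if (length(ok) < 5L) stop("too few rows with laminas on both sides")
  # work in half-widths about the divider so the interpolated band follows
  # the bow of the axis through the petiole and the apex tip
  med <- function(x) if (length(x) >= 21L) stats::runmed(x, 21L) else x
  wl <- stats::approx(ok, med(div[ok] - lo[ok]), xout = seq_len(H), rule = 2)$y
  wr <- stats::approx(ok, med(hi[ok] - div[ok]), xout = seq_len(H), rule = 2)$y
  lo_f <- div - wl + clearance
  hi_f <- div + wr - clearance
  band <- colmat > lo_f & colmat < hi_f
  BD & band
}
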