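# Skeletonization and skeleton-graph analysis.
#
# Thinning uses the Zhang-Suen parallel algorithm: it preserves topology,
# yields 1-px-wide 8-connected skeletons and leaves already-thin strokes
# untouched.  Skeleton pixels form a weighted graph (axial steps 1,
# diagonal steps sqrt(2)); endpoints have one skeleton neighbor, branch
# points three or more.

#' @keywords internal
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Topology-preserving thinning (Zhang-Suen)
#'
#' Parallel two-subiteration Zhang-Suen thinning followed by a sequential
#' simple-point cleanup (removal of non-endpoint pixels whose foreground
#' neighbors form a single 8-connected component), which eliminates the
#' 2-px staircase "dominoes" the parallel passes leave behind and yields
#' a strictly unit-width, 8-connected skeleton.  Implemented in C++.
#'
#' @param mask logical matrix.
#' @return logical matrix: the 1-px skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_thin(as_mask(mask))
}

#' Skeletonize a component and analyze the skeleton graph
#'
#' @param mask non-empty logical matrix.
#' @param thin set `FALSE` if `mask` is already a 1-px skeleton.
#' @return object of class `skeleton_graph`: `skeleton` (logical matrix),
#'   `coords` (n x 2), `endpoints`, `branch_points` (coordinate matrices),
#'   `segments` (list of ordered pixel paths between nodes),
#'   `total_length` (px, diagonal steps sqrt(2), plus the per-endpoint
#'   stroke-radius compensation for thinning retraction), and the weighted
#'   pixel `graph` (igraph) used for path queries.
#' @export
skeletonize_component <- function(mask, thin = TRUE) {
  if (!any(mask)) stop("empty mask")
  mask <- as_mask(mask)
  skel <- if (thin) thin_mask(mask) else mask
  coords <- mask_coords(skel)
  n <- nrow(coords)
  idx <- matrix(0L, nrow(skel), ncol(skel))
  idx[skel] <- seq_len(n)
  sk <- matrix(0L, nrow(skel), ncol(skel)); sk[skel] <- 1L
  nbr <- Reduce(`+`, lapply(list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                                 c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L)),
                            function(o) shift_mat(sk, o[1L], o[2L])))
  deg <- nbr[skel]
  endpoints <- coords[deg == 1L, , drop = FALSE]
  branch_points <- coords[deg >= 3L, , drop = FALSE]
  # pixel adjacency edges (each pair once)
  ed <- NULL; wt <- NULL
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(idx, o[1L], o[2L])
    sel <- skel & nb > 0L
    if (any(sel)) {
      ed <- rbind(ed, cbind(idx[sel], nb[sel]))
      wt <- c(wt, rep(sqrt(sum(o^2)), sum(sel)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(ed)) g <- igraph::add_edges(g, t(ed), weight = wt)
  total_length <- if (igraph::ecount(g) > 0)
    sum(igraph::E(igraph::mst(g))$weight) else 0
  # thinning retracts each skeleton tip by about the local stroke radius;
  # add it back from the distance transform (zero for already-thin strokes)
  if (thin && nrow(endpoints) > 0L) {
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
    total_length <- total_length + sum(pmax(dm[endpoints] - 1, 0))
  }
  segs <- trace_segments(skel, idx, coords, deg)
  structure(list(skeleton = skel, coords = coords, endpoints = endpoints,
                 branch_points = branch_points, segments = segs,
                 total_length = total_length, graph = g, degree = deg),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d px, length %.1f, %d endpoints, %d branch points, %d segments\n",
              nrow(x$coords), x$total_length, nrow(x$endpoints),
              nrow(x$branch_points), length(x$segments)))
  invisible(x)
}

#' @keywords internal
trace_segments <- function(skel, idx, coords, deg) {
  # remove branch pixels; the remainder decomposes into simple arcs
  arcs <- skel
  if (any(deg >= 3L)) arcs[coords[deg >= 3L, , drop = FALSE]] <- FALSE
  lab <- label_components(arcs, 8L)
  nseg <- max(lab)
  segs <- vector("list", nseg)
  if (nseg == 0L) return(segs)
  for (i in seq_len(nseg)) {
    w <- which(lab == i, arr.ind = TRUE)
    segs[[i]] <- order_arc_pixels(w)
  }
  segs
}

#' @keywords internal
order_arc_pixels <- function(w) {
  # order the pixels of a simple 8-connected arc by walking from a terminal
  n <- nrow(w)
  if (n <= 2L) return(w)
  key <- w[, 1L] * 1e6 + w[, 2L]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  nbrs <- function(i) {
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      k <- as.character((w[i, 1L] + dr) * 1e6 + (w[i, 2L] + dc))
      j <- get0(k, envir = lookup)
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  degs <- vapply(seq_len(n), function(i) length(nbrs(i)), integer(1))
  start <- if (any(degs <= 1L)) which(degs <= 1L)[1L] else 1L
  order <- integer(n); seen <- logical(n)
  cur <- start; order[1L] <- cur; seen[cur] <- TRUE
  for (k in 2L:n) {
    cand <- nbrs(cur)
    cand <- cand[!seen[cand]]
    if (length(cand) == 0L) { order <- order[seq_len(k - 1L)]; break }
    # prefer axial over diagonal continuation for a consistent arc length
    d <- abs(w[cand, 1L] - w[cur, 1L]) + abs(w[cand, 2L] - w[cur, 2L])
    cur <- cand[which.min(d)]
    order[k] <- cur; seen[cur] <- TRUE
  }
  w[order, , drop = FALSE]
}

#' Mid-rib axis: the longest end-to-end skeleton path with arc positions
#'
#' Skeletonizes the mid-rib, finds the endpoint pair with the largest
#' geodesic separation (warning if more than two endpoints are present),
#' orders the path from the basal endpoint (the lower one, larger row) and
#' returns cumulative arc positions.
#'
#' Short side branches (below `prune_len`), such as the spurs thinning
#' leaves at the shoulders where the petiole stroke narrows into the
#' first-order vein, are pruned before the path is selected.
#'
#' @param MR logical matrix (mid-rib mask), or a ready `skeleton_graph`.
#' @param prune_len spur branches shorter than this many px are removed
#'   (default 20).
#' @return object of class `midrib_axis`: `path` (ordered m x 2 from base),
#'   `arc` (cumulative arc length per path pixel), `length` (`MR_L`),
#'   `base` (`c(row, col)`), `skeleton_graph`.
#' @export
midrib_axis <- function(MR, prune_len = 20) {
  sg <- if (inherits(MR, "skeleton_graph")) MR else skeletonize_component(MR)
  if (nrow(sg$endpoints) > 2L) {
    pruned <- prune_spurs(sg$skeleton, prune_len)
    if (!identical(pruned, sg$skeleton)) sg <- skeletonize_component(pruned, thin = FALSE)
  }
  ep <- sg$endpoints
  if (nrow(ep) < 2L) stop("mid-rib skeleton has fewer than two endpoints")
  if (nrow(ep) > 2L)
    warning(sprintf("mid-rib skeleton has %d endpoints; using the longest end-to-end path", nrow(ep)))
  eidx <- apply(ep, 1L, function(p) which(sg$coords[, 1L] == p[1L] & sg$coords[, 2L] == p[2L])[1L])
  D <- igraph::distances(sg$graph, v = eidx, to = eidx)
  best <- which(D == max(D[is.finite(D)]), arr.ind = TRUE)[1L, ]
  v1 <- eidx[best[1L]]; v2 <- eidx[best[2L]]
  # base = the lower of the two chosen endpoints
  if (sg$coords[v1, 1L] < sg$coords[v2, 1L]) { tmp <- v1; v1 <- v2; v2 <- tmp }
  sp <- igraph::shortest_paths(sg$graph, from = v1, to = v2, output = "vpath")
  vp <- as.integer(sp$vpath[[1L]])
  path <- sg$coords[vp, , drop = FALSE]
  mask <- if (inherits(MR, "skeleton_graph")) NULL else as_mask(MR)
  refined <- FALSE
  if (!is.null(mask)) {
    rext <- diff(range(path[, 1L])); cext <- diff(range(path[, 2L]))
    if (rext >= 2 * cext) {
      # near-vertical mid-rib (the normalized pose): replace the pixel
      # chain by the row-wise mean column of the stroke, which runs the
      # full stroke extent and is free of thinning retraction and
      # staircase chamfer error
      path <- rowwise_centerline(mask, base_down = path[1L, 1L] >= path[nrow(path), 1L])
      refined <- TRUE
    } else {
      # oblique pose: extend the skeleton ends (thinning retracts them by
      # about the local stroke radius) along the end tangents, capped by
      # the distance-transform value at the tip
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
      path <- extend_path_end(path, mask, at_start = TRUE,
                              maxlen = dm[path[1L, 1L], path[1L, 2L]] + 1)
      path <- extend_path_end(path, mask, at_start = FALSE,
                              maxlen = dm[path[nrow(path), 1L], path[nrow(path), 2L]] + 1)
    }
  }
  # arc positions along a moving-average smoothed copy of the path: a raw
  # pixel chain overestimates curve length by the chamfer-metric error
  # (up to ~8% for directions between the axial and diagonal grid axes)
  sm <- smooth_path(path, half_window = if (refined) 2L else 8L)
  steps <- sqrt(rowSums((sm[-1L, , drop = FALSE] - sm[-nrow(sm), , drop = FALSE])^2))
  arc <- c(0, cumsum(steps))
  structure(list(path = path, arc = arc, length = arc[length(arc)],
                 base = path[1L, ], skeleton_graph = sg),
            class = "midrib_axis")
}

#' @keywords internal
rowwise_centerline <- function(mask, base_down = TRUE) {
  w <- which(mask, arr.ind = TRUE)
  agg <- tapply(w[, 2L], w[, 1L], mean)
  cnt <- tapply(w[, 2L], w[, 1L], length)
  rows <- as.integer(names(agg))
  o <- order(rows)
  rows <- rows[o]; agg <- as.numeric(agg)[o]; cnt <- as.integer(cnt)[o]
  # trim degenerate end rows (corner slivers of the rotated stroke whose
  # mean column is far off the stroke center)
  n <- length(rows)
  lo <- 1L; hi <- n
  while (lo < hi && cnt[lo] < 0.5 * stats::median(cnt[lo:min(lo + 7L, hi)])) lo <- lo + 1L
  while (hi > lo && cnt[hi] < 0.5 * stats::median(cnt[max(hi - 7L, lo):hi])) hi <- hi - 1L
  rows <- rows[lo:hi]; agg <- agg[lo:hi]
  ord <- if (base_down) order(rows, decreasing = TRUE) else order(rows)
  cbind(rows[ord], agg[ord])
}

#' @keywords internal
prune_spurs <- function(skel, prune_len = 20) {
  # repeatedly remove endpoint-to-branch-point twigs shorter than prune_len
  repeat {
    sg <- skeletonize_component(skel, thin = FALSE)
    if (nrow(sg$endpoints) <= 2L || nrow(sg$branch_points) == 0L) return(skel)
    removed <- FALSE
    bp <- sg$branch_points
    for (k in seq_len(nrow(sg$endpoints))) {
      twig <- walk_from_endpoint(skel, sg$endpoints[k, ], bp, maxlen = prune_len)
      if (!is.null(twig)) {
        skel[twig] <- FALSE
        removed <- TRUE
        break
      }
    }
    if (!removed) return(skel)
  }
}

#' @keywords internal
walk_from_endpoint <- function(skel, ep, branch_pts, maxlen) {
  # walk from an endpoint until a branch point; return the twig pixels
  # (excluding the branch point) if the walk is shorter than maxlen
  is_branch <- matrix(FALSE, nrow(skel), ncol(skel))
  is_branch[branch_pts] <- TRUE
  cur <- ep; prev <- c(NA_integer_, NA_integer_)
  twig <- matrix(ep, 1L, 2L)
  len <- 0
  while (len < maxlen) {
    nxt <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r <- cur[1L] + dr; c <- cur[2L] + dc
      if (r < 1L || r > nrow(skel) || c < 1L || c > ncol(skel) || !skel[r, c]) next
      if (!is.na(prev[1L]) && r == prev[1L] && c == prev[2L]) next
      if (nrow(twig) > 1L && any(twig[, 1L] == r & twig[, 2L] == c)) next
      nxt <- c(r, c); break
    }
    if (is.null(nxt)) return(NULL)          # hit another endpoint: main path
    if (is_branch[nxt[1L], nxt[2L]]) return(twig)
    len <- len + sqrt(sum((nxt - cur)^2))
    prev <- cur; cur <- nxt
    twig <- rbind(twig, cur)
  }
  NULL
}

#' @keywords internal
extend_path_end <- function(path, mask, at_start, maxlen = Inf, fit_n = 12L) {
  m <- nrow(path)
  fit_n <- min(fit_n, m)
  if (fit_n < 4L) return(path)
  idx <- if (at_start) seq_len(fit_n) else (m - fit_n + 1L):m
  pts <- path[idx, , drop = FALSE]
  tip <- if (at_start) path[1L, ] else path[m, ]
  # direction pointing outward from the path end
  dirv <- colMeans(pts[seq_len(fit_n %/% 2L), , drop = FALSE]) -
          colMeans(pts[(fit_n %/% 2L + 1L):fit_n, , drop = FALSE])
  if (!at_start) dirv <- -dirv
  len <- sqrt(sum(dirv^2))
  if (len == 0) return(path)
  dirv <- dirv / len
  ext <- NULL
  pos <- tip
  travelled <- 0
  repeat {
    pos <- pos + 0.5 * dirv
    travelled <- travelled + 0.5
    rc <- round(pos)
    if (travelled > maxlen ||
        rc[1L] < 1L || rc[1L] > nrow(mask) || rc[2L] < 1L || rc[2L] > ncol(mask) ||
        !mask[rc[1L], rc[2L]]) break
    if (is.null(ext) || any(ext[nrow(ext), ] != rc)) ext <- rbind(ext, rc)
  }
  if (is.null(ext)) return(path)
  if (at_start) rbind(ext[rev(seq_len(nrow(ext))), , drop = FALSE], path)
  else rbind(path, ext)
}

#' @keywords internal
smooth_path <- function(path, half_window = 8L) {
  m <- nrow(path)
  if (m < 3L) return(path)
  cs_r <- c(0, cumsum(path[, 1L]))
  cs_c <- c(0, cumsum(path[, 2L]))
  i <- seq_len(m)
  lo <- pmax(i - half_window, 1L); hi <- pmin(i + half_window, m)
  n <- hi - lo + 1
  cbind((cs_r[hi + 1L] - cs_r[lo]) / n, (cs_c[hi + 1L] - cs_c[lo]) / n)
}

#' Arc position along the mid-rib axis of arbitrary points
#'
#' Each query point is assigned the cumulative arc position of its nearest
#' axis pixel.
#'
#' @param axis a [midrib_axis()].
#' @param pts n x 2 matrix of `row`, `col` coordinates.
#' @return list `arc` (numeric n), `dist` (distance to the axis, px).
#' @export
arc_position <- function(axis, pts) {
  pts <- matrix(pts, ncol = 2L)
  nn <- pairwise_min_dist(pts, axis$path)
  list(arc = axis$arc[nn$index], dist = nn$dist)
}

#' Partition the blade into regions separated by a skeleton
#'
#' Connected components of the blade minus the skeleton pixels.  Regions
#' use 4-connectivity, the dual of the 8-connected skeleton curve, so
#' regions cannot leak through diagonal skeleton steps.  When a
#' `skeleton_graph` is supplied its tips are first extended along their
#' tangents to the blade border (thinning retracts them by the local
#' stroke radius), so regions cannot leak around free skeleton ends
#' either.
#'
#' @param BD logical matrix.
#' @param skel a `skeleton_graph` or logical skeleton matrix.
#' @param extend_tips maximal tip extension in px (0 disables).
#' @return integer label matrix with attribute `areas` (named region sizes).
#' @export
partition_blade_regions <- function(BD, skel, extend_tips = 40) {
  if (inherits(skel, "skeleton_graph")) {
    sk <- skel$skeleton
    if (extend_tips > 0 && nrow(skel$endpoints) > 0L) {
      for (k in seq_len(nrow(skel$endpoints))) {
        ep <- skel$endpoints[k, ]
        seg <- find_endpoint_segment(skel$segments, ep)
        if (is.null(seg)) next
        ext <- extend_path_end(seg, BD, at_start = FALSE, maxlen = extend_tips)
        if (nrow(ext) > nrow(seg)) sk[ext[(nrow(seg) + 1L):nrow(ext), , drop = FALSE]] <- TRUE
      }
    }
  } else sk <- as_mask(skel)
  lab <- label_components(BD & !sk, 4L)
  areas <- tabulate(lab[lab > 0L])
  attr(lab, "areas") <- stats::setNames(areas, seq_along(areas))
  lab
}

#' @keywords internal
find_endpoint_segment <- function(segments, ep) {
  # the segment that terminates at this endpoint, oriented endpoint-last
  for (seg in segments) {
    if (nrow(seg) == 0L) next
    if (seg[1L, 1L] == ep[1L] && seg[1L, 2L] == ep[2L])
      return(seg[rev(seq_len(nrow(seg))), , drop = FALSE])
    if (seg[nrow(seg), 1L] == ep[1L] && seg[nrow(seg), 2L] == ep[2L])
      return(seg)
  }
  NULL
}

#' Split a mask into left and right of the mid-rib
#'
#' The mid-rib axis is extended linearly from both endpoints to the image
#' border; each row's divider column assigns mask pixels to the left or
#' right side.  The divider column itself belongs to neither side, so
#' `left | right | divider` restores the mask and `left & right` is empty.
#'
#' @param mask logical matrix (any component of the upright leaf).
#' @param axis a [midrib_axis()] computed on the same canvas.
#' @return list `left`, `right` (logical matrices), `divider_col` (numeric
#'   per-row divider position).
#' @export
split_left_right <- function(mask, axis) {
  H <- nrow(mask); W <- ncol(mask)
  path <- axis$path
  xline <- rep(NA_real_, H)
  agg <- tapply(path[, 2L], path[, 1L], mean)
  xline[as.integer(names(agg))] <- agg
  have <- which(!is.na(xline))
  if (length(have) < 2L) stop("mid-rib axis spans fewer than two rows")
  # linear extension from the terminal 25% of the axis on each end
  fit_end <- function(rows_sel) {
    if (length(unique(rows_sel)) < 2L) return(NULL)
    stats::lm.fit(cbind(1, rows_sel), xline[rows_sel])$coefficients
  }
  top <- have[seq_len(max(2L, ceiling(length(have) * 0.25)))]
  bot <- have[seq(length(have) - max(2L, ceiling(length(have) * 0.25)) + 1L, length(have))]
  cf_top <- fit_end(top); cf_bot <- fit_end(bot)
  up_rows <- seq_len(min(have) - 1L)
  dn_rows <- if (max(have) < H) (max(have) + 1L):H else integer(0)
  if (length(up_rows) && !is.null(cf_top)) xline[up_rows] <- cf_top[1L] + cf_top[2L] * up_rows
  if (length(dn_rows) && !is.null(cf_bot)) xline[dn_rows] <- cf_bot[1L] + cf_bot[2L] * dn_rows
  xline[is.na(xline)] <- mean(xline, na.rm = TRUE)
  # interior gaps (rows the 8-connected path skips laterally): interpolate
  div <- round(xline)
  colmat <- matrix(rep(seq_len(W), each = H), H, W)
  left <- mask & colmat < div
  right <- mask & colmat > div
  list(left = left, right = right, divider_col = xline)
}
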