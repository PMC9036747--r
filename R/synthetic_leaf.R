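# Seeded parametric generator of annotated lettuce-style leaves.
#
# The generator builds a leaf directly in the upright pose (petiole at the
# bottom, apex at the top): a smooth ovate blade around a bowed mid-rib,
# a petiole segment markedly thicker than the veins, ordered second-order
# veins attached along the mid-rib at known angles, laminas as the regions
# between consecutive veins eroded by a marginal band.  Every quantity the
# phenotyping stages later estimate (areas, arc lengths, lamina counts,
# attachment points, vein angles) is emitted as exact ground truth.

#' Parameters of a synthetic leaf
#'
#' @param blade_length length of the ovate blade along the mid-rib, px.
#' @param blade_width maximal blade width, px.
#' @param midrib_curvature dimensionless bow factor; the mid-rib deviates
#'   laterally by up to `midrib_curvature * (blade_length + petiole_length)`.
#' @param petiole_length arc length of the petiole along the mid-rib, px.
#'   The first vein on each side attaches exactly where the petiole ends.
#' @param petiole_width,vein_width stroke widths, px; the petiole must be at
#'   least twice as wide as the veins so the petiole half of the mid-rib
#'   bounding box always carries the larger pixel mass.
#' @param n_veins_left,n_veins_right number of second-order veins per side.
#' @param vein_angles_left,vein_angles_right vein angles in degrees, strictly
#'   inside (0, 180), measured between the vein and the apex-ward mid-rib
#'   tangent at the attachment point.  Defaults spread over 55-95 degrees.
#' @param marginal_band_width width of the marginal band eroded off the
#'   blade outline before laminas are formed, px.
#' @param palette named list of RGB triplets (0-255) for `bg`, `margin`,
#'   `lamina`, `midrib`, `vein`.
#' @param noise_sd per-channel Gaussian noise added to the painted image,
#'   on the 0-255 scale.
#' @param seed integer seed controlling the image noise (the geometry is
#'   fully determined by the other parameters).
#' @return object of class `leaf_params`.
#' @export
leaf_params <- function(blade_length = 700, blade_width = 500,
                        midrib_curvature = 0.06,
                        petiole_length = 130,
                        petiole_width = 26, vein_width = 9,
                        n_veins_left = 4, n_veins_right = 4,
                        vein_angles_left = NULL, vein_angles_right = NULL,
                        marginal_band_width = 14,
                        palette = NULL, noise_sd = 3, seed = 1L) {
  if (is.null(vein_angles_left))
    vein_angles_left <- seq(55, 95, length.out = max(n_veins_left, 1L))[seq_len(n_veins_left)]
  if (is.null(vein_angles_right))
    vein_angles_right <- seq(55, 95, length.out = max(n_veins_right, 1L))[seq_len(n_veins_right)]
  if (is.null(palette)) palette <- default_palette()
  p <- list(blade_length = blade_length, blade_width = blade_width,
            midrib_curvature = midrib_curvature,
            petiole_length = petiole_length,
            petiole_width = petiole_width, vein_width = vein_width,
            n_veins_left = as.integer(n_veins_left),
            n_veins_right = as.integer(n_veins_right),
            vein_angles_left = as.numeric(vein_angles_left),
            vein_angles_right = as.numeric(vein_angles_right),
            marginal_band_width = marginal_band_width,
            palette = palette, noise_sd = noise_sd, seed = as.integer(seed))
  class(p) <- "leaf_params"
  validate_leaf_params(p)
  p
}

#' @keywords internal
validate_leaf_params <- function(p) {
  stopifnot(p$blade_length > 0, p$blade_width > 0,
            p$petiole_length > 0, p$petiole_length < p$blade_length + p$petiole_length,
            p$petiole_width >= 1, p$vein_width >= 1,
            p$marginal_band_width >= 1,
            p$n_veins_left >= 1, p$n_veins_right >= 1,
            length(p$vein_angles_left) == p$n_veins_left,
            length(p$vein_angles_right) == p$n_veins_right)
  ang <- c(p$vein_angles_left, p$vein_angles_right)
  if (any(ang <= 0 | ang >= 180)) stop("vein angles must lie strictly inside (0, 180) degrees")
  if (p$petiole_width < 2 * p$vein_width)
    warning("petiole_width < 2 * vein_width: petiole/apex disambiguation may be unreliable")
  invisible(p)
}

#' @keywords internal
default_palette <- function() {
  list(bg     = c(245, 245, 245),
       margin = c(150, 200, 120),
       lamina = c(120, 180, 90),
       midrib = c(225, 235, 190),
       vein   = c(205, 220, 160))
}

#' Generate a synthetic leaf with ground truth
#'
#' @param params a [leaf_params()] object.
#' @param id leaf identifier stored in the sample.
#' @param orientation `"positive"` or `"back"`.
#' @return list with elements `sample` (a `leaf_sample`: RGB image in
#'   `[0,1]`, six-component mask set, identity and pixel scale) and `truth`
#'   (a `leaf_truth`: per-component areas, petiole/mid-rib/apex arc lengths,
#'   lamina table with side, order, attachment, arc position and vein angle,
#'   applied transform, seed).
#' @export
generate_leaf <- function(params, id = sprintf("leaf%03d", params$seed),
                          orientation = c("positive", "back")) {
  orientation <- match.arg(orientation)
  p <- validate_leaf_params(params)

  pad <- ceiling(0.10 * p$blade_length)
  S <- p$blade_length + p$petiole_length      # vertical span of the mid-rib
  bow <- p$midrib_curvature * S
  W <- as.integer(ceiling(p$blade_width + 2 * abs(bow) + 2 * pad))
  H <- as.integer(ceiling(S + 2 * pad))
  base_row <- H - pad
  cx <- (W + 1) / 2

  # dense analytic centerline from base (t=0) to apex (t=1)
  nt <- 4000L
  t <- seq(0, 1, length.out = nt)
  cl_row <- base_row - t * S
  cl_col <- cx + bow * sin(pi * t)
  seg <- sqrt(diff(cl_row)^2 + diff(cl_col)^2)
  arc <- c(0, cumsum(seg))
  MR_L <- arc[nt]
  PE <- p$petiole_length
  if (PE >= MR_L) stop("petiole_length must be smaller than the mid-rib arc length")
  U <- MR_L - PE                              # blade arc span

  arc_of_row <- stats::approxfun(cl_row, arc)          # row -> arc (monotone)
  col_of_arc <- stats::approxfun(arc, cl_col)
  row_of_arc <- stats::approxfun(arc, cl_row)

  # ovate half-width profile over blade parameter u in [0, 1]
  gfun <- function(v) v^1.2 * (1 - v)^2.2
  gmax <- gfun(1.2 / (1.2 + 2.2) * 0.95 + 0.05)  # near-peak; exact peak found below
  vv <- seq(0, 1, length.out = 512)
  gmax <- max(gfun(0.05 + 0.95 * vv))
  half_width <- function(u) (p$blade_width / 2) * gfun(0.05 + 0.95 * pmin(pmax(u, 0), 1)) / gmax

  rows <- seq_len(H)
  row_arc <- arc_of_row(rows)                  # NA outside centerline span
  row_u <- (row_arc - PE) / U
  row_cx <- col_of_arc(row_arc)

  ovate <- matrix(FALSE, H, W)
  MR <- matrix(FALSE, H, W)
  colidx <- seq_len(W)
  for (r in rows) {
    if (is.na(row_arc[r])) next
    xc <- row_cx[r]
    if (row_u[r] >= 0) {                       # blade zone
      hw <- half_width(row_u[r])
      if (hw >= 0.5) ovate[r, abs(colidx - xc) <= hw] <- TRUE
    }
    mhw <- if (row_arc[r] < PE) p$petiole_width / 2 else p$vein_width / 2
    MR[r, abs(colidx - xc) <= mhw] <- TRUE
  }

  # second-order veins: straight strokes from attachment along the stated angle
  tangent_at <- function(s) {
    eps <- 2
    r1 <- row_of_arc(max(s - eps, 0)); c1 <- col_of_arc(max(s - eps, 0))
    r2 <- row_of_arc(min(s + eps, MR_L)); c2 <- col_of_arc(min(s + eps, MR_L))
    v <- c(c2 - c1, r2 - r1)                   # (dx, dy), dy < 0 going apex-ward
    v / sqrt(sum(v^2))
  }
  side_spec <- list(
    left  = list(n = p$n_veins_left,  ang = p$vein_angles_left,  sgn = -1),
    right = list(n = p$n_veins_right, ang = p$vein_angles_right, sgn = +1))

  # the first attachment sits above the blade base by the marginal band
  # plus the stroke clearance, so the basal lamina corner is shaped by the
  # vein (not by the eroded blade outline)
  delta0 <- p$marginal_band_width + ceiling(p$vein_width / 2) + 6
  vein_curve <- matrix(FALSE, H, W)
  lam_tab <- NULL
  for (sd_name in names(side_spec)) {
    sp <- side_spec[[sd_name]]
    spacing <- (0.82 * U - delta0) / sp$n
    for (i in seq_len(sp$n)) {
      s_i <- PE + delta0 + (i - 1) * spacing
      u <- tangent_at(s_i)                     # (dx, dy) apex-ward
      theta <- sp$ang[i] * pi / 180
      Ux <- u[1L]; Uy <- -u[2L]                # switch to y-up for the rotation
      if (sp$sgn > 0) {                        # rotate toward +x (right side)
        Dx <- Ux * cos(theta) + Uy * sin(theta)
        Dy <- -Ux * sin(theta) + Uy * cos(theta)
      } else {                                 # rotate toward -x (left side)
        Dx <- Ux * cos(theta) - Uy * sin(theta)
        Dy <- Ux * sin(theta) + Uy * cos(theta)
      }
      d <- c(Dx, -Dy)                          # back to (dx, dy), y down
      p0 <- c(row_of_arc(s_i), col_of_arc(s_i))
      steps <- seq(0.5, H + W, by = 0.5)
      rr <- p0[1L] + d[2L] * steps
      cc <- p0[2L] + d[1L] * steps
      a <- arc_of_row(rr)
      uu <- (a - PE) / U
      inside <- !is.na(a) & uu >= 0 & rr >= 1 & rr <= H & cc >= 1 & cc <= W &
        abs(cc - col_of_arc(a)) <= half_width(uu)
      k <- which(!inside)[1L]                  # stroke ends at first exit
      if (is.na(k)) k <- length(steps) + 1L
      if (k > 1L) {
        sel <- seq_len(k - 1L)
        vein_curve[cbind(round(rr[sel]), round(cc[sel]))] <- TRUE
      }
      ref_s <- min(s_i + 40, MR_L)
      lam_tab <- rbind(lam_tab, data.frame(
        side = sd_name, order = i, arc = s_i,
        att_row = row_of_arc(s_i), att_col = col_of_arc(s_i),
        dir_row = d[2L], dir_col = d[1L],
        ref_row = row_of_arc(ref_s), ref_col = col_of_arc(ref_s),
        angle = sp$ang[i], stringsAsFactors = FALSE))
    }
  }

  BD <- ovate | MR
  VS <- mask_dilate(vein_curve, floor(p$vein_width / 2)) & BD
  VV <- MR | VS

  core <- mask_erode(BD, p$marginal_band_width)
  lam_field <- core & !mask_dilate(VV, 2L)
  lam_assign <- assign_laminas(lam_field, lam_tab, col_of_arc, arc_of_row)
  LM <- lam_assign$mask
  lam_tab <- lam_tab[, c("side", "order", "arc", "att_row", "att_col", "angle")]

  # true petiole length: arc position where the rendered basal laminas make
  # contact with the mid-rib (the marginal band and the vein-stroke
  # clearance push the first lamina slightly above the nominal first
  # attachment, and the petiole physically ends at the first lamina)
  cl_sub <- cbind(row_of_arc(seq(0, MR_L, by = 1)), col_of_arc(seq(0, MR_L, by = 1)))
  contact <- function(pix) {
    bm <- matrix(FALSE, H, W); bm[pix] <- TRUE
    bd <- trace_boundary(bm)           # the minimum distance lies on it
    nn <- pairwise_min_dist(bd, cl_sub)
    near <- nn$dist <= min(nn$dist) + 1
    min(nn$index[near]) - 1            # arc sampled at 1-px steps
  }
  PE_L_true <- min(vapply(lam_assign$basal, contact, numeric(1)))
  MZ <- BD & !VV & !LM

  img <- paint_leaf(BD, MR, VS, LM, p)

  cs <- component_set(list(BD = BD, MR = MR, VS = VS, LM = LM, VV = VV, MZ = MZ),
                      provenance = c(BD = "annotated", MR = "annotated",
                                     VS = "annotated", LM = "annotated",
                                     VV = "derived", MZ = "derived"))
  sample <- leaf_sample(id = id, image = img, components = cs,
                        orientation = orientation)

  truth <- list(
    areas = vapply(cs$masks, sum, numeric(1)),
    PE_L = PE_L_true, PE_L_nominal = PE,
    MR_L = MR_L, AP_L = MR_L - PE_L_true,
    LM_N = p$n_veins_left + p$n_veins_right,
    LM_N_LT = p$n_veins_left, LM_N_RT = p$n_veins_right,
    laminas = lam_tab,
    rotation = 0, scale = 1, flip = FALSE,
    blade_width = p$blade_width,
    seed = p$seed)
  class(truth) <- "leaf_truth"

  list(sample = sample, truth = truth)
}

#' @keywords internal
assign_laminas <- function(lam_field, lam_tab, col_of_arc, arc_of_row) {
  # keep exactly one lamina per vein: the candidate region between vein i
  # and vein i+1 (or the apex) sits apexward of the rays of veins 1..i, so
  # its slot is the count of same-side vein rays it lies above; slot-0
  # regions (the basal wedge below the first vein) revert to marginal zone
  lab <- label_components(lam_field, 8L)
  n <- max(lab)
  if (n == 0L) stop("synthetic leaf has no laminas; parameters too extreme")
  keep <- matrix(FALSE, nrow(lam_field), ncol(lam_field))
  above_ray <- function(cen, vein) {
    cz <- vein$dir_col * (cen[1L] - vein$att_row) -
          vein$dir_row * (cen[2L] - vein$att_col)
    cz_ref <- vein$dir_col * (vein$ref_row - vein$att_row) -
              vein$dir_row * (vein$ref_col - vein$att_col)
    sign(cz) == sign(cz_ref)
  }
  slots <- list(left = list(), right = list())
  for (i in seq_len(n)) {
    w <- which(lab == i, arr.ind = TRUE)
    if (nrow(w) < 25L) next
    cen <- colMeans(w)
    a <- arc_of_row(w[, 1L])
    xc <- col_of_arc(a)
    side <- if (stats::median(w[, 2L] - xc, na.rm = TRUE) < 0) "left" else "right"
    veins <- lam_tab[lam_tab$side == side, , drop = FALSE]
    slot <- sum(vapply(seq_len(nrow(veins)),
                       function(j) above_ray(cen, veins[j, ]), logical(1)))
    if (slot < 1L) next
    prev <- slots[[side]][[as.character(slot)]]
    if (is.null(prev) || prev$area < nrow(w))
      slots[[side]][[as.character(slot)]] <- list(pix = w, area = nrow(w))
  }
  for (sd_name in c("left", "right")) {
    want <- sum(lam_tab$side == sd_name)
    got <- length(slots[[sd_name]])
    if (got != want)
      stop(sprintf("synthetic leaf construction failed: %d of %d %s laminas formed; adjust parameters",
                   got, want, sd_name))
    for (sl in slots[[sd_name]]) keep[sl$pix] <- TRUE
  }
  basal <- lapply(c("left", "right"), function(s) slots[[s]][["1"]]$pix)
  list(mask = keep, basal = basal[!vapply(basal, is.null, logical(1))])
}

#' @keywords internal
paint_leaf <- function(BD, MR, VS, LM, p) {
  H <- nrow(BD); W <- ncol(BD)
  img <- array(0, c(H, W, 3L))
  pal <- lapply(p$palette, function(v) v / 255)
  for (ch in 1:3) {
    m <- matrix(pal$bg[ch], H, W)
    m[BD] <- pal$margin[ch]
    m[LM] <- pal$lamina[ch]
    m[VS] <- pal$vein[ch]
    m[MR] <- pal$midrib[ch]
    img[, , ch] <- m
  }
  if (p$noise_sd > 0) {
    seed_keep <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, envir = globalenv()))
    set.seed(p$seed)
    img <- img + array(stats::rnorm(length(img), sd = p$noise_sd / 255), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  img
}

#' Leaf sample container
#'
#' Bundles the RGB image, the six-component mask set, the leaf identity and
#' the pixel scale.
#'
#' @param id leaf identifier.
#' @param image numeric H x W x 3 array in `[0, 1]`.
#' @param components a [component_set()].
#' @param orientation `"positive"` (adaxial) or `"back"` (abaxial).
#' @param scale_mm_per_px physical pixel size, mm/px.
#' @return object of class `leaf_sample`.
#' @export
leaf_sample <- function(id, image, components, orientation = "positive",
                        scale_mm_per_px = 4.785e-2) {
  stopifnot(length(dim(image)) == 3L,
            all(dim(image)[1:2] == dim(components$masks$BD)))
  structure(list(id = id, image = image, components = components,
                 orientation = orientation,
                 scale_mm_per_px = scale_mm_per_px),
            class = "leaf_sample")
}

#' @export
print.leaf_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<leaf_sample> %s (%s), %d x %d px, blade area %d px\n",
              x$id, x$orientation, d[1L], d[2L], sum(x$components$masks$BD)))
  invisible(x)
}

#' Apply a rigid transform (rotation, scaling, mirroring) to a leaf sample
#'
#' Masks are resampled with nearest-neighbor interpolation, the RGB image
#' bilinearly; the canvas is enlarged so no foreground is clipped.
#'
#' @param sample a `leaf_sample`.
#' @param angle rotation in degrees.
#' @param scale uniform size factor (> 0).
#' @param flip mirror about the vertical axis.
#' @return transformed `leaf_sample`.
#' @export
apply_rigid_transform <- function(sample, angle = 0, scale = 1, flip = FALSE) {
  stopifnot(inherits(sample, "leaf_sample"), scale > 0)
  masks <- sample$components$masks
  img <- sample$image
  if (angle %% 360 != 0) {
    masks <- lapply(masks, rotate_canvas, angle = angle, filter = "none")
    img <- rotate_canvas(img, angle, filter = "bilinear",
                         bg = grDevices::rgb(1, 1, 1))
  }
  if (scale != 1) {
    masks <- lapply(masks, resize_canvas, factor = scale, filter = "none")
    img <- resize_canvas(img, scale, filter = "bilinear")
  }
  if (flip) {
    masks <- lapply(masks, mirror_horizontal)
    img <- mirror_horizontal(img)
  }
  # rotation can leave image/mask dims off by a pixel; align by cropping
  d <- dim(masks$BD)
  img <- img[seq_len(min(d[1L], dim(img)[1L])), seq_len(min(d[2L], dim(img)[2L])), , drop = FALSE]
  if (any(dim(img)[1:2] != d)) {
    full <- array(1, c(d, 3L))
    full[seq_len(dim(img)[1L]), seq_len(dim(img)[2L]), ] <- img
    img <- full
  }
  cs <- component_set(masks, provenance = sample$components$provenance)
  leaf_sample(sample$id, img, cs, sample$orientation, sample$scale_mm_per_px)
}

#' Draw random leaf parameters from realistic ranges
#'
#' Convenience sampler used in simulations: blade 550-850 px long and
#' 380-620 px wide, 3-6 veins per side, mild bow, petiole 90-170 px.
#' Angle sequences run base to apex as a bounded random walk: consecutive
#' veins may open (decrease) freely but may steepen (increase) by at most
#' 10 degrees, because two consecutive straight veins whose angles increase
#' sharply would cross inside the blade -- a layout the leaf model cannot
#' render (real second-order veins do not cross either).
#'
#' @param seed integer seed (drives both the parameter draw and the image
#'   noise of the resulting leaf).
#' @param angle_range overall range the per-vein angles may span, degrees.
#' @param vary `"all"` draws the full geometry; `"angles"` keeps the
#'   default blade geometry (and 4 + 4 veins) and draws only the angle
#'   sequences — the controlled design for comparing angle regimes
#'   without confounding size variation.
#' @return a [leaf_params()] object.
#' @export
random_leaf_params <- function(seed, angle_range = c(40, 120),
                               vary = c("all", "angles")) {
  vary <- match.arg(vary)
  seed_keep <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, envir = globalenv()))
  set.seed(seed)
  draw_angles <- function(n) {
    a <- numeric(n)
    a[1L] <- stats::runif(1, max(angle_range[1L], 50), min(angle_range[2L], 115))
    for (i in seq_len(n - 1L))
      a[i + 1L] <- min(max(a[i] + stats::runif(1, -30, 10), angle_range[1L]),
                       angle_range[2L])
    round(a, 1)
  }
  if (vary == "angles")
    return(leaf_params(n_veins_left = 4L, n_veins_right = 4L,
                       vein_angles_left = draw_angles(4L),
                       vein_angles_right = draw_angles(4L),
                       seed = seed))
  nl <- sample(3:6, 1); nr <- sample(3:6, 1)
  leaf_params(
    blade_length = round(stats::runif(1, 550, 850)),
    blade_width = round(stats::runif(1, 380, 620)),
    midrib_curvature = stats::runif(1, 0.0, 0.09),
    petiole_length = round(stats::runif(1, 90, 170)),
    petiole_width = round(stats::runif(1, 22, 30)),
    vein_width = round(stats::runif(1, 7, 11)),
    n_veins_left = nl, n_veins_right = nr,
    vein_angles_left = draw_angles(nl),
    vein_angles_right = draw_angles(nr),
    marginal_band_width = round(stats::runif(1, 10, 18)),
    seed = seed)
}

#' Write a generated leaf to disk
#'
#' Emits `<id>_{BD,MR,VS,LM,VV,MZ}.png` (8-bit 0/255), `<id>_rgb.png` and
#' `<id>_truth.json` into `dir`.
#'
#' @param leaf list as returned by [generate_leaf()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
save_leaf <- function(leaf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- leaf$sample$id
  paths <- save_component_set(leaf$sample$components, dir, id)
  rgb_path <- file.path(dir, paste0(id, "_rgb.png"))
  png::writePNG(leaf$sample$image, rgb_path)
  tr <- leaf$truth
  tr$areas <- as.list(tr$areas)
  truth_path <- file.path(dir, paste0(id, "_truth.json"))
  jsonlite::write_json(unclass(tr), truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, rgb_path, truth_path))
}
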