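# The 266-trait vector: 30 geometry, 20 venation and 216 color traits per
# leaf, computed in the normalized space.  Trait names, groups and units
# are fixed by the registry so the CSV column order is stable across runs.

COLOR_COMPONENTS <- COMPONENT_KEYS
COLOR_SPACES <- c("RGB", "HSV", "LAB", "LUV", "YCrCb", "CIELab")

GEO_TRAIT_NAMES <- c(
  "BD_L", "BD_W", "BD_A", "BD_P", "BD_CHA", "BD_Solidity", "BD_AspectRatio",
  "ScalingFactor", "MR_A", "VS_A", "VV_A", "LM_A", "MZ_A",
  "MR_A_Ratio", "VS_A_Ratio", "VV_A_Ratio", "LM_A_Ratio", "MZ_A_Ratio",
  "MR_VS_A_Ratio", "MR_VV_A_Ratio", "VS_VV_A_Ratio",
  "EVA_MR_VS_2_VV", "EVA_LM_VV_2_BD", "EVA_MZ_LM_2_BD",
  "LM_A_LT", "LM_A_RT", "BD_A_LT", "BD_A_RT", "LM_CHA", "VV_CHA")

VEN_TRAIT_NAMES <- c(
  "PE_L", "MR_L", "AP_L", "BD_PE_PX", "LM_N", "LM_N_LT", "LM_N_RT",
  "LM1_A_LT", "LM1_A_RT", "LM_Ave_ANG", "LM_Ave_ANG_LT", "LM_Ave_ANG_RT",
  "LM_ANG_Std_LT", "LM_ANG_Std_RT", "VV_SKL_L", "VS_SKL_L",
  "SKL_EP_N", "SKL_BP_N", "VeinDensity", "PE_L_Ratio")

#' Trait registry: name, group and units of all 266 traits
#'
#' Geometry (30) and venation (20) traits carry the symbols used in the
#' field (`BD_L`, `PE_L`, `LM_Ave_ANG`, ...); color traits (216) are named
#' `<COMP>_<SPACE>_<stat>_<ch>` for the 6 components x 6 color spaces x
#' 3 channels x {mean, std}.
#'
#' @return data frame with columns `name`, `group` (GEO/VEN/CLR), `units`.
#' @export
trait_registry <- function() {
  geo_units <- c(BD_L = "px", BD_W = "px", BD_A = "px2", BD_P = "px",
                 BD_CHA = "px2", BD_Solidity = "", BD_AspectRatio = "",
                 ScalingFactor = "", MR_A = "px2", VS_A = "px2", VV_A = "px2",
                 LM_A = "px2", MZ_A = "px2")
  geo <- data.frame(name = GEO_TRAIT_NAMES, group = "GEO",
                    units = ifelse(GEO_TRAIT_NAMES %in% names(geo_units),
                                   geo_units[GEO_TRAIT_NAMES],
                                   ifelse(grepl("Ratio|EVA", GEO_TRAIT_NAMES), "%", "px2")),
                    stringsAsFactors = FALSE)
  ven_units <- ifelse(grepl("_L$|SKL_L", VEN_TRAIT_NAMES), "px",
               ifelse(grepl("ANG", VEN_TRAIT_NAMES), "deg",
               ifelse(grepl("PX$|A_", VEN_TRAIT_NAMES), "px2",
               ifelse(VEN_TRAIT_NAMES == "VeinDensity", "1/px", ""))))
  ven <- data.frame(name = VEN_TRAIT_NAMES, group = "VEN", units = ven_units,
                    stringsAsFactors = FALSE)
  clr_names <- as.vector(t(outer(COLOR_COMPONENTS, unlist(
    lapply(COLOR_SPACES, function(sp) paste0(sp, "_", rep(c("mean", "std"), each = 3),
                                             "_", rep(1:3, 2)))), paste, sep = "_")))
  clr <- data.frame(name = clr_names, group = "CLR", units = "",
                    stringsAsFactors = FALSE)
  rbind(geo, ven, clr)
}

#' Convert pixel lengths to millimetres
#'
#' @param length_px length in pixels.
#' @param scale_mm_per_px physical pixel size (default 4.785e-2 mm/px).
#' @return length in mm.
#' @export
pixels_to_mm <- function(length_px, scale_mm_per_px = 4.785e-2) {
  stopifnot(scale_mm_per_px > 0)
  length_px * scale_mm_per_px
}

#' Geometry traits (30) of a normalized leaf
#'
#' @param set normalized [component_set()].
#' @param norm the [normalize_leaf()] result (for the scaling factor); may
#'   be `NULL` (ScalingFactor reported as `NA`).
#' @param axis optional [midrib_axis()] used for the left/right split.
#' @return named numeric vector of the 30 GEO traits.
#' @export
geometry_traits <- function(set, norm = NULL, axis = NULL) {
  m <- set$masks
  bb <- mask_bbox(m$BD)
  if (is.null(bb)) stop("empty blade mask")
  BD_L <- bb[2L] - bb[1L] + 1
  BD_W <- bb[4L] - bb[3L] + 1
  BD_A <- sum(m$BD)
  BD_P <- path_length(trace_boundary(largest_component(m$BD)), closed = TRUE)
  BD_CHA <- hull_area(m$BD)
  ind <- area_indicators(set)
  if (is.null(axis)) axis <- midrib_axis(m$MR)
  sp_lm <- split_left_right(m$LM, axis)
  sp_bd <- split_left_right(m$BD, axis)
  out <- c(BD_L = BD_L, BD_W = BD_W, BD_A = BD_A, BD_P = BD_P,
           BD_CHA = BD_CHA,
           BD_Solidity = if (BD_CHA > 0) BD_A / BD_CHA else NA_real_,
           BD_AspectRatio = BD_L / BD_W,
           ScalingFactor = if (is.null(norm)) NA_real_ else norm$scaling_factor,
           MR_A = sum(m$MR), VS_A = sum(m$VS), VV_A = sum(m$VV),
           LM_A = sum(m$LM), MZ_A = sum(m$MZ),
           ind,
           LM_A_LT = sum(sp_lm$left), LM_A_RT = sum(sp_lm$right),
           BD_A_LT = sum(sp_bd$left), BD_A_RT = sum(sp_bd$right),
           LM_CHA = hull_area(m$LM), VV_CHA = hull_area(m$VV))
  stats::setNames(as.numeric(out), GEO_TRAIT_NAMES)
}

#' @keywords internal
largest_component <- function(mask) {
  lab <- label_components(mask, 8L)
  if (max(lab) <= 1L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

#' Venation traits (20) of a normalized leaf
#'
#' @param arch a [assemble_architecture()] result.
#' @param set normalized [component_set()] (for the VV/VS skeletons and
#'   blade area).
#' @return named numeric vector of the 20 VEN traits.
#' @export
venation_traits <- function(arch, set) {
  vv_sg <- skeletonize_component(set$masks$VV)
  vs_sg <- if (any(set$masks$VS)) skeletonize_component(set$masks$VS) else NULL
  lam <- arch$laminas
  lm1 <- function(side) {
    a <- lam$area[lam$side == side & lam$order == 1]
    if (length(a)) a[1L] else NA_real_
  }
  BD_A <- sum(set$masks$BD)
  out <- c(PE_L = arch$PE_L, MR_L = arch$MR_L, AP_L = arch$AP_L,
           BD_PE_PX = arch$BD_PE_PX,
           LM_N = arch$LM_N, LM_N_LT = arch$LM_N_LT, LM_N_RT = arch$LM_N_RT,
           LM1_A_LT = lm1("left"), LM1_A_RT = lm1("right"),
           LM_Ave_ANG = arch$LM_Ave_ANG, LM_Ave_ANG_LT = arch$LM_Ave_ANG_LT,
           LM_Ave_ANG_RT = arch$LM_Ave_ANG_RT,
           LM_ANG_Std_LT = arch$LM_ANG_Std_LT, LM_ANG_Std_RT = arch$LM_ANG_Std_RT,
           VV_SKL_L = vv_sg$total_length,
           VS_SKL_L = if (is.null(vs_sg)) NA_real_ else vs_sg$total_length,
           SKL_EP_N = nrow(vv_sg$endpoints), SKL_BP_N = nrow(vv_sg$branch_points),
           VeinDensity = vv_sg$total_length / BD_A,
           PE_L_Ratio = arch$PE_L / arch$MR_L)
  stats::setNames(as.numeric(out), VEN_TRAIT_NAMES)
}

#' Color traits (216): per-component channel means and stds in six spaces
#'
#' For each of the six components the masked pixels are converted into
#' RGB, HSV, LAB (8-bit-quantized L*a*b*), LUV (CIE L*u*v*, D65), YCrCb
#' (ITU-R BT.601) and CIELab (floating-point CIE L*a*b*, L in 0-100), and
#' the per-channel mean and population standard deviation (divisor N) are
#' reported.  Empty components yield `NA` for their 36 entries.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param set [component_set()] aligned with `image`.
#' @return named numeric vector of the 216 CLR traits.
#' @export
color_traits <- function(image, set) {
  stopifnot(all(dim(image)[1:2] == dim(set$masks$BD)))
  reg <- trait_registry()
  out <- stats::setNames(rep(NA_real_, 216L), reg$name[reg$group == "CLR"])
  for (comp in COLOR_COMPONENTS) {
    mask <- set$masks[[comp]]
    if (!any(mask)) next
    px <- cbind(image[, , 1L][mask], image[, , 2L][mask], image[, , 3L][mask]) * 255
    for (sp in COLOR_SPACES) {
      ch <- convert_color_space(px, sp)
      for (j in 1:3) {
        out[paste0(comp, "_", sp, "_mean_", j)] <- mean(ch[, j])
        out[paste0(comp, "_", sp, "_std_", j)] <- pop_sd(ch[, j])
      }
    }
  }
  out
}

#' @keywords internal
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Convert 8-bit RGB pixels into one of the six color spaces
#'
#' Conventions: HSV hue in `[0, 360)`, S and V in `[0, 1]`; LAB is the
#' 8-bit quantization of CIE L*a*b* (`L*255/100`, `a+128`, `b+128`,
#' clipped to 0-255); CIELab is floating-point CIE L*a*b* (L in 0-100);
#' LUV is CIE L*u*v*; YCrCb follows ITU-R BT.601 with full-range 0-255
#' luma and offset-128 chroma.  sRGB primaries and D65 white throughout.
#'
#' @param px n x 3 matrix of RGB values on the 0-255 scale.
#' @param space one of `"RGB"`, `"HSV"`, `"LAB"`, `"LUV"`, `"YCrCb"`,
#'   `"CIELab"`.
#' @return n x 3 matrix of channel values.
#' @export
convert_color_space <- function(px, space = COLOR_SPACES) {
  space <- match.arg(space)
  px <- matrix(px, ncol = 3L)
  out <- switch(space,
    RGB = px,
    HSV = {
      h <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
      cbind(h[1L, ] * 360, h[2L, ], h[3L, ])
    },
    LAB = {
      lab <- grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
      q <- cbind(lab[, 1L] * 255 / 100, lab[, 2L] + 128, lab[, 3L] + 128)
      q[q < 0] <- 0; q[q > 255] <- 255
      q
    },
    CIELab = grDevices::convertColor(px / 255, from = "sRGB", to = "Lab"),
    LUV = grDevices::convertColor(px / 255, from = "sRGB", to = "Luv"),
    YCrCb = {
      y <- 0.299 * px[, 1L] + 0.587 * px[, 2L] + 0.114 * px[, 3L]
      cr <- (px[, 1L] - y) * 0.713 + 128
      cb <- (px[, 3L] - y) * 0.564 + 128
      cbind(y, cr, cb)
    })
  dimnames(out) <- NULL
  out
}

#' Full 266-trait vector of one normalized leaf
#'
#' @param norm a [normalize_leaf()] (optionally [flip_to_canonical()])
#'   result.
#' @param arch optional [assemble_architecture()] result (computed from the
#'   normalized masks if missing).
#' @param r,tolerance,min_area architecture parameters, see
#'   [assemble_architecture()].
#' @return one-row data frame: `leaf_id`, `orientation`, then the 266
#'   traits in registry order.
#' @export
extract_traits <- function(norm, arch = NULL, r = 5L, tolerance = 5,
                           min_area = 25) {
  s <- norm$sample
  set <- s$components
  if (is.null(arch))
    arch <- assemble_architecture(set$masks$MR, set$masks$LM, set$masks$VS,
                                  r = r, tolerance = tolerance, min_area = min_area)
  geo <- geometry_traits(set, norm, axis = arch$axis)
  ven <- venation_traits(arch, set)
  clr <- color_traits(s$image, set)
  vals <- c(geo, ven, clr)
  reg <- trait_registry()
  stopifnot(identical(names(vals), reg$name))
  cbind(data.frame(leaf_id = s$id, orientation = s$orientation,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(vals), optional = TRUE))
}
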