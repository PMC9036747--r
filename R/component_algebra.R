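# Mask I/O and the set algebra of the six semantic components.
#
# A leaf decomposes into blade (BD), mid-rib (MR), second-order veins (VS)
# and laminas (LM); venation (VV = MR u VS) and the marginal zone
# (MZ = BD \ (VV u LM)) are derived from them.

COMPONENT_KEYS <- c("BD", "MR", "VS", "LM", "VV", "MZ")

#' Bundle the six component masks of one leaf
#'
#' Missing `VV`/`MZ` entries are derived ([derive_venation()],
#' [derive_marginal_zone()]) and flagged as such.
#'
#' @param masks named list of logical matrices; must contain at least
#'   `BD`, `MR`, `VS`, `LM`, all of identical dimensions.
#' @param provenance named character vector, `"annotated"` or `"derived"`
#'   per component; filled in automatically for derived masks.
#' @return object of class `component_set` with elements `masks` and
#'   `provenance`.
#' @export
component_set <- function(masks, provenance = NULL) {
  need <- c("BD", "MR", "VS", "LM")
  if (!all(need %in% names(masks)))
    stop("component_set requires masks BD, MR, VS, LM")
  masks <- lapply(masks, as_mask)
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- names(masks)[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1L]]
    stop(sprintf("mask dimension mismatch: '%s' is %dx%d but 'BD' is %dx%d",
                 bad, dims[1, bad], dims[2, bad], dims[1, "BD"], dims[2, "BD"]))
  }
  if (is.null(provenance))
    provenance <- stats::setNames(rep("annotated", length(masks)), names(masks))
  if (!"VV" %in% names(masks)) {
    masks$VV <- derive_venation(masks$MR, masks$VS)
    provenance["VV"] <- "derived"
  }
  if (!"MZ" %in% names(masks)) {
    masks$MZ <- derive_marginal_zone(masks$BD, masks$VV, masks$LM)
    provenance["MZ"] <- "derived"
  }
  structure(list(masks = masks[COMPONENT_KEYS],
                 provenance = provenance[COMPONENT_KEYS]),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  a <- vapply(x$masks, sum, numeric(1))
  cat("<component_set>", paste(sprintf("%s=%d(%s)", names(a), a,
                                       substr(x$provenance, 1, 1)), collapse = " "), "\n")
  invisible(x)
}

#' Venation: union of mid-rib and second-order veins
#'
#' @param MR,VS logical matrices of equal dimensions.
#' @return logical matrix `MR | VS`.
#' @export
derive_venation <- function(MR, VS) {
  MR <- as_mask(MR); VS <- as_mask(VS)
  stopifnot(all(dim(MR) == dim(VS)))
  MR | VS
}

#' Marginal zone: blade minus venation minus laminas
#'
#' @param BD,VV,LM logical matrices of equal dimensions.
#' @return logical matrix `BD & !VV & !LM`.
#' @export
derive_marginal_zone <- function(BD, VV, LM) {
  BD <- as_mask(BD); VV <- as_mask(VV); LM <- as_mask(LM)
  stopifnot(all(dim(BD) == dim(VV)), all(dim(BD) == dim(LM)))
  BD & !VV & !LM
}

#' Load a component set from PNG masks
#'
#' Reads `<id>_<KEY>.png` files (8-bit; any pixel above 127/255 is
#' foreground).  Missing `VV`/`MZ` files are derived and flagged.
#'
#' @param paths named character vector of file paths keyed by component
#'   (at least `BD`, `MR`, `VS`, `LM`), or a directory combined with `id`.
#' @param id leaf identifier used when `paths` is a directory.
#' @return a [component_set()].
#' @export
load_component_set <- function(paths, id = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    stopifnot(!is.null(id))
    paths <- stats::setNames(file.path(paths, paste0(id, "_", COMPONENT_KEYS, ".png")),
                             COMPONENT_KEYS)
    paths <- paths[file.exists(paths)]
  }
  masks <- lapply(paths, function(f) as_mask(png::readPNG(f) * 255))
  dims <- vapply(masks, dim, integer(2))
  if (length(masks) > 1L && (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))) {
    j <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1L]
    stop(sprintf("mask dimension mismatch between '%s' (%dx%d) and '%s' (%dx%d)",
                 paths[[j]], dims[1, j], dims[2, j], paths[[1L]], dims[1, 1], dims[2, 1]))
  }
  prov <- stats::setNames(rep("annotated", length(masks)), names(masks))
  component_set(masks, provenance = prov)
}

#' Save a component set as 0/255 PNG masks
#'
#' @param set a [component_set()].
#' @param dir output directory.
#' @param id leaf identifier prefix.
#' @return invisibly, the written paths.
#' @export
save_component_set <- function(set, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in names(set$masks)) {
    f <- file.path(dir, paste0(id, "_", k, ".png"))
    png::writePNG(set$masks[[k]] * 1.0, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Area-ratio and overlap indicators of the component set
#'
#' Component-to-blade percentages `X_A_Ratio = 100 |X| / |BD|` for
#' X in MR, VS, VV, LM, MZ; pairwise ratios `MR_VS_A_Ratio`,
#' `MR_VV_A_Ratio`, `VS_VV_A_Ratio`; and the three excess-area overlap
#' indicators `EVA_X_Y_2_Z = 100 (|X| + |Y| - |Z|) / |Z|`, which equal 0
#' exactly when X and Y partition Z and grow with the overlap (or shared
#' deficit) of the pair relative to the reference component.
#'
#' Indicators with an empty denominator are reported as `NA` (serialized as
#' empty cells), never as 0.
#'
#' @param set a [component_set()].
#' @return named numeric vector of 11 percentages.
#' @export
area_indicators <- function(set) {
  a <- vapply(set$masks, sum, numeric(1))
  if (a[["BD"]] == 0) stop("empty blade mask")
  rat <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(MR_A_Ratio = rat(a[["MR"]], a[["BD"]]),
    VS_A_Ratio = rat(a[["VS"]], a[["BD"]]),
    VV_A_Ratio = rat(a[["VV"]], a[["BD"]]),
    LM_A_Ratio = rat(a[["LM"]], a[["BD"]]),
    MZ_A_Ratio = rat(a[["MZ"]], a[["BD"]]),
    MR_VS_A_Ratio = rat(a[["MR"]], a[["VS"]]),
    MR_VV_A_Ratio = rat(a[["MR"]], a[["VV"]]),
    VS_VV_A_Ratio = rat(a[["VS"]], a[["VV"]]),
    EVA_MR_VS_2_VV = rat(a[["MR"]] + a[["VS"]] - a[["VV"]], a[["VV"]]),
    EVA_LM_VV_2_BD = rat(a[["LM"]] + a[["VV"]] - a[["BD"]], a[["BD"]]),
    EVA_MZ_LM_2_BD = rat(a[["MZ"]] + a[["LM"]] - a[["BD"]], a[["BD"]]))
}
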