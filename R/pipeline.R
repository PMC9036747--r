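# Orchestration: run the full phenotyping flow over a directory of leaves
# (load masks -> derive components -> normalize -> flip -> architecture ->
# traits) with per-leaf failure isolation and a config echo for provenance.

#' Pipeline configuration
#'
#' @param normalized_width target blade width after normalization, px.
#' @param dp_tolerance Douglas-Peucker tolerance, px.
#' @param adjacency_radius mid-rib dilation radius for lamina adjacency, px.
#' @param min_lamina_area smallest lamina kept, px^2.
#' @param scale_mm_per_px physical pixel size, mm/px.
#' @param flip_policy `"back"` (mirror back leaves) or `"never"`.
#' @param linkage clustering linkage.
#' @param k number of clusters.
#' @param seed integer seed.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(normalized_width = 500L, dp_tolerance = 5,
                            adjacency_radius = 5L, min_lamina_area = 25,
                            scale_mm_per_px = 4.785e-2,
                            flip_policy = c("back", "never"),
                            linkage = "ward", k = 4L, seed = 1L) {
  flip_policy <- match.arg(flip_policy)
  stopifnot(normalized_width > 0, dp_tolerance > 0, adjacency_radius > 0,
            min_lamina_area > 0, scale_mm_per_px > 0, k >= 1)
  structure(list(normalized_width = as.integer(normalized_width),
                 dp_tolerance = dp_tolerance,
                 adjacency_radius = as.integer(adjacency_radius),
                 min_lamina_area = min_lamina_area,
                 scale_mm_per_px = scale_mm_per_px,
                 flip_policy = flip_policy, linkage = linkage,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Phenotype one leaf sample end to end
#'
#' @param sample a `leaf_sample`.
#' @param config a [pipeline_config()].
#' @return list `norm`, `arch`, `traits` (one-row data frame).
#' @export
phenotype_leaf <- function(sample, config = pipeline_config()) {
  norm <- normalize_leaf(sample, width = config$normalized_width)
  norm <- flip_to_canonical(norm, policy = config$flip_policy)
  m <- norm$sample$components$masks
  arch <- assemble_architecture(m$MR, m$LM, m$VS,
                                r = config$adjacency_radius,
                                tolerance = config$dp_tolerance,
                                min_area = config$min_lamina_area)
  traits <- extract_traits(norm, arch)
  list(norm = norm, arch = arch, traits = traits)
}

#' Run the pipeline over a directory of leaves
#'
#' Leaves are discovered from `<id>_BD.png` files; each leaf needs the
#' `BD`, `MR`, `VS`, `LM` masks and an `<id>_rgb.png` image (orientation is
#' read from `<id>_truth.json` when present).  Per-leaf failures are
#' logged, flagged invalid and skipped; they do not abort the run.
#'
#' @param input_dir directory with per-leaf PNGs.
#' @param out_dir output directory; receives `traits.csv`,
#'   `normalization.csv`, per-leaf `<id>_arch.json` and `config.json`.
#' @param config a [pipeline_config()].
#' @return invisibly, list `traits` (data frame), `n_ok`, `n_failed`,
#'   `failed` (ids).
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  bd <- sort(list.files(input_dir, pattern = "_BD\\.png$", full.names = FALSE))
  if (length(bd) == 0L) stop("no '<id>_BD.png' masks found in ", input_dir)
  ids <- sub("_BD\\.png$", "", bd)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  traits <- NULL; norm_rows <- NULL; failed <- character(0)
  for (id in ids) {
    res <- tryCatch({
      cs <- load_component_set(input_dir, id = id)
      img <- png::readPNG(file.path(input_dir, paste0(id, "_rgb.png")))
      if (length(dim(img)) == 3L && dim(img)[3L] > 3L) img <- img[, , 1:3]
      orientation <- "positive"
      tj <- file.path(input_dir, paste0(id, "_truth.json"))
      if (file.exists(tj)) {
        tr <- jsonlite::read_json(tj)
        if (!is.null(tr$orientation)) orientation <- tr$orientation
      }
      sample <- leaf_sample(id, img, cs, orientation = orientation,
                            scale_mm_per_px = config$scale_mm_per_px)
      ph <- phenotype_leaf(sample, config)
      arch_path <- file.path(out_dir, paste0(id, "_arch.json"))
      jsonlite::write_json(architecture_report(ph$arch), arch_path,
                           auto_unbox = TRUE, digits = NA)
      list(traits = ph$traits,
           norm = data.frame(leaf_id = id, orientation = orientation,
                             scaling_factor = ph$norm$scaling_factor,
                             rotation_deg = ph$norm$rotation_applied,
                             flipped = ph$norm$flipped,
                             stringsAsFactors = FALSE))
    }, error = function(e) {
      message(sprintf("leaf '%s' flagged invalid: %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- c(failed, id); next }
    traits <- rbind(traits, res$traits)
    norm_rows <- rbind(norm_rows, res$norm)
  }
  if (!is.null(traits))
    utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE, na = "")
  if (!is.null(norm_rows))
    utils::write.csv(norm_rows, file.path(out_dir, "normalization.csv"),
                     row.names = FALSE, na = "")
  reg <- trait_registry()
  jsonlite::write_json(reg, file.path(out_dir, "traits_schema.json"),
                       dataframe = "rows")
  invisible(list(traits = traits, n_ok = length(ids) - length(failed),
                 n_failed = length(failed), failed = failed))
}

#' @keywords internal
architecture_report <- function(arch) {
  list(PE_L = arch$PE_L, AP_L = arch$AP_L, MR_L = arch$MR_L,
       BD_PE_PX = arch$BD_PE_PX,
       LM_N = arch$LM_N, LM_N_LT = arch$LM_N_LT, LM_N_RT = arch$LM_N_RT,
       LM_ANG_List_LT = arch$LM_ANG_List_LT,
       LM_ANG_List_RT = arch$LM_ANG_List_RT,
       LM_Ave_ANG = arch$LM_Ave_ANG,
       LM_Ave_ANG_LT = arch$LM_Ave_ANG_LT,
       LM_Ave_ANG_RT = arch$LM_Ave_ANG_RT,
       laminas = arch$laminas)
}
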