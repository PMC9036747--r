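# Shared fixtures: a scaled-down leaf for fast unit tests, and a cache so
# the expensive generate/normalize steps run once per session.

small_params <- function(seed = 1L, ...) {
  args <- list(blade_length = 360, blade_width = 260, midrib_curvature = 0.05,
               petiole_length = 70, petiole_width = 16, vein_width = 6,
               n_veins_left = 3, n_veins_right = 3,
               marginal_band_width = 8, seed = seed)
  do.call(leaf_params, utils::modifyList(args, list(...)))
}

.leaf_cache <- new.env(parent = emptyenv())

cached_leaf <- function(key, maker) {
  if (is.null(.leaf_cache[[key]])) .leaf_cache[[key]] <- maker()
  .leaf_cache[[key]]
}

small_leaf <- function(seed = 1L, ...) {
  key <- paste0("leaf", seed, paste(c(...), collapse = "_"))
  cached_leaf(key, function() generate_leaf(small_params(seed, ...)))
}

small_norm <- function(seed = 1L) {
  key <- paste0("norm", seed)
  cached_leaf(key, function() normalize_leaf(small_leaf(seed)$sample))
}

small_arch <- function(seed = 1L) {
  key <- paste0("arch", seed)
  cached_leaf(key, function() {
    m <- small_norm(seed)$sample$components$masks
    assemble_architecture(m$MR, m$LM, m$VS)
  })
}

random_mask <- function(nr = 32L, nc = 32L, p = 0.3) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
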