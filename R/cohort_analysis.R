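# Cohort-level statistics: agreement with manual measurement, trait
# differences between positive and back leaves, decision-tree color
# feature importance, PCA of the trait sets and hierarchical clustering.

#' Agreement between manual and computed trait values
#'
#' `R2 = 1 - SS_res / SS_tot` of the computed values against the manual
#' values, mean absolute error and mean absolute percentage error.
#'
#' @param manual,computed numeric vectors of equal length (>= 2).
#' @return list `R2` (NA when the manual values have zero variance), `MAE`,
#'   `MAPE` (percent; NA when any manual value is 0), `n`.
#' @export
agreement_stats <- function(manual, computed) {
  stopifnot(length(manual) == length(computed), length(manual) >= 2L)
  d <- computed - manual
  ss_tot <- sum((manual - mean(manual))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(d^2) / ss_tot
  mape <- if (any(manual == 0)) NA_real_ else mean(abs(d / manual)) * 100
  list(R2 = r2, MAE = mean(abs(d)), MAPE = mape, n = length(manual))
}

#' Per-trait positive-back differences
#'
#' Signed percentage difference relative to the positive leaf,
#' `PB_X = 100 (X_pos - X_back) / X_pos`, so deficits on the positive side
#' are negative.  Traits with `X_pos = 0` are reported as `NA`.
#'
#' @param pos,back one-row trait data frames (e.g. [extract_traits()]
#'   output) or named numeric vectors for the same leaf.
#' @return named numeric vector of PB values (percent), with attribute
#'   `sign_convention`.
#' @export
positive_back_difference <- function(pos, back) {
  to_vec <- function(x) {
    if (is.data.frame(x)) {
      num <- vapply(x, is.numeric, logical(1))
      stats::setNames(as.numeric(x[1L, num]), names(x)[num])
    } else x
  }
  p <- to_vec(pos); b <- to_vec(back)
  shared <- intersect(names(p), names(b))
  p <- p[shared]; b <- b[shared]
  pb <- ifelse(is.na(p) | is.na(b) | p == 0, NA_real_, 100 * (p - b) / p)
  structure(stats::setNames(pb, paste0("PB_", shared)),
            sign_convention = "100*(pos-back)/pos")
}

#' Decision-tree feature importance
#'
#' Fits a single classification tree (CART, Gini impurity) and reports the
#' per-feature importance scores scaled to percent (summing to 100 over
#' the features with nonzero importance).  Importance is the summed
#' impurity improvement of each feature's primary splits; surrogate and
#' competitor splits are excluded so uninformative features cannot borrow
#' credit from correlated ones.
#'
#' @param features data frame or matrix of numeric features (no missing
#'   values in used columns).
#' @param labels class labels (>= 2 classes).
#' @param seed integer seed (tree fitting is deterministic given the data;
#'   the seed pins any tie-breaking).
#' @return named numeric vector: importance in percent, descending;
#'   features with zero importance are omitted.
#' @export
tree_feature_importance <- function(features, labels, seed = 1L) {
  features <- as.data.frame(features)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need at least two classes")
  seed_keep <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, envir = globalenv()))
  set.seed(seed)
  dat <- cbind(.class = labels, features)
  fit <- rpart::rpart(.class ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(minsplit = 4L, cp = 0.0,
                                                     xval = 0L, maxcompete = 0L,
                                                     maxsurrogate = 0L))
  sp <- fit$splits
  if (is.null(sp) || nrow(sp) == 0L) {
    warning("tree has no splits; all importances zero")
    return(stats::setNames(numeric(0), character(0)))
  }
  imp <- tapply(sp[, "improve"], rownames(sp), sum)
  imp <- stats::setNames(as.numeric(imp), names(imp))
  sort(100 * imp / sum(imp), decreasing = TRUE)
}

#' Top principal components of a trait set
#'
#' Columns are z-score standardized (constant columns dropped with a
#' warning) before the decomposition.
#'
#' @param features numeric data frame/matrix with at least `n_components+1`
#'   rows.
#' @param n_components number of components to keep (default 10).
#' @return list `scores` (n x k matrix), `explained` (variance fractions of
#'   the kept components, non-increasing), `loadings`, `sdev` (all
#'   components), `kept` (names of the columns used).
#' @export
pca_top10 <- function(features, n_components = 10L) {
  X <- as.matrix(as.data.frame(features))
  stopifnot(nrow(X) > n_components)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning(sprintf("dropping %d constant column(s) before PCA", sum(sds == 0 | is.na(sds))))
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pr$x))
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)],
       loadings = pr$rotation[, seq_len(k), drop = FALSE],
       sdev = pr$sdev, kept = colnames(X))
}

#' Hierarchical clustering of PC scores
#'
#' Agglomerative clustering on Euclidean distances, Ward linkage by
#' default, cut into `k` groups.
#'
#' @param scores numeric matrix (e.g. `pca_top10()$scores`).
#' @param k number of clusters (1 <= k <= rows).
#' @param linkage `"ward"`, `"single"`, `"complete"` or `"average"`.
#' @return integer vector of cluster labels (1..k) with attribute
#'   `hclust` (the dendrogram object).
#' @export
hierarchical_cluster <- function(scores, k = 4L, linkage = c("ward", "single",
                                                             "complete", "average")) {
  linkage <- match.arg(linkage)
  scores <- as.matrix(scores)
  if (k < 1L || k > nrow(scores)) stop("k must be between 1 and the number of rows")
  method <- c(ward = "ward.D2", single = "single", complete = "complete",
              average = "average")[[linkage]]
  hc <- stats::hclust(stats::dist(scores, method = "euclidean"), method = method)
  structure(stats::cutree(hc, k = k), hclust = hc)
}

#' PCA + clustering over the four trait sets
#'
#' Convenience wrapper running [pca_top10()] and [hierarchical_cluster()]
#' for the GEO, VEN, CLR and COM (all 266) feature sets of a trait table
#' and assembling the 40-PC correlation matrix.
#'
#' @param traits trait table ([extract_traits()] rows).
#' @param sets subset of `c("GEO", "VEN", "CLR", "COM")`.
#' @param k clusters per set.
#' @param linkage see [hierarchical_cluster()].
#' @param n_components PCs per set.
#' @return list per set with `pca`, `labels`; plus `pc_correlation` (the
#'   correlation matrix of all kept PC scores across sets).
#' @export
cluster_trait_sets <- function(traits, sets = c("GEO", "VEN", "CLR", "COM"),
                               k = 4L, linkage = "ward", n_components = 10L) {
  reg <- trait_registry()
  out <- list()
  all_scores <- NULL
  for (s in sets) {
    cols <- if (s == "COM") reg$name else reg$name[reg$group == s]
    cols <- intersect(cols, colnames(traits))
    X <- traits[, cols, drop = FALSE]
    X <- X[, colSums(is.na(X)) == 0L, drop = FALSE]
    pca <- pca_top10(X, n_components = n_components)
    labels <- hierarchical_cluster(pca$scores, k = k, linkage = linkage)
    out[[s]] <- list(pca = pca, labels = labels)
    sc <- pca$scores
    colnames(sc) <- paste0(s, "_PC", seq_len(ncol(sc)))
    all_scores <- if (is.null(all_scores)) sc else cbind(all_scores, sc)
  }
  out$pc_correlation <- stats::cor(all_scores)
  out
}
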