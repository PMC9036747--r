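test_that("agreement statistics match direct formula evaluation", {
  m <- c(10, 12, 14, 16)
  expect_equal(agreement_stats(m, m), list(R2 = 1, MAE = 0, MAPE = 0, n = 4))
  shifted <- agreement_stats(m, m + 3)
  expect_equal(shifted$MAE, 3)
  # random vectors against an independent formula oracle
  set.seed(11)
  for (i in 1:10) {
    a <- stats::runif(10, 1, 100); b <- a + stats::rnorm(10, 0, 5)
    st <- agreement_stats(a, b)
    expect_equal(st$R2, 1 - sum((b - a)^2) / sum((a - mean(a))^2))
    expect_equal(st$MAE, sum(abs(b - a)) / 10)
    expect_equal(st$MAPE, 100 * sum(abs((b - a) / a)) / 10)
  }
  # zero variance in the manual values: R2 undefined
  expect_true(is.na(agreement_stats(rep(5, 4), 1:4)$R2))
  expect_error(agreement_stats(1:3, 1:4))
})

test_that("positive-back differences follow the signed convention", {
  p <- c(A = 100, B = 50, C = 0)
  b <- c(A = 50, B = 60, C = 10)
  pb <- positive_back_difference(p, b)
  expect_equal(unname(pb[["PB_A"]]), 50)
  expect_equal(unname(pb[["PB_B"]]), -20)
  expect_true(is.na(pb[["PB_C"]]))          # zero positive value: undefined
  expect_true(all(positive_back_difference(p, p)[c("PB_A", "PB_B")] == 0))
  # antisymmetry: PB(p,b) = -PB(b,p) * b/p
  pb_rev <- positive_back_difference(b, p)
  expect_equal(unname(pb[["PB_A"]]),
               -unname(pb_rev[["PB_A"]]) * b[["A"]] / p[["A"]])
})

test_that("decision-tree importance finds the informative feature", {
  set.seed(3)
  n <- 200
  lab <- rep(c("pos", "back"), each = n / 2)
  X <- data.frame(signal = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 6)),
                  noise1 = stats::rnorm(n), noise2 = stats::rnorm(n),
                  noise3 = stats::rnorm(n))
  imp <- tree_feature_importance(X, lab, seed = 1)
  expect_equal(sum(imp), 100, tolerance = 1e-9)
  expect_gte(imp[["signal"]], 95)
  # duplicated informative columns share the importance, total unchanged
  X2 <- X; X2$signal2 <- X$signal
  imp2 <- tree_feature_importance(X2, lab, seed = 1)
  expect_equal(sum(imp2[intersect(c("signal", "signal2"), names(imp2))]),
               imp[["signal"]], tolerance = 5)
  # all-noise features never dominate strongly
  set.seed(5)
  maxi <- replicate(20, {
    Xn <- as.data.frame(matrix(stats::rnorm(200 * 5), 200))
    max(tree_feature_importance(Xn, rep(c("a", "b"), 100), seed = 1))
  })
  expect_true(all(maxi <= 60))
  expect_error(tree_feature_importance(X, rep("a", n)), "two classes")
})

test_that("PCA matches an eigendecomposition oracle and orders variance", {
  set.seed(21)
  X <- matrix(stats::rnorm(20 * 6), 20, 6)
  res <- pca_top10(X, n_components = 6)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-9)
  # oracle: eigendecomposition of the correlation matrix
  Z <- scale(X)
  eig <- eigen(stats::cov(Z))
  expect_equal(res$explained, eig$values[1:6] / sum(eig$values), tolerance = 1e-8)
  for (k in 1:6) {
    sc_o <- Z %*% eig$vectors[, k]
    agree <- max(abs(res$scores[, k] - sc_o), abs(res$scores[, k] + sc_o))
    expect_lt(min(max(abs(res$scores[, k] - sc_o)),
                  max(abs(res$scores[, k] + sc_o))), 1e-8)
  }
  # orthogonal scores
  G <- crossprod(res$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # planar data: two components explain everything
  B <- matrix(stats::rnorm(30 * 2), 30, 2)
  P <- B %*% matrix(stats::rnorm(20), 2, 10)
  resP <- pca_top10(P, n_components = 5)
  expect_equal(sum(resP$explained[1:2]), 1, tolerance = 1e-9)
  # constant columns dropped with a warning
  Xc <- cbind(X, 7)
  expect_warning(pca_top10(Xc, n_components = 3), "constant")
})

test_that("hierarchical clustering recovers separated blobs", {
  set.seed(9)
  blob <- function(cx, cy, n) cbind(stats::rnorm(n, cx, 0.3), stats::rnorm(n, cy, 0.3))
  X2 <- rbind(blob(0, 0, 20), blob(8, 8, 20))
  lab2 <- hierarchical_cluster(X2, k = 2)
  expect_equal(length(unique(lab2[1:20])), 1)
  expect_equal(length(unique(lab2[21:40])), 1)
  expect_false(lab2[1] == lab2[21])
  X4 <- rbind(blob(0, 0, 10), blob(10, 0, 10), blob(0, 10, 10), blob(10, 10, 10))
  lab4 <- hierarchical_cluster(X4, k = 4)
  truth <- rep(1:4, each = 10)
  expect_equal(length(unique(paste(lab4, truth))), 4)   # perfect agreement
  # k = n: every point its own cluster
  labn <- hierarchical_cluster(X2[1:6, ], k = 6)
  expect_equal(sort(unname(labn)), 1:6)
  expect_error(hierarchical_cluster(X2, k = 0))
})

test_that("cluster_trait_sets assembles per-set PCs and their correlations", {
  set.seed(13)
  reg <- trait_registry()
  n <- 25
  fake <- as.data.frame(matrix(stats::rnorm(n * 266), n, 266))
  colnames(fake) <- reg$name
  res <- cluster_trait_sets(fake, sets = c("GEO", "VEN"), k = 3, n_components = 4)
  expect_equal(ncol(res$GEO$pca$scores), 4)
  expect_equal(length(res$GEO$labels), n)
  expect_equal(dim(res$pc_correlation), c(8, 8))
  expect_true(all(abs(diag(res$pc_correlation) - 1) < 1e-9))
})
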