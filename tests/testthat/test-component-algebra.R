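test_that("derived components obey the set identities on random masks", {
  set.seed(42)
  for (i in 1:100) {
    MR <- random_mask(); VS <- random_mask()
    VV <- derive_venation(MR, VS)
    # |VV| = |MR| + |VS| - |MR & VS|, checked by brute-force pixel count
    expect_identical(sum(VV), sum(MR) + sum(VS) - sum(MR & VS))
    BD <- random_mask(p = 0.7); LM <- random_mask(p = 0.4)
    MZ <- derive_marginal_zone(BD, VV, LM)
    expect_identical(sum(MZ), sum(BD) - sum(BD & (VV | LM)))
    expect_false(any(MZ & (VV | LM)))
  }
})

test_that("degenerate unions behave as set algebra dictates", {
  a <- matrix(FALSE, 5, 5); a[2, 2] <- TRUE
  b <- matrix(FALSE, 5, 5); b[4, 4] <- TRUE
  expect_equal(sum(derive_venation(a, b)), 2)
  expect_identical(derive_venation(a, a), a)
  BD <- matrix(TRUE, 5, 5)
  expect_identical(derive_marginal_zone(BD, a & FALSE, a & FALSE), BD)
  expect_false(any(derive_marginal_zone(BD, BD, BD & FALSE)))
})

test_that("component_set derives missing masks, flags them, and re-derivation is idempotent", {
  g <- small_leaf(1L)
  m <- g$sample$components$masks
  cs <- component_set(m[c("BD", "MR", "VS", "LM")])
  expect_identical(cs$masks$VV, m$MR | m$VS)
  expect_identical(cs$masks$MZ, m$BD & !cs$masks$VV & !m$LM)
  expect_equal(unname(cs$provenance[c("VV", "MZ")]), c("derived", "derived"))
  expect_equal(unname(cs$provenance[["BD"]]), "annotated")
  cs2 <- component_set(cs$masks[c("BD", "MR", "VS", "LM")])
  expect_identical(cs2$masks$VV, cs$masks$VV)
  expect_identical(cs2$masks$MZ, cs$masks$MZ)
})

test_that("PNG round trip preserves masks and thresholds 0/1 like 0/255", {
  g <- small_leaf(1L)
  dir <- withr::local_tempdir()
  save_component_set(g$sample$components, dir, "x")
  cs <- load_component_set(dir, id = "x")
  for (k in names(cs$masks))
    expect_identical(cs$masks[[k]], g$sample$components$masks[[k]])
  # a 0/1-valued and a 0/255-valued PNG load to the same mask
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  png::writePNG(m, file.path(dir, "a_BD.png"))          # 0/255 on disk
  png::writePNG(m / 255, file.path(dir, "b_BD.png"))    # 0/1 on disk
  a <- as_mask(png::readPNG(file.path(dir, "a_BD.png")) * 255)
  b <- as_mask(png::readPNG(file.path(dir, "b_BD.png")) * 255)
  expect_identical(a, m > 0)
  expect_identical(b, m > 0)
})

test_that("dimension mismatch is a hard error naming the offending file", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(1, 4, 4), file.path(dir, "y_BD.png"))
  png::writePNG(matrix(1, 5, 4), file.path(dir, "y_MR.png"))
  png::writePNG(matrix(1, 4, 4), file.path(dir, "y_VS.png"))
  png::writePNG(matrix(1, 4, 4), file.path(dir, "y_LM.png"))
  expect_error(load_component_set(dir, id = "y"), "y_MR\\.png")
})

test_that("area indicators implement the stated ratios and handle empties", {
  BD <- matrix(FALSE, 20, 20); BD[3:12, 3:12] <- TRUE      # |BD| = 100
  MR <- matrix(FALSE, 20, 20); MR[3:7, 3] <- TRUE          # |MR| = 5
  VS <- matrix(FALSE, 20, 20); VS[3:12, 4] <- TRUE         # |VS| = 10
  LM <- matrix(FALSE, 20, 20); LM[3:12, 6:10] <- TRUE      # |LM| = 50
  cs <- component_set(list(BD = BD, MR = MR, VS = VS, LM = LM))
  ind <- area_indicators(cs)
  expect_equal(ind[["MR_A_Ratio"]], 5)
  expect_equal(ind[["VS_A_Ratio"]], 10)
  expect_equal(ind[["LM_A_Ratio"]], 50)
  expect_equal(ind[["MR_VS_A_Ratio"]], 50)
  # partition identity: LM% + VV% - overlap% + MZ% = 100
  ov <- 100 * sum(cs$masks$LM & cs$masks$VV) / sum(BD)
  expect_equal(ind[["LM_A_Ratio"]] + ind[["VV_A_Ratio"]] - ov + ind[["MZ_A_Ratio"]], 100)
  # EVA of a perfect partition is 0
  expect_equal(ind[["EVA_MZ_LM_2_BD"]],
               100 * (sum(cs$masks$MZ) + sum(LM) - sum(BD)) / sum(BD))
  # empty denominators give NA, not 0
  cs2 <- component_set(list(BD = BD, MR = MR, VS = MR & FALSE, LM = LM))
  ind2 <- area_indicators(cs2)
  expect_true(is.na(ind2[["MR_VS_A_Ratio"]]))
  expect_error(area_indicators(component_set(list(BD = BD & FALSE, MR = MR,
                                                  VS = VS, LM = LM))), "empty blade")
})

test_that("area ratios are invariant under uniform rescaling within 1%", {
  # full-size leaf: the relative resampling error of the thinnest strokes
  # bounds this invariance, so it is asserted at the study scale
  g <- cached_leaf("fullscale1", function() generate_leaf(leaf_params(seed = 1)))
  ind0 <- area_indicators(g$sample$components)
  s2 <- apply_rigid_transform(g$sample, scale = 1.5)
  ind1 <- area_indicators(s2$components)
  for (k in names(ind0))
    expect_lt(abs(ind1[[k]] - ind0[[k]]) / max(abs(ind0[[k]]), 1), 0.01)
})
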