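test_that("trait registry defines 266 uniquely named traits in stable order", {
  reg <- trait_registry()
  expect_equal(nrow(reg), 266)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(sum(reg$group == "GEO"), 30)
  expect_equal(sum(reg$group == "VEN"), 20)
  expect_equal(sum(reg$group == "CLR"), 216)
  expect_identical(reg$name, trait_registry()$name)
  # color names follow <COMP>_<SPACE>_<stat>_<ch>
  expect_true(all(grepl("^(BD|MR|VS|LM|VV|MZ)_(RGB|HSV|LAB|LUV|YCrCb|CIELab)_(mean|std)_[123]$",
                        reg$name[reg$group == "CLR"])))
})

test_that("geometry traits on a solid rectangle blade match closed forms", {
  BD <- matrix(FALSE, 140, 520); BD[21:120, 11:510] <- TRUE   # 100 x 500
  MR <- matrix(FALSE, 140, 520); MR[21:120, 256:263] <- TRUE
  VS <- matrix(FALSE, 140, 520); VS[40, 100:200] <- TRUE
  LM <- matrix(FALSE, 140, 520); LM[90:110, 50:200] <- TRUE
  cs <- component_set(list(BD = BD, MR = MR, VS = VS, LM = LM))
  geo <- geometry_traits(cs, NULL)
  expect_equal(geo[["BD_A"]], 50000)
  expect_equal(geo[["BD_Solidity"]], 1.0, tolerance = 0.01)
  expect_equal(geo[["BD_L"]], 100)
  expect_equal(geo[["BD_W"]], 500)
  expect_equal(geo[["BD_AspectRatio"]], geo[["BD_L"]] / geo[["BD_W"]])
  expect_true(is.na(geo[["ScalingFactor"]]))
  expect_equal(length(geo), 30)
})

test_that("color traits: constant components have zero std and exact means", {
  H <- 40; W <- 40
  img <- array(0, c(H, W, 3))
  img[, , 1] <- 120 / 255; img[, , 2] <- 180 / 255; img[, , 3] <- 90 / 255
  BD <- matrix(TRUE, H, W)
  MR <- matrix(FALSE, H, W); MR[, 20] <- TRUE
  VS <- matrix(FALSE, H, W); VS[20, ] <- TRUE
  LM <- matrix(FALSE, H, W); LM[1:10, 1:10] <- TRUE
  cs <- component_set(list(BD = BD, MR = MR, VS = VS, LM = LM))
  clr <- color_traits(img, cs)
  expect_equal(length(clr), 216)
  stds <- clr[grepl("^BD_.*_std_", names(clr))]
  expect_true(all(abs(stds) < 1e-9))
  expect_equal(unname(clr[["BD_RGB_mean_1"]]), 120)
  expect_equal(unname(clr[["BD_RGB_mean_2"]]), 180)
  expect_equal(unname(clr[["BD_RGB_mean_3"]]), 90)
  ref <- convert_color_space(matrix(c(120, 180, 90), 1), "CIELab")
  expect_equal(unname(clr[["BD_CIELab_mean_1"]]), ref[1, 1])
  # empty MZ here? MZ derived is non-empty; check an empty component path
  cs2 <- component_set(list(BD = BD, MR = MR, VS = VS, LM = BD))  # MZ empty
  clr2 <- color_traits(img, cs2)
  expect_true(all(is.na(clr2[grepl("^MZ_", names(clr2))])))
})

test_that("two-tone 50/50 black-white region has RGB mean and std 127.5", {
  H <- 10; W <- 10
  img <- array(0, c(H, W, 3))
  img[, 6:10, ] <- 1
  BD <- matrix(TRUE, H, W)
  cs <- component_set(list(BD = BD, MR = BD & FALSE, VS = BD & FALSE, LM = BD & FALSE))
  clr <- suppressWarnings(color_traits(img, cs))
  for (ch in 1:3) {
    expect_equal(unname(clr[[paste0("BD_RGB_mean_", ch)]]), 127.5)
    expect_equal(unname(clr[[paste0("BD_RGB_std_", ch)]]), 127.5)
  }
})

test_that("color space conventions are honored", {
  px <- matrix(c(255, 0, 0), 1)     # pure red
  hsv <- convert_color_space(px, "HSV")
  expect_equal(hsv[1, 1], 0)        # hue 0 degrees
  expect_equal(hsv[1, 2], 1)        # full saturation
  expect_equal(hsv[1, 3], 1)        # full value
  g <- convert_color_space(matrix(c(0, 255, 0), 1), "HSV")
  expect_equal(g[1, 1], 120)        # green hue 120 degrees
  ycc <- convert_color_space(matrix(c(128, 128, 128), 1), "YCrCb")
  expect_equal(unname(ycc[1, ]), c(128, 128, 128), tolerance = 1e-6)
  lab8 <- convert_color_space(matrix(c(255, 255, 255), 1), "LAB")
  expect_equal(lab8[1, 1], 255, tolerance = 0.5)       # L of white
  expect_equal(lab8[1, 2], 128, tolerance = 0.5)
  labf <- convert_color_space(matrix(c(255, 255, 255), 1), "CIELab")
  expect_equal(labf[1, 1], 100, tolerance = 0.01)
})

test_that("pixel-to-mm conversion matches the camera scale", {
  expect_equal(pixels_to_mm(40), 1.914)
  expect_equal(round(pixels_to_mm(82), 3), 3.924)
  expect_equal(pixels_to_mm(0), 0)
  expect_equal(pixels_to_mm(100, scale_mm_per_px = 0.1), 10)
  expect_error(pixels_to_mm(10, scale_mm_per_px = 0))
})

test_that("the full trait vector has 266 entries and size traits are size-free", {
  nr1 <- small_norm(1L)
  tv <- extract_traits(nr1)
  expect_equal(ncol(tv), 268)       # leaf_id, orientation + 266 traits
  expect_identical(colnames(tv)[-(1:2)], trait_registry()$name)
  # the same leaf pre-scaled by 1.25 normalizes to near-identical size traits
  g <- small_leaf(1L)
  big <- apply_rigid_transform(g$sample, scale = 1.25)
  nrb <- normalize_leaf(big)
  tvb <- extract_traits(nrb)
  expect_equal(tvb$ScalingFactor / tv$ScalingFactor, 1.25, tolerance = 0.01)
  for (k in c("BD_A", "BD_L", "BD_W", "LM_A", "MR_L"))
    expect_equal(tvb[[k]], tv[[k]], tolerance = 0.02 * max(1, abs(tv[[k]])))
})
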