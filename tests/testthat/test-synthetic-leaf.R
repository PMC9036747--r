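test_that("generation is deterministic: same params give bit-identical output", {
  a <- generate_leaf(small_params(seed = 7))
  b <- generate_leaf(small_params(seed = 7))
  expect_identical(a$sample$image, b$sample$image)
  for (k in names(a$sample$components$masks))
    expect_identical(a$sample$components$masks[[k]], b$sample$components$masks[[k]])
  expect_identical(a$truth$laminas, b$truth$laminas)
})

test_that("lamina count equals one first-order lamina per vein", {
  g <- generate_leaf(small_params(seed = 2, n_veins_left = 3, n_veins_right = 4,
                                  vein_angles_left = c(60, 75, 90),
                                  vein_angles_right = c(55, 70, 85, 100)))
  expect_equal(g$truth$LM_N, 7)
  expect_equal(g$truth$LM_N_LT, 3)
  expect_equal(g$truth$LM_N_RT, 4)
  expect_equal(g$truth$LM_N, g$truth$LM_N_LT + g$truth$LM_N_RT)
})

test_that("ground-truth areas equal mask pixel counts and masks are consistent", {
  for (s in c(1L, 5L)) {
    g <- small_leaf(s)
    m <- g$sample$components$masks
    for (k in names(m)) expect_equal(unname(g$truth$areas[[k]]), sum(m[[k]]))
    # component algebra invariants
    expect_true(all(m$BD[m$MR]))
    expect_true(all(m$BD[m$VS]))
    expect_true(all(m$BD[m$LM]))
    expect_identical(m$VV, m$MR | m$VS)
    expect_false(any(m$MZ & (m$VV | m$LM)))
    # labeled lamina regions match the truth table
    lab <- label_components(m$LM, 8L)
    expect_equal(max(lab), g$truth$LM_N)
  }
})

test_that("ground-truth angle lists mirror the parameters", {
  p <- small_params(seed = 3, vein_angles_left = c(48, 77, 101),
                    vein_angles_right = c(66, 88, 122))
  g <- generate_leaf(p)
  tl <- g$truth$laminas
  expect_equal(tl$angle[tl$side == "left"][order(tl$order[tl$side == "left"])],
               c(48, 77, 101))
  expect_equal(tl$angle[tl$side == "right"][order(tl$order[tl$side == "right"])],
               c(66, 88, 122))
})

test_that("invalid parameters are rejected", {
  expect_error(leaf_params(vein_angles_left = c(0, 90), n_veins_left = 2),
               "inside \\(0, 180\\)")
  expect_error(leaf_params(vein_angles_right = c(90, 180), n_veins_right = 2),
               "inside \\(0, 180\\)")
  expect_error(leaf_params(n_veins_left = 2, vein_angles_left = 90))
  expect_warning(leaf_params(petiole_width = 10, vein_width = 9), "2 \\* vein_width")
})

test_that("rigid transform: identity, involution and area preservation", {
  g <- small_leaf(1L)
  s <- g$sample
  id <- apply_rigid_transform(s, angle = 0, scale = 1, flip = FALSE)
  expect_identical(id$components$masks$BD, s$components$masks$BD)

  # two 180-degree rotations restore the leaf up to a 1-px boundary band
  r2 <- apply_rigid_transform(apply_rigid_transform(s, angle = 180), angle = 180)
  bd0 <- s$components$masks$BD
  bd2 <- r2$components$masks$BD
  d <- dim(bd0); d2 <- dim(bd2)
  expect_true(all(abs(d - d2) <= 2))
  co <- pmin(d, d2)
  a <- bd0[seq_len(co[1]), seq_len(co[2])]
  b <- bd2[seq_len(co[1]), seq_len(co[2])]
  core <- mask_erode(a, 2)
  expect_true(all(b[core]))

  # rotation by an oblique angle preserves every mask area within 2%
  rot <- apply_rigid_transform(s, angle = 37)
  for (k in names(s$components$masks)) {
    a0 <- sum(s$components$masks[[k]])
    a1 <- sum(rot$components$masks[[k]])
    expect_lt(abs(a1 - a0) / a0, 0.02)
  }

  # flip is an involution
  f2 <- apply_rigid_transform(apply_rigid_transform(s, flip = TRUE), flip = TRUE)
  expect_identical(f2$components$masks$BD, s$components$masks$BD)
})

test_that("save_leaf round-trips masks, image and truth through disk", {
  g <- small_leaf(1L)
  dir <- withr::local_tempdir()
  save_leaf(g, dir)
  cs <- load_component_set(dir, id = g$sample$id)
  for (k in names(cs$masks))
    expect_identical(cs$masks[[k]], g$sample$components$masks[[k]])
  tr <- jsonlite::read_json(file.path(dir, paste0(g$sample$id, "_truth.json")))
  expect_equal(tr$LM_N, g$truth$LM_N)
  expect_equal(tr$PE_L, g$truth$PE_L, tolerance = 1e-8)
})
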