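test_that("landmark validation catches malformed input", {
  limb <- small_cohort(1)[[1]]
  lm <- limb$landmarks
  pts <- lm[landmark_point_names()]
  expect_s3_class(hto_landmarks(pts, 45), "hto_landmarks")
  expect_error(hto_landmarks(pts[-1], 45), "missing landmarks")
  bad <- pts; bad$hip_center <- c(0, NA, 1)
  expect_error(hto_landmarks(bad, 45), "non-finite")
  expect_error(hto_landmarks(pts, -1), "femoral_head_diameter")
})

test_that("landmark JSON round trip is lossless", {
  lm <- small_cohort(1)[[1]]$landmarks
  path <- tempfile(fileext = ".json")
  write_landmarks_json(lm, path)
  lm2 <- read_landmarks_json(path)
  for (nm in landmark_point_names()) {
    expect_identical(lm2[[nm]], lm[[nm]])
  }
  expect_identical(lm2$femoral_head_diameter, lm$femoral_head_diameter)
  bad_path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad_path)
  expect_error(read_landmarks_json(bad_path), "not an htosim landmark")
})

test_that("mirroring is an involution and swaps side labels", {
  lm <- small_cohort(1)[[1]]$landmarks
  m2 <- mirror_landmarks(mirror_landmarks(lm))
  for (nm in landmark_point_names()) expect_identical(m2[[nm]], lm[[nm]])
  m <- mirror_landmarks(lm)
  # the mirrored lateral edge is the reflection of the original medial edge
  expect_identical(m$lateral_plateau_edge,
                   htosim:::mirror_x(lm$medial_plateau_edge))
  # without relabelling it is a pure reflection
  g <- mirror_landmarks(lm, relabel = FALSE)
  expect_identical(g$lateral_plateau_edge,
                   htosim:::mirror_x(lm$lateral_plateau_edge))
})
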