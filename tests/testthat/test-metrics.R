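test_that("HKA angle: collinear, varus offset, and signed valgus cases", {
  expect_equal(hka_angle(hip = c(0, 0, 800), knee = c(0, 0, 400),
                         ankle = c(0, 0, 0)), 180, tolerance = 1e-9)
  # 13.96 mm coronal offset over 400 mm is a 2-degree deviation
  expect_equal(hka_angle(hip = c(0, 0, 800), knee = c(0, 0, 400),
                         ankle = c(13.96, 0, 0)), 178.00, tolerance = 0.01)
  expect_error(hka_angle(hip = c(0, 0, 1), knee = c(0, 0, 1),
                         ankle = c(1, 0, 0)), "coincident")
  # with full landmarks the angle is signed: a lateralised ankle reads
  # above 180 (valgus), so valgizing corrections are positive deltas
  limb <- fixed_limb(list(hka_deg = 185))
  expect_lt(abs(hka_angle(limb$landmarks) - 185), 1e-6)
})

test_that("TT-TG is the ML offset in the femoral axial plane", {
  limb <- fixed_limb()
  lm <- limb$landmarks
  lm$tibial_tuberosity_apex <- lm$trochlear_groove_point + c(4, 0, -40)
  expect_equal(tt_tg_axial(lm), 4, tolerance = 1e-9)
  # a known rigid lateral translation of the tuberosity moves TT-TG by
  # exactly its lateral component
  lm2 <- limb$landmarks
  before <- tt_tg_axial(lm2)
  lm2$tibial_tuberosity_apex <- lm2$tibial_tuberosity_apex + c(2.1, 0, -1.5)
  expect_lt(abs(tt_tg_axial(lm2) - before - 2.1), 1e-9)
})

test_that("Insall-Salvati is tendon length over patellar length", {
  limb <- fixed_limb()
  lm <- limb$landmarks
  lm$patella_proximal_pole <- c(0, 50, 50)
  lm$patella_distal_pole <- c(0, 50, 0)
  lm$patellar_tendon_insertion <- c(0, 50, -40)
  expect_equal(insall_salvati(lm), 0.8, tolerance = 1e-12)
  lm$patella_proximal_pole <- lm$patella_distal_pole
  expect_error(insall_salvati(lm), "zero patellar length")
})

test_that("frames are orthonormal and right-handed on generated limbs", {
  for (limb in small_cohort(3, 13)) {
    fr <- anatomical_frames(limb$landmarks)
    for (f in fr) {
      B <- cbind(f$ml, f$ap, f$pd)
      expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
      expect_lt(abs(det(B) - 1), 1e-9)
    }
  }
})

test_that("indices are invariant under rigid motions of the whole limb", {
  limb <- small_cohort(1)[[1]]
  m0 <- unlist(measure_indices(limb$landmarks))
  set.seed(31)
  for (i in 1:10) {
    tf <- htosim:::rigid_about_point(
      htosim:::rotation_about_axis(rnorm(3), runif(1, -pi, pi)),
      rnorm(3, sd = 100))
    lm2 <- transform_landmarks(limb$landmarks, tf)
    m1 <- unlist(measure_indices(lm2))
    expect_vec_equal(m1, m0, 1e-8)
  }
})

test_that("index table covers the grid and matches hand computation", {
  cohort <- small_cohort(2, 17)
  # identical pre/post input: all deltas zero
  fake_post <- lapply(cohort, function(l) {
    structure(list(limb_id = l$limb_id, variant = "descending",
                   wedge_height_mm = 6, landmarks = l$landmarks),
              class = "hto_osteotomized_limb")
  })
  tab0 <- build_index_table(cohort, fake_post)
  expect_true(all(tab0[c("d_hka", "d_ttg", "d_is")] == 0))

  grid <- run_osteotomy_grid(cohort, heights = c(6, 9))
  tab <- build_index_table(cohort, grid)
  expect_identical(nrow(tab), 2L + 2L * 2L * 2L)
  expect_true(check_index_table_grid(tab, heights = c(6, 9)))
  expect_error(check_index_table_grid(tab, heights = c(6, 9, 12)),
               "missing grid cell")

  sm <- index_table_summary(tab)
  cell <- tab[tab$variant == "ascending" & tab$wedge_height_mm == 9, ]
  expect_equal(sm$mean_d_hka[sm$variant == "ascending" &
                               sm$wedge_height_mm == 9],
               mean(cell$d_hka), tolerance = 1e-12)
  expect_equal(sm$sd_d_ttg[sm$variant == "ascending" &
                             sm$wedge_height_mm == 9],
               sd(cell$d_ttg), tolerance = 1e-12)
})
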