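test_that("descending repositioning is the identity", {
  limb <- small_cohort(1)[[1]]
  lm <- limb$landmarks
  st <- patella_state(lm$patella_center, lm$patella_proximal_pole,
                      lm$patella_distal_pole, 40)
  out <- reposition_patella(st, lm$patellar_tendon_insertion + c(3, 0, -4),
                            anatomical_frames(lm), "descending")
  expect_identical(out$center, st$center)
  expect_identical(out$distal_pole, st$distal_pole)
  expect_identical(attr(out, "pd_shift_mm"), 0)
})

test_that("the proximal root of the tendon-sphere intersection is taken", {
  # pre: distal pole at origin, insertion 50 mm distal, L0 = 50;
  # post insertion (3, 0, -54): solve 9 + (z + 54)^2 = 2500
  limb <- fixed_limb()  # frames of the generated limb are the global axes
  frames <- anatomical_frames(limb$landmarks)
  st <- patella_state(c(0, 0, 20), c(0, 0, 40), c(0, 0, 0), 50)
  out <- reposition_patella(st, c(3, 0, -54), frames, "ascending")
  expect_equal(out$distal_pole[3], -4.090, tolerance = 1e-3)
  expect_lt(abs(htosim:::vnorm(out$distal_pole - c(3, 0, -54)) - 50), 1e-9)
  # rigid translation: the whole patella moved by the same shift
  expect_vec_equal(out$proximal_pole - st$proximal_pole,
                   out$distal_pole - st$distal_pole, 1e-12)
  # infeasible: in-plane offset exceeds the tendon length
  expect_error(reposition_patella(st, c(60, 0, -54), frames, "ascending"),
               "infeasible")
})

test_that("ascending models conserve tendon length and move distally", {
  limb <- small_cohort(1)[[1]]
  plan <- plan_osteotomy(limb, "ascending")
  L0 <- htosim:::vnorm(limb$landmarks$patellar_tendon_insertion -
                         limb$landmarks$patella_distal_pole)
  shifts <- vapply(6:12, function(h) {
    ost <- reposition_patella_limb(apply_wedge(limb, plan, h), limb)
    L1 <- htosim:::vnorm(ost$landmarks$patellar_tendon_insertion -
                           ost$landmarks$patella_distal_pole)
    expect_lt(abs(L1 - L0), 1e-9)
    ost$patellar_shift_pd_mm
  }, numeric(1))
  expect_true(all(shifts < 0))            # patellar height decreases
  expect_true(all(diff(abs(shifts)) >= 0))  # monotone in wedge height
})
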