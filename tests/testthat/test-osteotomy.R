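test_that("the plan follows the surgical construction rules", {
  limb <- fixed_limb(list(plateau_width_mm = 70), meshes = FALSE)
  plan <- plan_osteotomy(limb, "ascending")
  # entry at half the plateau width below the plateau, on the medial cortex
  expect_equal(plan$medial_entry_point[3], -35, tolerance = 1e-9)
  expect_lt(plan$medial_entry_point[1], -25)
  # hinge 15 mm below the plateau at the lateral cortex
  expect_equal(plan$hinge_axis$point[3], -15, tolerance = 1e-9)
  expect_gt(plan$hinge_axis$point[1], 25)
  # biplanar plane 10 mm behind the tuberosity along the tibial AP axis
  fr <- anatomical_frames(limb$landmarks)
  off <- sum((limb$landmarks$tibial_tuberosity_apex -
                plan$biplanar_plane$point) * fr$tibial$ap)
  expect_equal(off, 10, tolerance = 1e-9)
  # hinge axis lies in the main cut plane; plane parallel to medial slope
  expect_lt(abs(sum(plan$main_cut_plane$normal * plan$hinge_axis$direction)),
            1e-9)
})

test_that("wedge angle formula matches its independent evaluation", {
  fake <- list(lever = 66, angle_mode = "chord")
  expect_equal(wedge_angle_from_height(0, fake), 0)
  expect_equal(wedge_angle_from_height(6, fake), 5.211, tolerance = 1e-3)
  expect_equal(wedge_angle_from_height(12, fake), 10.435, tolerance = 1e-3)
  expect_error(wedge_angle_from_height(140, fake), "impossible")
  expect_error(wedge_angle_from_height(-1, fake), "non-negative")
  expect_equal(wedge_angle_from_height(6, list(lever = 66, angle_mode = "arctan")),
               atan(6 / 66) * 180 / pi, tolerance = 1e-12)
  # strictly increasing in h
  th <- vapply(seq(0, 12, by = 0.5), wedge_angle_from_height, numeric(1),
               plan = fake)
  expect_true(all(diff(th) > 0))
})

test_that("fragment split respects the variant and conserves volume", {
  limb <- small_cohort(1, meshes = TRUE)[[1]]
  vol <- mesh_volume(limb$tibia_mesh)
  for (v in c("ascending", "descending")) {
    plan <- plan_osteotomy(limb, v)
    sf <- split_fragments(limb, plan)
    expect_true(mesh_is_watertight(sf$proximal))
    expect_true(mesh_is_watertight(sf$distal))
    vsum <- mesh_volume(sf$proximal) + mesh_volume(sf$distal)
    expect_lt(abs(vsum - vol) / vol, 1e-3)
    asg <- sf$landmark_assignment
    side <- if (v == "ascending") "distal" else "proximal"
    expect_identical(unname(asg["tibial_tuberosity_apex"]), side)
    expect_identical(unname(asg["patellar_tendon_insertion"]), side)
    expect_identical(unname(asg["ankle_center"]), "distal")
    expect_identical(unname(asg["knee_center_tibia"]), "proximal")
  }
})

test_that("wedge opening is a rigid valgizing rotation with exact gap", {
  limb <- small_cohort(1)[[1]]
  plan <- plan_osteotomy(limb, "ascending")
  # h = 0 returns the input bitwise
  o0 <- apply_wedge(limb, plan, 0)
  expect_identical(o0$landmarks, limb$landmarks)
  pre <- measure_indices(limb)
  for (h in c(6, 9, 12)) {
    ost <- apply_wedge(limb, plan, h)
    expect_true(htosim:::is_proper_rotation(ost$wedge_transform$R))
    # hinge axis points are fixed
    hp <- plan$hinge_axis$point + 7 * plan$hinge_axis$direction
    expect_vec_equal(htosim:::apply_rigid(ost$wedge_transform, hp), hp, 1e-9)
    expect_lt(abs(medial_gap(ost) - h), 1e-6)
    # rigidity of the moving fragment's landmarks
    dn <- names(ost$landmark_assignment)[ost$landmark_assignment == "distal"]
    for (a in dn) for (b in dn) {
      expect_lt(abs(htosim:::vnorm(ost$landmarks[[a]] - ost$landmarks[[b]]) -
                      htosim:::vnorm(limb$landmarks[[a]] - limb$landmarks[[b]])),
                1e-9)
    }
    post <- measure_indices(ost)
    expect_gt(post$hka_deg, pre$hka_deg)  # valgization
  }
})

test_that("HKA change is variant-independent; TT-TG/IS changes are not", {
  limb <- small_cohort(1)[[1]]
  pre <- measure_indices(limb)
  pa <- plan_osteotomy(limb, "ascending")
  pd <- plan_osteotomy(limb, "descending")
  d_hka <- d_ttg <- NULL
  for (h in 6:12) {
    oa <- apply_wedge(limb, pa, h)
    od <- apply_wedge(limb, pd, h)
    ma <- measure_indices(oa); md <- measure_indices(od)
    expect_identical(ma$hka_deg, md$hka_deg)
    expect_identical(md$ttg_mm, pre$ttg_mm)      # descending: exact zero delta
    expect_identical(md$is_ratio, pre$is_ratio)
    d_hka <- c(d_hka, ma$hka_deg - pre$hka_deg)
    d_ttg <- c(d_ttg, ma$ttg_mm - pre$ttg_mm)
  }
  expect_true(all(diff(d_hka) > 0))  # strictly increasing in h
  expect_true(all(diff(d_ttg) > 0))
  expect_true(all(d_ttg > 0))
})

test_that("the osteotomy grid has the right shape and fails loudly", {
  cohort <- small_cohort(1)
  grid <- run_osteotomy_grid(cohort)
  expect_length(grid, 14L)  # 2 variants x 7 heights
  expect_identical(sum(vapply(grid, function(o) o$variant, character(1)) ==
                         "ascending"), 7L)
  expect_error(run_osteotomy_grid(list()), "empty cohort")
})
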