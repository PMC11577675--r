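test_that("body weight regression is linear with guards", {
  expect_equal(estimate_body_weight(70, c(a = 1, b = 0)), 70)
  co <- default_knee_params()$bw_coefficients
  expect_equal(estimate_body_weight(45, co), co[["a"]] * 45 + co[["b"]])
  expect_equal(estimate_body_weight(90, c(a = 2, b = 0)),
               2 * estimate_body_weight(45, c(a = 2, b = 0)))
  expect_error(estimate_body_weight(-5), "positive")
  expect_error(estimate_body_weight(5, c(a = 1, b = -100)), "nonpositive")
})

test_that("models are slack at the reference pose and inherit calibration", {
  limb <- small_cohort(1)[[1]]
  km <- build_knee_model(limb)
  expect_equal(ligament_energy(km, 5, 0), 0)
  expect_gt(ligament_energy(km, 60, 5), 0)
  plan <- plan_osteotomy(limb, "descending")
  o0 <- apply_wedge(limb, plan, 0)
  k0 <- build_knee_model(o0, base = km)
  expect_identical(k0$slack, km$slack)
  expect_identical(k0$tib_rel, km$tib_rel)
  # ascending model keeps the preoperative tendon length
  pa <- plan_osteotomy(limb, "ascending")
  oa <- reposition_patella_limb(apply_wedge(limb, pa, 9), limb)
  ka <- build_knee_model(oa, base = km)
  expect_identical(ka$L0, km$L0)
})

test_that("analytic gradients match finite differences", {
  limb <- small_cohort(1)[[1]]
  km <- build_knee_model(limb)
  for (fx in c(5, 45, 95)) {
    ev <- htosim:::.make_pose_evaluator(km, fx)
    set.seed(fx)
    x <- c(rnorm(1, 0, 0.05), rnorm(1, 0, 2), rnorm(1, 0, 0.05),
           rnorm(1, 0, 0.05))
    r <- ev$evaluate(x)
    num <- vapply(1:4, function(j) {
      h <- 1e-6
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      (ev$evaluate(xp)$E - ev$evaluate(xm)$E) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(r$g - num)) / max(1, max(abs(num))), 1e-5)
  }
})

test_that("reduced one-DOF models match their closed forms", {
  limb <- small_cohort(1)[[1]]
  tp <- default_knee_params()
  tp$quad_min <- 0; tp$quad_gain <- 0; tp$hamstring_fraction <- 0
  tp$lig_stiffness <- c(acl = 0, pcl = 0, mcl = 0, lcl = 0)
  tp$ml_springs <- list(list(k = 10, rest = 3.7))
  km <- build_knee_model(limb, tp)
  p <- solve_equilibrium_at_flexion(km, 30)
  expect_lt(abs(p$patellar_shift - 3.7), 1e-8)
  expect_lt(abs(p$tibiofemoral_rotation), 1e-8)
  expect_lt(abs(p$patellar_tilt), 1e-8)
  # two springs: equilibrium at the stiffness-weighted mean rest position
  tp$ml_springs <- list(list(k = 10, rest = 3.7), list(k = 30, rest = -2))
  km2 <- build_knee_model(limb, tp)
  p2 <- solve_equilibrium_at_flexion(km2, 30)
  expect_lt(abs(p2$patellar_shift - (10 * 3.7 + 30 * (-2)) / 40), 1e-8)
})

test_that("mirrored models give sign-flipped kinematics", {
  limb <- small_cohort(1)[[1]]
  km <- build_knee_model(limb)
  limb_m <- limb
  limb_m$landmarks <- mirror_landmarks(limb$landmarks, relabel = FALSE)
  km_m <- build_knee_model(limb_m)
  for (fx in c(10, 55, 100)) {
    p <- solve_equilibrium_at_flexion(km, fx)
    pm <- solve_equilibrium_at_flexion(km_m, fx)
    expect_lt(abs(p$patellar_shift + pm$patellar_shift), 1e-6)
    expect_lt(abs(p$patellar_tilt + pm$patellar_tilt), 1e-6)
    expect_lt(abs(p$patellar_rotation + pm$patellar_rotation), 1e-6)
    expect_lt(abs(p$tibiofemoral_rotation + pm$tibiofemoral_rotation), 1e-6)
  }
})

test_that("the equilibrium is a minimum reached deterministically", {
  limb <- small_cohort(1)[[1]]
  km <- build_knee_model(limb)
  p40 <- solve_equilibrium_at_flexion(km, 40)
  expect_lt(p40$residual, 1e-8)
  # warm-started solve never ends above its starting energy
  p41 <- solve_equilibrium_at_flexion(km, 41, warm_start = p40)
  ev <- htosim:::.make_pose_evaluator(km, 41)
  ev$env$u <- p40$u
  expect_lte(p41$energy, ev$evaluate(p40$dofs)$E + 1e-9)
  # determinism
  p40b <- solve_equilibrium_at_flexion(km, 40)
  expect_identical(p40$dofs, p40b$dofs)
  expect_error(solve_equilibrium_at_flexion(km, 2), "within")
})

test_that("squat sweeps are complete, continuous, and identity at h = 0", {
  limb <- small_cohort(1)[[1]]
  km <- build_knee_model(limb)
  cv <- run_squat(km)
  expect_identical(nrow(cv), 96L)
  expect_true(all(is.finite(as.matrix(cv[-1]))))
  expect_lt(attr(cv, "max_jump"), 2)
  plan <- plan_osteotomy(limb, "descending")
  k0 <- build_knee_model(apply_wedge(limb, plan, 0), base = km)
  cv0 <- run_squat(k0)
  for (p in c("patellar_shift_mm", "patellar_tilt_deg",
              "patellar_rotation_deg", "tf_rotation_deg")) {
    expect_identical(rmse_curve(cv0[[p]], cv[[p]]), 0)
  }
})

test_that("a one-limb experiment has the documented bookkeeping", {
  res <- run_experiment(small_cohort(1, 19), heights = c(6, 12))
  expect_identical(res$meta$n_models, 5L)          # 1 + 2 x 2
  expect_identical(res$meta$n_samples_per_parameter, 480L)
  cl <- res$curves_long
  expect_identical(nrow(cl), 4L * 480L)
  expect_false(anyNA(cl$value))
  expect_identical(sort(unique(cl$variant)),
                   c("ascending", "descending", "preop"))
})
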