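test_that("generation is deterministic in (seed, index), independent of order", {
  spec <- cohort_spec(3, 7)
  a <- generate_limb(spec, 0, meshes = FALSE)
  generate_limb(spec, 2, meshes = FALSE)  # interleave another draw
  b <- generate_limb(spec, 0, meshes = FALSE)
  expect_identical(a$landmarks, b$landmarks)
  am <- generate_limb(spec, 1, meshes = TRUE)
  bm <- generate_limb(spec, 1, meshes = TRUE)
  expect_identical(am$tibia_mesh, bm$tibia_mesh)
  expect_error(generate_limb(spec, 3), "index")
})

test_that("degenerate distributions reproduce their means exactly", {
  limb <- fixed_limb(list(hka_deg = 180))
  m <- measure_indices(limb)
  expect_lt(abs(m$hka_deg - 180), 1e-6)
  limb2 <- fixed_limb()
  m2 <- measure_indices(limb2)
  expect_lt(abs(m2$hka_deg - 178.1), 1e-6)
  expect_lt(abs(m2$ttg_mm - 13.6), 1e-6)
  expect_lt(abs(m2$is_ratio - 0.8), 1e-6)
})

test_that("measured indices round-trip the drawn values on a cohort", {
  cohort <- generate_cohort(cohort_spec(20, 5), meshes = FALSE)
  expect_length(cohort, 20)
  ids <- vapply(cohort, function(l) l$limb_id, character(1))
  expect_false(any(duplicated(ids)))
  for (l in cohort) {
    m <- measure_indices(l)
    expect_lt(abs(m$hka_deg - l$draws$hka_deg), 1e-6)
    expect_lt(abs(m$ttg_mm - l$draws$ttg_mm), 1e-6)
    expect_lt(abs(m$is_ratio - l$draws$insall_salvati), 1e-6)
  }
})

test_that("infeasible specifications error after bounded resampling", {
  d <- default_cohort_distributions()
  d$plateau_width_mm <- c(20, 0)   # permanently infeasible
  expect_error(generate_limb(cohort_spec(1, 1, d), 0, meshes = FALSE),
               "infeasible")
})

test_that("sample means track the cohort distribution (reduced n)", {
  cohort <- generate_cohort(cohort_spec(200, 11), meshes = FALSE)
  idx <- vapply(cohort, function(l) unlist(measure_indices(l)), numeric(3))
  d <- default_cohort_distributions()
  for (k in 1:3) {
    target <- c(d$hka_deg[1], d$ttg_mm[1], d$insall_salvati[1])[k]
    se <- sd(idx[k, ]) / sqrt(ncol(idx))
    expect_lt(abs(mean(idx[k, ]) - target), 3 * se)
  }
})
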