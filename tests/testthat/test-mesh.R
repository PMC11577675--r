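test_that("generated bone meshes are closed surfaces of genus zero", {
  limb <- small_cohort(1, meshes = TRUE)[[1]]
  for (nm in c("tibia_mesh", "femur_mesh", "patella_mesh")) {
    m <- limb[[nm]]
    expect_true(mesh_is_watertight(m))
    expect_identical(mesh_euler_characteristic(m), 2L)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("tibia mesh hits the requested plateau width and tuberosity apex", {
  limb <- fixed_limb(list(plateau_width_mm = 75), meshes = TRUE)
  expect_lt(abs(mesh_ml_extent_at(limb$tibia_mesh, 0, 0.5) - 75), 0.5)
  ap <- limb$landmarks$tibial_tuberosity_apex
  dmin <- min(sqrt(rowSums(sweep(limb$tibia_mesh$vertices, 2, ap)^2)))
  expect_lt(dmin, 1)  # apex lies on the surface (it is a vertex)
})

test_that("mirrored generation equals the sagittal reflection", {
  limb <- small_cohort(1, meshes = TRUE)[[1]]
  m <- mirror_limb(limb)
  expect_identical(m$side, "left")
  v1 <- m$tibia_mesh$vertices
  v2 <- htosim:::mirror_x(limb$tibia_mesh$vertices)
  expect_identical(v1, v2)
  expect_true(mesh_is_watertight(m$tibia_mesh))
  expect_lt(abs(mesh_volume(m$tibia_mesh) - mesh_volume(limb$tibia_mesh)), 1e-6)
})

test_that("plane clipping conserves volume and closes the cut", {
  limb <- small_cohort(1, meshes = TRUE)[[1]]
  mesh <- limb$tibia_mesh
  vol <- mesh_volume(mesh)
  set.seed(21)
  for (i in 1:8) {
    pt <- c(rnorm(1, 0, 5), rnorm(1, 0, 5), runif(1, -150, -5))
    nr <- htosim:::unitv(rnorm(3))
    a <- clip_mesh(mesh, pt, nr)
    b <- clip_mesh(mesh, pt, -nr)
    va <- if (is.null(a)) 0 else mesh_volume(a)
    vb <- if (is.null(b)) 0 else mesh_volume(b)
    if (!is.null(a)) expect_true(mesh_is_watertight(a))
    if (!is.null(b)) expect_true(mesh_is_watertight(b))
    expect_lt(abs(va + vb - vol) / vol, 1e-3)
  }
})

test_that("STL and PLY export work; PLY round-trips", {
  limb <- small_cohort(1, meshes = TRUE)[[1]]
  mesh <- limb$patella_mesh
  ply <- tempfile(fileext = ".ply")
  write_ply(mesh, ply)
  m2 <- read_ply(ply)
  expect_lt(max(abs(m2$vertices - mesh$vertices)), 1e-9)
  expect_identical(m2$faces, mesh$faces)
  stl_b <- tempfile(fileext = ".stl")
  write_stl(mesh, stl_b, binary = TRUE)
  expect_identical(as.integer(file.size(stl_b)), 84L + 50L * nrow(mesh$faces))
  stl_a <- tempfile(fileext = ".stl")
  write_stl(mesh, stl_a, binary = FALSE)
  expect_match(readLines(stl_a, n = 1), "^solid")
})
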