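# Synthetic lower-limb cohort generator.
#
# Each limb is built directly from a draw of anatomical indices so that the
# measurement operators recover the drawn values exactly: the hip-knee-ankle
# angle is set by tilting the tibial shaft axis in the coronal plane below
# the plateau, the axial TT-TG by the mediolateral position of the tibial
# tuberosity relative to the trochlear groove, and the Insall-Salvati index
# by the patellar tendon / patellar length ratio. The construction therefore
# shares its frame conventions with the metrics module by design.
#
# Coordinates: right-handed, +X lateral (right limb), +Y anterior,
# +Z proximal, origin at the tibial knee centre (plateau level), mm.

#' Cohort specification
#'
#' Describes the distributions (mean, sd) from which per-limb anatomical
#' indices are drawn. The defaults equal the preoperative cohort statistics
#' this package is calibrated against: HKA 178.1 (2.7) degrees, axial TT-TG
#' 13.6 (2.4) mm, Insall-Salvati 0.8 (0.1); the remaining anthropometrics
#' (bone lengths, plateau width, femoral head diameter, medial tibial slope,
#' patellar length) use configurable population defaults.
#'
#' @param n_limbs number of limbs in the cohort (>= 1)
#' @param seed integer seed governing all draws
#' @param distributions named list of `c(mean, sd)` pairs; see
#'   [default_cohort_distributions()] for the recognised names. Partial
#'   lists override the defaults entry-wise.
#' @return object of class `hto_cohort_spec`
#' @export
cohort_spec <- function(n_limbs = 13L, seed = 42L, distributions = list()) {
  n_limbs <- as.integer(n_limbs)
  if (is.na(n_limbs) || n_limbs < 1L) stop("n_limbs must be >= 1")
  d <- default_cohort_distributions()
  unknown <- setdiff(names(distributions), names(d))
  if (length(unknown) > 0L) {
    stop("unknown distribution name(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(distributions)) {
    v <- as.numeric(distributions[[nm]])
    if (length(v) != 2L || !all(is.finite(v)) || v[2L] < 0) {
      stop("distribution '", nm, "' must be c(mean, sd) with sd >= 0")
    }
    d[[nm]] <- v
  }
  structure(list(n_limbs = n_limbs, seed = as.integer(seed),
                 distributions = d),
            class = "hto_cohort_spec")
}

#' Default per-limb index distributions, `c(mean, sd)`
#' @export
default_cohort_distributions <- function() {
  list(
    hka_deg = c(178.1, 2.7),
    ttg_mm = c(13.6, 2.4),
    insall_salvati = c(0.8, 0.1),
    plateau_width_mm = c(75, 5),
    tibia_length_mm = c(380, 25),
    femur_length_mm = c(430, 25),
    femoral_head_diameter_mm = c(46, 4),
    medial_slope_deg = c(7, 2.5),
    patellar_length_mm = c(40, 3)
  )
}

#' @export
print.hto_cohort_spec <- function(x, ...) {
  cat("<hto_cohort_spec> n_limbs =", x$n_limbs, ", seed =", x$seed, "\n")
  invisible(x)
}

# fixed construction constants (mm): tuberosity apex and tendon insertion
# depth below the plateau, and patellar anterior stand-off
TUBEROSITY_Z <- -32
TENDON_INSERTION_Z <- -26

# feasibility box used by rejection resampling
.draw_feasible <- function(dr) {
  dr$plateau_width_mm > 55 && dr$plateau_width_mm < 95 &&
    dr$tibia_length_mm > 300 && dr$tibia_length_mm < 460 &&
    dr$femur_length_mm > 340 && dr$femur_length_mm < 520 &&
    dr$femoral_head_diameter_mm > 36 && dr$femoral_head_diameter_mm < 58 &&
    dr$medial_slope_deg >= 0 && dr$medial_slope_deg < 14 &&
    dr$insall_salvati > 0.55 && dr$insall_salvati < 1.1 &&
    dr$ttg_mm > 2 && dr$ttg_mm < 28 &&
    dr$hka_deg > 166 && dr$hka_deg < 192 &&
    dr$patellar_length_mm > 30 && dr$patellar_length_mm < 50
}

#' Elliptic tibial cross-section at a given level
#'
#' Shared between the landmark construction and the mesh builder so that the
#' tuberosity apex lies exactly on the generated surface.
#'
#' @param z level (mm, 0 = plateau)
#' @param half_width plateau half width (mm)
#' @param ankle ankle centre (defines shaft axis tilt and length)
#' @return list with `center` (x, y at this level), `a` (ML semi-axis) and
#'   `b` (AP semi-axis)
#' @keywords internal
tibia_section <- function(z, half_width, ankle) {
  az <- ankle[3L]
  L <- vnorm(ankle)
  frac <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    t * t * (3 - 2 * t)
  }
  taper <- 1 - 0.52 * frac(-z / (0.28 * L))
  flare <- 0.12 * frac(1 - (z - az) / (0.15 * L))
  s <- taper + flare
  ctr <- (z / az) * ankle
  a <- half_width * s
  list(center = c(ctr[1L], ctr[2L]), a = a, b = 0.62 * a)
}

# solve the angular position and bump amplitude that place the tuberosity
# apex exactly on the extruded contour
.tuberosity_bump <- function(sec, apex_xy) {
  tx <- apex_xy[1L] - sec$center[1L]
  ty <- apex_xy[2L] - sec$center[2L]
  if (tx <= 0.5 || ty <= 0) stop("tuberosity apex must be anterolateral of the shaft axis")
  f <- function(psi) tx / cos(psi) - sec$a - (ty / sin(psi) - sec$b)
  lo <- 0.1; hi <- 1.47
  if (f(lo) * f(hi) > 0) stop("infeasible tuberosity geometry")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  amp <- tx / cos(root) - sec$a
  if (amp <= 0 || amp > 25) stop("infeasible tuberosity bump amplitude")
  list(psi = root, amplitude = amp)
}

# deterministic per-limb seed derived from (cohort seed, limb index)
.limb_seed <- function(seed, index) {
  as.integer((as.double(seed %% 1000003L) * 10007 + index * 7919 + 17) %%
               2147483629)
}

# draw one feasible set of anatomical indices; counts rejections
.draw_limb <- function(spec, max_reject = 100L) {
  d <- spec$distributions
  rejections <- 0L
  repeat {
    dr <- lapply(d, function(ms) stats::rnorm(1L, ms[1L], ms[2L]))
    feasible <- .draw_feasible(dr)
    if (feasible) {
      # Insall-Salvati geometric feasibility: the tendon must reach from the
      # tuberosity insertion to the patellar distal pole placement
      L0 <- dr$insall_salvati * dr$patellar_length_mm
      hw <- dr$plateau_width_mm / 2
      delta <- deg2rad(180 - dr$hka_deg)
      ankle <- c(-dr$tibia_length_mm * sin(delta), 0,
                 -dr$tibia_length_mm * cos(delta))
      sec <- tibia_section(TUBEROSITY_Z, hw, ankle)
      apex_y <- sec$center[2L] + sec$b + 7
      dxy2 <- (6 - dr$ttg_mm)^2 + (42 - (apex_y - 1))^2
      feasible <- L0^2 > dxy2 + 25
    }
    if (feasible) {
      dr$rejections <- rejections
      return(dr)
    }
    rejections <- rejections + 1L
    if (rejections > max_reject) {
      stop("more than ", max_reject, " infeasible anatomy draws; ",
           "check the cohort distributions")
    }
  }
}

#' Generate one synthetic limb
#'
#' Deterministic given `(spec$seed, index)`: the same pair always yields
#' bitwise-identical landmarks and meshes, independent of call order.
#' Infeasible draws are rejection-resampled (hard cap of 100, then an error).
#'
#' @param spec `hto_cohort_spec`
#' @param index 0-based limb index, `index < spec$n_limbs`
#' @param meshes also build the bone meshes (default TRUE). Landmark-only
#'   limbs are much faster to generate and support every landmark-level
#'   operation, including all anatomical indices.
#' @return object of class `hto_limb`: landmarks, optional meshes, `side`,
#'   `limb_id`, the drawn index values (`draws`) and the shaft profile
#'   parameters used by the osteotomy planner.
#' @export
generate_limb <- function(spec, index, meshes = TRUE) {
  stopifnot(inherits(spec, "hto_cohort_spec"))
  if (index < 0L || index >= spec$n_limbs) {
    stop("index must satisfy 0 <= index < n_limbs")
  }
  seed_i <- .limb_seed(spec$seed, index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed_i)
  dr <- .draw_limb(spec)

  hw <- dr$plateau_width_mm / 2
  Lt <- dr$tibia_length_mm
  Lf <- dr$femur_length_mm
  delta <- deg2rad(180 - dr$hka_deg)  # varus positive
  ankle <- c(-Lt * sin(delta), 0, -Lt * cos(delta))
  we <- dr$plateau_width_mm + 8      # epicondylar width

  sec_tt <- tibia_section(TUBEROSITY_Z, hw, ankle)
  apex <- c(dr$ttg_mm, sec_tt$center[2L] + sec_tt$b + 7, TUBEROSITY_Z)
  tendon_ins <- c(dr$ttg_mm, apex[2L] - 1, TENDON_INSERTION_Z)

  Lp <- dr$patellar_length_mm
  L0 <- dr$insall_salvati * Lp
  dp_xy <- c(6, 42)
  dz <- sqrt(L0^2 - (dp_xy[1L] - tendon_ins[1L])^2 - (dp_xy[2L] - tendon_ins[2L])^2)
  distal_pole <- c(dp_xy, tendon_ins[3L] + dz)
  proximal_pole <- distal_pole + c(0, 2, sqrt(Lp^2 - 4))

  sec70 <- tibia_section(-70, hw, ankle)

  pts <- list(
    hip_center = c(0, 0, Lf),
    knee_center_femur = c(0, 0, 4),
    knee_center_tibia = c(0, 0, 0),
    ankle_center = ankle,
    medial_plateau_edge = c(-hw, 0, 0),
    lateral_plateau_edge = c(hw, 0, 0),
    tibial_tuberosity_apex = apex,
    patellar_tendon_insertion = tendon_ins,
    trochlear_groove_point = c(0, 30, 16),
    medial_epicondyle = c(-we / 2, -2, 12),
    lateral_epicondyle = c(we / 2, -2, 12),
    patella_center = (distal_pole + proximal_pole) / 2,
    patella_proximal_pole = proximal_pole,
    patella_distal_pole = distal_pole,
    quadriceps_origin = c(5, 32, 170),
    acl_origin = c(9, -6, 6),
    acl_insertion = c(2, 10, -4),
    pcl_origin = c(-7, -9, 4),
    pcl_insertion = c(-2, -20, -8),
    mcl_origin = c(-we / 2, -2, 12),
    mcl_insertion = c(sec70$center[1L] - 0.85 * sec70$a, 6, -70),
    lcl_origin = c(we / 2, -2, 12),
    lcl_insertion = c(hw + 5, -8, -11),
    biceps_femoris_origin = c(18, -28, 150),
    biceps_femoris_insertion = c(hw + 4, -12, -11),
    semimembranosus_origin = c(-14, -28, 150),
    semimembranosus_insertion = c(-hw + 7, -16, -6)
  )
  lm <- hto_landmarks(pts, dr$femoral_head_diameter_mm)

  limb <- structure(list(
    limb_id = sprintf("limb_%03d", index + 1L),
    side = if (index %% 2L == 0L) "right" else "left",
    mirrored_from_left = index %% 2L != 0L,
    landmarks = lm,
    draws = dr,
    profile = list(half_width = hw, ankle = ankle,
                   medial_slope_deg = dr$medial_slope_deg),
    tibia_mesh = NULL, femur_mesh = NULL, patella_mesh = NULL
  ), class = "hto_limb")

  if (meshes) {
    limb$tibia_mesh <- build_tibia_mesh(lm, list(half_width = hw, ankle = ankle))
    limb$femur_mesh <- build_femur_mesh(lm)
    limb$patella_mesh <- build_patella_mesh(lm)
  }
  limb
}

#' @export
print.hto_limb <- function(x, ...) {
  cat("<hto_limb> ", x$limb_id, " (", x$side, ")",
      if (!is.null(x$tibia_mesh)) " with meshes" else " landmarks only",
      "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param spec `hto_cohort_spec`
#' @param meshes build bone meshes for each limb (default TRUE)
#' @return list of `hto_limb` with unique `limb_id`s, length `n_limbs`
#' @export
generate_cohort <- function(spec, meshes = TRUE) {
  stopifnot(inherits(spec, "hto_cohort_spec"))
  lapply(seq_len(spec$n_limbs) - 1L, function(i) {
    generate_limb(spec, i, meshes = meshes)
  })
}

# -- parametric bone meshes ---------------------------------------------------

#' Build the parametric tibia mesh
#'
#' An elliptic-contour extrusion along the (possibly varus-tilted) shaft
#' axis, with a radial bump whose peak passes exactly through the tibial
#' tuberosity apex, capped at the plateau and ankle. Watertight by
#' construction.
#'
#' @param landmarks `hto_landmarks`
#' @param params list with `half_width` (plateau half-width, mm) and `ankle`
#'   (ankle centre); defaults are derived from the landmarks.
#' @param n_theta base angular resolution
#' @return `hto_mesh`
#' @export
build_tibia_mesh <- function(landmarks, params = NULL, n_theta = 32L) {
  lm <- landmarks
  hw <- params$half_width %||%
    (vnorm(lm$lateral_plateau_edge - lm$medial_plateau_edge) / 2)
  ankle <- params$ankle %||% lm$ankle_center
  az <- ankle[3L]
  apex <- lm$tibial_tuberosity_apex
  z_tt <- apex[3L]

  sec_tt <- tibia_section(z_tt, hw, ankle)
  bump <- .tuberosity_bump(sec_tt, apex[1:2])

  zs <- sort(unique(c(0, -3, -7, -11, seq(-15, -75, by = -5), z_tt,
                      seq(-90, az + 0.12 * abs(az), length.out = 8L), az)),
             decreasing = TRUE)
  zs <- zs[zs >= az]
  # drop near-duplicates
  zs <- zs[c(TRUE, abs(diff(zs)) > 1e-6)]

  base_theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  thetas <- sort(unique(round(c(base_theta, 0, pi / 2, pi, 3 * pi / 2, bump$psi), 10)))
  nt <- length(thetas)

  sig_th <- 0.45; sig_z <- 10
  wrap <- function(dth) (dth + pi) %% (2 * pi) - pi

  verts <- matrix(0, nrow = length(zs) * nt, ncol = 3L)
  k <- 0L
  for (z in zs) {
    sec <- tibia_section(z, hw, ankle)
    g <- bump$amplitude *
      exp(-(wrap(thetas - bump$psi) / sig_th)^2 - ((z - z_tt) / sig_z)^2)
    x <- sec$center[1L] + (sec$a + g) * cos(thetas)
    y <- sec$center[2L] + (sec$b + g) * sin(thetas)
    verts[k + seq_len(nt), ] <- cbind(x, y, z)
    k <- k + nt
  }
  if (any((rep(vapply(zs, function(z) tibia_section(z, hw, ankle)$a, numeric(1L)), each = nt)) <= 0)) {
    stop("self-intersecting tibial contour")
  }

  idx <- function(i, j) (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  faces <- vector("list", (length(zs) - 1L) * nt * 2L + 2L * nt)
  fk <- 0L
  for (i in seq_len(length(zs) - 1L)) {
    for (j in seq_len(nt)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      faces[[fk + 1L]] <- c(a, b, c_)
      faces[[fk + 2L]] <- c(a, c_, d)
      fk <- fk + 2L
    }
  }
  # caps: plateau centre at the tibial knee centre, distal centre at the ankle
  top_c <- nrow(verts) + 1L
  bot_c <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), ankle)
  for (j in seq_len(nt)) {
    faces[[fk + 1L]] <- c(top_c, idx(1L, j), idx(1L, j + 1L))
    faces[[fk + 2L]] <- c(bot_c, idx(length(zs), j + 1L), idx(length(zs), j))
    fk <- fk + 2L
  }
  hto_mesh(verts, do.call(rbind, faces))
}

#' Build the parametric femur mesh
#'
#' Elliptic extrusion from the condylar block to the hip centre with a
#' distal condylar widening; geometric stand-in sufficient for completeness
#' of the limb model (no cutting is performed on the femur).
#'
#' @param landmarks `hto_landmarks`
#' @param n_theta angular resolution
#' @return `hto_mesh`
#' @export
build_femur_mesh <- function(landmarks, n_theta = 24L) {
  lm <- landmarks
  we <- vnorm(lm$lateral_epicondyle - lm$medial_epicondyle)
  Lf <- lm$hip_center[3L] - 2
  frac <- function(t) { t <- pmin(pmax(t, 0), 1); t * t * (3 - 2 * t) }
  zs <- c(seq(2, 40, by = 6), seq(50, Lf, length.out = 10L))
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  nt <- length(thetas)
  verts <- matrix(0, nrow = length(zs) * nt, ncol = 3L)
  k <- 0L
  for (z in zs) {
    s <- 1 - 0.62 * frac((z - 2) / (0.25 * Lf)) + 0.15 * frac((z - 0.85 * Lf) / (0.15 * Lf))
    a <- (we / 2) * s
    verts[k + seq_len(nt), ] <- cbind(a * cos(thetas), 0.75 * a * sin(thetas), z)
    k <- k + nt
  }
  idx <- function(i, j) (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  faces <- list()
  for (i in seq_len(length(zs) - 1L)) {
    for (j in seq_len(nt)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, c_, b)
      faces[[length(faces) + 1L]] <- c(a, d, c_)
    }
  }
  bot_c <- nrow(verts) + 1L
  top_c <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 2), c(0, 0, Lf))
  for (j in seq_len(nt)) {
    faces[[length(faces) + 1L]] <- c(bot_c, idx(1L, j + 1L), idx(1L, j))
    faces[[length(faces) + 1L]] <- c(top_c, idx(length(zs), j), idx(length(zs), j + 1L))
  }
  hto_mesh(verts, do.call(rbind, faces))
}

#' Build the patellar mesh
#'
#' Ellipsoid aligned with the pole axis; the proximal and distal poles are
#' exact mesh vertices.
#'
#' @param landmarks `hto_landmarks`
#' @param n_theta,n_phi resolution
#' @return `hto_mesh`
#' @export
build_patella_mesh <- function(landmarks, n_theta = 16L, n_phi = 9L) {
  lm <- landmarks
  dp <- lm$patella_distal_pole
  pp <- lm$patella_proximal_pole
  ctr <- (dp + pp) / 2
  zax <- unitv(pp - dp)
  xax <- orthogonalise(c(1, 0, 0), zax)
  yax <- vcross(zax, xax)
  c_ax <- vnorm(pp - dp) / 2
  a_ax <- 11; b_ax <- 8
  phis <- seq(-pi / 2, pi / 2, length.out = n_phi + 2L)
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  nt <- length(thetas)
  rings <- phis[-c(1L, length(phis))]
  verts <- matrix(0, nrow = length(rings) * nt, ncol = 3L)
  k <- 0L
  for (ph in rings) {
    for (th in thetas) {
      p <- ctr + a_ax * cos(ph) * cos(th) * xax +
        b_ax * cos(ph) * sin(th) * yax + c_ax * sin(ph) * zax
      k <- k + 1L
      verts[k, ] <- p
    }
  }
  idx <- function(i, j) (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  faces <- list()
  for (i in seq_len(length(rings) - 1L)) {
    for (j in seq_len(nt)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, c_, b)
      faces[[length(faces) + 1L]] <- c(a, d, c_)
    }
  }
  south <- nrow(verts) + 1L  # distal pole
  north <- nrow(verts) + 2L  # proximal pole
  verts <- rbind(verts, dp, pp)
  for (j in seq_len(nt)) {
    faces[[length(faces) + 1L]] <- c(south, idx(1L, j + 1L), idx(1L, j))
    faces[[length(faces) + 1L]] <- c(north, idx(length(rings), j), idx(length(rings), j + 1L))
  }
  hto_mesh(verts, do.call(rbind, faces))
}

#' Mirror a limb model in the sagittal plane
#'
#' Produces the opposite-side limb: landmarks are reflected and relabelled,
#' meshes reflected with winding fixed, and the side flag toggled.
#'
#' @param limb `hto_limb`
#' @return mirrored `hto_limb`
#' @export
mirror_limb <- function(limb) {
  limb$landmarks <- mirror_landmarks(limb$landmarks, relabel = TRUE)
  for (nm in c("tibia_mesh", "femur_mesh", "patella_mesh")) {
    if (!is.null(limb[[nm]])) limb[[nm]] <- mirror_mesh(limb[[nm]])
  }
  limb$side <- if (limb$side == "right") "left" else "right"
  if (!is.null(limb$profile)) limb$profile$ankle <- mirror_x(limb$profile$ankle)
  limb
}
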