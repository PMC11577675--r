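# Quasi-static knee model for the squat simulation.
#
# This is a self-contained, fully documented stand-in for a commercial
# multibody engine. The femur is fixed. The tibia is flexed by a prescribed
# angle about the epicondylar axis and keeps one free DOF
# (internal-external rotation about its long axis). The patella rides a
# parametric trochlear channel: its anterior-posterior position is bound to
# the channel surface, its proximodistal position is bound by an
# inextensible patellar tendon link of preoperative length L0, and its free
# DOFs are mediolateral shift, tilt (about its long axis) and mediolateral
# rotation (about its AP axis). Ligaments are tension-only springs slack at
# the preoperative reference pose; the quadriceps is a flexion-dependent
# force line scaled by the estimated body weight; both hamstrings are
# constant force lines. Equilibrium at each flexion angle minimises the
# total potential energy.
#
# All models must be expressed in the package's right-limb coordinate
# convention (+X lateral, +Y anterior, +Z proximal); the channel's
# mediolateral direction and the flexion axis direction are the global +X
# axis, while every position is taken from the landmarks.

#' Estimate body weight from the femoral head diameter
#'
#' Linear regression `BW = a * diameter + b`. The default coefficients are
#' a femoral-head-size stature regression of the Ruff type for adult males
#' (a = 2.741 kg/mm, b = -54.9 kg); both are configurable.
#'
#' @param femoral_head_diameter_mm femoral head diameter (mm, > 0)
#' @param coefficients named numeric `c(a, b)`
#' @return body weight in kg
#' @export
estimate_body_weight <- function(femoral_head_diameter_mm,
                                 coefficients = c(a = 2.741, b = -54.9)) {
  if (!is.finite(femoral_head_diameter_mm) || femoral_head_diameter_mm <= 0) {
    stop("femoral head diameter must be positive")
  }
  bw <- coefficients[["a"]] * femoral_head_diameter_mm + coefficients[["b"]]
  if (!is.finite(bw) || bw <= 0) stop("nonpositive body weight estimate")
  bw
}

#' Default simulator parameters
#'
#' Every internal model quantity is explicit configuration. Units: mm, N,
#' N/mm, N mm/rad, deg.
#'
#' * `groove_radius`, `groove_center_offset`: circular trochlear/condylar
#'   track of the patellar channel, relative to the femoral knee centre.
#' * `groove_wall` (1/mm): parabolic channel cross-section slope; the
#'   patellar centre rides at radial depth `R + groove_wall * shift^2`.
#' * `attachment_ap_offset` (mm): anterior stand-off of the quadriceps and
#'   tendon attachments on the patella (couples tilt/rotation to the loads).
#' * `quad_min`, `quad_gain`: quadriceps force = (quad_min + quad_gain *
#'   sin(flexion/2)) * body weight * g — a squat-like ramp.
#' * `hamstring_fraction`: constant force per hamstring as a body-weight
#'   fraction.
#' * `lig_stiffness` (N/mm): tension-only spring stiffnesses.
#' * `capsule_ie`, `patella_tilt_k`, `patella_rot_k` (N mm/rad): weak
#'   quadratic restraints that keep the free DOFs well-posed where the
#'   ligaments are slack.
#' * `ml_springs`: optional list of `list(k, rest)` springs acting directly
#'   on the shift DOF (used by reduced test models).
#' * `bw_coefficients`: see [estimate_body_weight()].
#' @return named list of parameters
#' @export
default_knee_params <- function() {
  list(
    groove_radius = 26,
    groove_center_offset = c(0, 2, 6),
    groove_wall = 0.06,
    attachment_ap_offset = 8,
    quad_min = 0.3,
    quad_gain = 1.7,
    hamstring_fraction = 0.08,
    lig_stiffness = c(acl = 120, pcl = 150, mcl = 80, lcl = 60),
    capsule_ie = 1000,
    patella_tilt_k = 20000,
    patella_rot_k = 20000,
    ml_springs = NULL,
    bw_coefficients = c(a = 2.741, b = -54.9),
    gravity = 9.81,
    reference_flexion_deg = 5,
    u_range = c(-2.1, 1.0)
  )
}

.lig_names <- c("acl", "pcl", "mcl", "lcl")
.ham_names <- c("biceps_femoris", "semimembranosus")

#' Build a knee model from a limb
#'
#' Ligament slack lengths are set so that every ligament is exactly at its
#' slack length at the preoperative reference pose (5 degrees flexion,
#' neutral free DOFs): zero pre-tension. When `base` (the preoperative model
#' of the same limb) is supplied, slack lengths, tendon length, patellar
#' length and body weight are inherited so that only the geometry differs —
#' this is how osteotomized models must be built.
#'
#' @param x `hto_limb` or `hto_osteotomized_limb`
#' @param params see [default_knee_params()]
#' @param base optional preoperative `hto_knee_model` to inherit
#'   calibration from
#' @return object of class `hto_knee_model`
#' @export
build_knee_model <- function(x, params = default_knee_params(), base = NULL) {
  lm <- x$landmarks
  if (is.null(lm)) stop("input carries no landmarks")
  for (nm in c(paste0(.lig_names, "_origin"), paste0(.lig_names, "_insertion"),
               paste0(.ham_names, "_origin"), paste0(.ham_names, "_insertion"),
               "patellar_tendon_insertion", "quadriceps_origin")) {
    if (is.null(lm[[nm]])) stop("missing attachment landmark: ", nm)
  }

  Kt <- lm$knee_center_tibia
  E0 <- (lm$medial_epicondyle + lm$lateral_epicondyle) / 2
  ie_axis <- unitv(Kt - lm$ankle_center)     # tibial long axis, proximal

  # tibial attachment points, relative to the tibial knee centre
  tib_rel <- rbind(
    acl = lm$acl_insertion - Kt,
    pcl = lm$pcl_insertion - Kt,
    mcl = lm$mcl_insertion - Kt,
    lcl = lm$lcl_insertion - Kt,
    biceps_femoris = lm$biceps_femoris_insertion - Kt,
    semimembranosus = lm$semimembranosus_insertion - Kt,
    tendon = lm$patellar_tendon_insertion - Kt
  )
  fem_pts <- rbind(
    acl = lm$acl_origin, pcl = lm$pcl_origin,
    mcl = lm$mcl_origin, lcl = lm$lcl_origin,
    biceps_femoris = lm$biceps_femoris_origin,
    semimembranosus = lm$semimembranosus_origin
  )

  if (is.null(base)) {
    L0 <- vnorm(lm$patellar_tendon_insertion - lm$patella_distal_pole)
    Lp <- vnorm(lm$patella_proximal_pole - lm$patella_distal_pole)
    bw <- estimate_body_weight(lm$femoral_head_diameter,
                               params$bw_coefficients)
    slack <- NULL  # computed below at the reference pose
  } else {
    L0 <- base$L0
    Lp <- base$Lp
    bw <- base$body_weight_kg
    slack <- base$slack
    params <- base$params
  }

  model <- structure(list(
    limb_id = x$limb_id,
    variant = x$variant %||% "preop",
    wedge_height_mm = x$wedge_height_mm %||% 0,
    params = params,
    Kt = Kt, E0 = E0, ie_axis = ie_axis,
    tib_rel = tib_rel, fem_pts = fem_pts,
    groove_center = lm$knee_center_femur + params$groove_center_offset,
    quad_origin = lm$quadriceps_origin,
    L0 = L0, Lp = Lp,
    body_weight_kg = bw,
    slack = slack
  ), class = "hto_knee_model")

  if (is.null(model$slack)) {
    ref <- .tibia_points(model, deg2rad(params$reference_flexion_deg), 0)
    lens <- sqrt(rowSums((fem_pts[.lig_names, , drop = FALSE] -
                            ref[.lig_names, , drop = FALSE])^2))
    model$slack <- lens
  }
  model
}

#' @export
print.hto_knee_model <- function(x, ...) {
  cat("<hto_knee_model> ", x$limb_id, " ", x$variant,
      if (x$variant != "preop") paste0(" h = ", x$wedge_height_mm, " mm"),
      ", BW = ", format(x$body_weight_kg, digits = 4), " kg\n", sep = "")
  invisible(x)
}

# positions of all tibial attachment points at flexion phi (rad) and
# external rotation psi (rad); rows as in model$tib_rel
.tibia_points <- function(model, phi, psi) {
  rel <- model$tib_rel
  if (psi != 0) {
    R_ie <- rotation_about_axis(model$ie_axis, -psi)
    rel <- rel %*% t(R_ie)
  }
  p1 <- sweep(rel, 2L, model$Kt, "+")
  # flexion about the global +X direction through the epicondylar midpoint
  cph <- cos(phi); sph <- sin(phi)
  rel2 <- sweep(p1, 2L, model$E0, "-")
  y <- rel2[, 2L]; z <- rel2[, 3L]
  rel2[, 2L] <- y * cph + z * sph
  rel2[, 3L] <- -y * sph + z * cph
  sweep(rel2, 2L, model$E0, "+")
}

#' Total ligament elastic energy at a pose
#'
#' @param model `hto_knee_model`
#' @param flexion_deg knee flexion (deg)
#' @param psi_deg external tibial rotation (deg)
#' @return energy in N mm
#' @export
ligament_energy <- function(model, flexion_deg, psi_deg = 0) {
  pts <- .tibia_points(model, deg2rad(flexion_deg), deg2rad(psi_deg))
  lens <- sqrt(rowSums((model$fem_pts[.lig_names, , drop = FALSE] -
                          pts[.lig_names, , drop = FALSE])^2))
  k <- model$params$lig_stiffness[.lig_names]
  sum(0.5 * k * pmax(0, lens - model$slack[.lig_names])^2)
}
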