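# Virtual biplanar medial open-wedge high tibial osteotomy.
#
# The main cut runs from a medial entry point (at a depth of half the
# plateau width below the plateau) to a lateral sagittal hinge axis 15 mm
# below the plateau, parallel to the medial tibial slope. A coronal biplanar
# cut passes 10 mm posterior to the tibial tuberosity and is extended
# proximally (ascending) or distally (descending), which decides whether the
# tuberosity travels with the moving distal fragment. Opening the wedge is a
# pure rotation of the distal fragment about the hinge axis; the proximal
# (plateau) fragment and the femur stay fixed, so all postoperative
# measurements live in the fixed frame.

#' Plan a biplanar open-wedge osteotomy
#'
#' @param limb `hto_limb`
#' @param variant `"ascending"` or `"descending"`
#' @param params list of plan parameters: `hinge_depth_mm` (depth of the
#'   hinge below the plateau, default 15), `biplanar_offset_mm` (posterior
#'   offset of the coronal cut behind the tuberosity apex, default 10),
#'   `angle_mode` (`"chord"` or `"arctan"`, see
#'   [wedge_angle_from_height()]), `medial_slope_deg` (overrides the limb's
#'   stored slope).
#' @return object of class `hto_osteotomy_plan`
#' @export
plan_osteotomy <- function(limb, variant = c("ascending", "descending"),
                           params = list()) {
  variant <- match.arg(variant)
  lm <- limb$landmarks
  hinge_depth <- params$hinge_depth_mm %||% 15
  bp_offset <- params$biplanar_offset_mm %||% 10
  angle_mode <- params$angle_mode %||% "chord"
  slope_deg <- params$medial_slope_deg %||% limb$profile$medial_slope_deg %||% 7

  plateau_width <- vnorm(lm$lateral_plateau_edge - lm$medial_plateau_edge)
  entry_depth <- plateau_width / 2

  cortex_x <- function(depth, side) {
    z <- -depth
    if (!is.null(limb$profile)) {
      sec <- tibia_section(z, limb$profile$half_width, limb$profile$ankle)
      sec$center[1L] + side * sec$a
    } else if (!is.null(limb$tibia_mesh)) {
      sel <- abs(limb$tibia_mesh$vertices[, 3L] - z) <= 1.5
      if (!any(sel)) stop("cannot locate tibial cortex at depth ", depth)
      if (side > 0) max(limb$tibia_mesh$vertices[sel, 1L]) else
        min(limb$tibia_mesh$vertices[sel, 1L])
    } else {
      stop("limb carries neither a shaft profile nor a tibia mesh")
    }
  }

  entry <- c(cortex_x(entry_depth, -1), 0, -entry_depth)
  hinge_point <- c(cortex_x(hinge_depth, +1), 0, -hinge_depth)
  slope <- deg2rad(slope_deg)
  hinge_dir <- c(0, cos(slope), sin(slope))  # sagittal, AP-oriented, sloped

  normal <- unitv(vcross(entry - hinge_point, hinge_dir))
  if (normal[3L] < 0) normal <- -normal

  frames <- anatomical_frames(lm)
  ap_t <- frames$tibial$ap
  apex <- lm$tibial_tuberosity_apex
  if (sum((apex - lm$knee_center_tibia) * ap_t) <= 0) {
    stop("degenerate anatomy: tuberosity not anterior to the plateau centre")
  }
  bp_point <- apex - bp_offset * ap_t

  z_exit <- min(apex[3L], lm$patellar_tendon_insertion[3L]) - 8

  structure(list(
    main_cut_plane = list(point = hinge_point, normal = normal),
    medial_entry_point = entry,
    hinge_axis = list(point = hinge_point, direction = hinge_dir),
    biplanar_plane = list(point = bp_point, normal = ap_t),
    variant = variant,
    W = vnorm(entry - hinge_point),
    lever = point_line_distance(entry, hinge_point, hinge_dir),
    angle_mode = angle_mode,
    z_exit = z_exit,
    plateau_width_mm = plateau_width,
    entry_depth_mm = entry_depth,
    hinge_depth_mm = hinge_depth,
    biplanar_offset_mm = bp_offset
  ), class = "hto_osteotomy_plan")
}

#' @export
print.hto_osteotomy_plan <- function(x, ...) {
  cat("<hto_osteotomy_plan> ", x$variant, " cut, W = ",
      format(x$W, digits = 5), " mm (lever ", format(x$lever, digits = 5),
      " mm)\n", sep = "")
  invisible(x)
}

#' Opening angle for a given medial wedge height
#'
#' With `angle_mode = "chord"` (default) the angle is
#' `theta = 2 asin(h / (2 W))`: the rotation about the hinge that separates
#' the images of the medial entry point on the two cut faces by a chord of
#' length `h`, where `W` is the perpendicular distance from the entry point
#' to the hinge axis. `"arctan"` gives the small-angle plate-gauge reading
#' `theta = atan(h / W)`.
#'
#' @param h wedge height in mm, `0 <= h < 2 W`
#' @param plan `hto_osteotomy_plan` (or any list with `lever` and
#'   `angle_mode`)
#' @return opening angle in degrees
#' @export
wedge_angle_from_height <- function(h, plan) {
  W <- plan$lever %||% plan$W
  mode <- plan$angle_mode %||% "chord"
  if (h < 0) stop("wedge height must be non-negative")
  if (h >= 2 * W) stop("geometrically impossible opening: h >= 2W")
  if (mode == "chord") {
    rad2deg(2 * asin(h / (2 * W)))
  } else if (mode == "arctan") {
    rad2deg(atan(h / W))
  } else {
    stop("unknown angle_mode: ", mode)
  }
}

# landmarks carried by the tuberosity block (side decided by the variant)
.tuberosity_block <- c("tibial_tuberosity_apex", "patellar_tendon_insertion")

#' Assign tibial landmarks to the proximal or distal fragment
#'
#' Assignment follows the signed distance to the main cut plane, except for
#' the tuberosity block which travels with the distal fragment for an
#' ascending cut and stays proximal for a descending cut. The ankle centre
#' must land distal and the plateau landmarks proximal, otherwise the plan
#' is degenerate.
#'
#' @param lm `hto_landmarks`
#' @param plan `hto_osteotomy_plan`
#' @return named character vector ("proximal"/"distal") over tibial landmarks
#' @export
assign_fragments <- function(lm, plan) {
  nms <- tibial_landmark_names()
  out <- vapply(nms, function(nm) {
    d <- plane_signed_distance(lm[[nm]], plan$main_cut_plane$point,
                               plan$main_cut_plane$normal)
    if (d >= 0) "proximal" else "distal"
  }, character(1L))
  out[.tuberosity_block] <-
    if (plan$variant == "ascending") "distal" else "proximal"
  if (out[["ankle_center"]] != "distal") {
    stop("degenerate plan: ankle centre not in the distal fragment")
  }
  for (nm in c("knee_center_tibia", "medial_plateau_edge", "lateral_plateau_edge")) {
    if (out[[nm]] != "proximal") stop("degenerate plan: ", nm, " not proximal")
  }
  out
}

#' Split the tibia into osteotomy fragments
#'
#' Cuts the tibia mesh with the main and biplanar planes. For an ascending
#' cut the anterior block above the main plane (carrying the tuberosity)
#' joins the distal fragment; for a descending cut the anterior block below
#' the main plane down to the exit level stays with the proximal fragment.
#' Fragments may consist of more than one closed shell (the anterior block
#' abuts its parent piece across the cut face); every shell is watertight
#' and volumes are additive.
#'
#' @param limb `hto_limb` with a tibia mesh
#' @param plan `hto_osteotomy_plan`
#' @return list with `proximal`, `distal` (`hto_mesh`) and
#'   `landmark_assignment`
#' @export
split_fragments <- function(limb, plan) {
  mesh <- limb$tibia_mesh
  if (is.null(mesh)) stop("limb has no tibia mesh")
  mp <- plan$main_cut_plane
  bp <- plan$biplanar_plane

  above <- clip_mesh(mesh, mp$point, mp$normal)
  below <- clip_mesh(mesh, mp$point, -mp$normal)
  if (is.null(above) || is.null(below)) stop("main cut misses the tibia")

  if (plan$variant == "ascending") {
    prox <- clip_mesh(above, bp$point, -bp$normal)     # posterior part
    ant_block <- clip_mesh(above, bp$point, bp$normal) # anterior block
    dist <- mesh_concat(below, ant_block)
  } else {
    below_ant <- clip_mesh(below, bp$point, bp$normal)
    below_post <- clip_mesh(below, bp$point, -bp$normal)
    exit_pt <- c(0, 0, plan$z_exit)
    block <- if (!is.null(below_ant))
      clip_mesh(below_ant, exit_pt, c(0, 0, 1)) else NULL
    tail_ <- if (!is.null(below_ant))
      clip_mesh(below_ant, exit_pt, c(0, 0, -1)) else NULL
    prox <- mesh_concat(above, block)
    dist <- mesh_concat(below_post, tail_)
  }
  if (is.null(prox) || is.null(dist)) stop("osteotomy produced an empty fragment")
  if (!mesh_is_watertight(prox) || !mesh_is_watertight(dist)) {
    stop("osteotomy produced a non-watertight fragment")
  }
  list(proximal = prox, distal = dist,
       landmark_assignment = assign_fragments(limb$landmarks, plan))
}

#' Execute the wedge opening
#'
#' Rotates the distal fragment (mesh, when present, and its landmarks) about
#' the hinge axis by the opening angle for wedge height `h`. `h = 0` returns
#' the input geometry unchanged (bitwise). The proximal fragment is the
#' fixed body.
#'
#' @param limb `hto_limb`
#' @param plan `hto_osteotomy_plan`
#' @param h wedge height in mm (the experimental grid uses 6 to 12)
#' @param meshes split and transform the fragment meshes (requires a tibia
#'   mesh on the limb)
#' @return object of class `hto_osteotomized_limb`
#' @export
apply_wedge <- function(limb, plan, h, meshes = FALSE) {
  if (h < 0 || h > 12) stop("wedge height must be in [0, 12] mm")
  theta <- wedge_angle_from_height(h, plan)
  assignment <- assign_fragments(limb$landmarks, plan)

  if (h == 0) {
    tf <- rigid_identity()
    lm <- limb$landmarks
  } else {
    R <- rotation_about_axis(plan$hinge_axis$direction, -deg2rad(theta))
    tf <- rigid_about_point(R, plan$hinge_axis$point)
    lm <- transform_landmarks(limb$landmarks, tf,
                              names(assignment)[assignment == "distal"])
  }

  frag <- NULL
  if (meshes) {
    frag <- split_fragments(limb, plan)
    if (h > 0) frag$distal <- transform_mesh(frag$distal, tf)
  }

  structure(list(
    limb_id = limb$limb_id,
    variant = plan$variant,
    wedge_height_mm = h,
    wedge_angle_deg = theta,
    landmarks = lm,
    wedge_transform = tf,
    landmark_assignment = assignment,
    plan = plan,
    proximal_fragment_mesh = frag$proximal,
    distal_fragment_mesh = frag$distal,
    patellar_shift_pd_mm = 0
  ), class = "hto_osteotomized_limb")
}

#' @export
print.hto_osteotomized_limb <- function(x, ...) {
  cat("<hto_osteotomized_limb> ", x$limb_id, " ", x$variant, " h = ",
      x$wedge_height_mm, " mm (theta = ", format(x$wedge_angle_deg, digits = 4),
      " deg)\n", sep = "")
  invisible(x)
}

#' Measured medial opening gap of an osteotomized limb
#'
#' Distance between the images of the medial entry point on the fixed and
#' the moving cut face; equals the wedge height by construction.
#'
#' @param ost `hto_osteotomized_limb`
#' @return gap in mm
#' @export
medial_gap <- function(ost) {
  e <- ost$plan$medial_entry_point
  vnorm(apply_rigid(ost$wedge_transform, e) - e)
}

#' Run the full osteotomy grid over a cohort
#'
#' Every limb is cut with every variant at every wedge height; ascending
#' models are followed by the patellar repositioning step (see
#' [reposition_patella()]) unless `reposition = FALSE`.
#'
#' @param cohort list of `hto_limb`
#' @param heights wedge heights in mm (default 6:12)
#' @param variants cut variants (default both)
#' @param meshes carry fragment meshes (slower; default FALSE)
#' @param reposition apply patellar repositioning to ascending models
#' @param params plan parameters forwarded to [plan_osteotomy()]
#' @return list of `hto_osteotomized_limb`, length
#'   `length(cohort) * length(variants) * length(heights)`
#' @export
run_osteotomy_grid <- function(cohort, heights = 6:12,
                               variants = c("ascending", "descending"),
                               meshes = FALSE, reposition = TRUE,
                               params = list()) {
  if (length(cohort) == 0L) stop("empty cohort")
  out <- vector("list", length(cohort) * length(variants) * length(heights))
  k <- 0L
  for (limb in cohort) {
    for (v in variants) {
      plan <- plan_osteotomy(limb, v, params)
      for (h in heights) {
        ost <- tryCatch(
          {
            o <- apply_wedge(limb, plan, h, meshes = meshes)
            if (reposition && v == "ascending") {
              o <- reposition_patella_limb(o, limb)
            }
            o
          },
          error = function(e) {
            stop("osteotomy failed for limb ", limb$limb_id, ", variant ", v,
                 ", height ", h, ": ", conditionMessage(e))
          })
        k <- k + 1L
        out[[k]] <- ost
      }
    }
  }
  names(out) <- vapply(out, function(o) {
    paste(o$limb_id, o$variant, o$wedge_height_mm, sep = "_")
  }, character(1L))
  out
}
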