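# Landmark sets: the geometric substrate of every operation in the package.
#
# A landmark set is a named list of 3D points (mm) plus the scalar femoral
# head diameter. The point names are fixed by `landmark_point_names()`;
# ligament and muscle attachments are stored as origin/insertion pairs with
# the femoral (or proximal) attachment called "origin".

#' Names of the 3D point landmarks
#'
#' @return character vector of required point-landmark names.
#' @export
landmark_point_names <- function() {
  c("hip_center", "knee_center_femur", "knee_center_tibia", "ankle_center",
    "medial_plateau_edge", "lateral_plateau_edge",
    "tibial_tuberosity_apex", "patellar_tendon_insertion",
    "trochlear_groove_point",
    "medial_epicondyle", "lateral_epicondyle",
    "patella_center", "patella_proximal_pole", "patella_distal_pole",
    "quadriceps_origin",
    "acl_origin", "acl_insertion", "pcl_origin", "pcl_insertion",
    "mcl_origin", "mcl_insertion", "lcl_origin", "lcl_insertion",
    "biceps_femoris_origin", "biceps_femoris_insertion",
    "semimembranosus_origin", "semimembranosus_insertion")
}

#' Landmarks that belong to the tibia (move in an osteotomy)
#' @keywords internal
tibial_landmark_names <- function() {
  c("knee_center_tibia", "ankle_center",
    "medial_plateau_edge", "lateral_plateau_edge",
    "tibial_tuberosity_apex", "patellar_tendon_insertion",
    "acl_insertion", "pcl_insertion", "mcl_insertion", "lcl_insertion",
    "biceps_femoris_insertion", "semimembranosus_insertion")
}

#' Construct and validate a landmark set
#'
#' @param points named list of numeric(3) points (mm); names must cover
#'   [landmark_point_names()].
#' @param femoral_head_diameter femoral head diameter in mm (> 0); input to
#'   the body-weight regression used by the squat simulator.
#' @return object of class `hto_landmarks`
#' @export
hto_landmarks <- function(points, femoral_head_diameter) {
  required <- landmark_point_names()
  missing <- setdiff(required, names(points))
  if (length(missing) > 0L) {
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  }
  points <- lapply(points[required], as.numeric)
  ok <- vapply(points, function(p) length(p) == 3L && all(is.finite(p)),
               logical(1L))
  if (!all(ok)) {
    stop("non-finite or malformed landmark(s): ",
         paste(required[!ok], collapse = ", "))
  }
  if (!is.finite(femoral_head_diameter) || femoral_head_diameter <= 0) {
    stop("femoral_head_diameter must be a positive finite scalar")
  }
  structure(c(points, list(femoral_head_diameter = femoral_head_diameter)),
            class = "hto_landmarks")
}

#' @export
print.hto_landmarks <- function(x, ...) {
  cat("<hto_landmarks> ", length(landmark_point_names()), " points, ",
      "femoral head diameter ", format(x$femoral_head_diameter, digits = 4),
      " mm\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to a subset of landmarks
#'
#' @param lm `hto_landmarks`
#' @param tf `hto_rigid`
#' @param which names of the landmarks to transform (default: all points)
#' @return transformed `hto_landmarks`
#' @export
transform_landmarks <- function(lm, tf, which = landmark_point_names()) {
  for (nm in which) lm[[nm]] <- apply_rigid(tf, lm[[nm]])
  lm
}

#' Mirror a landmark set in the sagittal plane
#'
#' Reflects all points in the x = 0 plane and swaps the medial/lateral
#' labels so that the result is a valid landmark set of the opposite side.
#'
#' @param lm `hto_landmarks`
#' @param relabel swap medial/lateral landmark names (default TRUE). With
#'   `relabel = FALSE` the output is a pure geometric reflection, useful for
#'   symmetry testing but not a valid opposite-side anatomy.
#' @return mirrored `hto_landmarks`
#' @export
mirror_landmarks <- function(lm, relabel = TRUE) {
  for (nm in landmark_point_names()) lm[[nm]] <- mirror_x(lm[[nm]])
  if (relabel) {
    swaps <- list(c("medial_plateau_edge", "lateral_plateau_edge"),
                  c("medial_epicondyle", "lateral_epicondyle"))
    for (sw in swaps) {
      tmp <- lm[[sw[1L]]]
      lm[[sw[1L]]] <- lm[[sw[2L]]]
      lm[[sw[2L]]] <- tmp
    }
  }
  lm
}

#' Landmark matrix (points as rows)
#' @keywords internal
landmarks_as_matrix <- function(lm) {
  nms <- landmark_point_names()
  m <- do.call(rbind, lm[nms])
  rownames(m) <- nms
  m
}

# -- JSON serialisation (schema-versioned) ------------------------------------

LANDMARK_SCHEMA_VERSION <- "1.0"

#' Write a landmark set to JSON
#'
#' The schema is a flat object `{schema, units, femoral_head_diameter,
#' points: {name: [x, y, z], ...}}` with coordinates in mm.
#'
#' @param lm `hto_landmarks`
#' @param path output file path
#' @export
write_landmarks_json <- function(lm, path) {
  obj <- list(
    schema = paste0("htosim-landmarks-", LANDMARK_SCHEMA_VERSION),
    units = "mm",
    femoral_head_diameter = lm$femoral_head_diameter,
    points = lm[landmark_point_names()]
  )
  # digits = I(17): full double precision, so the round trip is bitwise
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a landmark set from JSON
#'
#' @param path file written by [write_landmarks_json()]
#' @return `hto_landmarks`
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!grepl("^htosim-landmarks-", obj$schema %||% "")) {
    stop("not an htosim landmark file: ", path)
  }
  hto_landmarks(as.list(obj$points), obj$femoral_head_diameter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
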