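# Anatomical coordinate frames and index measurement.
#
# All indices are computed from landmarks alone, so they apply equally to
# generated, osteotomized, and user-supplied limbs. The femur never moves in
# an osteotomy, so postoperative indices are always expressed in the fixed
# femoral/plateau frame.

#' Anatomical coordinate frames from a landmark set
#'
#' Femoral frame: ML axis from the epicondyles (pointing lateral),
#' proximodistal axis toward the hip, AP axis completing the right-handed
#' set (pointing anterior). Tibial frame: origin at the tibial knee centre,
#' long axis toward the hip side (opposite the ankle), ML axis from the
#' plateau edges. Patellar frame: origin at the patella centre, long axis
#' from the poles, AP axis orthogonalised from the femoral AP axis.
#'
#' Each basis is orthonormal to 1e-9 and right-handed.
#'
#' @param lm `hto_landmarks`
#' @return object of class `hto_frames`, a list of three frames each with
#'   `origin`, `ml`, `ap`, `pd` unit axes.
#' @export
anatomical_frames <- function(lm) {
  ml_f <- unitv(lm$lateral_epicondyle - lm$medial_epicondyle)
  pd_raw <- lm$hip_center - lm$knee_center_femur
  if (vnorm(vcross(ml_f, pd_raw)) < 1e-9) stop("degenerate femoral axes")
  pd_f <- orthogonalise(pd_raw, ml_f)
  ap_f <- vcross(pd_f, ml_f)
  femoral <- list(origin = lm$knee_center_femur, ml = ml_f, ap = ap_f, pd = pd_f)

  pd_t_raw <- lm$knee_center_tibia - lm$ankle_center
  ml_t_raw <- lm$lateral_plateau_edge - lm$medial_plateau_edge
  pd_t <- unitv(pd_t_raw)
  ml_t <- orthogonalise(ml_t_raw, pd_t)
  ap_t <- vcross(pd_t, ml_t)
  tibial <- list(origin = lm$knee_center_tibia, ml = ml_t, ap = ap_t, pd = pd_t)

  pd_p <- unitv(lm$patella_proximal_pole - lm$patella_distal_pole)
  ap_p <- orthogonalise(ap_f, pd_p)
  ml_p <- vcross(ap_p, pd_p)
  patellar <- list(origin = lm$patella_center, ml = ml_p, ap = ap_p, pd = pd_p)

  structure(list(femoral = femoral, tibial = tibial, patellar = patellar),
            class = "hto_frames")
}

#' Hip-knee-ankle (HKA) angle in degrees
#'
#' The coronal-plane angle at the knee between the knee-to-hip and
#' knee-to-ankle vectors. 180 degrees is neutral alignment; varus gives
#' values below 180. When the full landmark set is available the angle is
#' signed through the mediolateral sense of the ankle offset, so valgus
#' alignment (including overcorrection past neutral) reads above 180 and a
#' valgizing osteotomy always produces a positive change. With only three
#' points the unsigned (varus-convention) angle is returned.
#'
#' @param lm `hto_landmarks`, or NULL when the three points are given
#'   explicitly
#' @param hip,knee,ankle explicit points (mm), used when `lm` is NULL;
#'   `knee` is the tibial knee centre.
#' @return HKA angle in degrees
#' @export
hka_angle <- function(lm = NULL, hip = NULL, knee = NULL, ankle = NULL) {
  ml <- NULL
  if (!is.null(lm)) {
    hip <- lm$hip_center
    knee <- lm$knee_center_tibia
    ankle <- lm$ankle_center
    ml <- unitv(lm$lateral_epicondyle - lm$medial_epicondyle)
  }
  u <- hip - knee
  v <- ankle - knee
  if (vnorm(u) < 1e-9 || vnorm(v) < 1e-9) stop("coincident HKA points")
  if (is.null(ml)) {
    return(vangle_deg(u, v))
  }
  if (vnorm(vcross(ml, u)) < 1e-9) stop("mechanical axis parallel to ML axis")
  ap <- unitv(vcross(ml, u))           # coronal-plane normal
  v_proj <- v - sum(v * ap) * ap
  if (vnorm(v_proj) < 1e-9) stop("degenerate ankle projection")
  alpha <- vangle_deg(u, v_proj)
  lat <- sum(v_proj * ml)
  if (lat > 0) 360 - alpha else alpha  # ankle lateral => valgus (> 180)
}

#' Axial tibial tuberosity-trochlear groove (TT-TG) distance in mm
#'
#' Signed mediolateral distance (along the femoral epicondylar ML axis,
#' lateral positive) between the tibial tuberosity apex and the trochlear
#' groove point after projection onto the femoral axial plane.
#'
#' @param lm `hto_landmarks`
#' @param frames optional precomputed [anatomical_frames()]
#' @return TT-TG in mm, lateral positive
#' @export
tt_tg_axial <- function(lm, frames = NULL) {
  if (is.null(frames)) frames <- anatomical_frames(lm)
  ml <- frames$femoral$ml
  if (abs(vnorm(ml) - 1) > 1e-6) stop("degenerate femoral ML axis")
  sum((lm$tibial_tuberosity_apex - lm$trochlear_groove_point) * ml)
}

#' Insall-Salvati index
#'
#' Patellar tendon length (3D distance from the distal patellar pole to the
#' tendon insertion on the tuberosity) divided by the patellar length (3D
#' pole-to-pole distance). Measured in 3D rather than on a simulated lateral
#' radiograph; see the methods vignette for the consequences.
#'
#' @param lm `hto_landmarks`
#' @return dimensionless ratio
#' @export
insall_salvati <- function(lm) {
  pat_len <- vnorm(lm$patella_proximal_pole - lm$patella_distal_pole)
  if (pat_len < 1e-9) stop("zero patellar length")
  vnorm(lm$patellar_tendon_insertion - lm$patella_distal_pole) / pat_len
}

#' Measure all anatomical indices of a limb
#'
#' @param x an `hto_limb`, `hto_osteotomized_limb`, or `hto_landmarks`
#' @return list with `hka_deg`, `ttg_mm`, `is_ratio`
#' @export
measure_indices <- function(x) {
  lm <- if (inherits(x, "hto_landmarks")) x else x$landmarks
  frames <- anatomical_frames(lm)
  list(hka_deg = hka_angle(lm),
       ttg_mm = tt_tg_axial(lm, frames),
       is_ratio = insall_salvati(lm))
}

#' Build the pre/post anatomical index table
#'
#' One row per preoperative limb (variant "pre", wedge height 0) and one per
#' osteotomized model, with deltas relative to the matching preoperative
#' limb computed as exactly post minus pre.
#'
#' @param cohort_pre list of `hto_limb`
#' @param cohort_post list of `hto_osteotomized_limb`
#' @return data.frame with columns limb_id, variant, wedge_height_mm,
#'   hka_deg, ttg_mm, is_ratio, d_hka, d_ttg, d_is
#' @export
build_index_table <- function(cohort_pre, cohort_post) {
  pre_ids <- vapply(cohort_pre, function(l) l$limb_id, character(1L))
  pre_idx <- lapply(cohort_pre, measure_indices)
  names(pre_idx) <- pre_ids

  rows <- vector("list", length(cohort_pre) + length(cohort_post))
  for (i in seq_along(cohort_pre)) {
    m <- pre_idx[[i]]
    rows[[i]] <- data.frame(limb_id = pre_ids[i], variant = "pre",
                            wedge_height_mm = 0,
                            hka_deg = m$hka_deg, ttg_mm = m$ttg_mm,
                            is_ratio = m$is_ratio,
                            d_hka = 0, d_ttg = 0, d_is = 0)
  }
  for (j in seq_along(cohort_post)) {
    ost <- cohort_post[[j]]
    if (!ost$limb_id %in% pre_ids) {
      stop("no preoperative limb for ", ost$limb_id)
    }
    m <- measure_indices(ost)
    p <- pre_idx[[ost$limb_id]]
    rows[[length(cohort_pre) + j]] <- data.frame(
      limb_id = ost$limb_id, variant = ost$variant,
      wedge_height_mm = ost$wedge_height_mm,
      hka_deg = m$hka_deg, ttg_mm = m$ttg_mm, is_ratio = m$is_ratio,
      d_hka = m$hka_deg - p$hka_deg,
      d_ttg = m$ttg_mm - p$ttg_mm,
      d_is = m$is_ratio - p$is_ratio)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check grid completeness of an index table
#'
#' Errors naming the first missing (limb, variant, height) cell.
#'
#' @param table output of [build_index_table()]
#' @param variants,heights the expected experimental grid
#' @return invisible TRUE when complete
#' @export
check_index_table_grid <- function(table, variants = c("ascending", "descending"),
                                   heights = 6:12) {
  limbs <- unique(table$limb_id)
  for (l in limbs) {
    for (v in variants) {
      for (h in heights) {
        hit <- table$limb_id == l & table$variant == v &
          table$wedge_height_mm == h
        if (!any(hit)) {
          stop("missing grid cell: limb ", l, ", variant ", v, ", height ", h)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Per-(variant, height) summary of index changes
#'
#' @param table output of [build_index_table()]
#' @return data.frame of means and SDs of the deltas per variant and height
#' @export
index_table_summary <- function(table) {
  post <- table[table$variant != "pre", , drop = FALSE]
  if (nrow(post) == 0L) stop("no postoperative rows")
  key <- paste(post$variant, post$wedge_height_mm, sep = "|")
  lv <- sort(unique(key))
  agg <- function(col, f) {
    vapply(lv, function(k) f(post[[col]][key == k]), numeric(1L))
  }
  meta <- do.call(rbind, strsplit(lv, "|", fixed = TRUE))
  out <- data.frame(
    variant = meta[, 1L],
    wedge_height_mm = as.numeric(meta[, 2L]),
    mean_d_hka = agg("d_hka", mean), sd_d_hka = agg("d_hka", stats::sd),
    mean_d_ttg = agg("d_ttg", mean), sd_d_ttg = agg("d_ttg", stats::sd),
    mean_d_is = agg("d_is", mean), sd_d_is = agg("d_is", stats::sd)
  )
  rownames(out) <- NULL
  out[order(out$variant, out$wedge_height_mm), , drop = FALSE]
}
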