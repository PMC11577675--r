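# Patellar repositioning after an ascending-cut osteotomy.
#
# When the tuberosity travels with the distal fragment, the patellar tendon
# insertion moves distally and laterally. The patella is then repositioned
# as a rigid body by a pure proximodistal translation: the distal pole keeps
# its anterior-posterior and mediolateral coordinates in the femoral frame
# and slides along the proximodistal axis until the tendon regains its
# preoperative length. Descending models are untouched. Any induced tilt or
# rotation is the squat simulator's business, not an anatomy update.

#' Patella state
#'
#' @param center,proximal_pole,distal_pole 3D points (mm)
#' @param tendon_length preoperative patellar tendon length L0 (mm)
#' @return object of class `hto_patella_state`
#' @export
patella_state <- function(center, proximal_pole, distal_pole, tendon_length) {
  if (vnorm(proximal_pole - distal_pole) <= 0) stop("zero pole distance")
  if (tendon_length <= 0) stop("tendon length must be positive")
  structure(list(center = center, proximal_pole = proximal_pole,
                 distal_pole = distal_pole, tendon_length = tendon_length),
            class = "hto_patella_state")
}

#' Reposition the patella under the tendon-length constraint
#'
#' For the descending variant the input is returned unchanged. For the
#' ascending variant the distal pole keeps its AP and ML femoral-frame
#' coordinates; its proximodistal coordinate `z` solves
#' `|distal_pole(z) - post_insertion| = L0`, taking the proximal (larger-z)
#' root, and the whole patella is translated rigidly by the same shift.
#'
#' @param pre `hto_patella_state` (preoperative)
#' @param post_insertion postoperative tendon insertion point (mm)
#' @param frames [anatomical_frames()] of the (unmoved) femur
#' @param variant `"ascending"` or `"descending"`
#' @return repositioned `hto_patella_state`; attribute `"pd_shift_mm"`
#'   carries the signed proximodistal translation (negative = distal).
#' @export
reposition_patella <- function(pre, post_insertion, frames,
                               variant = c("ascending", "descending")) {
  variant <- match.arg(variant)
  if (variant == "descending") {
    attr(pre, "pd_shift_mm") <- 0
    return(pre)
  }
  fem <- frames$femoral
  L0 <- pre$tendon_length
  rel <- pre$distal_pole - fem$origin
  q <- post_insertion - fem$origin
  dml <- sum(rel * fem$ml) - sum(q * fem$ml)
  dap <- sum(rel * fem$ap) - sum(q * fem$ap)
  disc <- L0^2 - dml^2 - dap^2
  if (disc < 0) {
    stop("patellar repositioning infeasible: tendon length ", format(L0),
         " mm cannot reach the new insertion (in-plane offset ",
         format(sqrt(dml^2 + dap^2)), " mm)")
  }
  z_old <- sum(rel * fem$pd)
  z_new <- sum(q * fem$pd) + sqrt(disc)  # proximal root
  shift <- (z_new - z_old) * fem$pd
  out <- patella_state(pre$center + shift, pre$proximal_pole + shift,
                       pre$distal_pole + shift, L0)
  attr(out, "pd_shift_mm") <- z_new - z_old
  out
}

#' Apply patellar repositioning to an osteotomized limb
#'
#' Builds the preoperative patella state from the parent limb, repositions
#' against the transformed tendon insertion, and writes the patellar
#' landmarks back. Infeasibility errors name the limb and wedge height.
#'
#' @param ost `hto_osteotomized_limb`
#' @param pre_limb the parent `hto_limb`
#' @return updated `hto_osteotomized_limb` (field `patellar_shift_pd_mm`)
#' @export
reposition_patella_limb <- function(ost, pre_limb) {
  lm_pre <- pre_limb$landmarks
  L0 <- vnorm(lm_pre$patellar_tendon_insertion - lm_pre$patella_distal_pole)
  pre <- patella_state(lm_pre$patella_center, lm_pre$patella_proximal_pole,
                       lm_pre$patella_distal_pole, L0)
  frames <- anatomical_frames(lm_pre)
  post <- tryCatch(
    reposition_patella(pre, ost$landmarks$patellar_tendon_insertion, frames,
                       ost$variant),
    error = function(e) {
      stop("limb ", ost$limb_id, ", height ", ost$wedge_height_mm, " mm: ",
           conditionMessage(e))
    })
  ost$landmarks$patella_center <- post$center
  ost$landmarks$patella_proximal_pole <- post$proximal_pole
  ost$landmarks$patella_distal_pole <- post$distal_pole
  ost$patellar_shift_pd_mm <- attr(post, "pd_shift_mm")
  ost
}
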