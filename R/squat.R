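# Quasi-static squat solver.
#
# At each prescribed flexion angle the free DOFs
#   x = (psi, s, tau, rho)
#     = (tibial external rotation [rad], patellar lateral shift [mm],
#        patellar tilt [rad], patellar mediolateral rotation [rad])
# minimise the total potential energy subject to two geometric constraints
# that are eliminated analytically: the patellar centre rides the trochlear
# channel surface, and the patellar track coordinate u is the root of the
# inextensible-tendon condition |A_t(u) - q| = L0. The energy gradient is
# analytic (including the implicit du/dx terms via the implicit function
# theorem), which lets the solver reach gradient norms near machine
# precision and keeps the 18k-solve default experiment fast.

.xhat <- c(1, 0, 0)

# cross(x_hat, w)
.xcross <- function(w) c(0, -w[3L], w[2L])

# energy and gradient evaluator at fixed flexion; returns a closure that
# carries the warm-started track coordinate u between calls
.make_pose_evaluator <- function(model, flexion_deg) {
  par <- model$params
  phi <- deg2rad(flexion_deg)
  cph <- cos(phi); sph <- sin(phi)
  E0 <- model$E0; Kt <- model$Kt
  ie <- model$ie_axis
  rel <- model$tib_rel
  fem <- model$fem_pts
  lig_idx <- match(.lig_names, rownames(rel))
  ham_idx <- match(.ham_names, rownames(rel))
  ten_idx <- match("tendon", rownames(rel))
  k_lig <- as.numeric(par$lig_stiffness[.lig_names])
  slack <- as.numeric(model$slack[.lig_names])
  g_N <- par$gravity
  bw_N <- model$body_weight_kg * g_N
  F_ham <- par$hamstring_fraction * bw_N
  F_q <- (par$quad_min + par$quad_gain * sin(phi / 2)) * bw_N
  Oq <- model$quad_origin
  C <- model$groove_center
  Rg <- par$groove_radius
  kap <- par$groove_wall
  o_ap <- par$attachment_ap_offset
  Lp <- model$Lp
  L0 <- model$L0
  l_t <- c(0, o_ap, -Lp / 2)
  l_q <- c(0, o_ap, Lp / 2)
  k_psi <- par$capsule_ie
  k_tau <- par$patella_tilt_k
  k_rho <- par$patella_rot_k
  ml_springs <- par$ml_springs
  u_range <- par$u_range

  flex <- function(m) {
    # rotate rows of m (positions) about the global +X axis through E0
    m2 <- sweep(m, 2L, E0, "-")
    y <- m2[, 2L]; z <- m2[, 3L]
    m2[, 2L] <- y * cph + z * sph
    m2[, 3L] <- -y * sph + z * cph
    sweep(m2, 2L, E0, "+")
  }
  flex_dir <- function(m) {
    # rotate direction rows (no translation)
    y <- m[, 2L]; z <- m[, 3L]
    m[, 2L] <- y * cph + z * sph
    m[, 3L] <- -y * sph + z * cph
    m
  }

  env <- new.env(parent = emptyenv())
  env$u <- NULL
  env$last_par <- NULL
  env$last_res <- NULL

  solve_u <- function(mt, q, u0) {
    # Newton on h(u) = |C + s x + Rx(u) mt - q|^2 - L0^2 (s-term folded
    # into q by the caller), fallback to a bracketed bisection scan
    f_pair <- function(u) {
      cu <- cos(u); su <- sin(u)
      w <- c(mt[1L], cu * mt[2L] - su * mt[3L], su * mt[2L] + cu * mt[3L])
      r <- w - q
      list(h = sum(r * r) - L0^2, hu = 2 * sum(r * .xcross(w)), w = w, r = r)
    }
    u <- u0
    for (it in 1:40) {
      fp <- f_pair(u)
      if (abs(fp$h) < 1e-9 * max(1, L0^2)) {
        # accept only the branch adjacent to the warm start: the constraint
        # has two roots and branch hopping would make the energy
        # history-dependent
        if (abs(u - u0) < 0.5 &&
            u >= u_range[1L] - 0.3 && u <= u_range[2L] + 0.3) {
          return(list(u = u, w = fp$w, r = fp$r, hu = fp$hu))
        }
        break
      }
      if (abs(fp$hu) < 1e-12) break
      step <- fp$h / fp$hu
      if (abs(step) > 0.25) step <- sign(step) * 0.25
      u <- u - step
    }
    # bracketed fallback
    us <- seq(u_range[1L], u_range[2L], length.out = 121L)
    hv <- vapply(us, function(uu) f_pair(uu)$h, numeric(1L))
    sgn <- which(hv[-1L] * hv[-length(hv)] <= 0)
    if (length(sgn) == 0L) {
      # no root: signal infeasibility (distant line-search trial points hit
      # this; the caller turns it into a finite penalty)
      return(list(failed = TRUE, gap = min(abs(hv))))
    }
    # pick the bracket closest to the warm start
    j <- sgn[which.min(abs(us[sgn] - u0))]
    lo <- us[j]; hi <- us[j + 1L]
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f_pair(lo)$h * f_pair(mid)$h <= 0) hi <- mid else lo <- mid
    }
    u <- (lo + hi) / 2
    fp <- f_pair(u)
    list(u = u, w = fp$w, r = fp$r, hu = fp$hu)
  }

  evaluate <- function(x) {
    psi <- x[1L]; s <- x[2L]; tau <- x[3L]; rho <- x[4L]

    # --- tibia-side geometry -------------------------------------------
    if (psi != 0) {
      R_ie <- rotation_about_axis(ie, -psi)
      rel_ie <- rel %*% t(R_ie)
    } else {
      rel_ie <- rel
    }
    pts <- flex(sweep(rel_ie, 2L, Kt, "+"))
    # d(points)/dpsi = flex_dir(-ie x rel_ie)
    dpts <- flex_dir(cbind(
      -(ie[2L] * rel_ie[, 3L] - ie[3L] * rel_ie[, 2L]),
      -(ie[3L] * rel_ie[, 1L] - ie[1L] * rel_ie[, 3L]),
      -(ie[1L] * rel_ie[, 2L] - ie[2L] * rel_ie[, 1L])
    ))

    E <- 0.5 * k_psi * psi^2 + 0.5 * k_tau * tau^2 + 0.5 * k_rho * rho^2
    g <- c(k_psi * psi, 0, k_tau * tau, k_rho * rho)

    dvec <- fem - pts[c(lig_idx, ham_idx), , drop = FALSE]
    lens <- sqrt(rowSums(dvec * dvec))
    # d(len)/dpsi = -(d . dp)/len
    dlen <- -rowSums(dvec * dpts[c(lig_idx, ham_idx), , drop = FALSE]) / lens
    ext <- pmax(0, lens[1:4] - slack)
    E <- E + 0.5 * sum(k_lig * ext^2) + F_ham * sum(lens[5:6])
    g[1L] <- g[1L] + sum(k_lig * ext * dlen[1:4]) + F_ham * sum(dlen[5:6])

    if (!is.null(ml_springs)) {
      for (sp in ml_springs) {
        E <- E + 0.5 * sp$k * (s - sp$rest)^2
        g[2L] <- g[2L] + sp$k * (s - sp$rest)
      }
    }

    # --- patella with tendon-track constraint --------------------------
    ct <- cos(tau); st <- sin(tau)
    cr <- cos(rho); sr <- sin(rho)
    Rz_ <- function(v) c(ct * v[1L] + st * v[2L], -st * v[1L] + ct * v[2L], v[3L])
    Ry_ <- function(v) c(cr * v[1L] - sr * v[3L], v[2L], sr * v[1L] + cr * v[3L])
    zc <- function(v) c(-v[2L], v[1L], 0)  # cross(z_hat, v)
    yc <- function(v) c(v[3L], 0, -v[1L])  # cross(y_hat, v)

    gt0 <- Rz_(l_t); gt <- Ry_(gt0)
    gq0 <- Rz_(l_q); gq <- Ry_(gq0)
    gt_tau <- Ry_(-zc(gt0)); gq_tau <- Ry_(-zc(gq0))
    gt_rho <- -yc(gt); gq_rho <- -yc(gq)

    rad <- Rg + kap * s * s
    mt <- c(0, rad, 0) + gt
    mq <- c(0, rad, 0) + gq

    q <- pts[ten_idx, ]
    dq <- dpts[ten_idx, ]
    # fold C + s*xhat into an effective target for the u-solve
    q_eff <- q - C - s * .xhat
    # the branch anchor env$u is only ever advanced by accepted equilibrium
    # solutions (see solve_equilibrium_at_flexion), so the energy is a pure
    # function of x within one solve
    u0 <- env$u %||% 0.3
    sol <- solve_u(mt, q_eff, u0)
    if (isTRUE(sol$failed)) {
      return(list(E = 1e8 + sol$gap, g = c(0, 0, 0, 0), u = u0,
                  infeasible = TRUE))
    }
    u <- sol$u
    cu <- cos(u); su <- sin(u)
    Rx_ <- function(v) c(v[1L], cu * v[2L] - su * v[3L], su * v[2L] + cu * v[3L])

    r <- sol$r                  # A_t - q (3-vector)
    hu <- sol$hu
    Rxy <- c(0, cu, su)         # Rx(u) %*% y_hat
    h_psi <- -2 * sum(r * dq)
    h_s <- 2 * sum(r * (.xhat + 2 * kap * s * Rxy))
    h_tau <- 2 * sum(r * Rx_(gt_tau))
    h_rho <- 2 * sum(r * Rx_(gt_rho))
    du <- -c(h_psi, h_s, h_tau, h_rho) / hu

    Aq <- C + s * .xhat + Rx_(mq)
    dvq <- Oq - Aq
    lq <- sqrt(sum(dvq * dvq))
    uq <- dvq / lq
    E <- E + F_q * lq
    Wq <- .xcross(Rx_(mq))      # dAq/du
    proj <- function(v) -sum(uq * v)
    base <- proj(Wq)            # d(lq)/du
    g[1L] <- g[1L] + F_q * (base * du[1L])
    g[2L] <- g[2L] + F_q * (proj(.xhat + 2 * kap * s * Rxy) + base * du[2L])
    g[3L] <- g[3L] + F_q * (proj(Rx_(gq_tau)) + base * du[3L])
    g[4L] <- g[4L] + F_q * (proj(Rx_(gq_rho)) + base * du[4L])

    list(E = E, g = g, u = u)
  }

  list(evaluate = evaluate, env = env, F_q = F_q, phi = phi)
}

#' Solve the quasi-static equilibrium at one flexion angle
#'
#' Minimises the total potential energy over the free DOFs with BFGS
#' followed by a damped Newton polish on the analytic gradient, down to a
#' relative gradient norm below `grad_tol`.
#'
#' @param model `hto_knee_model`
#' @param flexion_deg knee flexion in degrees (5 to 100)
#' @param warm_start optional previous `hto_knee_pose` (same model, nearby
#'   flexion) used to initialise the DOFs and track coordinate
#' @param grad_tol relative gradient-norm tolerance (default 1e-8)
#' @return object of class `hto_knee_pose` with fields `flexion`,
#'   `tibiofemoral_rotation` (deg, external positive), `patellar_shift`
#'   (mm, lateral positive), `patellar_tilt` (deg), `patellar_rotation`
#'   (deg), `residual` (relative gradient norm), `energy` (N mm), `u`
#'   (track coordinate) and `dofs` (raw solver state).
#' @export
solve_equilibrium_at_flexion <- function(model, flexion_deg, warm_start = NULL,
                                         grad_tol = 1e-8) {
  if (flexion_deg < 5 - 1e-9 || flexion_deg > 100 + 1e-9) {
    stop("flexion must be within [5, 100] degrees")
  }
  ev <- .make_pose_evaluator(model, flexion_deg)
  x0 <- c(0, 0, 0, 0)
  if (!is.null(warm_start)) {
    x0 <- warm_start$dofs
    ev$env$u <- warm_start$u
  }

  cache <- new.env(parent = emptyenv())
  fn <- function(x) {
    res <- ev$evaluate(x)
    cache$x <- x; cache$res <- res
    res$E
  }
  gr <- function(x) {
    if (!is.null(cache$x) && identical(cache$x, x)) return(cache$res$g)
    res <- ev$evaluate(x)
    cache$x <- x; cache$res <- res
    res$g
  }

  opt <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-15,
                                     parscale = c(0.2, 5, 0.2, 0.2)))
  x <- opt$par
  res <- ev$evaluate(x)
  if (isTRUE(res$infeasible)) {
    stop("equilibrium solve infeasible at flexion ", flexion_deg, " deg")
  }

  # damped Newton polish on the analytic gradient
  scale <- max(1, abs(res$E))
  for (it in 1:60) {
    if (max(abs(res$g)) < grad_tol * scale) break
    J <- matrix(0, 4L, 4L)
    hstep <- 1e-6
    for (j in 1:4) {
      xp <- x; xp[j] <- xp[j] + hstep
      xm <- x; xm[j] <- xm[j] - hstep
      J[, j] <- (ev$evaluate(xp)$g - ev$evaluate(xm)$g) / (2 * hstep)
    }
    step <- tryCatch(solve(J, res$g), error = function(e) res$g / max(abs(diag(J)), 1))
    lam <- 1
    gn0 <- sum(res$g^2)
    improved <- FALSE
    for (bt in 1:25) {
      xc <- x - lam * step
      rc <- ev$evaluate(xc)
      if (!isTRUE(rc$infeasible) && sum(rc$g^2) < gn0) {
        x <- xc; res <- rc; improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  rel <- max(abs(res$g)) / max(1, abs(res$E))
  if (rel > grad_tol) {
    stop("equilibrium solve did not converge at flexion ", flexion_deg,
         " deg (relative gradient norm ", format(rel, digits = 3), ")")
  }
  ev$env$u <- res$u  # advance the branch anchor for warm-started callers

  structure(list(
    flexion = flexion_deg,
    tibiofemoral_rotation = rad2deg(x[1L]),
    patellar_shift = x[2L],
    patellar_tilt = rad2deg(x[3L]),
    patellar_rotation = rad2deg(x[4L]),
    residual = rel,
    energy = res$E,
    u = res$u,
    dofs = x
  ), class = "hto_knee_pose")
}

#' Run a full squat sweep
#'
#' Solves the equilibrium at every integer flexion angle (default 5 to 100,
#' 96 samples), warm-starting each solve from the previous degree.
#'
#' @param model `hto_knee_model`
#' @param flexion vector of flexion angles in degrees
#' @return object of class `hto_kinematic_curves`: a data.frame with
#'   columns `flexion`, `patellar_shift_mm`, `patellar_tilt_deg`,
#'   `patellar_rotation_deg`, `tf_rotation_deg`, plus identity attributes
#'   and `max_jump` (largest per-step change of any series).
#' @export
run_squat <- function(model, flexion = 5:100) {
  n <- length(flexion)
  out <- matrix(NA_real_, n, 4L)
  pose <- NULL
  for (i in seq_len(n)) {
    pose <- solve_equilibrium_at_flexion(model, flexion[i], warm_start = pose)
    out[i, ] <- c(pose$patellar_shift, pose$patellar_tilt,
                  pose$patellar_rotation, pose$tibiofemoral_rotation)
  }
  df <- data.frame(flexion = flexion,
                   patellar_shift_mm = out[, 1L],
                   patellar_tilt_deg = out[, 2L],
                   patellar_rotation_deg = out[, 3L],
                   tf_rotation_deg = out[, 4L])
  attr(df, "limb_id") <- model$limb_id
  attr(df, "variant") <- model$variant
  attr(df, "wedge_height_mm") <- model$wedge_height_mm
  attr(df, "max_jump") <- if (n > 1L) max(abs(apply(out, 2L, diff))) else 0
  class(df) <- c("hto_kinematic_curves", "data.frame")
  df
}

.kin_parameters <- c("patellar_shift", "patellar_tilt", "patellar_rotation",
                     "tibiofemoral_rotation")

#' Run the complete in-silico experiment
#'
#' For every limb: one preoperative squat plus one squat per
#' (variant, wedge height) osteotomy model. With the default 13-limb
#' cohort, both variants and heights 6-12 mm this is 13 preoperative and
#' 182 osteotomy simulations, i.e. 195 x 96 = 18,720 kinematic samples per
#' parameter.
#'
#' @param cohort list of `hto_limb`
#' @param heights wedge heights (mm)
#' @param variants cut variants
#' @param params simulator parameters, see [default_knee_params()]
#' @param flexion flexion grid in degrees
#' @param plan_params osteotomy plan parameters
#' @param progress print one line per simulated model
#' @return object of class `hto_cohort_result`: `curves_long` (tidy
#'   data.frame limb_id, variant, wedge_height_mm, flexion, parameter,
#'   value), `index_table`, and `meta`.
#' @export
run_experiment <- function(cohort, heights = 6:12,
                           variants = c("ascending", "descending"),
                           params = default_knee_params(),
                           flexion = 5:100, plan_params = list(),
                           progress = FALSE) {
  grid <- run_osteotomy_grid(cohort, heights = heights, variants = variants,
                             reposition = TRUE, params = plan_params)
  index_table <- build_index_table(cohort, grid)

  pieces <- list()
  say <- function(...) if (progress) message(...)
  for (limb in cohort) {
    base_model <- build_knee_model(limb, params)
    say("squat: ", limb$limb_id, " preop")
    cv <- run_squat(base_model, flexion)
    pieces[[length(pieces) + 1L]] <- .curves_to_long(cv)
    for (v in variants) {
      for (h in heights) {
        ost <- grid[[paste(limb$limb_id, v, h, sep = "_")]]
        m <- build_knee_model(ost, params, base = base_model)
        say("squat: ", limb$limb_id, " ", v, " h=", h)
        cv <- run_squat(m, flexion)
        pieces[[length(pieces) + 1L]] <- .curves_to_long(cv)
      }
    }
  }
  curves_long <- do.call(rbind, pieces)
  rownames(curves_long) <- NULL
  structure(list(
    curves_long = curves_long,
    index_table = index_table,
    meta = list(
      n_limbs = length(cohort),
      heights = heights, variants = variants, flexion = flexion,
      n_preop_models = length(cohort),
      n_osteotomy_models = length(grid),
      n_models = length(cohort) + length(grid),
      n_samples_per_parameter = (length(cohort) + length(grid)) * length(flexion)
    )
  ), class = "hto_cohort_result")
}

.curves_to_long <- function(cv) {
  cols <- c(patellar_shift = "patellar_shift_mm",
            patellar_tilt = "patellar_tilt_deg",
            patellar_rotation = "patellar_rotation_deg",
            tibiofemoral_rotation = "tf_rotation_deg")
  n <- nrow(cv)
  data.frame(
    limb_id = rep(attr(cv, "limb_id"), 4L * n),
    variant = rep(attr(cv, "variant"), 4L * n),
    wedge_height_mm = rep(attr(cv, "wedge_height_mm"), 4L * n),
    flexion = rep(cv$flexion, 4L),
    parameter = rep(names(cols), each = n),
    value = c(cv[[cols[1L]]], cv[[cols[2L]]], cv[[cols[3L]]], cv[[cols[4L]]])
  )
}

#' @export
print.hto_cohort_result <- function(x, ...) {
  cat("<hto_cohort_result> ", x$meta$n_limbs, " limbs, ",
      x$meta$n_models, " models, ", x$meta$n_samples_per_parameter,
      " samples per parameter\n", sep = "")
  invisible(x)
}
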