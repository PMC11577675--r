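# Statistical pipeline: per-curve RMSE against the preoperative model,
# cohort summaries, paired change tests at a chosen flexion angle, and
# linear mixed models of kinematics on wedge height and cut variant.

#' Root-mean-square error between two curves
#'
#' @param post,pre equal-length numeric series on the same flexion grid
#' @return `sqrt(mean((post - pre)^2))`
#' @export
rmse_curve <- function(post, pre) {
  if (length(post) != length(pre)) stop("series length mismatch")
  sqrt(mean((post - pre)^2))
}

#' RMSE records for every osteotomy model of a cohort result
#'
#' One row per (limb, variant, wedge height, parameter), comparing the
#' postoperative flexion sweep with the preoperative sweep of the same limb.
#'
#' @param result `hto_cohort_result`
#' @return data.frame limb_id, variant, wedge_height_mm, parameter, rmse
#' @export
compute_rmse_records <- function(result) {
  cl <- result$curves_long
  pre <- cl[cl$variant == "preop", , drop = FALSE]
  post <- cl[cl$variant != "preop", , drop = FALSE]
  pre_key <- paste(pre$limb_id, pre$parameter)
  pre_split <- split(pre$value[order(pre$flexion)],
                     pre_key[order(pre$flexion)])
  key <- paste(post$limb_id, post$variant, post$wedge_height_mm, post$parameter)
  ord <- order(post$flexion)
  post_split <- split(post$value[ord], key[ord])
  ids <- names(post_split)
  meta <- do.call(rbind, strsplit(ids, " ", fixed = TRUE))
  rmse <- vapply(seq_along(ids), function(i) {
    pk <- paste(meta[i, 1L], meta[i, 4L])
    rmse_curve(post_split[[i]], pre_split[[pk]])
  }, numeric(1L))
  out <- data.frame(limb_id = meta[, 1L], variant = meta[, 2L],
                    wedge_height_mm = as.numeric(meta[, 3L]),
                    parameter = meta[, 4L], rmse = rmse)
  rownames(out) <- NULL
  out[order(out$parameter, out$variant, out$wedge_height_mm, out$limb_id), ,
      drop = FALSE]
}

#' Median and range of RMSE per (parameter, variant, wedge height)
#'
#' The boxplot-style summary of the flexion-sweep RMSE distribution.
#'
#' @param records output of [compute_rmse_records()]
#' @return data.frame parameter, variant, wedge_height_mm, median, min,
#'   max, n
#' @export
summarize_rmse <- function(records) {
  if (nrow(records) == 0L) stop("no RMSE records")
  key <- paste(records$parameter, records$variant, records$wedge_height_mm,
               sep = "|")
  lv <- sort(unique(key))
  meta <- do.call(rbind, strsplit(lv, "|", fixed = TRUE))
  stat <- function(f) vapply(lv, function(k) f(records$rmse[key == k]),
                             numeric(1L))
  n <- vapply(lv, function(k) sum(key == k), numeric(1L))
  if (any(n == 0L)) stop("empty RMSE summary cell")
  out <- data.frame(parameter = meta[, 1L], variant = meta[, 2L],
                    wedge_height_mm = as.numeric(meta[, 3L]),
                    median = stat(stats::median), min = stat(min),
                    max = stat(max), n = as.integer(n))
  rownames(out) <- NULL
  out[order(out$parameter, out$variant, out$wedge_height_mm), , drop = FALSE]
}

#' Paired t statistic and p value
#'
#' Two-sided one-sample t-test of the mean of `d` against zero, written out
#' explicitly: `t = mean(d) / (sd(d) / sqrt(n))`, df = n - 1.
#'
#' @param d numeric vector of paired differences (n >= 2)
#' @return list mean, sd, n, t, df, p, degenerate (TRUE when sd = 0, in
#'   which case no p-value is fabricated)
#' @export
paired_ttest <- function(d) {
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired differences")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(mean = m, sd = 0, n = n, t = NA_real_, df = n - 1L,
                p = NA_real_, degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  list(mean = m, sd = s, n = n, t = tstat, df = n - 1L,
       p = 2 * stats::pt(-abs(tstat), df = n - 1L), degenerate = FALSE)
}

#' Mean kinematic changes at a flexion angle, per parameter and variant
#'
#' Paired (post minus pre, per limb) one-sample t-tests of the change in
#' each kinematic parameter at the requested flexion angle and wedge
#' height. With flexion 100 and wedge height 12 this reproduces the layout
#' of a mean-changes-at-deep-flexion table: four parameters by two cut
#' variants.
#'
#' @param result `hto_cohort_result`
#' @param flexion flexion angle (deg, must be on the simulated grid)
#' @param wedge_height_mm wedge height of the compared models (default 12)
#' @param holm apply a Holm correction across the report's p-values
#' @return data.frame parameter, variant, mean_change, sd, n, t, df, p,
#'   degenerate
#' @export
change_ttest_at_flexion <- function(result, flexion = 100, wedge_height_mm = 12,
                                    holm = FALSE) {
  cl <- result$curves_long
  at <- cl[cl$flexion == flexion, , drop = FALSE]
  if (nrow(at) == 0L) stop("flexion angle ", flexion, " not on the grid")
  pre <- at[at$variant == "preop", , drop = FALSE]
  if (length(unique(pre$limb_id)) < 2L) stop("need at least 2 limbs")
  rows <- list()
  for (p in .kin_parameters) {
    for (v in setdiff(unique(at$variant), "preop")) {
      post <- at[at$variant == v & at$wedge_height_mm == wedge_height_mm &
                   at$parameter == p, , drop = FALSE]
      base <- pre[pre$parameter == p, , drop = FALSE]
      d <- post$value[match(base$limb_id, post$limb_id)] - base$value
      if (anyNA(d)) stop("missing post values for ", p, " / ", v)
      tt <- paired_ttest(d)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, variant = v, mean_change = tt$mean, sd = tt$sd,
        n = tt$n, t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate)
    }
  }
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Fit the kinematics mixed model on a prepared data frame
#'
#' `value ~ wedge_height_centred + variant + (1 | limb_id)`, fitted by
#' REML with lme4. Wedge height enters in mm, centred on its mean; the cut
#' variant is coded 0 = descending, 1 = ascending. Wald z inference is
#' reported (lme4 provides no denominator degrees of freedom); with the
#' default grid the fixed effects are within-limb contrasts with ample
#' replication, where the normal approximation is accurate. Standardised
#' coefficients (response and predictors scaled to unit SD) are reported
#' alongside the raw ones so effect sizes of height and variant are
#' directly comparable.
#'
#' @param data data.frame with columns value, wedge_height_mm, variant
#'   ("ascending"/"descending"), limb_id
#' @return object of class `hto_mixed_model`: coefficient table,
#'   standardised coefficients, random-intercept and residual SD,
#'   singularity flag, and the lme4 fit
#' @export
fit_mixed_model_df <- function(data) {
  stopifnot(all(c("value", "wedge_height_mm", "variant", "limb_id") %in%
                  names(data)))
  d <- data
  d$h_c <- d$wedge_height_mm - mean(d$wedge_height_mm)
  d$variant_asc <- as.numeric(d$variant == "ascending")
  fit <- lme4::lmer(value ~ h_c + variant_asc + (1 | limb_id), data = d,
                    REML = TRUE)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], z = sm[, "t value"])
  coefs$p <- 2 * stats::pnorm(-abs(coefs$z))
  coefs$ci_lo <- coefs$estimate - 1.96 * coefs$se
  coefs$ci_hi <- coefs$estimate + 1.96 * coefs$se
  rownames(coefs) <- NULL

  sd_y <- stats::sd(d$value)
  std <- c(h_c = NA_real_, variant_asc = NA_real_)
  if (sd_y > 0) {
    std["h_c"] <- coefs$estimate[coefs$term == "h_c"] *
      stats::sd(d$h_c) / sd_y
    std["variant_asc"] <- coefs$estimate[coefs$term == "variant_asc"] *
      stats::sd(d$variant_asc) / sd_y
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = coefs,
    standardized = std,
    random_intercept_sd = vc$sdcor[vc$grp == "limb_id"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    singular = lme4::isSingular(fit),
    n_obs = nrow(d),
    fit = fit
  ), class = "hto_mixed_model")
}

#' @export
print.hto_mixed_model <- function(x, ...) {
  cat("<hto_mixed_model> n =", x$n_obs,
      if (x$singular) "(singular fit)" else "", "\n")
  print(x$coefficients, digits = 4)
  cat("standardised: height", format(x$standardized[["h_c"]], digits = 3),
      ", variant", format(x$standardized[["variant_asc"]], digits = 3), "\n")
  invisible(x)
}

#' Mixed model of a kinematic parameter at one flexion angle
#'
#' Extracts the per-model values of `parameter` at `flexion` from a cohort
#' result and fits [fit_mixed_model_df()].
#'
#' @param result `hto_cohort_result`
#' @param flexion flexion angle on the simulated grid (deg)
#' @param parameter one of `"patellar_shift"`, `"patellar_tilt"`,
#'   `"patellar_rotation"`, `"tibiofemoral_rotation"`
#' @return `hto_mixed_model` (with `flexion` and `parameter` fields)
#' @export
fit_mixed_model <- function(result, flexion, parameter) {
  parameter <- match.arg(parameter, .kin_parameters)
  cl <- result$curves_long
  d <- cl[cl$flexion == flexion & cl$parameter == parameter &
            cl$variant != "preop", , drop = FALSE]
  if (nrow(d) == 0L) stop("no data at flexion ", flexion)
  full <- length(unique(d$limb_id)) * length(unique(d$variant)) *
    length(unique(d$wedge_height_mm))
  if (nrow(d) != full) stop("incomplete grid at flexion ", flexion)
  out <- fit_mixed_model_df(d)
  out$flexion <- flexion
  out$parameter <- parameter
  out
}

#' Simulate mixed-model data with known ground truth
#'
#' Generates one replicate of the experiment grid (limbs x variants x
#' heights) from `value = intercept + slope * h_c + variant_effect *
#' [ascending] + u_limb + noise`, with `u_limb ~ N(0, intercept_sd)` and
#' `noise ~ N(0, noise_sd)`. Used for parameter-recovery and type-I
#' calibration studies of the mixed-model pipeline.
#'
#' @param n_limbs number of limbs
#' @param heights wedge heights (mm)
#' @param slope fixed effect of centred wedge height (per mm)
#' @param variant_effect fixed effect of the ascending variant
#' @param intercept_sd SD of the per-limb random intercept
#' @param noise_sd residual SD
#' @param intercept grand mean
#' @param seed RNG seed
#' @return data.frame ready for [fit_mixed_model_df()]
#' @export
simulate_mixed_data <- function(n_limbs = 13L, heights = 6:12, slope = 0.3,
                                variant_effect = 0.5, intercept_sd = 1.0,
                                noise_sd = 0.1, intercept = 0, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  g <- expand.grid(limb_id = sprintf("limb_%03d", seq_len(n_limbs)),
                   variant = c("ascending", "descending"),
                   wedge_height_mm = heights, stringsAsFactors = FALSE)
  u <- stats::rnorm(n_limbs, 0, intercept_sd)
  names(u) <- sprintf("limb_%03d", seq_len(n_limbs))
  h_c <- g$wedge_height_mm - mean(g$wedge_height_mm)
  g$value <- intercept + slope * h_c +
    variant_effect * (g$variant == "ascending") +
    u[g$limb_id] + stats::rnorm(nrow(g), 0, noise_sd)
  g
}

#' Quantile-quantile export of kinematic values at a flexion angle
#'
#' Normality in this pipeline is assessed visually; this returns the sorted
#' sample and the matching normal quantiles per parameter for plotting, and
#' makes no automated decision.
#'
#' @param result `hto_cohort_result`
#' @param flexion flexion angle (deg)
#' @return data.frame parameter, sample_quantile, theoretical_quantile
#' @export
qq_export <- function(result, flexion = 100) {
  cl <- result$curves_long
  at <- cl[cl$flexion == flexion & cl$variant != "preop", , drop = FALSE]
  if (nrow(at) == 0L) stop("no data at flexion ", flexion)
  pieces <- lapply(split(at$value, at$parameter), function(v) {
    s <- sort(v)
    n <- length(s)
    data.frame(sample_quantile = s,
               theoretical_quantile = stats::qnorm(stats::ppoints(n)) *
                 stats::sd(v) + mean(v))
  })
  out <- do.call(rbind, Map(function(p, d) cbind(parameter = p, d),
                            names(pieces), pieces))
  rownames(out) <- NULL
  out
}

#' Qualitative concordance checks on the RMSE summaries
#'
#' Property-style comparisons of the simulated effect structure: at equal
#' wedge height the ascending cut should disturb patellar shift, tilt and
#' rotation more than the descending cut; the descending cut should disturb
#' tibiofemoral rotation at least as much as the ascending cut at 12 mm;
#' and RMSE medians should not decrease with wedge height. These are
#' reported (logged), not hard-asserted: they describe behaviour of the
#' synthetic stand-in cohort and simulator, not a reproduction of any
#' specific cadaver result.
#'
#' @param records output of [compute_rmse_records()]
#' @return data.frame check, parameter, passed, detail
#' @export
concordance_report <- function(records) {
  sm <- summarize_rmse(records)
  rows <- list()
  add <- function(check, parameter, passed, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, parameter = parameter, passed = passed, detail = detail)
  }
  pf_params <- c("patellar_shift", "patellar_tilt", "patellar_rotation")
  for (p in pf_params) {
    a <- sm[sm$parameter == p & sm$variant == "ascending", ]
    d <- sm[sm$parameter == p & sm$variant == "descending", ]
    hh <- intersect(a$wedge_height_mm, d$wedge_height_mm)
    ok <- all(a$median[match(hh, a$wedge_height_mm)] >
                d$median[match(hh, d$wedge_height_mm)])
    add("ascending_gt_descending_median", p, ok,
        paste0("heights ", paste(hh, collapse = ",")))
  }
  a12 <- sm[sm$parameter == "tibiofemoral_rotation" &
              sm$variant == "ascending" & sm$wedge_height_mm == 12, ]
  d12 <- sm[sm$parameter == "tibiofemoral_rotation" &
              sm$variant == "descending" & sm$wedge_height_mm == 12, ]
  if (nrow(a12) == 1L && nrow(d12) == 1L) {
    add("descending_ge_ascending_tf_rotation_12mm", "tibiofemoral_rotation",
        d12$median >= a12$median,
        sprintf("desc %.3f vs asc %.3f", d12$median, a12$median))
  }
  for (p in unique(sm$parameter)) {
    for (v in unique(sm$variant)) {
      cell <- sm[sm$parameter == p & sm$variant == v, ]
      cell <- cell[order(cell$wedge_height_mm), ]
      ok <- all(diff(cell$median) >= -1e-12)
      add("median_nondecreasing_in_height", paste(p, v), ok,
          paste(format(cell$median, digits = 3), collapse = " "))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
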