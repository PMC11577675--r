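# Experiment configuration, orchestration, artifact export and CLI.
#
# One JSON configuration describes a full reproducible run: cohort spec,
# wedge heights, variants, flexion grid, simulator parameters, statistics
# options, output directory and the single global seed (which governs only
# the anatomy generator; simulation and statistics are deterministic). The
# config hash and seed are recorded in the run log and output headers.

#' Default experiment configuration
#'
#' @param n_limbs cohort size (default 13)
#' @param seed global seed (default 42)
#' @return nested list; see the documented keys in the methods vignette
#' @export
default_config <- function(n_limbs = 13L, seed = 42L) {
  list(
    cohort = list(n_limbs = n_limbs, seed = seed,
                  distributions = default_cohort_distributions()),
    heights = 6:12,
    variants = c("ascending", "descending"),
    flexion = list(from = 5, to = 100, step = 1),
    knee_params = default_knee_params(),
    plan_params = list(hinge_depth_mm = 15, biplanar_offset_mm = 10,
                       angle_mode = "chord"),
    stats = list(mixed_model_flexion = c(20, 40, 60, 100),
                 ttest_flexion = 100, ttest_wedge_height = 12,
                 holm = FALSE),
    meshes = TRUE,
    output_dir = "htosim_out",
    seed = seed
  )
}

#' Validate an experiment configuration
#' @param config configuration list
#' @return the validated config (heights sorted)
#' @export
validate_config <- function(config) {
  need <- c("cohort", "heights", "variants", "flexion", "knee_params",
            "stats", "output_dir", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L) {
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  }
  h <- as.numeric(config$heights)
  if (any(h <= 0) || anyNA(h)) stop("wedge heights must be positive")
  config$heights <- sort(h)
  fx <- config$flexion
  if (fx$from < 5 || fx$to > 100 || fx$from >= fx$to || fx$step <= 0) {
    stop("flexion range must lie within [5, 100] with positive step")
  }
  if (!all(config$variants %in% c("ascending", "descending"))) {
    stop("variants must be 'ascending' and/or 'descending'")
  }
  config
}

#' Write / read a configuration as JSON
#'
#' The round trip is lossless for every documented key.
#'
#' @param config configuration list
#' @param path file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # restore shapes jsonlite flattens
  if (!is.null(cfg$cohort$distributions)) {
    cfg$cohort$distributions <- lapply(cfg$cohort$distributions, as.numeric)
  }
  for (nm in c("lig_stiffness", "bw_coefficients")) {
    if (!is.null(cfg$knee_params[[nm]])) {
      cfg$knee_params[[nm]] <- unlist(cfg$knee_params[[nm]])
    }
  }
  validate_config(cfg)
}

#' Content hash of a configuration (hex string)
#'
#' Stable 32-bit hash of the canonical JSON serialisation; recorded in run
#' logs and table headers so artifact trees can be traced to their
#' configuration. The output directory is excluded: it does not affect the
#' science, and two runs of one configuration into different directories
#' must produce identical tables including their hash headers.
#'
#' @param config configuration list
#' @return 8-character hex string
#' @export
config_hash <- function(config) {
  config$output_dir <- NULL
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  # polynomial rolling hash mod 2^31 - 1 (exact in double arithmetic)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.flexion_grid <- function(fx) seq(fx$from, fx$to, by = fx$step)

#' Run the full experiment described by a configuration
#'
#' Generation, osteotomy grid, patellar repositioning, squat simulations
#' and statistics, with all artifacts written below `config$output_dir`:
#' `landmarks/` (JSON), `meshes/` (STL, when `config$meshes`), `curves/`
#' (tidy CSV), `tables/` (CSV and a JSON report bundle) and `logs/`.
#' Re-running with the same configuration reproduces the tables exactly.
#'
#' @param config configuration list (see [default_config()])
#' @param dry_run print the execution plan without writing anything
#' @param progress print progress lines
#' @return (invisibly) the `hto_cohort_result`, or the plan when dry_run
#' @export
cli_run <- function(config = default_config(), dry_run = FALSE,
                    progress = FALSE) {
  config <- validate_config(config)
  hash <- config_hash(config)
  flexion <- .flexion_grid(config$flexion)
  n_models <- as.integer(config$cohort$n_limbs) *
    (1L + length(config$variants) * length(config$heights))
  plan <- list(
    config_hash = hash,
    seed = config$seed,
    n_preop_models = config$cohort$n_limbs,
    n_osteotomy_models = n_models - config$cohort$n_limbs,
    n_models = n_models,
    n_flexion_samples = length(flexion),
    output_dir = config$output_dir
  )
  if (dry_run) {
    cat("htosim run plan (dry run)\n")
    for (nm in names(plan)) cat("  ", nm, ": ", format(plan[[nm]]), "\n", sep = "")
    return(invisible(plan))
  }

  out <- config$output_dir
  for (d in c("", "landmarks", "meshes", "curves", "tables", "logs")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  header <- c(paste0("# htosim config_hash=", hash, " seed=", config$seed))

  spec <- cohort_spec(config$cohort$n_limbs, config$cohort$seed,
                      config$cohort$distributions %||% list())
  cohort <- generate_cohort(spec, meshes = isTRUE(config$meshes))
  for (limb in cohort) {
    write_landmarks_json(limb$landmarks,
                         file.path(out, "landmarks",
                                   paste0(limb$limb_id, "_pre.json")))
    if (!is.null(limb$tibia_mesh)) {
      write_stl(limb$tibia_mesh,
                file.path(out, "meshes", paste0(limb$limb_id, "_tibia.stl")))
    }
  }

  grid <- run_osteotomy_grid(cohort, heights = config$heights,
                             variants = config$variants,
                             meshes = isTRUE(config$meshes),
                             params = config$plan_params %||% list())
  manifest <- data.frame(
    limb_id = vapply(grid, function(o) o$limb_id, character(1L)),
    variant = vapply(grid, function(o) o$variant, character(1L)),
    wedge_height_mm = vapply(grid, function(o) o$wedge_height_mm, numeric(1L)),
    wedge_angle_deg = vapply(grid, function(o) o$wedge_angle_deg, numeric(1L))
  )
  .write_csv_with_header(manifest, file.path(out, "tables", "manifest.csv"),
                         header)
  for (ost in grid) {
    tag <- paste(ost$limb_id, ost$variant, ost$wedge_height_mm, sep = "_")
    write_landmarks_json(ost$landmarks,
                         file.path(out, "landmarks", paste0(tag, ".json")))
    if (!is.null(ost$distal_fragment_mesh)) {
      write_stl(ost$distal_fragment_mesh,
                file.path(out, "meshes", paste0(tag, "_distal.stl")))
      write_stl(ost$proximal_fragment_mesh,
                file.path(out, "meshes", paste0(tag, "_proximal.stl")))
    }
  }

  result <- run_experiment(cohort, heights = config$heights,
                           variants = config$variants,
                           params = config$knee_params,
                           flexion = flexion,
                           plan_params = config$plan_params %||% list(),
                           progress = progress)
  .write_csv_with_header(result$curves_long,
                         file.path(out, "curves", "kinematics.csv"), header)
  .write_csv_with_header(result$index_table,
                         file.path(out, "tables", "index_table.csv"), header)

  records <- compute_rmse_records(result)
  rmse_summary <- summarize_rmse(records)
  ttest <- change_ttest_at_flexion(result, config$stats$ttest_flexion,
                                   config$stats$ttest_wedge_height,
                                   holm = isTRUE(config$stats$holm))
  mm_angles <- intersect(config$stats$mixed_model_flexion, flexion)
  mixed <- list()
  for (a in mm_angles) {
    for (p in .kin_parameters) {
      mm <- fit_mixed_model(result, a, p)
      mixed[[paste(p, a, sep = "_")]] <- list(
        flexion = a, parameter = p,
        coefficients = mm$coefficients,
        standardized = as.list(mm$standardized),
        random_intercept_sd = mm$random_intercept_sd,
        residual_sd = mm$residual_sd, singular = mm$singular)
    }
  }
  conc <- concordance_report(records)

  .write_csv_with_header(records, file.path(out, "tables", "rmse_records.csv"), header)
  .write_csv_with_header(rmse_summary, file.path(out, "tables", "rmse_summary.csv"), header)
  .write_csv_with_header(ttest, file.path(out, "tables", "change_ttest.csv"), header)
  .write_csv_with_header(conc, file.path(out, "tables", "concordance.csv"), header)
  .write_csv_with_header(qq_export(result, config$stats$ttest_flexion),
                         file.path(out, "tables", "qq_export.csv"), header)

  report <- list(config_hash = hash, seed = config$seed,
                 meta = result$meta,
                 index_summary = index_table_summary(result$index_table),
                 rmse_summary = rmse_summary, change_ttest = ttest,
                 mixed_models = mixed, concordance = conc)
  jsonlite::write_json(report, file.path(out, "tables", "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  writeLines(c(header,
               paste0("models: ", result$meta$n_models),
               paste0("samples_per_parameter: ",
                      result$meta$n_samples_per_parameter),
               paste0("finished: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(out, "logs", "run.log"))
  invisible(result)
}

.write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [cli_run()] (skipping comment headers)
#' @param path file path
#' @keywords internal
read_artifact_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Validate an artifact tree
#'
#' Re-runs the invariant suite on a finished run directory: grid
#' completeness, descending-cut identity of TT-TG and Insall-Salvati,
#' ascending tendon-length conservation, and landmark rigidity of the
#' distal fragment (ankle-to-MCL-insertion distance preserved).
#'
#' @param model_dir output directory of a previous [cli_run()]
#' @return data.frame check, passed, detail
#' @export
cli_validate <- function(model_dir) {
  checks <- list()
  add <- function(check, passed, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check,
                                                 passed = passed,
                                                 detail = detail)
  }
  need <- c(file.path("tables", "index_table.csv"),
            file.path("tables", "manifest.csv"),
            file.path("curves", "kinematics.csv"),
            "landmarks")
  missing <- need[!file.exists(file.path(model_dir, need))]
  if (length(missing) > 0L) {
    for (m in missing) add("artifact_present", FALSE, m)
    out <- do.call(rbind, checks)
    rownames(out) <- NULL
    return(out)
  }
  add("artifact_present", TRUE, "all required artifacts found")

  idx <- read_artifact_csv(file.path(model_dir, "tables", "index_table.csv"))
  man <- read_artifact_csv(file.path(model_dir, "tables", "manifest.csv"))
  limbs <- unique(idx$limb_id)
  grid_ok <- tryCatch({
    check_index_table_grid(idx, variants = unique(man$variant),
                           heights = sort(unique(man$wedge_height_mm)))
    TRUE
  }, error = function(e) FALSE)
  add("grid_complete", grid_ok,
      paste0(nrow(man), " osteotomy models, ", length(limbs), " limbs"))

  desc <- idx[idx$variant == "descending", , drop = FALSE]
  if (nrow(desc) > 0L) {
    add("descending_ttg_identity", all(desc$d_ttg == 0),
        paste0("max |d_ttg| = ", format(max(abs(desc$d_ttg)))))
    add("descending_is_identity", all(desc$d_is == 0),
        paste0("max |d_is| = ", format(max(abs(desc$d_is)))))
  }

  tol <- 1e-9
  worst_tendon <- 0; worst_rigid <- 0
  for (l in limbs) {
    pre <- read_landmarks_json(file.path(model_dir, "landmarks",
                                         paste0(l, "_pre.json")))
    L0 <- vnorm(pre$patellar_tendon_insertion - pre$patella_distal_pole)
    d0 <- vnorm(pre$ankle_center - pre$mcl_insertion)
    rows <- man[man$limb_id == l, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      tag <- paste(l, rows$variant[i], rows$wedge_height_mm[i], sep = "_")
      post <- read_landmarks_json(file.path(model_dir, "landmarks",
                                            paste0(tag, ".json")))
      worst_rigid <- max(worst_rigid,
                         abs(vnorm(post$ankle_center - post$mcl_insertion) - d0))
      if (rows$variant[i] == "ascending") {
        worst_tendon <- max(worst_tendon,
                            abs(vnorm(post$patellar_tendon_insertion -
                                        post$patella_distal_pole) - L0))
      }
    }
  }
  add("ascending_tendon_length_conserved", worst_tendon < tol,
      paste0("max deviation ", format(worst_tendon, digits = 3), " mm"))
  add("distal_fragment_rigidity", worst_rigid < tol,
      paste0("max deviation ", format(worst_rigid, digits = 3), " mm"))

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `generate` (cohort only),
#' `osteotomize` (cohort + osteotomy grid, no simulation), `simulate`
#' (alias of run), `analyze` (alias of run), `validate <dir>`.
#' Flags: `--config <path>`, `--seed <int>`, `--out <dir>`,
#' `--heights a,b,...`, `--variants a,b`, `--limbs <n>`, `--dry-run`.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`)
#' @return exit status (0 on success), invisibly
#' @export
hto_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: htosim <run|generate|osteotomize|simulate|analyze|validate> [flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  flags <- list(dry_run = FALSE)
  pos <- character(0)
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (a == "--dry-run") { flags$dry_run <- TRUE; i <- i + 1L; next }
    if (startsWith(a, "--")) {
      if (i == length(rest)) stop("flag ", a, " needs a value")
      flags[[substring(a, 3L)]] <- rest[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }

  status <- tryCatch({
    if (cmd == "validate") {
      dir <- flags$out %||% pos[1L]
      if (is.na(dir) || is.null(dir)) stop("validate needs a directory")
      rep <- cli_validate(dir)
      print(rep)
      if (all(rep$passed)) 0L else 1L
    } else if (cmd %in% c("run", "generate", "osteotomize", "simulate", "analyze")) {
      cfg <- if (!is.null(flags$config)) read_config(flags$config) else default_config()
      if (!is.null(flags$seed)) {
        cfg$seed <- as.integer(flags$seed)
        cfg$cohort$seed <- as.integer(flags$seed)
      }
      if (!is.null(flags$out)) cfg$output_dir <- flags$out
      if (!is.null(flags$limbs)) cfg$cohort$n_limbs <- as.integer(flags$limbs)
      if (!is.null(flags$heights)) {
        cfg$heights <- as.numeric(strsplit(flags$heights, ",")[[1L]])
      }
      if (!is.null(flags$variants)) {
        cfg$variants <- strsplit(flags$variants, ",")[[1L]]
      }
      cfg <- validate_config(cfg)
      if (cmd == "generate") {
        if (flags$dry_run) {
          cat("would generate", cfg$cohort$n_limbs, "limbs\n")
        } else {
          spec <- cohort_spec(cfg$cohort$n_limbs, cfg$cohort$seed,
                              cfg$cohort$distributions %||% list())
          cohort <- generate_cohort(spec, meshes = isTRUE(cfg$meshes))
          dir.create(file.path(cfg$output_dir, "landmarks"), recursive = TRUE,
                     showWarnings = FALSE)
          dir.create(file.path(cfg$output_dir, "meshes"), recursive = TRUE,
                     showWarnings = FALSE)
          for (limb in cohort) {
            write_landmarks_json(limb$landmarks,
                                 file.path(cfg$output_dir, "landmarks",
                                           paste0(limb$limb_id, "_pre.json")))
            if (!is.null(limb$tibia_mesh)) {
              write_stl(limb$tibia_mesh,
                        file.path(cfg$output_dir, "meshes",
                                  paste0(limb$limb_id, "_tibia.stl")))
            }
          }
          cat("generated", length(cohort), "limbs in", cfg$output_dir, "\n")
        }
        0L
      } else if (cmd == "osteotomize") {
        spec <- cohort_spec(cfg$cohort$n_limbs, cfg$cohort$seed,
                            cfg$cohort$distributions %||% list())
        cohort <- generate_cohort(spec, meshes = isTRUE(cfg$meshes))
        grid <- run_osteotomy_grid(cohort, heights = cfg$heights,
                                   variants = cfg$variants,
                                   meshes = isTRUE(cfg$meshes))
        cat("osteotomized:", length(grid), "models\n")
        0L
      } else {
        cli_run(cfg, dry_run = flags$dry_run)
        0L
      }
    } else {
      stop("unknown subcommand: ", cmd)
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
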