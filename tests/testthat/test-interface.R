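test_that("configuration validates, hashes stably, and round-trips", {
  cfg <- default_config(n_limbs = 2, seed = 7)
  expect_silent(validate_config(cfg))
  bad <- cfg; bad$heights <- c(-1, 6)
  expect_error(validate_config(bad), "positive")
  bad2 <- cfg; bad2$flexion$from <- 1
  expect_error(validate_config(bad2), "flexion")
  bad3 <- cfg; bad3$cohort <- NULL
  expect_error(validate_config(bad3), "missing key")
  h1 <- config_hash(cfg)
  expect_match(h1, "^[0-9a-f]{8}$")
  expect_identical(h1, config_hash(cfg))
  expect_false(identical(h1, config_hash(default_config(n_limbs = 3, seed = 7))))
  path <- tempfile(fileext = ".json")
  write_config(validate_config(cfg), path)
  cfg2 <- read_config(path)
  expect_identical(config_hash(validate_config(cfg)), config_hash(cfg2))
})

test_that("a smoke-profile run writes a complete, reproducible artifact tree", {
  out1 <- file.path(tempdir(), "htosim_run1")
  out2 <- file.path(tempdir(), "htosim_run2")
  cfg <- default_config(n_limbs = 2, seed = 7)
  cfg$heights <- c(6, 12)
  cfg$meshes <- FALSE

  plan <- cli_run(within_dir(cfg, out1), dry_run = TRUE)
  expect_identical(plan$n_models, 10L)
  expect_false(dir.exists(file.path(out1, "tables")))

  t0 <- Sys.time()
  suppressMessages(cli_run(within_dir(cfg, out1)))
  smoke_secs <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(smoke_secs, 60)  # smoke profile budget
  for (f in c("tables/index_table.csv", "tables/manifest.csv",
              "tables/rmse_summary.csv", "tables/report.json",
              "curves/kinematics.csv", "logs/run.log")) {
    expect_true(file.exists(file.path(out1, f)))
  }
  man <- read.csv(file.path(out1, "tables", "manifest.csv"), comment.char = "#")
  expect_identical(nrow(man), 8L)

  suppressMessages(cli_run(within_dir(cfg, out2)))
  for (f in c("tables/index_table.csv", "curves/kinematics.csv",
              "tables/rmse_summary.csv")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }

  rep <- cli_validate(out1)
  expect_true(all(rep$passed))

  # tampering with a descending delta is detected
  idx <- read.csv(file.path(out1, "tables", "index_table.csv"),
                  comment.char = "#")
  idx$d_ttg[idx$variant == "descending"][1] <- 0.5
  con <- file(file.path(out1, "tables", "index_table.csv"), "w")
  writeLines("# tampered", con)
  write.csv(idx, con, row.names = FALSE)
  close(con)
  rep2 <- cli_validate(out1)
  expect_false(rep2$passed[rep2$check == "descending_ttg_identity"])

  # empty directory: enumerated missing artifacts
  rep3 <- cli_validate(file.path(tempdir(), "htosim_nothing_here"))
  expect_true(all(!rep3$passed))
  expect_gt(nrow(rep3), 2)
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("the CLI front end parses flags and reports failures", {
  expect_identical(hto_cli(character(0)), 1L)
  suppressMessages(expect_identical(hto_cli(c("frobnicate")), 2L))
  out <- file.path(tempdir(), "htosim_cli_gen")
  st <- hto_cli(c("generate", "--limbs", "1", "--seed", "3", "--out", out))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(out, "landmarks", "limb_001_pre.json")))
  unlink(out, recursive = TRUE)
})
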