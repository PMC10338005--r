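# Presets, config validation, time conversion, exports and the CLI.

test_that("presets are complete and carry the canonical scenario values", {
  expect_true(all(c("neutral-bolus", "light-bolus",
                    "meanflow-alpha4", "meanflow-alpha16") %in% presets()))
  cfg <- presets("light-bolus")
  expect_equal(cfg$params$beta, 0.2)
  expect_equal(cfg$params$alpha, 4)
  expect_equal(cfg$params$sigma, 1)
  expect_equal(cfg$params$Ri, 1)
  expect_equal(cfg$params$n, 3)
  expect_equal(cfg$ic$x0, 1.75)
  expect_equal(cfg$ic$delta, 0.2)
  expect_equal(cfg$run$tau_end, 8)
  n0 <- presets("neutral-bolus")
  expect_equal(n0$params$Ri, 0)
  expect_equal(n0$params[c("alpha", "beta", "sigma", "n")],
               cfg$params[c("alpha", "beta", "sigma", "n")])
  expect_equal(presets("meanflow-alpha16")$params$alpha, 16)
  expect_error(presets("nope"), "unknown preset")
})

test_that("config loading validates invariants and rejects unknown keys", {
  expect_error(load_config(overrides = list(params = list(beta = 1.2))),
               "invalid configuration")
  expect_error(load_config(overrides = list(params = list(alpha = -1))),
               "invalid configuration")
  expect_error(load_config(overrides = list(nonsense = 1)), "unknown config key")
  expect_error(load_config(overrides = list(params = list(zeta = 1))),
               "unknown config key")
  # empty config + preset -> fully populated defaults
  cfg <- load_config(overrides = list(preset = "neutral-bolus"))
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$grid$nx_cell, 200)
  # flags/overrides beat file values
  f <- tempfile(fileext = ".yaml")
  writeLines(c("preset: light-bolus", "params:", "  Ri: 0.5"), f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$params$Ri, 0.5)
  cfg3 <- load_config(f, overrides = list(params = list(Ri = 4)))
  expect_equal(cfg3$params$Ri, 4)
})

test_that("slow time converts to fast time and oscillation counts", {
  conv <- cycles_from_tau(8, 0.02)
  expect_equal(conv$t, 20000)
  expect_equal(conv$cycles, 20000 / (2 * pi))
  expect_equal(cycles_from_tau(0, 0.1)$cycles, 0)
  eps <- 0.05
  expect_equal(cycles_from_tau(2 * pi * eps^2, eps)$cycles, 1)
  expect_error(cycles_from_tau(1, 0), "positive")
})

test_that("transport runs are deterministic and the config echo round-trips", {
  p <- channel_params(alpha = 4, beta = 0.2, Ri = 1, sigma = 1, n = 3)
  # the over/undershoot monitor fires on this deliberately coarse grid
  r1 <- suppressWarnings(run_transport(p, 32, 17, tau_end = 0.2,
                                       snap_dt = 0.1, keep_fields = FALSE))
  r2 <- suppressWarnings(run_transport(p, 32, 17, tau_end = 0.2,
                                       snap_dt = 0.1, keep_fields = FALSE))
  expect_identical(r1$c_final, r2$c_final) # bit-reproducible
  expect_identical(r1$diagnostics$Q_b, r2$diagnostics$Q_b)

  dir <- tempfile()
  cfg <- load_config(overrides = list(preset = "light-bolus"))
  export_transport_run(r1, dir, config = cfg)
  expect_true(all(file.exists(file.path(dir, c("profiles.csv",
                                               "diagnostics.csv",
                                               "qb_series.csv",
                                               "config.json")))))
  echo <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  expect_equal(echo$params$Ri, cfg$params$Ri)
  expect_equal(echo$ic$x0, cfg$ic$x0)
  expect_equal(echo$run$tau_end, cfg$run$tau_end)
})

test_that("the CLI runs transport end to end and fails cleanly on bad input", {
  dir <- tempfile()
  status <- suppressWarnings(
    run_cli(c("transport", "--preset", "light-bolus",
              "--out", dir, "--nx-cell", "32", "--neta", "17",
              "--tau-end", "0.2", "--snap-dt", "0.1")))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(dir, "profiles.csv")))
  expect_true(file.exists(file.path(dir, "transport.log")))
  qb <- utils::read.csv(file.path(dir, "qb_series.csv"))
  expect_true(all(qb$Q_b < 0)) # light solute drafts upward

  expect_identical(suppressMessages(run_cli(c("transport", "--beta", "1.5"))), 1L)
  expect_identical(suppressMessages(run_cli(character())), 1L)
  expect_identical(suppressMessages(run_cli(c("bogus", "--alpha", "4"))), 1L)
})

test_that("the CLI sweep writes one flow-rate series per parameter value", {
  dir <- tempfile()
  status <- run_cli(c("sweep", "--preset", "light-bolus", "--out", dir,
                      "--nx-cell", "32", "--neta", "17",
                      "--tau-end", "0.1", "--snap-dt", "0.1",
                      "--param", "Ri", "--values", "0.25,1"))
  expect_identical(status, 0L)
  f1 <- file.path(dir, "qb_series_Ri_0.25.csv")
  f2 <- file.path(dir, "qb_series_Ri_1.csv")
  expect_true(file.exists(f1) && file.exists(f2))
  q1 <- utils::read.csv(f1); q2 <- utils::read.csv(f2)
  # draft scales close to linearly with the density contrast
  expect_lt(abs(q2$Q_b[1L] / q1$Q_b[1L] - 4), 0.2)
})

test_that("tidy and glance accessors return well-formed tibbles", {
  md <- mean_drift(channel_params(alpha = 4, beta = 0.4), 32, 33)
  td <- tidy(md)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 33L * 33L)
  expect_true(all(c("u_ss", "u_sd", "u_lagr") %in% names(td)))
  gl <- glance(md)
  expect_equal(nrow(gl), 1L)
  expect_gt(gl$psi_peak_ss, 0)

  p <- channel_params(alpha = 4, beta = 0.2, Ri = 1, sigma = 1, n = 3)
  run <- run_transport(p, 32, 17, tau_end = 0.1, snap_dt = 0.05)
  expect_s3_class(tidy(run), "tbl_df")
  expect_equal(nrow(glance(run)), 1L)
  flds <- tidy(run, what = "fields")
  expect_true(all(c("tau", "c") %in% names(flds)))
  pl <- autoplot(md, field = "streaming")
  expect_s3_class(pl, "ggplot")
  expect_s3_class(autoplot(run, what = "qb"), "ggplot")
})
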