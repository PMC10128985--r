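test_that("time to recovery finds the first crossing or reports none", {
  # undamaged constant series recovers at tick 0
  const <- data.frame(tick = 0:10, fibril = rep(100, 11))
  expect_identical(time_to_recovery(const, 100), 0L)

  # dip and cross back at a known tick
  fib <- c(rep(25840, 5), rep(25000, 295), rep(25900, 101))
  dip <- data.frame(tick = 0:400, fibril = fib)
  expect_identical(time_to_recovery(dip, 25840), 300L)

  # never recovering
  lost <- data.frame(tick = 0:50, fibril = rep(90, 51))
  expect_identical(time_to_recovery(lost, 100), NA_integer_)

  # bare numeric vector input
  expect_identical(time_to_recovery(c(5, 3, 4, 7, 8), 7), 3L)
})

test_that("peak reports the maximum and its first attaining tick", {
  expect_equal(peak(c(9, 7, 5, 3)), c(amplitude = 9, tick = 0))
  expect_equal(peak(rep(4, 10)), c(amplitude = 4, tick = 0))
  tri <- c(0:22, 21:0)
  expect_equal(peak(tri), c(amplitude = 22, tick = 22))
  df <- data.frame(tick = 10:20, neutrophils = c(1:6, 5:1))
  expect_equal(peak(df, "neutrophils"), c(amplitude = 6, tick = 15))
  expect_error(peak(numeric(0)), "empty")
})

test_that("condition comparison reports signed differences and round-trips", {
  mk <- function(ttr, npk, ntick, mpk, mtick) {
    s <- list(time_to_recovery = ttr, damage_clearance_time = 50L,
              peaks = list(neutrophils = c(amplitude = npk, tick = ntick),
                           macrophages = c(amplitude = mpk, tick = mtick),
                           sc_active = c(amplitude = 1, tick = 1),
                           myoblasts = c(amplitude = 1, tick = 1),
                           fibroblasts = c(amplitude = 21, tick = 0)),
              endpoint = c(fibril = 25900, ecm = 4320, sc_active = 0,
                           fibroblasts = 21),
              initial = c(fibril = 25840, ecm = 4318),
              ecm_pct_change = 0.05, sc_activated_total = 18, duration = 672L)
    class(s) <- "run_summary"
    s
  }
  a <- mk(152L, 900, 12, 700, 48)
  expect_true(all(compare_conditions(a, a)$difference == 0))

  b <- mk(165L, 700, 17, 900, 60)
  cmp <- compare_conditions(a, b)
  expect_identical(
    cmp$difference[cmp$metric == "neutrophil_peak_tick"], 5)
  expect_identical(
    cmp$difference[cmp$metric == "time_to_recovery"], 13)

  path <- withr::local_tempfile(fileext = ".json")
  save_comparison(cmp, path)
  back <- load_comparison(path)
  expect_equal(as.data.frame(unclass(back)), as.data.frame(unclass(cmp)))
})

test_that("summary statistics recomputed from exported CSV match in-memory", {
  g <- mid_geometry()
  cfg <- sim_config(damage_mode = "widespread", damage_fraction = 0.02,
                    duration = 48, seed = 5)
  sim <- run_simulation(cfg, g, baseline = mid_baseline())
  path <- withr::local_tempfile(fileext = ".csv")
  export_timeseries(sim$series, path)
  back <- import_timeseries(path)
  expect_equal(back$fibril, sim$series$fibril)
  expect_equal(time_to_recovery(back, sim$initial[["fibril"]]),
               time_to_recovery(sim$series, sim$initial[["fibril"]]))
  expect_equal(peak(back, "neutrophils"), peak(sim$series, "neutrophils"))
})

test_that("run_summary collects recovery, clearance, peaks and endpoints", {
  g <- mid_geometry()
  cfg <- sim_config(damage_mode = "widespread", damage_fraction = 0.05,
                    duration = 120, seed = 5)
  sim <- run_simulation(cfg, g, baseline = mid_baseline())
  sm <- run_summary(sim)
  expect_s3_class(sm, "run_summary")
  expect_identical(sm$initial[["fibril"]], 1200L)
  expect_true(is.na(sm$time_to_recovery) || sm$time_to_recovery > 0)
  expect_identical(sm$endpoint[["fibril"]],
                   sim$series$fibril[nrow(sim$series)])
  expect_true(sm$peaks$neutrophils[["amplitude"]] >= 30)
  # clearance time: damaged series must be zero there
  if (!is.na(sm$damage_clearance_time)) {
    row <- sim$series$tick == sm$damage_clearance_time
    expect_identical(sim$series$damaged_fibril[row], 0)
  }
})
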