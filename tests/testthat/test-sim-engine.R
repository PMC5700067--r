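test_that("initialisation honours counts, geometry and the seed", {
  cfg <- sim_config(rfc_count = 25, seed = 7)
  st <- init_simulation(cfg)
  counts <- table(st$cells$kind)
  expect_identical(unname(counts["T_INACTIVE"]), 30L)
  expect_identical(unname(counts["APC_OFF"]), 10L)
  expect_identical(unname(counts["RFC_OFF"]), 25L)
  expect_identical(st$radius, 200)
  # every RFC inside the patch disc, 2000 um from the tumor centre
  rfc <- dplyr::filter(st$cells, kind == "RFC_OFF")
  expect_true(all((rfc$x - 2000)^2 + rfc$y^2 <= 750^2))
  # initial motile cells obey the influx-annulus rule at R = 200
  mot <- dplyr::filter(st$cells, kind %in% c("APC_OFF", "T_INACTIVE"))
  r <- sqrt(mot$x^2 + mot$y^2)
  expect_true(all(r <= 200 + 1500 + 1e-9))
  # determinism
  st2 <- init_simulation(cfg)
  expect_identical(st$cells, st2$cells)
  # no RFC arm has no sources at all
  st0 <- init_simulation(sim_config(rfc_count = 0))
  expect_false(any(grepl("RFC", st0$cells$kind)))
  expect_warning(init_simulation(sim_config(rfc_count = 1,
                                            tumor_eln_distance = 800)),
                 "overlaps")
})

test_that("influx counts are Poisson and positions uniform in the annulus", {
  set.seed(71)
  # every spawned position lies in [max(0, R-500), R+1500]
  pos <- spawn_influx(rate = 50, tumor_radius = 700, dt = 1)
  r <- sqrt(pos$x^2 + pos$y^2)
  expect_true(all(r >= 200 - 1e-9 & r <= 2200 + 1e-9))
  # R below the inner offset: annulus reaches the centre
  pos2 <- spawn_influx(rate = 50, tumor_radius = 100, dt = 1)
  expect_true(all(sqrt(pos2$x^2 + pos2$y^2) <= 1600 + 1e-9))
  expect_identical(nrow(spawn_influx(0, 200)), 0L)
  # mean count over many minutes within 3 standard errors of rate * t
  n <- sum(vapply(1:1000, function(i)
    nrow(spawn_influx(0.84, 200, dt = 1)), 0L))
  expect_lt(abs(n - 840), 3 * sqrt(840))
})

test_that("null dynamics: no growth, no kill, no cells", {
  cfg <- quick_config(g = 0, k = 0, influx_rate_apc = 0, influx_rate_t = 0,
                      initial_t = 0, initial_apc = 0, seed = 3)
  ts <- run_simulation(cfg)
  expect_true(all(ts$radius_um == 200))
  counts <- dplyr::select(as.data.frame(ts), dplyr::starts_with("n_"))
  expect_true(all(as.matrix(counts) == 0))
})

test_that("with immunity off the radius grows exactly linearly", {
  cfg <- quick_config(influx_rate_apc = 0, influx_rate_t = 0,
                      initial_t = 0, initial_apc = 0, seed = 3)
  ts <- run_simulation(cfg)
  expect_equal(ts$radius_um, 200 + 0.2 * ts$time_min)
})

test_that("identical (config, seed) reproduces the trajectory byte for byte", {
  cfg <- quick_config(rfc_count = 40, seed = 99)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  tmp1 <- withr::local_tempfile(fileext = ".csv")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(a, tmp1)
  write_timeseries(b, tmp2)
  expect_identical(readBin(tmp1, "raw", file.size(tmp1)),
                   readBin(tmp2, "raw", file.size(tmp2)))
  # a different seed gives a different trajectory
  c2 <- run_simulation(quick_config(rfc_count = 40, seed = 100))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("deterministic influx mode spawns at exactly the configured rate", {
  cfg <- quick_config(influx_mode = "deterministic", seed = 5)
  ts <- run_simulation(cfg)
  last <- as.data.frame(ts)[nrow(ts), ]
  expect_equal(last$cum_influx_apc, floor(0.84 * last$time_min), tolerance = 1)
  expect_equal(last$cum_influx_t, floor(0.1 * last$time_min), tolerance = 1)
})

test_that("T-cell bookkeeping conserves counts at every recorded step", {
  cfg <- quick_config(seed = 8)
  ts <- as.data.frame(run_simulation(cfg))
  # inactive + active + TIL + expired = initial + influx
  lhs <- ts$n_t_inactive + ts$n_t_active + ts$n_til + ts$cum_til_expired
  expect_equal(lhs, 30 + ts$cum_influx_t)
})

test_that("activated RFC count is non-decreasing and zero without RFC", {
  cfg <- quick_config(rfc_count = 60, tumor_eln_distance = 900,
                      total_time_days = 1, seed = 13)
  suppressWarnings(ts <- run_simulation(cfg))
  expect_true(all(diff(ts$n_rfc_on) >= 0))
  ts0 <- run_simulation(quick_config(rfc_count = 0, seed = 13))
  expect_true(all(ts0$n_rfc_on == 0))
})

test_that("RFC positions are constant across a run", {
  cfg <- quick_config(rfc_count = 15, seed = 21)
  st <- init_simulation(cfg)
  ts <- run_simulation(cfg)
  rfc0 <- dplyr::filter(st$cells, grepl("RFC", kind))
  rfc1 <- attr(ts, "rfc")
  expect_equal(rfc0$x, rfc1$x)
  expect_equal(rfc0$y, rfc1$y)
})

test_that("per-step displacement never exceeds the speed bound", {
  # one-step run: compare initial agents with the post-step agent table
  cfg <- sim_config(total_time_days = 1 / 1440, record_every = 1, seed = 31,
                    influx_rate_apc = 0, influx_rate_t = 0)
  st <- init_simulation(cfg)
  ts <- run_simulation(cfg)
  fin <- attr(ts, "final_agents")
  joined <- dplyr::inner_join(st$cells, fin, by = "id",
                              suffix = c("_0", "_1"))
  d <- sqrt((joined$x_1 - joined$x_0)^2 + (joined$y_1 - joined$y_0)^2)
  bound <- ifelse(joined$kind_0 == "APC_OFF", 12 + 4,
                  ifelse(joined$kind_0 == "APC_M", 20 + 10, 10 + 100))
  expect_true(all(d <= bound + 1e-9))
})

test_that("configs round-trip through YAML with overrides", {
  cfg <- sim_config(rfc_count = 12, gaussian_sigma = 150, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, tmp)
  back <- read_sim_config(tmp)
  expect_equal(unclass(back), unclass(cfg))
  over <- read_sim_config(tmp, overrides = c("rfc_count=99", "seed=2"))
  expect_identical(over$rfc_count, 99L)
  expect_equal(over$seed, 2)
  expect_error(read_sim_config(tmp, overrides = "nope=1"), "unknown config")
  expect_error(sim_config(dt = -1), "positive")
  expect_error(sim_config(apc_m_capacity = 0), "capacity")
})
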