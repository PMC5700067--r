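test_that("random walk steps respect the maximum distance", {
  cells <- tibble::tibble(x = rep(0, 500), y = rep(0, 500))
  set.seed(1)
  out <- random_walk_step(cells, kinetic_speed = 12, dt = 1)
  d <- sqrt(out$x^2 + out$y^2)
  expect_true(all(d <= 12))
  expect_true(any(d > 6))  # not degenerate
  # zero speed leaves positions unchanged
  still <- random_walk_step(cells, kinetic_speed = 0, dt = 1)
  expect_equal(still, cells)
})

test_that("mean random-walk displacement matches the uniform-length law", {
  # E|step| = v * dt / 2 for length ~ Uniform(0, v dt)
  n <- 1e5
  set.seed(2)
  out <- random_walk_step(tibble::tibble(x = rep(0, n), y = rep(0, n)),
                          kinetic_speed = 12, dt = 1)
  d <- sqrt(out$x^2 + out$y^2)
  se <- 12 / sqrt(12) / sqrt(n)  # sd of Uniform(0, 12) is 12/sqrt(12)
  expect_lt(abs(mean(d) - 6), 3 * se)
})

test_that("tactic steps move along the fixed direction only", {
  cells <- tibble::tibble(x = rep(0, 1000), y = rep(0, 1000))
  dir <- tibble::tibble(dx = rep(1, 1000), dy = rep(0, 1000))
  set.seed(3)
  out <- tactic_step(cells, dir, tactic_speed = 10, bias_scale = 1, dt = 1)
  expect_true(all(out$y == 0))
  expect_true(all(out$x >= 0 & out$x <= 10))
  # zero bias or zero direction leaves the cell still
  expect_equal(tactic_step(cells, dir, 10, bias_scale = 0), cells)
  zero_dir <- tibble::tibble(dx = 0, dy = 0)
  expect_equal(tactic_step(tibble::tibble(x = 1, y = 2), zero_dir, 10),
               tibble::tibble(x = 1, y = 2))
  expect_error(tactic_step(cells, dir, 10, bias_scale = 1.4), "\\[0, 1\\]")
  expect_error(
    tactic_step(cells, tibble::tibble(dx = 2, dy = 0), 10), "unit")
})

test_that("mean tactic displacement scales with bias and speed", {
  n <- 1e5
  set.seed(4)
  out <- tactic_step(tibble::tibble(x = rep(0, n), y = rep(0, n)),
                     tibble::tibble(dx = rep(0, n), dy = rep(1, n)),
                     tactic_speed = 10, bias_scale = 0.6, dt = 1)
  se <- 6 / sqrt(12) / sqrt(n)
  expect_lt(abs(mean(out$y) - 0.6 * 10 / 2), 3 * se)
})

test_that("gradient bias saturates in [0, 1)", {
  kh <- bias_scale(c(0, 1e-3, 1), k_half = 1e-3)
  expect_equal(kh[1], 0)
  expect_equal(kh[2], 0.5)
  expect_lt(kh[3], 1)
  expect_true(all(diff(kh) > 0))
})

make_cells <- function(...) {
  rows <- list(...)
  tibble::tibble(
    id = seq_along(rows),
    kind = vapply(rows, `[[`, "", 1),
    x = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    y = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    age = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    activations = vapply(rows, function(r) as.integer(r[[5]]), 0L)
  )
}

test_that("T cells are activated within 15 um of an APC^M and not beyond", {
  cfg <- sim_config()
  cells <- make_cells(
    list("APC_M", 1000, 0, 0, 0L),
    list("T_INACTIVE", 1014, 0, 0, 0L),   # 14 um away
    list("T_INACTIVE", 1016.0001, 0, 0, 0L)  # 16 um away
  )
  res <- transition_cells(cells, tumor_radius = 200, config = cfg)
  out <- res$cells
  expect_identical(out$kind[out$id == 2], "T_ACTIVE")
  expect_identical(out$kind[out$id == 3], "T_INACTIVE")
  expect_identical(out$activations[out$id == 1], 1L)
  expect_identical(res$events$event[res$events$id == 2], "t_activated")
})

test_that("an APC^M is removed after exhausting its activation capacity", {
  cfg <- sim_config(apc_m_capacity = 3)
  cells <- make_cells(
    list("APC_M", 1000, 0, 0, 0L),
    list("T_INACTIVE", 1005, 0, 0, 0L),
    list("T_INACTIVE", 1000, 5, 0, 0L),
    list("T_INACTIVE", 995, 0, 0, 0L),
    list("T_INACTIVE", 1000, -5, 0, 0L)
  )
  res <- transition_cells(cells, tumor_radius = 200, config = cfg)
  out <- res$cells
  # capacity 3: exactly three T cells activated, the APC^M removed,
  # the fourth T cell left inactive
  expect_identical(sum(out$kind == "T_ACTIVE"), 3L)
  expect_identical(sum(out$kind == "T_INACTIVE"), 1L)
  expect_false(1L %in% out$id)
  expect_identical(sum(res$events$event == "apc_m_removed"), 1L)
})

test_that("each T cell is activated by its nearest APC^M, ties to lower id", {
  cfg <- sim_config()
  cells <- make_cells(
    list("APC_M", 990, 0, 0, 0L),    # id 1, 10 um from the T cell
    list("APC_M", 1005, 0, 0, 0L),   # id 2, 5 um away: nearest
    list("T_INACTIVE", 1000, 0, 0, 0L)
  )
  res <- transition_cells(cells, 200, cfg)
  out <- res$cells
  expect_identical(out$activations[out$id == 2], 1L)
  expect_identical(out$activations[out$id == 1], 0L)
  # exact tie: equidistant APC^M, the lower id presents
  cells2 <- make_cells(
    list("APC_M", 990, 0, 0, 0L),
    list("APC_M", 1010, 0, 0, 0L),
    list("T_INACTIVE", 1000, 0, 0, 0L)
  )
  out2 <- transition_cells(cells2, 200, cfg)$cells
  expect_identical(out2$activations[out2$id == 1], 1L)
  expect_identical(out2$activations[out2$id == 2], 0L)
})

test_that("APC^OFF loads antigen inside the tumor; APC^M activates RFC", {
  cfg <- sim_config()
  cells <- make_cells(
    list("APC_OFF", 100, 0, 0, 0L),      # inside R = 200
    list("APC_OFF", 300, 0, 0, 0L),      # outside
    list("APC_M", 2000, 10, 0, 0L),
    list("RFC_OFF", 2000, 0, 0, 0L),     # 10 um from the APC^M
    list("RFC_OFF", 2500, 0, 0, 0L)      # far away
  )
  res <- transition_cells(cells, 200, cfg)
  out <- res$cells
  expect_identical(out$kind[out$id == 1], "APC_M")
  expect_identical(out$kind[out$id == 2], "APC_OFF")
  expect_identical(out$kind[out$id == 4], "RFC_ON")
  expect_identical(out$kind[out$id == 5], "RFC_OFF")
  # degenerate tumor: no interior, no antigen loading
  out0 <- transition_cells(cells, 0, cfg)$cells
  expect_identical(out0$kind[out0$id == 1], "APC_OFF")
})

test_that("activated T cells become TIL at the boundary and expire on age", {
  cfg <- sim_config()
  cells <- make_cells(
    list("T_ACTIVE", 150, 0, 0, 0L),      # inside
    list("T_ACTIVE", 350, 0, 0, 0L),      # outside
    list("TIL", 10, 0, 1441, 0L),         # past the 1-day lifespan
    list("TIL", -20, 5, 100, 0L)
  )
  res <- transition_cells(cells, 200, cfg)
  out <- res$cells
  expect_identical(out$kind[out$id == 1], "TIL")
  expect_identical(out$kind[out$id == 2], "T_ACTIVE")
  expect_false(3L %in% out$id)
  expect_true(4L %in% out$id)
  expect_identical(sum(res$events$event == "til_expired"), 1L)
})

test_that("RFC never move and ages advance by dt", {
  cfg <- sim_config()
  cells <- make_cells(
    list("RFC_OFF", 2100, 40, 7, 0L),
    list("T_INACTIVE", 0, 900, 3, 0L)
  )
  out <- transition_cells(cells, 200, cfg)$cells
  rfc <- out[out$kind %in% c("RFC_OFF", "RFC_ON"), ]
  expect_equal(c(rfc$x, rfc$y), c(2100, 40))
  expect_equal(sort(out$age), c(4, 8))
})

test_that("spatial-hash neighbour search equals brute force", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(2:200, 1)
    # mixed scales: dense clusters and sparse spread, negative coordinates
    x <- c(runif(n %/% 2, -3000, 3000), rnorm(n - n %/% 2, 100, 20))
    y <- c(runif(n %/% 2, -3000, 3000), rnorm(n - n %/% 2, -50, 20))
    r <- sample(c(5, 15, 60), 1)
    expect_identical(neighbor_pairs(x, y, r, "hash"),
                     neighbor_pairs(x, y, r, "brute"))
  }
  # boundary inclusivity
  expect_identical(nrow(neighbor_pairs(c(0, 15), c(0, 0), 15)), 1L)
  expect_identical(nrow(neighbor_pairs(c(0, 15.0001), c(0, 0), 15)), 0L)
})
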