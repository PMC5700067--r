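#' Peak of a tumor radius trajectory
#'
#' Time and value of the global maximum of a radius trajectory; ties go to
#' the earliest time.
#'
#' @param trajectory An `eln_sim` time series, or any data frame with
#'   columns `time_min` and either `radius_um` or `mean_radius_um`.
#' @return A one-row tibble with `peak_day` and `peak_radius_um`.
#' @examples
#' detect_peak(tibble::tibble(time_min = c(0, 1440, 2880),
#'                            radius_um = c(1, 3, 2)))
#' @export
detect_peak <- function(trajectory) {
  stopifnot(is.data.frame(trajectory))
  if (nrow(trajectory) == 0) abort("empty trajectory")
  rcol <- intersect(c("radius_um", "mean_radius_um"), names(trajectory))[1]
  if (is.na(rcol) || !"time_min" %in% names(trajectory)) {
    abort("trajectory needs columns time_min and radius_um/mean_radius_um")
  }
  r <- trajectory[[rcol]]
  i <- which.max(r)  # earliest index on ties
  tibble(peak_day = trajectory$time_min[i] / 1440,
         peak_radius_um = r[i])
}

#' Replicate sweep over the number of RFC
#'
#' Reproduces the in-silico experiment comparing immune response strength
#' across ectopic-lymph-node sizes: for every value in `rfc_counts` it runs
#' `replicates` independently seeded simulations, averages the radius
#' trajectories pointwise, and summarises each arm by the peak of the
#' averaged trajectory, the radius at `horizon_day`, and the percent
#' difference versus the 0-RFC arm, `100 * (R0 - Rn) / R0` (positive =
#' smaller tumor than without an ELN).
#'
#' Per-run seeds are derived deterministically from `seed` as
#' `seed + 7919 * (arm_index * replicates + replicate - 1)`, so a sweep is
#' fully reproducible from the master seed.
#'
#' @param rfc_counts Integer vector of RFC numbers (one simulation arm per
#'   value).
#' @param replicates Runs per arm (default 5).
#' @param config Base [sim_config()]; `rfc_count` and `seed` are overridden
#'   per run.
#' @param seed Master seed.
#' @return An `rfc_sweep` object: list with `trajectories` (tibble:
#'   `rfc_count`, `time_min`, `mean_radius_um`, `sd_radius_um`), `runs`
#'   (per-replicate trajectories), `summary` (tibble: `rfc_count`,
#'   `peak_day`, `peak_radius_um`, `day30_radius_um`, `pct_peak_vs_zero`,
#'   `pct_day30_vs_zero`), `replicates`, `seed`, `config`.
#' @export
rfc_sweep <- function(rfc_counts, replicates = 5, config = sim_config(),
                      seed = 1L) {
  stopifnot(replicates >= 1, length(rfc_counts) >= 1)
  rfc_counts <- as.integer(rfc_counts)
  horizon_min <- config$total_time_days * 1440
  runs <- purrr::map_dfr(seq_along(rfc_counts), function(a) {
    purrr::map_dfr(seq_len(replicates), function(rep) {
      run_seed <- run_seed_for(seed, a, rep, replicates)
      cfg <- config
      cfg$rfc_count <- rfc_counts[a]
      cfg$seed <- run_seed
      ts <- run_simulation(cfg)
      tibble(rfc_count = rfc_counts[a], replicate = rep, seed = run_seed,
             time_min = ts$time_min, radius_um = ts$radius_um,
             n_til = ts$n_til, n_rfc_on = ts$n_rfc_on)
    })
  })
  trajectories <- runs %>%
    group_by(.data$rfc_count, .data$time_min) %>%
    summarise(mean_radius_um = mean(.data$radius_um),
              sd_radius_um = stats::sd(.data$radius_um),
              mean_til = mean(.data$n_til),
              .groups = "drop")
  summary <- trajectories %>%
    group_by(.data$rfc_count) %>%
    summarise(
      peak_day = detect_peak(dplyr::pick(dplyr::everything()))$peak_day,
      peak_radius_um =
        detect_peak(dplyr::pick(dplyr::everything()))$peak_radius_um,
      day30_radius_um = .data$mean_radius_um[
        which.min(abs(.data$time_min - horizon_min))],
      .groups = "drop"
    )
  if (0L %in% rfc_counts) {
    base <- summary[summary$rfc_count == 0L, ]
    summary <- summary %>%
      mutate(
        pct_peak_vs_zero = 100 * (base$peak_radius_um - .data$peak_radius_um) /
          base$peak_radius_um,
        pct_day30_vs_zero =
          100 * (base$day30_radius_um - .data$day30_radius_um) /
          base$day30_radius_um
      )
  } else {
    summary$pct_peak_vs_zero <- NA_real_
    summary$pct_day30_vs_zero <- NA_real_
  }
  structure(
    list(trajectories = trajectories, runs = runs, summary = summary,
         replicates = replicates, seed = seed, config = config),
    class = "rfc_sweep"
  )
}

run_seed_for <- function(master_seed, arm_index, replicate, replicates) {
  s <- as.numeric(master_seed) +
    7919 * ((arm_index - 1) * replicates + (replicate - 1))
  s %% 2147483647
}

#' @export
print.rfc_sweep <- function(x, ...) {
  cat("<rfc_sweep> ", length(unique(x$summary$rfc_count)), " arm(s) x ",
      x$replicates, " replicate(s), master seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Percent difference of a tumor radius versus the reference arm
#'
#' `100 * (reference - value) / reference`: 0 for identical arms, 50 for a
#' halved radius, negative when the arm did worse than the reference.
#'
#' @param value Radius (um) in the arm of interest.
#' @param reference Radius (um) in the reference (0-RFC) arm.
#' @return Percent difference.
#' @export
pct_vs_reference <- function(value, reference) {
  if (any(reference <= 0)) abort("`reference` must be positive")
  100 * (reference - value) / reference
}
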