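#' Simulation configuration
#'
#' Assembles and validates the full parameter set of the agent-based model.
#' Defaults are the published model parameters (growth and killing rates,
#' per-kind kinetic and chemotactic speeds, influx rates, activation
#' distance, TIL lifespan, geometry and initial conditions) together with
#' the gap-filling constants the source leaves open: the time step, the
#' Gaussian source width and amplitude, the APC^M presentation capacity,
#' the half-saturation constant of the gradient-sensing bias, and the
#' influx model.
#'
#' Speeds are in um/min, distances in um, rates per minute, times in the
#' units given below.  `k_half` defaults to the gradient magnitude one sigma
#' away from a single source, `amplitude * exp(-1/2) / sigma`, so a cell one
#' sigma from a lone activated RFC feels half the maximal chemotactic speed.
#'
#' @param g Tumor growth rate (um/min).
#' @param k Tumor death rate per TIL (um/min/cell).
#' @param dt Time step (min).
#' @param total_time_days Simulated horizon (days).
#' @param influx_rate_apc,influx_rate_t Influx of fresh APC^OFF / inactive T
#'   cells (cells/min) into the annulus.
#' @param annulus_inner_offset,annulus_outer_offset The influx annulus spans
#'   radii `[max(0, R - inner), R + outer]` around the tumor centre (um).
#' @param tumor_field_range Detection range of the tumor-centred
#'   inflammatory field: tumor-directed (and tumor-avoiding) bias acts on
#'   cells within `R + tumor_field_range` um of the centre.  `Inf` makes the
#'   directional field detectable everywhere.
#' @param activation_distance Maximum cell-cell distance for activation (um).
#' @param til_lifespan_min TIL lifespan before expiry (min; 1 day).
#' @param rfc_count Number of reticular fibroblast cells in the ELN patch.
#' @param rfc_patch_radius Radius of the circular ELN patch (um).
#' @param tumor_eln_distance Distance from tumor centre to patch centre (um).
#' @param initial_radius Initial tumor radius (um).
#' @param initial_t,initial_apc Initial inactive T / APC^OFF counts.
#' @param gaussian_sigma Width sigma of each RFC chemokine Gaussian (um).
#' @param gaussian_amplitude Peak height of each source (dimensionless).
#' @param k_half Half-saturation gradient magnitude of the ELN bias
#'   (concentration/um); `NULL` for the 1-sigma default.
#' @param apc_m_capacity T cells an APC^M can activate before removal.
#' @param apc_off_kinetic_speed,apc_off_tactic_speed,apc_m_kinetic_speed,apc_m_tactic_speed,t_kinetic_speed,t_tactic_speed
#'   Kinetic (random-walk) and chemotactic (directed) maximum speeds
#'   (um/min).
#' @param influx_mode `"poisson"` (counts per step are Poisson with mean
#'   rate x dt) or `"deterministic"` (a fractional accumulator, exact in the
#'   mean; useful for exactness tests).
#' @param inactive_t_bias `"away_from_tumor"` (inactive T cells are pushed
#'   out of the influx zone by the tumor's inflammatory field, the default;
#'   see the methods vignette for why this reading is adopted) or `"none"`
#'   (unbiased inactive T cells).
#' @param record_every Recording cadence (min).
#' @param seed Integer seed; with the configuration it fully determines the
#'   trajectory.
#' @return A `sim_config` (named list).
#' @examples
#' cfg <- sim_config(rfc_count = 30, seed = 1)
#' cfg$k_half
#' @export
sim_config <- function(g = 0.2,
                       k = 0.0015,
                       dt = 1,
                       total_time_days = 30,
                       influx_rate_apc = 0.84,
                       influx_rate_t = 0.1,
                       annulus_inner_offset = 500,
                       annulus_outer_offset = 1500,
                       tumor_field_range = 1500,
                       activation_distance = 15,
                       til_lifespan_min = 1440,
                       rfc_count = 0,
                       rfc_patch_radius = 750,
                       tumor_eln_distance = 2000,
                       initial_radius = 200,
                       initial_t = 30,
                       initial_apc = 10,
                       gaussian_sigma = 200,
                       gaussian_amplitude = 1,
                       k_half = NULL,
                       apc_m_capacity = 3,
                       apc_off_kinetic_speed = 12,
                       apc_off_tactic_speed = 4,
                       apc_m_kinetic_speed = 20,
                       apc_m_tactic_speed = 10,
                       t_kinetic_speed = 10,
                       t_tactic_speed = 100,
                       influx_mode = c("poisson", "deterministic"),
                       inactive_t_bias = c("away_from_tumor", "none"),
                       record_every = 60,
                       seed = 1L) {
  influx_mode <- match.arg(influx_mode)
  inactive_t_bias <- match.arg(inactive_t_bias)
  if (is.null(k_half)) {
    k_half <- gaussian_amplitude * exp(-0.5) / gaussian_sigma
  }
  cfg <- list(
    g = g, k = k, dt = dt, total_time_days = total_time_days,
    influx_rate_apc = influx_rate_apc, influx_rate_t = influx_rate_t,
    annulus_inner_offset = annulus_inner_offset,
    annulus_outer_offset = annulus_outer_offset,
    tumor_field_range = tumor_field_range,
    activation_distance = activation_distance,
    til_lifespan_min = til_lifespan_min,
    rfc_count = as.integer(rfc_count),
    rfc_patch_radius = rfc_patch_radius,
    tumor_eln_distance = tumor_eln_distance,
    initial_radius = initial_radius,
    initial_t = as.integer(initial_t), initial_apc = as.integer(initial_apc),
    gaussian_sigma = gaussian_sigma,
    gaussian_amplitude = gaussian_amplitude,
    k_half = k_half,
    apc_m_capacity = as.integer(apc_m_capacity),
    apc_off_kinetic_speed = apc_off_kinetic_speed,
    apc_off_tactic_speed = apc_off_tactic_speed,
    apc_m_kinetic_speed = apc_m_kinetic_speed,
    apc_m_tactic_speed = apc_m_tactic_speed,
    t_kinetic_speed = t_kinetic_speed,
    t_tactic_speed = t_tactic_speed,
    influx_mode = influx_mode,
    inactive_t_bias = inactive_t_bias,
    record_every = record_every,
    seed = as.numeric(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  nonneg <- c("g", "k", "total_time_days", "influx_rate_apc", "influx_rate_t",
              "annulus_inner_offset", "annulus_outer_offset",
              "activation_distance", "til_lifespan_min", "rfc_count",
              "rfc_patch_radius", "tumor_eln_distance", "initial_radius",
              "initial_t", "initial_apc", "gaussian_amplitude",
              "apc_off_kinetic_speed", "apc_off_tactic_speed",
              "apc_m_kinetic_speed", "apc_m_tactic_speed",
              "t_kinetic_speed", "t_tactic_speed")
  for (nm in nonneg) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0) {
      abort(paste0("`", nm, "` must be finite and >= 0"))
    }
  }
  for (nm in c("dt", "gaussian_sigma", "k_half", "record_every")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      abort(paste0("`", nm, "` must be positive"))
    }
  }
  if (is.na(cfg$tumor_field_range) || cfg$tumor_field_range < 0) {
    abort("`tumor_field_range` must be >= 0 (Inf allowed)")
  }
  if (cfg$apc_m_capacity < 1) abort("`apc_m_capacity` must be >= 1")
  if (cfg$annulus_outer_offset <= -cfg$annulus_inner_offset) {
    abort("the influx annulus must have outer radius above inner radius")
  }
  if (abs(cfg$seed) >= 2^53) abort("`seed` too large")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- unlist(x)
  for (nm in names(flat)) cat(sprintf("  %-24s %s\n", nm, flat[[nm]]))
  invisible(x)
}

#' Read / write a simulation configuration file
#'
#' Configurations are stored as flat key-value YAML whose keys match the
#' [sim_config()] argument names; unknown keys are an error, missing keys
#' take the defaults.
#'
#' @param path File path.
#' @param overrides Named list (or `key=value` character vector, as from a
#'   command line) applied on top of the file contents.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path, overrides = NULL) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) abort("config file must be a key-value mapping")
  vals <- modify_config_values(vals, overrides)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A `sim_config` to write.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

modify_config_values <- function(vals, overrides) {
  if (is.null(overrides)) return(vals)
  if (is.character(overrides)) {
    kv <- strsplit(overrides, "=", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) {
      abort(paste0("override must be key=value: ", overrides[bad][1]))
    }
    overrides <- setNames(
      lapply(kv, function(p) {
        v <- type.convert(p[2], as.is = TRUE)
        v
      }),
      vapply(kv, `[`, "", 1)
    )
  }
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  vals
}
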