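#' Chemotactic index from migrated fractions
#'
#' The chemotactic index (CI) of a transwell migration assay is the fraction
#' of seeded cells that migrated into the lower chamber under a chemokine
#' condition, divided by the fraction that migrated in control medium with no
#' chemokine (the chemokinesis baseline).  A CI of 1 therefore means "no
#' directional effect"; values above 1 indicate chemoattraction.
#'
#' @param condition_fraction Fraction of seeded cells migrating under the
#'   chemokine condition, in `(0, 1]` (0 is allowed and yields CI 0).
#' @param control_fraction Fraction migrating in control medium, in `(0, 1]`.
#'   Must be strictly positive: a zero baseline leaves the index undefined.
#' @return A numeric vector of dimensionless CI values,
#'   `condition_fraction / control_fraction`.
#' @examples
#' compute_ci(0.30, 0.10)  # CI = 3
#' @export
compute_ci <- function(condition_fraction, control_fraction) {
  if (!is.numeric(condition_fraction) || !is.numeric(control_fraction)) {
    abort("migrated fractions must be numeric")
  }
  bad <- function(f) any(!is.finite(f) | f < 0 | f > 1)
  if (bad(condition_fraction)) {
    abort("`condition_fraction` must lie in [0, 1]")
  }
  if (bad(control_fraction)) {
    abort("`control_fraction` must lie in [0, 1]")
  }
  if (any(control_fraction == 0)) {
    abort(paste("`control_fraction` is zero: the chemotactic index is",
                "undefined without a chemokinesis baseline"))
  }
  condition_fraction / control_fraction
}

.populations <- c("panT", "CD4T", "CD8T", "B", "NK")
.significance_levels <- c("ns", "p<0.05", "p<0.01", "p<0.001", "p<0.0001")
.panel_columns <- c("chemokine", "species_of_reagent", "cell_population",
                    "activation_state", "concentration_ng_ml", "ci_mean",
                    "ci_sd", "significance", "measured")

#' Load the standardized chemotactic-index panel
#'
#' Reads the packaged transwell chemotaxis dataset: 48 recombinant chemokines
#' assayed at 0/10/100/1000 ng/mL on five resting lymphocyte populations
#' (pan T, CD4+ T, CD8+ T, B, NK), four replicate wells per condition.  Two
#' chemokine-population pairs (CCL19 and CCL21 on NK cells) were not
#' determined and are kept as explicit unmeasured records, never as zeros.
#' The panel therefore covers 238 measured chemokine-population combinations.
#'
#' The printed dispersion ("+/-") of the source table is stored verbatim in
#' `ci_sd`; whether it denotes SD or SEM is not documented, so downstream
#' significance recomputation treats it as an SD and is used as a consistency
#' check only -- the printed significance labels are authoritative.
#'
#' @param path Path to a panel CSV.  Defaults to the dataset shipped with the
#'   package.
#' @param n_replicates Replicate count per assay well (4 in the source data).
#' @return A `chemokine_panel`: a tibble with columns `chemokine`,
#'   `species_of_reagent`, `cell_population`, `activation_state`,
#'   `concentration_ng_ml`, `ci_mean`, `ci_sd`, `significance` (ordered
#'   factor), `measured`, `n`, plus a `chemokinesis_baselines` attribute (see
#'   [set_chemokinesis_baselines()]).
#' @examples
#' panel <- load_panel()
#' dplyr::filter(panel, chemokine == "CCL19", cell_population == "panT")
#' @export
load_panel <- function(path = NULL, n_replicates = 4L) {
  if (is.null(path)) {
    path <- system.file("extdata", "chemokine_panel.csv", package = "elnsim")
  }
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    chemokine = readr::col_character(),
    species_of_reagent = readr::col_character(),
    cell_population = readr::col_character(),
    activation_state = readr::col_character(),
    concentration_ng_ml = readr::col_double(),
    ci_mean = readr::col_double(),
    ci_sd = readr::col_double(),
    significance = readr::col_character(),
    measured = readr::col_logical()
  ))
  missing_cols <- setdiff(.panel_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("panel file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_pop <- which(!raw$cell_population %in% .populations)
  if (length(bad_pop) > 0) {
    abort(paste0("row ", bad_pop[1] + 1L, ": unknown cell_population '",
                 raw$cell_population[bad_pop[1]], "'"))
  }
  bad_conc <- which(!raw$concentration_ng_ml %in% c(0, 10, 100, 1000))
  if (length(bad_conc) > 0) {
    abort(paste0("row ", bad_conc[1] + 1L, ": concentration must be one of ",
                 "0/10/100/1000 ng/mL"))
  }
  bad_sig <- which(raw$measured &
                     !raw$significance %in% .significance_levels)
  if (length(bad_sig) > 0) {
    abort(paste0("row ", bad_sig[1] + 1L, ": unknown significance label '",
                 raw$significance[bad_sig[1]], "'"))
  }
  bad_nd <- which(raw$measured != (!is.na(raw$ci_mean) & !is.na(raw$ci_sd)))
  if (length(bad_nd) > 0) {
    abort(paste0("row ", bad_nd[1] + 1L,
                 ": `measured` must match presence of ci_mean/ci_sd"))
  }
  dup <- duplicated(raw[, c("chemokine", "cell_population",
                            "concentration_ng_ml")])
  if (any(dup)) {
    abort(paste0("row ", which(dup)[1] + 1L,
                 ": duplicate (chemokine, population, concentration) key"))
  }
  panel <- raw %>%
    mutate(
      cell_population = factor(.data$cell_population, levels = .populations),
      significance = factor(.data$significance,
                            levels = .significance_levels, ordered = TRUE),
      n = ifelse(.data$measured, as.integer(n_replicates), NA_integer_)
    )
  attr(panel, "chemokinesis_baselines") <- default_chemokinesis_baselines()
  class(panel) <- c("chemokine_panel", class(panel))
  panel
}

#' Default chemokinesis baselines
#'
#' Baseline (no-gradient) migrated fractions per resting cell population.
#' The source assays report these graphically only, so the shipped values
#' are configurable placeholders -- NK cells noticeably higher than the
#' other resting populations -- not transcribed measurements.  Replace them
#' with [set_chemokinesis_baselines()] when calibrated values are available.
#'
#' @return A tibble with columns `cell_population`, `activation_state` and
#'   `fraction_migrating`.
#' @export
default_chemokinesis_baselines <- function() {
  tibble(
    cell_population = factor(.populations, levels = .populations),
    activation_state = "resting",
    fraction_migrating = c(0.02, 0.02, 0.02, 0.02, 0.10)
  )
}

#' Replace the chemokinesis baselines of a panel
#'
#' @param panel A `chemokine_panel`.
#' @param baselines A tibble with columns `cell_population`,
#'   `activation_state`, `fraction_migrating` (fractions in (0, 1]).
#' @return The panel with the new baselines attached.
#' @export
set_chemokinesis_baselines <- function(panel, baselines) {
  stopifnot(is.data.frame(baselines))
  need <- c("cell_population", "activation_state", "fraction_migrating")
  if (!all(need %in% names(baselines))) {
    abort(paste0("baselines need columns: ", paste(need, collapse = ", ")))
  }
  if (any(baselines$fraction_migrating <= 0 |
            baselines$fraction_migrating > 1)) {
    abort("baseline fractions must lie in (0, 1]")
  }
  attr(panel, "chemokinesis_baselines") <- as_tibble(baselines)
  panel
}

#' Validate the structural invariants of a chemotactic-index panel
#'
#' Checks the panel against the counts of the source dataset: 48 distinct
#' chemokines, 5 cell populations, 240 chemokine-population pairs of which
#' exactly 2 (CCL19/NK, CCL21/NK) are unmeasured, hence 238 measured assay
#' combinations; and control normalisation (CI = 1 at 0 ng/mL).  One printed
#' control cell (Chemerin on NK cells, 0.67) departs from unity in the source
#' table; it is stored verbatim and reported in `control_anomalies` rather
#' than failing validation.
#'
#' @param panel A `chemokine_panel` from [load_panel()].
#' @return A list with `n_chemokines`, `n_populations`, `n_measured_pairs`,
#'   `n_unmeasured_pairs`, `unmeasured_pairs` (tibble), `control_anomalies`
#'   (tibble), and `valid` (logical).
#' @export
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  pairs <- panel %>%
    group_by(.data$chemokine, .data$cell_population) %>%
    summarise(measured = any(.data$measured), .groups = "drop")
  unmeasured <- pairs %>% filter(!.data$measured) %>% select(-"measured")
  anomalies <- panel %>%
    filter(.data$concentration_ng_ml == 0, .data$measured,
           .data$ci_mean != 1) %>%
    select("chemokine", "cell_population", "ci_mean", "ci_sd")
  out <- list(
    n_chemokines = dplyr::n_distinct(panel$chemokine),
    n_populations = dplyr::n_distinct(panel$cell_population),
    n_measured_pairs = sum(pairs$measured),
    n_unmeasured_pairs = sum(!pairs$measured),
    unmeasured_pairs = unmeasured,
    control_anomalies = anomalies
  )
  out$valid <- out$n_chemokines == 48L && out$n_populations == 5L &&
    out$n_measured_pairs == 238L && out$n_unmeasured_pairs == 2L
  out
}

#' Look up one assay record
#'
#' @param panel A `chemokine_panel`.
#' @param chemokine Chemokine name, e.g. `"CCL19"`.
#' @param cell_population One of `"panT"`, `"CD4T"`, `"CD8T"`, `"B"`, `"NK"`.
#' @param concentration_ng_ml One of 0, 10, 100, 1000.
#' @return A one-row tibble (possibly an unmeasured record with
#'   `measured = FALSE`).  Errors if the key does not exist at all.
#' @examples
#' panel <- load_panel()
#' ci_lookup(panel, "CCL19", "panT", 1000)
#' @export
ci_lookup <- function(panel, chemokine, cell_population, concentration_ng_ml) {
  hit <- panel[panel$chemokine == chemokine &
                 panel$cell_population == cell_population &
                 panel$concentration_ng_ml == concentration_ng_ml, ]
  if (nrow(hit) == 0) {
    abort(paste0("no record for ", chemokine, " x ", cell_population, " x ",
                 concentration_ng_ml, " ng/mL"))
  }
  as_tibble(hit)
}

#' Two-sided unpaired Student t-test from summary statistics
#'
#' Recomputes the condition-versus-control comparison used for the panel from
#' the printed means and dispersions: a pooled-variance (Student) unpaired
#' t-test with `n` replicates per group and `2n - 2` degrees of freedom.
#' With both dispersions zero and equal means the statistic is defined as 0
#' and the p-value as 1.
#'
#' @param mean1,sd1 Mean and standard deviation of the condition group.
#' @param mean2,sd2 Mean and standard deviation of the control group.
#' @param n Replicates per group (default 4, as in the packaged panel).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @examples
#' ci_ttest(3, 0.5, 1, 0.3, n = 4)
#' @export
ci_ttest <- function(mean1, sd1, mean2, sd2, n = 4L) {
  if (any(n < 2)) abort("`n` must be at least 2 per group")
  if (any(c(sd1, sd2) < 0)) abort("standard deviations must be >= 0")
  sp2 <- (sd1^2 + sd2^2) / 2  # pooled variance, equal group sizes
  se <- sqrt(sp2 * 2 / n)
  tstat <- ifelse(se == 0, ifelse(mean1 == mean2, 0, Inf), (mean1 - mean2) / se)
  df <- 2 * n - 2
  p <- 2 * pt(-abs(tstat), df = df)
  pmin(pmax(p, 0), 1)
}

#' Classify chemokine-population responses
#'
#' Applies the responder rule used to summarise the panel: a pair is called
#' `"+"` when at least one chemokine dose is significant (better than `ns`)
#' *and* at least one dose has CI above 5; `"-/+"` when some dose is
#' significant but no dose exceeds CI 5; `"-"` when no dose reaches
#' significance; and `"ND"` when the pair was not measured.  The printed
#' significance labels stored in the panel are authoritative for this call;
#' [ci_ttest()] serves as an independent consistency check.
#'
#' @param records A `chemokine_panel` or any subset of its rows.  All
#'   (chemokine, population) pairs present are classified.
#' @param ci_threshold Magnitude cut-off on the chemotactic index (default 5).
#' @return A tibble with columns `chemokine`, `cell_population`, `category`
#'   (factor with levels `-`, `-/+`, `+`, `ND`), `max_ci`, `n_significant`.
#' @examples
#' panel <- load_panel()
#' classify_response(dplyr::filter(panel, chemokine == "CCL19"))
#' @export
classify_response <- function(records, ci_threshold = 5) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) abort("no assay records to classify")
  records %>%
    filter(.data$concentration_ng_ml > 0) %>%
    group_by(.data$chemokine, .data$cell_population) %>%
    summarise(
      any_measured = any(.data$measured),
      n_significant = sum(.data$measured & .data$significance != "ns",
                          na.rm = TRUE),
      max_ci = ifelse(any(.data$measured),
                      max(.data$ci_mean[.data$measured]), NA_real_),
      .groups = "drop"
    ) %>%
    mutate(
      category = factor(
        case_when(
          !.data$any_measured ~ "ND",
          .data$n_significant > 0 & .data$max_ci > ci_threshold ~ "+",
          .data$n_significant > 0 ~ "-/+",
          TRUE ~ "-"
        ),
        levels = c("-", "-/+", "+", "ND")
      )
    ) %>%
    select("chemokine", "cell_population", "category", "max_ci",
           "n_significant")
}

#' The 12-chemokine expression-signature panel members
#'
#' Chemokines forming the tumor gene-expression signature associated with
#' ectopic lymph node presence, all of which are covered by the packaged
#' panel.
#'
#' @return Character vector of 12 chemokine names.
#' @export
signature_chemokines <- function() {
  c("CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18",
    "CCL19", "CCL21", "CXCL9", "CXCL10", "CXCL11", "CXCL13")
}
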