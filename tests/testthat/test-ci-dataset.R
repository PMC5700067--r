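test_that("compute_ci is the migrated-fraction ratio with guarded baseline", {
  expect_equal(compute_ci(0.10, 0.10), 1.0)
  expect_equal(compute_ci(0.30, 0.10), 3.0)
  expect_error(compute_ci(0.05, 0), "baseline")
  expect_error(compute_ci(1.2, 0.1), "\\[0, 1\\]")
  expect_error(compute_ci(-0.1, 0.1), "\\[0, 1\\]")
  # scale invariance: multiplying both fractions by c leaves CI unchanged
  set.seed(11)
  a <- runif(50, 0.01, 0.5)
  b <- runif(50, 0.01, 0.5)
  expect_equal(compute_ci(a, b), compute_ci(a * 1.9, b * 1.9))
})

test_that("the packaged panel satisfies its structural invariants", {
  panel <- load_panel()
  v <- validate_panel(panel)
  expect_true(v$valid)
  expect_identical(v$n_chemokines, 48L)
  expect_identical(v$n_populations, 5L)
  expect_identical(v$n_measured_pairs, 238L)
  expect_identical(v$n_unmeasured_pairs, 2L)
  expect_setequal(v$unmeasured_pairs$chemokine, c("CCL19", "CCL21"))
  expect_true(all(v$unmeasured_pairs$cell_population == "NK"))
  # control normalisation at 0 ng/mL, bar the single printed anomaly
  ctrl <- dplyr::filter(panel, concentration_ng_ml == 0, measured)
  off <- dplyr::filter(ctrl, ci_mean != 1)
  expect_identical(nrow(off), 1L)
  expect_identical(off$chemokine, "Chemerin")
  expect_identical(as.character(off$cell_population), "NK")
  # unmeasured records are explicit missing markers, never zeros
  nd <- dplyr::filter(panel, !measured)
  expect_identical(nrow(nd), 8L)
  expect_true(all(is.na(nd$ci_mean)) && all(is.na(nd$ci_sd)))
})

test_that("panel lookups reproduce printed assay values", {
  panel <- load_panel()
  rec <- ci_lookup(panel, "CCL19", "panT", 1000)
  expect_equal(rec$ci_mean, 27.73)
  expect_equal(rec$ci_sd, 3.11)
  expect_identical(as.character(rec$significance), "p<0.001")
  expect_equal(ci_lookup(panel, "CCL21", "CD4T", 1000)$ci_mean, 71.8)
  expect_equal(ci_lookup(panel, "CXCL12", "B", 1000)$ci_mean, 10.3)
  expect_equal(ci_lookup(panel, "CCL2", "NK", 10)$ci_mean, 3.78)
  expect_false(ci_lookup(panel, "CCL19", "NK", 1000)$measured)
  expect_error(ci_lookup(panel, "CCL99", "panT", 10), "no record")
})

test_that("panel invariants survive a file round-trip", {
  panel <- load_panel()
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    dplyr::mutate(as.data.frame(panel)[names(panel) != "n"],
                  cell_population = as.character(cell_population),
                  significance = as.character(significance)),
    tmp, na = "")
  back <- load_panel(tmp)
  v <- validate_panel(back)
  expect_true(v$valid)
  expect_equal(ci_lookup(back, "CCL19", "panT", 1000)$ci_mean, 27.73)
})

test_that("malformed panels are rejected with the offending row named", {
  panel <- readr::read_csv(
    system.file("extdata", "chemokine_panel.csv", package = "elnsim"),
    col_types = readr::cols(), progress = FALSE)
  tmp <- withr::local_tempfile(fileext = ".csv")
  dup <- rbind(panel, panel[5, ])
  readr::write_csv(dup, tmp, na = "")
  expect_error(load_panel(tmp), "duplicate")
  bad <- panel
  bad$cell_population[3] <- "monocyte"
  readr::write_csv(bad, tmp, na = "")
  expect_error(load_panel(tmp), "row 4")
})

test_that("summary-statistics t-test matches an independent computation", {
  # oracle: raw samples reconstructed to the exact summary statistics,
  # passed through stats::t.test(var.equal = TRUE); value frozen
  expect_equal(ci_ttest(3, 0.5, 1, 0.3, n = 4), 0.0004724625639,
               tolerance = 1e-9)
  expect_equal(ci_ttest(2, 0.4, 2, 0.4, n = 4), 1.0)
  expect_equal(ci_ttest(2, 0, 2, 0, n = 4), 1.0)
  expect_error(ci_ttest(1, 0.1, 1, 0.1, n = 1), "at least 2")
  expect_error(ci_ttest(1, -0.1, 1, 0.1), ">= 0")
  # monotonicity: widening the mean gap at fixed sds never increases p
  gaps <- seq(0, 3, by = 0.25)
  ps <- ci_ttest(1 + gaps, 0.5, 1, 0.3, n = 4)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("classification reproduces every printed signature-panel call", {
  panel <- load_panel()
  calls <- classify_response(
    dplyr::filter(panel, chemokine %in% signature_chemokines()))
  merged <- dplyr::inner_join(
    calls, signature_calls(), by = c("chemokine", "cell_population"))
  expect_identical(nrow(merged), 60L)
  expect_identical(as.character(merged$category), merged$expected)
})

test_that("classification edge cases behave per the rule", {
  panel <- load_panel()
  one <- function(ck, pop) {
    as.character(classify_response(
      dplyr::filter(panel, chemokine == ck, cell_population == pop)
    )$category)
  }
  expect_identical(one("CCL19", "panT"), "+")
  expect_identical(one("CXCL9", "panT"), "-/+")
  expect_identical(one("CCL2", "panT"), "-")
  expect_identical(one("CCL19", "NK"), "ND")
  expect_error(classify_response(panel[0, ]), "no assay records")
})

test_that("stored significance is consistent with the recomputed t-test", {
  # the printed labels are authoritative; the pooled t-test from the stored
  # summary statistics should nonetheless agree in direction for the clear
  # calls (CI well above 1 with small dispersion)
  panel <- load_panel()
  strong <- dplyr::filter(panel, measured, concentration_ng_ml > 0,
                          ci_mean > 5)
  ctrl <- dplyr::semi_join(
    dplyr::filter(panel, concentration_ng_ml == 0),
    strong, by = c("chemokine", "cell_population"))
  joined <- dplyr::inner_join(
    strong, ctrl, by = c("chemokine", "cell_population"),
    suffix = c("", "_ctrl"))
  p <- ci_ttest(joined$ci_mean, joined$ci_sd,
                joined$ci_mean_ctrl, joined$ci_sd_ctrl, n = 4)
  expect_true(all(p < 0.05))
  expect_true(all(joined$significance != "ns"))
})
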