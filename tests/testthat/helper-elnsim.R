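# Small configurations used across tests: short horizons and reduced cell
# numbers keep the suite fast while exercising every engine code path.
quick_config <- function(...) {
  args <- utils::modifyList(list(total_time_days = 0.5, record_every = 60),
                            list(...))
  do.call(sim_config, args)
}

# printed Table-3-style calls for the 12 signature chemokines on the five
# resting populations (columns panT, CD4T, CD8T, B, NK)
signature_calls <- function() {
  tibble::tribble(
    ~chemokine, ~panT, ~CD4T, ~CD8T, ~B,    ~NK,
    "CCL2",     "-",   "-",   "-",   "-",   "-/+",
    "CCL3",     "-",   "-",   "-",   "-",   "-/+",
    "CCL4",     "-",   "-",   "-",   "-",   "-/+",
    "CCL5",     "-",   "-",   "-",   "-",   "-/+",
    "CCL8",     "-",   "-",   "-",   "-",   "-",
    "CCL18",    "-",   "-",   "-",   "-",   "-",
    "CCL19",    "+",   "+",   "+",   "-/+", "ND",
    "CCL21",    "+",   "+",   "+",   "-/+", "ND",
    "CXCL9",    "-/+", "-/+", "-/+", "-",   "-/+",
    "CXCL10",   "-/+", "-/+", "+",   "-",   "-/+",
    "CXCL11",   "+",   "-",   "+",   "-",   "-/+",
    "CXCL13",   "-/+", "-/+", "-/+", "+",   "-"
  ) |>
    tidyr::pivot_longer(-chemokine, names_to = "cell_population",
                        values_to = "expected")
}
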