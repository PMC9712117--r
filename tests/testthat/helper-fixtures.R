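# Small programmatic fixtures shared across test files.

# minimal valid spot data frame; override columns via ...
make_spots <- function(n = 3, slice_id = "S01", ...) {
  d <- data.frame(
    spot_id = seq_len(n), slice_id = slice_id,
    x_um = seq_len(n) * 100, y_um = 50,
    depth_mm = if (n <= 400) seq_len(n) * 0.1 else
      seq(0.05, 49.95, length.out = n),
    gs = 150, ca = 10, fe = 10, ti = 10, si = 10,
    i372 = 50, i373 = 50, sn372 = 20, sn373 = 20,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

make_slices <- function(ids = "S01", offset = 480) {
  data.frame(slice_id = ids,
             offset_cm_bsf = offset + 5 * (seq_along(ids) - 1),
             length_mm = 50, width_mm = 4, stringsAsFactors = FALSE)
}

make_table <- function(n = 3, ...) {
  spot_table(make_spots(n, ...), make_slices())
}

# a small, fast scenario: short record, single era, quiet climate
quiet_scenario <- function(age_start = 11.35, age_end = 11.2,
                           transition_age = 11.3, ...) {
  scenario_config(age_start = age_start, age_end = age_end,
                  transition_age = transition_age,
                  cycle_amplitudes = c(0, 0), interannual_sd = c(0, 0),
                  white_sd = 0, ...)
}

# default full-length scenario with a given seed
default_scenario <- function(seed = 1L, ...) scenario_config(seed = seed, ...)

# run simulate -> delta_gs -> qc -> ages for a scenario
sim_prepared <- function(cfg, sn_min = 3) {
  truth <- simulate_truth(cfg)
  tab <- compute_delta_gs(simulate_dataset(truth, cfg))
  am <- age_model_from_truth(truth)
  qc <- suppressMessages(qc_filter_spots(tab, sn_min = sn_min))
  ages <- depth_to_age(am, spot_composite_depth(qc))
  list(truth = truth, table = tab, qc = qc, ages = ages, age_model = am)
}
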