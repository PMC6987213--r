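# Reference sources and beamlines shared across tests.

# the three reference configurations (energy, gap, source parameters)
table1_sources <- function() {
  list(
    mev100_gap30 = list(src = beam_source(100, 0.01, 6.5, 10.0, 5, 5, -1, -1),
                        gap = 30, h = 1.67, v = 1.65,
                        h_lo = 1.67 - 0.19, v_lo = 1.65 - 0.40),
    mev100_gap10 = list(src = beam_source(100, 0.01, 4.0, 4.0, 3, 3, -1, -1),
                        gap = 10, h = 0.66, v = 0.68,
                        h_lo = 0.66 - 0.11, v_lo = 0.68 - 0.11),
    mev200_gap30 = list(src = beam_source(200, 0.01, 5.0, 3.5, 1, 0.5, 1, -1),
                        gap = 30, h = 0.87, v = 0.85,
                        h_lo = 0.87 - 0.14, v_lo = 0.85 - 0.07))
}

# band check: within the printed uncertainty or +/-25%, whichever is looser
in_table1_band <- function(value, printed, printed_lo) {
  lo <- min(printed_lo, printed * 0.75)
  hi <- max(printed + 0.001, printed * 1.25)
  value >= lo & value <= hi
}

random_vacuum_beamline <- function(n_el = 5, seed = 1) {
  set.seed(seed)
  els <- lapply(seq_len(n_el), function(i) {
    if (i %% 2 == 0) {
      el_quad(runif(1, 5, 30), runif(1, 0, 2), runif(1, 3, 6),
              sample(c("horizontal", "vertical"), 1), "vacuum")
    } else {
      el_drift(runif(1, 10, 80), "vacuum")
    }
  })
  nozzle_config(els, preset = "random_vacuum")
}
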