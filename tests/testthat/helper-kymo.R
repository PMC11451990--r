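# Construct a bare Kymograph object from a matrix, for unit tests that
# exercise trace detection without running the full imaging pipeline.
make_test_kymo <- function(values, adjacent_next = rep(TRUE, nrow(values)),
                           frame_interval_s = 1, pixel_size_nm = 65) {
  structure(list(values = values,
                 row_arclength_um = (seq_len(nrow(values)) - 1) *
                   pixel_size_nm / 1000,
                 adjacent_next = adjacent_next,
                 row_flagged = rep(FALSE, nrow(values)),
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 cell_id = 1L, compartment = "daughter", channel = "ch1",
                 width_px = 5, reduction = "max"),
            class = "Kymograph")
}

# A small, fast simulation configuration for pipeline-level tests.
small_sim_config <- function(duration_s = 60, ...) {
  sim_config(mother_radius_px = 26, daughter_radius_px = 18,
             neck_halfwidth_px = 6, duration_s = duration_s, ...)
}
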