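# Small synthetic-fish fixtures shared across test files.

# A compact fish that keeps per-frame processing fast in unit tests.
tiny_cfg <- function(...) {
  defaults <- list(body_length_px = 60, n_midline_samples = 40,
                   wave_frequency_hz = 10, amp_head_px = 1, amp_tail_px = 6,
                   thickness_profile = default_thickness_profile(60, h_max = 4),
                   frame_size = c(128, 64), fps = 500, duration_s = 0.2)
  do.call(fish_model_config, utils::modifyList(defaults, list(...)))
}

# Selection criteria for fin-less synthetic silhouettes, which are nearly
# convex when the body is straight (solidity ceiling relaxed to 1).
synth_criteria <- function(...) selection_criteria(max_solidity = 1, ...)

synth_gait_config <- function(cfg, gaussian_sigma = 0, ...) {
  gait_config(fps = cfg$fps, gaussian_sigma = gaussian_sigma,
              criteria = synth_criteria(), ...)
}
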