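# Draw a benchmark dataset, skipping degenerate realizations in which some
# class ends up with fewer than 2 samples (SNR and the k-NN score need every
# class populated).
gen_valid_sim <- function(design, seed0) {
  s <- seed0
  repeat {
    sim <- simulate_design(design, seed = s)
    if (all(table(sim$data$class) >= 2)) return(sim)
    s <- s + 17
  }
}
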