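# Construct-panel fixture: four kinetic archetypes (retained/slow,
# intermediate, weak/fast, unlocalized) with small Gaussian jitter.
panel_fixture <- function(noise_sd = 0.02, n_per = 3, seed = 42) {
  archetypes <- tibble::tribble(
    ~arch, ~pc, ~recovery_5s, ~recovery_100s,
    "retained",     12,  0.05, 0.15,
    "intermediate",  6,  0.25, 0.55,
    "weak",          2,  0.55, 0.90,
    "none",          1,  0.95, 1.00
  )
  set.seed(seed)
  purrr::pmap_dfr(archetypes, function(arch, pc, recovery_5s, recovery_100s) {
    tibble::tibble(
      construct_id = paste0(arch, "_", seq_len(n_per)),
      arch = arch,
      pc = pc * (1 + rnorm(n_per, 0, noise_sd)),
      recovery_5s = pmax(0, recovery_5s + rnorm(n_per, 0, noise_sd / 2)),
      recovery_100s = pmin(1.05, recovery_100s + rnorm(n_per, 0, noise_sd / 2)),
      mobile_fraction = pmin(1, recovery_100s + rnorm(n_per, 0, noise_sd / 2))
    )
  })
}
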