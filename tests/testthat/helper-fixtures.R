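# Shared fixtures: the packaged gemcitabine model and small builders used
# across test files. Everything is generated in code; no stored data.

gem <- gemcitabine_parameters()
subj70 <- subject_parameters()
phys_default <- default_human_physiology()
kel_gem <- gem$clearance / (gem$vc_per_kg * subj70$body_mass)  # 1.1823 1/h

# n equal small-intestine compartments with a chosen ka and total transit T:
# the pure transit-chain limit with a closed-form fraction absorbed.
cat_chain_physiology <- function(n, ka, total_transit) {
  r <- 2 * gem$peff_jejunal * 3600 / ka  # radius such that asf = 1 gives ka
  tbl <- tibble::tibble(
    compartment = c("stomach", paste0("si", seq_len(n)), "colon"),
    volume_ml = rep(100, n + 2),
    radius_cm = c(5, rep(r, n), 3),
    transit_h = c(0.01, rep(total_transit / n, n), 0.5),
    ph = 6.5,
    asf = c(0, rep(1, n), 0)
  )
  acatpk:::new_gi_physiology(tbl, small_intestine = paste0("si", seq_len(n)))
}

cat_closed_form_fa <- function(ka, total_transit, n) {
  1 - (1 + ka * total_transit / n)^(-n)
}

# high-solubility gemcitabine variant: dissolution never rate-limiting,
# keeps the lumen model in its linear regime
gem_soluble <- gemcitabine_parameters(solubility = 50.1)
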