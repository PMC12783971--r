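# small in-code fixtures shared across test files

AF_VPDB <- 0.0111802 / 1.0111802
AF_AIR <- 0.0036765 / 1.0036765

# one-compartment sample table whose excess is chosen directly in atom
# fraction units against a given reference
make_samples <- function(excess_af, af_ref, element = "C",
                         dry_mass_g = 1, element_pct = 42,
                         arm_id = "arm1", compartment_id = "comp1",
                         role = "medium", replicate = seq_along(excess_af)) {
  delta <- atom_fraction_to_delta(af_ref + excess_af, element)
  tibble::tibble(
    sample_id = paste0(compartment_id, "-", replicate),
    arm_id = arm_id, compartment_id = compartment_id, role = role,
    element = element, dry_mass_g = dry_mass_g, element_pct = element_pct,
    delta_permil = delta, replicate = as.integer(replicate)
  )
}

make_refs <- function(roles, element, af_ref) {
  tibble::tibble(role = roles, element = element, af_ref = af_ref)
}

quiet_recovery <- function(...) suppressWarnings(percent_recovery(...))

# noiseless generator configs used repeatedly
noiseless <- c(C = 0, N = 0, H = 0)
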