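ATOMIC_MASS <- c(C = 12.011, N = 14.007, H = 1.008)

#' Tracer compound registry
#'
#' The labelled compounds used to introduce tracer, with molar mass of the
#' compound, the number of labelled atom positions per molecule and the
#' isotopic purity of those positions. Purities default to 0.99 because
#' suppliers rarely certify beyond "all positions labelled"; override per
#' compound when the certificate states more.
#'
#' @param ... One-row data frames or named lists appended to (or replacing,
#'   by `name`) the built-in compounds.
#' @return A tibble with columns `name`, `element`, `molar_mass` (g/mol),
#'   `labelled_atoms`, `af_tracer`.
#' @examples
#' tracer_compounds()
#' @export
tracer_compounds <- function(...) {
  base <- tibble::tribble(
    ~name,            ~element, ~molar_mass, ~labelled_atoms, ~af_tracer,
    "13C-glucose",    "C",      186.11,      6L,              0.99,
    "15N-NH4Cl",      "N",      54.49,       1L,              0.99,
    "D2O",            "H",      20.028,      2L,              0.99
  )
  extra <- list(...)
  if (length(extra) > 0) {
    extra <- purrr::map_dfr(extra, tibble::as_tibble)
    base <- dplyr::bind_rows(
      dplyr::filter(base, !.data$name %in% extra$name), extra
    )
  }
  if (any(base$molar_mass <= 0) ||
      any(base$af_tracer <= 0 | base$af_tracer > 1) ||
      any(base$labelled_atoms < 1)) {
    abort("invalid compound definition", class = "mycoflux_config_error")
  }
  base
}

lookup_compound <- function(compound, compounds = tracer_compounds()) {
  if (is.character(compound)) {
    hit <- compounds[compounds$name == compound, ]
    if (nrow(hit) != 1) {
      abort(paste0("unknown tracer compound: ", compound),
            class = "mycoflux_config_error")
    }
    return(hit)
  }
  tibble::as_tibble(compound)
}

#' Moles of an element in a measured sample
#'
#' Dry mass times the element mass fraction, divided by the atomic mass
#' (C 12.011, N 14.007, H 1.008 g/mol).
#'
#' @param dry_mass_g Sample dry mass in grams.
#' @param element_pct Element content as percent of dry mass.
#' @param element `"C"`, `"N"` or `"H"`.
#' @return Moles of the element (vectorised).
#' @examples
#' element_moles(1, 42, "C")   # 0.42 g C -> 0.034968 mol
#' @export
element_moles <- function(dry_mass_g, element_pct, element) {
  if (any(dry_mass_g < 0) || any(element_pct < 0 | element_pct > 100)) {
    abort("dry mass must be >= 0 and element percent in [0, 100]",
          class = "mycoflux_domain_error")
  }
  mass <- ATOMIC_MASS[element]
  if (any(is.na(mass))) {
    abort("element must be one of C, N, H", class = "mycoflux_domain_error")
  }
  unname(dry_mass_g * element_pct / 100 / mass)
}

#' Signed heavy-isotope excess in a sample
#'
#' Moles of heavy isotope attributable to tracer: element moles times the
#' difference between the sample atom fraction and the natural-abundance
#' reference of the same material. Negative values (sample below the
#' reference) propagate unchanged so diagnostics can see them; clipping to
#' zero happens only at the percent-recovery stage.
#'
#' @param n_mol Element moles in the sample.
#' @param af Sample atom fraction.
#' @param af_ref Natural-abundance atom fraction of an unlabelled control of
#'   the same material.
#' @return Signed moles of heavy-isotope excess (vectorised).
#' @export
heavy_excess_moles <- function(n_mol, af, af_ref) {
  n_mol * (af - af_ref)
}

#' Heavy-isotope excess added by a labelling event
#'
#' Converts a dose in milligrams of labelled compound into moles of
#' heavy-isotope excess above natural abundance:
#' `(amount/molar_mass) * labelled_atoms * (af_tracer - af_nat)`.
#'
#' @param amount_mg Dose in mg of compound.
#' @param compound Compound name in `compounds`, or a one-row compound
#'   definition.
#' @param af_nat Natural-abundance atom fraction of the element.
#' @param compounds Registry from [tracer_compounds()].
#' @return Moles of heavy-atom excess added.
#' @examples
#' af_nat <- delta_to_atom_fraction(0, "C")
#' added_heavy_excess(5.5, "13C-glucose", af_nat)
#' @export
added_heavy_excess <- function(amount_mg, compound, af_nat,
                               compounds = tracer_compounds()) {
  cmp <- lookup_compound(compound, compounds)
  if (cmp$af_tracer <= af_nat) {
    abort("tracer atom fraction must exceed the natural abundance",
          class = "mycoflux_domain_error")
  }
  if (any(amount_mg <= 0)) {
    abort("dose must be > 0 mg", class = "mycoflux_domain_error")
  }
  amount_mg / 1000 / cmp$molar_mass * cmp$labelled_atoms *
    (cmp$af_tracer - af_nat)
}
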