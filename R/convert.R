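#' Convert between delta notation, isotope ratio and atom fraction
#'
#' Exact algebraic conversions for a two-isotope system. Delta values are
#' per-mil deviations of the heavy/light ratio R from the reference ratio
#' of the named standard: \eqn{R = R_{std}(\delta/1000 + 1)}. Atom fraction
#' is the heavy-isotope share of all atoms of the element, related to the
#' ratio by \eqn{AF = R/(1+R)} (the standard two-isotope approximation,
#' adequate at tracer-level enrichments; no multi-isotope corrections are
#' applied).
#'
#' All functions are vectorised and round-trip to within 1e-12 relative.
#'
#' @param delta Delta value(s) in per mil; must be > -1000.
#' @param ratio Dimensionless heavy/light isotope ratio(s); must be > 0
#'   (>= 0 for `ratio_to_atom_fraction()`).
#' @param af Atom fraction(s) in `[0, 1)`.
#' @param system Isotope pair, element or reference name understood by
#'   [iso_system()].
#' @param standards Registry tibble from [iso_standards()].
#'
#' @return A numeric vector of the target quantity.
#'
#' @examples
#' delta_to_ratio(0, "13C/12C")          # the VPDB ratio itself
#' delta_to_atom_fraction(1000, "C")     # doubling of the reference ratio
#' ratio_to_delta(0.012, "VPDB")
#' @name iso-conversions
NULL

#' @rdname iso-conversions
#' @export
delta_to_ratio <- function(delta, system, standards = iso_standards()) {
  if (any(!is.finite(delta) | delta <= -1000)) {
    abort("delta values must be finite and > -1000 permil",
          class = "mycoflux_domain_error")
  }
  r_std <- iso_system(system, standards)$reference_ratio
  r_std * (delta / 1000 + 1)
}

#' @rdname iso-conversions
#' @export
ratio_to_delta <- function(ratio, system, standards = iso_standards()) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    abort("isotope ratios must be finite and > 0",
          class = "mycoflux_domain_error")
  }
  r_std <- iso_system(system, standards)$reference_ratio
  (ratio / r_std - 1) * 1000
}

#' @rdname iso-conversions
#' @export
ratio_to_atom_fraction <- function(ratio) {
  if (any(!is.finite(ratio) | ratio < 0)) {
    abort("isotope ratios must be finite and >= 0",
          class = "mycoflux_domain_error")
  }
  ratio / (1 + ratio)
}

#' @rdname iso-conversions
#' @export
atom_fraction_to_ratio <- function(af) {
  if (any(!is.finite(af) | af < 0 | af >= 1)) {
    abort("atom fractions must lie in [0, 1)",
          class = "mycoflux_domain_error")
  }
  af / (1 - af)
}

#' @rdname iso-conversions
#' @export
delta_to_atom_fraction <- function(delta, system, standards = iso_standards()) {
  ratio_to_atom_fraction(delta_to_ratio(delta, system, standards))
}

#' @rdname iso-conversions
#' @export
atom_fraction_to_delta <- function(af, system, standards = iso_standards()) {
  ratio_to_delta(atom_fraction_to_ratio(af), system, standards)
}

#' Mix element pools by isotope mass balance
#'
#' Forward two-pool (or n-pool) mixing: the atom fraction of the mixture is
#' the mole-weighted mean of the pool atom fractions, which conserves both
#' total element moles and total heavy-isotope moles exactly.
#'
#' @param moles Moles of the element in each pool (all >= 0, at least one
#'   > 0).
#' @param af Atom fraction of each pool.
#' @return The atom fraction of the combined pool (length 1).
#' @examples
#' mix_pools(c(1, 1), c(0.01, 0.03))  # 0.02
#' @export
mix_pools <- function(moles, af) {
  if (length(moles) != length(af) || length(moles) == 0) {
    abort("`moles` and `af` must be equal-length, non-empty vectors",
          class = "mycoflux_domain_error")
  }
  if (any(!is.finite(moles) | moles < 0) || sum(moles) == 0) {
    abort("pool moles must be >= 0 with a positive total",
          class = "mycoflux_domain_error")
  }
  if (any(!is.finite(af) | af < 0 | af >= 1)) {
    abort("pool atom fractions must lie in [0, 1)",
          class = "mycoflux_domain_error")
  }
  sum(moles * af) / sum(moles)
}

#' Tracer dose for a target enrichment
#'
#' Moles of labelled-element atoms that must be added to an element pool at
#' natural abundance to raise its atom fraction to a target, by inverting
#' the two-pool mixing balance:
#' \deqn{n_{tracer} = n_{pool} \frac{AF_{target} - AF_{nat}}
#'                                  {AF_{tracer} - AF_{target}}}
#' Feeding the returned dose back through [mix_pools()] recovers the target
#' atom fraction exactly.
#'
#' @param pool_moles Moles of the element in the pool to be labelled.
#' @param af_nat Natural-abundance atom fraction of the pool.
#' @param af_target Desired atom fraction after labelling; must exceed
#'   `af_nat` and be below `af_tracer`.
#' @param af_tracer Atom fraction of the tracer compound's label positions
#'   (isotopic purity), in `(af_target, 1]`.
#' @return Moles of labelled-element atoms to add.
#' @examples
#' af0 <- delta_to_atom_fraction(0, "C")
#' aft <- delta_to_atom_fraction(500, "C")
#' dose <- required_tracer_amount(1, af0, aft, 0.99)
#' mix_pools(c(1, dose), c(af0, 0.99))  # equals aft
#' @export
required_tracer_amount <- function(pool_moles, af_nat, af_target, af_tracer) {
  if (any(!is.finite(c(pool_moles, af_nat, af_target, af_tracer))) ||
      pool_moles <= 0) {
    abort("pool_moles must be finite and > 0; atom fractions finite",
          class = "mycoflux_domain_error")
  }
  if (af_target <= af_nat) {
    abort("target atom fraction must exceed the natural abundance",
          class = "mycoflux_domain_error")
  }
  if (af_target >= af_tracer) {
    abort("target atom fraction at or above the tracer purity is infeasible",
          class = "mycoflux_infeasible_error")
  }
  pool_moles * (af_target - af_nat) / (af_tracer - af_target)
}
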