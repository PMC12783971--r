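SAMPLE_COLUMNS <- c("sample_id", "arm_id", "compartment_id", "role",
                    "element", "dry_mass_g", "element_pct", "delta_permil",
                    "replicate")

check_sample_table <- function(samples) {
  missing <- setdiff(SAMPLE_COLUMNS, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mycoflux_schema_error")
  }
  invisible(samples)
}

#' Natural-abundance references from unlabelled controls
#'
#' Computes the per-role natural-abundance atom fraction from unlabelled
#' control samples of the same materials. Compost, casing and malt medium
#' all sit at non-zero natural delta offsets, so material-matched controls
#' are preferred over the international standards; use [standard_refs()]
#' only when no control material was measured.
#'
#' @param controls Sample table (see [read_sample_table()]) of unlabelled
#'   material.
#' @param standards Registry from [iso_standards()].
#' @return A tibble with columns `role`, `element`, `af_ref`, `n`.
#' @export
natural_refs <- function(controls, standards = iso_standards()) {
  check_sample_table(controls)
  controls |>
    dplyr::group_by(.data$role, .data$element) |>
    dplyr::summarise(
      af_ref = mean(delta_to_atom_fraction(.data$delta_permil,
                                           .data$element[1], standards)),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Fallback references at the international standard composition
#'
#' @param roles Character vector of compartment roles to cover.
#' @param element `"C"`, `"N"` or `"H"`.
#' @param standards Registry from [iso_standards()].
#' @return A tibble with columns `role`, `element`, `af_ref`.
#' @export
standard_refs <- function(roles, element, standards = iso_standards()) {
  warn(paste0("no material-matched controls supplied for ", element,
              "; falling back to the international standard composition"))
  tibble::tibble(
    role = roles, element = element,
    af_ref = delta_to_atom_fraction(0, element, standards)
  )
}

#' Percent-of-added-tracer recovery per compartment
#'
#' Converts a bulk-IRMS sample table plus the labelling plan of one element
#' into a tracer mass balance: per sample, the atom fraction from its delta
#' value, the element moles from dry mass and element fraction, the signed
#' heavy-isotope excess above the material-matched reference, and the
#' percent of the arm's added tracer that the excess represents. Replicates
#' are aggregated as mean and SD per (arm, compartment); negative
#' per-replicate percentages are clipped to zero with a warning (the signed
#' excess is retained in the per-replicate table for diagnostics).
#'
#' @param samples Sample table with the columns listed under
#'   [read_sample_table()]; a single element.
#' @param events Labelling plan tibble with columns `arm_id`,
#'   `compartment_id`, `compound`, `amount_mg`.
#' @param refs Reference tibble (`role`, `element`, `af_ref`) from
#'   [natural_refs()] or [standard_refs()].
#' @param element Element to account for (`"C"`, `"N"` or `"H"`); defaults
#'   to the single element present in `samples`.
#' @param standards Registry from [iso_standards()].
#' @param compounds Registry from [tracer_compounds()].
#' @param denominator `"excess"` (default): the denominator is the added
#'   heavy-atom excess above natural abundance; `"gross"`: all added heavy
#'   atoms including the naturally occurring share of the tracer compound.
#' @return A `tracer_recovery` object: tibbles `compartments` (one row per
#'   arm x compartment: `excess_af`, `excess_mol`, `percent_of_added`,
#'   `percent_sd`, `n`), `arms` (`added_excess_mol`, `recovered_percent`,
#'   `unrecovered_percent`) and `replicates` (signed per-replicate detail),
#'   plus the element and denominator convention used.
#' @seealso [unrecovered_fraction()], [directionality_index()],
#'   [tracer_cn_ratio()]
#' @export
percent_recovery <- function(samples, events, refs,
                             element = NULL,
                             standards = iso_standards(),
                             compounds = tracer_compounds(),
                             denominator = c("excess", "gross")) {
  check_sample_table(samples)
  denominator <- match.arg(denominator)
  if (is.null(element)) {
    element <- unique(samples$element)
    if (length(element) != 1) {
      abort("sample table mixes elements; pass `element` explicitly",
            class = "mycoflux_domain_error")
    }
  }
  samples <- dplyr::filter(samples, .data$element == !!element)
  if (nrow(samples) == 0) {
    abort(paste0("no samples for element ", element),
          class = "mycoflux_domain_error")
  }
  refs <- dplyr::filter(refs, .data$element == !!element)
  missing_ref <- setdiff(unique(samples$role), refs$role)
  if (length(missing_ref) > 0) {
    abort(paste0("no natural-abundance reference for role(s): ",
                 paste(missing_ref, collapse = ", ")),
          class = "mycoflux_config_error")
  }

  # heavy-atom excess added per arm, for the recovery denominator
  ev <- dplyr::inner_join(events,
                          dplyr::rename(compounds, compound = "name"),
                          by = "compound") |>
    dplyr::filter(.data$element == !!element)
  missing_ev <- setdiff(unique(samples$arm_id), ev$arm_id)
  if (length(missing_ev) > 0) {
    abort(paste0("arm(s) without a ", element, " labelling event: ",
                 paste(missing_ev, collapse = ", ")),
          class = "mycoflux_config_error")
  }
  role_map <- dplyr::distinct(samples, .data$compartment_id, .data$role)
  ev <- ev |>
    dplyr::left_join(role_map, by = "compartment_id") |>
    dplyr::left_join(refs[, c("role", "af_ref")], by = "role")
  if (any(is.na(ev$af_ref))) {
    warn("labelled compartment not in the sample table; using the standard composition for the dose baseline")
    ev$af_ref[is.na(ev$af_ref)] <-
      delta_to_atom_fraction(0, element, standards)
  }
  af_floor <- if (denominator == "excess") ev$af_ref else 0
  added <- ev |>
    dplyr::mutate(added_mol = .data$amount_mg / 1000 / .data$molar_mass *
                    .data$labelled_atoms * (.data$af_tracer - af_floor)) |>
    dplyr::group_by(.data$arm_id) |>
    dplyr::summarise(added_excess_mol = sum(.data$added_mol),
                     .groups = "drop")

  reps <- samples |>
    dplyr::left_join(refs[, c("role", "af_ref")], by = "role") |>
    dplyr::mutate(
      af = delta_to_atom_fraction(.data$delta_permil, !!element, standards),
      n_mol = element_moles(.data$dry_mass_g, .data$element_pct, !!element),
      excess_af = .data$af - .data$af_ref,
      excess_mol = heavy_excess_moles(.data$n_mol, .data$af, .data$af_ref)
    ) |>
    dplyr::left_join(added, by = "arm_id") |>
    dplyr::mutate(percent_raw = 100 * .data$excess_mol /
                    .data$added_excess_mol,
                  percent_of_added = pmax(.data$percent_raw, 0))
  n_clipped <- sum(reps$percent_raw < 0)
  if (n_clipped > 0) {
    warn(paste0(n_clipped, " negative excess value(s) clipped to 0 %",
                " at the percent stage"))
  }

  compartments <- reps |>
    dplyr::group_by(.data$arm_id, .data$compartment_id, .data$role) |>
    dplyr::summarise(
      excess_af = mean(.data$excess_af),
      excess_mol = mean(.data$excess_mol),
      percent_sd = sd(.data$percent_of_added),
      percent_of_added = mean(.data$percent_of_added),
      n = dplyr::n(),
      .groups = "drop"
    )
  arms <- compartments |>
    dplyr::group_by(.data$arm_id) |>
    dplyr::summarise(recovered_percent = sum(.data$percent_of_added),
                     .groups = "drop") |>
    dplyr::left_join(added, by = "arm_id") |>
    dplyr::mutate(unrecovered_percent = 100 - .data$recovered_percent) |>
    dplyr::relocate("added_excess_mol", .after = "arm_id")

  structure(
    list(compartments = compartments, arms = arms,
         replicates = reps, element = element,
         denominator = denominator, n_clipped = n_clipped),
    class = "tracer_recovery"
  )
}

#' @export
print.tracer_recovery <- function(x, ...) {
  cat("<tracer_recovery> element:", x$element,
      "| denominator:", x$denominator, "\n")
  print(x$compartments, ...)
  cat("Arm closure:\n")
  print(x$arms, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname percent_recovery
#' @param x A `tracer_recovery` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tracer_recovery <- function(x, ...) x$compartments

#' @rdname percent_recovery
#' @exportS3Method generics::glance
glance.tracer_recovery <- function(x, ...) {
  dplyr::mutate(x$arms, element = x$element, denominator = x$denominator,
                n_clipped = x$n_clipped)
}

#' Unrecovered tracer (closure by difference)
#'
#' The share of added tracer not found in any sampled compartment of an
#' arm: respiration plus unmeasured losses for carbon, degassing and
#' unmeasured losses for nitrogen. May be negative under measurement noise;
#' negative closures are reported signed and flagged with a warning.
#'
#' @param result A [percent_recovery()] result.
#' @param arm Optional arm id; default returns a named vector over all arms.
#' @return Percent of added tracer, signed.
#' @export
unrecovered_fraction <- function(result, arm = NULL) {
  stopifnot(inherits(result, "tracer_recovery"))
  arms <- result$arms
  if (!is.null(arm)) arms <- arms[arms$arm_id %in% arm, ]
  if (any(arms$unrecovered_percent < 0)) {
    warn("negative closure (recoveries exceed 100 %): measurement noise or reference mismatch")
  }
  stats::setNames(arms$unrecovered_percent, arms$arm_id)
}

match_position <- function(compartment_id, layout) {
  idx <- rep(NA_integer_, length(compartment_id))
  for (i in seq_along(layout)) {
    hit <- compartment_id == layout[i] |
      startsWith(compartment_id, paste0(layout[i], "_"))
    idx[hit] <- i
  }
  idx
}

#' Directionality of tracer spread
#'
#' Summarises whether recovered tracer sits peripheral or central of the
#' labelled position along an ordered layout (ring 1..5 of a ring plate, or
#' layer 1..3 of a bed): `(peripheral - central) / (peripheral + central)`
#' over the percent recoveries of compartments away from the source.
#' +1 means all translocated tracer moved outward, -1 all inward, 0 a
#' symmetric spread (or nothing translocated).
#'
#' @param result A [percent_recovery()] result.
#' @param layout Character vector of position labels ordered from centre to
#'   periphery; compartment ids must equal a label or start with
#'   `"<label>_"`.
#' @param source Position label of the labelled compartment.
#' @return A single number in `[-1, 1]`.
#' @export
directionality_index <- function(result, layout, source) {
  stopifnot(inherits(result, "tracer_recovery"))
  src <- match(source, layout)
  if (is.na(src)) {
    abort("source position not in layout", class = "mycoflux_domain_error")
  }
  comp <- result$compartments
  pos <- match_position(comp$compartment_id, layout)
  if (any(is.na(pos))) {
    abort("compartment id(s) not matching any layout position",
          class = "mycoflux_domain_error")
  }
  peripheral <- sum(comp$percent_of_added[pos > src])
  central <- sum(comp$percent_of_added[pos < src])
  if (peripheral + central == 0) return(0)
  (peripheral - central) / (peripheral + central)
}

#' Tracer-derived C:N ratio of a compartment
#'
#' Moles of tracer-derived carbon divided by moles of tracer-derived
#' nitrogen in one compartment, from the element-wise recovery results of
#' the same arm.
#'
#' @param recovery_C,recovery_N [percent_recovery()] results for carbon and
#'   nitrogen.
#' @param compartment Compartment id.
#' @return The molar C:N ratio of the tracer-derived element pools.
#' @export
tracer_cn_ratio <- function(recovery_C, recovery_N, compartment) {
  stopifnot(inherits(recovery_C, "tracer_recovery"),
            inherits(recovery_N, "tracer_recovery"))
  get_excess <- function(res, what) {
    rows <- res$compartments[res$compartments$compartment_id == compartment, ]
    if (nrow(rows) == 0) {
      abort(paste0("compartment ", compartment, " absent from the ", what,
                   " recovery"), class = "mycoflux_domain_error")
    }
    mean(rows$excess_mol)
  }
  c_mol <- get_excess(recovery_C, "carbon")
  n_mol <- get_excess(recovery_N, "nitrogen")
  if (n_mol <= 0) {
    abort("nitrogen excess is zero or negative; C:N ratio undefined",
          class = "mycoflux_domain_error")
  }
  c_mol / n_mol
}
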