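#' Initial enrichment achieved per substrate layer
#'
#' In the layered-bed design the excess atom fraction actually reached in
#' each layer shortly after labelling is measured on a dedicated control
#' incubation in which all layers are labelled simultaneously and sampled
#' a few hours later. These initial enrichments normalise the sink
#' enrichment of each labelling arm before layers are compared, because the
#' dose, element stock and absorption differ between casing and compost.
#'
#' @param controls Sample table of the all-layer control arm.
#' @param refs Reference tibble (`role`, `element`, `af_ref`).
#' @param layers Roles that must be present; error if one has no control
#'   sample.
#' @param element Element; defaults to the single element in `controls`.
#' @param standards Registry from [iso_standards()].
#' @return A tibble (`layer`, `e0`, `e0_sd`, `n`) with `e0` the mean excess
#'   atom fraction over replicates.
#' @export
layer_initial_excess <- function(controls, refs,
                                 layers = c("casing", "compost_upper",
                                            "compost_lower"),
                                 element = NULL,
                                 standards = iso_standards()) {
  check_sample_table(controls)
  if (is.null(element)) {
    element <- unique(controls$element)
    if (length(element) != 1) {
      abort("control table mixes elements; pass `element` explicitly",
            class = "mycoflux_domain_error")
    }
  }
  controls <- dplyr::filter(controls, .data$element == !!element,
                            .data$role %in% layers)
  missing <- setdiff(layers, unique(controls$role))
  if (length(missing) > 0) {
    abort(paste0("no control sample for layer(s): ",
                 paste(missing, collapse = ", ")),
          class = "mycoflux_domain_error")
  }
  refs <- dplyr::filter(refs, .data$element == !!element)
  controls |>
    dplyr::left_join(refs[, c("role", "af_ref")], by = "role") |>
    dplyr::mutate(
      excess = delta_to_atom_fraction(.data$delta_permil, !!element,
                                      standards) - .data$af_ref
    ) |>
    dplyr::group_by(layer = .data$role) |>
    dplyr::summarise(e0 = mean(.data$excess), e0_sd = sd(.data$excess),
                     n = dplyr::n(), .groups = "drop")
}

#' Sink excess atom fraction per labelled layer
#'
#' Mean excess atom fraction of the sink samples (pins or mushrooms) of
#' each labelling arm, mapped to the layer that arm labelled.
#'
#' @param samples Sample table covering the sink samples of all arms.
#' @param refs Reference tibble (`role`, `element`, `af_ref`).
#' @param arm_layers Tibble (`arm_id`, `layer`) naming which layer each arm
#'   labelled.
#' @param element Element; defaults to the single element present.
#' @param sink_roles Roles treated as sink tissue.
#' @param standards Registry from [iso_standards()].
#' @return A tibble (`layer`, `e_sink`, `e_sink_sd`, `n`).
#' @export
sink_layer_excess <- function(samples, refs, arm_layers,
                              element = NULL,
                              sink_roles = c("pin", "mushroom"),
                              standards = iso_standards()) {
  check_sample_table(samples)
  if (is.null(element)) {
    element <- unique(samples$element)
    if (length(element) != 1) {
      abort("sample table mixes elements; pass `element` explicitly",
            class = "mycoflux_domain_error")
    }
  }
  sink <- dplyr::filter(samples, .data$element == !!element,
                        .data$role %in% sink_roles)
  if (nrow(sink) == 0) {
    abort("no sink samples found", class = "mycoflux_domain_error")
  }
  refs <- dplyr::filter(refs, .data$element == !!element)
  sink |>
    dplyr::left_join(refs[, c("role", "af_ref")], by = "role") |>
    dplyr::mutate(
      excess = delta_to_atom_fraction(.data$delta_permil, !!element,
                                      standards) - .data$af_ref
    ) |>
    dplyr::inner_join(arm_layers, by = "arm_id") |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(e_sink = mean(.data$excess),
                     e_sink_sd = sd(.data$excess),
                     n = dplyr::n(), .groups = "drop")
}

#' Partition sink tracer uptake across labelled source layers
#'
#' Attributes the tracer enrichment of a sink (pin or mushroom) to the
#' substrate layers, comparing arms in which different layers were
#' labelled. Each arm's sink excess atom fraction is first normalised by
#' the initial enrichment its layer actually reached
#' ([layer_initial_excess()]), then the normalised ratios are expressed as
#' percentages:
#' \deqn{U_i = \frac{E_{sink,i} / e_{0,i}}
#'                  {\sum_j E_{sink,j} / e_{0,j}} \times 100}
#' Contributions are non-negative and sum to 100 by construction; negative
#' sink excesses are clipped to zero before normalisation (with a warning).
#' The underlying assumptions (equal sink biomass across arms, initial
#' enrichment stable over the chase, no cross-arm contamination) are the
#' caller's to ensure; per-element partitions must be computed
#' independently and never pooled.
#'
#' @param sink_excess Tibble (`layer`, `e_sink`) from [sink_layer_excess()]
#'   (extra columns are carried through).
#' @param e0 Tibble (`layer`, `e0`) from [layer_initial_excess()], or a
#'   tibble with a `dose_mg` column when `normalise = "dose"`.
#' @param normalise `"e0"` (default): divide by the measured initial excess
#'   atom fraction; `"dose"`: divide by the added tracer mass per layer
#'   (`dose_mg` column in `e0`).
#' @return A `tracer_partition` object whose `layers` tibble carries the
#'   raw normalised ratios and `contribution_pct` per layer.
#' @export
partition_sink <- function(sink_excess, e0, normalise = c("e0", "dose")) {
  normalise <- match.arg(normalise)
  denom_col <- if (normalise == "e0") "e0" else "dose_mg"
  if (!denom_col %in% names(e0)) {
    abort(paste0("`e0` lacks the ", denom_col, " column"),
          class = "mycoflux_config_error")
  }
  tab <- dplyr::inner_join(sink_excess, e0, by = "layer")
  if (nrow(tab) < nrow(sink_excess)) {
    abort("initial enrichment missing for one or more layers",
          class = "mycoflux_config_error")
  }
  denom <- tab[[denom_col]]
  if (any(!is.finite(denom) | denom <= 0)) {
    abort("initial layer enrichments must be > 0 for partitioning",
          class = "mycoflux_domain_error")
  }
  e_sink <- tab$e_sink
  if (any(e_sink < 0)) {
    warn(paste0(sum(e_sink < 0),
                " negative sink excess value(s) clipped to 0 before normalisation"))
    e_sink <- pmax(e_sink, 0)
  }
  ratio <- e_sink / denom
  if (sum(ratio) == 0) {
    abort("all normalised ratios are zero; partition undefined",
          class = "mycoflux_domain_error")
  }
  tab <- dplyr::mutate(tab, ratio = ratio,
                       contribution_pct = 100 * ratio / sum(ratio))
  structure(list(layers = tab, normalise = normalise),
            class = "tracer_partition")
}

#' @export
print.tracer_partition <- function(x, ...) {
  cat("<tracer_partition> normalised by:", x$normalise, "\n")
  print(x$layers, ...)
  invisible(x)
}

#' @rdname partition_sink
#' @param x A `tracer_partition` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tracer_partition <- function(x, ...) x$layers

#' @rdname partition_sink
#' @exportS3Method generics::glance
glance.tracer_partition <- function(x, ...) {
  tibble::tibble(
    n_layers = nrow(x$layers),
    top_layer = x$layers$layer[which.max(x$layers$contribution_pct)],
    top_contribution_pct = max(x$layers$contribution_pct),
    normalise = x$normalise
  )
}
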