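with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic tracer experiment
#'
#' One seeded generator configuration shared by the ring-plate, dish and
#' layered-bed simulators. The process menu mirrors the mechanisms the
#' axenic control experiments were designed to separate: uptake by living
#' mycelium, respiration of taken-up carbon, biased transport along the
#' colony with per-step decay, secretion back into the medium, ammonia
#' degassing and redistribution, and a passive leak between compartments in
#' fungus-free arms. It is one documented, testable allocation mechanism --
#' not a claim about the real transport mechanism.
#'
#' @param layout `"ring_plate"`, `"dish"` or `"bed"`.
#' @param labelled Labelled position: ring `"R1"`/`"R3"`/`"R5"`
#'   (ring_plate), `"middle"`/`"rim"` (dish); ignored for `"bed"` where
#'   every layer gets its own arm.
#' @param preset Arm preset: `"living"` (colony present, uptake active),
#'   `"no_cover"` (medium exposed, degassing only), `"membrane"` (passive
#'   diffusion across a membrane) or `"dead"` (dead mycelium: leak/wicking
#'   but no uptake).
#' @param uptake Fraction `u` of labelled-compartment tracer taken up by
#'   the mycelium (living preset).
#' @param respired Fraction `f` of taken-up carbon respired (applies to C
#'   only).
#' @param transported Fraction of the unrespired, taken-up tracer that
#'   moves out of the labelled position.
#' @param bias Transport bias `b` in `[-1, 1]`: moved tracer goes
#'   peripheral with probability `(1+b)/2`.
#' @param decay Per-ring-step retention factor `lambda` in `(0, 1]` of
#'   moved tracer.
#' @param secretion Fraction `s` of arriving tracer secreted back into that
#'   position's medium.
#' @param degas Fraction `g` of labelled-medium nitrogen tracer that
#'   degasses (as ammonia) and redistributes across compartments in
#'   proportion to their area (N only).
#' @param leak Passive leak fraction from the labelled medium into the
#'   other medium compartments (fungus-free arms).
#' @param sink_weights Named true sink-uptake weights per layer (bed only;
#'   must sum to <= 1). Defaults reflect a top-compost-dominated feeding
#'   pattern with casing contributing least.
#' @param sink_uptake_scale Scale factor linking `w_i * e0_i` to the sink
#'   excess atom fraction (bed only).
#' @param sigma_delta Named per-element measurement noise SD of the
#'   generated delta values, in per mil. Defaults are typical EA-IRMS
#'   precisions (0.2 for C, 0.3 for N, 2 for H).
#' @param replicates Replicates per compartment.
#' @param seed Integer seed; one generator drives all randomness of a run.
#' @param ... Overrides for layout internals (ring volumes, backgrounds,
#'   doses); see the package vignette.
#' @return A `sim_config` list.
#' @export
sim_config <- function(layout = c("ring_plate", "dish", "bed"),
                       labelled = NULL,
                       preset = c("living", "no_cover", "membrane", "dead"),
                       uptake = 1, respired = 0.5, transported = 0.4,
                       bias = 0.3, decay = 0.7, secretion = 0.2,
                       degas = 0, leak = 0,
                       sink_weights = c(casing = 0.15, compost_upper = 0.55,
                                        compost_lower = 0.30),
                       sink_uptake_scale = 0.2,
                       sigma_delta = c(C = 0.2, N = 0.3, H = 2),
                       replicates = 3, seed = 1, ...) {
  layout <- match.arg(layout)
  preset <- match.arg(preset)
  if (preset != "living") uptake <- 0
  frac <- c(uptake = uptake, respired = respired, transported = transported,
            secretion = secretion, degas = degas, leak = leak)
  if (any(frac < 0 | frac > 1)) {
    abort("process fractions must lie in [0, 1]",
          class = "mycoflux_config_error")
  }
  if (bias < -1 || bias > 1 || decay <= 0 || decay > 1) {
    abort("bias must lie in [-1, 1] and decay in (0, 1]",
          class = "mycoflux_config_error")
  }
  if (any(sink_weights < 0) || sum(sink_weights) > 1 + 1e-12) {
    abort("sink weights must be >= 0 and sum to at most 1",
          class = "mycoflux_config_error")
  }
  if (is.null(labelled)) {
    labelled <- if (layout == "dish") "middle" else "R3"
  }
  defaults <- list(
    # ring plate: 5 concentric MEA rings, equal volumes (configurable)
    ring_volume_ml = rep(10, 5),
    mea_solids_g_per_l = 50,
    # per-200 mL MEA doses scaled to the labelled ring volume
    ring_dose_mg_per_200ml = c(`13C-glucose` = 2950, `15N-NH4Cl` = 160),
    dish_dose_mg = c(`13C-glucose` = 5.5, `15N-NH4Cl` = 0.21),
    bed_dose_mg = c(`13C-glucose` = 30, `15N-NH4Cl` = 1.5),
    sink_role = "pin",
    # natural backgrounds; deltas uniform per element by default so the
    # material-matched references cancel exactly in mass-balance checks
    backgrounds = tibble::tribble(
      ~role,            ~dry_mass_g, ~pct_C, ~pct_N, ~delta_C, ~delta_N,
      "medium",         0.5,         40,     1.4,    -25,      2,
      "mycelium",       0.02,        45,     5,      -25,      2,
      "compost_middle", 4.0,         35,     2,      -25,      2,
      "compost_rim",    4.0,         35,     2,      -25,      2,
      "casing",         5.0,         20,     1,      -25,      2,
      "compost_upper",  7.9,         35,     2,      -25,      2,
      "compost_lower",  7.9,         35,     2,      -25,      2,
      "pin",            0.2,         40,     4,      -25,      2,
      "mushroom",       2.0,         40,     4,      -25,      2
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "mycoflux_config_error")
  }
  defaults[names(dots)] <- dots
  structure(
    c(list(layout = layout, labelled = labelled, preset = preset,
           uptake = uptake, respired = respired, transported = transported,
           bias = bias, decay = decay, secretion = secretion,
           degas = degas, leak = leak, sink_weights = sink_weights,
           sink_uptake_scale = sink_uptake_scale,
           sigma_delta = sigma_delta, replicates = replicates, seed = seed),
      defaults),
    class = "sim_config"
  )
}

sim_refs <- function(config, standards = iso_standards()) {
  bg <- config$backgrounds
  # element-wise conversion (reference ratio differs per element)
  purrr::map_dfr(c("C", "N"), function(el) {
    tibble::tibble(
      role = bg$role, element = el,
      af_ref = delta_to_atom_fraction(bg[[paste0("delta_", el)]], el,
                                      standards)
    )
  })
}

sim_background <- function(config, role, element) {
  bg <- config$backgrounds[config$backgrounds$role == role, ]
  list(dry_mass_g = bg$dry_mass_g,
       pct = bg[[paste0("pct_", element)]],
       delta = bg[[paste0("delta_", element)]])
}

# allocation of tracer atoms A (moles of labelled-element atoms carried by
# the dose) across an ordered layout; returns per-position medium and
# mycelium atom vectors plus loss terms, conserving A exactly
allocate_tracer <- function(A, src, n_pos, element, config) {
  med <- numeric(n_pos); myc <- numeric(n_pos)
  med[src] <- A
  degassed <- 0; respired <- 0
  if (element == "N" && config$degas > 0) {
    d <- config$degas * med[src]
    med[src] <- med[src] - d
    med <- med + d / n_pos           # equal-area redistribution
    degassed <- d
  }
  if (config$leak > 0 && n_pos > 1) {
    l <- config$leak * med[src]
    med[src] <- med[src] - l
    med[-src] <- med[-src] + l / (n_pos - 1)
  }
  if (config$uptake > 0) {
    up <- config$uptake * med[src]
    med[src] <- med[src] - up
    f <- if (element == "C") config$respired else 0
    respired <- f * up
    rem <- up - respired
    moved <- config$transported * rem
    myc[src] <- myc[src] + (rem - moved)
    if (moved > 0 && n_pos > 1) {
      peripheral <- which(seq_len(n_pos) > src)
      central <- which(seq_len(n_pos) < src)
      p_per <- (1 + config$bias) / 2
      share <- c(peripheral = p_per, central = 1 - p_per)
      if (length(peripheral) == 0) share <- c(peripheral = 0, central = 1)
      if (length(central) == 0) share <- c(peripheral = 1, central = 0)
      for (side in c("peripheral", "central")) {
        idx <- if (side == "peripheral") peripheral else central
        if (length(idx) == 0 || share[side] == 0) next
        wts <- config$decay^(abs(idx - src) - 1)
        wts <- wts / sum(wts)
        arriving <- moved * share[side] * wts
        med[idx] <- med[idx] + config$secretion * arriving
        myc[idx] <- myc[idx] + (1 - config$secretion) * arriving
      }
    }
  }
  list(medium = med, mycelium = myc, respired = respired,
       degassed = degassed)
}

# forward-mix `atoms` moles of tracer atoms (at purity af_tracer) into the
# compartment's natural element pool; the written dry mass grows with the
# pool so the analysis recovers the allocated atoms exactly
sample_rows <- function(config, arm_id, compartment_id, role, element,
                        atoms, af_tracer, standards) {
  bg <- sim_background(config, role, element)
  n_bg <- element_moles(bg$dry_mass_g, bg$pct, element)
  af_ref <- delta_to_atom_fraction(bg$delta, element, standards)
  n_tot <- n_bg + atoms
  af <- (af_ref * n_bg + af_tracer * atoms) / n_tot
  delta_true <- atom_fraction_to_delta(af, element, standards)
  sigma <- unname(config$sigma_delta[element])
  reps <- seq_len(config$replicates)
  tibble::tibble(
    sample_id = paste(arm_id, compartment_id, element, reps, sep = "-"),
    arm_id = arm_id,
    compartment_id = compartment_id,
    role = role,
    element = element,
    dry_mass_g = bg$dry_mass_g * n_tot / n_bg,
    element_pct = bg$pct,
    delta_permil = delta_true + rnorm(length(reps), 0, sigma),
    replicate = reps
  )
}

# moles of labelled-element atoms carried by a dose
dose_atoms <- function(amount_mg, compound, compounds = tracer_compounds()) {
  cmp <- lookup_compound(compound, compounds)
  amount_mg / 1000 / cmp$molar_mass * cmp$labelled_atoms
}

ring_events <- function(config, arm_id, labelled_compartment) {
  dose <- config$ring_dose_mg_per_200ml *
    config$ring_volume_ml[1] / 200
  tibble::tibble(
    arm_id = arm_id,
    compartment_id = labelled_compartment,
    compound = names(dose),
    amount_mg = unname(dose)
  )
}

#' Simulate a ring-plate translocation experiment
#'
#' Generates the bulk-IRMS sample table of one ring-plate arm (five
#' concentric medium rings, mycelium sampled separately in the living
#' preset) with known ground truth. Tracer excess is allocated
#' deterministically by the process model of [sim_config()], the allocated
#' excess is forward-mixed into each compartment's element pool to produce
#' delta values, and Gaussian measurement noise is added per replicate.
#' Pre-noise mass balance is exact: added excess equals the sum over
#' compartments plus respiration.
#'
#' @param config A [sim_config()] with `layout = "ring_plate"`.
#' @param standards Registry from [iso_standards()].
#' @return A list: `samples` (sample table for C and N), `events`
#'   (labelling plan), `refs` (natural-abundance references), `truth`
#'   (per-compartment true excess moles and loss terms), `config`.
#' @export
simulate_ring_plate <- function(config = sim_config("ring_plate"),
                                standards = iso_standards()) {
  stopifnot(inherits(config, "sim_config"), config$layout == "ring_plate")
  with_sim_seed(config$seed, {
    n_pos <- length(config$ring_volume_ml)
    src <- match(config$labelled, paste0("R", seq_len(n_pos)))
    if (is.na(src)) {
      abort("labelled ring must be one of R1..R5",
            class = "mycoflux_config_error")
    }
    arm_id <- paste0(config$preset, "_", config$labelled)
    labelled_comp <- paste0(config$labelled, "_medium")
    events <- ring_events(config, arm_id, labelled_comp)
    refs <- sim_refs(config, standards)
    compounds <- tracer_compounds()

    out <- purrr::map(c("C", "N"), function(el) {
      ev <- events[compounds$element[match(events$compound,
                                           compounds$name)] == el, ]
      af_ref <- refs$af_ref[refs$role == "medium" & refs$element == el]
      af_tracer <- lookup_compound(ev$compound, compounds)$af_tracer
      atoms_added <- dose_atoms(ev$amount_mg, ev$compound, compounds)
      alloc <- allocate_tracer(atoms_added, src, n_pos, el, config)
      pos <- paste0("R", seq_len(n_pos))
      truth <- tibble::tibble(
        element = el,
        compartment_id = c(paste0(pos, "_medium"),
                           paste0(pos, "_mycelium")),
        role = rep(c("medium", "mycelium"), each = n_pos),
        tracer_atoms_mol = c(alloc$medium, alloc$mycelium)
      ) |>
        dplyr::left_join(refs[refs$element == el, c("role", "af_ref")],
                         by = "role") |>
        dplyr::mutate(excess_mol = .data$tracer_atoms_mol *
                        (af_tracer - .data$af_ref))
      sampled <- if (config$preset == "living") truth else
        truth[truth$role == "medium", ]
      samples <- purrr::pmap_dfr(
        sampled[, c("compartment_id", "role", "tracer_atoms_mol")],
        function(compartment_id, role, tracer_atoms_mol) {
          sample_rows(config, arm_id, compartment_id, role, el,
                      tracer_atoms_mol, af_tracer, standards)
        }
      )
      list(truth = dplyr::mutate(
             truth,
             added_excess_mol = atoms_added * (af_tracer - af_ref),
             respired_mol = alloc$respired * (af_tracer - af_ref),
             degassed_mol = alloc$degassed * (af_tracer - af_ref)),
           samples = samples)
    })
    list(samples = dplyr::bind_rows(purrr::map(out, "samples")),
         events = events,
         refs = refs,
         truth = dplyr::bind_rows(purrr::map(out, "truth")),
         config = config)
  })
}

#' Simulate a compost-dish experiment
#'
#' Two compost zones (middle, rim) in a round dish, one labelled. The same
#' process model as the ring plate applies over the two-position layout;
#' mycelium is not separable from compost, so only bulk compost samples are
#' produced.
#'
#' @inheritParams simulate_ring_plate
#' @param config A [sim_config()] with `layout = "dish"`.
#' @return As [simulate_ring_plate()].
#' @export
simulate_dish <- function(config = sim_config("dish"),
                          standards = iso_standards()) {
  stopifnot(inherits(config, "sim_config"), config$layout == "dish")
  with_sim_seed(config$seed, {
    zones <- c("middle", "rim")
    roles <- c("compost_middle", "compost_rim")
    src <- match(config$labelled, zones)
    if (is.na(src)) {
      abort("labelled zone must be 'middle' or 'rim'",
            class = "mycoflux_config_error")
    }
    arm_id <- paste0(config$preset, "_", config$labelled)
    labelled_comp <- paste0(zones[src], "_compost")
    events <- tibble::tibble(
      arm_id = arm_id, compartment_id = labelled_comp,
      compound = names(config$dish_dose_mg),
      amount_mg = unname(config$dish_dose_mg)
    )
    refs <- sim_refs(config, standards)
    compounds <- tracer_compounds()
    out <- purrr::map(c("C", "N"), function(el) {
      ev <- events[compounds$element[match(events$compound,
                                           compounds$name)] == el, ]
      af_ref <- refs$af_ref[refs$role == roles[src] & refs$element == el]
      af_tracer <- lookup_compound(ev$compound, compounds)$af_tracer
      atoms_added <- dose_atoms(ev$amount_mg, ev$compound, compounds)
      alloc <- allocate_tracer(atoms_added, src, 2, el, config)
      # compost holds both substrate and mycelium signal in one bulk sample
      atoms <- alloc$medium + alloc$mycelium
      truth <- tibble::tibble(
        element = el,
        compartment_id = paste0(zones, "_compost"),
        role = roles,
        tracer_atoms_mol = atoms
      ) |>
        dplyr::left_join(refs[refs$element == el, c("role", "af_ref")],
                         by = "role") |>
        dplyr::mutate(excess_mol = .data$tracer_atoms_mol *
                        (af_tracer - .data$af_ref))
      samples <- purrr::pmap_dfr(
        truth[, c("compartment_id", "role", "tracer_atoms_mol")],
        function(compartment_id, role, tracer_atoms_mol) {
          sample_rows(config, arm_id, compartment_id, role, el,
                      tracer_atoms_mol, af_tracer, standards)
        }
      )
      list(truth = dplyr::mutate(
             truth,
             added_excess_mol = atoms_added * (af_tracer - af_ref),
             respired_mol = alloc$respired * (af_tracer - af_ref),
             degassed_mol = alloc$degassed * (af_tracer - af_ref)),
           samples = samples)
    })
    list(samples = dplyr::bind_rows(purrr::map(out, "samples")),
         events = events, refs = refs,
         truth = dplyr::bind_rows(purrr::map(out, "truth")),
         config = config)
  })
}

#' Simulate a layered mushroom-bed experiment
#'
#' Three substrate layers (casing, upper compost, lower compost) plus a
#' sink (pin or mushroom). One arm per layer labels that layer only; a
#' dedicated control arm labels all layers simultaneously and is sampled
#' shortly after labelling to measure the initial enrichment `e0` each
#' layer actually reached. The sink's excess atom fraction in arm `i` is
#' `sink_uptake_scale * w_i * e0_i`, so [partition_sink()] recovers the
#' true uptake weights `w` exactly in the noiseless limit.
#'
#' @inheritParams simulate_ring_plate
#' @param config A [sim_config()] with `layout = "bed"`.
#' @return A list: `samples` (layer + sink samples of all labelling arms),
#'   `control_samples` (the all-layer 3 h control arm), `events`,
#'   `arm_layers` (arm to labelled-layer map), `refs`, `truth` (true
#'   weights, per-layer `e0`, sink contributions), `config`.
#' @export
simulate_bed <- function(config = sim_config("bed"),
                         standards = iso_standards()) {
  stopifnot(inherits(config, "sim_config"), config$layout == "bed")
  with_sim_seed(config$seed, {
    layers <- c("casing", "compost_upper", "compost_lower")
    w <- config$sink_weights[layers]
    if (any(is.na(w))) {
      abort("sink_weights must name casing, compost_upper, compost_lower",
            class = "mycoflux_config_error")
    }
    refs <- sim_refs(config, standards)
    compounds <- tracer_compounds()
    sink_role <- config$sink_role
    dose <- config$bed_dose_mg

    arm_ids <- paste0("label_", layers)
    events <- purrr::map_dfr(seq_along(layers), function(i) {
      tibble::tibble(arm_id = arm_ids[i], compartment_id = layers[i],
                     compound = names(dose), amount_mg = unname(dose))
    })
    arm_layers <- tibble::tibble(arm_id = arm_ids, layer = layers)

    per_element <- purrr::map(c("C", "N"), function(el) {
      cmp_name <- names(dose)[compounds$element[match(names(dose),
                                                      compounds$name)] == el]
      af_tracer <- lookup_compound(cmp_name, compounds)$af_tracer
      af_ref <- stats::setNames(
        refs$af_ref[refs$element == el][match(layers,
                                              refs$role[refs$element == el])],
        layers)
      n_layer <- vapply(layers, function(r) {
        bg <- sim_background(config, r, el)
        element_moles(bg$dry_mass_g, bg$pct, el)
      }, numeric(1))
      atoms_layer <- rep(dose_atoms(dose[[cmp_name]], cmp_name, compounds),
                         length(layers))
      names(atoms_layer) <- layers
      # true initial excess atom fraction reached in each labelled layer
      e0 <- atoms_layer * (af_tracer - af_ref) / (n_layer + atoms_layer)
      sink_bg <- sim_background(config, sink_role, el)
      n_sink <- element_moles(sink_bg$dry_mass_g, sink_bg$pct, el)
      af_ref_sink <- refs$af_ref[refs$element == el &
                                   refs$role == sink_role]
      # sink tracer atoms chosen so the sink's measured excess atom
      # fraction is exactly sink_uptake_scale * w_i * e0_i
      e_sink <- config$sink_uptake_scale * w * e0
      atoms_sink <- e_sink * n_sink / (af_tracer - af_ref_sink - e_sink)

      # labelling arms: labelled layer keeps the rest; sink takes its share
      arm_samples <- purrr::map_dfr(seq_along(layers), function(i) {
        atoms <- stats::setNames(numeric(3), layers)
        atoms[layers[i]] <- atoms_layer[i] - atoms_sink[i]
        rows <- purrr::map_dfr(layers, function(r) {
          sample_rows(config, arm_ids[i], r, r, el, atoms[r], af_tracer,
                      standards)
        })
        dplyr::bind_rows(
          rows,
          sample_rows(config, arm_ids[i], sink_role, sink_role, el,
                      atoms_sink[i], af_tracer, standards)
        )
      })
      # all-layer control arm sampled 3 h after labelling: full dose present
      control_samples <- purrr::map_dfr(layers, function(r) {
        sample_rows(config, "control_all_layers", r, r, el,
                    atoms_layer[[r]], af_tracer, standards)
      })
      truth <- tibble::tibble(
        element = el, layer = layers,
        added_excess_mol = unname(atoms_layer * (af_tracer - af_ref)),
        e0 = unname(e0),
        sink_excess_af = unname(e_sink),
        sink_excess_mol = unname(atoms_sink * (af_tracer - af_ref_sink)),
        weight = unname(w),
        contribution_pct = 100 * unname(w) / sum(w)
      )
      list(samples = arm_samples, control = control_samples, truth = truth)
    })

    list(samples = dplyr::bind_rows(purrr::map(per_element, "samples")),
         control_samples = dplyr::bind_rows(purrr::map(per_element,
                                                       "control")),
         events = events, arm_layers = arm_layers, refs = refs,
         truth = dplyr::bind_rows(purrr::map(per_element, "truth")),
         config = config)
  })
}

#' Simulate nanoSIMS ion-count images
#'
#' Lays cells out as square ROIs on a grid and draws per-pixel, per-plane
#' Poisson counts for each secondary-ion species. The expected dimer count
#' of a cell follows its true delta through the 0.5-corrected ratio:
#' `E[12C13C] = 2 * r13 * E[12C2]` with `r13 = r13_control *
#' (1 + delta13C/1000)`, and `E[12C15N] = r15 * E[12C14N]` likewise, so the
#' analysis pipeline should recover each group's deltas within
#' Poisson-propagated error.
#'
#' @param groups Tibble with one row per cell group: `group`, `n_cells`,
#'   `delta13C`, `delta15N`, `morphotype`. A group named `"control"` is
#'   expected at natural composition (delta = 0).
#' @param mean_counts Named expected total (all-plane) counts per pixel for
#'   the major species.
#' @param r13_control,r15_control Control-cell isotope ratios on the
#'   instrument's scale.
#' @param cell_px Cell (ROI) edge length in pixels.
#' @param planes Number of acquisition planes.
#' @param seed Integer seed.
#' @return A list: `images` (named list of plane lists per species),
#'   `mask`, `morphotypes`, `rois` (per-ROI truth: group, true deltas,
#'   control flag), `control_rois`, `config`-like settings.
#' @export
simulate_nanosims <- function(groups = tibble::tibble(
                                group = c("control", "enriched"),
                                n_cells = c(20L, 20L),
                                delta13C = c(0, 60),
                                delta15N = c(0, 800),
                                morphotype = c("void", "membrane_rich")),
                              mean_counts = c(`16O` = 400, `12C2` = 400,
                                              `12C14N` = 400, `31P` = 40,
                                              `32S` = 20),
                              r13_control = 0.011,
                              r15_control = 0.0037,
                              cell_px = 6, planes = 3, seed = 1) {
  with_sim_seed(seed, {
    n_total <- sum(groups$n_cells)
    per_row <- ceiling(sqrt(n_total))
    pitch <- cell_px + 2
    side <- per_row * pitch + 2
    mask <- matrix(0L, side, side)
    rois <- tibble::tibble(
      roi_id = seq_len(n_total),
      group = rep(groups$group, groups$n_cells),
      delta13C = rep(groups$delta13C, groups$n_cells),
      delta15N = rep(groups$delta15N, groups$n_cells),
      morphotype = rep(groups$morphotype, groups$n_cells)
    )
    for (k in seq_len(n_total)) {
      r0 <- 2 + ((k - 1) %/% per_row) * pitch
      c0 <- 2 + ((k - 1) %% per_row) * pitch
      mask[r0:(r0 + cell_px - 1), c0:(c0 + cell_px - 1)] <- k
    }
    lam_cell <- function(species_total) species_total / planes
    # per-pixel expected counts per plane, per species, depending on ROI
    r13 <- r13_control * (1 + rois$delta13C / 1000)
    r15 <- r15_control * (1 + rois$delta15N / 1000)
    lam_map <- function(base, per_roi = NULL) {
      m <- matrix(base * 0.05, side, side)   # faint background
      scale <- if (is.null(per_roi)) rep(1, n_total) else per_roi
      for (k in seq_len(n_total)) m[mask == k] <- base * scale[k]
      m / planes
    }
    lambdas <- list(
      `16O`    = lam_map(mean_counts[["16O"]]),
      `12C2`   = lam_map(mean_counts[["12C2"]]),
      `12C13C` = lam_map(mean_counts[["12C2"]], 2 * r13),
      `12C14N` = lam_map(mean_counts[["12C14N"]]),
      `12C15N` = lam_map(mean_counts[["12C14N"]], r15),
      `31P`    = lam_map(mean_counts[["31P"]]),
      `32S`    = lam_map(mean_counts[["32S"]])
    )
    images <- purrr::map(lambdas, function(lam) {
      purrr::map(seq_len(planes), function(p) {
        matrix(rpois(side * side, lam), side, side)
      })
    })
    list(images = images, mask = mask,
         morphotypes = rois[, c("roi_id", "morphotype")],
         rois = rois,
         control_rois = rois$roi_id[rois$group == "control"],
         r13_control = r13_control, r15_control = r15_control,
         planes = planes, seed = seed)
  })
}
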