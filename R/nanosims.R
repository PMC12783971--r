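ION_SPECIES <- c("16O", "12C2", "12C13C", "12C14N", "12C15N", "31P", "32S")

#' Accumulate aligned nanoSIMS planes
#'
#' Element-wise sum of a stack of pre-aligned 2-D ion-count planes for one
#' secondary-ion species. Plane alignment is assumed done upstream (by the
#' acquisition/processing software); this is only the accumulation step.
#'
#' @param planes A list of equally shaped non-negative count matrices, a
#'   3-D array (row, col, plane), or a single matrix.
#' @return The total-count matrix.
#' @export
accumulate_planes <- function(planes) {
  if (is.matrix(planes)) return(planes)
  if (is.array(planes) && length(dim(planes)) == 3) {
    planes <- lapply(seq_len(dim(planes)[3]), function(k) planes[, , k])
  }
  if (!is.list(planes) || length(planes) == 0) {
    abort("need at least one count plane", class = "mycoflux_domain_error")
  }
  shape <- dim(planes[[1]])
  ok <- vapply(planes, function(p) is.matrix(p) && identical(dim(p), shape),
               logical(1))
  if (!all(ok)) {
    abort("all planes must be matrices of identical shape",
          class = "mycoflux_domain_error")
  }
  if (any(vapply(planes, function(p) any(p < 0), logical(1)))) {
    abort("ion counts must be non-negative", class = "mycoflux_domain_error")
  }
  Reduce(`+`, planes)
}

check_image_set <- function(images, mask = NULL) {
  if (is.null(names(images)) || any(names(images) == "")) {
    abort("ion images must be a named list (species names)",
          class = "mycoflux_domain_error")
  }
  images <- lapply(images, accumulate_planes)
  shape <- dim(images[[1]])
  ok <- vapply(images, function(m) identical(dim(m), shape), logical(1))
  if (!all(ok)) {
    abort("all species images must share one shape",
          class = "mycoflux_domain_error")
  }
  if (!is.null(mask) && !identical(dim(mask), shape)) {
    abort("ROI mask shape differs from the ion images",
          class = "mycoflux_domain_error")
  }
  images
}

#' Total ion counts per region of interest
#'
#' Sums the accumulated counts of every species over the pixels of each
#' labelled ROI (one hyphal cell cross-section per ROI).
#'
#' @param images Named list of count matrices (or plane stacks), one per
#'   species.
#' @param mask Integer ROI label matrix of the same shape; 0 is background.
#' @param roi_id Optional ROI id(s) to restrict to; unknown ids error.
#' @return A tibble with `roi_id`, `n_pixels` and one count column per
#'   species.
#' @export
roi_ion_totals <- function(images, mask, roi_id = NULL) {
  images <- check_image_set(images, mask)
  ids <- sort(unique(as.integer(mask[mask > 0])))
  if (!is.null(roi_id)) {
    unknown <- setdiff(roi_id, ids)
    if (length(unknown) > 0) {
      abort(paste0("ROI id(s) not present in the mask: ",
                   paste(unknown, collapse = ", ")),
            class = "mycoflux_domain_error")
    }
    ids <- roi_id
  }
  inside <- mask > 0
  grp <- as.integer(mask[inside])
  totals <- purrr::map(images, function(m) {
    s <- rowsum(as.numeric(m[inside]), grp)
    stats::setNames(s[, 1], rownames(s))
  })
  out <- tibble::tibble(
    roi_id = ids,
    n_pixels = as.integer(table(factor(grp, levels = ids)))
  )
  for (sp in names(totals)) out[[sp]] <- unname(totals[[sp]][as.character(ids)])
  out
}

#' Single-cell isotope ratios with the carbon-dimer correction
#'
#' Carbon is imaged as the C2- molecular ion, so the heavy-isotope dimer
#' 12C13C- carries one heavy atom per two carbons and the atomic ratio is
#' half the count ratio: `ratio_13C = 0.5 * n(12C13C) / n(12C2)`. Nitrogen
#' is imaged as CN- with one nitrogen per ion:
#' `ratio_15N = n(12C15N) / n(12C14N)`. Cells with a zero denominator are
#' dropped with a warning.
#'
#' @param totals Tibble from [roi_ion_totals()] containing the `12C2`,
#'   `12C13C`, `12C14N` and `12C15N` columns.
#' @return `totals` with `ratio_13C` and `ratio_15N` columns appended.
#' @export
roi_isotope_ratios <- function(totals) {
  needed <- c("12C2", "12C13C", "12C14N", "12C15N")
  missing <- setdiff(needed, names(totals))
  if (length(missing) > 0) {
    abort(paste0("missing ion count column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mycoflux_domain_error")
  }
  bad <- totals[["12C2"]] <= 0 | totals[["12C14N"]] <= 0
  if (all(bad)) {
    abort("all cells have zero denominator counts; ratios undefined",
          class = "mycoflux_domain_error")
  }
  if (any(bad)) {
    warn(paste0(sum(bad), " cell(s) with zero denominator counts excluded"))
    totals <- totals[!bad, ]
  }
  dplyr::mutate(
    totals,
    ratio_13C = 0.5 * .data[["12C13C"]] / .data[["12C2"]],
    ratio_15N = .data[["12C15N"]] / .data[["12C14N"]]
  )
}

#' Delta values relative to control cells
#'
#' Expresses a cell's isotope ratio in delta notation relative to the mean
#' ratio of designated control cells of natural isotopic composition:
#' `delta = (ratio / mean(control_ratios) - 1) * 1000`. By construction the
#' control cells' own deltas average exactly zero.
#'
#' @param ratio Cell ratio(s).
#' @param control_ratios Ratios of at least two control cells (or, for the
#'   pooled-counts convention, a length-2+ vector whose mean is the pooled
#'   ratio).
#' @return Delta values in per mil (vectorised over `ratio`).
#' @export
control_relative_delta <- function(ratio, control_ratios) {
  if (length(control_ratios) < 2 || any(!is.finite(control_ratios))) {
    abort("need at least two finite control ratios",
          class = "mycoflux_domain_error")
  }
  m <- mean(control_ratios)
  if (m <= 0) {
    abort("control mean ratio must be > 0", class = "mycoflux_domain_error")
  }
  (ratio / m - 1) * 1000
}

#' Classify cells as significantly enriched
#'
#' Boundaries are the control mean plus/minus twice the control sample SD
#' (n-1 denominator). A cell is enriched when its delta lies strictly above
#' the upper boundary (one-sided: only points above the upper line count as
#' significant; the symmetric lower boundary is reported but not used for
#' flagging, and ties at the boundary are not enriched).
#'
#' @param deltas Per-cell delta values (per mil).
#' @param control_deltas Delta values of at least three control cells with
#'   nonzero spread.
#' @return A list with `enriched` (logical per cell), `lower`, `upper` and
#'   `centre` (control mean).
#' @export
classify_enriched <- function(deltas, control_deltas) {
  if (length(control_deltas) < 3) {
    abort("need at least three control cells", class = "mycoflux_domain_error")
  }
  s <- sd(control_deltas)
  if (!is.finite(s) || s == 0) {
    abort("control deltas have zero spread; boundaries undefined",
          class = "mycoflux_domain_error")
  }
  m <- mean(control_deltas)
  list(enriched = deltas > m + 2 * s,
       lower = m - 2 * s, upper = m + 2 * s, centre = m)
}

#' Pearson correlation between carbon and nitrogen enrichment
#'
#' @param delta13C,delta15N Paired per-cell delta values (typically of the
#'   enriched cells only).
#' @return A tibble with `r`, `p` (two-sided) and `n`.
#' @export
enrichment_correlation <- function(delta13C, delta15N) {
  if (length(delta13C) != length(delta15N) || length(delta13C) < 3) {
    abort("need >= 3 paired cells", class = "mycoflux_domain_error")
  }
  if (sd(delta13C) == 0 || sd(delta15N) == 0) {
    abort("zero variance in one axis; correlation undefined",
          class = "mycoflux_domain_error")
  }
  ct <- cor.test(delta13C, delta15N, method = "pearson",
                 alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(delta13C))
}

#' Summary statistics per cell morphotype
#'
#' @param cells Tibble with `morphotype`, `delta13C`, `delta15N` and the
#'   `enriched_13C`/`enriched_15N` flags (as produced by
#'   [nanosims_cells()]).
#' @return One row per morphotype present: n, mean and SD of each delta,
#'   and enriched counts.
#' @export
morphotype_summary <- function(cells) {
  if (any(is.na(cells$morphotype))) {
    abort("every cell needs a morphotype", class = "mycoflux_domain_error")
  }
  cells |>
    dplyr::group_by(.data$morphotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delta13C = mean(.data$delta13C),
      sd_delta13C = sd(.data$delta13C),
      mean_delta15N = mean(.data$delta15N),
      sd_delta15N = sd(.data$delta15N),
      n_enriched_13C = sum(.data$enriched_13C),
      n_enriched_15N = sum(.data$enriched_15N),
      .groups = "drop"
    )
}

#' Single-cell nanoSIMS pipeline
#'
#' Accumulates planes, sums counts per ROI, computes dimer-corrected
#' isotope ratios, expresses them as deltas relative to the designated
#' control cells and flags significant enrichment at the +2 SD boundary.
#'
#' @param images Named list of count matrices or plane stacks per species.
#' @param mask Integer ROI label matrix.
#' @param morphotypes Tibble (`roi_id`, `morphotype`); optional.
#' @param control Either ROI ids within `mask` designating the control
#'   cells (from an unlabelled sample imaged in the same session), or a
#'   tibble of control cells carrying `ratio_13C` and `ratio_15N` columns.
#' @param control_method `"cell_mean"` (default): the control reference
#'   ratio is the mean of per-cell control ratios; `"pooled"`: it is the
#'   ratio of total counts pooled over all control ROIs (only available
#'   when `control` is a set of ROI ids).
#' @return A `nanosims_cells` object: `cells` tibble (counts, ratios,
#'   deltas, flags, morphotype, `is_control`) and `boundaries` tibble.
#' @export
nanosims_cells <- function(images, mask, morphotypes = NULL, control,
                           control_method = c("cell_mean", "pooled")) {
  control_method <- match.arg(control_method)
  cells <- roi_isotope_ratios(roi_ion_totals(images, mask))

  if (is.data.frame(control)) {
    if (control_method == "pooled") {
      abort("pooled control ratios need control ROI ids, not a table",
            class = "mycoflux_config_error")
    }
    ctl_r13 <- control$ratio_13C
    ctl_r15 <- control$ratio_15N
    cells$is_control <- FALSE
  } else {
    if (!all(control %in% cells$roi_id)) {
      abort("control ROI id(s) missing from the mask",
            class = "mycoflux_domain_error")
    }
    cells$is_control <- cells$roi_id %in% control
    ctl <- cells[cells$is_control, ]
    if (control_method == "pooled") {
      ctl_r13 <- rep(0.5 * sum(ctl[["12C13C"]]) / sum(ctl[["12C2"]]), 2)
      ctl_r15 <- rep(sum(ctl[["12C15N"]]) / sum(ctl[["12C14N"]]), 2)
    } else {
      ctl_r13 <- ctl$ratio_13C
      ctl_r15 <- ctl$ratio_15N
    }
  }

  cells$delta13C <- control_relative_delta(cells$ratio_13C, ctl_r13)
  cells$delta15N <- control_relative_delta(cells$ratio_15N, ctl_r15)
  ctl_d13 <- control_relative_delta(ctl_r13, ctl_r13)
  ctl_d15 <- control_relative_delta(ctl_r15, ctl_r15)
  if (control_method == "pooled" && !is.data.frame(control)) {
    # per-cell control deltas still define the spread for the boundaries
    ctl <- cells[cells$is_control, ]
    ctl_d13 <- cells$delta13C[cells$is_control]
    ctl_d15 <- cells$delta15N[cells$is_control]
  }
  cls13 <- classify_enriched(cells$delta13C, ctl_d13)
  cls15 <- classify_enriched(cells$delta15N, ctl_d15)
  cells$enriched_13C <- cls13$enriched
  cells$enriched_15N <- cls15$enriched
  if (!is.null(morphotypes)) {
    cells <- dplyr::left_join(cells, morphotypes, by = "roi_id")
  } else {
    cells$morphotype <- "other"
  }
  boundaries <- tibble::tibble(
    isotope = c("13C", "15N"),
    lower = c(cls13$lower, cls15$lower),
    centre = c(cls13$centre, cls15$centre),
    upper = c(cls13$upper, cls15$upper)
  )
  structure(list(cells = cells, boundaries = boundaries,
                 control_method = control_method),
            class = "nanosims_cells")
}

#' @export
print.nanosims_cells <- function(x, ...) {
  cat("<nanosims_cells>", nrow(x$cells), "cells | control:",
      x$control_method, "\n")
  print(x$boundaries, ...)
  print(x$cells, ...)
  invisible(x)
}

#' @rdname nanosims_cells
#' @param x A `nanosims_cells` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nanosims_cells <- function(x, ...) x$cells

#' @rdname nanosims_cells
#' @exportS3Method generics::glance
glance.nanosims_cells <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_control = sum(x$cells$is_control),
    n_enriched_13C = sum(x$cells$enriched_13C),
    n_enriched_15N = sum(x$cells$enriched_15N),
    upper_13C = x$boundaries$upper[x$boundaries$isotope == "13C"],
    upper_15N = x$boundaries$upper[x$boundaries$isotope == "15N"],
    control_method = x$control_method
  )
}
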