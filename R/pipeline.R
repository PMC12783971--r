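#' Compare groups the way tracer studies report them
#'
#' Routine inferential statistics for per-compartment comparisons:
#' independent two-sample Student's t-test, one-way ANOVA with Tukey HSD,
#' or one-way ANOVA with Fisher's LSD post hoc (pairwise t-tests on the
#' pooled residual variance, unadjusted). Significance is flagged at
#' p < 0.05. These are reporting plumbing delegated to base R fits; no
#' additional multiple-testing layer is added.
#'
#' @param data Data frame with the value and grouping columns.
#' @param value,group Column names (strings) of the response and the group.
#' @param design `"ttest"`, `"anova_tukey"` or `"anova_lsd"`.
#' @return A tibble with one row per comparison (plus, for the ANOVA
#'   designs, a leading `(anova)` row carrying the overall F): `comparison`,
#'   `estimate` (mean difference), `statistic`, `p`, `significant`.
#' @export
compare_groups <- function(data, value, group,
                           design = c("ttest", "anova_tukey", "anova_lsd")) {
  design <- match.arg(design)
  y <- data[[value]]
  g <- factor(data[[group]])
  if (any(is.na(y)) || any(is.na(g))) {
    abort("missing values in response or group",
          class = "mycoflux_domain_error")
  }
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("need >= 2 groups with >= 2 observations each",
          class = "mycoflux_domain_error")
  }
  if (design == "ttest") {
    if (length(counts) != 2) {
      abort("the t-test design needs exactly 2 groups",
            class = "mycoflux_domain_error")
    }
    tt <- t.test(y ~ g, var.equal = TRUE)
    out <- tibble::tibble(
      comparison = paste(levels(g)[1], "-", levels(g)[2]),
      estimate = unname(diff(rev(tt$estimate))),
      statistic = unname(tt$statistic),
      p = tt$p.value
    )
  } else {
    fit <- aov(y ~ g)
    an <- summary(fit)[[1]]
    overall <- tibble::tibble(
      comparison = "(anova)", estimate = NA_real_,
      statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1]
    )
    mse <- an[["Mean Sq"]][2]
    df_res <- an[["Df"]][2]
    means <- tapply(y, g, mean)
    pairs <- utils::combn(levels(g), 2)
    pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      diff <- means[[b]] - means[[a]]
      se <- sqrt(mse * (1 / counts[[a]] + 1 / counts[[b]]))
      tstat <- diff / se
      p <- if (design == "anova_tukey") {
        ptukey(abs(tstat) * sqrt(2), nmeans = length(counts),
               df = df_res, lower.tail = FALSE)
      } else {
        2 * pt(abs(tstat), df = df_res, lower.tail = FALSE)
      }
      tibble::tibble(comparison = paste(b, "-", a), estimate = diff,
                     statistic = tstat, p = p)
    })
    out <- dplyr::bind_rows(overall, pw)
  }
  dplyr::mutate(out, significant = .data$p < 0.05)
}

#' Run the full tracer-accounting pipeline
#'
#' Reads a sample table and labelling plan, builds natural-abundance
#' references from a control table (or falls back to the international
#' standards with a warning), computes percent-of-added recovery per
#' element, optionally partitions sink enrichment across layers, writes the
#' result tables and a run log recording every design-decision flag, and
#' returns the result objects.
#'
#' @param samples Path to the sample table, or a sample tibble.
#' @param plan Path to the labelling-plan YAML, or a list as returned by
#'   [read_labelling_plan()].
#' @param out_dir Output directory (created if missing).
#' @param controls Optional unlabelled-control sample table (path or
#'   tibble) for [natural_refs()].
#' @param bed_control Optional all-layer control-arm table (path or tibble)
#'   enabling source partitioning.
#' @param arm_layers Optional tibble (`arm_id`, `layer`) mapping labelling
#'   arms to layers (required with `bed_control`).
#' @param standards_path Optional standards registry YAML.
#' @param denominator,normalise Convention flags passed to
#'   [percent_recovery()] and [partition_sink()].
#' @param seed Seed recorded in the log (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with `recovery` (per element), `partition`
#'   (per element or NULL) and the paths written.
#' @export
run_pipeline <- function(samples, plan, out_dir,
                         controls = NULL, bed_control = NULL,
                         arm_layers = NULL, standards_path = NULL,
                         denominator = "excess", normalise = "e0",
                         seed = 1) {
  standards <- iso_standards(standards_path)
  if (is.character(samples)) samples <- read_sample_table(samples)
  check_sample_table(samples)
  if (is.character(plan)) plan <- read_labelling_plan(plan)
  if (is.character(controls)) controls <- read_sample_table(controls)
  if (is.character(bed_control)) bed_control <- read_sample_table(bed_control)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  elements <- unique(samples$element)
  refs <- if (!is.null(controls)) {
    natural_refs(controls, standards)
  } else {
    purrr::map_dfr(elements, function(el) {
      standard_refs(unique(samples$role), el, standards)
    })
  }

  written <- character(0)
  recovery <- purrr::map(stats::setNames(elements, elements), function(el) {
    res <- percent_recovery(samples, plan$events, refs, element = el,
                            standards = standards,
                            compounds = plan$compounds,
                            denominator = denominator)
    p <- file.path(out_dir, paste0("recovery_", el, ".csv"))
    readr::write_csv(tidy(res), p)
    written <<- c(written, p)
    res
  })

  partition <- NULL
  if (!is.null(bed_control)) {
    if (is.null(arm_layers)) {
      abort("partitioning needs `arm_layers` (arm to labelled-layer map)",
            class = "mycoflux_config_error")
    }
    partition <- purrr::map(stats::setNames(elements, elements),
                            function(el) {
      e0 <- layer_initial_excess(bed_control, refs,
                                 layers = arm_layers$layer, element = el,
                                 standards = standards)
      es <- sink_layer_excess(samples, refs, arm_layers, element = el,
                              standards = standards)
      res <- partition_sink(es, e0, normalise = normalise)
      p <- file.path(out_dir, paste0("partition_", el, ".csv"))
      readr::write_csv(tidy(res), p)
      written <<- c(written, p)
      res
    })
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("mycoflux run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("seed: ", seed),
    paste0("elements: ", paste(elements, collapse = ", ")),
    paste0("denominator: ", denominator),
    paste0("normalise: ", normalise),
    paste0("standards: ",
           if (is.null(standards_path)) "built-in" else standards_path),
    paste0("references: ",
           if (is.null(controls)) "international standards (fallback)"
           else "material-matched controls"),
    paste0("outputs: ", paste(written, collapse = ", "))
  ), log_path)

  invisible(list(recovery = recovery, partition = partition,
                 paths = c(written, log_path)))
}
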