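test_that("sample tables round-trip through the delimited readers", {
  cfg <- sim_config("ring_plate", seed = 9)
  samples <- simulate_ring_plate(cfg)$samples
  for (delim in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_sample_table(samples, path, delim = delim)
    back <- read_sample_table(path)
    expect_equal(as.data.frame(back), as.data.frame(samples),
                 tolerance = 1e-12)
  }
})

test_that("schema violations are reported by name and row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,arm_id,compartment_id,role,element",
               "s1,a,c,medium,C"), path)
  expect_error(read_sample_table(path), "delta_permil",
               class = "mycoflux_schema_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste("sample_id", "arm_id", "compartment_id", "role",
                     "element", "dry_mass_g", "element_pct",
                     "delta_permil", "replicate", sep = ","),
               "s1,a,c,medium,C,1,40,not_a_number,1"), path2)
  expect_error(read_sample_table(path2), class = "mycoflux_schema_error")
})

test_that("labelling plans parse events and compound overrides", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "compounds:",
    "  13C-urea:",
    "    element: C",
    "    molar_mass: 61.05",
    "    labelled_atoms: 1",
    "    af_tracer: 0.995",
    "events:",
    "  - arm_id: arm1",
    "    compartment_id: R3_medium",
    "    compound: 13C-urea",
    "    amount_mg: 12.5"
  ), path)
  plan <- read_labelling_plan(path)
  expect_equal(nrow(plan$events), 1)
  expect_equal(plan$events$amount_mg, 12.5)
  urea <- plan$compounds[plan$compounds$name == "13C-urea", ]
  expect_equal(urea$af_tracer, 0.995)
  # built-ins still present
  expect_true("13C-glucose" %in% plan$compounds$name)

  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("compounds: {}", bad)
  expect_error(read_labelling_plan(bad), class = "mycoflux_schema_error")
})

test_that("ion matrices round-trip and reject malformed input", {
  m <- matrix(rpois(30, 20), 5, 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ion_matrix(m, path)
  expect_equal(read_ion_matrix(path), m)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1\t-2\n3\t4", bad)
  expect_error(read_ion_matrix(bad), class = "mycoflux_schema_error")
})

test_that("compare_groups matches hand-computed statistics", {
  # identical groups: t = 0, p = 1
  d <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  tt <- compare_groups(d, "v", "g", design = "ttest")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  expect_false(tt$significant)

  # clear separation is significant
  d2 <- data.frame(v = c(0.01, -0.01, 0, 10.01, 9.99, 10),
                   g = rep(c("a", "b"), each = 3))
  expect_true(compare_groups(d2, "v", "g", design = "ttest")$significant)

  # 3-group ANOVA F equals the sums-of-squares oracle
  set.seed(12)
  d3 <- data.frame(v = c(rnorm(4, 0), rnorm(4, 1), rnorm(4, 3)),
                   g = rep(c("a", "b", "c"), each = 4))
  res <- compare_groups(d3, "v", "g", design = "anova_tukey")
  gm <- mean(d3$v)
  means <- tapply(d3$v, d3$g, mean)
  ss_between <- sum(4 * (means - gm)^2)
  ss_within <- sum((d3$v - means[d3$g])^2)
  f_oracle <- (ss_between / 2) / (ss_within / 9)
  expect_equal(res$statistic[res$comparison == "(anova)"], f_oracle,
               tolerance = 1e-12)
  # Tukey p values agree with stats::TukeyHSD
  tk <- stats::TukeyHSD(stats::aov(v ~ g, data = d3))$g
  pw <- res[res$comparison != "(anova)", ]
  expect_equal(sort(pw$p), sort(unname(tk[, "p adj"])), tolerance = 1e-9)

  # LSD: unadjusted pairwise t on the pooled residual variance
  lsd <- compare_groups(d3, "v", "g", design = "anova_lsd")
  pwl <- lsd[lsd$comparison != "(anova)", ]
  se <- sqrt((ss_within / 9) * (1 / 4 + 1 / 4))
  t_ab <- (means[["b"]] - means[["a"]]) / se
  expect_equal(pwl$statistic[pwl$comparison == "b - a"], t_ab,
               tolerance = 1e-12)
  expect_equal(pwl$p[pwl$comparison == "b - a"],
               2 * pt(abs(t_ab), 9, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(compare_groups(data.frame(v = 1:3, g = c("a", "a", "b")),
                              "v", "g"),
               class = "mycoflux_domain_error")
})

test_that("run_pipeline reproduces the direct analysis and logs its flags", {
  cfg <- sim_config("ring_plate", labelled = "R3",
                    sigma_delta = noiseless, seed = 13)
  sim <- simulate_ring_plate(cfg)
  dir <- withr::local_tempdir()
  sample_path <- file.path(dir, "samples.csv")
  write_sample_table(sim$samples, sample_path)
  plan_path <- file.path(dir, "plan.yml")
  writeLines(c(
    "events:",
    paste0("  - {arm_id: ", sim$events$arm_id,
           ", compartment_id: ", sim$events$compartment_id,
           ", compound: ", sim$events$compound,
           ", amount_mg: ", sim$events$amount_mg, "}")
  ), plan_path)
  # unlabelled controls at the generator's natural backgrounds
  ctl_cfg <- sim_config("ring_plate", labelled = "R3", uptake = 0,
                        sigma_delta = noiseless, seed = 14)
  ctl <- simulate_ring_plate(ctl_cfg)
  ctl_samples <- ctl$samples[ctl$samples$compartment_id != "R3_medium", ]

  out <- run_pipeline(sample_path, plan_path, file.path(dir, "out"),
                      controls = ctl_samples, seed = 13)
  expect_true(file.exists(file.path(dir, "out", "recovery_C.csv")))
  log <- readLines(file.path(dir, "out", "run_log.txt"))
  expect_true(any(grepl("denominator: excess", log)))
  expect_true(any(grepl("material-matched controls", log)))

  direct <- percent_recovery(sim$samples, sim$events,
                             natural_refs(ctl_samples), element = "C")
  expect_equal(tidy(out$recovery$C)$percent_of_added,
               tidy(direct)$percent_of_added, tolerance = 1e-9)

  # rerun: identical outputs
  out2 <- run_pipeline(sample_path, plan_path, file.path(dir, "out2"),
                       controls = ctl_samples, seed = 13)
  expect_equal(tidy(out2$recovery$C), tidy(out$recovery$C))

  # corrupted input aborts with a schema error
  bad_path <- file.path(dir, "bad.csv")
  writeLines("nonsense", bad_path)
  expect_error(run_pipeline(bad_path, plan_path, file.path(dir, "out3")),
               class = "mycoflux_schema_error")
})

test_that("result objects expose tidy, glance and autoplot surfaces", {
  cfg <- sim_config("ring_plate", sigma_delta = noiseless, seed = 15)
  sim <- simulate_ring_plate(cfg)
  rec <- percent_recovery(sim$samples, sim$events, sim$refs, element = "C")
  expect_s3_class(tidy(rec), "tbl_df")
  expect_equal(glance(rec)$element, "C")
  expect_s3_class(autoplot(rec), "ggplot")

  ns <- simulate_nanosims(seed = 16)
  cells <- nanosims_cells(ns$images, ns$mask, ns$morphotypes,
                          control = ns$control_rois)
  expect_s3_class(autoplot(cells), "ggplot")
  expect_equal(glance(cells)$n_cells, nrow(tidy(cells)))
})
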