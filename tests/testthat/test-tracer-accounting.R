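test_that("element_moles uses the dry mass, fraction and atomic mass", {
  expect_equal(element_moles(1, 42, "C"), 0.42 / 12.011)
  expect_equal(element_moles(0, 42, "C"), 0)
  expect_equal(element_moles(1, 1.4, "N"), 0.014 / 14.007)
  expect_error(element_moles(1, 120, "C"), class = "mycoflux_domain_error")
  expect_error(element_moles(1, 50, "O"), class = "mycoflux_domain_error")
})

test_that("heavy_excess_moles is signed and zero at the reference", {
  expect_equal(heavy_excess_moles(0.010, 0.015, 0.0110566),
               0.010 * (0.015 - 0.0110566))
  expect_equal(heavy_excess_moles(1, 0.011, 0.011), 0)
  expect_equal(heavy_excess_moles(1e-3, 0.010, 0.011), -1e-6)
})

test_that("added_heavy_excess converts doses to heavy-atom excess", {
  # 5.5 mg U-13C glucose and 0.21 mg 15NH4Cl (dish doses)
  expect_equal(added_heavy_excess(5.5, "13C-glucose", AF_VPDB),
               1.735809e-4, tolerance = 1e-6)
  expect_equal(added_heavy_excess(0.21, "15N-NH4Cl", AF_AIR),
               3.801262e-6, tolerance = 1e-6)
  expect_error(added_heavy_excess(5.5, "13C-glucose", 0.99),
               class = "mycoflux_domain_error")
})

test_that("percent_recovery recovers a single-compartment balance", {
  refs <- make_refs("medium", "C", AF_VPDB)
  events <- tibble::tibble(arm_id = "arm1", compartment_id = "comp1",
                           compound = "13C-glucose", amount_mg = 5.5)
  added <- added_heavy_excess(5.5, "13C-glucose", AF_VPDB)
  n_mol <- element_moles(1, 42, "C")
  # noiseless: the one compartment holds exactly the added excess
  samples <- make_samples(added / n_mol, AF_VPDB)
  res <- percent_recovery(samples, events, refs)
  expect_equal(res$compartments$percent_of_added, 100, tolerance = 1e-9)
  expect_equal(unname(unrecovered_fraction(res)), 0, tolerance = 1e-9)
})

test_that("percent_recovery matches the division oracle and clips negatives", {
  refs <- make_refs("medium", "C", AF_VPDB)
  n_mol <- element_moles(1, 42, "C")
  # excess 0.039434 mmol against an arm dose of 0.29368 mmol excess
  amount_mg <- 0.29368e-3 * 1000 * 186.11 / 6 / (0.99 - AF_VPDB)
  events <- tibble::tibble(arm_id = "arm1", compartment_id = "comp1",
                           compound = "13C-glucose", amount_mg = amount_mg)
  samples <- make_samples(3.9434e-5 / n_mol, AF_VPDB)
  res <- percent_recovery(samples, events, refs)
  expect_equal(res$compartments$percent_of_added,
               100 * 3.9434e-5 / 0.29368e-4 / 10, tolerance = 1e-6)

  neg <- make_samples(-1e-6, AF_VPDB)
  expect_warning(res_neg <- percent_recovery(neg, events, refs),
                 "clipped")
  expect_equal(res_neg$compartments$percent_of_added, 0)
  expect_lt(res_neg$replicates$excess_mol[1], 0) # signed value retained
})

test_that("recovery errors name the missing configuration", {
  refs <- make_refs("medium", "C", AF_VPDB)
  events <- tibble::tibble(arm_id = "arm1", compartment_id = "comp1",
                           compound = "13C-glucose", amount_mg = 5)
  samples <- make_samples(1e-5, AF_VPDB, role = "mycelium")
  expect_error(percent_recovery(samples, events, refs),
               class = "mycoflux_config_error")
  two_el <- dplyr::bind_rows(make_samples(1e-5, AF_VPDB),
                             make_samples(1e-5, AF_AIR, element = "N"))
  expect_error(percent_recovery(two_el, events, refs),
               class = "mycoflux_domain_error")
  expect_error(percent_recovery(make_samples(1e-5, AF_VPDB),
                                events[0, ], refs),
               class = "mycoflux_config_error")
})

test_that("recovery is invariant to splitting a compartment at the same AF", {
  refs <- make_refs("medium", "C", AF_VPDB)
  events <- tibble::tibble(arm_id = "arm1", compartment_id = "whole",
                           compound = "13C-glucose", amount_mg = 5.5)
  excess_af <- 2e-4
  whole <- make_samples(excess_af, AF_VPDB, compartment_id = "whole",
                        dry_mass_g = 1)
  halves <- dplyr::bind_rows(
    make_samples(excess_af, AF_VPDB, compartment_id = "whole_a",
                 dry_mass_g = 0.5),
    make_samples(excess_af, AF_VPDB, compartment_id = "whole_b",
                 dry_mass_g = 0.5)
  )
  r_whole <- quiet_recovery(whole, events, refs)
  r_halves <- quiet_recovery(halves, events, refs)
  expect_equal(sum(r_halves$compartments$percent_of_added),
               sum(r_whole$compartments$percent_of_added),
               tolerance = 1e-12)
})

test_that("directionality index summarises spread around the source", {
  layout <- paste0("R", 1:5)
  build <- function(percents) {
    refs <- make_refs("medium", "C", AF_VPDB)
    events <- tibble::tibble(arm_id = "arm1", compartment_id = "R3_medium",
                             compound = "13C-glucose", amount_mg = 5.5)
    added <- added_heavy_excess(5.5, "13C-glucose", AF_VPDB)
    n_mol <- element_moles(1, 42, "C")
    samples <- purrr::map_dfr(seq_along(percents), function(i) {
      make_samples(percents[i] / 100 * added / n_mol, AF_VPDB,
                   compartment_id = paste0("R", i, "_medium"))
    })
    percent_recovery(samples, events, refs)
  }
  expect_equal(directionality_index(build(c(0, 0, 0, 30, 30)), layout, "R3"),
               1)
  expect_equal(directionality_index(build(c(10, 10, 20, 10, 10)), layout,
                                    "R3"), 0)
  expect_equal(directionality_index(build(c(5, 5, 20, 15, 15)), layout,
                                    "R3"), 0.5)
  # antisymmetric under reversal of the layout order
  res <- build(c(2, 8, 20, 30, 10))
  expect_equal(directionality_index(res, rev(layout), "R3"),
               -directionality_index(res, layout, "R3"))
  expect_error(directionality_index(res, layout, "R9"),
               class = "mycoflux_domain_error")
})

test_that("tracer C:N ratio divides the element-wise excesses", {
  refs_c <- make_refs("medium", "C", AF_VPDB)
  refs_n <- make_refs("medium", "N", AF_AIR)
  ev_c <- tibble::tibble(arm_id = "arm1", compartment_id = "comp1",
                         compound = "13C-glucose", amount_mg = 30)
  ev_n <- tibble::tibble(arm_id = "arm1", compartment_id = "comp1",
                         compound = "15N-NH4Cl", amount_mg = 1.5)
  n_c <- element_moles(1, 42, "C")
  n_n <- element_moles(1, 1.4, "N")
  rec_c <- percent_recovery(make_samples(1.5e-4 / n_c, AF_VPDB), ev_c,
                            refs_c)
  rec_n <- percent_recovery(
    make_samples(1e-5 / n_n, AF_AIR, element = "N", element_pct = 1.4),
    ev_n, refs_n)
  expect_equal(tracer_cn_ratio(rec_c, rec_n, "comp1"), 15, tolerance = 1e-9)

  rec_n0 <- quiet_recovery(
    make_samples(0, AF_AIR, element = "N", element_pct = 1.4), ev_n, refs_n)
  expect_error(tracer_cn_ratio(rec_c, rec_n0, "comp1"),
               class = "mycoflux_domain_error")
})

test_that("natural_refs averages control measurements per role", {
  controls <- dplyr::bind_rows(
    make_samples(c(1e-4, -1e-4), AF_VPDB),
    make_samples(0, AF_AIR, element = "N")
  )
  refs <- natural_refs(controls)
  expect_equal(refs$af_ref[refs$element == "C"], AF_VPDB, tolerance = 1e-9)
  expect_equal(refs$af_ref[refs$element == "N"], AF_AIR, tolerance = 1e-12)
  expect_warning(standard_refs("medium", "C"), "falling back")
})
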