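test_that("plane accumulation is the element-wise sum", {
  ones <- matrix(1L, 4, 4)
  expect_equal(accumulate_planes(list(ones, ones, ones)),
               matrix(3L, 4, 4))
  expect_equal(accumulate_planes(list(ones)), ones)
  set.seed(7)
  stack <- purrr::map(1:5, ~matrix(rpois(20, 10), 4, 5))
  oracle <- matrix(0, 4, 5)
  for (p in stack) for (i in 1:4) for (j in 1:5)
    oracle[i, j] <- oracle[i, j] + p[i, j]
  expect_equal(accumulate_planes(stack), oracle)
  expect_error(accumulate_planes(list(ones, matrix(1, 3, 3))),
               class = "mycoflux_domain_error")
  expect_error(accumulate_planes(list()), class = "mycoflux_domain_error")
})

test_that("ROI totals sum counts over labelled pixels", {
  img <- matrix(0L, 2, 2)
  img[1, 1] <- 3L; img[1, 2] <- 4L
  mask <- matrix(c(1L, 0L, 1L, 0L), 2, 2)   # ROI 1 = the two top pixels
  tot <- roi_ion_totals(list(`12C2` = img), mask)
  expect_equal(tot[["12C2"]], 7)
  expect_equal(tot$n_pixels, 2L)
  expect_error(roi_ion_totals(list(`12C2` = img), mask, roi_id = 9),
               class = "mycoflux_domain_error")

  # checkerboard mask against a brute-force pixel loop
  set.seed(8)
  big <- matrix(rpois(64, 20), 8, 8)
  cb <- matrix(rep_len(c(1L, 2L), 64), 8, 8)
  tot2 <- roi_ion_totals(list(x = big), cb)
  for (k in 1:2) {
    acc <- 0
    for (i in 1:8) for (j in 1:8) if (cb[i, j] == k) acc <- acc + big[i, j]
    expect_equal(tot2$x[tot2$roi_id == k], acc)
  }
})

test_that("isotope ratios apply the 0.5 carbon-dimer correction", {
  tot <- tibble::tibble(roi_id = 1:3,
                        `12C2` = c(1000, 100000, 10000),
                        `12C13C` = c(500, 2236, 220),
                        `12C14N` = c(10000, 10000, 10000),
                        `12C15N` = c(37, 37, 37))
  r <- roi_isotope_ratios(tot)
  expect_equal(r$ratio_13C[1], 0.25)
  expect_equal(r$ratio_13C[2], 0.011180)
  expect_equal(r$ratio_15N, rep(0.0037, 3))
  # homogeneity of degree 0: scaling all counts leaves ratios unchanged
  scaled <- roi_isotope_ratios(
    dplyr::mutate(tot, dplyr::across(-"roi_id", ~.x * 17)))
  expect_equal(scaled$ratio_13C, r$ratio_13C)
  expect_equal(scaled$ratio_15N, r$ratio_15N)

  tot$`12C2`[2] <- 0
  expect_warning(dropped <- roi_isotope_ratios(tot), "excluded")
  expect_equal(dropped$roi_id, c(1L, 3L))
})

test_that("control-relative deltas centre the control population at zero", {
  ctl <- c(0.0111802, 0.0111802)
  expect_equal(control_relative_delta(0.0111802, ctl), 0)
  expect_equal(control_relative_delta(2 * 0.0111802, ctl), 1000)
  expect_equal(control_relative_delta(0.0120, ctl), 73.33,
               tolerance = 1e-4)
  set.seed(9)
  ratios <- stats::rnorm(50, 0.011, 1e-4)
  expect_equal(mean(control_relative_delta(ratios, ratios)), 0,
               tolerance = 1e-12)
  expect_error(control_relative_delta(0.01, 0.011),
               class = "mycoflux_domain_error")
})

test_that("enrichment classification is one-sided at +2 SD with strict ties", {
  ctl <- c(-50, 0, 50)   # mean 0, sd 50
  cls <- classify_enriched(c(120, 100, -150), ctl)
  expect_equal(cls$upper, 100)
  expect_equal(cls$lower, -100)
  expect_equal(cls$enriched, c(TRUE, FALSE, FALSE))
  expect_error(classify_enriched(1, c(5, 5, 5)),
               class = "mycoflux_domain_error")
  expect_error(classify_enriched(1, c(1, 2)),
               class = "mycoflux_domain_error")
})

test_that("Pearson correlation helper matches closed-form cases", {
  x <- 1:10
  expect_equal(enrichment_correlation(x, 2 * x + 3)$r, 1)
  expect_equal(enrichment_correlation(x, -x)$r, -1)
  out <- enrichment_correlation(c(1, 2, 3, 5), c(2, 2.5, 3.5, 5.5))
  expect_equal(out$n, 4)
  expect_true(out$p >= 0 && out$p <= 1)
  expect_error(enrichment_correlation(1:2, 1:2),
               class = "mycoflux_domain_error")
  expect_error(enrichment_correlation(c(1, 1, 1), 1:3),
               class = "mycoflux_domain_error")
})

test_that("morphotype summaries equal brute-force group statistics", {
  cells <- tibble::tibble(
    morphotype = c("void", "membrane_rich", "void", "membrane_rich"),
    delta13C = c(1, 11, 3, 13),
    delta15N = c(2, 12, 4, 14),
    enriched_13C = c(FALSE, TRUE, FALSE, TRUE),
    enriched_15N = c(FALSE, TRUE, TRUE, TRUE)
  )
  s <- morphotype_summary(cells)
  expect_equal(s$mean_delta13C[s$morphotype == "void"], mean(c(1, 3)))
  expect_equal(s$mean_delta13C[s$morphotype == "membrane_rich"] -
                 s$mean_delta13C[s$morphotype == "void"], 10)
  expect_equal(s$n_enriched_15N[s$morphotype == "void"], 1L)
  one <- morphotype_summary(cells[1, ])
  expect_equal(one$mean_delta13C, 1)
})

test_that("the full single-cell pipeline recovers simulated group deltas", {
  sim <- simulate_nanosims(seed = 21)
  res <- nanosims_cells(sim$images, sim$mask, sim$morphotypes,
                        control = sim$control_rois)
  cells <- tidy(res)
  expect_equal(nrow(cells), nrow(sim$rois))
  # control deltas centre at zero by construction
  expect_equal(mean(cells$delta13C[cells$is_control]), 0,
               tolerance = 1e-10)
  # Poisson-propagated SE oracle on the group means (pooled counts)
  for (grp in c("control", "enriched")) {
    ids <- sim$rois$roi_id[sim$rois$group == grp]
    sub <- cells[cells$roi_id %in% ids, ]
    ctl <- cells[cells$is_control, ]
    for (iso in c("13C", "15N")) {
      minor <- if (iso == "13C") "12C13C" else "12C15N"
      major <- if (iso == "13C") "12C2" else "12C14N"
      se <- 1000 * sqrt(1 / sum(sub[[minor]]) + 1 / sum(sub[[major]]) +
                          1 / sum(ctl[[minor]]) + 1 / sum(ctl[[major]]))
      truth <- sim$rois[[paste0("delta", iso)]][match(ids[1],
                                                      sim$rois$roi_id)]
      got <- mean(sub[[paste0("delta", iso)]])
      expect_lt(abs(got - truth), 3 * se)
    }
  }
  # the same analysis under the pooled-counts control convention agrees
  pooled <- nanosims_cells(sim$images, sim$mask, sim$morphotypes,
                           control = sim$control_rois,
                           control_method = "pooled")
  expect_equal(tidy(pooled)$delta15N, cells$delta15N, tolerance = 0.05)
})

test_that("nanoSIMS simulation is reproducible for a given seed", {
  a <- simulate_nanosims(seed = 33)
  b <- simulate_nanosims(seed = 33)
  expect_identical(a$images, b$images)
  expect_identical(a$mask, b$mask)
  c_ <- simulate_nanosims(seed = 34)
  expect_false(identical(a$images, c_$images))
})
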