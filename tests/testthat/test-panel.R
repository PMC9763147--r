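test_that("window aggregation computes mean/max/min over exact windows", {
  norm <- make_normalized(list(
    A1 = list(ocr = c(0, 10, 12, 14, 30, 45, 40, 5, 5),
              ecar = c(0, 10, 12, 14, 30, 45, 40, 5, 5))
  ))
  expect_equal(window_aggregate(norm, "baseline", "mean")$ocr, 12)
  expect_equal(window_aggregate(norm, "treatment", "max")$ecar, 45)
  expect_equal(window_aggregate(norm, "treatment", "min")$ocr, 30)

  const <- make_normalized(list(A1 = list(ocr = rep(4, 9), ecar = rep(2, 9))))
  for (m in c("mean", "max", "min")) {
    expect_equal(window_aggregate(const, "treatment", m)$ocr, 4)
  }

  short <- make_normalized(list(A1 = list(ocr = 1:5, ecar = 1:5)))
  expect_error(window_aggregate(short, "treatment", "mean"),
               class = "fluxcap_validation_error")
})

test_that("basal respiration subtracts the A+R floor, with fallback flag", {
  norm <- make_normalized(list(
    A1 = list(ocr = flat_cycles(100, tr = 100, ar = 5), ecar = rep(1, 9))
  ))
  b <- basal_respiration(norm)
  expect_equal(b$basal_respiration, 95)
  expect_equal(b$nonmito_respiration, 5)
  expect_false(b$nonmito_uncorrected)

  null_resp <- make_normalized(list(
    A1 = list(ocr = rep(50, 9), ecar = rep(1, 9))
  ))
  expect_equal(basal_respiration(null_resp)$basal_respiration, 0)

  truncated <- make_normalized(
    list(A1 = list(ocr = rep(80, 7), ecar = rep(1, 7))),
    windows = cycle_windows(ar = integer(0))
  )
  bt <- basal_respiration(truncated)
  expect_equal(bt$basal_respiration, 80)
  expect_true(bt$nonmito_uncorrected)
})

test_that("proton leak and ATP-linked respiration partition basal OCR", {
  norm <- make_normalized(list(
    B = list(ocr = flat_cycles(100, tr = 100, ar = 5), ecar = rep(20, 9),
             treatment = "baseline"),
    O = list(ocr = flat_cycles(100, tr = 40, ar = 5), ecar = rep(20, 9),
             treatment = "oligomycin")
  ))
  r <- proton_leak_atp_linked(norm, "B", "O")
  expect_equal(r$basal, 95)
  expect_equal(r$proton_leak_pct, 100 * 35 / 95) # 36.842...
  expect_equal(r$atp_linked_pct, 100 - 100 * 35 / 95)

  # oligomycin OCR equal to the A+R floor: fully coupled respiration
  full <- make_normalized(list(
    B = list(ocr = flat_cycles(100, ar = 5), ecar = rep(20, 9)),
    O = list(ocr = flat_cycles(100, tr = 5, ar = 5), ecar = rep(20, 9),
             treatment = "oligomycin")
  ))
  r2 <- proton_leak_atp_linked(full, "B", "O")
  expect_equal(r2$proton_leak_pct, 0)
  expect_equal(r2$atp_linked_pct, 100)

  flat0 <- make_normalized(list(
    B = list(ocr = rep(5, 9), ecar = rep(20, 9)),
    O = list(ocr = rep(5, 9), ecar = rep(20, 9), treatment = "oligomycin")
  ))
  expect_error(proton_leak_atp_linked(flat0, "B", "O"),
               class = "fluxcap_panel_error")
})

test_that("maximal respiration uses the treatment-window peak", {
  norm <- make_normalized(list(
    F1 = list(ocr = c(0, 100, 100, 100, 700, 800, 750, 5, 5),
              ecar = rep(20, 9), treatment = "fccp")
  ))
  r <- maximal_spare(norm, "F1", basal = 95)
  expect_equal(r$maximal_respiration_pct, 100 * 795 / 95) # 836.84...
  expect_equal(r$spare_capacity_pct, 100 * 795 / 95 - 100)

  # no uncoupling response: maximal equals basal, spare capacity zero
  r2 <- maximal_spare(
    make_normalized(list(F1 = list(ocr = flat_cycles(100, tr = 100, ar = 5),
                                   ecar = rep(1, 9), treatment = "fccp"))),
    "F1", basal = 95
  )
  expect_equal(r2$maximal_respiration_pct, 100)
  expect_equal(r2$spare_capacity_pct, 0)

  expect_error(maximal_spare(norm, "F1", basal = 0),
               class = "fluxcap_panel_error")
})

test_that("glycolytic reserve is the oligomycin ECAR peak over basal", {
  norm <- make_normalized(list(
    B = list(ocr = rep(100, 9), ecar = rep(18.9, 9)),
    O = list(ocr = rep(40, 9), ecar = flat_cycles(18.9, tr = 31.7, ar = 20),
             treatment = "oligomycin")
  ))
  r <- glycolysis_panel(norm, "B", "O")
  expect_equal(r$basal_glycolysis, 18.9)
  expect_equal(r$glycolytic_reserve_pct, 100 * (31.7 - 18.9) / 18.9,
               tolerance = 1e-12) # 67.72...

  r2 <- glycolysis_panel(
    make_normalized(list(
      B = list(ocr = rep(1, 9), ecar = rep(20, 9)),
      O = list(ocr = rep(1, 9), ecar = rep(20, 9), treatment = "oligomycin")
    )), "B", "O")
  expect_equal(r2$glycolytic_reserve_pct, 0)
})

test_that("OCR/ECAR ratio is per-well, basal, and scale-invariant", {
  norm <- make_normalized(list(
    A = list(ocr = rep(300, 9), ecar = rep(60, 9))
  ))
  expect_equal(ocr_ecar_ratio(norm)$ocr_ecar_ratio, 5)

  scaled <- norm
  scaled$ocr <- scaled$ocr * 11.3
  scaled$ecar <- scaled$ecar * 11.3
  expect_equal(ocr_ecar_ratio(scaled)$ocr_ecar_ratio, 5)

  zero <- make_normalized(list(A = list(ocr = rep(1, 9), ecar = rep(0, 9))))
  expect_error(ocr_ecar_ratio(zero), class = "fluxcap_panel_error")
})

test_that("percent responses follow the A+R-corrected baseline convention", {
  norm <- make_normalized(list(
    O = list(ocr = flat_cycles(100, tr = 40, ar = 5),
             ecar = rep(20, 9), treatment = "oligomycin")
  ))
  r <- response_percent(norm)
  ocr <- r[r$signal == "OCR", ]
  expect_equal(ocr$percent_of_baseline, 100 * 35 / 95) # 36.8
  expect_equal(ocr$delta_percent, 100 * 35 / 95 - 100)  # -63.2
  expect_true(ocr$ar_corrected)

  # identical baseline and treatment windows: percent 100, delta 0
  ident <- make_normalized(list(A = list(ocr = flat_cycles(50, ar = 2),
                                         ecar = rep(10, 9))))
  ri <- response_percent(ident)
  expect_equal(ri$percent_of_baseline[ri$signal == "OCR"], 100)
  expect_equal(ri$delta_percent[ri$signal == "ECAR" &
                                  ri$treatment != "ar"], 0)
})

test_that("table3 convention uses ECAR extremes under oligomycin and 2DOG", {
  norm <- make_normalized(list(
    O = list(ocr = rep(100, 9),
             ecar = c(0, 20, 20, 20, 30, 45, 40, 25, 25),
             treatment = "oligomycin"),
    D = list(ocr = rep(100, 9),
             ecar = c(0, 20, 20, 20, 15, 9, 12, 10, 10),
             treatment = "2dog")
  ))
  r3 <- response_percent(norm, convention = "table3", include_ar = FALSE)
  e_o <- r3[r3$signal == "ECAR" & r3$treatment == "oligomycin", ]
  e_d <- r3[r3$signal == "ECAR" & r3$treatment == "2dog", ]
  expect_equal(e_o$percent_of_baseline, 100 * 45 / 20)
  expect_equal(e_o$aggregation, "max_5_7")
  expect_equal(e_d$percent_of_baseline, 100 * 9 / 20)
  expect_equal(e_d$aggregation, "min_5_7")

  r2 <- response_percent(norm, convention = "table2", include_ar = FALSE)
  e_o2 <- r2[r2$signal == "ECAR" & r2$treatment == "oligomycin", ]
  expect_equal(e_o2$percent_of_baseline, 100 * mean(c(30, 45, 40)) / 20)
})

test_that("wells with non-positive corrected baseline OCR are excluded", {
  norm <- make_normalized(list(
    A = list(ocr = flat_cycles(5, tr = 4, ar = 8), ecar = rep(10, 9))
  ))
  expect_message(r <- response_percent(norm), regexp = "excluded")
  expect_true(r$excluded[r$signal == "OCR"])
  expect_true(is.na(r$percent_of_baseline[r$signal == "OCR"]))
  expect_false(any(r$excluded[r$signal == "ECAR"]))
})

test_that("A+R correction makes OCR responses invariant to additive shifts", {
  set.seed(21)
  norm <- random_normalized(seed = 21)
  r1 <- suppressMessages(response_percent(norm))
  shifted <- norm
  shifted$ocr <- shifted$ocr + 250
  r2 <- suppressMessages(response_percent(shifted))
  ocr1 <- r1[r1$signal == "OCR", ]
  ocr2 <- r2[r2$signal == "OCR", ]
  expect_equal(ocr2$percent_of_baseline, ocr1$percent_of_baseline,
               tolerance = 1e-10)
})

test_that("condition percent change matches the reported species figures", {
  expect_equal(round(condition_percent_change(315, 231, "decrease")), 27)
  expect_equal(round(condition_percent_change(18.9, 25.7, "increase")), 36)
  expect_equal(condition_percent_change(42, 42, "decrease"), 0)
  expect_equal(condition_percent_change(42, 42, "increase"), 0)
  expect_error(condition_percent_change(0, 5, "decrease"),
               class = "fluxcap_panel_error")
})

test_that("panel satisfies its exact identities and aggregation ordering", {
  g <- generate_plate(generator_config(n_experiments = 3, seed = 9))
  norm <- g$run |> background_correct() |> normalize_per_sperm()
  panel <- metabolic_panel(norm)

  oligo <- panel[!is.na(panel$proton_leak_pct), ]
  expect_gt(nrow(oligo), 0)
  expect_equal(oligo$proton_leak_pct + oligo$atp_linked_pct,
               rep(100, nrow(oligo)))
  fccp <- panel[!is.na(panel$maximal_respiration_pct), ]
  expect_gt(nrow(fccp), 0)
  expect_equal(fccp$spare_capacity_pct,
               fccp$maximal_respiration_pct - 100)

  r <- suppressMessages(response_percent(norm))
  expect_equal(r$delta_percent, r$percent_of_baseline - 100)

  # min <= mean <= max over the treatment window for every well and signal
  agg_min <- window_aggregate(norm, "treatment", "min")
  agg_mean <- window_aggregate(norm, "treatment", "mean")
  agg_max <- window_aggregate(norm, "treatment", "max")
  expect_true(all(agg_min$ocr <= agg_mean$ocr + 1e-12))
  expect_true(all(agg_mean$ocr <= agg_max$ocr + 1e-12))
  expect_true(all(agg_min$ecar <= agg_mean$ecar + 1e-12))
  expect_true(all(agg_mean$ecar <= agg_max$ecar + 1e-12))
})

test_that("panel and responses agree with the brute-force oracle", {
  for (seed in c(2, 3)) {
    norm <- random_normalized(n_experiments = 2, wells_per_treatment = 2,
                              seed = seed)
    panel <- metabolic_panel(norm)
    orc <- oracle_panel(norm)
    for (id in names(orc)) {
      for (q in c("basal_respiration", "nonmito_respiration",
                  "basal_glycolysis", "ocr_ecar_ratio", "proton_leak_pct",
                  "atp_linked_pct", "maximal_respiration_pct",
                  "spare_capacity_pct", "glycolytic_reserve_pct")) {
        expect_equal(panel_val(panel, id, q), unlist(orc[[id]][q]),
                     tolerance = 1e-12, ignore_attr = TRUE,
                     label = paste(id, q))
      }
    }
    resp <- suppressMessages(response_percent(norm, include_ar = FALSE))
    orr <- oracle_responses(norm)
    for (id in names(orr)) {
      expect_equal(
        resp$percent_of_baseline[resp$well_id == id & resp$signal == "OCR"],
        orr[[id]]$ocr, tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(
        resp$percent_of_baseline[resp$well_id == id & resp$signal == "ECAR"],
        orr[[id]]$ecar, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})
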