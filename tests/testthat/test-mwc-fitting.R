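# The stepwise calibration is exercised on self-generated data: noise-free
# curves must be recovered to optimizer tolerance, seeded noisy curves
# within the stated coverage bands.

optics136 <- glic_sensor_optics("Bim136-Q101W")
truth136 <- glic_reference_truth("Bim136-Q101W")
anchor_truth <- two_state_params(K_R = 3.6e-6, K_pA = 1.0e-6, L_pA = 100)

test_that("anchor fit recovers the printed two-state affinities from noise-free data", {
  s <- model_fluor_series(anchor_truth, optics136)
  fit <- step1_anchor_fit(s, optics136, fit_config())
  expect_equal(fit$K_R, 3.6e-6, tolerance = 1e-4)
  expect_equal(fit$K_pA, 1.0e-6, tolerance = 1e-4)
  expect_true(fit$K_R >= fit$K_pA)
  expect_lt(fit$rss, 1e-12)
})

test_that("anchor fit holds up under generator noise", {
  spec <- generator_spec(truth = list(model = "mwc", params = anchor_truth,
                                      optics = optics136),
                         noise_sd = 0.01, replicates = 3, seed = 1)
  panel <- normalize_fluorescence(generate_fluorescence_panel(spec))
  fit <- step1_anchor_fit(panel, optics136, fit_config())
  expect_lt(abs(log(fit$K_R / 3.6e-6)), log(1.25))
  expect_lt(abs(log(fit$K_pA / 1.0e-6)), log(1.25))
})

test_that("anchor fit rejects flat and direction-mismatched series", {
  flat <- make_series(study_grid, rep(0.7, length(study_grid)))
  expect_error(step1_anchor_fit(flat, optics136, fit_config()), "flat")
  rising <- model_fluor_series(anchor_truth, glic_sensor_optics("Bim250-Y197"))
  expect_error(step1_anchor_fit(rising, optics136, fit_config()),
               "direction mismatch")
})

test_that("unanchored joint two-state fit is refused as under-determined", {
  s <- model_fluor_series(anchor_truth, optics136)
  expect_error(step1_anchor_fit(s, optics136, fit_config(), anchor = NULL),
               "under-determined")
})

test_that("L_pA-only fit recovers truth and preserves monotonicity", {
  for (L in c(100, 1e4)) {
    p <- two_state_params(K_R = 3.6e-6, K_pA = 1.0e-6, L_pA = L)
    s <- model_fluor_series(p, optics136)
    fit <- step1_fit_LpA(s, optics136, 3.6e-6, 1.0e-6, fit_config())
    expect_equal(fit$L_pA, L, tolerance = 0.01)
  }
  # larger L_pA pushes the midpoint to higher proton concentration
  mid <- function(L) half_transition_pH(
    two_state_params(3.6e-6, 1.0e-6, L), "fluorescence-amplitude",
    optics = optics136)
  expect_lt(mid(1e4), mid(100))
})

test_that("noisy L_pA recovery stays within a factor of two in log space", {
  p <- two_state_params(K_R = 3.6e-6, K_pA = 1.0e-6, L_pA = 1000)
  spec <- generator_spec(truth = list(model = "mwc", params = p,
                                      optics = optics136),
                         noise_sd = 0.01, replicates = 3, seed = 7)
  panel <- normalize_fluorescence(generate_fluorescence_panel(spec))
  fit <- step1_fit_LpA(panel, optics136, 3.6e-6, 1.0e-6, fit_config())
  expect_lt(abs(log10(fit$L_pA / 1000)), log10(2))
})

test_that("activation fit recovers the primed-site constants from noise-free data", {
  class1 <- list(K_R = truth136$K_R, K_pA = truth136$K_pA,
                 L_pA = truth136$L_pA)
  sf <- model_fluor_series(truth136, optics136)
  sc <- model_current_series(truth136)
  fit <- step2_activation_fit(sf, sc, class1, optics136,
                              fit_config(activation_affinities = NULL))
  expect_equal(fit$params$K_pAp, truth136$K_pAp, tolerance = 1e-3)
  expect_equal(fit$params$K_Ap, truth136$K_Ap, tolerance = 1e-3)
  expect_equal(fit$params$L_A, truth136$L_A, tolerance = 1e-3)
  expect_gt(fit$params$K_pAp, fit$params$K_Ap)
  # both modality midpoints reproduced within 0.1 pH
  expect_equal(fit$midpoint_fluorescence,
               half_transition_pH(truth136, "fluorescence-amplitude",
                                  optics = optics136), tolerance = 0.1)
  expect_equal(fit$midpoint_current,
               half_transition_pH(truth136, "a", level = "amplitude"),
               tolerance = 0.1)
  # the pre-active state peaks between the two midpoints
  h_between <- pH_to_conc(mean(c(fit$midpoint_fluorescence,
                                 fit$midpoint_current)))
  expect_gt(state_fractions(fit$params, h_between)$pa, 0.3)
})

test_that("sensor-like fits show lower apparent steepness in fluorescence than current", {
  for (sensor in c("Bim136-Q101W", "Bim250-Y197")) {
    p <- glic_reference_truth(sensor)
    o <- glic_sensor_optics(sensor)
    expect_lt(apparent_hill(p, "fluorescence-amplitude", optics = o),
              apparent_hill(p, "a", level = "amplitude"))
  }
})

test_that("mutant multiplier fits recover known fold-changes", {
  cal <- step2_activation_fit(
    model_fluor_series(truth136, optics136),
    model_current_series(truth136),
    list(K_R = truth136$K_R, K_pA = truth136$K_pA, L_pA = truth136$L_pA),
    optics136, fit_config())
  # noise-free unit factors come back as unity
  ph0 <- fit_mutant_multipliers(model_fluor_series(truth136, optics136),
                                model_current_series(truth136), cal)
  expect_equal(ph0$f_L_pA, 1, tolerance = 0.02)
  expect_equal(ph0$f_L_A, 1, tolerance = 0.02)
  expect_equal(ph0$quality, "ok")
  # published-style factors (15, 10) with generator noise
  mut <- mwc_params(truth136$K_R, truth136$K_pA, truth136$K_A,
                    truth136$K_Rp, truth136$K_pAp, truth136$K_Ap,
                    L_pA = 15 * truth136$L_pA, L_A = 10 * truth136$L_A)
  spec <- generator_spec(truth = list(model = "mwc", params = mut,
                                      optics = optics136),
                         noise_sd = 0.01, replicates = 3, seed = 1)
  mf <- normalize_fluorescence(generate_fluorescence_panel(spec))
  mc_raw <- generate_current_recording(spec)
  mc <- normalize_current_to_max(rundown_correct(mc_raw))
  ph <- fit_mutant_multipliers(mf, mc, cal)
  expect_lt(abs(ph$f_L_pA / 15 - 1), 0.3)
  expect_lt(abs(ph$f_L_A / 10 - 1), 0.3)
})

test_that("pre-activation-only mutants show near-coincident modality midpoints", {
  # the loss-of-function signature: a large f_L_pA alone drags both curves
  # together because fluorescence changes become driven by activation itself
  mut <- mwc_params(truth136$K_R, truth136$K_pA, truth136$K_A,
                    truth136$K_Rp, truth136$K_pAp, truth136$K_Ap,
                    L_pA = 3000 * truth136$L_pA, L_A = truth136$L_A)
  mid_f <- half_transition_pH(mut, "fluorescence-amplitude", optics = optics136)
  mid_c <- half_transition_pH(mut, "a", level = "amplitude")
  expect_lt(abs(mid_f - mid_c), 0.15)
  # and the pre-active state stays essentially unpopulated at equilibrium
  pa_max <- max(state_fractions(mut, pH_to_conc(seq(8, 2, by = -0.05)))$pa)
  expect_lt(pa_max, 0.01)
  # the sensor itself keeps a clear separation
  sep_sensor <- half_transition_pH(truth136, "fluorescence-amplitude",
                                   optics = optics136) -
    half_transition_pH(truth136, "a", level = "amplitude")
  expect_gt(sep_sensor, 0.3)
})

test_that("two-state-only mode fits non-functional mutants without an activation factor", {
  cal <- step2_activation_fit(
    model_fluor_series(truth136, optics136),
    model_current_series(truth136),
    list(K_R = truth136$K_R, K_pA = truth136$K_pA, L_pA = truth136$L_pA),
    optics136, fit_config())
  dead <- two_state_params(truth136$K_R, truth136$K_pA,
                           L_pA = 30 * truth136$L_pA)
  ph <- fit_mutant_multipliers(model_fluor_series(dead, optics136), NULL, cal,
                               construct = "dead")
  expect_equal(ph$mode, "two-state-only")
  expect_true(is.na(ph$f_L_A))
  expect_equal(ph$f_L_pA, 30, tolerance = 0.1)
  expect_error(fit_mutant_multipliers(NULL, NULL, cal), "required")
})

test_that("anchor choice rescales constants but not mutant rank order", {
  spec <- generator_spec(truth = list(model = "mwc", params = truth136,
                                      optics = optics136),
                         noise_sd = 0.01, replicates = 2, seed = 5)
  sensor_fluor <- normalize_fluorescence(generate_fluorescence_panel(spec))
  sensor_cur <- normalize_current_to_max(
    rundown_correct(generate_current_recording(spec)))
  anchor_spec <- generator_spec(truth = list(model = "mwc",
                                             params = anchor_truth,
                                             optics = optics136),
                                noise_sd = 0.01, replicates = 2, seed = 6)
  anchor_fluor <- normalize_fluorescence(generate_fluorescence_panel(anchor_spec))
  raw_panel <- generate_mutant_panel(
    truth136, list(m_a = c(2, 80), m_b = c(15, 10), m_c = c(7, 700)),
    generator_spec(truth = list(model = "mwc", params = truth136,
                                optics = optics136),
                   noise_sd = 0.01, replicates = 2, seed = 100))
  mutants <- lapply(raw_panel, function(m) list(
    fluor = normalize_fluorescence(m$fluor),
    current = normalize_current_to_max(rundown_correct(m$current[[1]]))))
  panel <- list(anchor_fluor = anchor_fluor, sensor_fluor = sensor_fluor,
                sensor_current = sensor_cur, optics = optics136,
                mutants = mutants)
  tab <- sensitivity_scan(panel, fit_config(n_starts = 5),
                          anchors = c(100, 1000))
  muts <- tab[tab$construct != "(sensor)", ]
  by_anchor <- split(muts, muts$anchor)
  expect_length(by_anchor, 2)
  r1 <- by_anchor[[1]][order(by_anchor[[1]]$construct), ]
  r2 <- by_anchor[[2]][order(by_anchor[[2]]$construct), ]
  expect_equal(cor(rank(r1$f_L_A), rank(r2$f_L_A), method = "spearman"), 1)
  expect_equal(cor(rank(r1$f_L_pA), rank(r2$f_L_pA), method = "spearman"), 1)
  expect_error(sensitivity_scan(panel, fit_config(), anchors = c(-1)),
               "positive")
})

test_that("the single-site model cannot separate the modality midpoints widely", {
  scan <- single_site_separation_scan(n_K = 8, n_L = 8)
  expect_gt(scan$n_admissible, 0)
  expect_lt(scan$max_fold, 5)
  # while the calibrated two-site loop-sensor model exceeds a 10-fold
  # separation in proton concentration
  p250 <- glic_reference_truth("Bim250-Y197")
  o250 <- glic_sensor_optics("Bim250-Y197")
  sep <- half_transition_pH(p250, "fluorescence-amplitude", optics = o250) -
    half_transition_pH(p250, "a", level = "amplitude")
  expect_gt(10^sep, 10)
})
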