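test_that("state fractions reduce to the isomerization-constant ratios at zero ligand", {
  p <- mwc_params(K_R = 1e-6, K_pA = 1e-6, K_A = 1e-6,
                  K_Rp = 1e-7, K_pAp = 1e-7, K_Ap = 1e-7,
                  L_pA = 100, L_A = 50)
  fr <- state_fractions(p, 1e-14)
  expect_equal(fr$r, 5000 / 5051, tolerance = 1e-6)
  expect_equal(fr$pa, 50 / 5051, tolerance = 1e-6)
  expect_equal(fr$a, 1 / 5051, tolerance = 1e-6)
})

test_that("equal affinities across states make fractions pH-independent", {
  p <- mwc_params(K_R = 2e-6, K_pA = 2e-6, K_A = 2e-6,
                  K_Rp = 5e-7, K_pAp = 5e-7, K_Ap = 5e-7,
                  L_pA = 7, L_A = 3)
  f1 <- state_fractions(p, 1e-8)
  f2 <- state_fractions(p, 1e-4)
  expect_equal(f1$r, f2$r, tolerance = 1e-12)
  expect_equal(f1$pa, f2$pa, tolerance = 1e-12)
})

test_that("two-state reduction matches the closed-form oracle and its midpoint", {
  p <- two_state_params(K_R = 3.6e-6, K_pA = 1.0e-6, L_pA = 100)
  fr <- state_fractions(p, 5.0e-6)
  expect_equal(fr$pa, oracle_two_state_pa(5.0e-6, 3.6e-6, 1.0e-6, 100),
               tolerance = 1e-9)
  expect_equal(fr$pa, 0.5, tolerance = 0.01)
  # oracle equivalence across a wide concentration range (L_A >= 1e10)
  h <- 10^seq(-9, -2, by = 0.25)
  expect_equal(state_fractions(p, h)$pa,
               oracle_two_state_pa(h, 3.6e-6, 1.0e-6, 100),
               tolerance = 1e-6)
})

test_that("fractions sum to one and are stable over extreme parameter draws", {
  set.seed(42)
  n <- 20000
  draw <- function() 10^runif(n, -9, -3)
  p_list <- list(K_R = draw(), K_pA = draw(), K_A = draw(),
                 K_Rp = draw(), K_pAp = draw(), K_Ap = draw(),
                 L_pA = 10^runif(n, -4, 8), L_A = 10^runif(n, -4, 8))
  h <- 10^runif(n, -9, -2)
  worst <- 0
  for (i in seq(1, n, by = 1000)) {
    idx <- i:min(i + 999, n)
    for (j in idx[seq(1, length(idx), by = 200)]) {
      p <- mwc_params(p_list$K_R[j], p_list$K_pA[j], p_list$K_A[j],
                      p_list$K_Rp[j], p_list$K_pAp[j], p_list$K_Ap[j],
                      p_list$L_pA[j], p_list$L_A[j])
      fr <- state_fractions(p, h[j])
      worst <- max(worst, abs(fr$r + fr$pa + fr$a - 1))
      expect_true(all(c(fr$r, fr$pa, fr$a) >= 0 & c(fr$r, fr$pa, fr$a) <= 1))
    }
  }
  expect_lt(worst, 1e-12)
  # numerically stable at the extremes of the concentration range
  p <- mwc_params(1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, L_pA = 1e8, L_A = 1e8)
  expect_false(any(is.na(unlist(state_fractions(p, c(1e-14, 1))[, -1]))))
})

test_that("active fraction is monotone in proton concentration for agonist ordering", {
  set.seed(7)
  for (i in 1:5) {
    lKR <- runif(1, -6, -4)
    p <- mwc_params(K_R = 10^lKR, K_pA = 10^(lKR - runif(1, 0, 2)),
                    K_A = 10^(lKR - runif(1, 2, 3)),
                    K_Rp = 1e-6, K_pAp = 1e-6, K_Ap = 10^(-6 - runif(1, 0, 2)),
                    L_pA = 10^runif(1, 0, 3), L_A = 10^runif(1, 0, 4))
    fr <- state_fractions(p, 10^seq(-9, -2, by = 0.05))
    expect_true(all(diff(fr$a) >= -1e-12))
    expect_true(all(diff(fr$r) <= 1e-12))
  }
})

test_that("disabling the primed site reproduces the single-site model", {
  p2 <- mwc_params(K_R = 3.6e-6, K_pA = 1e-6, K_A = 2e-7,
                   K_Rp = 1e-6, K_pAp = 1e-6, K_Ap = 1e-6,
                   L_pA = 30, L_A = 100)
  h <- 10^seq(-8, -3, by = 0.5)
  expected <- t(vapply(h, function(hh) oracle_fractions(p2, hh), numeric(3)))
  fr <- state_fractions(p2, h)
  expect_equal(fr$r, expected[, "r"], tolerance = 1e-9)
  expect_equal(fr$a, expected[, "a"], tolerance = 1e-9)
})

test_that("fluorescence response is a convex combination of the state intensities", {
  p <- glic_reference_truth("Bim136-Q101W")
  o <- glic_sensor_optics("Bim136-Q101W")
  fc <- fluorescence_response(p, o, seq(8, 3, by = -0.25))
  expect_true(all(fc$response >= 0.30 - 1e-12 & fc$response <= 0.70 + 1e-12))
  # constant optics give a constant curve
  oc <- sensor_optics(0.5, 0.5, 0.5)
  expect_equal(fluorescence_response(p, oc, study_grid)$response,
               rep(0.5, length(study_grid)))
  # resting-dominated parameters approach F_R
  pr <- mwc_params(K_R = 1e-6, K_pA = 1e-6, L_pA = 1e8, L_A = 1e8)
  expect_equal(fluorescence_response(pr, o, c(8))$response, 0.70,
               tolerance = 1e-6)
})

test_that("two-state fluorescence at pH 4 matches the hand-computed value", {
  p <- two_state_params(K_R = 3.6e-6, K_pA = 1.0e-6, L_pA = 100)
  o <- glic_sensor_optics("Bim136-Q101W")
  pa <- oracle_two_state_pa(1e-4, 3.6e-6, 1e-6, 100)
  expect_equal(fluorescence_response(p, o, c(4))$response,
               (1 - pa) * 0.70 + pa * 0.30, tolerance = 1e-9)
  expect_equal(fluorescence_response(p, o, c(4))$response, 0.363,
               tolerance = 1e-3)
})

test_that("label symmetry: swapping pA and A under equal optics and affinities", {
  o <- sensor_optics(0.70, 0.30, 0.30)
  base <- list(K_R = 3.6e-6, K_pA = 1e-6, K_A = 1e-6,
               K_Rp = 2e-6, K_pAp = 2e-6, K_Ap = 2e-6)
  p1 <- do.call(mwc_params, c(base, list(L_pA = 40, L_A = 1)))
  # with L_A = 1 and identical pA/A affinities and optics, relabeling the
  # two non-resting states leaves the observable unchanged
  f <- fluorescence_response(p1, o, study_grid)$response
  fr <- state_fractions(p1, pH_to_conc(study_grid))
  expect_equal(f, fr$r * 0.70 + (fr$pa + fr$a) * 0.30, tolerance = 1e-12)
  expect_equal(fr$pa, fr$a, tolerance = 1e-12)
})

test_that("current response honours normalization contracts", {
  p <- glic_reference_truth("Bim136-Q101W")
  cn <- current_response(p, study_grid, "max")
  expect_equal(max(cn$response), 1)
  # A-suppressed model yields negligible active fraction
  dead <- two_state_params(K_R = 3.6e-6, K_pA = 1e-6, L_pA = 100)
  expect_lt(max(current_response(dead, study_grid, "none")$response), 1e-6)
  expect_error(current_response(
    mwc_params(1e-6, 1e-6, L_pA = 1, L_A = 0), study_grid, "max"), NA)
  # equal weights with unit isomerization constants: A is exactly 1/3
  flat <- mwc_params(K_R = 1e-6, K_pA = 1e-6, K_A = 1e-6,
                     K_Rp = 1e-6, K_pAp = 1e-6, K_Ap = 1e-6,
                     L_pA = 1, L_A = 1)
  expect_equal(current_response(flat, study_grid, "none")$response,
               rep(1 / 3, length(study_grid)), tolerance = 1e-12)
})

test_that("half-transition midpoint solves the two-state closed form", {
  p <- two_state_params(K_R = 3.6e-6, K_pA = 1.0e-6, L_pA = 100)
  mid <- half_transition_pH(p, "pa")
  # oracle: (1 + h/K_pA) = 100^(1/5) (1 + h/K_R) solved linearly
  rat <- 100^(1 / 5)
  h_star <- (rat - 1) / (1 / 1.0e-6 - rat / 3.6e-6)
  expect_equal(mid, -log10(h_star), tolerance = 1e-4)
  expect_equal(mid, 5.30, tolerance = 1e-2)
})

test_that("half-transition errors are explicit for flat and bell-shaped responses", {
  flat <- two_state_params(K_R = 1e-6, K_pA = 1e-6, L_pA = 100)
  expect_error(half_transition_pH(flat, "pa"), "no half-level crossing")
  # amplitude-level midpoints of r and pa coincide in a two-state model
  p <- two_state_params(K_R = 1e-5, K_pA = 1e-6, L_pA = 1)
  expect_equal(half_transition_pH(p, "r", level = "amplitude"),
               half_transition_pH(p, "pa", level = "amplitude"),
               tolerance = 1e-3)
})

test_that("apparent Hill slope matches the analytic two-state derivative", {
  p <- two_state_params(K_R = 3.6e-6, K_pA = 1.0e-6, L_pA = 100)
  mid <- half_transition_pH(p, "pa")
  expect_equal(apparent_hill(p, "pa"),
               oracle_two_state_slope(10^-mid, 3.6e-6, 1.0e-6),
               tolerance = 1e-3)
  expect_equal(apparent_hill(p, "pa"), 1.26, tolerance = 0.01)
  # a single-copy site behaves like a one-site binding curve
  p1 <- two_state_params(K_R = 1e-3, K_pA = 1e-7, L_pA = 100, n_sites = 1)
  expect_equal(apparent_hill(p1, "pa"), 1, tolerance = 0.05)
  # dimensional invariance: scaling all K's rescales the pH axis only
  p_a <- two_state_params(K_R = 3.6e-6, K_pA = 1e-6, L_pA = 100)
  p_b <- two_state_params(K_R = 3.6e-5, K_pA = 1e-5, L_pA = 100)
  expect_equal(apparent_hill(p_a, "pa"), apparent_hill(p_b, "pa"),
               tolerance = 1e-6)
})

test_that("parameter validation and serialization round trip", {
  expect_error(mwc_params(K_R = -1e-6, K_pA = 1e-6), "positive")
  expect_error(mwc_params(K_R = 1e-6, K_pA = 1e-6, L_pA = -2), "L_pA")
  expect_error(mwc_params(K_R = 1e-6, K_pA = 2e-6, K_A = 1e-6,
                          enforce_site_assignment = TRUE), "K_pA == K_A")
  expect_error(sensor_optics(0.7, 0.3, 0.31), "F_pA must equal F_A")
  expect_error(state_fractions(glic_reference_truth("Bim136-Q101W"), -1),
               "positive")
  expect_error(fluorescence_response(glic_reference_truth("Bim136-Q101W"),
                                     glic_sensor_optics("Bim136-Q101W"),
                                     numeric(0)), "empty")
  p <- glic_reference_truth("Bim250-Y197")
  for (ext in c("json", "yaml")) {
    path <- file.path(tempdir(), paste0("params.", ext))
    write_mwc_params(p, path)
    q <- read_mwc_params(path)
    expect_equal(unclass(q)[1:8], unclass(p)[1:8], tolerance = 1e-12)
  }
})

test_that("model curves export with a kind-annotated header", {
  p <- glic_reference_truth("Bim136-Q101W")
  cu <- current_response(p, study_grid, "none")
  path <- file.path(tempdir(), "curve.csv")
  write_model_curve(cu, path)
  lines <- readLines(path)
  expect_match(lines[1], "active-fraction")
  reread <- utils::read.csv(path, comment.char = "#")
  expect_equal(reread$response, cu$response, tolerance = 1e-12)
})
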