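# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive model quantities through closed forms,
# never through the package's own state-population code path.

# two-state (R/pA) closed form: fraction of pre-active protein with a
# single class of n identical proton sites
oracle_two_state_pa <- function(h, K_R, K_pA, L_pA, n = 5) {
  1 / (1 + L_pA * ((1 + h / K_R) / (1 + h / K_pA))^n)
}

# analytic apparent Hill slope of the two-state pa fraction at concentration h
oracle_two_state_slope <- function(h, K_R, K_pA, n = 5) {
  n * h * (1 / (K_pA + h) - 1 / (K_R + h))
}

# direct three-state populations without log-space tricks (safe for
# moderate h only)
oracle_fractions <- function(p, h) {
  wa <- (1 + h / p$K_A)^p$n_sites * (1 + h / p$K_Ap)^p$n_sites
  wpa <- p$L_A * (1 + h / p$K_pA)^p$n_sites * (1 + h / p$K_pAp)^p$n_sites
  wr <- p$L_pA * p$L_A * (1 + h / p$K_R)^p$n_sites * (1 + h / p$K_Rp)^p$n_sites
  z <- wa + wpa + wr
  c(r = wr / z, pa = wpa / z, a = wa / z)
}

hill_fluor <- function(pH, pH50, nH, F0, dF_signed) {
  h <- 10^-pH
  F0 + dF_signed * (1 / (1 + (10^-pH50 / h)^nH))
}

hill_current <- function(pH, pH50, nH, Imax) {
  h <- 10^-pH
  Imax * (1 / (1 + (10^-pH50 / h)^nH))
}

make_series <- function(pH, y, modality = "fluorescence", construct = "x",
                        replicate = 1, normalized = (modality == "fluorescence"),
                        f_sds = 1) {
  titration_series(
    data.frame(construct = construct, modality = modality,
               replicate = replicate, order = seq_along(pH), pH = pH,
               response = y, is_reference = FALSE, f_sds = f_sds),
    normalized = normalized)
}

study_grid <- seq(8, 3, by = -0.5)

# fast generation of noise-free model series for fitting tests
model_fluor_series <- function(params, optics, pH = study_grid, ...) {
  make_series(pH, fluorescence_response(params, optics, pH)$response, ...)
}

model_current_series <- function(params, pH = study_grid, ...) {
  make_series(pH, current_response(params, pH, "max")$response,
              modality = "current", ...)
}

# random rigid-body rotation matrix (QR of a seeded Gaussian, det +1)
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
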