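#' Three-state, two-site-class MWC parameter set
#'
#' Container for the constants of a concerted three-state allosteric model of
#' a homopentameric proton-gated channel. The protein is in equilibrium
#' between a resting (R), a pre-active (pA) and an active (A) state. Two
#' classes of proton-binding sites are carried, each present in `n_sites`
#' identical copies: class 1 (dissociation constants `K_R`, `K_pA`, `K_A` in
#' the three states) conventionally drives pre-activation, class 2 (the
#' "primed" site, `K_Rp`, `K_pAp`, `K_Ap`) drives activation. `L_pA` and
#' `L_A` are the zero-ligand isomerization constants R/pA and pA/A.
#'
#' The affinity ratios `C_pA = K_pA/K_R`, `C_A = K_A/K_pA`,
#' `C_pAp = K_pAp/K_Rp`, `C_Ap = K_Ap/K_pAp` are always derived from the
#' stored dissociation constants (see [mwc_constants()]), never stored
#' independently.
#'
#' @param K_R,K_pA,K_A Molar proton dissociation constants of site class 1 in
#'   the R, pA and A states. All must be positive.
#' @param K_Rp,K_pAp,K_Ap Molar dissociation constants of site class 2
#'   ("primed"). Defaults make the class inert (all equal), reducing the
#'   model to the single-site form.
#' @param L_pA,L_A Dimensionless zero-ligand isomerization constants,
#'   `L_pA = R/pA` and `L_A = pA/A` in the absence of bound protons.
#'   Must be non-negative.
#' @param n_sites Number of copies of each site class (default 5, one per
#'   subunit of the pentamer).
#' @param enforce_site_assignment If `TRUE`, the site-class assignment used
#'   for the sensors (`K_pA == K_A`, class 1 inert for activation, and
#'   `K_Rp == K_pAp`, class 2 inert for pre-activation) is checked exactly
#'   and an error is raised on violation.
#'
#' @return An object of class `mwc_params` (a named list).
#' @seealso [mwc_constants()], [state_fractions()], [two_state_params()]
#' @export
#' @examples
#' p <- mwc_params(K_R = 3.6e-6, K_pA = 1e-6, K_A = 1e-6,
#'                 L_pA = 100, L_A = 50)
#' mwc_constants(p)
mwc_params <- function(K_R, K_pA, K_A = K_pA,
                       K_Rp = 1e-6, K_pAp = K_Rp, K_Ap = K_Rp,
                       L_pA = 1, L_A = 1, n_sites = 5L,
                       enforce_site_assignment = FALSE) {
  ks <- c(K_R = K_R, K_pA = K_pA, K_A = K_A,
          K_Rp = K_Rp, K_pAp = K_pAp, K_Ap = K_Ap)
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("all dissociation constants must be positive and finite", call. = FALSE)
  }
  if (!is.finite(L_pA) || !is.finite(L_A) || L_pA < 0 || L_A < 0) {
    stop("isomerization constants L_pA and L_A must be finite and >= 0", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be a positive integer", call. = FALSE)
  if (isTRUE(enforce_site_assignment)) {
    if (K_pA != K_A) stop("site assignment requires K_pA == K_A exactly", call. = FALSE)
    if (K_Rp != K_pAp) stop("site assignment requires K_Rp == K_pAp exactly", call. = FALSE)
  }
  structure(
    list(K_R = K_R, K_pA = K_pA, K_A = K_A,
         K_Rp = K_Rp, K_pAp = K_pAp, K_Ap = K_Ap,
         L_pA = L_pA, L_A = L_A, n_sites = n_sites,
         enforce_site_assignment = isTRUE(enforce_site_assignment)),
    class = "mwc_params"
  )
}

#' Derived affinity ratios of an MWC parameter set
#'
#' @param params An [mwc_params()] object.
#' @return Named numeric vector with `C_pA`, `C_A`, `C_pAp`, `C_Ap`.
#' @export
mwc_constants <- function(params) {
  stopifnot(inherits(params, "mwc_params"))
  c(C_pA  = params$K_pA / params$K_R,
    C_A   = params$K_A / params$K_pA,
    C_pAp = params$K_pAp / params$K_Rp,
    C_Ap  = params$K_Ap / params$K_pAp)
}

#' @export
print.mwc_params <- function(x, ...) {
  cat("<mwc_params> three-state, two-site-class MWC model\n")
  cat(sprintf("  site class 1: K_R = %.3g  K_pA = %.3g  K_A = %.3g M\n",
              x$K_R, x$K_pA, x$K_A))
  cat(sprintf("  site class 2: K_Rp = %.3g  K_pAp = %.3g  K_Ap = %.3g M\n",
              x$K_Rp, x$K_pAp, x$K_Ap))
  cat(sprintf("  L_pA = %.4g  L_A = %.4g  (n_sites = %d)\n",
              x$L_pA, x$L_A, x$n_sites))
  invisible(x)
}

#' Two-state (R/pA) reduction of the MWC model
#'
#' Convenience constructor for the pore-opening-dead reduction used to fit
#' non-functional constructs: the active state is suppressed by a very large
#' `L_A` and site class 2 is inert, leaving a two-state model with a single
#' class of `n_sites` proton sites.
#'
#' @inheritParams mwc_params
#' @param L_A_suppress Isomerization constant used to suppress the A state
#'   (default `1e12`).
#' @return An `mwc_params` object.
#' @export
two_state_params <- function(K_R, K_pA, L_pA, n_sites = 5L,
                             L_A_suppress = 1e12) {
  mwc_params(K_R = K_R, K_pA = K_pA, K_A = K_pA,
             K_Rp = 1e-6, K_pAp = 1e-6, K_Ap = 1e-6,
             L_pA = L_pA, L_A = L_A_suppress, n_sites = n_sites)
}

#' Intrinsic state fluorescence of a conformational sensor
#'
#' Fluorescence intensity of each allosteric state on the F/F_SDS scale
#' (fluorescence normalized to the SDS-denatured protein). When
#' `pre_active_equals_active` is `TRUE` the quenching is assumed complete at
#' pre-activation, so `F_pA == F_A` is required exactly.
#'
#' @param F_R,F_pA,F_A Non-negative intensities of the R, pA and A states.
#' @param pre_active_equals_active Enforce `F_pA == F_A` (default `TRUE`,
#'   the hypothesis under which the sensors are analysed).
#' @return An object of class `sensor_optics`.
#' @export
#' @examples
#' sensor_optics(0.70, 0.30, 0.30)
sensor_optics <- function(F_R, F_pA, F_A = F_pA,
                          pre_active_equals_active = TRUE) {
  v <- c(F_R = F_R, F_pA = F_pA, F_A = F_A)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("state fluorescence values must be finite and non-negative", call. = FALSE)
  }
  if (isTRUE(pre_active_equals_active) && F_pA != F_A) {
    stop("F_pA must equal F_A exactly when pre_active_equals_active = TRUE",
         call. = FALSE)
  }
  structure(list(F_R = F_R, F_pA = F_pA, F_A = F_A,
                 pre_active_equals_active = isTRUE(pre_active_equals_active)),
            class = "sensor_optics")
}

#' @export
print.sensor_optics <- function(x, ...) {
  cat(sprintf("<sensor_optics> F_R = %.3g  F_pA = %.3g  F_A = %.3g (F/F_SDS)\n",
              x$F_R, x$F_pA, x$F_A))
  invisible(x)
}

#' Published intrinsic fluorescence values of the two GLIC sensors
#'
#' State fluorescence intensities (F/F_SDS) of the ECD-compaction sensor
#' Bim136-Q101W (0.70 / 0.30 / 0.30, quenched on pre-activation) and the
#' M2-M3 loop sensor Bim250-Y197 (0.56 / 0.92 / 0.92, de-quenched on
#' pre-activation).
#'
#' @param sensor `"Bim136-Q101W"` or `"Bim250-Y197"`.
#' @return A [sensor_optics()] object.
#' @export
glic_sensor_optics <- function(sensor = c("Bim136-Q101W", "Bim250-Y197")) {
  sensor <- match.arg(sensor)
  switch(sensor,
         "Bim136-Q101W" = sensor_optics(0.70, 0.30, 0.30),
         "Bim250-Y197"  = sensor_optics(0.56, 0.92, 0.92))
}

#' Serialize / deserialize MWC parameters
#'
#' Parameters are written as a flat JSON or YAML mapping with the field
#' names `K_R`, `K_pA`, `K_A`, `K_Rp`, `K_pAp`, `K_Ap`, `L_pA`, `L_A`,
#' `n_sites`, `enforce_site_assignment`.
#'
#' @param params An `mwc_params` object.
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `write_mwc_params()` returns `path` invisibly;
#'   `read_mwc_params()` returns an `mwc_params` object.
#' @export
write_mwc_params <- function(params, path) {
  stopifnot(inherits(params, "mwc_params"))
  flat <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(flat, path)
  } else {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_mwc_params
#' @export
read_mwc_params <- function(path) {
  flat <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mwc_params, flat)
}
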