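#' Specification of a synthetic titration experiment
#'
#' Defines the truth model and the experimental design emulated by the
#' generator: per-replicate fluorescence series on an 11-point pH 8-to-3
#' grid with additive Gaussian noise on the normalized scale, and oocyte
#' current recordings with interleaved reference applications and
#' multiplicative rundown.
#'
#' @param truth A list describing the truth model. Either
#'   `list(model = "hill", pH50 =, nH =, F0 =, dF_signed =)` (fluorescence)
#'   / `list(model = "hill", pH50 =, nH =, Imax =)` (current), or
#'   `list(model = "mwc", params = <mwc_params>, optics = <sensor_optics>)`.
#' @param pH_grid Test pH grid (default the study-like 11 points from 8.0
#'   to 3.0). An extra sub-3.5 point can be added with `artifact_pH`.
#' @param noise_sd Gaussian noise SD on the normalized response scale
#'   (default 0.02).
#' @param replicates Number of replicates (default 3).
#' @param seed Integer seed; the full panel is deterministic given it.
#' @param f_sds Denatured-protein fluorescence used as the raw scale. The
#'   default 1024 is an exact binary power so that generation followed by
#'   [normalize_fluorescence()] is bit-exact.
#' @param f_sds_jitter Lognormal SD of a per-replicate F_SDS scale factor
#'   (0 disables jitter and keeps normalization exact).
#' @param current_scale Reference peak-current scale in nA.
#' @param rundown_end Rundown factor at the final application (linear
#'   decline from 1; default 0.8, i.e. 20% rundown).
#' @param reference_pH Reference-solution pH (default 5.0).
#' @param reference_spacing References interleaved every this many test
#'   applications (default 3), plus one at each end.
#' @param artifact_pH,artifact_amplitude Optional extra low-pH fluorescence
#'   point deviating in the direction opposite to the quenching curve, to
#'   exercise the exclusion rule (`NULL` disables).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(truth, pH_grid = seq(8, 3, by = -0.5),
                           noise_sd = 0.02, replicates = 3, seed = 1,
                           f_sds = 1024, f_sds_jitter = 0,
                           current_scale = 1000, rundown_end = 0.8,
                           reference_pH = 5.0, reference_spacing = 3,
                           artifact_pH = NULL, artifact_amplitude = 0.05) {
  if (!is.list(truth) || is.null(truth$model) ||
      !truth$model %in% c("hill", "mwc")) {
    stop("truth must be a list with model = 'hill' or 'mwc'", call. = FALSE)
  }
  if (truth$model == "mwc") {
    stopifnot(inherits(truth$params, "mwc_params"))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (rundown_end <= 0 || rundown_end > 1) {
    stop("rundown_end must be in (0, 1]", call. = FALSE)
  }
  if (reference_spacing < 1) stop("reference_spacing must be >= 1", call. = FALSE)
  structure(list(truth = truth, pH_grid = pH_grid, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 f_sds = f_sds, f_sds_jitter = f_sds_jitter,
                 current_scale = current_scale, rundown_end = rundown_end,
                 reference_pH = reference_pH,
                 reference_spacing = as.integer(reference_spacing),
                 artifact_pH = artifact_pH,
                 artifact_amplitude = artifact_amplitude),
            class = "generator_spec")
}

# truth response on the normalized scale
.truth_response <- function(spec, pH, modality) {
  t <- spec$truth
  h <- pH_to_conc(pH)
  if (t$model == "hill") {
    hill <- .hill_term(h, pH_to_conc(t$pH50), t$nH)
    if (modality == "fluorescence") t$F0 + t$dF_signed * hill else t$Imax * hill
  } else {
    if (modality == "fluorescence") {
      .fluor_model(t$params, t$optics, pH)
    } else {
      state_fractions(t$params, h)$a
    }
  }
}

# one shared stream per panel, split per series by counter so that
# generation is reproducible under series reordering; double arithmetic
# keeps the derived seed inside the 32-bit integer range
.series_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(counter) * 104729) %%
               2147483647)
}

#' Generate a fluorescence titration panel
#'
#' Raw fluorescence is the truth (F/F_SDS) response multiplied by the
#' per-replicate F_SDS; with the default exact-binary F_SDS and
#' `noise_sd = 0`, normalization recovers the truth exactly.
#'
#' @param spec A [generator_spec()].
#' @param construct Construct label.
#' @return A raw (un-normalized) `titration` object.
#' @export
generate_fluorescence_panel <- function(spec, construct = "synthetic") {
  stopifnot(inherits(spec, "generator_spec"))
  pH <- spec$pH_grid
  if (!is.null(spec$artifact_pH)) pH <- c(pH, spec$artifact_pH)
  truth <- .truth_response(spec, pH, "fluorescence")
  if (!is.null(spec$artifact_pH)) {
    k <- length(truth)
    truth[k] <- truth[k] - sign(.truth_response(spec, 3, "fluorescence") -
                                  .truth_response(spec, 8, "fluorescence")) *
      spec$artifact_amplitude
  }
  rows <- purrr::map_dfr(seq_len(spec$replicates), function(r) {
    set.seed(.series_seed(spec$seed, r))
    f_sds <- spec$f_sds *
      if (spec$f_sds_jitter > 0) exp(stats::rnorm(1, 0, spec$f_sds_jitter)) else 1
    y <- truth + if (spec$noise_sd > 0) stats::rnorm(length(truth), 0, spec$noise_sd) else 0
    tibble::tibble(construct = construct, modality = "fluorescence",
                   replicate = r, order = seq_along(pH), pH = pH,
                   response = y * f_sds, is_reference = FALSE, f_sds = f_sds)
  })
  titration_series(rows, normalized = FALSE,
                   provenance = sprintf("synthetic fluorescence (seed %d)", spec$seed))
}

#' Generate one oocyte current recording with rundown
#'
#' Applications run in order: a reference at the start, a reference after
#' every `reference_spacing` test applications, and a reference at the end.
#' A linear rundown factor (1 down to `rundown_end`) multiplies every
#' response; noise is added on the normalized scale and scaled to nA.
#'
#' @param spec A [generator_spec()].
#' @param construct Construct label.
#' @param replicate Replicate id.
#' @return A raw `titration` object (modality `"current"`) with reference
#'   applications flagged.
#' @export
generate_current_recording <- function(spec, construct = "synthetic",
                                       replicate = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  n_test <- length(spec$pH_grid)
  if (spec$reference_spacing > n_test) {
    stop("reference spacing exceeds the number of test applications", call. = FALSE)
  }
  pH <- c(); is_ref <- c()
  for (i in seq_len(n_test)) {
    if ((i - 1) %% spec$reference_spacing == 0) {
      pH <- c(pH, spec$reference_pH); is_ref <- c(is_ref, TRUE)
    }
    pH <- c(pH, spec$pH_grid[i]); is_ref <- c(is_ref, FALSE)
  }
  pH <- c(pH, spec$reference_pH); is_ref <- c(is_ref, TRUE)
  k <- length(pH)
  rundown <- 1 - (1 - spec$rundown_end) * (seq_len(k) - 1) / (k - 1)
  truth <- .truth_response(spec, pH, "current")
  set.seed(.series_seed(spec$seed, 10000L + as.integer(replicate)))
  noise <- if (spec$noise_sd > 0) stats::rnorm(k, 0, spec$noise_sd) else numeric(k)
  resp <- (truth + noise) * rundown * spec$current_scale
  rows <- tibble::tibble(construct = construct, modality = "current",
                         replicate = replicate, order = seq_len(k), pH = pH,
                         response = resp, is_reference = is_ref,
                         f_sds = NA_real_)
  titration_series(rows, normalized = FALSE,
                   provenance = sprintf("synthetic recording (seed %d, rundown to %.2f)",
                                        spec$seed, spec$rundown_end))
}

#' Normalize a corrected current series to its maximal response
#'
#' Divides rundown-corrected test currents by the series maximum,
#' producing the normalized activation curve the MWC model is fitted on.
#'
#' @param series A `titration` (modality `"current"`).
#' @return The normalized `titration`.
#' @export
normalize_current_to_max <- function(series) {
  stopifnot(inherits(series, "titration"))
  cur <- series$modality == "current" & !series$is_reference
  m <- max(series$response[cur])
  if (m <= 0) stop("non-functional: maximal current is not positive", call. = FALSE)
  series$response[cur] <- series$response[cur] / m
  .add_provenance(series, "current normalized to maximal response")
}

#' Generate a full mutant panel from sensor truth
#'
#' Applies per-construct multiplication factors to the sensor's
#' isomerization constants and emits both modalities for every construct.
#' A non-functional construct is marked with `f_L_A = Inf`: its currents
#' are pure noise around zero.
#'
#' @param sensor_params Sensor truth [mwc_params()].
#' @param multiplier_map Named list/ list of `c(f_L_pA, f_L_A)` per
#'   construct (`f_L_A = Inf` for non-functional).
#' @param spec A [generator_spec()] providing optics (via `truth$optics`),
#'   grids, noise and design. Its `truth$params` is ignored per construct.
#' @return A list per construct with elements `fluor` (raw fluorescence
#'   `titration`) and `current` (list of raw recordings, or noise-only
#'   recordings when non-functional), plus attribute `truth_params`.
#' @export
generate_mutant_panel <- function(sensor_params, multiplier_map, spec) {
  stopifnot(inherits(sensor_params, "mwc_params"),
            inherits(spec, "generator_spec"))
  optics <- spec$truth$optics
  if (is.null(optics)) stop("spec$truth$optics is required", call. = FALSE)
  out <- purrr::imap(multiplier_map, function(f, name) {
    f_pA <- f[[1]]; f_A <- f[[2]]
    nonfunctional <- is.infinite(f_A)
    p <- mwc_params(K_R = sensor_params$K_R, K_pA = sensor_params$K_pA,
                    K_A = sensor_params$K_A, K_Rp = sensor_params$K_Rp,
                    K_pAp = sensor_params$K_pAp, K_Ap = sensor_params$K_Ap,
                    L_pA = f_pA * sensor_params$L_pA,
                    L_A = if (nonfunctional) 1e12 else f_A * sensor_params$L_A,
                    n_sites = sensor_params$n_sites)
    sub <- spec
    sub$truth <- list(model = "mwc", params = p, optics = optics)
    sub$seed <- .series_seed(spec$seed, match(name, names(multiplier_map)) * 131L)
    if (!nonfunctional) {
      # the reference solution sits in the middle of the construct's own
      # response range, as in the recording protocol; snap to the grid pH
      # where the truth current is closest to half-maximal
      a <- .truth_response(sub, spec$pH_grid, "current")
      sub$reference_pH <- spec$pH_grid[which.min(abs(a - max(a) / 2))]
    }
    fluor <- generate_fluorescence_panel(sub, construct = name)
    currents <- lapply(seq_len(spec$replicates), function(r) {
      rec <- generate_current_recording(sub, construct = name, replicate = r)
      if (nonfunctional) {
        set.seed(.series_seed(sub$seed, 20000L + r))
        rec$response <- stats::rnorm(nrow(rec), 0, spec$noise_sd) *
          spec$current_scale
        # keep references positive so the recording is still correctable
        rec$response[rec$is_reference] <- abs(rec$response[rec$is_reference]) +
          0.01 * spec$current_scale
      }
      rec
    })
    structure(list(fluor = fluor, current = currents,
                   nonfunctional = nonfunctional),
              truth_params = p)
  })
  out
}
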