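#' Normalize fluorescence to the denatured-protein signal
#'
#' Divides raw fluorescence responses by the per-series F_SDS value
#' (fluorescence of the SDS-denatured protein), placing them on the
#' F/F_SDS scale on which the models are defined. Calling it twice is an
#' error (idempotence guard).
#'
#' @param series A `titration` object, modality `"fluorescence"`, with
#'   positive `f_sds`.
#' @return The normalized `titration` object.
#' @export
normalize_fluorescence <- function(series) {
  stopifnot(inherits(series, "titration"))
  if (isTRUE(attr(series, "normalized"))) {
    stop("series is already normalized to F_SDS", call. = FALSE)
  }
  fl <- series$modality == "fluorescence"
  if (!any(fl)) stop("no fluorescence points in series", call. = FALSE)
  if (any(is.na(series$f_sds[fl])) || any(series$f_sds[fl] <= 0)) {
    stop("F_SDS must be present and positive for every fluorescence point",
         call. = FALSE)
  }
  series$response[fl] <- series$response[fl] / series$f_sds[fl]
  attr(series, "normalized") <- TRUE
  .add_provenance(series, "fluorescence divided by F_SDS")
}

#' Correct oocyte peak currents for rundown
#'
#' Recordings interleave applications of a reference pH (flagged with
#' `is_reference`) at the beginning and end and every few test
#' applications. The rundown factor at each application index is obtained
#' by interpolating between consecutive reference responses (each expressed
#' relative to the first reference), piecewise-linearly in application
#' index by default or exponentially (linear in log response) with
#' `method = "exponential"`. Every test response is divided by the factor
#' at its index and the references are dropped from the output.
#'
#' @param series A `titration` object, modality `"current"`, with at least
#'   two reference applications bracketing all test applications.
#' @param method `"linear"` (default) or `"exponential"` interpolation of
#'   the rundown factor.
#' @return The corrected `titration` object (references removed).
#' @export
rundown_correct <- function(series, method = c("linear", "exponential")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "titration"))
  cur <- series$modality == "current"
  if (!all(cur)) stop("rundown correction applies to current series only", call. = FALSE)
  o <- order(series$order)
  series <- series[o, , drop = FALSE]
  ref <- which(series$is_reference)
  if (length(ref) < 2) {
    stop("at least two reference applications are required", call. = FALSE)
  }
  if (min(ref) > 1 || max(ref) < nrow(series)) {
    stop("reference applications must bracket all test applications", call. = FALSE)
  }
  if (any(series$response[ref] <= 0)) {
    stop("reference responses must be positive", call. = FALSE)
  }
  rel <- series$response[ref] / series$response[ref[1]]
  idx <- series$order[ref]
  factor_at <- if (method == "linear") {
    stats::approx(idx, rel, xout = series$order, rule = 2)$y
  } else {
    exp(stats::approx(idx, log(rel), xout = series$order, rule = 2)$y)
  }
  series$response <- series$response / factor_at
  out <- series[!series$is_reference, , drop = FALSE]
  out <- titration_series(out, normalized = attr(series, "normalized"),
                          provenance = attr(series, "provenance"))
  .add_provenance(out, sprintf("rundown-corrected (%s interpolation, %d references)",
                               method, length(ref)))
}

#' Renormalize a series to the amplitude scale of a reference construct
#'
#' Affinely maps the target series so that its fitted plateau-to-plateau
#' range coincides with the reference's, the correction applied when a
#' mutation alters the resting-state fluorescence itself (e.g. E26Q versus
#' its parent sensor) or when responses must be expressed relative to a
#' potentiated condition. Both inputs are Hill-fitted and the affine
#' coefficients `(scale, offset)` mapping target plateaus onto reference
#' plateaus are recorded in the provenance.
#'
#' @param target,reference `titration` objects on the same modality scale,
#'   or pre-computed [hill_fit] objects for the plateau estimation (the
#'   target itself must be a `titration`).
#' @param target_fit,reference_fit Optional [fit_hill_fluorescence()] /
#'   [fit_hill_current()] results; fitted internally when omitted.
#' @return The mapped target `titration`, with attribute `renorm_coef`
#'   (named vector `scale`, `offset`).
#' @export
renormalize_to_reference <- function(target, reference,
                                     target_fit = NULL, reference_fit = NULL) {
  stopifnot(inherits(target, "titration"))
  modality <- unique(target$modality)
  if (inherits(reference, "titration") &&
      !identical(sort(unique(reference$modality)), modality)) {
    stop("target and reference must share the same modality", call. = FALSE)
  }
  plateaus <- function(x, fit) {
    if (is.null(fit)) {
      fit <- if (modality == "fluorescence") fit_hill_fluorescence(x) else fit_hill_current(x)
    }
    if (!identical(fit$status, "ok")) {
      stop("plateau fit failed (status: ", fit$status,
           "); cannot renormalize", call. = FALSE)
    }
    if (modality == "fluorescence") c(fit$F0, fit$F0 + fit$dF_signed) else c(0, fit$Imax)
  }
  pt <- plateaus(target, target_fit)
  pr <- plateaus(reference, reference_fit)
  if (abs(diff(pr)) < 1e-8) {
    stop("reference has zero fitted amplitude; cannot renormalize", call. = FALSE)
  }
  if (abs(diff(pt)) < 1e-8) {
    stop("target has zero fitted amplitude; cannot renormalize", call. = FALSE)
  }
  scale <- diff(pr) / diff(pt)
  offset <- pr[1] - scale * pt[1]
  target$response <- scale * target$response + offset
  target <- .add_provenance(
    target, sprintf("renormalized to reference range (scale %.6g, offset %.6g)",
                    scale, offset))
  attr(target, "renorm_coef") <- c(scale = scale, offset = offset)
  target
}

#' Per-pH replicate summary
#'
#' Mean and standard deviation of the response at each pH across
#' replicates, for display; fitting is always done per replicate.
#'
#' @param series A `titration` object.
#' @return A tibble (`construct`, `modality`, `pH`, `mean`, `sd`, `n`).
#' @export
aggregate_replicates <- function(series) {
  stopifnot(inherits(series, "titration"))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(series), construct, modality, pH),
    mean = mean(response), sd = stats::sd(response), n = dplyr::n(),
    .groups = "drop")
}
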