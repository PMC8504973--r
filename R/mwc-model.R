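#' Fractional state populations of the three-state MWC model
#'
#' Computes the equilibrium fractions of the resting (R), pre-active (pA)
#' and active (A) states at one or more proton concentrations. With
#' `h = [H+]`, the (unnormalized) statistical weights are
#'
#' \deqn{w_A = (1 + h/K_A)^n (1 + h/K_{Ap})^n}
#' \deqn{w_{pA} = L_A (1 + h/K_{pA})^n (1 + h/K_{pAp})^n}
#' \deqn{w_R = L_{pA} L_A (1 + h/K_R)^n (1 + h/K_{Rp})^n}
#'
#' and each fraction is its weight divided by the sum. The products are
#' evaluated in log space (log1p terms, max-subtracted before
#' exponentiation) so the computation is stable for `h` up to 1 M even when
#' `h/K` reaches 1e8.
#'
#' @param params An [mwc_params()] object.
#' @param proton_conc Proton concentration(s) in molar; all must be > 0.
#' @return A tibble with columns `proton_conc`, `r`, `pa`, `a`; each row
#'   sums to 1 within 1e-12.
#' @export
#' @examples
#' p <- mwc_params(K_R = 3.6e-6, K_pA = 1e-6, L_pA = 100, L_A = 50)
#' state_fractions(p, 10^-(4:7))
state_fractions <- function(params, proton_conc) {
  stopifnot(inherits(params, "mwc_params"))
  h <- as.numeric(proton_conc)
  if (length(h) == 0 || any(!is.finite(h)) || any(h <= 0)) {
    stop("proton_conc must be positive and finite", call. = FALSE)
  }
  lw <- .mwc_log_weights(params, h)
  m <- pmax(lw$r, lw$pa, lw$a)
  wr <- exp(lw$r - m); wpa <- exp(lw$pa - m); wa <- exp(lw$a - m)
  z <- wr + wpa + wa
  tibble::tibble(proton_conc = h, r = wr / z, pa = wpa / z, a = wa / z)
}

# log statistical weights of the three states at proton concentration h
.mwc_log_weights <- function(params, h) {
  n <- params$n_sites
  list(
    a  = n * log1p(h / params$K_A) + n * log1p(h / params$K_Ap),
    pa = log(params$L_A) + n * log1p(h / params$K_pA) + n * log1p(h / params$K_pAp),
    r  = log(params$L_pA) + log(params$L_A) +
      n * log1p(h / params$K_R) + n * log1p(h / params$K_Rp)
  )
}

#' Convert between pH and proton concentration
#'
#' `[H+] = 10^(-pH)` exactly; activity corrections are not applied.
#'
#' @param pH,proton_conc Numeric vectors.
#' @return Numeric vector.
#' @export
pH_to_conc <- function(pH) 10^(-pH)

#' @rdname pH_to_conc
#' @export
conc_to_pH <- function(proton_conc) -log10(proton_conc)

.check_pH_grid <- function(pH_grid) {
  if (length(pH_grid) == 0) stop("pH grid is empty", call. = FALSE)
  if (any(!is.finite(pH_grid)) || any(pH_grid < 0) || any(pH_grid > 14)) {
    stop("pH grid values must lie in [0, 14]", call. = FALSE)
  }
  if (length(pH_grid) > 1) {
    d <- diff(pH_grid)
    if (!(all(d > 0) || all(d < 0))) {
      stop("pH grid must be strictly monotone", call. = FALSE)
    }
  }
  invisible(pH_grid)
}

.model_curve <- function(pH, response, kind, note = NA_character_) {
  out <- tibble::tibble(pH = pH, response = response)
  attr(out, "kind") <- kind
  attr(out, "normalization") <- note
  class(out) <- c("model_curve", class(out))
  out
}

#' @export
print.model_curve <- function(x, ...) {
  cat(sprintf("<model_curve> kind: %s (%d points)\n",
              attr(x, "kind"), nrow(x)))
  if (!is.na(attr(x, "normalization"))) {
    cat("  normalization:", attr(x, "normalization"), "\n")
  }
  NextMethod()
}

#' Write a model curve as a two-column CSV
#'
#' The response kind is recorded in a `#`-prefixed header comment.
#'
#' @param curve A `model_curve` (from [fluorescence_response()] or
#'   [current_response()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_curve <- function(curve, path) {
  stopifnot(inherits(curve, "model_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# response kind: %s", attr(curve, "kind")), con)
  if (!is.na(attr(curve, "normalization"))) {
    writeLines(sprintf("# normalization: %s", attr(curve, "normalization")), con)
  }
  utils::write.csv(as.data.frame(curve[, c("pH", "response")]), con,
                   row.names = FALSE)
  invisible(path)
}

#' Predicted steady-state fluorescence of a sensor
#'
#' Population-weighted fluorescence
#' `F = r * F_R + pa * F_pA + a * F_A` on the F/F_SDS scale.
#'
#' @param params An [mwc_params()] object.
#' @param optics A [sensor_optics()] object.
#' @param pH_grid Strictly monotone pH grid in \[0, 14\].
#' @return A `model_curve` tibble (`pH`, `response`), kind `"fluorescence"`.
#' @export
fluorescence_response <- function(params, optics, pH_grid) {
  stopifnot(inherits(optics, "sensor_optics"))
  .check_pH_grid(pH_grid)
  fr <- state_fractions(params, pH_to_conc(pH_grid))
  f <- fr$r * optics$F_R + fr$pa * optics$F_pA + fr$a * optics$F_A
  .model_curve(pH_grid, f, "fluorescence")
}

#' Predicted active-state population / normalized current
#'
#' The electrophysiological observable is the active-state fraction. With
#' `normalization = "max"` the curve is divided by its maximum over the
#' grid, mirroring the normalization of peak-current recordings for
#' constructs whose active population does not reach 1.
#'
#' @inheritParams fluorescence_response
#' @param normalization `"none"` (active fraction) or `"max"`.
#' @return A `model_curve`, kind `"active-fraction"` or
#'   `"normalized-current"`.
#' @export
current_response <- function(params, pH_grid, normalization = c("none", "max")) {
  normalization <- match.arg(normalization)
  .check_pH_grid(pH_grid)
  a <- state_fractions(params, pH_to_conc(pH_grid))$a
  if (normalization == "max") {
    m <- max(a)
    if (m <= 0) stop("active fraction is identically zero: non-functional construct",
                     call. = FALSE)
    return(.model_curve(pH_grid, a / m, "normalized-current",
                        note = "divided by maximum over grid"))
  }
  .model_curve(pH_grid, a, "active-fraction")
}

.response_fun <- function(params, which, optics = NULL) {
  if (which == "fluorescence-amplitude") {
    if (is.null(optics)) stop("optics required for fluorescence response", call. = FALSE)
    function(pH) {
      fr <- state_fractions(params, pH_to_conc(pH))
      fr$r * optics$F_R + fr$pa * optics$F_pA + fr$a * optics$F_A
    }
  } else {
    function(pH) state_fractions(params, pH_to_conc(pH))[[which]]
  }
}

#' pH of half-transition of a model observable
#'
#' Finds, by sign scan plus bisection, the pH at which the requested
#' quantity crosses its half level. For state fractions (`which` one of
#' `"r"`, `"pa"`, `"a"`) the default half level is the absolute value 0.5;
#' with `level = "amplitude"` the midpoint of the quantity's extreme values
#' over `range` is used instead (always the case for
#' `"fluorescence-amplitude"`).
#'
#' @param params An [mwc_params()] object.
#' @param which `"r"`, `"pa"`, `"a"` or `"fluorescence-amplitude"`.
#' @param optics [sensor_optics()], required for fluorescence.
#' @param range pH interval scanned (default `c(0, 10)`).
#' @param level `"absolute"` (fractions cross 0.5) or `"amplitude"`.
#' @param tol Bisection tolerance in pH units (default 1e-5, well inside
#'   the 1e-4 contract).
#' @return The crossing pH (scalar). Errors if the quantity does not cross,
#'   or crosses more than once (e.g. a bell-shaped response).
#' @export
half_transition_pH <- function(params, which = c("pa", "r", "a", "fluorescence-amplitude"),
                               optics = NULL, range = c(0, 10),
                               level = c("absolute", "amplitude"), tol = 1e-5) {
  which <- match.arg(which)
  level <- match.arg(level)
  f <- .response_fun(params, which, optics)
  grid <- seq(range[1], range[2], by = 0.01)
  y <- f(grid)
  half <- if (which == "fluorescence-amplitude" || level == "amplitude") {
    (min(y) + max(y)) / 2
  } else 0.5
  s <- sign(y - half)
  cross <- which(s[-1] * s[-length(s)] < 0 | (s[-1] != 0 & s[-length(s)] == 0))
  if (length(cross) == 0) {
    stop(sprintf("no half-level crossing of '%s' on pH [%g, %g]", which,
                 range[1], range[2]), call. = FALSE)
  }
  if (length(cross) > 1) {
    stop(sprintf("multiple half-level crossings of '%s' (non-monotone, e.g. bell-shaped response)",
                 which), call. = FALSE)
  }
  stats::uniroot(function(p) f(p) - half,
                 lower = grid[cross], upper = grid[cross + 1], tol = tol)$root
}

#' Apparent Hill coefficient of a model observable at its midpoint
#'
#' Steepness of the titration curve in the standard Hill sense,
#' `nH = d logit(y) / d ln[H+]` evaluated at the half-transition point by a
#' centered finite difference with a 0.01-pH step. State fractions are used
#' on their natural \[0, 1\] scale; the fluorescence response is first
#' normalized to its amplitude over the scan range.
#'
#' @inheritParams half_transition_pH
#' @return Apparent `nH` (positive).
#' @export
apparent_hill <- function(params, which = c("pa", "r", "a", "fluorescence-amplitude"),
                          optics = NULL, range = c(0, 10),
                          level = c("absolute", "amplitude")) {
  which <- match.arg(which)
  level <- match.arg(level)
  mid <- half_transition_pH(params, which, optics = optics, range = range,
                            level = level)
  f <- .response_fun(params, which, optics)
  norm <- identity
  if (which == "fluorescence-amplitude" || level == "amplitude") {
    grid <- seq(range[1], range[2], by = 0.01)
    y <- f(grid)
    lo <- min(y); hi <- max(y)
    norm <- function(v) (v - lo) / (hi - lo)
  }
  step <- 0.01
  logit <- function(p) log(p / (1 - p))
  # moving down in pH increases [H+]; divide by ln(10) for the per-ln-h slope
  abs((logit(norm(f(mid - step))) - logit(norm(f(mid + step)))) /
        (2 * step) / log(10))
}
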