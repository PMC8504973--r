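#' @importFrom stats coef resid sd setNames
NULL

.hill_term <- function(h, EC50, nH) 1 / (1 + (EC50 / h)^nH)

.noise_estimate <- function(y) {
  # robust sigma from first differences of the pH-ordered responses
  if (length(y) < 3) return(0)
  max(stats::mad(diff(y)) / sqrt(2), 1e-6)
}

# bell-shape screen: interior extremum deviating beyond noise from BOTH ends
.is_bell_shaped <- function(pH, y) {
  o <- order(pH, decreasing = TRUE)
  y <- y[o]
  n <- length(y)
  if (n < 5) return(FALSE)
  thr <- 4 * max(.noise_estimate(y), 0.02)
  i_min <- which.min(y); i_max <- which.max(y)
  dip  <- i_min > 1 && i_min < n &&
    (y[1] - y[i_min]) > thr && (y[n] - y[i_min]) > thr
  bump <- i_max > 1 && i_max < n &&
    (y[i_max] - y[1]) > thr && (y[i_max] - y[n]) > thr
  dip || bump
}

.new_hill_fit <- function(est, rss, n_points, constraints, status, modality,
                          construct = NA_character_, replicate = NA,
                          excluded = 0L, message = NA_character_) {
  structure(
    list(EC50 = est[["EC50"]], pH50 = -log10(est[["EC50"]]),
         nH = est[["nH"]],
         F0 = est[["F0"]], dF_signed = est[["dF_signed"]],
         dF_max = abs(est[["dF_signed"]]),
         Imax = est[["Imax"]],
         rss = rss, n_points = n_points,
         constraints = constraints, status = status, modality = modality,
         construct = construct, replicate = replicate,
         excluded = excluded, message = message),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> %s [%s]\n", x$modality, x$status))
  if (x$status == "ok") {
    cat(sprintf("  pH50 = %.3f  nH = %.3f  (EC50 = %.3g M)\n",
                x$pH50, x$nH, x$EC50))
    if (x$modality == "fluorescence") {
      cat(sprintf("  F0 = %.3f  dF_signed = %+.3f\n", x$F0, x$dF_signed))
    } else {
      cat(sprintf("  Imax = %.3f\n", x$Imax))
    }
    cat(sprintf("  RSS = %.3g over %d points", x$rss, x$n_points))
    if (x$excluded > 0) cat(sprintf(" (%d excluded)", x$excluded))
    cat("\n")
    if (length(x$constraints)) cat("  constraints:",
                                   paste(x$constraints, collapse = "; "), "\n")
  } else if (!is.na(x$message)) cat("  ", x$message, "\n")
  invisible(x)
}

#' Tidy one-row summary of a Hill fit
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy_hill_fit <- function(x, ...) {
  tibble::tibble(construct = x$construct, modality = x$modality,
                 replicate = as.character(x$replicate),
                 status = x$status, pH50 = x$pH50, nH = x$nH,
                 F0 = x$F0, dF_max = x$dF_max, Imax = x$Imax,
                 rss = x$rss, n_points = x$n_points)
}

.multistart_nls <- function(df, formula, starts, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = df, start = as.list(starts[i, , drop = FALSE]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    nh <- tryCatch(coef(fit)[["nH"]], error = function(e) NA_real_)
    if (is.null(best) || rss < best$rss - 1e-14 ||
        (abs(rss - best$rss) <= 1e-14 && !is.na(nh) && !is.na(best$nH) &&
         nh < best$nH)) {
      best <- list(fit = fit, rss = rss, nH = nh)
    }
  }
  best
}

.hill_prepare <- function(series, modality, exclude_below_pH) {
  stopifnot(inherits(series, "titration"))
  df <- tibble::as_tibble(series)
  df <- df[df$modality == modality & !df$is_reference, , drop = FALSE]
  if (nrow(df) == 0) stop("no ", modality, " points to fit", call. = FALSE)
  n_all <- nrow(df)
  if (!is.null(exclude_below_pH)) {
    df <- df[df$pH >= exclude_below_pH, , drop = FALSE]
  }
  df <- df[order(df$pH, decreasing = TRUE), , drop = FALSE]
  if (nrow(df) < 4) stop("fewer than 4 points after exclusions", call. = FALSE)
  df$h <- pH_to_conc(df$pH)
  list(df = df, excluded = n_all - nrow(df))
}

#' Fit the fluorescence Hill equation to one titration series
#'
#' Fits `y = F0 + dF_signed * h^nH / (h^nH + EC50^nH)` with `h = [H+]` by
#' multi-start trust-region least squares. `F0` is the fluorescence at the
#' low-proton plateau and `dF_signed` the signed amplitude (negative for
#' quenching, positive for de-quenching); the reported `dF_max` is its
#' absolute value. Points below `exclude_below_pH` (when given) are dropped
#' before fitting, the convention for constructs whose lowest-pH point
#' deviates in the direction opposite to the quenching curve. Bell-shaped
#' series (significant deviations of both signs) are flagged
#' `"not_fitted_bell"` and not fitted.
#'
#' @param series A normalized (F/F_SDS) `titration` object.
#' @param fix_nH Fix the Hill coefficient to this value.
#' @param nH_upper_bound Upper bound applied to `nH` (the returned `nH`
#'   equals the bound when it is active).
#' @param exclude_below_pH Drop points with pH strictly below this value
#'   (use 3.5 for the published convention); `NULL` keeps all points.
#' @param n_starts Number of log-spaced EC50 starting values (>= 5).
#' @return A `hill_fit` object.
#' @export
fit_hill_fluorescence <- function(series, fix_nH = NULL, nH_upper_bound = NULL,
                                  exclude_below_pH = NULL, n_starts = 7) {
  if (!isTRUE(attr(series, "normalized"))) {
    stop("fluorescence series must be normalized to F_SDS before fitting",
         call. = FALSE)
  }
  prep <- .hill_prepare(series, "fluorescence", exclude_below_pH)
  df <- prep$df
  constraints <- character()
  if (!is.null(exclude_below_pH)) {
    constraints <- c(constraints,
                     sprintf("points below pH %.2f excluded", exclude_below_pH))
  }
  if (.is_bell_shaped(df$pH, df$response)) {
    return(.new_hill_fit(
      c(EC50 = NA_real_, nH = NA_real_, F0 = NA_real_, dF_signed = NA_real_,
        Imax = NA_real_),
      NA_real_, nrow(df), constraints, "not_fitted_bell", "fluorescence",
      construct = df$construct[1], replicate = df$replicate[1],
      excluded = prep$excluded,
      message = "bell-shaped response: not fitted"))
  }
  # plateau direction: high-pH end versus low-pH end
  dF0 <- mean(utils::tail(df$response, 2)) - mean(utils::head(df$response, 2))
  lEC_starts <- seq(-max(df$pH) + 0.3, -min(df$pH) - 0.3,
                    length.out = max(5, n_starts))
  nH_upper <- if (!is.null(nH_upper_bound)) nH_upper_bound else 10
  nH_starts <- c(0.8, 1.5, min(3, nH_upper))
  starts <- expand.grid(F0 = mean(utils::head(df$response, 2)),
                        dF_signed = c(dF0, dF0 / 2),
                        lEC50 = lEC_starts, nH = nH_starts)
  if (!is.null(fix_nH)) {
    form <- stats::as.formula(sprintf(
      "response ~ F0 + dF_signed / (1 + (10^lEC50 / h)^%.12g)", fix_nH))
    starts$nH <- NULL
    lower <- c(F0 = -10, dF_signed = -10, lEC50 = -12)
    upper <- c(F0 = 10, dF_signed = 10, lEC50 = 0)
    constraints <- c(constraints, sprintf("nH fixed at %g", fix_nH))
  } else {
    form <- response ~ F0 + dF_signed / (1 + (10^lEC50 / h)^nH)
    lower <- c(F0 = -10, dF_signed = -10, lEC50 = -12, nH = 0.05)
    upper <- c(F0 = 10, dF_signed = 10, lEC50 = 0, nH = nH_upper)
    if (!is.null(nH_upper_bound)) {
      constraints <- c(constraints, sprintf("nH bounded below %g", nH_upper_bound))
    }
  }
  starts <- unique(starts)
  best <- .multistart_nls(df, form, starts, lower, upper)
  if (is.null(best)) {
    return(.new_hill_fit(
      c(EC50 = NA_real_, nH = NA_real_, F0 = NA_real_, dF_signed = NA_real_,
        Imax = NA_real_),
      NA_real_, nrow(df), constraints, "failed", "fluorescence",
      construct = df$construct[1], replicate = df$replicate[1],
      excluded = prep$excluded, message = "no start converged"))
  }
  cf <- coef(best$fit)
  nH_hat <- if (!is.null(fix_nH)) fix_nH else cf[["nH"]]
  if (!is.null(nH_upper_bound) && abs(nH_hat - nH_upper_bound) < 1e-6) {
    nH_hat <- nH_upper_bound  # bound active
  }
  .new_hill_fit(
    c(EC50 = 10^cf[["lEC50"]], nH = nH_hat, F0 = cf[["F0"]],
      dF_signed = cf[["dF_signed"]], Imax = NA_real_),
    best$rss, nrow(df), constraints, "ok", "fluorescence",
    construct = df$construct[1], replicate = df$replicate[1],
    excluded = prep$excluded)
}

#' Fit the current Hill equation to one titration series
#'
#' Fits `y = Imax * h^nH / (h^nH + EC50^nH)` to rundown-corrected,
#' normalized peak currents, `Imax` being the maximal current relative to
#' the reference-solution response.
#'
#' @param series A `titration` object (modality `"current"`, references
#'   already removed by [rundown_correct()]).
#' @inheritParams fit_hill_fluorescence
#' @return A `hill_fit` object. An all-zero (non-functional) series is an
#'   error.
#' @export
fit_hill_current <- function(series, fix_nH = NULL, nH_upper_bound = NULL,
                             n_starts = 7) {
  prep <- .hill_prepare(series, "current", NULL)
  df <- prep$df
  amp <- diff(range(df$response))
  if (max(abs(df$response)) < 1e-10 || amp < 1e-10 ||
      amp < 4 * .noise_estimate(df$response)) {
    stop("non-functional: current responses are flat or indistinguishable from noise",
         call. = FALSE)
  }
  constraints <- character()
  lEC_starts <- seq(-max(df$pH) + 0.3, -min(df$pH) - 0.3, length.out = max(5, n_starts))
  nH_upper <- if (!is.null(nH_upper_bound)) nH_upper_bound else 10
  starts <- expand.grid(Imax = max(df$response),
                        lEC50 = lEC_starts, nH = c(1, 2, min(3, nH_upper)))
  if (!is.null(fix_nH)) {
    form <- stats::as.formula(sprintf(
      "response ~ Imax / (1 + (10^lEC50 / h)^%.12g)", fix_nH))
    starts$nH <- NULL
    lower <- c(Imax = 0, lEC50 = -12)
    upper <- c(Imax = 100, lEC50 = 0)
    constraints <- c(constraints, sprintf("nH fixed at %g", fix_nH))
  } else {
    form <- response ~ Imax / (1 + (10^lEC50 / h)^nH)
    lower <- c(Imax = 0, lEC50 = -12, nH = 0.05)
    upper <- c(Imax = 100, lEC50 = 0, nH = nH_upper)
    if (!is.null(nH_upper_bound)) {
      constraints <- c(constraints, sprintf("nH bounded below %g", nH_upper_bound))
    }
  }
  starts <- unique(starts)
  best <- .multistart_nls(df, form, starts, lower, upper)
  if (is.null(best)) {
    return(.new_hill_fit(
      c(EC50 = NA_real_, nH = NA_real_, F0 = NA_real_, dF_signed = NA_real_,
        Imax = NA_real_),
      NA_real_, nrow(df), constraints, "failed", "current",
      construct = df$construct[1], replicate = df$replicate[1],
      message = "no start converged"))
  }
  cf <- coef(best$fit)
  nH_hat <- if (!is.null(fix_nH)) fix_nH else cf[["nH"]]
  if (!is.null(nH_upper_bound) && abs(nH_hat - nH_upper_bound) < 1e-6) {
    nH_hat <- nH_upper_bound
  }
  .new_hill_fit(
    c(EC50 = 10^cf[["lEC50"]], nH = nH_hat, F0 = NA_real_,
      dF_signed = NA_real_, Imax = cf[["Imax"]]),
    best$rss, nrow(df), constraints, "ok", "current",
    construct = df$construct[1], replicate = df$replicate[1],
    excluded = prep$excluded)
}

#' Midpoint shift between two fitted curves
#'
#' `delta_pH50(a, b) = pH50(a) - pH50(b)`, the signed shift of construct
#' `a` relative to `b` (conventionally the mutant minus its parent sensor).
#' Accepts `hill_fit` objects or bare pH50 numbers.
#'
#' @param fit_a,fit_b `hill_fit` objects or numeric pH50 values.
#' @return Signed shift in pH units.
#' @export
delta_pH50 <- function(fit_a, fit_b) {
  p <- function(x) {
    if (inherits(x, "hill_fit")) {
      if (!identical(x$status, "ok")) stop("fit is not valid (status: ",
                                           x$status, ")", call. = FALSE)
      x$pH50
    } else as.numeric(x)
  }
  p(fit_a) - p(fit_b)
}

.stars <- function(p) {
  if (is.na(p)) return("ND")
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' Compare per-replicate pH50 panels between groups
#'
#' Statistical comparison of per-replicate midpoints, either of each mutant
#' against its parent construct (`design = "vs-parent"`; Welch two-sample
#' t-tests with Holm adjustment across the mutant family, a documented
#' stand-in for the Dunnett procedure used with summary tables) or of the
#' fluorescence versus electrophysiological midpoints of each construct
#' (`design = "fluor-vs-electro"`; unpaired two-tailed Welch tests).
#' Groups with a single replicate report the difference with the test
#' marked `ND`.
#'
#' @param panel Tibble with columns `construct`, `modality`, `replicate`,
#'   `pH50`.
#' @param design `"vs-parent"` or `"fluor-vs-electro"`.
#' @param parent Parent construct id (required for `"vs-parent"`).
#' @param modality Modality analysed for `"vs-parent"` (default both,
#'   separately).
#' @return A tibble with the group means, differences, p-values (raw and
#'   Holm-adjusted where applicable) and significance stars binned at
#'   0.05 / 0.01 / 0.001 / 0.0001.
#' @export
compare_groups <- function(panel, design = c("vs-parent", "fluor-vs-electro"),
                           parent = NULL, modality = NULL) {
  design <- match.arg(design)
  panel <- tibble::as_tibble(panel)
  stopifnot(all(c("construct", "modality", "pH50") %in% names(panel)))
  welch <- function(x, y) {
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    stats::t.test(x, y)$p.value
  }
  if (design == "vs-parent") {
    if (is.null(parent)) stop("parent construct id required", call. = FALSE)
    mods <- if (is.null(modality)) unique(panel$modality) else modality
    out <- purrr::map_dfr(mods, function(m) {
      sub <- panel[panel$modality == m, ]
      ref <- sub$pH50[sub$construct == parent]
      if (length(ref) == 0) return(tibble::tibble())
      muts <- setdiff(unique(sub$construct), parent)
      res <- purrr::map_dfr(muts, function(ct) {
        g <- sub$pH50[sub$construct == ct]
        tibble::tibble(construct = ct, modality = m,
                       n = length(g), n_parent = length(ref),
                       mean = mean(g), parent_mean = mean(ref),
                       delta_pH50 = mean(g) - mean(ref),
                       p = welch(g, ref))
      })
      if (nrow(res) == 0) return(res)
      res$p_adj <- NA_real_
      ok <- !is.na(res$p)
      res$p_adj[ok] <- stats::p.adjust(res$p[ok], method = "holm")
      res$stars <- vapply(res$p_adj, .stars, character(1))
      res
    })
    attr(out, "method") <- "Welch t-tests, Holm-adjusted (stand-in for Dunnett)"
    out
  } else {
    cts <- unique(panel$construct)
    out <- purrr::map_dfr(cts, function(ct) {
      f <- panel$pH50[panel$construct == ct & panel$modality == "fluorescence"]
      e <- panel$pH50[panel$construct == ct & panel$modality == "current"]
      if (length(f) == 0 || length(e) == 0) return(tibble::tibble())
      tibble::tibble(construct = ct, n_fluor = length(f), n_electro = length(e),
                     delta_pH50 = mean(f) - mean(e),
                     p = welch(f, e))
    })
    out$stars <- vapply(out$p, .stars, character(1))
    attr(out, "method") <- "unpaired two-tailed Welch t-tests"
    out
  }
}
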