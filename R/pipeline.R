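#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]: the
#' construct roster with parent-sensor links and per-construct options, the
#' anchor values, seeds, and the output directory. Can be loaded from a
#' YAML or JSON file with the same structure.
#'
#' @param roster A named list, one entry per construct:
#'   `list(role = "sensor"|"anchor"|"mutant", parent = <sensor id or NA>,
#'   exclude_below_pH = <num or NULL>, two_state_only = <logical>)`.
#' @param optics A [sensor_optics()] (applies to the sensor background).
#' @param anchors Anchor `L_pA` values (first is the primary).
#' @param seed Integer seed for all stochastic steps.
#' @param output_dir Directory for report tables (created if needed);
#'   `NULL` disables writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(roster, optics, anchors = c(100, 1000),
                            seed = 1, output_dir = NULL) {
  if (length(roster) == 0) stop("construct roster is empty", call. = FALSE)
  roles <- vapply(roster, function(x) x$role %||% "mutant", character(1))
  if (sum(roles == "sensor") != 1) {
    stop("roster must contain exactly one sensor construct", call. = FALSE)
  }
  if (sum(roles == "anchor") != 1) {
    stop("roster must contain exactly one anchor (pore-opening-dead) construct",
         call. = FALSE)
  }
  sensor_id <- names(roster)[roles == "sensor"]
  for (nm in names(roster)[roles == "mutant"]) {
    parent <- roster[[nm]]$parent %||% sensor_id
    if (!parent %in% names(roster)) {
      stop(sprintf("mutant '%s' references unknown parent '%s'", nm, parent),
           call. = FALSE)
    }
    roster[[nm]]$parent <- parent
  }
  structure(list(roster = roster, optics = optics, anchors = anchors,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`). Optics are
#'   given as a mapping `optics: {F_R:, F_pA:, F_A:}`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  optics <- do.call(sensor_optics, as.list(raw$optics))
  pipeline_config(roster = raw$roster, optics = optics,
                  anchors = as.numeric(raw$anchors %||% c(100, 1000)),
                  seed = raw$seed %||% 1,
                  output_dir = raw$output_dir)
}

.write_table_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

#' Run the full titration-analysis pipeline
#'
#' End-to-end orchestration on a prepared data set: per-replicate Hill
#' fits of every construct and modality, a summary table in the shape of
#' the published per-construct table (midpoints, Hill coefficients,
#' amplitudes, midpoint shifts versus parent with significance stars), the
#' stepwise MWC calibration on the sensor/anchor pair, and per-mutant
#' isomerization-constant multiplication factors across all configured
#' anchors. Per-construct failures are collected, not fatal.
#'
#' @param config A [pipeline_config()].
#' @param data A `titration` object holding all constructs (raw scales:
#'   fluorescence with `f_sds`, currents with reference applications), or
#'   a path to a titration CSV.
#' @return A `pipeline_result` list: `hill_table` (summary tibble),
#'   `hill_fits` (per-replicate fits), `factors` (anchor x construct
#'   multiplication factors), `sensor_fits` (per anchor), `failures`
#'   (named character vector), `log` (character). Tables are also written
#'   to `config$output_dir` when set (`table1.csv`, `factors.csv`,
#'   `predicted_<construct>.csv`, `run_log.txt`).
#' @export
run_pipeline <- function(config, data) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(data)) data <- read_titration(data)
  stopifnot(inherits(data, "titration"))
  log <- c(sprintf("run_pipeline seed=%d anchors=%s", config$seed,
                   paste(config$anchors, collapse = ",")),
           sprintf("constructs: %s", paste(names(config$roster), collapse = ", ")))
  failures <- character()
  roster <- config$roster
  roles <- vapply(roster, function(x) x$role %||% "mutant", character(1))
  sensor_id <- names(roster)[roles == "sensor"]
  anchor_id <- names(roster)[roles == "anchor"]

  # --- prep: normalize fluorescence, rundown-correct currents ------------
  prep <- list()
  for (nm in names(roster)) {
    sub <- data[data$construct == nm, , drop = FALSE]
    if (nrow(sub) == 0) {
      failures[nm] <- "no data"
      next
    }
    sub <- titration_series(sub, normalized = attr(data, "normalized"))
    entry <- list(fluor = NULL, currents = list())
    fl <- sub[sub$modality == "fluorescence", , drop = FALSE]
    if (nrow(fl) > 0) {
      fl <- titration_series(fl, normalized = attr(data, "normalized"))
      entry$fluor <- tryCatch(
        if (isTRUE(attr(fl, "normalized"))) fl else normalize_fluorescence(fl),
        error = function(e) {
          failures[nm] <<- conditionMessage(e); NULL
        })
    }
    cu <- sub[sub$modality == "current", , drop = FALSE]
    if (nrow(cu) > 0) {
      cu <- titration_series(cu, normalized = FALSE)
      entry$currents <- purrr::map(split_series(cu), function(s) {
        tryCatch(rundown_correct(s), error = function(e) NULL)
      })
      entry$currents <- purrr::compact(entry$currents)
    }
    prep[[nm]] <- entry
  }

  # --- per-replicate Hill fits ------------------------------------------
  hill_fits <- list()
  for (nm in names(prep)) {
    opts <- roster[[nm]]
    excl <- opts$exclude_below_pH %||% NULL
    if (!is.null(prep[[nm]]$fluor)) {
      for (s in split_series(prep[[nm]]$fluor)) {
        fit <- tryCatch(
          fit_hill_fluorescence(s, exclude_below_pH = excl,
                                nH_upper_bound = opts$nH_upper_bound %||% NULL,
                                fix_nH = opts$fix_nH_fluor %||% NULL),
          error = function(e) NULL)
        if (!is.null(fit)) hill_fits[[length(hill_fits) + 1]] <- fit
      }
    }
    for (s in prep[[nm]]$currents) {
      fit <- tryCatch(
        fit_hill_current(s, fix_nH = opts$fix_nH_current %||% NULL),
        error = function(e) NULL)
      if (!is.null(fit)) hill_fits[[length(hill_fits) + 1]] <- fit
    }
  }
  per_fit <- purrr::map_dfr(hill_fits, tidy_hill_fit)
  per_fit <- per_fit[per_fit$status == "ok", , drop = FALSE]

  # --- Table-1-shaped summary -------------------------------------------
  hill_table <- dplyr::summarise(
    dplyr::group_by(per_fit, construct, modality),
    pH50_mean = mean(pH50), pH50_sd = stats::sd(pH50),
    nH_mean = mean(nH), nH_sd = stats::sd(nH),
    F0_mean = mean(F0), dF_max_mean = mean(dF_max),
    Imax_mean = mean(Imax), n = dplyr::n(), .groups = "drop")
  parent_of <- function(nm) {
    if (nm %in% c(sensor_id)) NA_character_ else roster[[nm]]$parent %||% sensor_id
  }
  hill_table$parent <- vapply(hill_table$construct, parent_of, character(1))
  hill_table$delta_pH50 <- NA_real_
  for (i in seq_len(nrow(hill_table))) {
    p <- hill_table$parent[i]
    if (is.na(p)) next
    j <- which(hill_table$construct == p &
                 hill_table$modality == hill_table$modality[i])
    if (length(j) == 1) {
      hill_table$delta_pH50[i] <- hill_table$pH50_mean[i] - hill_table$pH50_mean[j]
    }
  }
  stats_tbl <- tryCatch(
    compare_groups(per_fit, "vs-parent", parent = sensor_id),
    error = function(e) NULL)
  if (!is.null(stats_tbl) && nrow(stats_tbl) > 0) {
    hill_table <- dplyr::left_join(
      hill_table,
      stats_tbl[, c("construct", "modality", "p_adj", "stars")],
      by = c("construct", "modality"))
  }

  # --- MWC calibration + mutant factors ---------------------------------
  fit_cfg <- fit_config(anchor_L_pA = config$anchors[1],
                        alternates = config$anchors[-1], seed = config$seed)
  pool_currents <- function(entry) {
    if (length(entry$currents) == 0) return(NULL)
    pooled <- dplyr::bind_rows(lapply(entry$currents, tibble::as_tibble))
    normalize_current_to_max(titration_series(pooled, normalized = FALSE))
  }
  panel <- list(anchor_fluor = prep[[anchor_id]]$fluor,
                sensor_fluor = prep[[sensor_id]]$fluor,
                sensor_current = pool_currents(prep[[sensor_id]]),
                optics = config$optics,
                mutants = list())
  for (nm in names(prep)[roles[names(prep)] == "mutant"]) {
    two_state <- isTRUE(roster[[nm]]$two_state_only) ||
      length(prep[[nm]]$currents) == 0
    panel$mutants[[nm]] <- list(
      fluor = prep[[nm]]$fluor,
      current = if (two_state) NULL else pool_currents(prep[[nm]]))
  }
  factors <- tryCatch(sensitivity_scan(panel, fit_cfg),
                      error = function(e) {
                        failures["(mwc)"] <- conditionMessage(e)
                        tibble::tibble()
                      })

  # --- predicted curves + outputs ---------------------------------------
  predicted <- list()
  if (nrow(factors) > 0) {
    main <- factors[factors$anchor == config$anchors[1] &
                      factors$construct == "(sensor)", , drop = FALSE]
    if (nrow(main) == 1 && !is.na(main$L_pA)) {
      sensor_params <- mwc_params(K_R = main$K_R, K_pA = main$K_pA,
                                  K_A = main$K_pA, K_Rp = main$K_Rp,
                                  K_pAp = main$K_Rp, K_Ap = main$K_Ap,
                                  L_pA = main$L_pA, L_A = main$L_A)
      grid <- seq(8, 3, by = -0.1)
      for (nm in c(sensor_id, names(panel$mutants))) {
        row <- factors[factors$anchor == config$anchors[1] &
                         factors$construct == ifelse(nm == sensor_id, "(sensor)", nm), ]
        if (nrow(row) != 1 || is.na(row$f_L_pA)) next
        p <- mwc_params(K_R = sensor_params$K_R, K_pA = sensor_params$K_pA,
                        K_A = sensor_params$K_A, K_Rp = sensor_params$K_Rp,
                        K_pAp = sensor_params$K_pAp, K_Ap = sensor_params$K_Ap,
                        L_pA = row$f_L_pA * sensor_params$L_pA,
                        L_A = if (is.na(row$f_L_A)) 1e12
                              else row$f_L_A * sensor_params$L_A)
        predicted[[nm]] <- list(
          fluorescence = fluorescence_response(p, config$optics, grid),
          current = current_response(p, grid, "none"))
      }
    }
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    .write_table_with_header(
      hill_table, file.path(config$output_dir, "table1.csv"),
      c("per-construct Hill-fit summary (per-replicate fits averaged)",
        sprintf("seed %d", config$seed)))
    .write_table_with_header(
      factors, file.path(config$output_dir, "factors.csv"),
      c("isomerization-constant multiplication factors vs parent sensor",
        sprintf("anchors: %s", paste(config$anchors, collapse = ", "))))
    for (nm in names(predicted)) {
      write_model_curve(predicted[[nm]]$fluorescence,
                        file.path(config$output_dir,
                                  sprintf("predicted_%s_fluorescence.csv", nm)))
      write_model_curve(predicted[[nm]]$current,
                        file.path(config$output_dir,
                                  sprintf("predicted_%s_current.csv", nm)))
    }
    writeLines(c(log, sprintf("failures: %d", length(failures)),
                 paste(names(failures), unname(failures), sep = ": ")),
               file.path(config$output_dir, "run_log.txt"))
  }

  structure(list(hill_table = hill_table, hill_fits = hill_fits,
                 factors = factors, predicted = predicted,
                 failures = failures, log = log,
                 status = if (length(failures) == 0) 0L else 2L),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> status %d (%d construct failures)\n",
              x$status, length(x$failures)))
  cat(sprintf("  %d Hill fits, %d factor rows\n",
              length(x$hill_fits), nrow(x$factors)))
  invisible(x)
}
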