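#' Titration series container
#'
#' A `titration` object is a tibble of (pH, response) points for one or more
#' constructs/replicates with the columns `construct`, `modality`
#' (`"fluorescence"` or `"current"`), `replicate`, `order` (application
#' index), `pH`, `response`, `is_reference` (current only; reference-pH
#' applications used for rundown correction) and `f_sds` (fluorescence only;
#' fluorescence of the SDS-denatured protein, arbitrary units).
#' Normalization state and provenance notes are carried as attributes.
#'
#' @param df A data frame with the columns above (missing optional columns
#'   are filled: `is_reference` with `FALSE`, `f_sds` with `NA`).
#' @param normalized Whether fluorescence responses are already on the
#'   F/F_SDS scale.
#' @param provenance Character vector of free-text processing notes.
#' @return A `titration` tibble.
#' @export
titration_series <- function(df, normalized = FALSE, provenance = character()) {
  df <- tibble::as_tibble(df)
  if (!"is_reference" %in% names(df)) df$is_reference <- FALSE
  if (!"f_sds" %in% names(df)) df$f_sds <- NA_real_
  required <- c("construct", "modality", "replicate", "order", "pH", "response")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing titration columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$is_reference[is.na(df$is_reference)] <- FALSE
  .validate_titration(df)
  structure(df, class = c("titration", class(df)),
            normalized = isTRUE(normalized),
            provenance = as.character(provenance))
}

.validate_titration <- function(df) {
  if (any(!df$modality %in% c("fluorescence", "current"))) {
    stop("modality must be 'fluorescence' or 'current'", call. = FALSE)
  }
  if (any(!is.finite(df$pH)) || any(df$pH < 0) || any(df$pH > 14)) {
    stop("pH values must lie in [0, 14]", call. = FALSE)
  }
  fl <- df$modality == "fluorescence"
  if (any(fl) && any(!is.na(df$f_sds[fl]) & df$f_sds[fl] <= 0)) {
    stop("F_SDS must be positive for fluorescence series", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("<titration> %d points, %d series; normalized: %s\n",
              nrow(x),
              nrow(unique(x[, c("construct", "modality", "replicate")])),
              attr(x, "normalized")))
  prov <- attr(x, "provenance")
  if (length(prov) > 0) cat("  provenance:", paste(prov, collapse = "; "), "\n")
  NextMethod()
}

.add_provenance <- function(series, note) {
  attr(series, "provenance") <- c(attr(series, "provenance"), note)
  series
}

#' Split a titration table into single series
#'
#' @param series A `titration` object.
#' @return Named list of `titration` objects, one per
#'   (construct, modality, replicate).
#' @export
split_series <- function(series) {
  key <- interaction(series$construct, series$modality, series$replicate,
                     drop = TRUE, sep = "/")
  lapply(split(seq_len(nrow(series)), key), function(i) {
    titration_series(series[i, , drop = FALSE],
                     normalized = attr(series, "normalized"),
                     provenance = attr(series, "provenance"))
  })
}

#' Read a titration CSV/TSV file
#'
#' Expects the columns `construct`, `modality`, `replicate`, `order`, `pH`,
#' `response`, `is_reference`, `f_sds` (the two last may be omitted).
#' Schema violations are reported with line numbers.
#'
#' @param path Delimited text file; delimiter inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @param normalized Whether fluorescence responses in the file are already
#'   on the F/F_SDS scale.
#' @return A `titration` object.
#' @export
read_titration <- function(path, normalized = FALSE) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          comment = "#")
  required <- c("construct", "modality", "replicate", "order", "pH", "response")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("order", "pH", "response", "f_sds")) {
    if (col %in% names(df) && !is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))
      stop(sprintf("%s: column '%s' is not numeric (first offending data line: %d)",
                   path, col, if (length(bad)) bad[1] + 1L else NA_integer_),
           call. = FALSE)
    }
  }
  bad_mod <- which(!df$modality %in% c("fluorescence", "current"))
  if (length(bad_mod) > 0) {
    stop(sprintf("%s: invalid modality '%s' at data line %d", path,
                 df$modality[bad_mod[1]], bad_mod[1] + 1L), call. = FALSE)
  }
  bad_ph <- which(!is.finite(df$pH) | df$pH < 0 | df$pH > 14)
  if (length(bad_ph) > 0) {
    stop(sprintf("%s: pH out of [0, 14] at data line %d", path, bad_ph[1] + 1L),
         call. = FALSE)
  }
  titration_series(df, normalized = normalized,
                   provenance = sprintf("read from %s", basename(path)))
}

#' Write a titration table to CSV
#'
#' @param series A `titration` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path)
  invisible(path)
}
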