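#' Published pH-dependence summary of the GLIC sensor/mutant panel
#'
#' Per-construct mean and standard deviation of the midpoint pH (`pH50`),
#' Hill coefficient (`nH`), high-pH fluorescence plateau (`F0`) and
#' absolute fluorescence amplitude (`dF_max`) for the bimane-labeled GLIC
#' constructs, transcribed from the published summary of individual curve
#' fits. `modality` is `"current"` (two-electrode voltage clamp in
#' oocytes) or `"fluorescence"` (steady-state quenching on purified
#' protein, F/F_SDS scale). Non-functional constructs (`NF`) carry `NA`
#' current entries. `parent` names the reference construct against which
#' published midpoint shifts are computed.
#'
#' @return A tibble with columns `construct`, `parent`, `modality`,
#'   `pH50`, `pH50_sd`, `nH`, `nH_sd`, `n`, `F0`, `F0_sd`, `dF_max`,
#'   `dF_max_sd`.
#' @export
#' @examples
#' t1 <- glic_table1()
#' # midpoint shift of E26Q relative to its parent sensor, by modality
#' subset(t1, construct %in% c("Bim136-Q101W", "E26Q"))
glic_table1 <- function() {
  tribble <- tibble::tribble
  electro <- tribble(
    ~construct,        ~parent,         ~pH50, ~pH50_sd, ~nH,  ~nH_sd, ~n,
    "Bim136-Q101W",    NA,              5.42,  0.08,     2.68, 0.33,   10,
    "E26Q",            "Bim136-Q101W",  4.83,  0.12,     2.98, 0.64,   6,
    "Y28F",            "Bim136-Q101W",  3.88,  0.08,     2.63, 0.68,   3,
    "Y28F-C27",        "Bim136-Q101W",  5.34,  0.11,     2.03, 0.12,   6,
    "D32E",            "Bim136-Q101W",  4.65,  0.12,     2.62, 1.51,   6,
    "E222Q",           "Bim136-Q101W",  4.68,  0.09,     2.51, 0.33,   5,
    "H235Q",           "Bim136-Q101W",  4.04,  0.21,     1.19, 0.31,   6,
    "propofol",        "Bim136-Q101W",  5.16,  0.13,     2.5,  NA,     3,
    "H235Q+propofol",  "H235Q",         4.71,  0.15,     1.53, 0.48,   6,
    "H235F",           "Bim136-Q101W",  NA,    NA,       NA,   NA,     3,
    "L157A",           "Bim136-Q101W",  NA,    NA,       NA,   NA,     3,
    "L246A",           "Bim136-Q101W",  NA,    NA,       NA,   NA,     3,
    "Bim250-Y197",     "Bim136-Q101W",  4.66,  0.18,     2.20, 0.54,   12)
  electro$modality <- "current"
  electro$F0 <- NA_real_; electro$F0_sd <- NA_real_
  electro$dF_max <- NA_real_; electro$dF_max_sd <- NA_real_

  fluor <- tribble(
    ~construct,         ~parent,        ~pH50, ~pH50_sd, ~F0,  ~F0_sd, ~dF_max, ~dF_max_sd, ~nH,  ~nH_sd, ~n,
    "Bim136-Q101W",     NA,             5.85,  0.21,     0.71, 0.03,   0.45,    0.06,       0.77, 0.18,   17,
    "E26Q",             "Bim136-Q101W", 5.28,  0.34,     0.53, 0.02,   0.22,    0.02,       1.13, 0.27,   4,
    "Y28F",             "Bim136-Q101W", 3.68,  0.34,     0.70, 0.01,   0.38,    0.09,       3.0,  NA,     3,
    "D32E",             "Bim136-Q101W", 5.52,  0.05,     0.68, 0.02,   0.38,    0.01,       0.75, 0.05,   3,
    "E222Q",            "Bim136-Q101W", 5.36,  0.14,     0.66, 0.03,   0.40,    0.04,       0.74, 0.18,   3,
    "H235Q",            "Bim136-Q101W", 5.00,  0.09,     0.70, 0.01,   0.42,    0.01,       0.78, 0.10,   3,
    "propofol",         "Bim136-Q101W", 5.33,  0.06,     0.67, 0.02,   0.38,    0.01,       1.21, 0.21,   4,
    "H235Q+propofol",   "H235Q",        5.67,  0.14,     0.70, 0.01,   0.43,    0.01,       1.25, 0.04,   3,
    "H235F",            "Bim136-Q101W", 5.25,  0.08,     0.70, 0.05,   0.38,    0.04,       1.06, 0.17,   3,
    "L157A",            "Bim136-Q101W", 5.42,  0.65,     0.67, 0.01,   0.19,    0.09,       0.71, 0.46,   4,
    "L246A",            "Bim136-Q101W", 4.87,  0.14,     0.65, 0.01,   0.24,    0.01,       0.79, 0.12,   3,
    "Bim250-Y197",      "Bim136-Q101W", 5.83,  0.17,     0.59, 0.04,   0.33,    0.09,       1.19, 0.28,   8,
    "H235F (Bim250)",   "Bim250-Y197",  5.40,  0.13,     0.54, 0.01,   0.20,    0.01,       1.16, 0.15,   4,
    "L157A (Bim250)",   "Bim250-Y197",  5.81,  0.19,     0.49, 0.06,   0.45,    0.07,       0.64, 0.19,   3,
    "L246A (Bim250)",   "Bim250-Y197",  5.53,  0.03,     0.64, 0.01,   0.30,    0.01,       1.69, 0.29,   3)
  fluor$modality <- "fluorescence"

  cols <- c("construct", "parent", "modality", "pH50", "pH50_sd", "nH",
            "nH_sd", "n", "F0", "F0_sd", "dF_max", "dF_max_sd")
  dplyr::bind_rows(electro[cols], fluor[cols])
}

#' Published isomerization-constant multiplication factors
#'
#' Fold-changes of the pre-activation (`f_L_pA`) and activation (`f_L_A`)
#' isomerization constants of four moderate loss-of-function mutants
#' relative to the Bim136-Q101W parent sensor, as reported for the
#' anchored three-state fit.
#'
#' @return A tibble (`construct`, `f_L_pA`, `f_L_A`).
#' @export
glic_published_factors <- function() {
  tibble::tribble(
    ~construct, ~f_L_pA, ~f_L_A,
    "E26Q",     15,      10,
    "D32E",     2,       80,
    "H235Q",    1.5,     40,
    "E222Q",    7,       700)
}
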