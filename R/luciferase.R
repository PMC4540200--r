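#' Renilla/firefly normalization
#'
#' Per well, renilla (reporter) luminescence normalized to firefly
#' (transfection control): `rl / fl`.
#'
#' @param wells Well tibble with columns `rl` and `fl` (and ideally
#'   `construct`, `condition`, `bio_rep`, `tech_rep`).
#' @return The input tibble with a `ratio` column added.
#' @export
rl_fl_ratio <- function(wells) {
  stopifnot(is.data.frame(wells), all(c("rl", "fl") %in% names(wells)))
  bad <- which(wells$fl <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive firefly reading in well row(s): ",
                 paste(bad, collapse = ", ")),
          class = "placentamir_data_error")
  }
  if (any(wells$rl < 0)) {
    abort("negative renilla reading", class = "placentamir_data_error")
  }
  mutate(as_tibble(wells), ratio = .data$rl / .data$fl)
}

# collapse technical replicates: mean RL/FL ratio per biological replicate
per_bio_ratios <- function(wells) {
  rl_fl_ratio(wells) |>
    group_by(.data$condition, .data$bio_rep) |>
    summarise(ratio = mean(.data$ratio), .groups = "drop")
}

#' Percent repression of a reporter under FSK
#'
#' `100 * (1 - center(FSK ratios) / center(DMSO ratios))`, where RL/FL ratios
#' are first averaged over technical replicates within each biological
#' replicate and then centered (mean by default, median by flag) across
#' biological replicates. Invariant under rescaling all readings by a common
#' positive factor; 0 when the two conditions are identical; 100 exactly when
#' every FSK renilla reading is zero.
#'
#' @param wells Well tibble with `condition` (`"FSK"`/`"DMSO"`), `bio_rep`,
#'   `rl`, `fl`.
#' @param center `"mean"` (default) or `"median"`.
#' @return Percent repression (a single number).
#' @export
percent_repression <- function(wells, center = c("mean", "median")) {
  center <- match.arg(center)
  bio <- per_bio_ratios(wells)
  fsk <- bio$ratio[bio$condition == "FSK"]
  dmso <- bio$ratio[bio$condition == "DMSO"]
  if (length(fsk) < 1 || length(dmso) < 1) {
    abort("need at least one well per condition", class = "placentamir_data_error")
  }
  f <- if (center == "mean") mean else median
  if (f(dmso) <= 0) {
    abort("DMSO center must be positive", class = "placentamir_data_error")
  }
  100 * (1 - f(fsk) / f(dmso))
}

#' Test FSK vs DMSO reporter activity
#'
#' Two-sided Mann-Whitney comparison of per-biological-replicate RL/FL ratios
#' (technical replicates are averaged first, so the sample size is the number
#' of biological replicates).
#'
#' @param wells Well tibble (see [percent_repression()]).
#' @param mode Mann-Whitney mode (default `"auto"`).
#' @return A `group_comparison`; `direction > 0` means FSK ratios are higher.
#' @export
condition_test <- function(wells, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  bio <- per_bio_ratios(wells)
  fsk <- bio$ratio[bio$condition == "FSK"]
  dmso <- bio$ratio[bio$condition == "DMSO"]
  if (length(fsk) < 2 || length(dmso) < 2) {
    abort("need at least two biological replicates per condition",
          class = "placentamir_parameter_error")
  }
  mann_whitney(fsk, dmso, mode)
}
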