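#' Filter samples by RNA integrity number
#'
#' Retains only samples with RIN strictly greater than the threshold
#' (default 7.5), the standard quality gate for placental RNA.
#'
#' @param samples Sample tibble with an `rin` column.
#' @param threshold RIN threshold; retention requires `rin > threshold`.
#' @return The retained rows, with attribute `n_removed` giving the number of
#'   distinct placenta pieces removed.
#' @export
rin_filter <- function(samples, threshold = 7.5) {
  stopifnot(is.data.frame(samples), "rin" %in% names(samples))
  keep <- samples$rin > threshold
  out <- samples[keep, , drop = FALSE]
  removed <- samples[!keep, , drop = FALSE]
  n_rem <- if ("piece_id" %in% names(samples)) {
    length(unique(removed$piece_id))
  } else {
    sum(!keep)
  }
  attr(out, "n_removed") <- n_rem
  out
}

#' Relative expression from a delta-Ct
#'
#' Standard efficiency-1 relative quantification: `2^-(Ct_target -
#' Ct_reference)`. Lower target Ct than the reference means higher abundance.
#'
#' @param ct_target,ct_reference Ct values (cycles); vectorized.
#' @return Relative abundance (linear scale).
#' @export
#' @examples
#' relative_expression(25, 20)  # 2^-5
relative_expression <- function(ct_target, ct_reference) {
  2^-(ct_target - ct_reference)
}

#' Aggregate a cohort sample sheet to per-unit relative expression
#'
#' Collapses technical replicates by median, computes each piece's relative
#' expression of `target` against `reference_target`
#' (`2^-(Ct_target - Ct_ref)` on the technical medians), then either averages
#' pieces within each placenta (`unit = "placenta"`, the default, avoiding
#' pseudoreplication) or keeps pieces as separate observations
#' (`unit = "piece"`).
#'
#' @param samples Long sample sheet (`placenta_id`, `group`, `piece_id`,
#'   `target`, `tech_rep`, `ct`).
#' @param target,reference_target Target names present in the panel.
#' @param unit `"placenta"` or `"piece"`.
#' @return Tibble `placenta_id`, `group` (and `piece_id` for unit "piece"),
#'   `rel_expr`.
#' @export
aggregate_expression <- function(samples, target, reference_target = "U6",
                                 unit = c("placenta", "piece")) {
  unit <- match.arg(unit)
  needed <- c(target, reference_target)
  sub <- samples[samples$target %in% needed, , drop = FALSE]
  med <- sub |>
    group_by(.data$placenta_id, .data$group, .data$piece_id, .data$target) |>
    summarise(ct = median(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(med, names_from = "target", values_from = "ct")
  if (!all(needed %in% names(wide)) || anyNA(wide[needed])) {
    bad <- if (!all(needed %in% names(wide))) "all samples" else {
      paste(wide$piece_id[!stats::complete.cases(wide[needed])], collapse = ", ")
    }
    abort(paste0("missing target or reference Ct for: ", bad),
          class = "placentamir_data_error")
  }
  wide$rel_expr <- relative_expression(wide[[target]], wide[[reference_target]])
  per_piece <- wide[c("placenta_id", "group", "piece_id", "rel_expr")]
  if (unit == "piece") return(as_tibble(per_piece))
  per_piece |>
    group_by(.data$placenta_id, .data$group) |>
    summarise(rel_expr = mean(.data$rel_expr), .groups = "drop")
}

#' Mann-Whitney (Wilcoxon rank-sum) two-group comparison
#'
#' The U statistic is computed from rank sums with midranks for ties. The
#' p-value is exact (full-enumeration null) when requested, or automatically
#' when `n1 + n2 <= 12` and the data are tie-free; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided throughout. When every value in both groups is identical the
#' p-value is 1 by convention.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return A `group_comparison` object (list with `u_statistic`, `p_value`,
#'   `n1`, `n2`, `direction`), with [tidy()] and [glance()] methods.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    abort("both groups need at least one value", class = "placentamir_parameter_error")
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    p <- 1
  } else {
    use_exact <- switch(mode,
                        exact = TRUE,
                        asymptotic = FALSE,
                        auto = (n1 + n2 <= 12) && !ties)
    if (use_exact && ties) {
      abort("exact mode requires tie-free data", class = "placentamir_data_error")
    }
    p <- suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value
    )
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(list(u_statistic = u, p_value = p, n1 = n1, n2 = n2,
                 direction = sign(median(x) - median(y)), mode = mode),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney comparison: U = %.1f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$u_statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Five-number box summary with 5th/95th percentile whiskers
#'
#' Percentiles are computed by linear interpolation between order statistics
#' (the inclusive method), so `P5 <= Q1 <= median <= Q3 <= P95` always holds.
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble: `median`, `q1`, `q3`, `p5`, `p95`, `n`.
#' @export
box_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values))) {
    abort("box_summary needs at least one value", class = "placentamir_data_error")
  }
  q <- quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE, type = 7)
  tibble(median = q[[3]], q1 = q[[2]], q3 = q[[4]], p5 = q[[1]], p95 = q[[5]],
         n = sum(!is.na(values)))
}

#' Classify patients against the severe-preeclampsia eligibility rule
#'
#' Severe preeclampsia requires both: a qualifying blood pressure (at least
#' two readings meeting the 160/100 mmHg threshold separated by at least six
#' hours) and qualifying proteinuria (dipstick grade >= 2+ recorded at least
#' twice within a 24-hour window). By the standard obstetric convention a BP
#' reading qualifies when systolic >= 160 OR diastolic >= 100; set
#' `bp_rule = "and"` to require both in the same reading.
#'
#' @param patients Patient tibble with list-columns `bp_readings` (tibbles
#'   with `time` in hours, `systolic`, `diastolic`) and `proteinuria_readings`
#'   (tibbles with `time`, `dipstick_grade`), e.g. from [simulate_cohort()].
#' @param bp_rule `"or"` (default) or `"and"`.
#' @return Logical vector, one element per patient row.
#' @export
classify_severe_pe <- function(patients, bp_rule = c("or", "and")) {
  bp_rule <- match.arg(bp_rule)
  stopifnot(is.data.frame(patients),
            all(c("bp_readings", "proteinuria_readings") %in% names(patients)))
  purrr::map2_lgl(patients$bp_readings, patients$proteinuria_readings,
                  function(bp, prot) {
    qual_bp <- if (bp_rule == "or") {
      bp$systolic >= 160 | bp$diastolic >= 100
    } else {
      bp$systolic >= 160 & bp$diastolic >= 100
    }
    t_bp <- sort(bp$time[qual_bp])
    bp_ok <- length(t_bp) >= 2 && (max(t_bp) - min(t_bp)) >= 6
    t_pr <- sort(prot$time[prot$dipstick_grade >= 2])
    prot_ok <- length(t_pr) >= 2 && any(diff(t_pr) <= 24)
    bp_ok && prot_ok
  })
}

#' miR210/miR455 ratio biomarker score
#'
#' Linear-space abundance ratio of miR210 over miR455 computed from their Ct
#' values: `2^(Ct_miR455 - Ct_miR210)`. Because miR210 rises and miR455 falls
#' in preeclamptic placenta, the two effects add and the ratio separates the
#' groups more strongly than either single marker. A delta-Ct variant
#' (`Ct_miR455 - Ct_miR210`, the log2 of the same score) gives identical ROC
#' behaviour since monotone transforms leave rank-based measures unchanged.
#'
#' @param ct_mir210,ct_mir455 Ct values (cycles); vectorized.
#' @return Ratio score (higher in preeclampsia).
#' @export
#' @examples
#' ratio_score(24, 27)  # 2^3 = 8
ratio_score <- function(ct_mir210, ct_mir455) {
  2^(ct_mir455 - ct_mir210)
}

#' ROC curve and AUC of a biomarker score
#'
#' The AUC is computed via the rank-statistic identity `AUC = U / (n1 * n2)`
#' with midrank tie handling, where `U` is the Mann-Whitney statistic of the
#' positive-class scores; the curve is traced at every distinct threshold.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical (TRUE = positive class) or a vector coercible to it.
#' @return A `roc_curve` object: list with `auc`, `points` (tibble `threshold`,
#'   `tpr`, `fpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present", class = "placentamir_data_error")
  }
  r <- rank(scores)
  u <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1)))
  )
  structure(list(auc = auc, points = pts, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Full cohort comparison for one target
#'
#' The complete placenta-cohort pipeline for a single target: RIN quality
#' filter, technical-median delta-Ct relative expression against the reference
#' target, per-placenta (or per-piece) aggregation, then a two-sided
#' Mann-Whitney comparison of the PE and control groups.
#'
#' @param samples Long sample sheet (see [simulate_cohort()]).
#' @param target Target miRNA/gene to test.
#' @param reference_target Normalizer (default `"U6"`).
#' @param unit Observation unit, `"placenta"` (default) or `"piece"`.
#' @param rin_threshold RIN gate (default 7.5).
#' @param mode Mann-Whitney mode (default `"auto"`).
#' @return A `group_comparison` with extra fields `target`, `unit`,
#'   `n_removed_rin`; `direction > 0` means the PE median is higher.
#' @export
compare_cohort <- function(samples, target, reference_target = "U6",
                           unit = c("placenta", "piece"), rin_threshold = 7.5,
                           mode = c("auto", "exact", "asymptotic")) {
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  filtered <- rin_filter(samples, rin_threshold)
  agg <- aggregate_expression(filtered, target, reference_target, unit)
  res <- mann_whitney(agg$rel_expr[agg$group == "PE"],
                      agg$rel_expr[agg$group == "CONTROL"], mode)
  res$target <- target
  res$unit <- unit
  res$n_removed_rin <- attr(filtered, "n_removed")
  res
}
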