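# broom-style tidiers for the package's result objects

#' Tidy a Mann-Whitney group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble: `u_statistic`, `p_value`, `n1`, `n2`, `direction`
#'   (and `target` when present).
#' @export
tidy.group_comparison <- function(x, ...) {
  out <- tibble(u_statistic = x$u_statistic, p_value = x$p_value,
                n1 = x$n1, n2 = x$n2, direction = x$direction)
  if (!is.null(x$target)) out <- mutate(out, target = x$target, .before = 1)
  out
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tidy(x, ...)
}

#' Tidy a condition comparison
#'
#' @param x A `mirna_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return Tibble with one row per miRNA: `name`, `mean_log2fc`,
#'   `consistently_deregulated`, `direction`.
#' @export
tidy.mirna_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.mirna_comparison
#' @export
glance.mirna_comparison <- function(x, ...) {
  tibble(n_mirna = nrow(x),
         n_flagged = sum(x$consistently_deregulated),
         fc_threshold_log2 = attr(x, "fc_threshold_log2"),
         n_pairs = attr(x, "n_pairs"))
}

#' Tidy a ROC curve
#'
#' @param x A `roc_curve` from [roc_auc()].
#' @param ... Unused.
#' @return The curve points tibble (`threshold`, `tpr`, `fpr`).
#' @export
tidy.roc_curve <- function(x, ...) {
  x$points
}

#' @rdname tidy.roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
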