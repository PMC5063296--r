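# broom-style tidiers for the selection report.

#' Tidy a selection report
#'
#' @param x A `selection_report` from [select_parameters()].
#' @param ... Unused.
#' @return The per-parameter verdict tibble: category, reproducibility
#'   summary, sensitivity score and per-criterion / final pass flags.
#' @method tidy selection_report
#' @export
tidy.selection_report <- function(x, ...) {
  x$verdicts
}

#' Glance at a selection report
#'
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return One-row tibble: `n_parameters`, `n_volume_independent` (category
#'   A, CoV included), `n_matrix_converging` (category A among the 26
#'   matrix-based parameters), `n_reproducible`, `n_sensitive`, `n_selected`.
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  v <- x$verdicts
  tibble(
    n_parameters = nrow(v),
    n_volume_independent = sum(v$volume_ok),
    n_matrix_converging = sum(v$volume_ok & v$parameter != "CoV"),
    n_reproducible = sum(v$repro_ok),
    n_sensitive = sum(v$sensitivity_ok),
    n_selected = sum(v$selected)
  )
}

#' @rdname tidy.selection_report
#' @method tidy study_result
#' @export
tidy.study_result <- function(x, ...) tidy(x$report)

#' @rdname glance.selection_report
#' @method glance study_result
#' @export
glance.study_result <- function(x, ...) glance(x$report)
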