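#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model summary, in the broom convention.
#'
#' @param x A `decay_fit`, `test_plan`, `stat_result` or `run_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name endokin-tidiers
NULL

#' @rdname endokin-tidiers
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = "tau", estimate = x$tau)
}

#' @rdname endokin-tidiers
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(tau = x$tau, rss = x$rss, n_points = x$n_points,
         peak_time = x$peak_time, converged = x$converged)
}

#' @rdname endokin-tidiers
#' @method tidy test_plan
#' @export
tidy.test_plan <- function(x, ...) {
  dplyr::mutate(x$normality, branch = x$branch, test = x$test,
                gate_applied = x$gate_applied)
}

#' @rdname endokin-tidiers
#' @method glance test_plan
#' @export
glance.test_plan <- function(x, ...) {
  tibble(branch = x$branch, test = x$test, gate_applied = x$gate_applied,
         gate_skipped_small_n = x$gate_skipped_small_n,
         n_total = x$n_total, design = x$design)
}

#' @rdname endokin-tidiers
#' @method tidy stat_result
#' @export
tidy.stat_result <- function(x, ...) as_tibble(x)

#' @rdname endokin-tidiers
#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) {
  out <- tidyr::pivot_wider(
    dplyr::select(x$conditions, "condition", "tau"),
    names_from = "condition", values_from = "tau", names_prefix = "tau_")
  out$p_value <- if (!is.null(x$stats)) x$stats$p_value[1] else NA_real_
  out$n_excluded <- nrow(x$excluded)
  out
}
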