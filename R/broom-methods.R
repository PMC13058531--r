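#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired bootstrap Wald test
#'
#' @param x A `sepsis_paired_test`.
#' @param ... Unused.
#' @return A one-row tibble: `estimate_a`, `estimate_b`, `estimate`
#'   (the difference), `std.error`, `statistic`, `p.value`.
#' @export
tidy.sepsis_paired_test <- function(x, ...) {
  tibble::tibble(
    estimate_a = x$estimate_a,
    estimate_b = x$estimate_b,
    estimate = x$delta_observed,
    std.error = x$se_boot,
    statistic = x$z,
    p.value = x$p_raw
  )
}

#' @rdname tidy.sepsis_paired_test
#' @export
glance.sepsis_paired_test <- function(x, ...) {
  tibble::tibble(n_replicates = x$n_used, B = x$B, center = x$center)
}

#' Tidy a bootstrap confidence interval
#'
#' @param x A `sepsis_boot_ci`.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.sepsis_boot_ci <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$conf_low,
                 conf.high = x$conf_high)
}

#' @rdname tidy.sepsis_boot_ci
#' @export
glance.sepsis_boot_ci <- function(x, ...) {
  tibble::tibble(B = x$B, n_failed = x$n_failed, conf = x$conf)
}

#' Tidy an experiment run
#'
#' @param x A `sepsis_experiment`.
#' @param ... Unused.
#' @return The per-cell results tibble.
#' @export
tidy.sepsis_experiment <- function(x, ...) x$results

#' @rdname tidy.sepsis_experiment
#' @export
glance.sepsis_experiment <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$exclusions),
    n_contrasts = nrow(x$contrasts),
    B = x$grid$B,
    seed = x$grid$seed
  )
}

#' @export
print.sepsis_paired_test <- function(x, ...) {
  cat("Paired bootstrap Wald test (B =", x$B, ")\n")
  cat(sprintf("  delta = %.4f, SE = %.4f, z = %.3f, p = %.4g\n",
              x$delta_observed, x$se_boot, x$z, x$p_raw))
  invisible(x)
}

#' @export
print.sepsis_boot_ci <- function(x, ...) {
  cat(sprintf("%.4f (%g%% CI %.4f–%.4f), B = %d\n", x$estimate,
              100 * x$conf, x$conf_low, x$conf_high, x$B))
  invisible(x)
}
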