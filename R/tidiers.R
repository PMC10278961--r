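#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an end-point binding free energy result
#'
#' @param x An `endpoint_result`.
#' @param ... Unused.
#' @return Tibble with one row per energy term (`term`, `estimate`, `sd`).
#' @export
tidy.endpoint_result <- function(x, ...) {
  dplyr::rename(x$summary, estimate = "mean")
}

#' One-row summary of an end-point result
#'
#' @param x An `endpoint_result`.
#' @param ... Unused.
#' @return One-row tibble: model, dielectric, frame count, enthalpy,
#'   entropy term and binding free energy.
#' @export
glance.endpoint_result <- function(x, ...) {
  tibble::tibble(
    model = x$model, eps_in = x$eps_in, n_frames = x$n_frames,
    dh = x$summary$mean[x$summary$term == "dh"],
    minus_tds = x$minus_tds %||% NA_real_,
    dg_bind = x$dg_bind
  )
}

#' Tidy a TI result
#'
#' @param x A `ti_result`.
#' @param ... Unused.
#' @return Tibble with one row per replica.
#' @export
tidy.ti_result <- function(x, ...) x$per_replica

#' One-row summary of a TI result
#'
#' @param x A `ti_result`.
#' @param ... Unused.
#' @return One-row tibble: replica count, lambda count, mean dG, SD.
#' @export
glance.ti_result <- function(x, ...) {
  tibble::tibble(n_replicas = nrow(x$per_replica),
                 n_lambdas = length(x$lambdas),
                 dg = x$mean, sd = x$sd)
}

#' Plot a PMF profile
#'
#' Free energy against the reaction coordinate, with a +/- SD ribbon for
#' round-averaged profiles.
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$xi,
                                            y = .data$free_energy))
  if ("sd" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy - .data$sd,
                   ymax = .data$free_energy + .data$sd),
      alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate (Å)",
                  y = "PMF (kcal/mol)")
}

#' Plot a benchmark report's per-system scatter
#'
#' Experimental vs predicted ddG per method, with the identity line.
#'
#' @param object A `benchmark_report` carrying per-system tables.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_report <- function(object, ...) {
  per <- attr(object, "per_system")
  if (is.null(per)) stop("report carries no per-system tables")
  df <- dplyr::bind_rows(per, .id = "method")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ddg_exp,
                                   y = .data$ddg_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = expression(Delta * Delta * G[exp] ~ "(kcal/mol)"),
                  y = expression(Delta * Delta * G[pred] ~ "(kcal/mol)"))
}

#' Plot a per-residue decomposition table
#'
#' Stacked per-term contributions per residue.
#'
#' @param object A `decomposition_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decomposition_table <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("residue_id", "ele", "vdw", "polar",
                                  "nonpolar")],
    -"residue_id", names_to = "term", values_to = "energy")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$residue_id),
                                   y = .data$energy,
                                   fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue", y = "contribution (kcal/mol)")
}
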