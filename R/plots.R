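#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an information-bottleneck curve
#'
#' Predictive information against encoded past information along the swept
#' tradeoff.
#'
#' @param object A `pib_info_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pib_info_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$i_past_bits, .data$i_future_bits)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 0.6, color = "#2c7fb8") +
    ggplot2::labs(x = "I(past; representation) [bits]",
                  y = "I(representation; future) [bits]",
                  title = "Information bottleneck curve") +
    ggplot2::theme_minimal()
}

#' Plot a transferability surface
#'
#' Heatmap of transferred predictive information over target dynamics
#' parameters, annotated with the integrated transferability Q.
#'
#' @param object A `pib_transfer_map` from [q_transfer()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pib_transfer_map <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(.data$zeta_t, .data$dt_t,
                               fill = .data$i_future_bits)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "transferred\nI_future [bits]") +
    ggplot2::labs(x = "target damping zeta'", y = "target lag dt'",
                  title = sprintf("Transferred predictive information (Q = %.3f)",
                                  object$q)) +
    ggplot2::theme_minimal()
}

#' Plot discrete decoder tilings
#'
#' The inferred historical (or predicted future) allele-frequency
#' distribution for each representation value, over the stationary law.
#'
#' @param object A `pib_discrete_encoder`.
#' @param joint The [discrete_joint()] it was trained on.
#' @param which `"past"` or `"future"` decoders.
#' @param mass_tol Clusters below this marginal mass are not drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pib_discrete_encoder <- function(object, joint, which = "past",
                                          mass_tol = 1e-3, ...) {
  dec <- decoders(object, joint)
  M <- if (which == "past") dec$past else dec$future
  keep <- which(dec$weights >= mass_tol)
  df <- tibble::tibble(
    x = rep(joint$grid, times = length(keep)),
    xtilde = factor(rep(keep, each = length(joint$grid))),
    p = as.vector(t(M[keep, , drop = FALSE]))
  )
  base <- tibble::tibble(x = joint$grid, p = joint$p_past)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$p, color = .data$xtilde)) +
    ggplot2::geom_line(data = base, ggplot2::aes(.data$x, .data$p),
                       inherit.aes = FALSE, linetype = 2, color = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "allele frequency",
                  y = sprintf("P(X_%s | representation)",
                              if (which == "past") "t" else "t+dt"),
                  color = "cluster") +
    ggplot2::theme_minimal()
}

#' Conditional-uncertainty ellipses across a parameter sweep
#'
#' Draws the one-sigma ellipses of the current state given the
#' representation (and of the future state given the representation) for
#' each cell of a [fixed_info_sweep()], in coordinates rescaled by the prior
#' standard deviations so the prior is the unit circle.
#'
#' @param sweep A tibble from [fixed_info_sweep()].
#' @param n_arc Points per ellipse.
#' @return A ggplot object faceted by (zeta, dt).
#' @export
plot_conditional_ellipses <- function(sweep, n_arc = 100) {
  arcs <- purrr::pmap(sweep, function(zeta, dt, past_xx, past_xv, past_vv,
                                      fut_xx, fut_xv, fut_vv, ...) {
    S0 <- sddho_stationary_cov(zeta)
    sc <- sqrt(diag(S0))
    mk <- function(S, lab) {
      S <- diag(1 / sc) %*% S %*% diag(1 / sc)
      e <- eigen(symmetrize(S), symmetric = TRUE)
      th <- seq(0, 2 * pi, length.out = n_arc)
      pts <- e$vectors %*% rbind(sqrt(pmax(e$values[1], 0)) * cos(th),
                                 sqrt(pmax(e$values[2], 0)) * sin(th))
      tibble::tibble(zeta = zeta, dt = dt, which = lab,
                     x = pts[1, ], v = pts[2, ])
    }
    dplyr::bind_rows(
      mk(matrix(c(past_xx, past_xv, past_xv, past_vv), 2, 2), "past | repr"),
      mk(matrix(c(fut_xx, fut_xv, fut_xv, fut_vv), 2, 2), "future | repr")
    )
  })
  df <- dplyr::bind_rows(arcs)
  circ <- tidyr::expand_grid(
    dplyr::distinct(sweep, .data$zeta, .data$dt),
    tibble::tibble(th = seq(0, 2 * pi, length.out = n_arc))
  )
  circ <- dplyr::mutate(circ, x = cos(.data$th), v = sin(.data$th))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$v, color = .data$which)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$v),
                       inherit.aes = FALSE, color = "grey60", linetype = 3) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_grid(zeta ~ dt,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position / sd", y = "velocity / sd", color = NULL) +
    ggplot2::theme_minimal()
}
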