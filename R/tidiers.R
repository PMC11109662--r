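#' Tidy a free-energy surface into a long tibble
#'
#' @param x A [free_energy_surface()].
#' @param ... Unused.
#' @return A tibble with one row per grid point: the axis coordinate
#'   column(s) and `free_energy` (kJ mol^-1).
#' @export
tidy.fes <- function(x, ...) {
  if (fes_ndim(x) == 1) {
    out <- tibble(!!names(x$axes)[1] := x$axes[[1]],
                  free_energy = x$values)
  } else {
    g <- expand.grid(i = seq_along(x$axes[[1]]), j = seq_along(x$axes[[2]]))
    out <- tibble(!!names(x$axes)[1] := x$axes[[1]][g$i],
                  !!names(x$axes)[2] := x$axes[[2]][g$j],
                  free_energy = x$values[cbind(g$i, g$j)])
  }
  out
}

#' @importFrom rlang := !!
NULL

#' Plot a free-energy surface
#'
#' 1-D surfaces as a profile line, 2-D surfaces as a filled raster.
#'
#' @param object A [free_energy_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fes <- function(object, ...) {
  df <- tidy(object)
  nms <- names(object$axes)
  if (fes_ndim(object) == 1) {
    ggplot2::ggplot(df, ggplot2::aes(.data[[nms[1]]], .data$free_energy)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "free energy (kJ/mol)")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data[[nms[1]]], .data[[nms[2]]],
                                     fill = .data$free_energy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)")
  }
}

#' Tidy a DCC matrix into a long tibble
#'
#' @param x A `dcc_matrix` from [dcc_map()].
#' @param ... Unused.
#' @return A tibble with columns `resno_i`, `resno_j`, `dcc`.
#' @export
tidy.dcc_matrix <- function(x, ...) {
  resnos <- as.integer(rownames(x))
  g <- expand.grid(i = seq_along(resnos), j = seq_along(resnos))
  tibble(resno_i = resnos[g$i], resno_j = resnos[g$j],
         dcc = unclass(x)[cbind(g$i, g$j)])
}

#' Plot a DCC map
#'
#' Cells with |DCC| below the display threshold (stored on the matrix,
#' default 0.4) are blanked, mirroring the customary presentation of
#' cross-correlation maps.
#'
#' @param object A `dcc_matrix`.
#' @param threshold Override the display threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcc_matrix <- function(object, threshold = NULL, ...) {
  thr <- threshold %||% attr(object, "threshold_display") %||% 0.4
  df <- tidy(object)
  df$dcc[!is.na(df$dcc) & abs(df$dcc) < thr] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$resno_i, .data$resno_j,
                                   fill = .data$dcc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), na.value = "grey95",
                                  name = "DCC") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue")
}

#' Tidy a binding estimate
#'
#' @param x A `binding_estimate` from [binding_delta_g()].
#' @param ... Unused.
#' @return A tibble with one row per reported quantity (`delta_g` in
#'   kcal mol^-1, `kd` in nM) with standard errors where available.
#' @export
tidy.binding_estimate <- function(x, ...) {
  tibble(term = c("delta_g", "kd"),
         estimate = c(x$delta_g, x$kd),
         std.error = c(x$uncertainty, x$kd_uncertainty),
         unit = c("kcal/mol", "nM"))
}

#' One-row summary of a binding estimate
#'
#' @param x A `binding_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `delta_g`, `kd`, `kb_nm3`, `temperature`,
#'   `standard_concentration`, `convergence_warning`.
#' @export
glance.binding_estimate <- function(x, ...) {
  tibble(delta_g = x$delta_g, kd = x$kd, kb_nm3 = x$kb_nm3,
         temperature = x$temperature,
         standard_concentration = x$standard_concentration,
         convergence_warning = x$convergence_warning)
}

#' Plot deposited hill heights over time
#'
#' The decaying staircase of hill heights is the quickest visual check of
#' well-tempered damping.
#'
#' @param object A [hills_log()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hills_log <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(.data$time, .data$height)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::labs(x = "time (ps)", y = "hill height (kJ/mol)")
}
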