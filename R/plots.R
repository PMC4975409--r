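#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_path
#'   labs facet_wrap scale_color_viridis_c coord_equal theme_minimal
NULL

#' Plot a morphology shape
#'
#' @param object an `mm_morphology`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mm_morphology <- function(object, ...) {
  g <- object$grid[!object$grid$masked, ]
  ggplot(g, aes(x = .data$t_norm, y = .data$v_norm)) +
    geom_line() +
    labs(x = "normalized time (activation = 0, APD90 = 1)",
         y = "normalized voltage",
         title = "Action potential morphology") +
    theme_minimal()
}

#' Plot S1-S2 restitution curves
#'
#' @param object an `mm_s1s2`.
#' @param ... unused.
#' @return A ggplot of APD and CV against diastolic interval.
#' @export
autoplot.mm_s1s2 <- function(object, ...) {
  pts <- dplyr::filter(object$points, .data$captured)
  long <- tidyr::pivot_longer(pts[, c("DI", "APD", "CV")],
                              c("APD", "CV"), names_to = "curve")
  ggplot(long, aes(x = .data$DI, y = .data$value)) +
    geom_point() + geom_line() +
    facet_wrap(~curve, scales = "free_y") +
    labs(x = "diastolic interval (ms)", y = NULL,
         title = "S1-S2 restitution") +
    theme_minimal()
}

#' Plot an annealing trace
#'
#' @param object an `mm_fit`.
#' @param ... unused.
#' @return A ggplot of best/current error against iteration.
#' @export
autoplot.mm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace[, c("iteration", "E_current",
                                               "E_best")],
                              c("E_current", "E_best"), names_to = "series")
  ggplot(long, aes(x = .data$iteration, y = .data$value,
                   linetype = .data$series)) +
    geom_line() +
    labs(x = "iteration", y = "total error (%)",
         title = "Simulated annealing trace") +
    theme_minimal()
}

#' Plot a spiral tip trajectory
#'
#' @param object an `mm_tip_trajectory`.
#' @param ... unused.
#' @return A ggplot of tip positions colored by time.
#' @export
autoplot.mm_tip_trajectory <- function(object, ...) {
  ggplot(object$tips, aes(x = .data$x, y = .data$y, color = .data$time,
                          group = .data$track)) +
    geom_path() +
    coord_equal() +
    scale_color_viridis_c() +
    labs(x = "x (cm)", y = "y (cm)", color = "time (ms)",
         title = "Spiral tip trajectory") +
    theme_minimal()
}

#' Plot a clinical dataset's target curves
#'
#' @param object a `clinical_dataset`.
#' @param ... unused.
#' @return A ggplot faceted over morphology, APD and CV restitution.
#' @export
autoplot.clinical_dataset <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$x, y = .data$y)) +
    geom_point(size = 0.8) +
    facet_wrap(~curve, scales = "free") +
    labs(x = NULL, y = NULL, title = object$label) +
    theme_minimal()
}
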