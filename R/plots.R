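#' Plot a simulated trajectory
#'
#' 1-D trajectories are drawn as position against time (coloured by
#' behavioural state when present); 2-D trajectories as the path in the
#' plane with start and end marked.
#'
#' @param object an `mvt_trajectory`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mvt_trajectory <- function(object, ...) {
  has_y <- "y" %in% names(object)
  if (!has_y) {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x))
    if ("state" %in% names(object)) {
      p <- p + ggplot2::geom_path(ggplot2::aes(colour = factor(.data$state),
                                               group = 1)) +
        ggplot2::labs(colour = "state")
    } else {
      p <- p + ggplot2::geom_path()
    }
    return(p + ggplot2::labs(x = "time", y = "position"))
  }
  ends <- object[c(1, nrow(object)), ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::geom_point(data = ends[1, ], shape = 16, size = 2) +
    ggplot2::geom_point(data = ends[2, ], shape = 17, size = 2) +
    ggplot2::coord_equal()
}

#' Plot a velocity-jump path
#'
#' Straight segments between events; bounce/reorientation events marked
#' with triangles.
#'
#' @param object an `mvt_pdmp_path`.
#' @param ... unused.
#' @export
autoplot.mvt_pdmp_path <- function(object, ...) {
  tr <- path_to_trajectory(object,
                           dt = (object$t_end - object$t0) / 2000)
  p <- autoplot.mvt_trajectory(tr)
  ev <- object$events[object$events$kind != "refresh", , drop = FALSE]
  if (nrow(ev) > 0 && all(c("x", "y") %in% names(ev))) {
    p <- p + ggplot2::geom_point(data = ev,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 17, size = 1, alpha = 0.6)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.mvt_trajectory <- function(x, ...) print(autoplot.mvt_trajectory(x, ...))

#' @export
plot.mvt_pdmp_path <- function(x, ...) print(autoplot.mvt_pdmp_path(x, ...))
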