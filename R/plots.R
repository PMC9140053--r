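# Base-graphics displays: moving-average velocity graphs (mean +/- SD band
# across subjects, injection marker) and super-resolved images.

#' Plot a moving-average velocity series
#'
#' @param series data.frame from [moving_average_series()] or
#'   [aggregate_subject_series()] (columns `t`, `mean`, optionally `sd`).
#' @param t_inj optional injection time to mark with a dotted line.
#' @param main,ylab plot annotations.
#' @export
plot_velocity_series <- function(series, t_inj = NULL,
                                 main = "moving-average velocity",
                                 ylab = "speed (mm/s)") {
  has_sd <- "sd" %in% names(series) && any(is.finite(series$sd))
  ylim <- range(c(series$mean,
                  if (has_sd) series$mean + series$sd,
                  if (has_sd) series$mean - series$sd), na.rm = TRUE)
  plot(series$t, series$mean, type = "n", xlab = "time (s)", ylab = ylab,
       main = main, ylim = ylim)
  if (has_sd) {
    ok <- is.finite(series$mean) & is.finite(series$sd)
    graphics::polygon(c(series$t[ok], rev(series$t[ok])),
                      c(series$mean[ok] + series$sd[ok],
                        rev(series$mean[ok] - series$sd[ok])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(series$t, series$mean, col = "steelblue", lwd = 2)
  if (!is.null(t_inj)) graphics::abline(v = t_inj, lty = 3)
  invisible(series)
}

#' Display a super-resolved image
#'
#' Density images are shown on a log1p gray scale; velocity maps as RGB.
#'
#' @param img an `srus_image` from [accumulate_density()] or
#'   [velocity_map()].
#' @param main title.
#' @export
plot_srus <- function(img, main = attr(img, "kind")) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  if (identical(attr(img, "kind"), "velocity")) {
    nr <- dim(img)[1]; nc <- dim(img)[2]
    rast <- grDevices::as.raster(unclass(img))
    graphics::plot(c(0, nc), c(0, nr), type = "n", axes = FALSE,
                   xlab = "", ylab = "", main = main, asp = 1)
    graphics::rasterImage(rast, 0, 0, nc, nr)
  } else {
    m <- log1p(unclass(img))
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256),
                    axes = FALSE, main = main, asp = nrow(m) / ncol(m))
  }
  invisible(img)
}
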