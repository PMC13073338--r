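#' Fit the center line of a 2D effect-size cloud
#'
#' Ordinary least squares of the stratum-B effect sizes on the stratum-A
#' effect sizes (with intercept). The signed perpendicular distance of each
#' point to the fitted line is
#' \code{d = (y - slope * x - intercept) / sqrt(1 + slope^2)}, and
#' \code{sigma} is the sample standard deviation of those distances. Points
#' within \code{band_mult * sigma} of the line are later treated as
#' effect-size concordant.
#'
#' @param x,y Paired effect sizes (stratum A on x, stratum B on y).
#' @param band_mult Half-width of the concordance band, in units of sigma
#'   (default 1.5, i.e. a total band of 3 sigma).
#' @return An object of class \code{center_line}: \code{slope, intercept,
#'   sigma, band_mult, n}.
#' @export
fit_center_line <- function(x, y, band_mult = 1.5) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("center line needs at least 3 finite points")
  if (stats::var(x) == 0) stop("degenerate input: x values all equal")
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  d <- (y - slope * x - intercept) / sqrt(1 + slope^2)
  structure(list(slope = slope, intercept = intercept,
                 sigma = stats::sd(d), band_mult = band_mult, n = length(x)),
            class = "center_line")
}

#' @export
print.center_line <- function(x, ...) {
  cat(sprintf("Center line: y = %.4f x + %.4f  (n = %d)\n",
              x$slope, x$intercept, x$n))
  cat(sprintf("sigma of perpendicular distances = %.4f; band = +/- %.2f sigma\n",
              x$sigma, x$band_mult))
  invisible(x)
}

#' Predicted y value on the center line
#' @param object A \code{center_line}.
#' @param newdata Numeric vector of x values.
#' @param ... Unused.
#' @export
predict.center_line <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

#' Classify effect-size pairs into concordance bands and quadrants
#'
#' Points within \code{band_mult * sigma} of the center line and lying in
#' quadrant 1 (both effects positive) or 3 (both negative) are labeled
#' \code{consistent_up} / \code{consistent_down}. Points outside the band are
#' labeled by quadrant; in Q1 and Q3 the sign of the perpendicular residual
#' subdivides them (\code{_top}: above the line, i.e. stronger effect in
#' stratum B; \code{_bottom}: stronger in stratum A). Q2 is x<0, y>0 and Q4 is
#' x>0, y<0. A coordinate exactly at zero is treated as positive for the
#' quadrant decision; with \code{sigma = 0} any off-line point falls outside
#' the band.
#'
#' @param x,y Paired effect sizes.
#' @param model A [fit_center_line()] object (fitted on these or compatible
#'   points).
#' @param analyte_id Optional identifiers carried into the output.
#' @return Data frame: \code{analyte_id, x, y, distance, label}.
#' @export
classify_effect_pairs <- function(x, y, model, analyte_id = NULL) {
  stopifnot(inherits(model, "center_line"), length(x) == length(y))
  if (is.null(analyte_id)) analyte_id <- as.character(seq_along(x))
  d <- (y - model$slope * x - model$intercept) / sqrt(1 + model$slope^2)
  within <- abs(d) <= model$band_mult * model$sigma
  xp <- x >= 0   # zero treated as positive
  yp <- y >= 0
  lab <- character(length(x))
  q1 <- xp & yp
  q2 <- !xp & yp
  q3 <- !xp & !yp
  q4 <- xp & !yp
  lab[q1 & within] <- "consistent_up"
  lab[q3 & within] <- "consistent_down"
  lab[q1 & !within] <- ifelse(d[q1 & !within] > 0, "Q1_top", "Q1_bottom")
  lab[q3 & !within] <- ifelse(d[q3 & !within] > 0, "Q3_top", "Q3_bottom")
  lab[q2] <- "Q2"
  lab[q4] <- "Q4"
  data.frame(analyte_id = analyte_id, x = x, y = y, distance = d, label = lab,
             stringsAsFactors = FALSE)
}

#' Fraction of pairs classified as concordant
#'
#' @param assignments Data frame from [classify_effect_pairs()].
#' @return Fraction of points labeled \code{consistent_up} or
#'   \code{consistent_down}, in [0, 1].
#' @export
concordance_fraction <- function(assignments) {
  if (nrow(assignments) == 0L) stop("empty assignment set")
  mean(assignments$label %in% c("consistent_up", "consistent_down"))
}

#' Quadrant scatter of paired effect sizes with the fitted band
#' @param x A \code{center_line}.
#' @param assignments Data frame from [classify_effect_pairs()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.center_line <- function(x, assignments, ...) {
  cols <- c(consistent_up = "firebrick", consistent_down = "steelblue",
            Q1_top = "darkorange", Q1_bottom = "darkorange",
            Q3_top = "purple", Q3_bottom = "purple",
            Q2 = "darkgreen", Q4 = "darkgreen")
  graphics::plot(assignments$x, assignments$y,
                 col = cols[assignments$label], pch = 16, cex = 0.7,
                 xlab = "effect size, stratum A", ylab = "effect size, stratum B",
                 ...)
  graphics::abline(x$intercept, x$slope, col = "purple", lty = 2)
  off <- x$band_mult * x$sigma * sqrt(1 + x$slope^2)
  graphics::abline(x$intercept + off, x$slope, col = "red", lty = 3)
  graphics::abline(x$intercept - off, x$slope, col = "red", lty = 3)
  graphics::abline(h = 0, v = 0, col = "grey80")
  invisible(x)
}
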