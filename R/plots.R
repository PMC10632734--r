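#' Plot a precision versus true-positives curve
#'
#' Precision on the y-axis against the absolute number of true positives
#' (log-scaled x-axis by convention for dependency-map benchmarks).
#'
#' @param pr data.frame from [prCurve()] (or a named list of them, drawn
#'   as overlaid curves).
#' @param log use a logarithmic TP axis (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @return `NULL`, invisibly; draws on the active device.
#' @export
plotPrCurve <- function(pr, log = TRUE, ...) {
    curves <- if (is.data.frame(pr)) list(curve = pr) else pr
    xmax <- max(vapply(curves, function(d) max(d$tp), numeric(1)))
    graphics::plot(NA, xlim = c(1, max(xmax, 2)), ylim = c(0, 1),
                   log = if (log) "x" else "",
                   xlab = "true positives", ylab = "precision", ...)
    cols <- seq_along(curves)
    for (i in cols) {
        d <- curves[[i]]
        keep <- d$tp > 0
        graphics::lines(d$tp[keep], d$precision[keep], col = i, lwd = 2)
    }
    if (length(curves) > 1L)
        graphics::legend("topright", legend = names(curves), col = cols,
                         lwd = 2, bty = "n")
    invisible(NULL)
}

#' Plot a contribution diversity breakdown
#'
#' Stacked horizontal bars of per-complex true-positive fractions at each
#' attained precision cutoff.
#'
#' @param dv long data.frame from [diversityBreakdown()].
#' @param ... passed to [graphics::barplot()].
#' @return `NULL`, invisibly.
#' @export
plotDiversity <- function(dv, ...) {
    if (!nrow(dv)) {
        warning("empty diversity breakdown", call. = FALSE)
        return(invisible(NULL))
    }
    wide <- stats::xtabs(fraction ~ complexId + cutoff, data = dv)
    graphics::barplot(wide, horiz = TRUE, xlab = "fraction of TP pairs",
                      ylab = "precision cutoff", legend.text = rownames(wide),
                      ...)
    invisible(NULL)
}
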