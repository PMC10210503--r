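# Simple base-graphics views of the standard small RNA diagnostics.

#' Plot a size distribution
#'
#' Sense counts up, antisense counts down, the usual small RNA
#' representation.
#'
#' @param x A [size_distribution()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_size_distribution <- function(x, ...) {
  lens <- sort(unique(x$length))
  s <- x$count[x$strand == "sense"][order(x$length[x$strand == "sense"])]
  a <- x$count[x$strand == "antisense"][
    order(x$length[x$strand == "antisense"])]
  ylim <- range(c(s, -a, 0))
  graphics::barplot(s, names.arg = lens, ylim = ylim, col = "firebrick",
                    xlab = "read length (nt)", ylab = "normalized count",
                    main = attr(x, "region"), ...)
  graphics::barplot(-a, add = TRUE, col = "steelblue", names.arg = FALSE)
  graphics::abline(h = 0)
  invisible(x)
}

#' Plot a strand-resolved coverage profile
#'
#' @param x A [coverage_profile()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_coverage <- function(x, ...) {
  L <- length(x$sense)
  ylim <- range(c(x$sense, -x$antisense, 0))
  graphics::plot(seq_len(L) - 1L, x$sense, type = "h", col = "firebrick",
                 ylim = ylim, xlab = "position (bp)",
                 ylab = "normalized 5' count",
                 main = sprintf("%s [%d-%d nt]", x$region, x$window[1],
                                x$window[2]), ...)
  graphics::lines(seq_len(L) - 1L, -x$antisense, type = "h",
                  col = "steelblue")
  graphics::abline(h = 0)
  invisible(x)
}
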