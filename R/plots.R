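#' Plot informativeness profiles
#'
#' One line per partition for a chosen variant, mirroring the standard
#' informativeness-profile figure (time on the x axis, informativeness
#' on the y axis).
#'
#' @param profile A `"pi_profile"` data frame from [pi_profile()].
#' @param variant Which variant to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the wide matrix of plotted values.
#' @export
plot_pi_profile <- function(profile, variant = "modified", ...) {
  d <- profile[profile$variant == variant, ]
  if (!nrow(d)) stopf("variant '%s' not present in profile", variant)
  parts <- unique(d$partition)
  tg <- sort(unique(d$t_ma))
  m <- vapply(parts, function(p)
    d$pi[d$partition == p][order(d$t_ma[d$partition == p])],
    numeric(length(tg)))
  graphics::matplot(tg, m, type = "l", lty = 1, col = seq_along(parts),
                    xlab = "Time (Ma)",
                    ylab = sprintf("Informativeness (%s)", variant), ...)
  graphics::legend("topright", legend = parts, col = seq_along(parts),
                   lty = 1, cex = 0.6, bty = "n")
  invisible(m)
}

#' Plot a saturation panel
#'
#' Scatter of uncorrected p-distance against patristic distance for one
#' partition, with its OLS fit.
#'
#' @param sat A `"saturation_table"` from [saturation_table()].
#' @param partition Partition name (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_saturation <- function(sat, partition = NULL, ...) {
  if (is.null(partition)) partition <- sat$summary$partition[1]
  d <- sat$pairs[sat$pairs$partition == partition, ]
  if (!nrow(d)) stopf("partition '%s' not present", partition)
  graphics::plot(d$tree_distance, d$p_distance, pch = 16, cex = 0.6,
                 xlab = "Patristic distance (Ma)",
                 ylab = "Uncorrected p-distance", main = partition, ...)
  s <- sat$summary[sat$summary$partition == partition, ]
  graphics::abline(s$intercept, s$slope, col = 2)
  invisible(d)
}
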