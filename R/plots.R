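# Figure helpers.  All writers fall back from png() to pdf() so headless
# hosts without a bitmap device still produce output.

open_device <- function(file, width = 6, height = 4.5) {
  ok <- tryCatch({
    grDevices::png(file, width = width * 100, height = height * 100,
                   res = 100)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) grDevices::pdf(sub("\\.png$", ".pdf", file),
                          width = width, height = height)
  invisible(NULL)
}

#' Plot group-average traces with confidence band
#'
#' Mean normalized trace per group with a pointwise 95% CI band.
#'
#' @param traces an `svc_traces`.
#' @param file output file (PNG; falls back to PDF headless).
#' @return Invisibly, `file`.
#' @export
plot_average_traces <- function(traces, file) {
  open_device(file)
  on.exit(grDevices::dev.off())
  groups <- unique(traces$meta$group)
  cols <- grDevices::hcl.colors(max(2, length(groups)), "Dark 2")
  keep <- traces$meta$qc_status == "kept"
  ylim <- range(traces$norm[keep, ], finite = TRUE)
  plot(NA, xlim = range(traces$time), ylim = ylim, xlab = "time (s)",
       ylab = "F / F(NH4Cl)", main = "average normalized traces")
  for (i in seq_along(groups)) {
    sel <- keep & traces$meta$group == groups[i]
    if (!any(sel)) next
    m <- colMeans(traces$norm[sel, , drop = FALSE])
    s <- apply(traces$norm[sel, , drop = FALSE], 2, stats::sd)
    ci <- 1.96 * s / sqrt(sum(sel))
    graphics::polygon(c(traces$time, rev(traces$time)),
                      c(m + ci, rev(m - ci)), border = NA,
                      col = grDevices::adjustcolor(cols[i], 0.25))
    graphics::lines(traces$time, m, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(file)
}

#' Boxplot of per-bouton rates by group
#'
#' @param rates an `svc_rate_table` (or data.frame with `group` and rate
#'   columns).
#' @param file output file.
#' @param what rate column to plot.
#' @return Invisibly, `file`.
#' @export
plot_rate_boxplot <- function(rates, file, what = "exo_rate") {
  open_device(file)
  on.exit(grDevices::dev.off())
  graphics::boxplot(rates[[what]] ~ rates$group, xlab = "group",
                    ylab = paste(what, "(norm dF / s)"), main = what)
  invisible(file)
}

#' Cumulative distribution of calcium peaks per group
#'
#' @param summary an `svc_ca_summary` from [ca_summaries()].
#' @param file output file.
#' @return Invisibly, `file`.
#' @export
plot_ca_cdf <- function(summary, file) {
  open_device(file)
  on.exit(grDevices::dev.off())
  groups <- unique(summary$cdf$group)
  cols <- grDevices::hcl.colors(max(2, length(groups)), "Dark 2")
  plot(NA, xlim = range(summary$cdf$x), ylim = c(0, 1),
       xlab = "normalized peak", ylab = "cumulative probability",
       main = "calcium peak CDF")
  for (i in seq_along(groups)) {
    d <- summary$cdf[summary$cdf$group == groups[i], ]
    graphics::lines(d$x, d$p, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = groups,
                   col = cols[seq_along(groups)], lwd = 2, bty = "n")
  invisible(file)
}
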