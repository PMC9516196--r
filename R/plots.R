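#' Plot a SNP-index genome scan
#'
#' Draws the per-site SNP indices as dots with the sliding-window mean as
#' a line, one panel per chromosome (or a single requested chromosome),
#' shading called peak regions. This is the standard diagnostic panel for
#' bulked-segregant mapping: the causal region stands out as a run of
#' indices close to 1 decaying with recombination distance.
#'
#' @param scan result of [scan_genome()].
#' @param regions optional peak regions from [call_peak_regions()].
#' @param chrom optional single chromosome to plot.
#' @param index_threshold horizontal reference line (default 0.9).
#' @importFrom graphics abline axis lines par plot.new plot.window rect
#'   title points
#' @export
plot_snp_index <- function(scan, regions = NULL, chrom = NULL,
                           index_threshold = 0.9) {
  sites <- scan$sites
  windows <- scan$windows
  chroms <- if (is.null(chrom)) unique(sites$chrom) else chrom
  old <- par(mfrow = c(length(chroms), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  for (ch in chroms) {
    s <- sites[sites$chrom == ch, ]
    w <- windows[windows$chrom == ch, ]
    plot.new()
    plot.window(xlim = c(0, max(s$pos) / 1e6), ylim = c(0, 1))
    if (!is.null(regions)) {
      r <- regions[regions$chrom == ch, ]
      if (nrow(r)) {
        rect(r$start / 1e6, 0, r$end / 1e6, 1, col = "grey85",
             border = NA)
      }
    }
    points(s$pos / 1e6, s$snp_index, pch = 16, cex = 0.4,
           col = "steelblue")
    ok <- !is.na(w$mean_index)
    lines((w$start[ok] + (w$end[ok] - w$start[ok]) / 2) / 1e6,
          w$mean_index[ok], col = "firebrick", lwd = 1.5)
    abline(h = index_threshold, lty = 2, col = "grey40")
    axis(1); axis(2, las = 1)
    title(main = ch, ylab = "SNP index", xlab = "position (Mb)")
  }
  invisible(NULL)
}
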