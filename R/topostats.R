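#' Channel-wise nonparametric comparison of control vs non-control features
#'
#' Tests, independently for every channel, whether the sample-entropy
#' features of control characters differ from those of non-control
#' characters.  The default paired Wilcoxon signed-rank test pairs rows by
#' within-state recording order (balanced sets guarantee equal counts);
#' `"rank-sum"` (Mann-Whitney) drops the pairing requirement.  Zero
#' differences are discarded before ranking; exact null distributions are
#' used for small samples without ties, the tie-corrected normal
#' approximation otherwise (the policy of [stats::wilcox.test()]).  When
#' all paired differences are zero the statistic is degenerate and the
#' p-value is 1.
#'
#' @param control_features,noncontrol_features Numeric matrices
#'   (characters x channels) with matching channel counts; signed-rank
#'   mode also requires matching row counts.
#' @param mode `"signed-rank"` (paired, default) or `"rank-sum"`.
#' @return Numeric vector of two-sided p-values, one per channel.
#' @export
channelwise_test <- function(control_features, noncontrol_features,
                             mode = c("signed-rank", "rank-sum")) {
  mode <- match.arg(mode)
  a <- as.matrix(control_features)
  b <- as.matrix(noncontrol_features)
  if (ncol(a) != ncol(b))
    stop("feature matrices must have the same number of channels",
         call. = FALSE)
  if (mode == "signed-rank" && nrow(a) != nrow(b))
    stop("signed-rank mode requires equal row counts (pairs by row index)",
         call. = FALSE)
  vapply(seq_len(ncol(a)), function(ch) {
    x <- a[, ch]; y <- b[, ch]
    if (mode == "signed-rank") {
      if (all(x == y)) return(1)  # degenerate: every difference is zero
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))$p.value
    } else {
      suppressWarnings(stats::wilcox.test(x, y))$p.value
    }
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple comparisons with the
#' Benjamini-Hochberg false-discovery-rate step-up procedure: sorted
#' ascending, `adj_(k) = min over j >= k of p_(j) * M / j`, capped at 1
#' and mapped back to the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.005, 0.009, 0.05, 0.5))
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Channel-wise statistics table for one subject
#'
#' Runs [channelwise_test()] on per-channel sample-entropy features,
#' adjusts the p-values with [bh_fdr()] and flags channels significant at
#' the given level - the per-subject topographic summary of where the
#' control/non-control regularity difference concentrates.
#'
#' @inheritParams channelwise_test
#' @param channel_labels Optional channel names (default `Ch1..ChK`).
#' @param alpha Significance level for the adjusted p-values.
#' @return Data frame with columns `channel`, `p`, `p_adj`, `significant`.
#' @export
topo_stats <- function(control_features, noncontrol_features,
                       channel_labels = NULL, alpha = 0.05,
                       mode = c("signed-rank", "rank-sum")) {
  mode <- match.arg(mode)
  p <- channelwise_test(control_features, noncontrol_features, mode)
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%d", seq_along(p))
  if (length(channel_labels) != length(p))
    stop("`channel_labels` must match the channel count", call. = FALSE)
  p_adj <- bh_fdr(p)
  data.frame(channel = channel_labels, p = p, p_adj = p_adj,
             significant = p_adj < alpha, stringsAsFactors = FALSE)
}

# approximate 10-20 scalp coordinates for the standard montage
topo_coords <- function() {
  data.frame(
    channel = bci_channels,
    x = c(0, -0.35, 0.35, 0, -0.4, 0.4, 0, 0, -0.35, 0.35,
          0, -0.25, 0.25, -0.55, 0.55, 0),
    y = c(0.7, 0.65, 0.65, 0.25, 0.25, 0.25, 0.05, -0.15, -0.15, -0.15,
          -0.4, -0.42, -0.42, -0.5, -0.5, -0.65))
}

#' Plot a significance topography
#'
#' Simple scalp map of a [topo_stats()] table for the standard 16-channel
#' montage: channels are drawn at approximate 10-20 positions, filled when
#' significant.
#'
#' @param stats Data frame from [topo_stats()] (standard montage labels).
#' @param main Plot title.
#' @return Invisibly, the plotted coordinates.
#' @export
plot_topography <- function(stats, main = "Significant channels") {
  co <- merge(topo_coords(), stats, by = "channel", sort = FALSE)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(0.85 * cos(th), 0.85 * sin(th))
  graphics::points(co$x, co$y, pch = 21, cex = 3,
                   bg = ifelse(co$significant, "tomato", "white"))
  graphics::text(co$x, co$y - 0.12, co$channel, cex = 0.7)
  invisible(co)
}
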