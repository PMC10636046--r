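#' Pool myelin sheath segment lengths across axons
#'
#' One entry per contiguous >80%-wrapped segment (the pixel-level proxy for
#' internode length), pooled over all non-border axons of a condition.
#'
#' @param profiles List of `axon_wrap_profile`s.
#' @return Numeric vector of segment lengths, um.
#' @export
sheath_lengths <- function(profiles) {
  profiles <- Filter(function(p) !isTRUE(p$border_touching), profiles)
  unlist(lapply(profiles, function(p) p$segments$length_um), use.names = FALSE)
}

#' Boxplot-style summary of sheath lengths
#'
#' Quantiles by linear interpolation between order statistics; whiskers at
#' `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`; observations outside the whiskers are
#' reported as outliers.
#'
#' @param lengths Numeric vector of sheath lengths (um), `n >= 1`.
#' @return List: `n`, `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
length_stats <- function(lengths) {
  if (length(lengths) < 1L)
    abort_validation("no wrapped sheaths: cannot summarize an empty length set")
  q <- unname(stats::quantile(lengths, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  wl <- q[1] - 1.5 * iqr
  wh <- q[3] + 1.5 * iqr
  list(n = length(lengths), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = wl, whisker_high = wh,
       outliers = lengths[lengths < wl | lengths > wh])
}

#' Normalized histogram of sheath lengths above a minimum
#'
#' Bins lengths `>= min_length` into bins of `bin_width` um (default one
#' z-step, since lengths are quantized at z-step resolution); frequencies
#' sum to 1 whenever any qualifying length exists.
#'
#' @param lengths Numeric vector of lengths, um.
#' @param min_length Minimum qualifying length, um.
#' @param bin_width Bin width, um (> 0).
#' @return Data frame `bin_start`, `bin_end`, `count`, `frequency`
#'   (zero rows when nothing qualifies).
#' @export
length_histogram <- function(lengths, min_length = 6, bin_width = 2) {
  assert_scalar_num(bin_width, "bin_width", positive = TRUE)
  keep <- lengths[lengths >= min_length]
  if (length(keep) == 0L)
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0), frequency = numeric(0)))
  nb <- ceiling((max(keep) - min_length) / bin_width + 1e-9)
  nb <- max(nb, 1L)
  breaks <- min_length + bin_width * (0:nb)
  idx <- pmin(floor((keep - min_length) / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts, frequency = counts / sum(counts))
}

#' Wrapping index under an alternative sheath-length threshold
#'
#' Recomputes the wrapping index after reclassifying full wrapping with a
#' different minimum segment length (e.g. > 6 um vs > 10 um), keeping the
#' per-slice wrap fractions fixed. Monotone non-increasing in the
#' threshold.
#'
#' @param profiles List of `axon_wrap_profile`s for one field.
#' @param n_nuclei Nuclei count of the field (> 0).
#' @param min_segment_length Alternative threshold, um (> 0).
#' @return Wrapping index (fully wrapped / nuclei) at the new threshold.
#' @export
index_at_length_threshold <- function(profiles, n_nuclei, min_segment_length) {
  assert_scalar_num(min_segment_length, "min_segment_length", positive = TRUE)
  if (n_nuclei <= 0)
    abort_validation("wrapping index undefined for n_nuclei <= 0")
  profiles <- Filter(function(p) !isTRUE(p$border_touching), profiles)
  nfw <- sum(vapply(profiles, function(p)
    is_fully_wrapped(p$segments, min_segment_length), logical(1)))
  nfw / n_nuclei
}
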