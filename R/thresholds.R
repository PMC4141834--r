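#' Calling thresholds for the two-stage presence procedure
#'
#' Bundles every cutoff used by [call_otus()]. Defaults are the published
#' PhyloChip-style operating point: stage 1 requires at least seven scored
#' probe pairs, at least seven positive pairs (PM strictly greater than MM),
#' ranked response score (r) quartiles of at least 0.80 / 0.93 / 0.98, and a
#' positive fraction of at least 0.92. Stage 2 requires cross-hybridization
#' adjusted (rx) score quartiles of at least 0.22 / 0.40 / 0.42 at species
#' level. Consensus requires presence in at least 2 of 3 sample replicates.
#'
#' @param stage1_min_pairs Minimum number of scored probe pairs.
#' @param stage1_min_positive Minimum number of positive probe pairs.
#' @param stage1_r_quartiles Length-3 non-decreasing vector of minimum r-score
#'   quartiles (Q1, Q2, Q3).
#' @param stage1_positive_fraction Minimum fraction of positive pairs.
#' @param stage2_rx_quartiles Length-3 non-decreasing vector of minimum
#'   rx-score quartiles applied to the pooled pairs of a species.
#' @param consensus_min_replicates Replicates an OTU must be present in for
#'   the sample-level consensus call.
#' @return A list of class `call_thresholds`.
#' @export
call_thresholds <- function(stage1_min_pairs = 7L,
                            stage1_min_positive = 7L,
                            stage1_r_quartiles = c(0.80, 0.93, 0.98),
                            stage1_positive_fraction = 0.92,
                            stage2_rx_quartiles = c(0.22, 0.40, 0.42),
                            consensus_min_replicates = 2L) {
  stopifnot(
    stage1_min_pairs >= 1, stage1_min_positive >= 0,
    length(stage1_r_quartiles) == 3, length(stage2_rx_quartiles) == 3,
    !is.unsorted(stage1_r_quartiles), !is.unsorted(stage2_rx_quartiles),
    all(stage1_r_quartiles >= 0 & stage1_r_quartiles <= 1),
    all(stage2_rx_quartiles >= 0 & stage2_rx_quartiles <= 1),
    stage1_positive_fraction >= 0, stage1_positive_fraction <= 1,
    consensus_min_replicates >= 1
  )
  structure(
    list(
      stage1_min_pairs = as.integer(stage1_min_pairs),
      stage1_min_positive = as.integer(stage1_min_positive),
      stage1_r_quartiles = as.numeric(stage1_r_quartiles),
      stage1_positive_fraction = as.numeric(stage1_positive_fraction),
      stage2_rx_quartiles = as.numeric(stage2_rx_quartiles),
      consensus_min_replicates = as.integer(consensus_min_replicates)
    ),
    class = "call_thresholds"
  )
}

#' @export
print.call_thresholds <- function(x, ...) {
  cat("Two-stage calling thresholds\n")
  cat(sprintf("  stage 1: >=%d pairs scored, >=%d positive, r quartiles >= (%s), positive fraction >= %.2f\n",
              x$stage1_min_pairs, x$stage1_min_positive,
              paste(format(x$stage1_r_quartiles), collapse = ", "),
              x$stage1_positive_fraction))
  cat(sprintf("  stage 2: rx quartiles >= (%s) at species level\n",
              paste(format(x$stage2_rx_quartiles), collapse = ", ")))
  cat(sprintf("  consensus: present in >= %d replicates\n",
              x$consensus_min_replicates))
  invisible(x)
}
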