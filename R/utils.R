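#' @importFrom rlang .data .env
#' @importFrom stats quantile rnorm runif sd
NULL

# Type-7 (linear interpolation) quartiles, pinned for reproducibility.
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

# abort with a consistent condition class so callers can catch pipeline errors
pc_stop <- function(..., class = "phylocall_error") {
  rlang::abort(paste0(...), class = class)
}

pc_warn <- function(...) {
  rlang::warn(paste0(...), class = "phylocall_warning")
}

is_control_probe <- function(probe_id) startsWith(probe_id, "CTRL_")
is_spikein_probe <- function(probe_id) startsWith(probe_id, "CTRL_SPK")
is_background_control <- function(probe_id) {
  is_control_probe(probe_id) & !is_spikein_probe(probe_id)
}

# single array identifier used as column / ordination labels
array_id <- function(sample_id, replicate_id) {
  paste(sample_id, replicate_id, sep = ".")
}

#' Trimmed-mean hybridization score
#'
#' The abundance proxy for an OTU on one array: the mean of its
#' perfect-match (PM) probe intensities after removing exactly one maximum
#' and one minimum occurrence (not all tied extremes), so the score is
#' deterministic under ties.
#'
#' @param pm Numeric vector of PM intensities for one OTU (length >= 3).
#' @return A single numeric intensity.
#' @examples
#' hybridization_score(c(1, 2, 3, 4, 5)) # mean of 2,3,4 = 3
#' @export
hybridization_score <- function(pm) {
  if (length(pm) < 3) {
    pc_stop("hybridization score undefined: need >= 3 PM intensities, got ",
            length(pm))
  }
  s <- sort(pm)
  mean(s[-c(1L, length(s))])
}

# vectorised-by-group version returning NA rather than erroring (used in
# bulk call tables where degenerate sets simply fail the calling criteria)
hyb_score_or_na <- function(pm) {
  if (length(pm) < 3) return(NA_real_)
  s <- sort(pm)
  mean(s[-c(1L, length(s))])
}
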