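#' Background-subtract and spike-in-scale arrays
#'
#' Per replicate array: the background `b` is the 2nd percentile of all probe
#' intensities on the array (PM and MM, controls included); `b` is subtracted
#' from every intensity, intensities are rescaled so the mean
#' background-subtracted spike-in PM intensity equals `spikein_level`, and
#' finally floored at 1 intensity unit. The floor keeps log2 abundance
#' weights non-negative downstream; applying it after scaling makes the
#' result exactly invariant to a common multiplicative factor on the raw
#' intensities.
#'
#' @param arrays Long-format array tibble ([read_intensity_table()] /
#'   [simulate_arrays()]).
#' @param spikein_level Reference intensity the spike-in standards are scaled
#'   to (arbitrary units).
#' @return The same tibble with `pm` and `mm` replaced by preprocessed values.
#' @export
preprocess_arrays <- function(arrays, spikein_level = 1000) {
  arrays |>
    dplyr::group_by(.data$array_id) |>
    dplyr::group_modify(function(df, key) {
      b <- stats::quantile(c(df$pm, df$mm), probs = 0.02, type = 7,
                           names = FALSE)
      spk <- is_spikein_probe(df$probe_id)
      if (!any(spk)) {
        pc_stop("array ", key$array_id, " has no spike-in (CTRL_SPK) probes")
      }
      spk_mean <- mean(df$pm[spk] - b)
      if (spk_mean <= 0) {
        pc_stop("array ", key$array_id,
                " has non-positive mean spike-in intensity after background ",
                "subtraction")
      }
      f <- spikein_level / spk_mean
      df$pm <- pmax((df$pm - b) * f, 1)
      df$mm <- pmax((df$mm - b) * f, 1)
      df
    }) |>
    dplyr::ungroup()
}

# A+T bin index; the top bin absorbs at_count = 25 when width divides 25
at_bin <- function(at_count, bin_width) {
  pmin(at_count %/% bin_width,
       (25L %/% bin_width) - as.integer(25L %% bin_width == 0L))
}

#' Probe-pair response and ranked response scores
#'
#' For every scored probe pair, the response score
#' `d = (PM - MM) / (PM + MM)` (0 when the denominator is 0) and the ranked
#' response score `r`: the fraction of background-pool pairs in the same A+T
#' bin whose `d` is strictly less than this pair's `d`. The background pool
#' is array-specific and label-free: all background control probes plus the
#' probes of OTUs ineligible for stage 1 (fewer positive pairs than
#' `stage1_min_positive`). A probe shared with any eligible OTU stays out of
#' the pool.
#'
#' @param arrays Preprocessed long-format array tibble.
#' @param reference A [reference_set()].
#' @param thresholds A [call_thresholds()].
#' @param bin_width Width of the A+T bins (default 5: 0-4, 5-9, ...).
#' @return A tibble with one row per scored (array, OTU, probe) with columns
#'   `positive`, `d`, `r`.
#' @export
score_probes <- function(arrays, reference, thresholds = call_thresholds(),
                         bin_width = 5L) {
  bg_ids <- reference$controls$probe_id[
    reference$controls$control_type == "background"]
  bg_at <- stats::setNames(reference$controls$at_count, reference$controls$probe_id)

  arrays |>
    dplyr::group_by(.data$array_id, .data$sample_id, .data$replicate_id,
                    .data$condition_label) |>
    dplyr::group_modify(function(df, key) {
      score_one_array(df, key$array_id, reference, thresholds,
                      bin_width, bg_ids, bg_at)
    }) |>
    dplyr::ungroup()
}

score_one_array <- function(df, this_array, reference, thresholds,
                            bin_width, bg_ids, bg_at) {
  scored <- dplyr::inner_join(reference$probes, df[, c("probe_id", "pm", "mm")],
                              by = "probe_id",
                              relationship = "many-to-many")
  if (nrow(scored) == 0) {
    pc_stop("array ", this_array, " shares no probes with the reference")
  }
  tot <- scored$pm + scored$mm
  scored$d <- ifelse(tot == 0, 0, (scored$pm - scored$mm) / tot)
  scored$positive <- scored$pm > scored$mm

  n_pos <- tapply(scored$positive, scored$otu_id, sum)
  ineligible <- names(n_pos)[n_pos < thresholds$stage1_min_positive]

  # pool: background controls + probes belonging only to ineligible OTUs
  probe_eligible <- tapply(!(scored$otu_id %in% ineligible), scored$probe_id, any)
  pool_target <- scored[!duplicated(scored$probe_id), ]
  pool_target <- pool_target[!probe_eligible[pool_target$probe_id], ]

  bg_rows <- df[df$probe_id %in% bg_ids, c("probe_id", "pm", "mm")]
  bg_tot <- bg_rows$pm + bg_rows$mm
  pool <- tibble::tibble(
    at_count = c(unname(bg_at[bg_rows$probe_id]), pool_target$at_count),
    d = c(ifelse(bg_tot == 0, 0, (bg_rows$pm - bg_rows$mm) / bg_tot),
          pool_target$d)
  )
  pool$bin <- at_bin(pool$at_count, bin_width)
  scored$bin <- at_bin(scored$at_count, bin_width)

  pool_split <- split(pool$d, pool$bin)
  need <- unique(scored$bin)
  empty <- setdiff(as.character(need), names(pool_split))
  if (length(empty) > 0) {
    pc_stop("empty background A+T bin(s) ", paste(empty, collapse = ", "),
            " on array ", this_array, "; widen the binning (bin_width)")
  }
  small <- names(pool_split)[lengths(pool_split) < 50 &
                               names(pool_split) %in% as.character(need)]
  if (length(small) > 0) {
    pc_warn("background pool has fewer than 50 pairs in A+T bin(s) ",
            paste(small, collapse = ", "), " on array ", this_array)
  }

  scored$r <- NA_real_
  for (b in as.character(need)) {
    idx <- scored$bin == as.integer(b)
    srt <- sort(pool_split[[b]])
    scored$r[idx] <- findInterval(scored$d[idx], srt, left.open = TRUE) /
      length(srt)
  }
  scored[, c("otu_id", "species_id", "probe_id", "at_count",
             "pm", "mm", "positive", "d", "r")]
}

#' Stage-1 presence criteria per OTU
#'
#' An OTU passes stage 1 on an array when (1) at least `stage1_min_pairs`
#' probe pairs were scored, (2) at least `stage1_min_positive` pairs are
#' positive (PM strictly greater than MM), (3) its r-score quartiles meet the
#' quartile cutoffs, and (4) its positive fraction meets the cutoff. All four
#' criterion flags are recorded; degenerate probe sets fail criteria rather
#' than raise.
#'
#' @param scores Scored pairs from [score_probes()] (may cover many arrays).
#' @param thresholds A [call_thresholds()].
#' @return A per-(array, OTU) tibble with criterion flags, `stage1_pass`, and
#'   the trimmed-mean `hybridization_score` (NA when fewer than 3 pairs).
#' @export
stage1_call <- function(scores, thresholds = call_thresholds()) {
  grp_cols <- intersect(c("array_id", "sample_id", "replicate_id",
                          "condition_label", "otu_id", "species_id"),
                        names(scores))
  scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_positive = sum(.data$positive),
      positive_fraction = n_positive / n_pairs,
      r_q1 = quartiles(.data$r)[1],
      r_q2 = quartiles(.data$r)[2],
      r_q3 = quartiles(.data$r)[3],
      hybridization_score = hyb_score_or_na(.data$pm),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      crit_min_pairs = .data$n_pairs >= thresholds$stage1_min_pairs,
      crit_min_positive = .data$n_positive >= thresholds$stage1_min_positive,
      crit_r_quartiles = .data$r_q1 >= thresholds$stage1_r_quartiles[1] &
        .data$r_q2 >= thresholds$stage1_r_quartiles[2] &
        .data$r_q3 >= thresholds$stage1_r_quartiles[3],
      crit_positive_fraction =
        .data$positive_fraction >= thresholds$stage1_positive_fraction,
      stage1_pass = .data$crit_min_pairs & .data$crit_min_positive &
        .data$crit_r_quartiles & .data$crit_positive_fraction
    )
}

#' Stage-2 cross-hybridization adjustment and species-level presence
#'
#' For every pair of a stage-1-passing OTU, the adjusted score `rx = r / s`
#' where `s` counts the stage-1-passing OTUs on the same array whose probe
#' sets contain that probe (so `rx <= r`, `s >= 1`). A species is present
#' when the rx quartiles over the pooled pairs of its stage-1-passing OTUs
#' meet the stage-2 cutoffs; an OTU is present when it passed stage 1 and its
#' species is present. Species with no stage-1 passer are absent.
#'
#' @param scores Scored pairs from [score_probes()].
#' @param stage1 Stage-1 table from [stage1_call()].
#' @param reference A [reference_set()].
#' @param thresholds A [call_thresholds()].
#' @return The stage-1 table with species-level `rx_q1..rx_q3`, `stage2_pass`
#'   and the final per-array `present` flag appended.
#' @export
stage2_call <- function(scores, stage1, reference,
                        thresholds = call_thresholds()) {
  passers <- stage1[stage1$stage1_pass,
                    c("array_id", "otu_id", "species_id")]
  if (nrow(passers) == 0) {
    return(dplyr::mutate(stage1, rx_q1 = NA_real_, rx_q2 = NA_real_,
                         rx_q3 = NA_real_, stage2_pass = FALSE,
                         present = FALSE))
  }

  # s: per array, how many passing OTUs' probe sets contain each probe
  share <- passers |>
    dplyr::inner_join(reference$probes[, c("probe_id", "otu_id")],
                      by = "otu_id", relationship = "many-to-many") |>
    dplyr::count(.data$array_id, .data$probe_id, name = "s")

  sp <- scores |>
    dplyr::semi_join(passers, by = c("array_id", "otu_id")) |>
    dplyr::inner_join(share, by = c("array_id", "probe_id")) |>
    dplyr::mutate(rx = .data$r / .data$s) |>
    dplyr::group_by(.data$array_id, .data$species_id) |>
    dplyr::summarise(
      rx_q1 = quartiles(.data$rx)[1],
      rx_q2 = quartiles(.data$rx)[2],
      rx_q3 = quartiles(.data$rx)[3],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      stage2_pass = .data$rx_q1 >= thresholds$stage2_rx_quartiles[1] &
        .data$rx_q2 >= thresholds$stage2_rx_quartiles[2] &
        .data$rx_q3 >= thresholds$stage2_rx_quartiles[3]
    )

  stage1 |>
    dplyr::left_join(sp, by = c("array_id", "species_id")) |>
    dplyr::mutate(
      stage2_pass = !is.na(.data$stage2_pass) & .data$stage2_pass,
      present = .data$stage1_pass & .data$stage2_pass
    )
}

#' Run the full two-stage calling procedure on a set of arrays
#'
#' Convenience wrapper: [score_probes()] then [stage1_call()] then
#' [stage2_call()]. Arrays must be preprocessed first
#' ([preprocess_arrays()]). OTUs with no scored probe on an array do not
#' appear in the table and are treated as absent downstream.
#'
#' @inheritParams score_probes
#' @return The per-(array, OTU) call table.
#' @export
call_otus <- function(arrays, reference, thresholds = call_thresholds(),
                      bin_width = 5L) {
  scores <- score_probes(arrays, reference, thresholds, bin_width)
  s1 <- stage1_call(scores, thresholds)
  stage2_call(scores, s1, reference, thresholds)
}

#' Replicate consensus presence per sample
#'
#' With separate replicates (`pooled = FALSE`) an OTU is present in a sample
#' when it is present on at least `consensus_min_replicates` of its replicate
#' arrays (default 2 of 3). With `pooled = TRUE` (a single array hybridized
#' with pooled biomass) any detection counts.
#'
#' @param calls Per-array call table from [call_otus()].
#' @param thresholds A [call_thresholds()].
#' @param pooled Logical: replicates were pooled onto one array.
#' @return A per-(sample, OTU) tibble with `n_replicates`, `n_present`,
#'   `present`.
#' @export
consensus_presence <- function(calls, thresholds = call_thresholds(),
                               pooled = FALSE) {
  if (nrow(calls) == 0) pc_stop("no replicate calls supplied")
  reps <- calls |>
    dplyr::distinct(.data$sample_id, .data$replicate_id) |>
    dplyr::count(.data$sample_id, name = "n_replicates")
  calls |>
    dplyr::group_by(.data$sample_id, .data$condition_label, .data$otu_id,
                    .data$species_id) |>
    dplyr::summarise(n_present = sum(.data$present), .groups = "drop") |>
    dplyr::left_join(reps, by = "sample_id") |>
    dplyr::mutate(
      present = if (pooled) .data$n_present >= 1L
                else .data$n_present >= thresholds$consensus_min_replicates
    )
}

#' Roll consensus OTU presence up the taxonomy
#'
#' A taxon at any rank (species up to phylum) is present in a sample when at
#' least one present OTU carries it in its lineage, i.e. at least one species
#' of the lineage was called present.
#'
#' @param consensus Consensus table from [consensus_presence()].
#' @param reference A [reference_set()] supplying the lineages.
#' @return A tibble with one row per (sample, rank, taxon) over all taxa in
#'   the reference, with a `present` flag.
#' @export
rollup_taxa <- function(consensus, reference) {
  missing <- setdiff(unique(consensus$otu_id), reference$taxonomy$otu_id)
  if (length(missing) > 0) {
    pc_stop("OTU(s) without lineage: ", paste(utils::head(missing, 5),
                                              collapse = ", "))
  }
  tax_long <- reference$taxonomy |>
    tidyr::pivot_longer(dplyr::all_of(rank_names()),
                        names_to = "rank", values_to = "taxon")
  all_taxa <- dplyr::distinct(tax_long, .data$rank, .data$taxon)

  present_taxa <- consensus |>
    dplyr::filter(.data$present) |>
    dplyr::inner_join(tax_long, by = "otu_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$sample_id, .data$rank, .data$taxon) |>
    dplyr::mutate(present = TRUE)

  tidyr::crossing(sample_id = unique(consensus$sample_id), all_taxa) |>
    dplyr::left_join(present_taxa, by = c("sample_id", "rank", "taxon")) |>
    dplyr::mutate(present = !is.na(.data$present),
                  rank = factor(.data$rank, levels = rank_names())) |>
    dplyr::arrange(.data$sample_id, .data$rank, .data$taxon)
}

#' Count present taxa per rank (OTU level included)
#'
#' The per-sample richness summary: number of present OTUs and of present
#' taxa at each rank from species to phylum.
#'
#' @param rollup Output of [rollup_taxa()].
#' @param consensus Output of [consensus_presence()] (for the OTU counts).
#' @return A tibble with columns `sample_id`, `rank`, `n_present`.
#' @export
count_taxa <- function(rollup, consensus) {
  taxa_counts <- rollup |>
    dplyr::group_by(.data$sample_id, .data$rank) |>
    dplyr::summarise(n_present = sum(.data$present), .groups = "drop") |>
    dplyr::mutate(rank = as.character(.data$rank))
  otu_counts <- consensus |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_present = sum(.data$present), .groups = "drop") |>
    dplyr::mutate(rank = "otu")
  dplyr::bind_rows(otu_counts, taxa_counts) |>
    dplyr::mutate(rank = factor(.data$rank, levels = c("otu", rev(rank_names())))) |>
    dplyr::arrange(.data$sample_id, .data$rank)
}
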