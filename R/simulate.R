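#' Configuration for the synthetic chip experiment
#'
#' Defines the simulated study: a chip whose per-OTU probe-pair counts are
#' drawn from Normal(37, 9.6) truncated below at `pairs_min`, a taxonomy and
#' matching rooted phylogeny, group-structured communities sampled in
#' triplicate, planted indicator OTUs with perfect fidelity and specificity,
#' and PM/MM intensity generation with a mismatch leak, probe-level noise,
#' tree-targeted cross-hybridization, spike-in standards, and background
#' controls.
#'
#' @param n_otus Number of target OTUs on the chip.
#' @param n_species Number of species (OTUs are sub-species bins; contiguous
#'   blocks of OTUs share a species).
#' @param n_groups Number of a priori groups (e.g. sampling dates or carbon
#'   sources).
#' @param samples_per_group Biological samples per group.
#' @param replicates Replicate arrays per sample (default 3).
#' @param pairs_mean,pairs_sd,pairs_min Probe-pair count distribution per OTU.
#' @param at_count_range Inclusive range for per-probe A+T counts.
#' @param probe_share_rate Fraction of an OTU's probes shared with a sibling
#'   OTU of the same species (exercises the stage-2 adjustment).
#' @param base_presence Fraction of OTUs present in every sample.
#' @param n_shifted Core OTUs per group receiving an abundance shift.
#' @param effect_size Between-group abundance shift in log2 units.
#' @param n_indicators Planted indicator OTUs per group (present in all
#'   replicates of their group, absent elsewhere).
#' @param crosshyb_rate Probability a probe also receives signal from the
#'   tree-nearest other present OTU.
#' @param crosshyb_strength Fraction of the neighbour's signal leaking in.
#' @param noise_sd Relative noise (lognormal replicate jitter of abundances
#'   and Gaussian probe-level noise).
#' @param background_mean,background_sd Per-pair shared background intensity.
#' @param gain Intensity units per abundance unit.
#' @param leak MM response as a fraction of PM response (< 1).
#' @param spikein_level Spike-in standard intensity.
#' @param n_spikein,n_bg_controls Numbers of spike-in and background control
#'   probes.
#' @param abundance_meanlog,abundance_sdlog Lognormal baseline abundances.
#' @param seed Integer master seed; every generator is deterministic under it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_otus = 150, n_species = 60, n_groups = 3,
                              samples_per_group = 1, replicates = 3,
                              pairs_mean = 37, pairs_sd = 9.6, pairs_min = 10,
                              at_count_range = c(8L, 17L),
                              probe_share_rate = 0.10,
                              base_presence = 0.40, n_shifted = 20,
                              effect_size = 2, n_indicators = 5,
                              crosshyb_rate = 0.10, crosshyb_strength = 0.5,
                              noise_sd = 0.2,
                              background_mean = 50, background_sd = 10,
                              gain = 100, leak = 0.3,
                              spikein_level = 1000,
                              n_spikein = 20, n_bg_controls = 300,
                              abundance_meanlog = log(30),
                              abundance_sdlog = 0.7,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_otus >= 1, n_species >= 1, n_species <= n_otus, n_groups >= 1,
    samples_per_group >= 1, replicates >= 1,
    pairs_min >= 3, pairs_mean > 0, pairs_sd >= 0,
    probe_share_rate >= 0, probe_share_rate <= 1,
    crosshyb_rate >= 0, crosshyb_rate <= 1,
    base_presence >= 0, base_presence <= 1,
    noise_sd >= 0, leak >= 0, leak < 1, gain > 0, spikein_level > 0,
    n_spikein >= 1
  )
  if (n_otus < n_groups * n_indicators) {
    pc_stop("n_otus must be at least n_groups * n_indicators (",
            n_groups * n_indicators, ")")
  }
  structure(cfg, class = "simulation_config")
}

# split n items into k contiguous blocks with sizes differing by <= 1
contiguous_blocks <- function(n, k) {
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Simulate the chip reference: probe design, taxonomy, and tree
#'
#' Per-OTU probe-pair counts are `max(pairs_min, round(Normal(37, 9.6)))`;
#' A+T counts are uniform over `at_count_range`. OTUs nest into species,
#' species into a fixed genus/family/order/class/phylum hierarchy, and the
#' rooted tree is built along that hierarchy (clades align with taxonomy
#' ranks) with uniform random branch lengths. Within multi-OTU species a
#' fraction of probes is shared between sibling OTUs.
#'
#' @param config A [simulation_config()].
#' @return A [reference_set()] (with tree).
#' @export
simulate_reference <- function(config) {
  withr::with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(config) {
  n <- config$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(n))
  sp_of_otu <- contiguous_blocks(n, config$n_species)
  species_ids <- sprintf("SP%03d", sp_of_otu)

  # fixed nested hierarchy above species (halving fan-in per rank)
  up <- function(x, width) (x - 1L) %/% width + 1L
  sp <- seq_len(config$n_species)
  genus <- up(sp, 2L); family <- up(genus, 2L); order <- up(family, 2L)
  class <- up(order, 2L); phylum <- up(class, 2L)
  taxonomy <- tibble::tibble(
    otu_id = otu_ids,
    phylum = sprintf("p%02d", phylum[sp_of_otu]),
    class = sprintf("c%02d", class[sp_of_otu]),
    order = sprintf("o%02d", order[sp_of_otu]),
    family = sprintf("f%02d", family[sp_of_otu]),
    genus = sprintf("g%02d", genus[sp_of_otu]),
    species = sprintf("s%03d", sp_of_otu)
  )

  tree <- ape::read.tree(text = hierarchy_newick(taxonomy))

  n_pairs <- pmax(config$pairs_min,
                  round(rnorm(n, config$pairs_mean, config$pairs_sd)))
  at_lo <- config$at_count_range[1]; at_hi <- config$at_count_range[2]

  probes_by_otu <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_pairs[i]
    own <- tibble::tibble(
      probe_id = sprintf("PR_%s_%03d", otu_ids[i], seq_len(k)),
      otu_id = otu_ids[i],
      species_id = species_ids[i],
      at_count = sample(at_lo:at_hi, k, replace = TRUE)
    )
    # share a slice of probes with the first OTU of the same species
    first <- match(sp_of_otu[i], sp_of_otu)
    n_share <- floor(config$probe_share_rate * k)
    if (i != first && n_share > 0) {
      donor <- probes_by_otu[[first]]
      n_share <- min(n_share, nrow(donor))
      pick <- sample(nrow(donor), n_share)
      own[seq_len(n_share), c("probe_id", "at_count")] <-
        donor[pick, c("probe_id", "at_count")]
    }
    probes_by_otu[[i]] <- own
  }
  probes <- dplyr::bind_rows(probes_by_otu)

  controls <- tibble::tibble(
    probe_id = c(sprintf("CTRL_SPK_%03d", seq_len(config$n_spikein)),
                 sprintf("CTRL_BG_%03d", seq_len(config$n_bg_controls))),
    control_type = c(rep("spikein", config$n_spikein),
                     rep("background", config$n_bg_controls)),
    at_count = sample(at_lo:at_hi, config$n_spikein + config$n_bg_controls,
                      replace = TRUE)
  )

  reference_set(probes, taxonomy, controls = controls, tree = tree)
}

# newick over OTUs following the taxonomy hierarchy; single-child internal
# nodes are collapsed so every internal node has >= 2 children
hierarchy_newick <- function(taxonomy) {
  build <- function(rows, level) {
    if (level > length(rank_names())) {
      tips <- rows$otu_id
      if (length(tips) == 1) {
        return(sprintf("%s:%.6f", tips, runif(1, 0.05, 1)))
      }
      return(sprintf("(%s):%.6f",
                     paste(sprintf("%s:%.6f", tips,
                                   runif(length(tips), 0.05, 1)),
                           collapse = ","),
                     runif(1, 0.05, 1)))
    }
    rank <- rank_names()[level]
    parts <- split(rows, rows[[rank]])
    subs <- vapply(parts[order(names(parts))], build, character(1),
                   level = level + 1)
    if (length(subs) == 1) return(unname(subs))
    sprintf("(%s):%.6f", paste(subs, collapse = ","), runif(1, 0.05, 1))
  }
  # the root itself must be binary (a basal multifurcation reads as
  # unrooted), so phylum subtrees are joined pairwise
  parts <- split(taxonomy, taxonomy$phylum)
  subs <- vapply(parts[order(names(parts))], build, character(1), level = 2L)
  while (length(subs) > 2) {
    subs <- c(sprintf("(%s,%s):%.6f", subs[1], subs[2], runif(1, 0.05, 1)),
              subs[-(1:2)])
  }
  if (length(subs) == 1) {
    sprintf("%s;", sub(":[0-9.]+$", "", subs))
  } else {
    sprintf("(%s,%s);", subs[1], subs[2])
  }
}

#' Simulate group-structured communities with known ground truth
#'
#' A core of OTUs (fraction `base_presence`) is present in every sample with
#' shared lognormal baseline abundances. Per group, `n_shifted` core OTUs
#' receive a `2^effect_size` multiplicative abundance shift, and
#' `n_indicators` planted indicator OTUs are present only in that group's
#' samples. Everything else is absent.
#'
#' @param config A [simulation_config()].
#' @param reference The [simulate_reference()] output.
#' @return A list of class `ground_truth`: `samples` (sample metadata with
#'   group labels), `presence` (OTU x sample logical matrix), `abundance`
#'   (OTU x sample matrix), `indicators` (tibble otu_id, group).
#' @export
simulate_communities <- function(config, reference) {
  withr::with_seed(config$seed + 1L, simulate_communities_impl(config, reference))
}

simulate_communities_impl <- function(config, reference) {
  otu_ids <- unique(reference$probes$otu_id)
  n <- length(otu_ids)
  groups <- sprintf("G%d", seq_len(config$n_groups))
  samples <- tibble::tibble(
    sample_id = as.vector(t(outer(groups, seq_len(config$samples_per_group),
                                  function(g, s) sprintf("%s_S%d", g, s)))),
    condition_label = rep(groups, each = config$samples_per_group)
  )

  n_core <- floor(config$base_presence * n)
  core <- sample(otu_ids, n_core)
  pool <- setdiff(otu_ids, core)
  n_ind <- config$n_indicators * config$n_groups
  if (length(pool) < n_ind) pc_stop("not enough OTUs left to plant indicators")
  ind_otus <- sample(pool, n_ind)
  indicators <- tibble::tibble(
    otu_id = ind_otus,
    group = rep(groups, each = config$n_indicators)
  )

  base <- stats::setNames(
    stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog),
    otu_ids)

  shifted <- lapply(groups, function(g) {
    if (config$n_shifted == 0 || n_core == 0) return(character(0))
    sample(core, min(config$n_shifted, n_core))
  })
  names(shifted) <- groups

  presence <- matrix(FALSE, n, nrow(samples),
                     dimnames = list(otu_ids, samples$sample_id))
  abundance <- matrix(0, n, nrow(samples),
                      dimnames = list(otu_ids, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    g <- samples$condition_label[s]
    present <- c(core, indicators$otu_id[indicators$group == g])
    presence[present, s] <- TRUE
    a <- base[present]
    a[names(a) %in% shifted[[g]]] <- a[names(a) %in% shifted[[g]]] *
      2^config$effect_size
    abundance[present, s] <- a
  }

  structure(
    list(samples = samples, presence = presence, abundance = abundance,
         indicators = indicators),
    class = "ground_truth"
  )
}

#' Simulate replicate PM/MM arrays from a ground truth
#'
#' For each replicate array, true abundances get a lognormal jitter
#' (`noise_sd`). Each probe pair shares one background draw; the PM channel
#' receives `gain * abundance * (1 + e1)` of signal summed over every present
#' OTU whose probe set contains the probe, the MM channel receives `leak`
#' times that; with probability `crosshyb_rate` a probe additionally receives
#' `crosshyb_strength` of the signal of the tree-nearest other present OTU.
#' Channel noise is Normal(0, `noise_sd * background_mean`). Spike-in
#' controls sit at `spikein_level`; background controls at background only.
#'
#' @param truth A `ground_truth` from [simulate_communities()].
#' @param reference The [simulate_reference()] output.
#' @param config The [simulation_config()].
#' @return A long-format array tibble (same shape as
#'   [read_intensity_table()]).
#' @export
simulate_arrays <- function(truth, reference, config) {
  withr::with_seed(config$seed + 2L,
                   simulate_arrays_impl(truth, reference, config))
}

simulate_arrays_impl <- function(truth, reference, config) {
  probes <- reference$probes
  controls <- reference$controls
  coph <- ape::cophenetic.phylo(reference$tree)
  otu_ids <- rownames(truth$presence)

  out <- vector("list", nrow(truth$samples) * config$replicates)
  k <- 0L
  for (s in seq_len(nrow(truth$samples))) {
    sid <- truth$samples$sample_id[s]
    cond <- truth$samples$condition_label[s]
    present <- otu_ids[truth$presence[, s]]
    for (r in seq_len(config$replicates)) {
      k <- k + 1L
      a <- truth$abundance[, s] *
        exp(rnorm(length(otu_ids), 0, config$noise_sd))
      names(a) <- otu_ids
      a[!otu_ids %in% present] <- 0

      # nearest present neighbour of every OTU (for cross-hybridization)
      nearest <- rep(NA_character_, length(otu_ids))
      names(nearest) <- otu_ids
      if (config$crosshyb_rate > 0 && length(present) > 0) {
        for (o in otu_ids) {
          cand <- setdiff(present, o)
          if (length(cand) > 0) {
            nearest[o] <- cand[which.min(coph[o, cand])]
          }
        }
      }

      # signal per probe: abundance summed over OTUs whose sets share it
      per_probe <- tapply(a[probes$otu_id], probes$probe_id, sum)
      sig <- as.numeric(per_probe[probes$probe_id])

      if (config$crosshyb_rate > 0 && length(present) > 0) {
        hit <- runif(nrow(probes)) < config$crosshyb_rate
        nb <- nearest[probes$otu_id]
        extra <- ifelse(hit & !is.na(nb),
                        config$crosshyb_strength * a[nb], 0)
        extra[is.na(extra)] <- 0
        sig <- sig + extra
      }

      target <- probe_intensities(sig, config, n = nrow(probes))
      # controls: spike-ins at spikein_level (as abundance-equivalents),
      # background controls at pure background
      ctrl_sig <- ifelse(controls$control_type == "spikein",
                         config$spikein_level / config$gain, 0)
      ctrl <- probe_intensities(ctrl_sig, config, n = nrow(controls))

      dedup <- !duplicated(probes$probe_id)
      out[[k]] <- tibble::tibble(
        sample_id = sid,
        replicate_id = sprintf("R%d", r),
        condition_label = cond,
        probe_id = c(probes$probe_id[dedup], controls$probe_id),
        pm = unname(c(target$pm[dedup], ctrl$pm)),
        mm = unname(c(target$mm[dedup], ctrl$mm))
      )
    }
  }
  tbl <- dplyr::bind_rows(out)
  tbl$array_id <- array_id(tbl$sample_id, tbl$replicate_id)
  tbl
}

# One background draw is shared by the two probes of a pair (they sit in the
# same neighbourhood of the chip); each channel then fluctuates by a small
# multiplicative factor (cv = noise_sd / 10), and the target signal itself
# carries multiplicative noise_sd. With noise_sd = 0 a present OTU's PM
# strictly exceeds its MM (leak < 1) while absent pairs tie.
probe_intensities <- function(abund_sig, config, n) {
  bg <- pmax(rnorm(n, config$background_mean, config$background_sd), 0)
  cv <- config$noise_sd / 10
  signal <- config$gain * abund_sig
  pm <- bg * (1 + rnorm(n, 0, cv)) +
    signal * (1 + rnorm(n, 0, config$noise_sd))
  mm <- bg * (1 + rnorm(n, 0, cv)) +
    config$leak * signal * (1 + rnorm(n, 0, config$noise_sd))
  list(pm = pmax(pm, 0), mm = pmax(mm, 0))
}

#' Run the full synthetic chip experiment
#'
#' [simulate_reference()], [simulate_communities()] and [simulate_arrays()]
#' in sequence, each deterministic under `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `chip_simulation`: `config`, `reference`, `truth`,
#'   `arrays`.
#' @export
simulate_chip_experiment <- function(config = simulation_config()) {
  reference <- simulate_reference(config)
  truth <- simulate_communities(config, reference)
  arrays <- simulate_arrays(truth, reference, config)
  structure(list(config = config, reference = reference, truth = truth,
                 arrays = arrays),
            class = "chip_simulation")
}

#' Write a simulation to a fixture directory
#'
#' Emits `annotation.tsv`, `taxonomy.tsv`, `tree.nwk`, `intensities.tsv`,
#' `metadata.tsv`, and `truth.json` — the complete input set for
#' [run_pipeline()] plus the ground truth for recovery checks.
#'
#' @param sim A [simulate_chip_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_probe_annotation(sim$reference, p("annotation.tsv"), p("taxonomy.tsv"),
                         tree_path = p("tree.nwk"))
  write_intensity_table(sim$arrays, p("intensities.tsv"))
  readr::write_tsv(sim$truth$samples, p("metadata.tsv"))
  jsonlite::write_json(
    list(
      presence = as.data.frame(sim$truth$presence) |>
        tibble::rownames_to_column("otu_id"),
      abundance = as.data.frame(sim$truth$abundance) |>
        tibble::rownames_to_column("otu_id"),
      indicators = sim$truth$indicators,
      samples = sim$truth$samples,
      seed = sim$config$seed
    ),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(file.path(dir, c("annotation.tsv", "taxonomy.tsv", "tree.nwk",
                             "intensities.tsv", "metadata.tsv", "truth.json")))
}
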