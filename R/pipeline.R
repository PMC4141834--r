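#' Configure an end-to-end pipeline run
#'
#' Bundles input paths, thresholds, transform and linkage choices, the
#' permutation budget, the seed, and the output directory. Referenced input
#' files must exist at validation time.
#'
#' @param annotation,taxonomy,intensities Input TSV paths.
#' @param tree Optional Newick path (required when the `unifrac` stage is
#'   enabled).
#' @param out_dir Output directory.
#' @param thresholds A [call_thresholds()].
#' @param spikein_level Reference spike-in level for preprocessing.
#' @param bin_width A+T bin width for r scores.
#' @param pooled Treat each sample's replicates as pooled (single-array
#'   presence rule).
#' @param transform Matrix fed to the distance functions: `"arcsine"` or
#'   `"relativized"`.
#' @param linkage,beta Clustering linkage and flexible-beta parameter.
#' @param cut_level Dendrogram cut level (default: number of conditions).
#' @param n_permutations Permutations for MRPP / INDVAL (default 1000).
#' @param seed Integer seed recorded in every output.
#' @param stages Stages to run, a subset of
#'   `c("call", "matrix", "cluster", "mrpp", "indval", "unifrac", "pcoa")`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, taxonomy, intensities, tree = NULL,
                            out_dir,
                            thresholds = call_thresholds(),
                            spikein_level = 1000, bin_width = 5L,
                            pooled = FALSE,
                            transform = c("arcsine", "relativized"),
                            linkage = c("group_average", "flexible_beta"),
                            beta = -0.25, cut_level = NULL,
                            n_permutations = 1000, seed = 1L,
                            stages = c("call", "matrix", "cluster", "mrpp",
                                       "indval", "unifrac", "pcoa")) {
  transform <- match.arg(transform)
  linkage <- match.arg(linkage)
  stages <- match.arg(stages, several.ok = TRUE)
  for (f in c(annotation, taxonomy, intensities, tree)) {
    if (!file.exists(f)) pc_stop("input file not found: ", f)
  }
  structure(
    list(annotation = annotation, taxonomy = taxonomy,
         intensities = intensities, tree = tree, out_dir = out_dir,
         thresholds = thresholds, spikein_level = spikein_level,
         bin_width = bin_width, pooled = pooled, transform = transform,
         linkage = linkage, beta = beta, cut_level = cut_level,
         n_permutations = n_permutations, seed = as.integer(seed),
         stages = stages),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; threshold overrides go
#' under a `thresholds:` mapping.
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @param seed Optional override of the configured seed.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  thr <- do.call(call_thresholds, y$thresholds %||% list())
  y$thresholds <- NULL
  args <- y
  args$thresholds <- thr
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes preprocess -> two-stage calling -> replicate consensus ->
#' taxonomic roll-up -> community matrix and transforms -> Bray-Curtis
#' clustering, MRPP, indicator analysis, weighted UniFrac, and PCoA (as
#' enabled), writing TSV/JSON outputs and a run manifest. Any stage error
#' aborts with the stage name. Identical config and seed produce
#' byte-identical output trees; wall-clock stage timings therefore live only
#' in the returned manifest object, not in the files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run manifest (list): config snapshot, stage
#'   timings, accumulated warnings, file inventory, package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if ("unifrac" %in% config$stages && is.null(config$tree)) {
    pc_stop("stage 'unifrac' failed: no tree supplied in the configuration")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  warnings <- character()
  timings <- list()

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        pc_stop("stage '", name, "' failed: ", conditionMessage(e))
      }),
      warning = function(w) {
        warnings[[length(warnings) + 1]] <<-
          paste0(name, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  emit <- function(name) {
    files <<- c(files, name)
    file.path(config$out_dir, name)
  }
  wjson <- function(x, name) {
    jsonlite::write_json(x, emit(name), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  wdist <- function(d, name) {
    readr::write_tsv(tibble::as_tibble(as.matrix(d), rownames = "array_id"),
                     emit(name))
  }

  reference <- run_stage("input", read_probe_annotation(
    config$annotation, config$taxonomy, tree_path = config$tree))
  arrays <- run_stage("input", read_intensity_table(config$intensities,
                                                    reference))

  arrays <- run_stage("preprocess",
                      preprocess_arrays(arrays, config$spikein_level))

  calls <- run_stage("call", call_otus(arrays, reference, config$thresholds,
                                       config$bin_width))
  consensus <- run_stage("call", consensus_presence(calls, config$thresholds,
                                                    pooled = config$pooled))
  rollup <- run_stage("call", rollup_taxa(consensus, reference))
  counts <- run_stage("call", count_taxa(rollup, consensus))
  readr::write_tsv(calls, emit("calls.tsv"))
  readr::write_tsv(consensus, emit("consensus.tsv"))
  readr::write_tsv(counts, emit("taxon_counts.tsv"))

  groups <- calls |>
    dplyr::distinct(.data$array_id, .data$condition_label)
  n_conditions <- dplyr::n_distinct(groups$condition_label)

  m_raw <- m_std <- NULL
  if (any(c("matrix", "cluster", "mrpp", "indval", "pcoa") %in%
            config$stages)) {
    m_raw <- run_stage("matrix", build_community_matrix(calls, consensus))
    m_rel <- run_stage("matrix", relativize_columns(m_raw))
    m_std <- if (config$transform == "arcsine") {
      run_stage("matrix", arcsine_sqrt(m_rel))
    } else m_rel
    write_community_matrix(m_raw, emit("matrix_raw.tsv"))
    files <- c(files, "matrix_raw.tsv.json")
    write_community_matrix(m_rel, emit("matrix_relativized.tsv"))
    files <- c(files, "matrix_relativized.tsv.json")
    if (config$transform == "arcsine") {
      write_community_matrix(m_std, emit("matrix_arcsine.tsv"))
      files <- c(files, "matrix_arcsine.tsv.json")
    }
  }

  d_bray <- NULL
  if (any(c("cluster", "mrpp", "indval", "pcoa") %in% config$stages)) {
    d_bray <- run_stage("cluster", bray_curtis(m_std))
    wdist(d_bray, "bray_curtis.tsv")
  }

  if ("cluster" %in% config$stages) {
    dend <- run_stage("cluster", hier_cluster(d_bray, config$linkage,
                                              config$beta))
    level <- config$cut_level %||% n_conditions
    clusters <- run_stage("cluster", cut_dendrogram(dend, level))
    wjson(list(merge = apply(dend$merge, 1, as.list),
               height = dend$height, labels = dend$labels,
               order = dend$order, method = dend$method,
               cut_level = level, seed = config$seed),
          "dendrogram.json")
    readr::write_tsv(clusters, emit("clusters.tsv"))
  }

  if ("mrpp" %in% config$stages) {
    mr <- run_stage("mrpp", mrpp(d_bray, groups,
                                 n_permutations = config$n_permutations,
                                 seed = config$seed))
    wjson(list(delta_observed = mr$delta_observed,
               delta_expected = mr$delta_expected, A = mr$A, p = mr$p,
               n_permutations = mr$n_permutations, method = mr$method,
               group_sizes = mr$group_sizes, seed = config$seed),
          "mrpp.json")
  }

  if ("indval" %in% config$stages) {
    iv_input <- if (config$transform == "arcsine") {
      relativize_columns(m_raw)
    } else m_std
    iv <- run_stage("indval", indval(
      iv_input, calls[, c("array_id", "otu_id", "present")], groups,
      n_permutations = config$n_permutations, seed = config$seed))
    readr::write_tsv(iv$summary, emit("indval.tsv"))
    wjson(list(summary = iv$summary, n_permutations = iv$n_permutations,
               method = iv$method, seed = config$seed),
          "indval.json")
  }

  d_uf <- NULL
  if ("unifrac" %in% config$stages) {
    w <- run_stage("unifrac", leaf_weights(calls))
    d_uf <- run_stage("unifrac", unifrac_matrix(reference$tree, w))
    wdist(d_uf, "unifrac.tsv")
  }

  if ("pcoa" %in% config$stages) {
    d_ord <- d_uf %||% d_bray
    pc <- run_stage("pcoa", pcoa(d_ord))
    readr::write_tsv(pc$coordinates, emit("pcoa_coordinates.tsv"))
    wjson(list(eigenvalues = pc$eigenvalues,
               pct_variation = pc$pct_variation,
               distance = if (is.null(d_uf)) "bray_curtis" else "unifrac",
               seed = config$seed),
          "pcoa.json")
  }

  manifest <- list(
    config = config_snapshot(config),
    warnings = warnings,
    files = sort(unique(files)),
    version = as.character(utils::packageVersion("phylocall"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- sort(c(manifest$files, "manifest.json"))
  manifest$timings = timings
  invisible(manifest)
}

# out_dir is omitted: it is where the manifest itself sits, and keeping it
# out makes result trees byte-identical across runs into different locations
config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$thresholds <- unclass(snap$thresholds)
  snap$out_dir <- NULL
  snap
}
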