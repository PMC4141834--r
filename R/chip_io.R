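#' Assemble and validate a chip reference set
#'
#' A reference set carries everything fixed about the chip design and its
#' target database: the probe annotation (which PM/MM probe pairs interrogate
#' which OTU, with per-probe A+T counts), the control probes, the taxonomy
#' (one 6-rank lineage per OTU), and optionally a rooted phylogeny over the
#' OTU identifiers.
#'
#' @param probes Tibble with columns `probe_id`, `otu_id`, `species_id`,
#'   `at_count` (target probes only).
#' @param taxonomy Tibble with columns `otu_id`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`.
#' @param controls Tibble with columns `probe_id`, `control_type`
#'   (`"background"` or `"spikein"`), `at_count`; may be empty.
#' @param tree An [ape::phylo] rooted tree whose tips are a subset of the
#'   OTU ids, or `NULL`.
#' @return A list of class `reference_set`.
#' @export
reference_set <- function(probes, taxonomy,
                          controls = empty_controls(), tree = NULL) {
  probes <- tibble::as_tibble(probes)
  taxonomy <- tibble::as_tibble(taxonomy)
  controls <- tibble::as_tibble(controls)

  need <- c("probe_id", "otu_id", "species_id", "at_count")
  if (!all(need %in% names(probes))) {
    pc_stop("probe annotation must have columns ",
            paste(need, collapse = ", "))
  }
  if (nrow(probes) == 0) pc_stop("probe annotation is empty")
  bad_at <- which(!is.finite(probes$at_count) |
                    probes$at_count < 0 | probes$at_count > 25)
  if (length(bad_at) > 0) {
    pc_stop("at_count out of range 0-25 for probe(s) ",
            paste(utils::head(probes$probe_id[bad_at], 5), collapse = ", "))
  }
  dup <- duplicated(probes[, c("probe_id", "otu_id")])
  if (any(dup)) {
    pc_stop("duplicate probe_id within an OTU: ",
            paste(utils::head(probes$probe_id[dup], 5), collapse = ", "))
  }

  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  if (!all(c("otu_id", ranks) %in% names(taxonomy))) {
    pc_stop("taxonomy must have columns otu_id, ", paste(ranks, collapse = ", "))
  }
  missing_tax <- setdiff(unique(probes$otu_id), taxonomy$otu_id)
  if (length(missing_tax) > 0) {
    pc_stop("OTU(s) without a taxonomy lineage: ",
            paste(utils::head(missing_tax, 5), collapse = ", "))
  }
  # several OTUs may share one species_id, but a species_id must map to a
  # single species-rank label
  sp_map <- dplyr::distinct(
    dplyr::inner_join(
      dplyr::distinct(probes, .data$otu_id, .data$species_id),
      taxonomy[, c("otu_id", "species")], by = "otu_id"
    ),
    .data$species_id, .data$species
  )
  clash <- sp_map$species_id[duplicated(sp_map$species_id)]
  if (length(clash) > 0) {
    pc_stop("species_id maps to multiple species-rank labels: ",
            paste(utils::head(unique(clash), 5), collapse = ", "))
  }

  if (nrow(controls) > 0) {
    if (!all(c("probe_id", "control_type", "at_count") %in% names(controls))) {
      pc_stop("controls must have columns probe_id, control_type, at_count")
    }
    if (!all(controls$control_type %in% c("background", "spikein"))) {
      pc_stop("control_type must be 'background' or 'spikein'")
    }
  }

  if (!is.null(tree)) {
    validate_tree(tree, reference_otus = unique(probes$otu_id))
  }

  structure(
    list(probes = probes, taxonomy = taxonomy, controls = controls,
         tree = tree),
    class = "reference_set"
  )
}

empty_controls <- function() {
  tibble::tibble(probe_id = character(), control_type = character(),
                 at_count = integer())
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set> %d probe pairs over %d OTUs (%d species), %d control probes, tree: %s\n",
    nrow(x$probes), dplyr::n_distinct(x$probes$otu_id),
    dplyr::n_distinct(x$probes$species_id), nrow(x$controls),
    if (is.null(x$tree)) "none" else paste0(length(x$tree$tip.label), " tips")
  ))
  invisible(x)
}

rank_names <- function() c("phylum", "class", "order", "family", "genus", "species")

# ---- probe annotation + taxonomy -------------------------------------------

#' Read probe annotation and taxonomy into a reference set
#'
#' The annotation file is tab-separated with header columns `probe_id`,
#' `otu_id`, `species_id`, `at_count`. Control probes are flagged by the
#' reserved `probe_id` prefix `CTRL_` (spike-in quantitative standards by
#' `CTRL_SPK`); their `otu_id`/`species_id` fields are ignored. The taxonomy
#' file is tab-separated with columns `otu_id` and `lineage`, the latter a
#' semicolon-delimited 6-rank string (phylum;class;order;family;genus;species);
#' empty ranks become `"unclassified"`.
#'
#' @param annotation_path,taxonomy_path Paths to the two TSV files.
#' @param tree_path Optional path to a rooted Newick tree over the OTU ids.
#' @return A validated [reference_set()].
#' @export
read_probe_annotation <- function(annotation_path, taxonomy_path,
                                  tree_path = NULL) {
  ann <- read_tsv_strict(annotation_path,
                         c("probe_id", "otu_id", "species_id", "at_count"),
                         readr::cols(probe_id = "c", otu_id = "c",
                                     species_id = "c", at_count = "i"))
  bad <- which(is.na(ann$probe_id) | is.na(ann$at_count))
  if (length(bad) > 0) {
    pc_stop("malformed annotation row at line ", bad[1] + 1L,
            " of ", annotation_path, class = "phylocall_parse_error")
  }
  is_ctrl <- is_control_probe(ann$probe_id)
  controls <- tibble::tibble(
    probe_id = ann$probe_id[is_ctrl],
    control_type = ifelse(is_spikein_probe(ann$probe_id[is_ctrl]),
                          "spikein", "background"),
    at_count = ann$at_count[is_ctrl]
  )
  probes <- ann[!is_ctrl, ]

  taxonomy <- read_taxonomy(taxonomy_path)
  tree <- if (!is.null(tree_path)) {
    read_newick(tree_path, reference_otus = unique(probes$otu_id))
  }
  reference_set(probes, taxonomy, controls = controls, tree = tree)
}

read_taxonomy <- function(path) {
  tx <- read_tsv_strict(path, c("otu_id", "lineage"),
                        readr::cols(otu_id = "c", lineage = "c"))
  parts <- strsplit(ifelse(is.na(tx$lineage), "", tx$lineage), ";", fixed = TRUE)
  ranks <- rank_names()
  wide <- purrr::map(parts, function(p) {
    p <- trimws(p)
    if (length(p) > 6) {
      pc_stop("lineage has more than 6 ranks: ", paste(p, collapse = ";"))
    }
    p <- c(p, rep("", 6 - length(p)))
    p[p == ""] <- "unclassified"
    p
  })
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(do.call(rbind, wide), stringsAsFactors = FALSE), ranks))
  dplyr::bind_cols(tibble::tibble(otu_id = tx$otu_id), out)
}

lineage_string <- function(taxonomy) {
  apply(as.matrix(taxonomy[, rank_names()]), 1, paste, collapse = ";")
}

#' Write a reference set to TSV (and Newick) files
#'
#' Inverse of [read_probe_annotation()]: round-trips through these files
#' reproduce the reference set exactly.
#'
#' @param reference A [reference_set()].
#' @param annotation_path,taxonomy_path Output TSV paths.
#' @param tree_path Optional output Newick path (written when the reference
#'   carries a tree).
#' @return Invisibly, the paths written.
#' @export
write_probe_annotation <- function(reference, annotation_path, taxonomy_path,
                                   tree_path = NULL) {
  ctrl <- reference$controls
  ann <- dplyr::bind_rows(
    reference$probes,
    tibble::tibble(probe_id = ctrl$probe_id, otu_id = "CTRL",
                   species_id = "CTRL", at_count = ctrl$at_count)
  )
  readr::write_tsv(ann, annotation_path)
  readr::write_tsv(
    tibble::tibble(otu_id = reference$taxonomy$otu_id,
                   lineage = lineage_string(reference$taxonomy)),
    taxonomy_path
  )
  paths <- c(annotation_path, taxonomy_path)
  if (!is.null(reference$tree) && !is.null(tree_path)) {
    ape::write.tree(reference$tree, file = tree_path)
    paths <- c(paths, tree_path)
  }
  invisible(paths)
}

# ---- intensity tables -------------------------------------------------------

#' Read a long-format probe intensity table
#'
#' Tab-separated with header columns `sample_id`, `replicate_id`,
#' `condition_label`, `probe_id`, `pm`, `mm`: one row per probe pair per
#' replicate array. Control probes carry the reserved `CTRL_` prefix. Probes
#' absent from the reference are kept but reported as a warning; negative or
#' missing intensities and duplicate (replicate, probe) rows are errors.
#'
#' @param path Path to the TSV file.
#' @param reference Optional [reference_set()] used to flag unknown probes.
#' @return A tibble of arrays in long format, one row per probe pair, with an
#'   `array_id` column identifying each (sample, replicate) chip.
#' @export
read_intensity_table <- function(path, reference = NULL) {
  cols <- c("sample_id", "replicate_id", "condition_label",
            "probe_id", "pm", "mm")
  tbl <- read_tsv_strict(path, cols,
                         readr::cols(sample_id = "c", replicate_id = "c",
                                     condition_label = "c", probe_id = "c",
                                     pm = "d", mm = "d"))
  bad <- which(is.na(tbl$pm) | is.na(tbl$mm))
  if (length(bad) > 0) {
    pc_stop("unparseable intensity at line ", bad[1] + 1L, " of ", path,
            class = "phylocall_parse_error")
  }
  validate_arrays(tbl, reference = reference)
}

#' @rdname read_intensity_table
#' @param arrays A long-format array tibble as returned by
#'   [read_intensity_table()] or [simulate_arrays()].
#' @export
write_intensity_table <- function(arrays, path) {
  readr::write_tsv(
    arrays[, c("sample_id", "replicate_id", "condition_label",
               "probe_id", "pm", "mm")],
    path
  )
  invisible(path)
}

validate_arrays <- function(tbl, reference = NULL) {
  neg <- which(tbl$pm < 0 | tbl$mm < 0)
  if (length(neg) > 0) {
    pc_stop("negative intensity at row ", neg[1], " (probe ",
            tbl$probe_id[neg[1]], ")")
  }
  dup <- duplicated(tbl[, c("sample_id", "replicate_id", "probe_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    pc_stop("duplicate (replicate, probe) row: sample ", tbl$sample_id[i],
            " replicate ", tbl$replicate_id[i], " probe ", tbl$probe_id[i])
  }
  if (!is.null(reference)) {
    known <- c(reference$probes$probe_id, reference$controls$probe_id)
    unknown <- setdiff(unique(tbl$probe_id), known)
    if (length(unknown) > 0) {
      pc_warn(length(unknown), " probe id(s) not in the reference (e.g. ",
              paste(utils::head(unknown, 3), collapse = ", "), ")")
    }
  }
  tbl$array_id <- array_id(tbl$sample_id, tbl$replicate_id)
  tibble::as_tibble(tbl)
}

# strict TSV reading: mandatory header, named columns, '.' decimal separator
read_tsv_strict <- function(path, required, col_types) {
  if (!file.exists(path)) pc_stop("file not found: ", path)
  tbl <- readr::read_tsv(path, col_types = col_types, progress = FALSE,
                         na = "NA")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    pc_stop(path, " is missing required column(s): ",
            paste(missing, collapse = ", "), class = "phylocall_parse_error")
  }
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    pc_stop("parse error in ", path, " at line ", probs$row[1] + 1L, ": ",
            probs$expected[1], " expected, got '", probs$actual[1], "'",
            class = "phylocall_parse_error")
  }
  tbl[, required]
}

# ---- Newick trees -----------------------------------------------------------

#' Read and validate a rooted Newick tree
#'
#' The tree must be rooted (no silent midpoint rooting), all branch lengths
#' must be non-negative, and when a reference OTU set is supplied every leaf
#' label must belong to it.
#'
#' @param path Path to a Newick file.
#' @param reference_otus Optional character vector of admissible leaf labels.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path, reference_otus = NULL) {
  if (!file.exists(path)) pc_stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    pc_stop("unbalanced parentheses in Newick file ", path,
            class = "phylocall_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || inherits(tree, "multiPhylo")) {
    pc_stop("could not parse Newick file ", path,
            class = "phylocall_parse_error")
  }
  validate_tree(tree, reference_otus = reference_otus)
  tree
}

validate_tree <- function(tree, reference_otus = NULL) {
  if (!inherits(tree, "phylo")) pc_stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) pc_stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) {
    pc_stop("negative branch length in tree")
  }
  if (!ape::is.rooted(tree)) {
    pc_stop("tree is not rooted; supply a rooted tree (no midpoint rooting ",
            "is applied)")
  }
  if (anyDuplicated(tree$tip.label)) pc_stop("duplicate leaf labels in tree")
  if (!is.null(reference_otus)) {
    stray <- setdiff(tree$tip.label, reference_otus)
    if (length(stray) > 0) {
      pc_stop("tree leaf/leaves not in the reference: ",
              paste(utils::head(stray, 5), collapse = ", "))
    }
  }
  invisible(tree)
}
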