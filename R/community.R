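#' Community matrices and the standardizations applied before comparison
#'
#' A community matrix holds one row per OTU and one column per replicate
#' array, carrying hybridization intensities (or transformed values). Its
#' `kind` tag enforces the pipeline order: `raw` -> `relativized` ->
#' `arcsine`; distance functions accept only relativized or arcsine input,
#' and the heat-plot row scaling produces `row_z`.
#'
#' @param values Numeric matrix, OTUs x arrays, with dimnames.
#' @param kind One of `"raw"`, `"relativized"`, `"arcsine"`, `"row_z"`.
#' @param array_info Optional tibble with `array_id`, `sample_id`,
#'   `replicate_id`, `condition_label` describing the columns.
#' @return An object of class `community_matrix`.
#' @export
community_matrix <- function(values, kind = c("raw", "relativized",
                                              "arcsine", "row_z"),
                             array_info = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    pc_stop("community matrix needs OTU row names and array column names")
  }
  if (kind != "row_z" && any(values < 0)) {
    pc_stop("community matrix values must be non-negative")
  }
  structure(
    list(values = values, kind = kind, array_info = array_info,
         constant_rows = character()),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d OTUs x %d arrays, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @export
as.matrix.community_matrix <- function(x, ...) x$values

#' Convert a community matrix to a tidy tibble
#'
#' @param x A [community_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `otu_id`, `array_id`, `value`, `kind`.
#' @export
tidy.community_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "otu_id") |>
    tidyr::pivot_longer(-"otu_id", names_to = "array_id",
                        values_to = "value") |>
    dplyr::mutate(kind = x$kind)
}

#' Build the raw OTU x array intensity matrix from presence calls
#'
#' Rows are the OTUs called present in at least one sample by the replicate
#' consensus; columns are the individual replicate arrays (group
#' comparisons treat replicates as group members). A cell holds the
#' replicate's trimmed-mean hybridization score when that replicate called
#' the OTU present, and 0 otherwise.
#'
#' @param calls Per-array call table from [call_otus()].
#' @param consensus Consensus table from [consensus_presence()].
#' @return A [community_matrix()] of kind `"raw"`.
#' @export
build_community_matrix <- function(calls, consensus) {
  keep_otus <- consensus |>
    dplyr::filter(.data$present) |>
    dplyr::distinct(.data$otu_id) |>
    dplyr::pull()
  if (length(keep_otus) == 0) {
    pc_stop("no OTU is present in any sample; nothing to compare")
  }
  info <- calls |>
    dplyr::distinct(.data$array_id, .data$sample_id, .data$replicate_id,
                    .data$condition_label) |>
    dplyr::arrange(.data$array_id)

  cells <- calls |>
    dplyr::filter(.data$otu_id %in% keep_otus) |>
    dplyr::mutate(value = ifelse(.data$present,
                                 .data$hybridization_score, 0)) |>
    dplyr::select("otu_id", "array_id", "value")

  wide <- tidyr::crossing(otu_id = sort(keep_otus),
                          array_id = info$array_id) |>
    dplyr::left_join(cells, by = c("otu_id", "array_id")) |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0)) |>
    tidyr::pivot_wider(names_from = "array_id", values_from = "value")

  values <- as.matrix(wide[, -1, drop = FALSE])
  rownames(values) <- wide$otu_id
  community_matrix(values, kind = "raw", array_info = info)
}

#' General relativization by columns
#'
#' Divides each column (array) by its total so every column sums to 1 —
#' intensities become within-sample relative abundances. Idempotent.
#'
#' @param m A [community_matrix()] of kind `"raw"` or `"relativized"`.
#' @return A [community_matrix()] of kind `"relativized"`.
#' @export
relativize_columns <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (!m$kind %in% c("raw", "relativized")) {
    pc_stop("relativization expects a raw (or already relativized) matrix, got ",
            m$kind)
  }
  totals <- colSums(m$values)
  zero <- colnames(m$values)[totals == 0]
  if (length(zero) > 0) {
    pc_stop("zero-sum sample column(s): ", paste(zero, collapse = ", "))
  }
  out <- community_matrix(sweep(m$values, 2, totals, "/"),
                          kind = "relativized", array_info = m$array_info)
  out
}

#' Arcsine square root transform
#'
#' Elementwise `v -> asin(sqrt(v))`, mapping relative abundances in `[0, 1]`
#' to `[0, pi/2]`. Applied after relativization to bring intensity data
#' closer to the hybridized amplicon amounts.
#'
#' @param m A [community_matrix()] of kind `"relativized"`.
#' @return A [community_matrix()] of kind `"arcsine"`.
#' @export
arcsine_sqrt <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (m$kind != "relativized") {
    pc_stop("arcsine square root expects a relativized matrix, got ", m$kind)
  }
  if (any(m$values < 0 | m$values > 1)) {
    pc_stop("arcsine square root needs values in [0, 1]")
  }
  community_matrix(asin(sqrt(m$values)), kind = "arcsine",
                   array_info = m$array_info)
}

#' Row z-scores for heat-plot display
#'
#' Centers each OTU row by its mean across arrays and divides by its sample
#' standard deviation; rows are then comparable across samples (but not to
#' each other). Constant rows map to all zeros and are flagged in the
#' `constant_rows` field rather than erroring.
#'
#' @param m A [community_matrix()] with at least 2 columns.
#' @return A [community_matrix()] of kind `"row_z"`.
#' @export
row_zscore <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (ncol(m$values) < 2) pc_stop("row z-scores need at least 2 columns")
  mu <- rowMeans(m$values)
  s <- apply(m$values, 1, stats::sd)
  const <- s == 0
  s[const] <- 1
  z <- sweep(sweep(m$values, 1, mu, "-"), 1, s, "/")
  out <- community_matrix(z, kind = "row_z", array_info = m$array_info)
  out$constant_rows <- rownames(m$values)[const]
  if (any(const)) {
    pc_warn(sum(const), " constant row(s) mapped to zero in row z-scoring")
  }
  out
}

#' Write / read a community matrix as TSV plus a JSON sidecar
#'
#' The TSV has an `otu_id` column then one column per array; the sidecar
#' stores the `kind` tag and array metadata so the pipeline-order guard
#' survives a round trip.
#'
#' @param m A [community_matrix()].
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_community_matrix <- function(m, path) {
  readr::write_tsv(tibble::as_tibble(m$values, rownames = "otu_id"), path)
  jsonlite::write_json(
    list(kind = m$kind, constant_rows = m$constant_rows,
         array_info = m$array_info),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(otu_id = "c",
                                                       .default = "d"),
                         progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(values) <- tbl$otu_id
  info <- if (!is.null(side$array_info)) tibble::as_tibble(side$array_info)
  m <- community_matrix(values, kind = side$kind, array_info = info)
  m$constant_rows <- as.character(side$constant_rows)
  m
}
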