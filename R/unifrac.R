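#' Log2-intensity leaf weights for weighted UniFrac
#'
#' For each replicate array, present OTUs get raw weight
#' `log2(hybridization intensity)` (intensities are floored at 1 by
#' preprocessing, so weights are non-negative); absent OTUs contribute 0, not
#' the log of a pseudo-intensity. Weights are then normalized within the
#' array to sum to 1.
#'
#' @param calls Per-array call table from [call_otus()].
#' @param normalize Normalize weights within each array (default TRUE).
#' @return A tibble with `array_id`, `otu_id`, `weight`.
#' @export
leaf_weights <- function(calls, normalize = TRUE) {
  w <- calls |>
    dplyr::filter(.data$present) |>
    dplyr::mutate(weight = log2(pmax(.data$hybridization_score, 1))) |>
    dplyr::select("array_id", "otu_id", "weight")
  empty <- setdiff(unique(calls$array_id), unique(w$array_id))
  if (length(empty) > 0) {
    pc_stop("array(s) with no present OTU: ", paste(empty, collapse = ", "))
  }
  if (normalize) {
    w <- w |>
      dplyr::group_by(.data$array_id) |>
      dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
      dplyr::ungroup()
    bad <- w |>
      dplyr::group_by(.data$array_id) |>
      dplyr::summarise(s = sum(.data$weight), .groups = "drop") |>
      dplyr::filter(!is.finite(.data$s))
    if (nrow(bad) > 0) {
      pc_stop("array(s) with zero total log2 weight: ",
              paste(bad$array_id, collapse = ", "))
    }
  }
  w
}

# per-branch descendant weight proportions via one postorder accumulation
branch_proportions <- function(tree, w) {
  nt <- length(tree$tip.label)
  acc <- numeric(nt + tree$Nnode)
  idx <- match(names(w), tree$tip.label)
  if (anyNA(idx)) {
    pc_stop("weight on leaf/leaves not in the tree: ",
            paste(names(w)[is.na(idx)], collapse = ", "))
  }
  acc[idx] <- w
  tree <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(tree$edge))) {
    acc[tree$edge[k, 1]] <- acc[tree$edge[k, 1]] + acc[tree$edge[k, 2]]
  }
  list(tree = tree, acc = acc)
}

#' Weighted UniFrac distance between two samples
#'
#' `u = sum_b l_b * |p_A(b) - p_B(b)|` over branches, where `p(b)` is the
#' summed normalized leaf weight below branch `b`. With `normalized = TRUE`
#' (default) `u` is divided by
#' `D = sum_leaves depth(leaf) * (p_A(leaf) + p_B(leaf))` (depth = root-to-leaf
#' branch length), bounding the distance in `[0, 1]`.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param wA,wB Named numeric weight vectors (names = tip labels); should sum
#'   to 1 each.
#' @param normalized Divide by the maximal dispersion `D` (default TRUE).
#' @return A single numeric distance.
#' @export
weighted_unifrac <- function(tree, wA, wB, normalized = TRUE) {
  validate_tree(tree)
  pa <- branch_proportions(tree, wA)
  pb <- branch_proportions(tree, wB)
  tr <- pa$tree
  u <- sum(tr$edge.length * abs(pa$acc[tr$edge[, 2]] - pb$acc[tr$edge[, 2]]))
  if (!normalized) return(u)
  nt <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)[seq_len(nt)]
  D <- sum(depth * (pa$acc[seq_len(nt)] + pb$acc[seq_len(nt)]))
  if (D == 0) return(0)
  u / D
}

#' Pairwise weighted UniFrac distance matrix
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param weights Leaf-weight tibble from [leaf_weights()].
#' @param normalized Passed to [weighted_unifrac()].
#' @return A [stats::dist] over arrays.
#' @export
unifrac_matrix <- function(tree, weights, normalized = TRUE) {
  arrays <- sort(unique(weights$array_id))
  if (length(arrays) < 2) pc_stop("UniFrac matrix needs >= 2 samples")
  wlist <- lapply(arrays, function(a) {
    wi <- weights[weights$array_id == a, ]
    stats::setNames(wi$weight, wi$otu_id)
  })
  n <- length(arrays)
  D <- matrix(0, n, n, dimnames = list(arrays, arrays))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      D[i, j] <- D[j, i] <- weighted_unifrac(tree, wlist[[i]], wlist[[j]],
                                             normalized = normalized)
    }
  }
  stats::as.dist(D)
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' eigenvalue; axes are ordered P1 >= P2 >= ... by eigenvalue; negative
#' eigenvalues are excluded from the percent-variation shares (which sum to
#' 100 over the retained axes). Each axis' sign is fixed so its first
#' nonzero coordinate is positive.
#'
#' @param d A [stats::dist] over at least 3 samples.
#' @param n_axes Number of axes to keep (default: all positive-eigenvalue
#'   axes; at most n - 1).
#' @return An object of class `pcoa_result` with `coordinates` (tibble:
#'   `array_id`, `P1`, `P2`, ...), `eigenvalues`, and `pct_variation`.
#' @export
pcoa <- function(d, n_axes = NULL) {
  n <- attr(d, "Size")
  ids <- attr(d, "Labels")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(n) || n < 3) pc_stop("PCoA needs at least 3 samples")
  if (!is.null(n_axes) && n_axes > n - 1) {
    pc_stop("n_axes cannot exceed n - 1 = ", n - 1)
  }
  A <- -0.5 * as.matrix(d)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)

  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (length(pos) == 0) pc_stop("no positive eigenvalue: degenerate distances")
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  keep <- pos[seq_len(k)]

  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  # sign convention: first nonzero coordinate of each axis positive
  for (a in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("P", seq_len(ncol(coords)))

  pct <- 100 * e$values[pos] / sum(e$values[pos])
  structure(
    list(coordinates = dplyr::bind_cols(tibble::tibble(array_id = ids),
                                        tibble::as_tibble(coords)),
         eigenvalues = e$values[pos],
         pct_variation = pct,
         n_samples = n),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA over %d samples: %d positive axes\n", x$n_samples,
              length(x$eigenvalues)))
  cat("  % variation: ",
      paste(sprintf("P%d=%.1f%%", seq_along(x$pct_variation),
                    x$pct_variation), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(axis = paste0("P", seq_along(x$eigenvalues)),
                 eigenvalue = x$eigenvalues,
                 pct_variation = x$pct_variation)
}
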