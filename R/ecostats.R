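#' Bray-Curtis distances between arrays
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over OTUs, computed between
#' the columns of a standardized community matrix. The pipeline-order guard
#' rejects raw matrices: distances are meant to be taken on relativized or
#' arcsine-transformed abundances.
#'
#' @param m A [community_matrix()] of kind `"relativized"` or `"arcsine"`.
#' @return A [stats::dist] object labelled by array id.
#' @export
bray_curtis <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (!m$kind %in% c("relativized", "arcsine")) {
    pc_stop("Bray-Curtis expects a relativized or arcsine matrix, got ",
            m$kind, " (pipeline-order guard)")
  }
  zero <- colSums(m$values) == 0
  if (sum(zero) >= 2) {
    pc_stop("Bray-Curtis undefined for all-zero column pair: ",
            paste(colnames(m$values)[zero], collapse = ", "))
  }
  vegan::vegdist(t(m$values), method = "bray")
}

#' Agglomerative clustering with group-average or flexible-beta linkage
#'
#' Lance-Williams agglomeration: `group_average` (UPGMA) uses
#' size-proportional coefficients; `flexible_beta` uses
#' `alpha = (1 - beta)/2`, `gamma = 0` (default `beta = -0.25`). Ties in the
#' minimum inter-cluster distance are broken by merging the pair that was
#' created earliest (lexicographically smallest pair of cluster indices), so
#' the dendrogram is deterministic.
#'
#' @param d A [stats::dist] object.
#' @param linkage `"group_average"` or `"flexible_beta"`.
#' @param beta Flexible-beta parameter (< 1).
#' @return An object of classes `chip_dendrogram` and `hclust` (so
#'   [stats::cutree()] and plotting work as usual).
#' @export
hier_cluster <- function(d, linkage = c("group_average", "flexible_beta"),
                         beta = -0.25) {
  linkage <- match.arg(linkage)
  if (beta >= 1) pc_stop("flexible beta requires beta < 1")
  labels <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (is.null(n) || n < 2) pc_stop("clustering needs at least 2 samples")
  if (is.null(labels)) labels <- as.character(seq_len(n))

  D <- as.matrix(d)
  diag(D) <- Inf
  sizes <- rep(1L, n)
  ids <- -seq_len(n)          # hclust convention: negatives are singletons
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    # first index pair (row-major over i < j in current index order) at the
    # minimum: deterministic lexicographic tie-break
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in seq.int(ii + 1L, length(act))) {
        if (sub[ii, jj] < best_d) {
          best_d <- sub[ii, jj]
          best <- c(act[ii], act[jj])
        }
      }
    }
    i <- best[1]; j <- best[2]
    height[step] <- best_d
    merge[step, ] <- sort(c(ids[i], ids[j]))

    ni <- sizes[i]; nj <- sizes[j]
    others <- setdiff(act, c(i, j))
    dij <- D[i, j]
    new_d <- if (linkage == "group_average") {
      (ni * D[i, others] + nj * D[j, others]) / (ni + nj)
    } else {
      alpha <- (1 - beta) / 2
      alpha * (D[i, others] + D[j, others]) + beta * dij
    }
    D[i, others] <- new_d
    D[others, i] <- new_d
    active[j] <- FALSE
    sizes[i] <- ni + nj
    ids[i] <- step
  }

  out <- structure(
    list(merge = merge, height = height, order = dendrogram_order(merge),
         labels = labels,
         method = if (linkage == "group_average") "average"
                  else sprintf("flexible_beta(%g)", beta),
         call = match.call(), dist.method = "bray"),
    class = c("chip_dendrogram", "hclust")
  )
  out
}

# leaf order by traversing the merge tree (left before right)
dendrogram_order <- function(merge) {
  unpack <- function(node) {
    if (node < 0) return(-node)
    c(unpack(merge[node, 1]), unpack(merge[node, 2]))
  }
  unpack(nrow(merge))
}

#' Cut a dendrogram at a hierarchical cluster level
#'
#' Level `k` removes the top `k - 1` merges, leaving `k` clusters (level 1 is
#' everything together; level n puts every sample in its own cluster).
#'
#' @param dend A dendrogram from [hier_cluster()].
#' @param level Integer number of clusters, `1 <= level <= n`.
#' @return A tibble with `array_id` and integer `cluster`.
#' @export
cut_dendrogram <- function(dend, level) {
  n <- length(dend$labels)
  if (level < 1) pc_stop("cluster level must be >= 1")
  if (level > n) pc_stop("cluster level exceeds the number of samples")
  cl <- stats::cutree(dend, k = level)
  tibble::tibble(array_id = names(cl), cluster = unname(cl))
}

# ---- MRPP -------------------------------------------------------------------

# weighted mean within-group distance, weights C_g = n_g / N
mrpp_delta <- function(D, labels) {
  N <- length(labels)
  delta <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    ng <- length(idx)
    delta <- delta + (ng / N) *
      mean(D[idx, idx][upper.tri(matrix(0, ng, ng))])
  }
  delta
}

# all distinct arrangements of a label multiset (as a list of vectors);
# count must be modest (the caller guards with <= 10,000)
multiset_permutations <- function(labels) {
  rec <- function(counts) {
    if (sum(counts) == 0) return(list(character(0)))
    out <- list()
    for (v in names(counts)[counts > 0]) {
      cc <- counts
      cc[v] <- cc[v] - 1L
      out <- c(out, lapply(rec(cc), function(tail) c(v, tail)))
    }
    out
  }
  rec(table(labels))
}

n_arrangements <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

#' Multi-response permutation procedure (MRPP)
#'
#' Tests a priori group structure against a distance matrix. The statistic
#' `delta` is the weighted mean within-group distance (weights
#' `C_g = n_g / N`); significance comes from permuting the group labels.
#' `A = 1 - delta_obs / delta_exp` is the chance-corrected within-group
#' agreement: 1 when all items are identical within groups, about 0 when
#' within-group heterogeneity matches chance, negative when it exceeds it.
#'
#' When the number of distinct label arrangements is at most
#' `exhaustive_limit` (and `method = "auto"`), all arrangements are
#' enumerated: `p` is the exact fraction of arrangements with
#' `delta <= delta_obs` and `delta_exp` their mean. Otherwise `n_permutations`
#' Monte Carlo shuffles are drawn, `delta_exp` is their mean, and
#' `p = (1 + #{delta_perm <= delta_obs}) / (1 + n_permutations)`.
#'
#' @param d A [stats::dist] over samples.
#' @param groups Group labels: a vector aligned with (or named by) the
#'   distance labels, or a two-column data frame (id, group).
#' @param n_permutations Monte Carlo permutations (default 1000).
#' @param seed Optional integer seed making the permutation stream
#'   reproducible.
#' @param method `"auto"`, `"montecarlo"`, or `"exhaustive"`.
#' @param exhaustive_limit Arrangement count below which `"auto"` enumerates.
#' @return An object of class `mrpp_result`.
#' @export
mrpp <- function(d, groups, n_permutations = 1000, seed = NULL,
                 method = c("auto", "montecarlo", "exhaustive"),
                 exhaustive_limit = 10000) {
  method <- match.arg(method)
  labels <- align_groups(d, groups)
  tab <- table(labels)
  if (length(tab) < 2) pc_stop("MRPP needs at least 2 groups")
  if (any(tab < 2)) {
    pc_stop("every MRPP group needs >= 2 samples; group(s) of size 1: ",
            paste(names(tab)[tab < 2], collapse = ", "))
  }
  D <- as.matrix(d)
  obs <- mrpp_delta(D, labels)

  M <- n_arrangements(labels)
  if (method == "auto") {
    method <- if (M <= exhaustive_limit) "exhaustive" else "montecarlo"
  }

  if (method == "exhaustive") {
    if (M > exhaustive_limit) {
      pc_stop("too many arrangements (", round(M), ") for exhaustive MRPP")
    }
    perms <- multiset_permutations(labels)
    deltas <- vapply(perms, function(l) mrpp_delta(D, l), numeric(1))
    p <- mean(deltas <= obs + 1e-12)
    expected <- mean(deltas)
    n_used <- length(deltas)
  } else {
    run <- function() {
      deltas <- replicate(n_permutations, mrpp_delta(D, sample(labels)))
      deltas
    }
    deltas <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    p <- (1 + sum(deltas <= obs + 1e-12)) / (1 + n_permutations)
    expected <- mean(deltas)
    n_used <- n_permutations
  }

  structure(
    list(delta_observed = obs, delta_expected = expected,
         A = 1 - obs / expected, p = p,
         n_permutations = n_used, method = method, seed = seed,
         group_sizes = as.list(tab), groups = labels),
    class = "mrpp_result"
  )
}

align_groups <- function(d, groups) {
  ids <- attr(d, "Labels")
  if (is.data.frame(groups)) {
    if (ncol(groups) < 2) pc_stop("groups data frame needs (id, group) columns")
    key <- stats::setNames(as.character(groups[[2]]), groups[[1]])
    if (!all(ids %in% names(key))) {
      pc_stop("unlabelled sample(s): ",
              paste(setdiff(ids, names(key)), collapse = ", "))
    }
    unname(key[ids])
  } else if (!is.null(names(groups)) && !is.null(ids)) {
    if (!all(ids %in% names(groups))) {
      pc_stop("unlabelled sample(s): ",
              paste(setdiff(ids, names(groups)), collapse = ", "))
    }
    unname(as.character(groups[ids]))
  } else {
    if (length(groups) != attr(d, "Size")) {
      pc_stop("group labels must match the number of samples")
    }
    as.character(groups)
  }
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat(sprintf(
    "MRPP: delta_obs = %.4f, delta_exp = %.4f, A = %.4f, p = %.4g (%s, %d permutations)\n",
    x$delta_observed, x$delta_expected, x$A, x$p, x$method, x$n_permutations))
  invisible(x)
}

#' @export
tidy.mrpp_result <- function(x, ...) {
  tibble::tibble(group = names(x$group_sizes),
                 n = as.integer(unlist(x$group_sizes)))
}

#' @export
glance.mrpp_result <- function(x, ...) {
  tibble::tibble(delta_observed = x$delta_observed,
                 delta_expected = x$delta_expected,
                 A = x$A, p.value = x$p,
                 n_permutations = x$n_permutations, method = x$method)
}

# ---- indicator species analysis --------------------------------------------

#' Dufrene-Legendre indicator species analysis (INDVAL)
#'
#' For OTU `i` and group `j`: specificity `A_ij` is the mean abundance of `i`
#' in `j` divided by the sum of its group mean abundances; fidelity `B_ij` is
#' the fraction of members of `j` where `i` was called present;
#' `INDVAL_ij = A_ij * B_ij * 100`. The per-OTU statistic is the maximum over
#' groups; its significance is assessed by Monte Carlo randomization of the
#' sample-to-group assignment (default 1,000 permutations, add-one
#' correction), or exhaustively for small designs.
#'
#' Abundance conventionally comes from the relativized (pre-arcsine) matrix;
#' presence for fidelity comes from the calling procedure, not from
#' abundance > 0.
#'
#' @param m A [community_matrix()] (relativized recommended).
#' @param presence Per-array presence: tibble with columns `array_id`,
#'   `otu_id`, `present` (e.g. from the [call_otus()] table).
#' @param groups Group labels for the matrix columns (vector, named vector,
#'   or (id, group) data frame).
#' @param n_permutations Monte Carlo permutations (default 1000).
#' @param seed Optional integer seed.
#' @param method `"auto"`, `"montecarlo"`, or `"exhaustive"`.
#' @param exhaustive_limit Arrangement count below which `"auto"` enumerates.
#' @return An object of class `indval_result` with a per-(OTU, group) `table`
#'   and a per-OTU `summary` (best group, max indval, p).
#' @export
indval <- function(m, presence, groups, n_permutations = 1000, seed = NULL,
                   method = c("auto", "montecarlo", "exhaustive"),
                   exhaustive_limit = 10000) {
  method <- match.arg(method)
  stopifnot(inherits(m, "community_matrix"))
  V <- m$values
  fake_d <- structure(numeric(0), Labels = colnames(V), Size = ncol(V),
                      class = "dist")
  labels <- align_groups(fake_d, groups)
  if (length(unique(labels)) < 2) pc_stop("INDVAL needs at least 2 groups")

  P <- matrix(FALSE, nrow(V), ncol(V), dimnames = dimnames(V))
  pres <- presence[presence$otu_id %in% rownames(V) &
                     presence$array_id %in% colnames(V), ]
  P[cbind(match(pres$otu_id, rownames(V)),
          match(pres$array_id, colnames(V)))] <- pres$present

  iv_stats <- function(lab) {
    groups_u <- sort(unique(lab))
    ind <- sapply(groups_u, function(g) as.numeric(lab == g))
    ngroup <- colSums(ind)
    gm <- (V %*% ind) %*% diag(1 / ngroup, length(ngroup))
    tot <- rowSums(gm)
    a <- gm / ifelse(tot == 0, 1, tot)     # zero-abundance OTUs flagged later
    b <- (P %*% ind) %*% diag(1 / ngroup, length(ngroup))
    iv <- a * b * 100
    iv[tot == 0, ] <- 0
    colnames(iv) <- colnames(a) <- colnames(b) <- groups_u
    list(a = a, b = b, iv = iv, max = apply(iv, 1, max))
  }

  obs <- iv_stats(labels)
  zero_flag <- rowSums(V) == 0

  if (method == "auto") {
    method <- if (n_arrangements(labels) <= exhaustive_limit) "exhaustive"
              else "montecarlo"
  }
  if (method == "exhaustive") {
    perms <- multiset_permutations(labels)
    exceed <- matrix(0, nrow(V), 1)
    for (l in perms) exceed <- exceed + (iv_stats(l)$max >= obs$max - 1e-12)
    p <- as.numeric(exceed) / length(perms)
    n_used <- length(perms)
  } else {
    run <- function() {
      exceed <- numeric(nrow(V))
      for (b in seq_len(n_permutations)) {
        exceed <- exceed + (iv_stats(sample(labels))$max >= obs$max - 1e-12)
      }
      exceed
    }
    exceed <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    p <- (1 + exceed) / (1 + n_permutations)
    n_used <- n_permutations
  }

  groups_u <- colnames(obs$iv)
  table <- tibble::tibble(
    otu_id = rep(rownames(V), times = length(groups_u)),
    group = rep(groups_u, each = nrow(V)),
    a_spec = as.numeric(obs$a),
    b_fid = as.numeric(obs$b),
    indval = as.numeric(obs$iv)
  )
  summary <- tibble::tibble(
    otu_id = rownames(V),
    best_group = groups_u[apply(obs$iv, 1, which.max)],
    indval = unname(obs$max),
    p.value = unname(p),
    zero_abundance = zero_flag
  ) |>
    dplyr::arrange(dplyr::desc(.data$indval), .data$otu_id)

  structure(
    list(table = table, summary = summary, n_permutations = n_used,
         method = method, seed = seed, groups = labels),
    class = "indval_result"
  )
}

#' @export
print.indval_result <- function(x, ...) {
  cat(sprintf("INDVAL over %d OTUs, %d groups (%s, %d permutations)\n",
              nrow(x$summary), length(unique(x$groups)), x$method,
              x$n_permutations))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' @export
tidy.indval_result <- function(x, ...) x$summary

#' @export
glance.indval_result <- function(x, ...) {
  tibble::tibble(n_otus = nrow(x$summary),
                 n_groups = length(unique(x$groups)),
                 n_significant = sum(x$summary$p.value < 0.05),
                 n_permutations = x$n_permutations, method = x$method)
}

#' Filter an indicator table the way published heat plots are assembled
#'
#' @param x An `indval_result`.
#' @param min_indval Minimum max-INDVAL (0-100 scale).
#' @param max_p Maximum permutation p-value.
#' @return The filtered per-OTU summary tibble, sorted by indval.
#' @export
top_indicators <- function(x, min_indval = 40.5, max_p = 0.05) {
  dplyr::filter(x$summary, .data$indval >= min_indval,
                .data$p.value < max_p)
}
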