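# Small fixtures and independent brute-force oracles used across tests.

# a fast, small simulation for tests that do not need the default study size
small_config <- function(seed = 1, ...) {
  defaults <- list(n_otus = 40, n_species = 16, n_groups = 2,
                   n_shifted = 6, n_indicators = 3, n_bg_controls = 300,
                   seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# hand-built scored-pair table for stage-1/stage-2 unit tests
make_scores <- function(otu_id, positive, r, species_id = otu_id,
                        probe_id = NULL, pm = NULL,
                        array = "A.R1") {
  n <- length(positive)
  tibble::tibble(
    array_id = array, sample_id = sub("\\..*$", "", array),
    replicate_id = sub("^.*\\.", "", array), condition_label = "g",
    otu_id = otu_id, species_id = species_id,
    probe_id = probe_id %||% sprintf("PR_%s_%02d", otu_id, seq_len(n)),
    at_count = 12L,
    pm = pm %||% rep(100, n), mm = 50,
    positive = positive, d = ifelse(positive, 0.5, 0), r = r
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal reference around a probe table (taxonomy generated per species)
ref_from_probes <- function(probes) {
  sp <- unique(probes[, c("otu_id", "species_id")])
  taxonomy <- tibble::tibble(
    otu_id = sp$otu_id, phylum = "p1", class = "c1", order = "o1",
    family = "f1", genus = "g1", species = sp$species_id
  )
  reference_set(probes, taxonomy)
}

# random distance matrix over n labelled points (metric by construction:
# Euclidean distances of random points)
rand_dist <- function(n, dim = 3) {
  x <- matrix(runif(n * dim), n)
  rownames(x) <- paste0("s", seq_len(n))
  stats::dist(x)
}

# --- Bray-Curtis: direct double-loop evaluation -----------------------------
bray_oracle <- function(values) {
  n <- ncol(values)
  D <- matrix(0, n, n, dimnames = list(colnames(values), colnames(values)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      x <- values[, i]; y <- values[, j]
      D[i, j] <- D[j, i] <- sum(abs(x - y)) / sum(x + y)
    }
  }
  stats::as.dist(D)
}

# --- UPGMA: recompute every merge height from the raw distances -------------
upgma_oracle <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights[step] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# --- weighted UniFrac: explicit per-edge descendant enumeration -------------
unifrac_oracle <- function(tree, wA, wB, normalized = TRUE) {
  nt <- length(tree$tip.label)
  wa <- wb <- stats::setNames(numeric(nt), tree$tip.label)
  wa[names(wA)] <- wA
  wb[names(wB)] <- wB
  u <- 0
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    tips <- if (child <= nt) child
            else unlist(phangorn::Descendants(tree, child, type = "tips"))
    u <- u + tree$edge.length[k] *
      abs(sum(wa[tips]) - sum(wb[tips]))
  }
  if (!normalized) return(u)
  depth <- ape::node.depth.edgelength(tree)[seq_len(nt)]
  D <- sum(depth * (wa + wb))
  if (D == 0) 0 else u / D
}

# random normalized leaf weights over a subset of tips
rand_weights <- function(tree, k = NULL) {
  tips <- tree$tip.label
  k <- k %||% sample(seq_along(tips), 1)
  pick <- sample(tips, max(1, k))
  w <- runif(length(pick), 0.1, 1)
  stats::setNames(w / sum(w), pick)
}

# exhaustive MRPP / INDVAL enumeration helpers for 6 samples, 2 groups of 3
all_label_splits <- function(ids, k) {
  picks <- utils::combn(ids, k, simplify = FALSE)
  lapply(picks, function(p) ifelse(ids %in% p, "g1", "g2"))
}

delta_oracle <- function(D, labels) {
  N <- length(labels); out <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    pair <- utils::combn(idx, 2)
    out <- out + (length(idx) / N) * mean(D[t(pair)])
  }
  out
}
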