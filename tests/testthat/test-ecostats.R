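rel_mat <- function(values) {
  if (is.null(dimnames(values))) {
    dimnames(values) <- list(paste0("O", seq_len(nrow(values))),
                             paste0("s", seq_len(ncol(values))))
  }
  community_matrix(values, kind = "arcsine")
}

test_that("Bray-Curtis matches hand values and the double-loop oracle", {
  m <- rel_mat(matrix(c(1, 1, 0, 0, 1, 1, 1, 1, 0), ncol = 3))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s2"], 0.5)       # (1+0+1)/(1+2+1)
  expect_equal(d["s1", "s3"], 0)         # identical columns
  dm <- rel_mat(matrix(c(1, 0, 0, 1), ncol = 2))
  expect_equal(as.numeric(bray_curtis(dm)), 1)  # disjoint supports

  withr::with_seed(11, v <- matrix(runif(60), nrow = 10))
  got <- as.matrix(bray_curtis(rel_mat(v)))
  want <- as.matrix(bray_oracle(v))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)

  raw <- community_matrix(matrix(1:4, 2, dimnames = list(c("a","b"), c("x","y"))),
                          kind = "raw")
  expect_error(bray_curtis(raw), "pipeline-order")
})

test_that("group-average clustering reproduces UPGMA on random and ultrametric input", {
  # two samples at 0.4 -> one merge at 0.4
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  h2 <- hier_cluster(d2)
  expect_equal(h2$height, 0.4)

  # a generating ultrametric is reproduced exactly
  D <- matrix(0.8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.2
  D["c", "d"] <- D["d", "c"] <- 0.3
  diag(D) <- 0
  hu <- hier_cluster(stats::as.dist(D))
  expect_equal(sort(hu$height), c(0.2, 0.3, 0.8))
  expect_equal(as.matrix(stats::cophenetic(hu))[rownames(D), colnames(D)], D)

  withr::with_seed(21, {
    for (i in 1:25) {
      d <- rand_dist(sample(4:8, 1))
      mine <- hier_cluster(d)
      expect_equal(mine$height, upgma_oracle(d), tolerance = 1e-12)
      # cross-check full tree against stats::hclust average linkage
      expect_equal(as.matrix(stats::cophenetic(mine)),
                   as.matrix(stats::cophenetic(stats::hclust(d, "average"))),
                   tolerance = 1e-12)
      # UPGMA heights are monotone non-decreasing
      expect_true(!is.unsorted(mine$height))
    }
  })
  expect_error(hier_cluster(stats::dist(1)), "at least 2")
})

test_that("flexible-beta linkage agrees with cluster::agnes", {
  skip_if_not_installed("cluster")
  withr::with_seed(22, {
    for (i in 1:10) {
      d <- rand_dist(sample(4:8, 1))
      mine <- hier_cluster(d, linkage = "flexible_beta", beta = -0.25)
      ag <- stats::as.hclust(cluster::agnes(d, method = "flexible",
                                            par.method = 0.625))
      expect_equal(as.matrix(stats::cophenetic(mine)),
                   as.matrix(stats::cophenetic(ag))[mine$labels, mine$labels],
                   tolerance = 1e-9)
    }
  })
})

test_that("dendrogram cuts produce the expected partitions", {
  withr::with_seed(23, d <- rand_dist(7))
  h <- hier_cluster(d)
  expect_equal(unique(cut_dendrogram(h, 1)$cluster), 1)
  expect_equal(sort(cut_dendrogram(h, 7)$cluster), 1:7)
  for (k in 2:6) {
    cl <- cut_dendrogram(h, k)
    expect_equal(dplyr::n_distinct(cl$cluster), k)
    expect_equal(nrow(cl), 7)
  }
  expect_error(cut_dendrogram(h, 0), ">= 1")
  expect_error(cut_dendrogram(h, 8), "exceeds")
})

test_that("MRPP recovers the analytic extremes and matches enumeration", {
  # all within-group distances zero -> delta = 0, A = 1
  X <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  X[1:3, 4:6] <- X[4:6, 1:3] <- 0.7
  g <- rep(c("u", "v"), each = 3)
  res <- mrpp(stats::as.dist(X), g, method = "exhaustive")
  expect_equal(res$delta_observed, 0)
  expect_equal(res$A, 1)
  expect_equal(res$p, 1 / choose(6, 3) * 2 * 1)  # only the 2 mirror splits

  # exhaustive p equals a from-scratch enumeration over all 20 splits
  withr::with_seed(31, d <- rand_dist(6))
  D <- as.matrix(d)
  ids <- attr(d, "Labels")
  res_ex <- mrpp(d, g, method = "exhaustive")
  deltas <- vapply(all_label_splits(ids, 3), function(l) delta_oracle(D, l),
                   numeric(1))
  # each split appears 3!*3! times among label permutations: proportions match
  expect_equal(res_ex$p, mean(deltas <= res_ex$delta_observed + 1e-12))
  expect_equal(res_ex$delta_expected, mean(deltas))
  expect_equal(res_ex$A, 1 - res_ex$delta_observed / mean(deltas))

  # vegan cross-check of the observed statistic (same n_g/N weighting)
  vg <- vegan::mrpp(d, g, permutations = 10, weight.type = 1)
  expect_equal(res_ex$delta_observed, vg$delta, tolerance = 1e-12)

  expect_error(mrpp(d, c(g[-1], "w")), "size 1")
  expect_error(mrpp(d, rep("u", 6)), "2 groups")
})

test_that("Monte Carlo MRPP p sits near the exhaustive p and is reproducible", {
  withr::with_seed(33, d <- rand_dist(6))
  g <- rep(c("u", "v"), each = 3)
  ex <- mrpp(d, g, method = "exhaustive")
  mc <- mrpp(d, g, n_permutations = 1000, seed = 99, method = "montecarlo")
  se <- sqrt(ex$p * (1 - ex$p) / 1000)
  expect_lt(abs(mc$p - ex$p), 3 * se + 2 / 1000)
  mc2 <- mrpp(d, g, n_permutations = 1000, seed = 99, method = "montecarlo")
  expect_identical(mc$p, mc2$p)
  expect_identical(mc$delta_expected, mc2$delta_expected)
})

test_that("INDVAL evaluates the specificity x fidelity formula exactly", {
  # 6 arrays, 2 groups; O1: all abundance in g1, present everywhere in g1
  v <- rbind(O1 = c(3, 2, 1, 0, 0, 0),
             O2 = c(1, 1, 1, 1, 1, 1),
             O3 = c(0, 0, 0, 0, 0, 0))
  colnames(v) <- paste0("s", 1:6)
  m <- community_matrix(v, kind = "relativized")
  pres <- tidyr::crossing(array_id = colnames(v), otu_id = rownames(v)) |>
    dplyr::mutate(present = !(otu_id == "O1" &
                                array_id %in% paste0("s", 4:6)) &
                    otu_id != "O3")
  g <- rep(c("g1", "g2"), each = 3)
  res <- indval(m, pres, g, method = "exhaustive")

  tab <- res$table
  expect_equal(tab$indval[tab$otu_id == "O1" & tab$group == "g1"], 100)
  expect_equal(tab$a_spec[tab$otu_id == "O2" & tab$group == "g1"], 0.5)
  expect_equal(tab$indval[tab$otu_id == "O2" & tab$group == "g1"], 50)
  # specificity sums to 1 over groups for OTUs with abundance
  sums <- tapply(tab$a_spec, tab$otu_id, sum)
  expect_equal(as.numeric(sums[c("O1", "O2")]), c(1, 1))
  # zero-abundance OTU flagged with indval 0
  s <- res$summary
  expect_true(s$zero_abundance[s$otu_id == "O3"])
  expect_equal(s$indval[s$otu_id == "O3"], 0)
  # the perfect indicator ranks first
  expect_equal(s$otu_id[1], "O1")
})

test_that("an OTU uniform over g groups scores 100/g", {
  for (g_n in 2:4) {
    n_per <- 2
    v <- matrix(1, 1, g_n * n_per,
                dimnames = list("O1", paste0("s", seq_len(g_n * n_per))))
    pres <- tidyr::crossing(array_id = colnames(v), otu_id = "O1") |>
      dplyr::mutate(present = TRUE)
    res <- indval(community_matrix(v, kind = "relativized"), pres,
                  rep(paste0("g", seq_len(g_n)), each = n_per),
                  method = "montecarlo", n_permutations = 20, seed = 1)
    expect_equal(res$summary$indval, 100 / g_n, tolerance = 1e-9)
  }
})

test_that("INDVAL permutation p matches exhaustive enumeration on 6 samples", {
  withr::with_seed(41, {
    v <- matrix(rexp(5 * 6), 5, 6,
                dimnames = list(paste0("O", 1:5), paste0("s", 1:6)))
  })
  pres <- tidyr::crossing(array_id = colnames(v),
                          otu_id = rownames(v)) |>
    dplyr::mutate(present = TRUE)
  m <- community_matrix(v, kind = "relativized")
  g <- rep(c("g1", "g2"), each = 3)
  ex <- indval(m, pres, g, method = "exhaustive")
  mc <- indval(m, pres, g, n_permutations = 1000, seed = 5,
               method = "montecarlo")
  s_ex <- ex$summary[order(ex$summary$otu_id), ]
  s_mc <- mc$summary[order(mc$summary$otu_id), ]
  expect_equal(s_ex$indval, s_mc$indval)
  for (i in seq_len(nrow(s_ex))) {
    se <- sqrt(s_ex$p.value[i] * (1 - s_ex$p.value[i]) / 1000)
    expect_lt(abs(s_mc$p.value[i] - s_ex$p.value[i]), 3 * se + 2 / 1000)
  }
})

test_that("moving abundance into a group never lowers that group's indval", {
  withr::with_seed(43, {
    for (rep_i in 1:15) {
      v <- matrix(rexp(12), 2, 6,
                  dimnames = list(c("O1", "O2"), paste0("s", 1:6)))
      pres <- tidyr::crossing(array_id = colnames(v),
                              otu_id = c("O1", "O2")) |>
        dplyr::mutate(present = TRUE)
      g <- rep(c("g1", "g2"), each = 3)
      base <- indval(community_matrix(v, kind = "relativized"), pres, g,
                     method = "montecarlo", n_permutations = 5, seed = 1)
      # shift abundance of O1 from a g2 array into a g1 array
      v2 <- v
      moved <- min(v2["O1", 4], v2["O1", 4])
      v2["O1", 1] <- v2["O1", 1] + moved
      v2["O1", 4] <- v2["O1", 4] - moved
      upd <- indval(community_matrix(v2, kind = "relativized"), pres, g,
                    method = "montecarlo", n_permutations = 5, seed = 1)
      iv1 <- base$table$indval[base$table$otu_id == "O1" &
                                 base$table$group == "g1"]
      iv2 <- upd$table$indval[upd$table$otu_id == "O1" &
                                upd$table$group == "g1"]
      expect_gte(iv2, iv1 - 1e-12)
      expect_true(all(base$table$indval <= 100 + 1e-12))
    }
  })
})
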