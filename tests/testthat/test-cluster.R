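test_that("levenshtein is exact against a DP oracle", {
  expect_equal(levenshtein("GGGA", "GGGA"), 0L)
  expect_equal(levenshtein("GGGAGGG", "GGGTGGG"), 1L)
  expect_equal(levenshtein("", "GGG"), 3L)

  set.seed(4)
  pool <- random_dna(30, 12, seed = 4)
  for (i in 1:20) {
    a <- sample(pool, 1); b <- sample(pool, 1)
    expect_equal(levenshtein(a, b), dp_levenshtein(a, b))
  }
  # triangle inequality on random triples
  for (i in 1:20) {
    tri <- sample(pool, 3)
    expect_lte(levenshtein(tri[1], tri[3]),
               levenshtein(tri[1], tri[2]) + levenshtein(tri[2], tri[3]))
  }
})

test_that("sphere clustering groups within-radius sequences deterministically", {
  # 10 copies of one sequence -> one cluster of 10
  same <- stats::setNames(rep("GGGATGGGTTGGGCAGGG", 10), paste0("c", 1:10))
  cl <- cluster_spheres(same)
  expect_equal(unique(cl$cluster), 1L)
  expect_true(all(cl$stage == "sphere"))

  # template + one-edit variants cluster; a 5-edit outlier stays out
  template <- "GGGATGGGTTGGGCAGGG"
  variants <- c("GGGATGGGTTGGGCTGGG", "GGGACGGGTTGGGCAGGG",
                "GGGATGGGATGGGCAGGG", "GGGATGGGTTGGGAAGGG",
                "GGGTTGGGTTGGGCAGGG")
  outlier <- "GGGCCCCGGGAAAAGGGTTTTGGG"
  seqs <- stats::setNames(c(template, variants, outlier),
                          paste0("s", 1:7))
  expect_true(all(utils::adist(template, variants) <= 2))
  cl <- cluster_spheres(seqs)
  expect_equal(sum(cl$stage == "sphere"), 6L)
  expect_equal(cl$stage[cl$seq_id == "s7"], "unassigned")

  # members always lie within the radius of their sphere center (post hoc:
  # center is a member, so all pairwise member-center distances <= radius)
  big <- simulate_g4_family(template, 30, sim_config(sub_rate = 0.04),
                            seed = 2, family_id = "f")
  out <- cluster_spheres(big)
  for (k in unique(stats::na.omit(out$cluster))) {
    members <- out$seq[!is.na(out$cluster) & out$cluster == k]
    center <- members[order(-nchar(members), members)][1]
    expect_true(all(utils::adist(center, members) <= 2))
  }

  # determinism
  expect_identical(cluster_spheres(seqs), cluster_spheres(seqs))
})

test_that("pairwise similarity follows the Karlin-Altschul closed form", {
  seqs <- c(a = "GGGAGGGAGGGAGGG", b = "GGGAGGGAGGGAGGG",
            c = "GGGTTTTCCCCAAAG")
  D <- pairwise_similarity(seqs)
  # identical sequences: SW score 2*15, E = K*m*n*exp(-lambda*S)
  s_aa <- 2 * 15
  e_aa <- 0.41 * 15 * 15 * exp(-0.625 * s_aa)
  expect_equal(D$similarity["a", "b"], -log(e_aa), tolerance = 1e-9)
  expect_equal(D$values["a", "b"], 0, tolerance = 1e-9)
  expect_equal(diag(D$values), stats::setNames(rep(0, 3), names(seqs)))
  expect_true(max(abs(D$values - t(D$values))) < 1e-9)
  # unrelated pair is farther than the identical pair
  expect_gt(D$values["a", "c"], D$values["a", "b"])
})

test_that("extra mismatches never increase similarity", {
  base <- "GGGAGGGAGGGAGGGAGGGA"
  worsen <- function(s, k) {
    chars <- strsplit(s, "")[[1]]
    pos <- seq(2, by = 4, length.out = k)
    chars[pos] <- "T"
    paste(chars, collapse = "")
  }
  sims <- vapply(0:4, function(k) {
    D <- pairwise_similarity(c(a = base, b = worsen(base, k)))
    D$similarity["a", "b"]
  }, numeric(1))
  expect_true(all(diff(sims) <= 1e-9))
})

test_that("hierarchical clustering recovers planted partitions", {
  pb <- planted_blob_dist(c(6, 6), sep = 20, seed = 2)
  for (lk in c("ward", "complete", "average", "divisive")) {
    tree <- hierarchical_cluster(g4_dist(pb$d), lk)
    cut2 <- stats::cutree(tree, 2)
    expect_equal(length(unique(paste(cut2, pb$labels))), 2L, info = lk)
  }
  # a single pair merges at its distance
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree2 <- hierarchical_cluster(g4_dist(d2), "average")
  expect_equal(tree2$height, 3)
  expect_error(hierarchical_cluster(g4_dist(matrix(0, 1, 1))), "at least 2")
})

test_that("average-linkage heights match a brute-force recomputation", {
  pb <- planted_blob_dist(c(3, 3, 2), sep = 8, noise = 1, seed = 9)
  tree <- hierarchical_cluster(g4_dist(pb$d), "average")
  # brute-force UPGMA: repeatedly merge the closest pair of clusters where
  # cluster distance is the mean of member pairwise distances
  clusters <- as.list(seq_len(nrow(pb$d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(pb$d[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(tree$height, sort(heights), tolerance = 1e-9)
})

test_that("inertia-ratio rule finds planted blob counts", {
  for (k_true in 2:3) {
    pb <- planted_blob_dist(rep(6, k_true), sep = 15, seed = k_true)
    rep_k <- select_k_inertia(g4_dist(pb$d))
    expect_equal(rep_k$k, k_true)
    # I_m is nonincreasing in m for every linkage
    for (lk in unique(rep_k$report$linkage)) {
      inert <- rep_k$report$inertia[rep_k$report$linkage == lk]
      expect_true(all(diff(inert) <= 1e-9))
    }
  }
  # constant matrix: undefined, flagged
  d0 <- matrix(0, 6, 6, dimnames = list(paste0("x", 1:6), paste0("x", 1:6)))
  expect_false(select_k_inertia(g4_dist(d0))$defined)
})

test_that("five-index consensus votes for planted partition counts", {
  # idealized planted partition: every index has its optimum at the truth
  pb <- block_dist(c(7, 7), seed = 5)
  rep_k <- select_k_consensus(g4_dist(pb$d))
  expect_equal(rep_k$k, 2L)
  expect_equal(unname(rep_k$mode_of[c("silhouette", "dunn", "cindex",
                                      "mcclain")]), rep(2L, 4))

  pb3 <- block_dist(c(6, 6, 6), seed = 6)
  expect_equal(select_k_consensus(g4_dist(pb3$d))$k, 3L)

  # on noisy Gaussian blobs the consensus still lands on the truth even
  # though individual indices may wander
  pg <- planted_blob_dist(c(7, 7), sep = 20, seed = 5)
  expect_equal(select_k_consensus(g4_dist(pg$d))$k, 2L)
})

test_that("silhouette matches a manual computation on a 4-point matrix", {
  # two tight pairs: {a,b} at distance 1, {c,d} at distance 1, across = 10
  d <- matrix(10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 1
  diag(d) <- 0
  labels <- c(1L, 1L, 2L, 2L)
  # for every point: a(i) = 1, b(i) = 10, s(i) = (10-1)/10
  expect_equal(quadfam:::index_silhouette(d, labels), 9 / 10)
  # consensus voting is invariant to cluster relabelling
  expect_equal(quadfam:::index_silhouette(d, c(2L, 2L, 1L, 1L)), 9 / 10)
})
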