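# small shared fixture: three well-separated synthetic families
make_three_families <- function(n = 8, sub_rate = 0.03, seed = 42) {
  tpl <- random_g4_template(3, seed = seed)
  dplyr::bind_rows(lapply(seq_along(tpl), function(i) {
    simulate_g4_family(tpl[i], n, sim_config(sub_rate = sub_rate),
                       seed = seed + i, family_id = sprintf("fam%d", i))
  }))
}

test_that("one-sided rank-sum p-values match exhaustive enumeration", {
  # all 20 arrangements of {1..6} into two triples: the observed rank sum of
  # a fully dominated x is the minimum, so P(W >= W_obs) covers all 20
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 20 / 20)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)),
               enum_wilcoxon_greater(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3)), 1 / 20)
  expect_gte(wilcoxon_rank_sum(c(1.5, 2.5, 3.5), c(1, 2, 3)), 0.35)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")

  set.seed(8)
  for (i in 1:10) {
    x <- round(rnorm(sample(2:6, 1)), 3)
    y <- round(rnorm(sample(2:6, 1)), 3)
    expect_equal(wilcoxon_rank_sum(x, y),
                 enum_wilcoxon_greater(x, y), tolerance = 1e-12)
  }
})

test_that("Akaike weights match closed forms and normalise", {
  expect_equal(akaike_weights(rep(-3, 4)), rep(1 / 4, 4))
  # two models, delta AIC = 2: weights 1/(1+e^-1), e^-1/(1+e^-1)
  w <- akaike_weights(c(-1, -2))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  # complexity penalty shifts weight toward the smaller model
  w_k <- akaike_weights(c(-1, -1), ks = c(0, 1))
  expect_gt(w_k[1], w_k[2])
  # stability and normalisation on extreme inputs
  set.seed(5)
  for (i in 1:10) {
    w <- akaike_weights(rnorm(6, sd = 200))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= 0))
  }
  expect_error(akaike_weights(numeric(0)), "empty")
})

test_that("score_matrix scores every set against every profile", {
  fams <- make_three_families(n = 4)
  sets <- split(fams[, c("seq_id", "seq")], fams$family)
  profiles <- lapply(sets, function(s) build_phmm(align_sequences(s)))
  sc <- score_matrix(profiles, sets)
  expect_equal(nrow(sc), 3 * 3 * 4)
  expect_setequal(unique(sc$set), names(sets))
  expect_setequal(unique(sc$profile), names(sets))
  # own-profile scores dominate on well-separated families
  means <- dplyr::summarise(dplyr::group_by(sc, .data$set, .data$profile),
                            m = mean(log_odds), .groups = "drop")
  for (s in names(sets)) {
    own <- means$m[means$set == s & means$profile == s]
    other <- means$m[means$set == s & means$profile != s]
    expect_true(all(own > other))
  }
})

test_that("divergence test flags duplicated profiles as non-distinct", {
  fams <- make_three_families(n = 6)
  sets <- split(fams[, c("seq_id", "seq")], fams$family)
  profiles <- lapply(sets, function(s) build_phmm(align_sequences(s)))
  # add a duplicate of family 1 under a new name
  sets$dup <- sets[[1]]
  sets$dup$seq_id <- paste0("dup_", sets$dup$seq_id)
  profiles$dup <- profiles[[1]]
  sc <- score_matrix(profiles, sets)
  dv <- divergence_test(sc, alpha = 0.05)
  expect_false(dv$distinct[["fam1"]])
  expect_false(dv$distinct[["dup"]])
  expect_true(dv$distinct[["fam2"]])
  expect_true(dv$distinct[["fam3"]])
  # identical score distributions: p-value far from significant
  expect_gt(dv$p_values["fam1", "dup"], 0.4)
  expect_error(divergence_test(sc[sc$set == "fam1", ]), "at least 2")
})

test_that("refinement recovers well-separated synthetic families", {
  fams <- make_three_families(n = 8)
  dat <- dplyr::rename(fams, cluster = family)
  fs <- refine_families(dat, refinement_config(seed = 7))
  expect_s3_class(fs, "g4_family_set")
  expect_equal(length(fs), 3L)
  expect_true(fs$converged)
  pred <- dplyr::bind_rows(lapply(fs$families, function(f) {
    dplyr::mutate(f$members, family = f$id)
  }))
  ev <- evaluate_recovery(pred, fams)
  expect_gte(ev$ari, 0.9)
  # post hoc: every accepted family satisfies the acceptance conditions
  for (f in fs$families) {
    expect_gte(nrow(f$members), 4)
    expect_lt(f$gap_score, 0.10)
  }
})

test_that("two identical clusters collapse into one family", {
  one <- simulate_g4_family("GGGATGGGTTGGGCAGGG", 6,
                            sim_config(sub_rate = 0.02), seed = 3,
                            family_id = "f")
  dat <- dplyr::bind_rows(
    dplyr::mutate(one, cluster = 1),
    dplyr::mutate(one, seq_id = paste0("b_", seq_id), cluster = 2))
  fs <- refine_families(dat, refinement_config(seed = 3))
  expect_equal(length(fs), 1L)
  expect_equal(nrow(fs$families[[1]]$members), 12L)
})

test_that("refinement respects max_iter and empty input", {
  empty <- refine_families(tibble::tibble(seq_id = character(),
                                          seq = character(),
                                          cluster = character()))
  expect_equal(length(empty), 0L)
  expect_true(empty$converged)

  one <- simulate_g4_family("GGGATGGGTTGGGCAGGG", 6,
                            sim_config(sub_rate = 0.02), seed = 3,
                            family_id = "f")
  dat <- dplyr::bind_rows(
    dplyr::mutate(one, cluster = 1),
    dplyr::mutate(one, seq_id = paste0("b_", seq_id), cluster = 2))
  fs1 <- refine_families(dat, refinement_config(seed = 3, max_iter = 1))
  expect_lte(fs1$iterations, 1L)
})

test_that("refinement is idempotent on its own accepted output", {
  fams <- make_three_families(n = 8)
  fs <- refine_families(dplyr::rename(fams, cluster = family),
                        refinement_config(seed = 7))
  again_in <- dplyr::bind_rows(lapply(fs$families, function(f) {
    dplyr::mutate(f$members, cluster = f$id)
  }))
  fs2 <- refine_families(again_in, refinement_config(seed = 7))
  expect_equal(length(fs2), length(fs))
  members1 <- lapply(fs$families, function(f) sort(f$members$seq_id))
  members2 <- lapply(fs2$families, function(f) sort(f$members$seq_id))
  expect_setequal(unname(vapply(members1, paste, "", collapse = ",")),
                  unname(vapply(members2, paste, "", collapse = ",")))
})

test_that("classification reports Akaike weights across families", {
  fams <- make_three_families(n = 8)
  fs <- refine_families(dplyr::rename(fams, cluster = family),
                        refinement_config(seed = 7))
  # a verbatim member wins its own family with the merge-threshold weight
  res <- classify_g4(fams[1, c("seq_id", "seq")], fs)
  own_family <- res$family[1]
  expect_gte(res$akaike_weight[1], 0.7)
  expect_true(fams$seq_id[1] %in% fs$families[[own_family]]$members$seq_id)
  # full score vector: weights sum to 1, best is the argmax
  sc <- res$scores[[1]]
  expect_equal(sum(sc$akaike_weight), 1, tolerance = 1e-9)
  expect_equal(sc$family[which.max(sc$akaike_weight)], res$family[1])

  # single-family set gives weight 1
  single <- refine_families(
    dplyr::mutate(simulate_g4_family("GGGATGGGTTGGGCAGGG", 6,
                                     sim_config(sub_rate = 0.02), seed = 3),
                  cluster = 1),
    refinement_config(seed = 3))
  res1 <- classify_g4("GGGATGGGTTGGGCAGGG", single)
  expect_equal(res1$akaike_weight, 1)
})

test_that("classification emits the published report columns for Pu27", {
  fams <- make_three_families(n = 8)
  fs <- refine_families(dplyr::rename(fams, cluster = family),
                        refinement_config(seed = 7))
  pu27 <- "TGGGGAGGGTGGGGAGGGTGGGGAAGG"
  regions <- detect_g4(c(pu27 = pu27), detection_params(strands = "plus"))
  matches <- enumerate_g4_matches(regions)
  report <- classify_g4(
    tibble::tibble(seq_id = paste0("pu27_sub", seq_len(nrow(matches))),
                   seq = matches$seq), fs)
  report$length <- nchar(report$seq)
  # one row per minimal subsequence with the report columns populated
  expect_equal(nrow(report), nrow(matches))
  expect_true(all(c("seq_id", "seq", "length", "log_odds", "akaike_weight",
                    "family") %in% names(report)))
  expect_true(all(is.finite(report$log_odds)))
  expect_true(all(report$akaike_weight > 0 & report$akaike_weight <= 1))
})

test_that("merging deduplicates rediscovered families and only merges", {
  fams <- make_three_families(n = 8)
  fs1 <- refine_families(dplyr::rename(fams, cluster = family),
                         refinement_config(seed = 7))
  # a second route rediscovers the same families under different ids
  fams2 <- fams
  fams2$seq_id <- paste0("route2_", fams2$seq_id)
  fs2 <- refine_families(dplyr::rename(fams2, cluster = family),
                         refinement_config(seed = 8))
  merged <- merge_family_sets(list(fs1, fs2))
  expect_equal(length(merged), 3L)
  for (f in merged$families) {
    expect_equal(nrow(f$members), 16L)
  }
  # disjoint families stay apart; count can only shrink
  alone <- merge_family_sets(fs1)
  expect_equal(length(alone), length(fs1))
  expect_lte(length(merge_family_sets(list(fs1, fs2))),
             length(fs1) + length(fs2))
})
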