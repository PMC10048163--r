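#' One-sided Wilcoxon rank-sum test
#'
#' One-sided Mann-Whitney p-value for "x tends to be greater than y": exact
#' for small samples without ties, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative Only `"greater"` is used by the refinement engine.
#' @return The p-value.
#' @examples
#' wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3)) # 1/20
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "greater") {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = NULL,
                       correct = TRUE)$p.value
  )
}

#' Refinement configuration
#'
#' Thresholds of the iterative profile-refinement loop: a profile is accepted
#' as a family when it is distinct from every other profile (one-sided
#' rank-sum p < `alpha`), its own test sequences give it a mean membership
#' (Akaike) weight of at least `member_prob`, and its alignment gap score is
#' below `gap_max`. Non-distinct profiles are pooled and re-clustered; merged
#' alignments with gap score >= `merge_gap_max` are dropped. The loop runs to
#' convergence or `max_iter` passes.
#'
#' @param alpha Distinctness significance level.
#' @param member_prob Required mean membership probability (`prob_rule`
#'   switches between the `"mean"` and `"min"` reading).
#' @param gap_max Gap-score ceiling for acceptance.
#' @param merge_gap_max Gap-score ceiling applied after pooling.
#' @param max_iter Iteration cap.
#' @param test_set Score profiles on cluster `"members"` or on `"sampled"`
#'   sequences drawn from each profile.
#' @param sample_n Sequences to sample per profile when `test_set="sampled"`.
#' @param prob_rule `"mean"` or `"min"` membership aggregation.
#' @param min_size Minimum family size.
#' @param seed Seed for any sampling.
#' @return An object of class `g4_refinement_config`.
#' @export
refinement_config <- function(alpha = 0.05, member_prob = 0.99, gap_max = 0.10,
                              merge_gap_max = 0.6, max_iter = 100L,
                              test_set = c("members", "sampled"),
                              sample_n = 20L, prob_rule = c("mean", "min"),
                              min_size = 4L, seed = 1L) {
  test_set <- match.arg(test_set)
  prob_rule <- match.arg(prob_rule)
  stopifnot(alpha > 0, alpha < 1, member_prob >= 0, member_prob <= 1,
            gap_max >= 0, gap_max <= 1, merge_gap_max >= 0, merge_gap_max <= 1,
            max_iter >= 1)
  structure(list(alpha = alpha, member_prob = member_prob, gap_max = gap_max,
                 merge_gap_max = merge_gap_max, max_iter = as.integer(max_iter),
                 test_set = test_set, sample_n = as.integer(sample_n),
                 prob_rule = prob_rule, min_size = as.integer(min_size),
                 seed = as.integer(seed)),
            class = "g4_refinement_config")
}

#' Redundancy-merge configuration
#'
#' Thresholds for merging redundant families discovered by different
#' clustering routes: members of one family must cross-score above
#' `log_odds_min` on the other profile with cross-family Akaike weight at
#' least `akaike_min`, and the merged alignment must keep its gap score at or
#' below `gap_max`.
#'
#' @param log_odds_min Minimum mean cross log odds (nats).
#' @param akaike_min Minimum mean cross Akaike weight.
#' @param gap_max Gap-score ceiling for an accepted merge.
#' @param alpha Significance level of the rank-sum distinctness test reused
#'   from the refinement step: candidate pairs must be statistically
#'   indistinguishable before the thresholds are even consulted.
#' @return An object of class `g4_merge_config`.
#' @export
merge_config <- function(log_odds_min = 5, akaike_min = 0.7, gap_max = 0.07,
                         alpha = 0.05) {
  stopifnot(akaike_min >= 0, akaike_min <= 1, gap_max >= 0, gap_max <= 1,
            alpha > 0, alpha < 1)
  structure(list(log_odds_min = log_odds_min, akaike_min = akaike_min,
                 gap_max = gap_max, alpha = alpha),
            class = "g4_merge_config")
}

#' Normalized Akaike weights
#'
#' \eqn{AIC_i = 2 k_i - 2 \ell_i}; weights are
#' \eqn{w_i = e^{-\Delta_i / 2} / \sum_j e^{-\Delta_j / 2}} with
#' \eqn{\Delta_i = AIC_i - \min AIC}, computed stably in log space. With all
#' `ks = 0` (the default used for family models of similar length) the
#' weights reduce to normalized likelihood weights.
#'
#' @param logliks Finite log-likelihoods.
#' @param ks Model complexity per model (same length, recycled).
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(-1, -2)) # two models, delta AIC = 2
#' @export
akaike_weights <- function(logliks, ks = 0) {
  if (length(logliks) == 0L) stop("empty log-likelihood vector")
  stopifnot(all(is.finite(logliks)))
  ks <- rep_len(ks, length(logliks))
  aic <- 2 * ks - 2 * logliks
  delta <- aic - min(aic)
  lw <- -delta / 2
  w <- exp(lw - logsumexp(lw))
  w / sum(w)
}

#' Score sequence sets against profiles
#'
#' Every sequence of every set is scored (forward log odds) against every
#' profile.
#'
#' @param profiles A list of [build_phmm()] models (one per set).
#' @param seq_sets A list (same length) of data frames with `seq_id`, `seq`.
#' @param null A [null_model()].
#' @return A tibble `set`, `profile`, `seq_id`, `log_odds`, `forward_loglik`.
#' @export
score_matrix <- function(profiles, seq_sets, null = null_model()) {
  stopifnot(length(profiles) == length(seq_sets))
  set_names <- names(profiles)
  if (is.null(set_names)) set_names <- as.character(seq_along(profiles))
  out <- list()
  for (i in seq_along(seq_sets)) {
    set_i <- as_seq_tbl(seq_sets[[i]])
    for (j in seq_along(profiles)) {
      sc <- purrr::map_dfr(set_i$seq,
                           function(s) forward_log_odds(profiles[[j]], s, null))
      out[[length(out) + 1L]] <- tibble::tibble(
        set = set_names[i], profile = set_names[j], seq_id = set_i$seq_id,
        log_odds = sc$log_odds, forward_loglik = sc$forward_loglik)
    }
  }
  dplyr::bind_rows(out)
}

#' Profile distinctness test
#'
#' Profile i is distinct iff, for every other profile j, the one-sided
#' rank-sum test of (scores of set i on profile i) vs (scores of set i on
#' profile j) gives p < `alpha`. P-values are reported raw (no multiplicity
#' correction), with an optional Benjamini-Hochberg switch.
#'
#' @param scores A [score_matrix()] tibble.
#' @param alpha Significance level.
#' @param adjust Apply Benjamini-Hochberg to each profile's p-value row.
#' @return A list: `distinct` (named logical), `p_values` (matrix, rows =
#'   scored set, cols = competing profile).
#' @export
divergence_test <- function(scores, alpha = 0.05, adjust = FALSE) {
  sets <- unique(scores$set)
  if (length(sets) < 2L) stop("need at least 2 profiles")
  p <- matrix(NA_real_, length(sets), length(sets),
              dimnames = list(sets, sets))
  for (i in sets) {
    own <- scores$log_odds[scores$set == i & scores$profile == i]
    for (j in setdiff(sets, i)) {
      other <- scores$log_odds[scores$set == i & scores$profile == j]
      p[i, j] <- wilcoxon_rank_sum(own, other, "greater")
    }
  }
  pe <- p
  if (adjust) {
    for (i in sets) pe[i, ] <- stats::p.adjust(p[i, ], method = "BH")
  }
  distinct <- apply(pe, 1L, function(row) all(row[!is.na(row)] < alpha))
  list(distinct = distinct, p_values = p)
}

# ---- family / family set containers ---------------------------------------

new_family <- function(id, members, aln, hmm, provenance = list()) {
  structure(list(id = id, members = tibble::as_tibble(members),
                 alignment = aln, hmm = hmm,
                 gap_score = gap_score(aln),
                 consensus = iupac_consensus(aln),
                 provenance = provenance),
            class = "g4_family")
}

#' @export
print.g4_family <- function(x, ...) {
  cat(sprintf("G4 family %s: %d members, gap score %.3f\n  consensus %s\n",
              x$id, nrow(x$members), x$gap_score, x$consensus))
  invisible(x)
}

new_family_set <- function(families, config = NULL, converged = NA,
                           iterations = NA_integer_) {
  names(families) <- vapply(families, `[[`, character(1L), "id")
  structure(list(families = families, config = config,
                 converged = converged, iterations = iterations),
            class = "g4_family_set")
}

#' @export
print.g4_family_set <- function(x, ...) {
  cat(sprintf("G4 family set: %d families (converged: %s, iterations: %s)\n",
              length(x$families), x$converged, x$iterations))
  for (f in x$families) {
    cat(sprintf("  %-8s %3d members  gap %.3f  %s\n", f$id, nrow(f$members),
                f$gap_score, f$consensus))
  }
  invisible(x)
}

#' @export
length.g4_family_set <- function(x) length(x$families)

# align + adjust + train for one member tibble
fit_cluster <- function(members) {
  aln <- adjust_gaps(align_sequences(members))
  list(aln = aln, hmm = build_phmm(aln))
}

# membership probability of each profile for its own test set:
# Akaike weight of profile i across all profiles, aggregated per prob_rule
membership_prob <- function(scores, rule = "mean") {
  sets <- unique(scores$set)
  vapply(sets, function(i) {
    sub <- scores[scores$set == i, ]
    per_seq <- vapply(split(sub, sub$seq_id), function(ss) {
      ss <- ss[order(match(ss$profile, sets)), ]
      w <- akaike_weights(ss$log_odds)
      w[match(i, sets)]
    }, numeric(1L))
    if (rule == "mean") mean(per_seq) else min(per_seq)
  }, numeric(1L))
}

#' Iterative family refinement
#'
#' The core refinement loop: align each cluster, train a profile HMM, score
#' every cluster's test sequences against every profile, and test profile
#' distinctness with one-sided rank-sum tests. Profiles that are distinct,
#' claim their own sequences with high membership probability, and have a
#' clean alignment are accepted as families. Non-distinct profiles are pooled
#' by connected components of the mutual non-distinctness relation and
#' re-clustered with average-linkage agglomeration (k chosen by the
#' inertia-ratio rule, k = 1 allowed so duplicated clusters can collapse);
#' pooled alignments whose gap score reaches `merge_gap_max` are dropped.
#' Repeats until convergence or `max_iter`. Deterministic given the seed.
#'
#' @param data A data frame with `seq_id`, `seq` and `cluster` columns
#'   (clusters already size-filtered, see [filter_clusters()]).
#' @param config A [refinement_config()].
#' @return A `g4_family_set`.
#' @export
refine_families <- function(data, config = refinement_config()) {
  if (is.null(data) || nrow(data) == 0L) {
    return(new_family_set(list(), config, converged = TRUE, iterations = 0L))
  }
  stopifnot(all(c("seq_id", "seq", "cluster") %in% names(data)))
  clusters <- split(tibble::as_tibble(data)[, c("seq_id", "seq")],
                    data$cluster)
  accepted <- list()
  prev_sig <- NULL
  iter <- 0L
  converged <- FALSE
  while (iter < config$max_iter) {
    iter <- iter + 1L
    clusters <- Filter(function(cl) nrow(cl) >= config$min_size, clusters)
    if (length(clusters) == 0L) { converged <- TRUE; break }
    fits <- lapply(clusters, fit_cluster)
    profiles <- lapply(fits, `[[`, "hmm")
    names(profiles) <- as.character(seq_along(profiles))
    test_sets <- if (config$test_set == "members") {
      clusters
    } else {
      lapply(seq_along(profiles), function(i) {
        tibble::tibble(
          seq_id = paste0("samp", seq_len(config$sample_n)),
          seq = sample_phmm(profiles[[i]], config$sample_n,
                            seed = config$seed + i))
      })
    }
    names(test_sets) <- names(profiles)
    if (length(profiles) == 1L) {
      ok_gap <- gap_score(fits[[1L]]$aln) < config$gap_max
      # distinctness is vacuous for a single remaining profile
      if (ok_gap) {
        accepted[[length(accepted) + 1L]] <-
          list(members = clusters[[1L]], fit = fits[[1L]], iteration = iter)
      }
      converged <- TRUE
      break
    }
    sc <- score_matrix(profiles, test_sets)
    dv <- divergence_test(sc, config$alpha)
    memb <- membership_prob(sc, config$prob_rule)
    gaps <- vapply(fits, function(f) gap_score(f$aln), numeric(1L))
    # a non-distinctness edge in either direction ties both profiles into
    # the same pool: the profile a fragment cannot be told apart from must
    # not be accepted separately, or the fragment is stranded
    np <- length(profiles)
    adj <- matrix(FALSE, np, np)
    for (a in seq_len(np - 1L)) {
      for (b in seq.int(a + 1L, np)) {
        i <- names(profiles)[a]; j <- names(profiles)[b]
        ns <- dv$p_values[i, j] >= config$alpha ||
          dv$p_values[j, i] >= config$alpha
        adj[a, b] <- adj[b, a] <- isTRUE(ns)
      }
    }
    untied <- !apply(adj, 1L, any)
    accept <- dv$distinct & untied & memb >= config$member_prob &
      gaps < config$gap_max
    for (i in which(accept)) {
      accepted[[length(accepted) + 1L]] <-
        list(members = clusters[[i]], fit = fits[[i]], iteration = iter)
    }
    rest <- which(!accept)
    if (length(rest) == 0L) { converged <- TRUE; break }
    comp <- components_of(adj[rest, rest, drop = FALSE])
    new_clusters <- list()
    for (cids in comp) {
      pooled <- dplyr::bind_rows(clusters[rest[cids]])
      pooled <- pooled[!duplicated(pooled$seq_id), ]
      if (length(cids) == 1L) {
        new_clusters[[length(new_clusters) + 1L]] <- pooled
        next
      }
      parts <- recluster_pool(pooled)
      for (pp in parts) {
        aln <- adjust_gaps(align_sequences(pp))
        if (gap_score(aln) >= config$merge_gap_max) next
        new_clusters[[length(new_clusters) + 1L]] <- pp
      }
    }
    sig <- sort(vapply(new_clusters,
                       function(cl) paste(sort(cl$seq_id), collapse = ","),
                       character(1L)))
    if (!is.null(prev_sig) && identical(sig, prev_sig)) {
      # no further movement: keep remaining clusters unaccepted
      converged <- TRUE
      clusters <- new_clusters
      break
    }
    prev_sig <- sig
    clusters <- new_clusters
  }
  fams <- lapply(seq_along(accepted), function(i) {
    a <- accepted[[i]]
    new_family(id = sprintf("F%02d", i), members = a$members,
               aln = a$fit$aln, hmm = a$fit$hmm,
               provenance = list(iteration = a$iteration))
  })
  new_family_set(fams, config, converged = converged, iterations = iter)
}

components_of <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; comp <- integer(0L)
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# re-cluster a pooled set of sequences: average linkage on edit distance,
# k by the inertia-ratio rule over 1..kmax. Undersized split-offs are
# reassigned to the nearest sizeable part instead of being lost downstream.
recluster_pool <- function(pooled, kmax = 6L, min_size = 4L) {
  n <- nrow(pooled)
  if (n < 2L) return(list(pooled))
  dm <- utils::adist(pooled$seq)
  dimnames(dm) <- list(pooled$seq_id, pooled$seq_id)
  if (max(dm) == 0) return(list(pooled))
  tree <- hierarchical_cluster(g4_dist(dm), "average")
  ks <- seq_len(min(kmax, n - 1L))
  inertia <- vapply(ks, function(k) inertia_of_cut(dm, stats::cutree(tree, k)),
                    numeric(1L))
  # successive inertia ratio I_{k-1}/I_k; a pool without real substructure
  # (all ratios below 2) stays a single cluster so duplicated clusters can
  # collapse into one family
  ratio <- inertia[-length(ks)] / pmax(inertia[-1L], 1e-12)
  k <- if (length(ratio) == 0L || all(inertia == 0) || max(ratio) < 2) {
    1L
  } else {
    ks[which.max(ratio) + 1L]
  }
  labels <- stats::cutree(tree, k)
  sizes <- table(labels)
  big <- as.integer(names(sizes)[sizes >= min_size])
  if (length(big) >= 1L && length(big) < length(sizes)) {
    for (i in which(!labels %in% big)) {
      near <- big[which.min(vapply(big, function(b) {
        mean(dm[i, labels == b & seq_len(n) != i])
      }, numeric(1L)))]
      labels[i] <- near
    }
  }
  lapply(split(seq_len(n), labels), function(idx) pooled[idx, ])
}

#' Classify sequences against a family set
#'
#' Scores each query against every family profile with the forward algorithm
#' and converts the log odds into normalized Akaike weights across families;
#' the maximum-weight family is reported (ties to the lowest family id).
#'
#' @param data A data frame with `seq_id` and `seq` (or a character vector).
#' @param family_set A `g4_family_set`.
#' @param null A [null_model()].
#' @return A tibble `seq_id`, `seq`, `family`, `log_odds`, `akaike_weight`
#'   plus a `scores` list-column holding the full per-family score tibble.
#' @export
classify_g4 <- function(data, family_set, null = null_model()) {
  stopifnot(inherits(family_set, "g4_family_set"),
            length(family_set$families) >= 1L)
  data <- as_seq_tbl(data)
  fam_ids <- names(family_set$families)
  purrr::pmap_dfr(data[, c("seq_id", "seq")], function(seq_id, seq) {
    sc <- purrr::map_dfr(family_set$families, function(f) {
      forward_log_odds(f$hmm, seq, null)
    })
    w <- akaike_weights(sc$log_odds)
    best <- which(w == max(w))[1L]   # ties to lowest family id (list order)
    tibble::tibble(
      seq_id = seq_id, seq = seq,
      family = fam_ids[best],
      log_odds = sc$log_odds[best],
      akaike_weight = w[best],
      scores = list(tibble::tibble(family = fam_ids,
                                   log_odds = sc$log_odds,
                                   akaike_weight = w)))
  })
}

#' Merge redundant families across family sets
#'
#' Families discovered by different clustering routes are checked pairwise
#' for redundancy with the refinement step's rank-sum machinery plus the
#' merge thresholds: direction i to j passes when i's members score above
#' `log_odds_min` on j's profile on average, the rank-sum test cannot tell
#' their own-profile scores from the cross scores (p >= `alpha`), and j
#' receives a mean cross-family Akaike weight (computed with family i
#' excluded from the candidate set) of at least `akaike_min`; both directions
#' must pass, so a broad profile cannot absorb a distinct narrow one.
#' Redundant groups are re-aligned and re-trained; a
#' merge is kept only if the merged gap score stays at or below `gap_max`.
#'
#' @param sets A list of `g4_family_set` objects (or a single set).
#' @param config A [merge_config()].
#' @param null A [null_model()].
#' @return A merged `g4_family_set`.
#' @export
merge_family_sets <- function(sets, config = merge_config(),
                              null = null_model()) {
  if (inherits(sets, "g4_family_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  fams <- list()
  for (si in seq_along(sets)) {
    for (f in sets[[si]]$families) {
      f$id <- sprintf("S%d.%s", si, f$id)
      fams[[f$id]] <- f
    }
  }
  n <- length(fams)
  if (n <= 1L) return(new_family_set(fams, config))
  ids <- names(fams)
  direction_pass <- function(i, j) {
    members <- fams[[i]]$members
    lo_j <- vapply(members$seq, function(s) {
      forward_log_odds(fams[[j]]$hmm, s, null)$log_odds
    }, numeric(1L), USE.NAMES = FALSE)
    if (mean(lo_j) < config$log_odds_min) return(FALSE)
    # rank-sum distinctness as in the refinement step: i's members must NOT
    # score detectably better on their own profile than on j's
    lo_i <- vapply(members$seq, function(s) {
      forward_log_odds(fams[[i]]$hmm, s, null)$log_odds
    }, numeric(1L), USE.NAMES = FALSE)
    if (wilcoxon_rank_sum(lo_i, lo_j, "greater") < config$alpha) return(FALSE)
    others <- setdiff(ids, i)
    w_j <- vapply(members$seq, function(s) {
      lo <- vapply(others, function(k) {
        forward_log_odds(fams[[k]]$hmm, s, null)$log_odds
      }, numeric(1L))
      akaike_weights(lo)[match(j, others)]
    }, numeric(1L), USE.NAMES = FALSE)
    mean(w_j) >= config$akaike_min
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      if (find(a) == find(b)) next
      # redundancy must be mutual: a one-way attraction (a broad profile
      # absorbing a narrow one) is not evidence the families coincide
      if (direction_pass(ids[a], ids[b]) && direction_pass(ids[b], ids[a])) {
        # candidate merge: verify the merged alignment stays clean
        members <- dplyr::bind_rows(fams[[ids[a]]]$members,
                                    fams[[ids[b]]]$members)
        members <- members[!duplicated(members$seq_id), ]
        aln <- adjust_gaps(align_sequences(members))
        if (gap_score(aln) <= config$gap_max) {
          parent[find(b)] <- find(a)
        }
      }
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1L)))
  merged <- lapply(seq_along(groups), function(gi) {
    idx <- groups[[gi]]
    members <- dplyr::bind_rows(lapply(fams[idx], `[[`, "members"))
    members <- members[!duplicated(members$seq_id), ]
    fit <- fit_cluster(members)
    new_family(id = sprintf("M%02d", gi), members = members,
               aln = fit$aln, hmm = fit$hmm,
               provenance = list(merged_from = ids[idx]))
  })
  new_family_set(merged, config)
}
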