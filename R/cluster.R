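#' Levenshtein edit distance
#'
#' Exact unit-cost edit distance between two strings.
#'
#' @param a,b Character scalars (or equal-length vectors, compared pairwise).
#' @return Integer distance(s).
#' @examples
#' levenshtein("GGGAGGG", "GGGTGGG")
#' @export
levenshtein <- function(a, b) {
  as.integer(diag(utils::adist(a, b)))
}

#' Sphere-clustering parameters
#'
#' @param radius Levenshtein radius (>= 1; default 2).
#' @param ordering Center selection order: `"length_desc"` (longest first,
#'   ties lexicographic) or `"input"`.
#' @param group_filter Require members to share the center's tract count and
#'   have length within `radius` of the center's.
#' @return An object of class `g4_sphere_params`.
#' @export
sphere_params <- function(radius = 2L, ordering = c("length_desc", "input"),
                          group_filter = TRUE) {
  ordering <- match.arg(ordering)
  stopifnot(radius >= 1)
  structure(list(radius = as.integer(radius), ordering = ordering,
                 group_filter = group_filter),
            class = "g4_sphere_params")
}

#' Levenshtein sphere clustering
#'
#' Deterministic sphere clustering: centers are taken in the configured order
#' and every not-yet-assigned sequence within `radius` edits of the center
#' (and passing the group filter) joins its cluster. Sequences ending up in
#' singleton spheres are returned as unassigned, to be handled by the
#' alignment-similarity stage.
#'
#' @param data A data frame with `seq_id` and `seq` (or a character vector).
#' @param params A [sphere_params()].
#' @return A tibble `seq_id`, `seq`, `cluster` (NA when unassigned) and
#'   `stage` (`"sphere"` or `"unassigned"`).
#' @export
cluster_spheres <- function(data, params = sphere_params()) {
  data <- as_seq_tbl(data)
  stopifnot(nrow(data) >= 1L)
  n <- nrow(data)
  ord <- if (params$ordering == "length_desc") {
    order(-nchar(data$seq), data$seq, data$seq_id)
  } else {
    seq_len(n)
  }
  tract_counts <- vapply(data$seq, function(s) nrow(find_g_tracts(s)),
                         integer(1L), USE.NAMES = FALSE)
  assigned <- rep(NA_integer_, n)
  next_id <- 0L
  for (ci in ord) {
    if (!is.na(assigned[ci])) next
    cand <- which(is.na(assigned))
    d <- utils::adist(data$seq[ci], data$seq[cand])[1L, ]
    keep <- d <= params$radius
    if (params$group_filter) {
      keep <- keep &
        tract_counts[cand] == tract_counts[ci] &
        abs(nchar(data$seq[cand]) - nchar(data$seq[ci])) <= params$radius
    }
    members <- cand[keep | cand == ci]
    if (length(members) >= 2L) {
      next_id <- next_id + 1L
      assigned[members] <- next_id
    } else {
      assigned[ci] <- 0L   # provisional singleton
    }
  }
  tibble::tibble(
    seq_id = data$seq_id, seq = data$seq,
    cluster = ifelse(assigned > 0L, assigned, NA_integer_),
    stage = ifelse(assigned > 0L, "sphere", "unassigned")
  )
}

#' Symmetric distance matrix container
#'
#' @param values A symmetric nonnegative matrix with zero diagonal.
#' @param labels Row/column labels.
#' @return An object of class `g4_dist`.
#' @export
g4_dist <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values),
            max(abs(values - t(values))) < 1e-8,
            all(diag(values) == 0), all(values >= 0))
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "g4_dist")
}

#' @export
print.g4_dist <- function(x, ...) {
  cat(sprintf("G4 distance matrix: %d sequences, max distance %.3f\n",
              length(x$labels), max(x$values)))
  invisible(x)
}

#' Alignment-based all-vs-all similarity
#'
#' Replacement for an all-vs-all BLAST: each pair is aligned locally
#' (Smith-Waterman) and the score S converted to an E-value by the
#' Karlin-Altschul formula \eqn{E = K m n e^{-\lambda S}}; similarity is
#' \eqn{\max(0, -\log E)} and distance is the matrix maximum minus the
#' similarity (diagonal forced to zero).
#'
#' @param data A data frame with `seq_id` and `seq` (>= 2 rows).
#' @param match,mismatch,gap_open,gap_extend Local alignment scores.
#' @param lambda,K Karlin-Altschul parameters.
#' @return A [g4_dist()] with a `similarity` element attached.
#' @export
pairwise_similarity <- function(data, match = 2, mismatch = -3,
                                gap_open = -5, gap_extend = -2,
                                lambda = 0.625, K = 0.41) {
  data <- as_seq_tbl(data)
  n <- nrow(data)
  stopifnot(n >= 2L)
  subj <- Biostrings::DNAStringSet(toupper(data$seq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  sim <- matrix(0, n, n, dimnames = list(data$seq_id, data$seq_id))
  len <- nchar(data$seq)
  for (i in seq_len(n)) {
    js <- seq_len(n)[seq_len(n) >= i]
    sc <- Biostrings::pairwiseAlignment(
      subj[js], subj[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = -gap_open, gapExtension = -gap_extend, scoreOnly = TRUE)
    e <- K * len[i] * len[js] * exp(-lambda * sc)
    s <- pmax(-log(e), 0)
    sim[i, js] <- s
    sim[js, i] <- s
  }
  d <- max(sim) - sim
  diag(d) <- 0
  out <- g4_dist(d, data$seq_id)
  out$similarity <- sim
  out
}

#' Hierarchical clustering of a G4 distance matrix
#'
#' @param D A [g4_dist()] (or a symmetric matrix / `dist`).
#' @param linkage `"ward"`, `"complete"`, `"average"`, or `"divisive"`
#'   (DIANA-style divisive analysis).
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(D, linkage = c("ward", "complete", "average",
                                                "divisive")) {
  linkage <- match.arg(linkage)
  d <- as_dist_obj(D)
  if (attr(d, "Size") < 2L) stop("need at least 2 sequences to cluster")
  if (linkage == "divisive") {
    stats::as.hclust(cluster::diana(d, diss = TRUE))
  } else {
    stats::hclust(d, method = switch(linkage, ward = "ward.D2",
                                     complete = "complete",
                                     average = "average"))
  }
}

as_dist_obj <- function(D) {
  if (inherits(D, "g4_dist")) return(stats::as.dist(D$values))
  if (inherits(D, "dist")) return(D)
  stats::as.dist(as.matrix(D))
}

# within-cluster inertia: sum of squared distances to the cluster medoid
inertia_of_cut <- function(dm, labels) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) == 1L) return(0)
    sub <- dm[idx, idx, drop = FALSE]
    min(colSums(sub^2))
  }, numeric(1L)))
}

#' Choose k by the inertia-ratio rule
#'
#' For each cut of the tree, the within-cluster inertia \eqn{I_m} is the sum
#' of squared distances to cluster medoids; the chosen k realises the maximum
#' successive inertia ratio (the split whose creation collapses the most
#' within-cluster inertia). With `linkage` a vector, the rule is applied per
#' linkage and the mode of the choices reported.
#'
#' @param D A [g4_dist()].
#' @param k_range Candidate cluster counts (within `[2, n-1]`; extended
#'   internally by one to form the final ratio).
#' @param linkage Linkage method(s); see [hierarchical_cluster()].
#' @return A `g4_k_report`: chosen `k`, `mode_of` per-linkage picks, and a
#'   per-k `report` tibble. Degenerate (constant-distance) input yields
#'   `k = NA` with `defined = FALSE`.
#' @export
select_k_inertia <- function(D, k_range = NULL,
                             linkage = c("ward", "complete", "average",
                                         "divisive")) {
  dm <- if (inherits(D, "g4_dist")) D$values else as.matrix(D)
  n <- nrow(dm)
  if (is.null(k_range)) k_range <- 2:min(15L, n - 1L)
  stopifnot(all(k_range >= 1L), all(k_range <= n - 1L))
  picks <- integer(0L)
  reports <- list()
  for (lk in linkage) {
    tree <- hierarchical_cluster(g4_dist(dm), lk)
    # the inertia drop realised by moving from k-1 to k clusters: the chosen
    # k is the cut whose creation collapses the most within-cluster inertia
    ks <- sort(unique(c(min(k_range) - 1L, k_range)))
    ks <- ks[ks >= 1L & ks <= n]
    inertia <- vapply(ks, function(k) {
      inertia_of_cut(dm, stats::cutree(tree, k = k))
    }, numeric(1L))
    ratio <- rep(NA_real_, length(ks))
    idx <- match(k_range, ks)
    prv <- match(k_range - 1L, ks)
    ok <- !is.na(prv) & inertia[idx] > 0
    ratio[idx[ok]] <- inertia[prv[ok]] / inertia[idx[ok]]
    reports[[lk]] <- tibble::tibble(linkage = lk, k = ks, inertia = inertia,
                                    ratio = ratio)
    if (any(!is.na(ratio))) {
      picks <- c(picks, ks[which.max(ratio)])
    }
  }
  report <- dplyr::bind_rows(reports)
  if (length(picks) == 0L) {
    return(structure(list(k = NA_integer_, defined = FALSE, mode_of = picks,
                          report = report, method = "inertia"),
                     class = "g4_k_report"))
  }
  structure(list(k = stat_mode(picks), defined = TRUE, mode_of = picks,
                 report = report, method = "inertia"),
            class = "g4_k_report")
}

# smallest modal value
stat_mode <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' @export
print.g4_k_report <- function(x, ...) {
  cat(sprintf("k-selection (%s): chosen k = %s\n", x$method, x$k))
  if (length(x$mode_of)) {
    cat("  votes:", paste(x$mode_of, collapse = ", "), "\n")
  }
  invisible(x)
}

# --- internal validity indices (computed from the distance matrix) ---------

index_silhouette <- function(dm, labels) {
  mean(cluster::silhouette(labels, stats::as.dist(dm))[, "sil_width"])
}

index_dunn <- function(dm, labels) {
  cl <- unique(labels)
  within <- max(vapply(cl, function(c1) {
    idx <- which(labels == c1)
    if (length(idx) < 2L) return(0)
    max(dm[idx, idx])
  }, numeric(1L)))
  between <- min(vapply(utils::combn(cl, 2L, simplify = FALSE), function(pr) {
    min(dm[labels == pr[1L], labels == pr[2L], drop = FALSE])
  }, numeric(1L)))
  if (within == 0) return(Inf)
  between / within
}

# C-index: (S - Smin) / (Smax - Smin), S = sum of within-cluster distances
index_cindex <- function(dm, labels) {
  pairs <- which(upper.tri(dm))
  dvec <- dm[pairs]
  same <- outer(labels, labels, "==")[pairs]
  nw <- sum(same)
  if (nw == 0L) return(NA_real_)
  s <- sum(dvec[same])
  sorted <- sort(dvec)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq.int(length(sorted) - nw + 1L, length(sorted))])
  if (smax == smin) return(NA_real_)
  (s - smin) / (smax - smin)
}

# McClain-Rao: mean within-cluster distance / mean between-cluster distance
index_mcclain <- function(dm, labels) {
  pairs <- which(upper.tri(dm))
  dvec <- dm[pairs]
  same <- outer(labels, labels, "==")[pairs]
  if (!any(same) || all(same)) return(NA_real_)
  mean(dvec[same]) / mean(dvec[!same])
}

# mean between / mean within at a cut (used by the Frey-van Groenewoud rule)
frey_components <- function(dm, labels) {
  pairs <- which(upper.tri(dm))
  dvec <- dm[pairs]
  same <- outer(labels, labels, "==")[pairs]
  c(between = if (any(!same)) mean(dvec[!same]) else NA_real_,
    within = if (any(same)) mean(dvec[same]) else NA_real_)
}

#' Choose k by consensus of five internal indices
#'
#' Computes silhouette (max), Dunn (max), C-index (min), McClain-Rao (min)
#' and the Frey-van Groenewoud ratio across the candidate cuts of the tree,
#' and returns the mode of the five per-index optima (ties toward smaller k).
#'
#' @inheritParams select_k_inertia
#' @param linkage A single linkage for the tree being cut.
#' @return A `g4_k_report` with per-index votes.
#' @export
select_k_consensus <- function(D, k_range = NULL, linkage = "average") {
  dm <- if (inherits(D, "g4_dist")) D$values else as.matrix(D)
  n <- nrow(dm)
  if (is.null(k_range)) k_range <- 2:min(15L, n - 1L)
  stopifnot(all(k_range >= 2L), all(k_range <= n - 1L))
  tree <- hierarchical_cluster(g4_dist(dm), linkage)
  cuts <- lapply(k_range, function(k) stats::cutree(tree, k = k))
  per_k <- tibble::tibble(
    k = k_range,
    silhouette = vapply(cuts, function(l) index_silhouette(dm, l), numeric(1L)),
    dunn = vapply(cuts, function(l) index_dunn(dm, l), numeric(1L)),
    cindex = vapply(cuts, function(l) index_cindex(dm, l), numeric(1L)),
    mcclain = vapply(cuts, function(l) index_mcclain(dm, l), numeric(1L))
  )
  fc <- vapply(cuts, function(l) frey_components(dm, l), numeric(2L))
  # Frey: ratio of successive differences of mean between / mean within;
  # take the last k before the ratio first drops below 1 (fallback: k_range
  # start when it never does)
  frey_ratio <- rep(NA_real_, length(k_range))
  if (length(k_range) > 1L) {
    db <- diff(fc["between", ]); dw <- diff(fc["within", ])
    frey_ratio[-1L] <- ifelse(dw == 0, NA_real_, db / dw)
  }
  per_k$frey <- frey_ratio
  vote <- function(values, optimum) {
    if (all(is.na(values))) return(NA_integer_)
    if (optimum == "max") k_range[which.max(values)]
    else k_range[which.min(values)]
  }
  below <- which(!is.na(frey_ratio) & frey_ratio < 1)
  frey_pick <- if (length(below)) k_range[max(below[1L] - 1L, 1L)] else k_range[1L]
  votes <- c(silhouette = vote(per_k$silhouette, "max"),
             dunn = vote(per_k$dunn, "max"),
             cindex = vote(per_k$cindex, "min"),
             mcclain = vote(per_k$mcclain, "min"),
             frey = frey_pick)
  votes_ok <- votes[!is.na(votes)]
  if (length(votes_ok) == 0L) {
    return(structure(list(k = NA_integer_, defined = FALSE, mode_of = votes,
                          report = per_k, method = "consensus"),
                     class = "g4_k_report"))
  }
  tab <- table(votes_ok)
  k <- as.integer(names(tab)[which.max(tab)])  # ties toward smaller k
  structure(list(k = k, defined = TRUE, mode_of = votes, report = per_k,
                 method = "consensus"),
            class = "g4_k_report")
}
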