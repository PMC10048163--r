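#' Two-stage initial clustering
#'
#' The clustering front half of the discovery pipeline: Levenshtein sphere
#' clustering first, then alignment-similarity plus hierarchical clustering
#' (k chosen by the inertia-ratio rule) on the sequences the spheres leave
#' unassigned.
#'
#' @param data A data frame with `seq_id` and `seq` (or a character vector).
#' @param sphere A [sphere_params()].
#' @param linkage Linkage for the similarity-stage tree.
#' @return A tibble `seq_id`, `seq`, `cluster`, `stage` (`"sphere"`,
#'   `"similarity"`, or `"unassigned"` when the similarity stage could not
#'   place a sequence).
#' @export
cluster_g4 <- function(data, sphere = sphere_params(), linkage = "ward") {
  data <- as_seq_tbl(data)
  sp <- cluster_spheres(data, sphere)
  left <- sp[sp$stage == "unassigned", ]
  if (nrow(left) >= 4L) {
    D <- pairwise_similarity(left)
    ks <- select_k_inertia(D)
    if (isTRUE(ks$defined)) {
      labels <- stats::cutree(hierarchical_cluster(D, linkage), k = ks$k)
      base <- max(sp$cluster, 0L, na.rm = TRUE)
      idx <- match(left$seq_id, sp$seq_id)
      sp$cluster[idx] <- base + labels
      sp$stage[idx] <- "similarity"
    }
  }
  sp
}

#' Discover G4 families in sequences
#'
#' End-to-end discovery: [cluster_g4()], size filtering, iterative
#' [refine_families()], and a final [merge_family_sets()] redundancy pass.
#'
#' @param data A data frame with `seq_id` and `seq` (e.g. region sequences
#'   from [detect_g4()]), or a character vector.
#' @param refinement A [refinement_config()].
#' @param merge A [merge_config()].
#' @param sphere A [sphere_params()].
#' @return A `g4_family_set`.
#' @examples
#' \donttest{
#' seqs <- simulate_g4_family("GGGATGGGTTGGGCAGGG", 8, seed = 1)
#' discover_g4_families(seqs)
#' }
#' @export
discover_g4_families <- function(data, refinement = refinement_config(),
                                 merge = merge_config(),
                                 sphere = sphere_params()) {
  clustered <- cluster_g4(data, sphere)
  clustered <- filter_clusters(clustered[!is.na(clustered$cluster), ],
                               refinement$min_size)
  fs <- refine_families(clustered, refinement)
  merge_family_sets(fs, merge)
}
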