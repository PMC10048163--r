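#' Synthetic G4 family and genome simulation
#'
#' Generates G4 families and genomes with known truth so the whole pipeline
#' can be validated without external data. The mutation structure mirrors the
#' biological prior the clustering relies on: guanine tracts are conserved
#' while loops accumulate substitutions and short indels.
#'
#' @name g4sim
NULL

#' Simulation configuration
#'
#' @param n_families Number of planted families.
#' @param members_per_family Sequences per family.
#' @param templates Optional character vector of template G4s (one per
#'   family); when `NULL`, templates are drawn by [random_g4_template()].
#' @param sub_rate Per-loop-base substitution probability.
#' @param indel_rate Per-loop probability of a single length-1 indel (loop
#'   lengths are kept within the detection bounds).
#' @param tract_mutation_rate Per-tract probability of eroding one guanine
#'   (default 0: tracts conserved).
#' @param background_length Genome background length (nt).
#' @param gc_content Background GC fraction.
#' @param seed Integer seed.
#' @return An object of class `g4_sim_config`.
#' @export
sim_config <- function(n_families = 5L, members_per_family = 20L,
                       templates = NULL, sub_rate = 0.05, indel_rate = 0.02,
                       tract_mutation_rate = 0, background_length = 20000L,
                       gc_content = 0.4, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            tract_mutation_rate >= 0, tract_mutation_rate <= 1,
            gc_content > 0, gc_content < 1)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 templates = templates, sub_rate = sub_rate,
                 indel_rate = indel_rate,
                 tract_mutation_rate = tract_mutation_rate,
                 background_length = as.integer(background_length),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "g4_sim_config")
}

#' Random G4 template
#'
#' Draws a canonical G4 template: four tracts of 3-4 guanines separated by
#' random non-G loops of 1-5 nt. Templates within one call are kept mutually
#' separated by at least `min_dist` edits, so each planted family is a
#' genuinely distinct entity (two templates a couple of edits apart would be
#' one family under two labels, making any recovery truth ill-defined).
#'
#' @param n Number of templates.
#' @param seed Integer seed.
#' @param min_dist Minimum pairwise Levenshtein distance between templates.
#' @return A character vector of valid G4 sequences.
#' @export
random_g4_template <- function(n = 1L, seed = 1L, min_dist = 6L) {
  set.seed(seed)
  one <- function() {
    tracts <- vapply(1:4, function(i) {
      strrep("G", sample(3:4, 1L))
    }, character(1L))
    loops <- vapply(1:3, function(i) {
      paste(sample(c("A", "C", "T"), sample(1:5, 1L), replace = TRUE),
            collapse = "")
    }, character(1L))
    paste0(tracts[1L], loops[1L], tracts[2L], loops[2L], tracts[3L],
           loops[3L], tracts[4L])
  }
  out <- character(0L)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) stop("cannot draw ", n, " mutually distinct templates")
    cand <- one()
    if (length(out) == 0L || min(utils::adist(cand, out)) >= min_dist) {
      out <- c(out, cand)
    }
  }
  out
}

# split a template into tract/loop segments (list of list(type, seq))
segment_template <- function(template, params = detection_params()) {
  tr <- find_g_tracts(template, params)
  if (nrow(tr) < 4L) stop("template is not a valid G4 (needs >= 4 tracts)")
  segs <- list()
  pos <- 0L
  for (i in seq_len(nrow(tr))) {
    if (tr$start[i] > pos) {
      segs[[length(segs) + 1L]] <-
        list(type = "loop", seq = substr(template, pos + 1L, tr$start[i]))
    }
    segs[[length(segs) + 1L]] <-
      list(type = "tract",
           seq = substr(template, tr$start[i] + 1L, tr$start[i] + tr$length[i]))
    pos <- tr$start[i] + tr$length[i]
  }
  if (pos < nchar(template)) {
    segs[[length(segs) + 1L]] <-
      list(type = "loop", seq = substr(template, pos + 1L, nchar(template)))
  }
  segs
}

#' Simulate one mutated G4 family
#'
#' Produces `n` mutated copies of a template. Substitutions hit loop bases
#' only (replacement drawn from A/C/T so tract structure is preserved) and
#' indels add or remove a single loop base while keeping each loop within the
#' detection loop bounds; tract erosion is opt-in via
#' `tract_mutation_rate > 0`.
#'
#' @param template A valid G4 sequence.
#' @param n Number of members.
#' @param config A [sim_config()] (rates are read from it).
#' @param seed Integer seed.
#' @param family_id Label used in `seq_id`s and the truth table.
#' @return A tibble `seq_id`, `seq`, `family`.
#' @export
simulate_g4_family <- function(template, n, config = sim_config(), seed = 1L,
                               family_id = "fam1") {
  set.seed(seed)
  segs <- segment_template(template)
  mutate_one <- function() {
    out <- vapply(segs, function(sg) {
      if (sg$type == "tract") {
        s <- sg$seq
        if (config$tract_mutation_rate > 0 &&
            stats::runif(1L) < config$tract_mutation_rate && nchar(s) > 2L) {
          pos <- sample(nchar(s), 1L)
          substr(s, pos, pos) <- sample(c("A", "C", "T"), 1L)
        }
        return(s)
      }
      chars <- strsplit(sg$seq, "", fixed = TRUE)[[1L]]
      hit <- stats::runif(length(chars)) < config$sub_rate
      chars[hit] <- sample(c("A", "C", "T"), sum(hit), replace = TRUE)
      if (stats::runif(1L) < config$indel_rate) {
        if (length(chars) > 1L && (length(chars) >= 7L || stats::runif(1L) < 0.5)) {
          chars <- chars[-sample(length(chars), 1L)]
        } else if (length(chars) < 7L) {
          at <- sample(length(chars) + 1L, 1L)
          chars <- append(chars, sample(c("A", "C", "T"), 1L), after = at - 1L)
        }
      }
      paste(chars, collapse = "")
    }, character(1L))
    paste(out, collapse = "")
  }
  tibble::tibble(
    seq_id = sprintf("%s_m%03d", family_id, seq_len(n)),
    seq = vapply(seq_len(n), function(i) mutate_one(), character(1L)),
    family = family_id
  )
}

#' Simulate a genome with planted G4 families
#'
#' Plants every member of every simulated family at a non-overlapping random
#' position on a random strand in an i.i.d. background of the configured GC
#' content, and returns the genome together with its interval and label
#' truth.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (tibble `seq_id`, `seq`), `members` (tibble
#'   `seq_id`, `seq`, `family`: the planted sequences), and `truth` (BED-like
#'   tibble `contig`, `start`, `end`, `seq_id`, `family`, `strand`).
#' @export
simulate_g4_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  templates <- config$templates
  if (is.null(templates)) {
    templates <- random_g4_template(config$n_families, seed = config$seed)
  }
  stopifnot(length(templates) == config$n_families)
  members <- dplyr::bind_rows(lapply(seq_len(config$n_families), function(i) {
    simulate_g4_family(templates[i], config$members_per_family, config,
                       seed = config$seed + i,
                       family_id = sprintf("fam%02d", i))
  }))
  # background without accidental G tracts is not enforced; real backgrounds
  # contain decoys and the detector must cope
  glen <- config$background_length
  total_insert <- sum(nchar(members$seq))
  if (glen < 2L * total_insert) stop("genome too short to host all plants")
  probs <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
             G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  genome <- sample(names(probs), glen, replace = TRUE, prob = probs)
  # choose non-overlapping slots (with 10 nt spacing)
  n <- nrow(members)
  lens <- nchar(members$seq)
  slots <- integer(n)
  occupied <- matrix(numeric(0), ncol = 2L)
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > 10000L) stop("genome too short to host all plants")
      s <- sample(glen - lens[i], 1L)
      e <- s + lens[i]
      clash <- nrow(occupied) > 0L &&
        any(pmax(occupied[, 1L], s - 10L) <= pmin(occupied[, 2L], e + 10L))
      if (!clash) {
        occupied <- rbind(occupied, c(s - 10L, e + 10L))
        slots[i] <- s
        break
      }
    }
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)
  for (i in seq_len(n)) {
    planted <- if (strands[i] == "+") members$seq[i] else revcomp(members$seq[i])
    genome[seq.int(slots[i], slots[i] + lens[i] - 1L)] <-
      strsplit(planted, "", fixed = TRUE)[[1L]]
    # W flanks (non-G on either strand) so a chance background guanine never
    # extends a planted tract: the truth interval stays the planted structure
    flanks <- seq.int(max(slots[i] - 1L, 1L), min(slots[i] + lens[i], glen))
    flanks <- setdiff(flanks, seq.int(slots[i], slots[i] + lens[i] - 1L))
    genome[flanks] <- sample(c("A", "T"), length(flanks), replace = TRUE)
  }
  truth <- tibble::tibble(
    contig = "sim1",
    start = slots - 1L,                    # 0-based half-open
    end = slots - 1L + lens,
    seq_id = members$seq_id, family = members$family, strand = strands
  )
  list(genome = tibble::tibble(seq_id = "sim1",
                               seq = paste(genome, collapse = "")),
       members = members,
       truth = dplyr::arrange(truth, .data$start))
}

#' Recovery metrics against planted truth
#'
#' @param predicted A data frame with `seq_id` and a predicted label column
#'   (`cluster` or `family`).
#' @param truth A data frame with `seq_id` and `family` (the planted labels).
#' @return A list: `ari` (adjusted Rand index over the shared sequences),
#'   `n_shared`, and `per_family` precision/recall (each predicted label
#'   matched to its plurality truth family).
#' @export
evaluate_recovery <- function(predicted, truth) {
  label_col <- intersect(c("family", "cluster"), names(predicted))[1L]
  if (is.na(label_col)) stop("`predicted` needs a `family` or `cluster` column")
  shared <- intersect(predicted$seq_id, truth$seq_id)
  if (length(shared) == 0L) stop("no shared sequence ids between predicted and truth")
  p <- predicted[[label_col]][match(shared, predicted$seq_id)]
  t <- truth$family[match(shared, truth$seq_id)]
  ari <- mclust::adjustedRandIndex(p, t)
  per_family <- purrr::map_dfr(split(seq_along(p), p), function(idx) {
    tt <- t[idx]
    best <- names(sort(table(tt), decreasing = TRUE))[1L]
    tibble::tibble(predicted = p[idx[1L]], truth = best,
                   precision = mean(tt == best),
                   recall = sum(tt == best) / sum(t == best))
  })
  list(ari = ari, n_shared = length(shared), per_family = per_family)
}
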