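# Independent oracles used across the suite. Everything here is written
# against the definitions, not against the package's implementation paths.

# full-matrix dynamic-programming edit distance
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1L] <- 0:length(x)
  d[1L, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

# naive regex scan for maximal G runs of length >= 3 (0-based starts)
regex_tract_starts <- function(seq, min_len = 3L) {
  m <- gregexpr(sprintf("G{%d,}", min_len), seq)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

# exhaustive one-sided rank-sum p-value by enumerating all group assignments
enum_wilcoxon_greater <- function(x, y) {
  n <- length(x) + length(y)
  pooled <- c(x, y)
  combos <- utils::combn(n, length(x), simplify = FALSE)
  w_obs <- sum(rank(pooled)[seq_along(x)])
  ws <- vapply(combos, function(ix) sum(rank(pooled)[ix]), numeric(1))
  mean(ws >= w_obs)
}

# brute-force sum/max over all plan7 state paths of P(seq, path | hmm).
# Paths are enumerated recursively from (node 0, Begin-as-M) to the End
# transition out of node m.
enum_phmm <- function(hmm, seq, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  m <- hmm$m
  tr <- hmm$trans
  best <- if (mode == "sum") 0 else -Inf
  acc <- function(p) {
    p <- unname(p)
    if (mode == "sum") best <<- best + p else best <<- max(best, p)
  }
  # state: "M","I","D"; k: node; i: symbols emitted so far; p: path prob
  step <- function(state, k, i, p) {
    if (p == 0) return()
    ki <- k + 1L
    if (state == "M" || state == "D") {
      pm <- if (state == "M") tr$mm[ki] else tr$dm[ki]
      pi_ <- if (state == "M") tr$mi[ki] else 0
      pd <- if (state == "M") tr$md[ki] else tr$dd[ki]
      if (k == m) {
        if (i == length(x)) acc(p * pm)
      } else {
        if (i < length(x)) {
          step("M", k + 1L, i + 1L, p * pm * hmm$match_emis[k + 1L, x[i + 1L]])
        }
        step("D", k + 1L, i, p * pd)
      }
      if (pi_ > 0 && i < length(x)) {
        step("I", k, i + 1L, p * pi_ * hmm$insert_emis[ki, x[i + 1L]])
      }
    } else { # insert
      if (k == m) {
        if (i == length(x)) acc(p * tr$im[ki])
      } else if (i < length(x)) {
        step("M", k + 1L, i + 1L,
             p * tr$im[ki] * hmm$match_emis[k + 1L, x[i + 1L]])
      }
      if (i < length(x)) {
        step("I", k, i + 1L, p * tr$ii[ki] * hmm$insert_emis[ki, x[i + 1L]])
      }
    }
  }
  step("M", 0L, 0L, 1)
  best
}

# random ungapped/gapped alignment fixture
random_alignment <- function(n_rows, n_cols, gap_prob = 0.15, seed = 1) {
  set.seed(seed)
  rows <- replicate(n_rows, {
    chars <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
    gaps <- runif(n_cols) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  })
  # ensure no all-gap row
  rows[rows == strrep("-", n_cols)] <- strrep("G", n_cols)
  g4_alignment(tibble::tibble(seq_id = paste0("s", seq_len(n_rows)),
                              aligned = rows))
}

random_dna <- function(n, len, seed = 1, probs = c(0.3, 0.2, 0.2, 0.3)) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

# two/three well-separated planted blobs as a distance matrix
planted_blob_dist <- function(sizes, sep = 10, noise = 0.5, seed = 1) {
  set.seed(seed)
  centers <- seq_along(sizes) * sep
  pts <- unlist(mapply(function(c, n) c + rnorm(n, sd = noise), centers, sizes,
                       SIMPLIFY = FALSE))
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("p", seq_along(pts)), paste0("p", seq_along(pts)))
  list(d = d, labels = rep(seq_along(sizes), sizes))
}

# idealized planted partition: constant within/between distances plus a
# deterministic tie-breaking jitter
block_dist <- function(sizes, within = 1, between = 10, jitter = 0.01,
                       seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  d[outer(labels, labels, "==")] <- within
  jit <- matrix(stats::runif(n * n, 0, jitter), n, n)
  d <- d + (jit + t(jit)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
  list(d = d, labels = labels)
}

# brute-force exhaustive multiple alignment score: enumerate all gap
# placements up to max_cols columns and return the best sum-of-pairs score
exhaustive_msa_score <- function(seqs, max_extra = 2L) {
  lens <- nchar(seqs)
  best <- -Inf
  for (L in max(lens):(max(lens) + max_extra)) {
    placements <- lapply(seqs, function(s) {
      n <- nchar(s)
      utils::combn(L, n, simplify = FALSE)
    })
    grid <- expand.grid(lapply(placements, seq_along))
    for (g in seq_len(nrow(grid))) {
      rows <- vapply(seq_along(seqs), function(i) {
        pos <- placements[[i]][[grid[g, i]]]
        out <- rep("-", L)
        out[pos] <- strsplit(seqs[i], "")[[1]]
        paste(out, collapse = "")
      }, character(1))
      if (any(vapply(seq_len(L), function(j) {
        all(substr(rows, j, j) == "-")
      }, logical(1)))) next
      aln <- g4_alignment(tibble::tibble(seq_id = as.character(seq_along(rows)),
                                         aligned = rows))
      best <- max(best, quadfam:::sp_score(aln))
    }
  }
  best
}
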