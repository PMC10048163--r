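#' Plan7 profile hidden Markov models for G4 alignments
#'
#' A profile HMM in the plan7 architecture: one node per match column with
#' match (M), insert (I) and delete (D) states and the seven transition types
#' M-M, M-I, M-D, I-I, I-M, D-M, D-D. Node 0 is the begin state (its "match"
#' transitions leave Begin); transitions out of node m lead to End. Training
#' is by counting state paths through an alignment with Laplace pseudocounts.
#'
#' @name g4_phmm
NULL

logsumexp <- function(x) {
  x <- x[!is.na(x) & x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Uniform or empirical background null model
#'
#' @param freqs Background base probabilities for A, C, G, T; must sum to 1.
#' @return A named numeric 4-vector of class `g4_null`.
#' @export
null_model <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(length(freqs) == 4L, abs(sum(freqs) - 1) < 1e-9, all(freqs > 0))
  names(freqs) <- BASES
  structure(freqs, class = "g4_null")
}

#' Train a plan7 profile HMM from an alignment
#'
#' Columns whose gap fraction is at most `match_rule` become match states;
#' the rest are modelled by insert states. Observed emission and transition
#' counts receive a Laplace pseudocount before normalization, keeping every
#' transition finite for tiny clusters. Deterministic.
#'
#' @param aln A [g4_alignment()] with at least one match-eligible column.
#' @param pseudocount Laplace pseudocount added to every count.
#' @param match_rule Maximum gap fraction for a column to be a match state.
#' @return An object of class `g4_phmm` with elements `m` (model length),
#'   `match_emis` (m x 4), `insert_emis` ((m+1) x 4) and `trans` (a list of
#'   per-node transition probability vectors `mm`, `mi`, `md`, `im`, `ii`,
#'   `dm`, `dd`).
#' @examples
#' build_phmm(align_sequences(c(a = "GGGAGGG", b = "GGGTGGG")))
#' @export
build_phmm <- function(aln, pseudocount = 1, match_rule = 0.5) {
  stopifnot(inherits(aln, "g4_alignment"), nrow(aln$rows) >= 1L)
  mat <- aln_matrix(aln)
  gap_frac <- colMeans(mat == "-")
  is_match <- gap_frac <= match_rule
  m <- sum(is_match)
  if (m == 0L) stop("no match-eligible columns in alignment")
  node_of_col <- cumsum(is_match)      # node index reached after this column

  me <- matrix(pseudocount, m, 4L, dimnames = list(NULL, BASES))
  ie <- matrix(pseudocount, m + 1L, 4L, dimnames = list(NULL, BASES))
  # transition counts, node index 0..m stored at position k+1
  tc <- list(mm = rep(pseudocount, m + 1L), mi = rep(pseudocount, m + 1L),
             md = rep(pseudocount, m + 1L), im = rep(pseudocount, m + 1L),
             ii = rep(pseudocount, m + 1L), dm = rep(pseudocount, m + 1L),
             dd = rep(pseudocount, m + 1L))
  # structurally impossible transitions get no pseudocount and probability 0:
  tc$md[m + 1L] <- 0   # M_m -> D_{m+1}
  tc$dd[m + 1L] <- 0   # D_m -> D_{m+1}
  tc$dm[1L] <- 0; tc$dd[1L] <- 0  # no delete state at node 0

  for (r in seq_len(nrow(mat))) {
    state <- "M"; node <- 0L
    for (j in seq_len(ncol(mat))) {
      ch <- mat[r, j]
      if (is_match[j]) {
        to <- if (ch == "-") "D" else "M"
        k <- node + 1L
        slot <- paste0(tolower(state), tolower(to))
        tc[[slot]][node + 1L] <- tc[[slot]][node + 1L] + 1
        if (to == "M") me[k, ch] <- me[k, ch] + 1
        state <- to; node <- k
      } else if (ch != "-") {
        if (state == "D") {
          # plan7 has no D->I; route through the match layer is disallowed,
          # so count the insert against the node's M->I (delete-adjacent
          # inserts are rare in practice and the model stays proper)
          slot <- "mi"
        } else {
          slot <- paste0(tolower(state), "i")
        }
        tc[[slot]][node + 1L] <- tc[[slot]][node + 1L] + 1
        ie[node + 1L, ch] <- ie[node + 1L, ch] + 1
        state <- "I"
      }
    }
    slot <- paste0(tolower(state), "m")   # transition to End
    tc[[slot]][node + 1L] <- tc[[slot]][node + 1L] + 1
  }

  # unobserved transition groups (possible with pseudocount = 0) default to
  # the deterministic main-path transition so the model stays proper
  norm3 <- function(a, b, c) {
    s <- a + b + c
    if (s == 0) return(list(1, 0, 0))
    list(a / s, b / s, c / s)
  }
  trans <- list(mm = numeric(m + 1L), mi = numeric(m + 1L),
                md = numeric(m + 1L), im = numeric(m + 1L),
                ii = numeric(m + 1L), dm = numeric(m + 1L),
                dd = numeric(m + 1L))
  for (k in seq_len(m + 1L)) {
    nm <- norm3(tc$mm[k], tc$mi[k], tc$md[k])
    trans$mm[k] <- nm[[1]]; trans$mi[k] <- nm[[2]]; trans$md[k] <- nm[[3]]
    si <- tc$im[k] + tc$ii[k]
    if (si > 0) {
      trans$im[k] <- tc$im[k] / si; trans$ii[k] <- tc$ii[k] / si
    } else {
      trans$im[k] <- 1
    }
    sd <- tc$dm[k] + tc$dd[k]
    if (sd > 0) {
      trans$dm[k] <- tc$dm[k] / sd; trans$dd[k] <- tc$dd[k] / sd
    }
  }
  structure(
    list(m = m,
         match_emis = me / rowSums(me),
         insert_emis = ie / rowSums(ie),
         trans = trans,
         metadata = list(n_seqs = nrow(mat), pseudocount = pseudocount,
                         match_rule = match_rule)),
    class = "g4_phmm"
  )
}

#' @export
print.g4_phmm <- function(x, ...) {
  cat(sprintf("Plan7 profile HMM: %d match states (trained on %d sequences)\n",
              x$m, x$metadata$n_seqs))
  cat("Match consensus:",
      paste(BASES[apply(x$match_emis, 1L, which.max)], collapse = ""), "\n")
  invisible(x)
}

seq_to_idx <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(v, BASES)
  if (anyNA(idx)) stop("sequence must be over {A,C,G,T}: ", seq, call. = FALSE)
  idx
}

# forward/viterbi share one log-space DP; mode = "sum" or "max"
phmm_dp <- function(hmm, seq, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  x <- seq_to_idx(seq)
  n <- length(x)
  if (n == 0L) stop("empty sequence")
  m <- hmm$m
  lt <- lapply(hmm$trans, log)
  lme <- log(hmm$match_emis)
  lie <- log(hmm$insert_emis)
  safe_max <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) -Inf else max(x)
  }
  comb <- if (mode == "sum") logsumexp else safe_max
  # layers indexed [node 0..m][position 0..n]
  M <- matrix(-Inf, m + 1L, n + 1L)
  I <- matrix(-Inf, m + 1L, n + 1L)
  D <- matrix(-Inf, m + 1L, n + 1L)
  M[1L, 1L] <- 0   # begin state, nothing emitted
  for (i in 0:n) {
    for (k in 0:m) {
      ki <- k + 1L
      if (i > 0L) {
        if (k > 0L) {
          M[ki, i + 1L] <- lme[k, x[i]] +
            comb(c(M[ki - 1L, i] + lt$mm[ki - 1L],
                   I[ki - 1L, i] + lt$im[ki - 1L],
                   D[ki - 1L, i] + lt$dm[ki - 1L]))
        }
        I[ki, i + 1L] <- lie[ki, x[i]] +
          comb(c(M[ki, i] + lt$mi[ki],
                 I[ki, i] + lt$ii[ki]))
      }
      if (k > 0L) {
        D[ki, i + 1L] <- comb(c(M[ki - 1L, i + 1L] + lt$md[ki - 1L],
                                D[ki - 1L, i + 1L] + lt$dd[ki - 1L]))
      }
    }
  }
  final <- c(M = M[m + 1L, n + 1L] + lt$mm[m + 1L],
             I = I[m + 1L, n + 1L] + lt$im[m + 1L],
             D = D[m + 1L, n + 1L] + lt$dm[m + 1L])
  list(M = M, I = I, D = D, final = final, loglik = comb(final), x = x)
}

null_loglik <- function(seq, null = null_model()) {
  sum(log(null[seq_to_idx(seq)]))
}

#' Forward-algorithm log odds
#'
#' Sums probability over all state paths of the model and reports the
#' natural-log odds against the background null.
#'
#' @param hmm A [build_phmm()] model.
#' @param seq A sequence over A/C/G/T.
#' @param null A [null_model()].
#' @return A one-row tibble: `forward_loglik` = log P(seq | hmm) and
#'   `log_odds` = forward_loglik - log P(seq | null), both in nats.
#' @examples
#' hmm <- build_phmm(align_sequences(c(a = "GGGAGGG", b = "GGGAGGG")))
#' forward_log_odds(hmm, "GGGAGGG")
#' @export
forward_log_odds <- function(hmm, seq, null = null_model()) {
  fl <- phmm_dp(hmm, seq, "sum")$loglik
  tibble::tibble(forward_loglik = fl,
                 log_odds = fl - null_loglik(seq, null))
}

#' Viterbi path and score
#'
#' Best single state path; traceback ties broken M > D > I.
#'
#' @inheritParams forward_log_odds
#' @return A list with `path` (character vector like `"M1"`, `"I0"`, `"D2"`),
#'   `viterbi_loglik` and `log_odds`.
#' @export
viterbi <- function(hmm, seq, null = null_model()) {
  dp <- phmm_dp(hmm, seq, "max")
  m <- hmm$m; n <- length(dp$x)
  lt <- lapply(hmm$trans, log)
  lme <- log(hmm$match_emis); lie <- log(hmm$insert_emis)
  pick <- function(scores) c("M", "D", "I")[which.max(scores[c("M", "D", "I")])]
  state <- pick(dp$final)
  k <- m; i <- n
  path <- character(0L)
  while (!(state == "M" && k == 0L)) {
    path <- c(paste0(state, k), path)
    if (state == "M") {
      prev <- c(M = dp$M[k, i] + lt$mm[k], D = dp$D[k, i] + lt$dm[k],
                I = dp$I[k, i] + lt$im[k])
      state <- pick(prev); k <- k - 1L; i <- i - 1L
    } else if (state == "I") {
      prev <- c(M = dp$M[k + 1L, i] + lt$mi[k + 1L], D = -Inf,
                I = dp$I[k + 1L, i] + lt$ii[k + 1L])
      state <- pick(prev); i <- i - 1L
    } else {
      prev <- c(M = dp$M[k, i + 1L] + lt$md[k], D = dp$D[k, i + 1L] + lt$dd[k],
                I = -Inf)
      state <- pick(prev); k <- k - 1L
    }
  }
  list(path = path, viterbi_loglik = dp$loglik,
       log_odds = dp$loglik - null_loglik(seq, null))
}

#' Sample sequences from a profile HMM
#'
#' Independent generative walks from Begin to End; reproducible given `seed`.
#'
#' @param hmm A [build_phmm()] model.
#' @param n Number of sequences (>= 1).
#' @param seed Integer seed (required: every stochastic operation in the
#'   package takes an explicit seed).
#' @return A character vector of length `n`.
#' @export
sample_phmm <- function(hmm, n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  m <- hmm$m
  tr <- hmm$trans
  one <- function() {
    out <- character(0L)
    state <- "M"; k <- 0L
    repeat {
      ki <- k + 1L
      if (state == "M" || state == "D") {
        p <- if (state == "M") c(tr$mm[ki], tr$mi[ki], tr$md[ki])
             else c(tr$dm[ki], 0, tr$dd[ki])
        nxt <- sample(c("M", "I", "D"), 1L, prob = p)
      } else {
        nxt <- sample(c("M", "I"), 1L, prob = c(tr$im[ki], tr$ii[ki]))
      }
      if (nxt == "I") {
        out <- c(out, sample(BASES, 1L, prob = hmm$insert_emis[ki, ]))
        state <- "I"
      } else {
        k <- k + 1L
        if (k > m) break
        if (nxt == "M") out <- c(out, sample(BASES, 1L, prob = hmm$match_emis[k, ]))
        state <- nxt
      }
    }
    paste(out, collapse = "")
  }
  vapply(seq_len(n), function(i) one(), character(1L))
}

PHMM_SCHEMA_VERSION <- "1.0"

phmm_to_list <- function(hmm) {
  list(version = PHMM_SCHEMA_VERSION,
       m = hmm$m,
       match_emis = unname(apply(hmm$match_emis, 1L, as.numeric, simplify = FALSE)),
       insert_emis = unname(apply(hmm$insert_emis, 1L, as.numeric, simplify = FALSE)),
       trans = lapply(hmm$trans, as.numeric),
       metadata = hmm$metadata)
}

phmm_from_list <- function(x) {
  need <- c("version", "m", "match_emis", "insert_emis", "trans")
  if (!all(need %in% names(x))) {
    stop("profile HMM schema mismatch: missing ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  if (!identical(as.character(x$version), PHMM_SCHEMA_VERSION)) {
    stop("unsupported profile HMM schema version: ", x$version, call. = FALSE)
  }
  as_emis <- function(v) {
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
    if (!is.matrix(v)) v <- matrix(as.numeric(v), nrow = 1L)
    colnames(v) <- BASES
    v
  }
  me <- as_emis(x$match_emis)
  ie <- as_emis(x$insert_emis)
  hmm <- structure(
    list(m = as.integer(x$m), match_emis = me, insert_emis = ie,
         trans = lapply(x$trans, as.numeric),
         metadata = x$metadata),
    class = "g4_phmm"
  )
  validate_phmm(hmm)
  hmm
}

validate_phmm <- function(hmm, tol = 1e-9) {
  stopifnot(hmm$m >= 1L,
            nrow(hmm$match_emis) == hmm$m,
            nrow(hmm$insert_emis) == hmm$m + 1L)
  if (any(abs(rowSums(hmm$match_emis) - 1) > tol) ||
      any(abs(rowSums(hmm$insert_emis) - 1) > tol)) {
    stop("profile HMM emission rows must sum to 1", call. = FALSE)
  }
  tr <- hmm$trans
  for (k in seq_len(hmm$m + 1L)) {
    if (abs(tr$mm[k] + tr$mi[k] + tr$md[k] - 1) > tol ||
        abs(tr$im[k] + tr$ii[k] - 1) > tol) {
      stop("profile HMM transition groups must sum to 1", call. = FALSE)
    }
    s <- tr$dm[k] + tr$dd[k]
    if (s > 0 && abs(s - 1) > tol) {
      stop("profile HMM transition groups must sum to 1", call. = FALSE)
    }
  }
  invisible(hmm)
}

#' Serialize / deserialize profile HMMs as JSON
#'
#' Versioned, lossless round trip; [read_phmm()] errors on schema mismatch.
#'
#' @param hmm A [build_phmm()] model.
#' @param path File path.
#' @return `write_phmm()` returns `path` invisibly; `read_phmm()` a `g4_phmm`.
#' @export
write_phmm <- function(hmm, path) {
  jsonlite::write_json(phmm_to_list(hmm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phmm
#' @export
read_phmm <- function(path) {
  phmm_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
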