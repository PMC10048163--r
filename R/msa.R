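#' Multiple alignment container
#'
#' @param rows A data frame with columns `seq_id` and `aligned` (equal-length
#'   gapped strings, gap character `-`).
#' @return An object of class `g4_alignment`.
#' @export
g4_alignment <- function(rows) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("seq_id", "aligned") %in% names(rows)), nrow(rows) >= 1L)
  w <- nchar(rows$aligned)
  if (length(unique(w)) != 1L) stop("alignment rows differ in length")
  structure(list(rows = rows, n_cols = w[1L]), class = "g4_alignment")
}

#' @export
print.g4_alignment <- function(x, ...) {
  cat(sprintf("G4 alignment: %d sequences x %d columns (gap score %.3f)\n",
              nrow(x$rows), x$n_cols, gap_score(x)))
  n <- min(nrow(x$rows), 10L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-12s %s\n", x$rows$seq_id[i], x$rows$aligned[i]))
  }
  if (nrow(x$rows) > n) cat("  ...\n")
  invisible(x)
}

# alignment as a character matrix (rows x cols)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows$aligned, "", fixed = TRUE))
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment tailored to short G-rich sequences: a
#' UPGMA guide tree is built from pairwise edit distances, then profiles are
#' merged bottom-up with profile-profile Needleman-Wunsch under affine gap
#' costs. Fully deterministic.
#'
#' @param data A data frame with `seq_id` and `seq` columns (or a character
#'   vector). A single sequence aligns trivially to itself.
#' @param match,mismatch Per-pair column scores.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @return A [g4_alignment()].
#' @examples
#' align_sequences(c(a = "GGGAGGG", b = "GGGTAGGG"))
#' @export
align_sequences <- function(data, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -0.5) {
  data <- as_seq_tbl(data)
  seqs <- toupper(data$seq)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in alignment input")
  n <- length(seqs)
  if (n == 1L) {
    return(g4_alignment(tibble::tibble(seq_id = data$seq_id, aligned = seqs)))
  }
  profiles <- lapply(seq_len(n), function(i) {
    list(ids = data$seq_id[i], rows = seqs[i])
  })
  if (n == 2L) {
    merged <- merge_profiles(profiles[[1L]], profiles[[2L]],
                             match, mismatch, gap_open, gap_extend)
  } else {
    d <- utils::adist(seqs)
    dimnames(d) <- list(data$seq_id, data$seq_id)
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    merged <- profiles
    for (s in seq_len(nrow(tree$merge))) {
      a <- tree$merge[s, 1L]; b <- tree$merge[s, 2L]
      pa <- if (a < 0) profiles[[-a]] else merged[[n + a]]
      pb <- if (b < 0) profiles[[-b]] else merged[[n + b]]
      merged[[n + s]] <- merge_profiles(pa, pb, match, mismatch,
                                        gap_open, gap_extend)
    }
    merged <- merged[[n + nrow(tree$merge)]]
  }
  rows <- tibble::tibble(seq_id = merged$ids, aligned = merged$rows)
  g4_alignment(rows[match(data$seq_id, rows$seq_id), ])
}

BASES <- c("A", "C", "G", "T")

# column frequency profile over A,C,G,T plus gap fraction
profile_freqs <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ncol_ <- ncol(m)
  f <- matrix(0, nrow = 5L, ncol = ncol_,
              dimnames = list(c(BASES, "-"), NULL))
  for (b in rownames(f)) f[b, ] <- colMeans(m == b)
  f
}

# profile-profile global alignment with affine gaps; 3-state DP.
# Tie-break on traceback: M > gap-in-B (advance A) > gap-in-A.
merge_profiles <- function(pa, pb, match, mismatch, gap_open, gap_extend) {
  fa <- profile_freqs(pa$rows); fb <- profile_freqs(pb$rows)
  la <- ncol(fa); lb <- ncol(fb)
  # substitution score between columns: expectation over non-gap symbols
  sub <- matrix(0, la, lb)
  qa <- fa[BASES, , drop = FALSE]; qb <- fb[BASES, , drop = FALSE]
  smat <- matrix(mismatch, 4L, 4L); diag(smat) <- match
  sub <- t(qa) %*% smat %*% qb
  neg <- -Inf
  M <- X <- Y <- matrix(neg, la + 1L, lb + 1L)
  M[1L, 1L] <- 0
  # X: gap in pb (consume A column); Y: gap in pa (consume B column)
  for (i in seq_len(la)) {
    X[i + 1L, 1L] <- gap_open + gap_extend * (i - 1L)
  }
  for (j in seq_len(lb)) {
    Y[1L, j + 1L] <- gap_open + gap_extend * (j - 1L)
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + sub[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open,
                               X[i, j + 1L] + gap_extend,
                               Y[i, j + 1L] + gap_open)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open,
                               X[i + 1L, j] + gap_open,
                               Y[i + 1L, j] + gap_extend)
    }
  }
  # traceback
  i <- la; j <- lb
  state <- which.max(c(M[i + 1L, j + 1L], X[i + 1L, j + 1L], Y[i + 1L, j + 1L]))
  ops <- character(0L)
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      ops <- c("M", ops)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      ops <- c("X", ops)
      prev <- c(M[i, j + 1L] + gap_open, X[i, j + 1L] + gap_extend,
                Y[i, j + 1L] + gap_open)
      i <- i - 1L
      state <- which.max(prev)
    } else {
      ops <- c("Y", ops)
      prev <- c(M[i + 1L, j] + gap_open, X[i + 1L, j] + gap_open,
                Y[i + 1L, j] + gap_extend)
      j <- j - 1L
      state <- which.max(prev)
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  expand <- function(rows, take) {
    chm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow(chm), length(ops))
    out[, take != 0L] <- chm
    apply(out, 1L, paste, collapse = "")
  }
  take_a <- cumsum(ops %in% c("M", "X")) * (ops %in% c("M", "X"))
  take_b <- cumsum(ops %in% c("M", "Y")) * (ops %in% c("M", "Y"))
  list(ids = c(pa$ids, pb$ids),
       rows = c(expand(pa$rows, take_a), expand(pb$rows, take_b)))
}

# sum-of-pairs score of an alignment under the align_sequences scoring
sp_score <- function(aln, match = 1, mismatch = -1,
                     gap_open = -2, gap_extend = -0.5) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- m[i, ]; b <- m[j, ]
      both <- a != "-" & b != "-"
      total <- total + sum(ifelse(a[both] == b[both], match, mismatch))
      # affine gaps on the pairwise projection (columns gapped in both dropped)
      keep <- !(a == "-" & b == "-")
      for (row in list(a[keep] == "-" & b[keep] != "-",
                       b[keep] == "-" & a[keep] != "-")) {
        r <- rle(row)
        runs <- r$lengths[r$values]
        if (length(runs)) {
          total <- total + sum(gap_open + gap_extend * (runs - 1L))
        }
      }
    }
  }
  total
}

#' Shift gaps to purify guanine-tract columns
#'
#' Among score-neutral rearrangements, single gap characters are swapped with
#' adjacent residues when doing so concentrates guanines into fewer, purer
#' columns. Greedy passes repeat until a fixed point, so the operation is
#' idempotent; degapped rows are never altered.
#'
#' @param aln A [g4_alignment()].
#' @return A [g4_alignment()] with identical degapped rows.
#' @export
adjust_gaps <- function(aln) {
  m <- aln_matrix(aln)
  score0 <- sp_score(aln)
  purity <- function(mm) sum(colSums(mm == "G")^2)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        if (m[i, j] != "-") next
        for (dj in c(-1L, 1L)) {
          jj <- j + dj
          if (jj < 1L || jj > ncol(m) || m[i, jj] == "-") next
          m2 <- m
          m2[i, j] <- m2[i, jj]; m2[i, jj] <- "-"
          cand <- g4_alignment(tibble::tibble(
            seq_id = aln$rows$seq_id,
            aligned = apply(m2, 1L, paste, collapse = "")))
          if (abs(sp_score(cand) - score0) < 1e-9 &&
              purity(m2) > purity(m)) {
            m <- m2
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  g4_alignment(tibble::tibble(seq_id = aln$rows$seq_id,
                              aligned = apply(m, 1L, paste, collapse = "")))
}

#' Alignment gap score
#'
#' Overall gap fraction of the alignment: total gap characters divided by
#' rows x columns. Bounded in \[0, 1\], 0 iff ungapped — the scale on which
#' the family-refinement thresholds (0.07 / 0.10 / 0.6) operate.
#'
#' @param aln A [g4_alignment()].
#' @return A number in \[0, 1\].
#' @export
gap_score <- function(aln) {
  stopifnot(inherits(aln, "g4_alignment"), nrow(aln$rows) >= 1L)
  m <- aln_matrix(aln)
  sum(m == "-") / length(m)
}

#' Drop undersized clusters
#'
#' @param data A data frame with a `cluster` column.
#' @param min_size Minimum members per cluster (default 4).
#' @return The rows of `data` whose cluster has at least `min_size` members.
#' @export
filter_clusters <- function(data, min_size = 4L) {
  dplyr::ungroup(dplyr::filter(dplyr::group_by(data, .data$cluster),
                               dplyr::n() >= min_size))
}

IUPAC_CODE <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
)

#' IUPAC consensus of an alignment
#'
#' Per column, the minimal IUPAC degeneracy code covering every base whose
#' frequency reaches `plurality` times the most frequent base; columns with a
#' gap majority emit `-`.
#'
#' @param aln A [g4_alignment()].
#' @param plurality Inclusion threshold relative to the modal base frequency.
#' @return A character scalar (one symbol per alignment column).
#' @examples
#' iupac_consensus(align_sequences(c(a = "GGGA", b = "GGGG")))
#' @export
iupac_consensus <- function(aln, plurality = 0.5) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (sum(col == "-") > n / 2) return("-")
    counts <- table(factor(col[col %in% BASES], levels = BASES))
    keep <- names(counts)[counts >= plurality * max(counts) & counts > 0]
    IUPAC_CODE[[paste(sort(keep), collapse = "")]]
  }, character(1L))
  paste(cons, collapse = "")
}
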