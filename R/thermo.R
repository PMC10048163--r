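#' Quadruplex folding energy model
#'
#' Parameters of the restricted intramolecular G-quadruplex energy model.
#' A placement of `L` stacked tetrad layers connected by three linkers of
#' total length `ltot` is scored
#' \deqn{E = \alpha (L - 1) + \mathrm{trunc}(\beta \ln(l_{tot} - 2))}
#' in kcal/mol, where the linker term is truncated toward zero at the stated
#' energy resolution. With three single-base linkers (`ltot = 3`) the linker
#' term vanishes and the energy is a pure stacking term.
#'
#' @param alpha Stack-step energy per added layer (kcal/mol); must be negative.
#' @param beta Linker-length penalty scale (kcal/mol); must be positive.
#' @param resolution Energy resolution (kcal/mol) at which the linker term is
#'   truncated toward zero.
#' @param rt Thermal energy RT (kcal/mol); default is 37 degrees C.
#' @param min_layers Minimum number of tetrad layers in a placement.
#' @param linker_min,linker_max Allowed per-linker length range (nt).
#' @return An object of class `g4_energy_model`.
#' @examples
#' energy_model()
#' @export
energy_model <- function(alpha = -18, beta = 12, resolution = 0.01,
                         rt = 0.61633, min_layers = 2L,
                         linker_min = 1L, linker_max = 7L) {
  stopifnot(alpha < 0, beta > 0, resolution > 0, rt > 0,
            min_layers >= 1, linker_min >= 1, linker_max >= linker_min)
  structure(
    list(alpha = alpha, beta = beta, resolution = resolution, rt = rt,
         min_layers = as.integer(min_layers),
         linker_min = as.integer(linker_min),
         linker_max = as.integer(linker_max)),
    class = "g4_energy_model"
  )
}

#' @export
print.g4_energy_model <- function(x, ...) {
  cat("Quadruplex energy model\n")
  cat(sprintf("  E = %.2f*(L-1) + trunc(%.2f*ln(ltot-2)) kcal/mol\n",
              x$alpha, x$beta))
  cat(sprintf("  RT = %.5f kcal/mol; layers >= %d; linkers %d..%d nt\n",
              x$rt, x$min_layers, x$linker_min, x$linker_max))
  invisible(x)
}

# Strip gaps, uppercase; IUPAC ambiguity codes are legal but never count as G.
clean_seq <- function(seq) {
  s <- toupper(gsub("-", "", seq, fixed = TRUE))
  bad <- gsub("[ACGTUNRYSWKMBDHV]", "", s)
  if (nchar(bad) > 0L) {
    stop("invalid sequence characters: ", substr(bad, 1L, 10L), call. = FALSE)
  }
  gsub("U", "T", s, fixed = TRUE)
}

# Runs of G of length >= min_len: tibble(start [0-based], length)
g_runs <- function(seq, min_len = 1L) {
  m <- gregexpr(sprintf("G{%d,}", min_len), seq)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(start = integer(), length = integer()))
  }
  tibble::tibble(start = as.integer(m) - 1L,
                 length = attr(m, "match.length"))
}

#' Enumerate quadruplex placements in a sequence
#'
#' Lists every way of placing four ordered, equal-length guanine sub-tracts
#' (the quadruplex layers) in `seq` such that the three linkers between them
#' fall within the model's allowed range. Ambiguity codes and `N` count as
#' loop bases, never as G; gap characters are stripped first.
#'
#' @param seq A single DNA sequence (character scalar).
#' @param model A [energy_model()].
#' @return A tibble with one row per placement: `layers`, the four 0-based
#'   sub-tract starts `s1..s4`, linker lengths `l1..l3`, `ltot`, and `energy`
#'   (kcal/mol). Sequences with fewer than four usable tracts yield zero rows.
#' @examples
#' enumerate_placements("GGGAGGGAGGGAGGG")
#' @export
enumerate_placements <- function(seq, model = energy_model()) {
  s <- clean_seq(seq)
  runs <- g_runs(s, model$min_layers)
  empty <- tibble::tibble(layers = integer(),
                          s1 = integer(), s2 = integer(),
                          s3 = integer(), s4 = integer(),
                          l1 = integer(), l2 = integer(), l3 = integer(),
                          ltot = integer(), energy = double())
  if (nrow(runs) == 0L) return(empty)
  max_l <- max(runs$length)
  out <- vector("list", 0L)
  for (L in seq.int(model$min_layers, max_l)) {
    ok <- runs[runs$length >= L, , drop = FALSE]
    if (nrow(ok) == 0L) next
    # all sub-tracts of length L inside the qualifying runs, ascending
    starts <- unlist(lapply(seq_len(nrow(ok)), function(i) {
      ok$start[i] + 0:(ok$length[i] - L)
    }))
    starts <- sort(unique(starts))
    if (length(starts) < 4L) next
    combos <- chain_subtracts(starts, L, model$linker_min, model$linker_max)
    if (length(combos) == 0L) next
    mat <- do.call(rbind, combos)
    l1 <- mat[, 2] - mat[, 1] - L
    l2 <- mat[, 3] - mat[, 2] - L
    l3 <- mat[, 4] - mat[, 3] - L
    ltot <- l1 + l2 + l3
    out[[length(out) + 1L]] <- tibble::tibble(
      layers = L,
      s1 = mat[, 1], s2 = mat[, 2], s3 = mat[, 3], s4 = mat[, 4],
      l1 = l1, l2 = l2, l3 = l3, ltot = ltot,
      energy = placement_energy(L, ltot, model)
    )
  }
  if (length(out) == 0L) return(empty)
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$energy, .data$s1, .data$s4 - .data$s1)
}

# choose 4 ascending sub-tract starts with linker constraints
chain_subtracts <- function(starts, L, lmin, lmax) {
  res <- list()
  n <- length(starts)
  # successors within linker range, precomputed
  succ <- lapply(seq_len(n), function(i) {
    gap <- starts - (starts[i] + L)
    which(gap >= lmin & gap <= lmax)
  })
  for (i1 in seq_len(n)) {
    for (i2 in succ[[i1]]) {
      for (i3 in succ[[i2]]) {
        for (i4 in succ[[i3]]) {
          res[[length(res) + 1L]] <-
            c(starts[i1], starts[i2], starts[i3], starts[i4])
        }
      }
    }
  }
  res
}

#' Energy of a quadruplex placement
#'
#' @param layers Number of stacked tetrad layers (L >= 2).
#' @param ltot Total linker length (>= 3).
#' @param model A [energy_model()].
#' @return Energy in kcal/mol. The linker term `beta*ln(ltot-2)` is truncated
#'   toward zero at the model resolution before being added, so that e.g.
#'   `12*ln(2) = 8.3178` contributes exactly 8.31.
#' @examples
#' placement_energy(3, 3) # -36
#' placement_energy(3, 4) # -27.69
#' @export
placement_energy <- function(layers, ltot, model = energy_model()) {
  stopifnot(all(layers >= 2), all(ltot >= 3))
  linker <- trunc(model$beta * log(ltot - 2) / model$resolution) *
    model$resolution
  model$alpha * (layers - 1) + linker
}

#' Minimum free energy quadruplex placement
#'
#' @inheritParams enumerate_placements
#' @return A one-row tibble (the minimal-energy placement, ties broken by
#'   leftmost start then most compact span), or a zero-row tibble with
#'   `energy = NA` semantics when no placement exists.
#' @examples
#' g4_mfe("GGGGTGGGTGGGGAGGG")$energy # -27.69
#' @export
g4_mfe <- function(seq, model = energy_model()) {
  pl <- enumerate_placements(seq, model)
  if (nrow(pl) == 0L) return(pl)
  pl <- dplyr::filter(pl, .data$energy == min(.data$energy))
  pl <- dplyr::arrange(pl, .data$s1, .data$s4 + .data$layers - .data$s1)
  pl[1L, ]
}

#' Restricted Boltzmann ensemble summary
#'
#' Treats the structure space of `seq` as the open chain (energy 0) plus every
#' quadruplex placement, Boltzmann-weighted at the model temperature, and
#' summarises the ensemble the way folding programs report it.
#'
#' @inheritParams enumerate_placements
#' @return A one-row tibble: `mfe` (kcal/mol; 0 with no placement),
#'   `ensemble_fe` = -RT ln Z, `mfe_frequency` (percent), `diversity`
#'   (expected pairwise distance between ensemble structures, where the
#'   distance between two structures is the symmetric difference of their
#'   quadruplex-involved position sets), and `n_placements`.
#' @examples
#' g4_ensemble("GGGAGGGAGGGAGGG")
#' @export
g4_ensemble <- function(seq, model = energy_model()) {
  s <- clean_seq(seq)
  pl <- enumerate_placements(s, model)
  if (nrow(pl) == 0L) {
    return(tibble::tibble(mfe = 0, ensemble_fe = 0, mfe_frequency = 100,
                          diversity = 0, n_placements = 0L))
  }
  e <- c(0, pl$energy)                      # state 1 = open chain
  w <- exp(-(e - min(e)) / model$rt)        # shifted for stability
  z <- sum(w)
  p <- w / z
  ensemble_fe <- -model$rt * (log(z) + (-min(e) / model$rt))
  e_mfe <- min(pl$energy)
  # frequency of the single MFE structure (tie-broken as in g4_mfe), matching
  # how folding programs report it when minima are degenerate
  ties <- which(pl$energy == e_mfe)
  ord <- order(pl$s1[ties], pl$s4[ties] + pl$layers[ties] - pl$s1[ties])
  mfe_frequency <- 100 * p[-1][ties[ord][1L]]
  # involved-position sets; open chain is the empty set
  sets <- c(list(integer()), lapply(seq_len(nrow(pl)), function(i) {
    placement_positions(pl[i, ])
  }))
  n <- length(sets)
  div <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (p[i] * p[j] == 0) next
      d <- length(setdiff(sets[[i]], sets[[j]])) +
        length(setdiff(sets[[j]], sets[[i]]))
      div <- div + 2 * p[i] * p[j] * d
    }
  }
  tibble::tibble(mfe = e_mfe, ensemble_fe = ensemble_fe,
                 mfe_frequency = mfe_frequency, diversity = div,
                 n_placements = nrow(pl))
}

# 0-based positions of the guanines involved in a placement (one tibble row)
placement_positions <- function(pl) {
  L <- pl$layers
  sort(unlist(lapply(c(pl$s1, pl$s2, pl$s3, pl$s4), function(s) s + 0:(L - 1L))))
}

#' Quadruplex dot-bracket string
#'
#' Renders a placement in the quadruplex dialect of dot-bracket notation:
#' `+` marks guanines engaged in tetrads, `.` everything else.
#'
#' @param placement A one-row placement tibble (from [enumerate_placements()]
#'   or [g4_mfe()]), or a zero-row tibble for "no structure".
#' @param seq_len Length of the sequence the string should cover.
#' @return A character scalar of length `seq_len`.
#' @examples
#' dot_bracket(g4_mfe("GGGAGGGAGGGAGGG"), 15)
#' @export
dot_bracket <- function(placement, seq_len) {
  out <- rep(".", seq_len)
  if (!is.null(placement) && nrow(placement) > 0L) {
    out[placement_positions(placement[1L, ]) + 1L] <- "+"
  }
  paste(out, collapse = "")
}

#' Thermodynamic annotation of G4 sequences
#'
#' Tidy front-end over [g4_mfe()] and [g4_ensemble()]: one row in, one row of
#' folding summaries out.
#'
#' @param data A data frame with columns `seq_id` and `seq` (gaps and IUPAC
#'   ambiguity codes tolerated), or a character vector of sequences.
#' @param model A [energy_model()].
#' @return A tibble with columns `seq_id`, `seq`, `mfe`, `ensemble_fe`,
#'   `mfe_frequency`, `diversity`, `n_placements`, `dot_bracket`.
#' @examples
#' g4_thermo("GGGAGGGAGGGAGGG")
#' @export
g4_thermo <- function(data, model = energy_model()) {
  data <- as_seq_tbl(data)
  purrr::pmap_dfr(data[, c("seq_id", "seq")], function(seq_id, seq) {
    s <- clean_seq(seq)
    ens <- g4_ensemble(s, model)
    mfe_pl <- g4_mfe(s, model)
    tibble::tibble(seq_id = seq_id, seq = s, ens,
                   dot_bracket = dot_bracket(mfe_pl, nchar(s)))
  })
}

# coerce character vectors / data frames to the canonical (seq_id, seq) tibble
as_seq_tbl <- function(data) {
  if (is.character(data)) {
    ids <- names(data)
    if (is.null(ids)) ids <- paste0("seq", seq_along(data))
    return(tibble::tibble(seq_id = ids, seq = unname(data)))
  }
  stopifnot(is.data.frame(data))
  if (!all(c("seq_id", "seq") %in% names(data))) {
    stop("`data` must have columns `seq_id` and `seq`", call. = FALSE)
  }
  tibble::as_tibble(data)
}
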