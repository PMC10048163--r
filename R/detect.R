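#' Detection parameters
#'
#' Canonical putative G4s follow the pattern GxN1-7 GxN1-7 GxN1-7 Gx with
#' x >= 3: at least four runs of guanine separated by loops of 1-7 nt.
#' Two-tetrad scanning (`min_tract_len = 2`) is available but off by default
#' because of its elevated false-positive rate.
#'
#' @param min_tract_len Minimum guanine-run length (>= 2; default 3).
#' @param loop_min,loop_max Allowed loop length range (nt).
#' @param min_tracts Minimum number of tracts chained into a region (>= 4).
#' @param strands Which strands to scan: `"both"`, `"plus"` or `"minus"`.
#' @return An object of class `g4_detection_params`.
#' @export
detection_params <- function(min_tract_len = 3L, loop_min = 1L, loop_max = 7L,
                             min_tracts = 4L,
                             strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  stopifnot(min_tract_len >= 2, loop_min >= 1, loop_min <= loop_max,
            min_tracts >= 4)
  structure(
    list(min_tract_len = as.integer(min_tract_len),
         loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
         min_tracts = as.integer(min_tracts), strands = strands),
    class = "g4_detection_params"
  )
}

#' Find maximal guanine tracts
#'
#' @param seq A single DNA sequence. `N` and IUPAC ambiguity codes never
#'   count as G.
#' @param params A [detection_params()].
#' @return A tibble of maximal G runs with 0-based `start` and `length`
#'   (`length >= min_tract_len`), in ascending order.
#' @examples
#' find_g_tracts("GGGAGGGAGGGAGGG")
#' @export
find_g_tracts <- function(seq, params = detection_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  g_runs(toupper(seq), params$min_tract_len)
}

#' Reverse complement
#'
#' @param seq DNA string(s); IUPAC codes supported.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

#' Detect putative G-quadruplex regions
#'
#' Scans sequences for maximal chains of at least `min_tracts` guanine tracts
#' whose consecutive gaps all lie within the loop bounds (tract-chaining, not
#' a greedy regex, so total vs non-overlapping placement counts are well
#' defined). With `strands = "both"` the reverse complement is also scanned;
#' minus-strand regions are reported with plus-strand half-open coordinates
#' while `seq` holds the G-rich scanned-strand sequence.
#'
#' @param data A data frame with columns `seq_id` (used as contig name) and
#'   `seq`, or a (optionally named) character vector.
#' @param params A [detection_params()].
#' @return A tibble with one row per region: `contig`, 0-based half-open
#'   `start`/`end` on the plus strand, `strand`, `n_tracts`, `seq`
#'   (scanned strand) and a `tracts` list-column of tibbles with tract
#'   `start` (0-based, relative to the region on the scanned strand) and
#'   `length`.
#' @examples
#' detect_g4(c(pu27 = "TGGGGAGGGTGGGGAGGGTGGGGAAGG"))
#' @export
detect_g4 <- function(data, params = detection_params()) {
  data <- as_seq_tbl(data)
  out <- purrr::pmap_dfr(data[, c("seq_id", "seq")], function(seq_id, seq) {
    seq <- toupper(seq)
    res <- list()
    if (params$strands %in% c("both", "plus")) {
      res[[1L]] <- scan_strand(seq_id, seq, "+", params)
    }
    if (params$strands %in% c("both", "minus")) {
      res[[length(res) + 1L]] <- scan_strand(seq_id, revcomp(seq), "-", params,
                                             contig_len = nchar(seq))
    }
    dplyr::bind_rows(res)
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), strand = character(),
                          n_tracts = integer(), seq = character(),
                          tracts = list()))
  }
  dplyr::arrange(out, .data$contig, .data$start, .data$strand)
}

# scan one strand; `seq` is the scanned-strand sequence. For the minus strand
# coordinates are mirrored back to the plus strand.
scan_strand <- function(contig, seq, strand, params, contig_len = nchar(seq)) {
  tr <- g_runs(seq, params$min_tract_len)
  n <- nrow(tr)
  if (n < params$min_tracts) return(NULL)
  gaps <- if (n > 1L) tr$start[-1L] - (tr$start[-n] + tr$length[-n]) else integer()
  breaks <- which(gaps < params$loop_min | gaps > params$loop_max)
  chain_id <- cumsum(c(1L, seq_len(n - 1L) %in% breaks))
  rows <- lapply(split(seq_len(n), chain_id), function(idx) {
    if (length(idx) < params$min_tracts) return(NULL)
    s0 <- tr$start[idx[1L]]
    e0 <- tr$start[idx[length(idx)]] + tr$length[idx[length(idx)]]
    region_seq <- substr(seq, s0 + 1L, e0)
    if (strand == "+") {
      start <- s0; end <- e0
    } else {
      start <- contig_len - e0; end <- contig_len - s0
    }
    tibble::tibble(
      contig = contig, start = start, end = end, strand = strand,
      n_tracts = length(idx), seq = region_seq,
      tracts = list(tibble::tibble(start = tr$start[idx] - s0,
                                   length = tr$length[idx]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Enumerate 4-tract placements within regions
#'
#' The canonical set used for counting is every window of four consecutive
#' tracts. `extended = TRUE` additionally emits non-consecutive tract subsets
#' whose implied loops (which then contain the skipped tracts) stay within
#' the loop bounds.
#'
#' @param regions A region tibble from [detect_g4()].
#' @param params A [detection_params()].
#' @param extended Also enumerate non-consecutive tract quadruples.
#' @return A tibble with `contig`, `strand`, `region_start`, `region_end`,
#'   `tract_indices` (list of 4 ascending 1-based indices), loop lengths
#'   `loop1..loop3`, `span_start`/`span_end` (0-based, relative to the region
#'   on the scanned strand) and `seq` (the matched subsequence).
#' @export
enumerate_g4_matches <- function(regions, params = detection_params(),
                                 extended = FALSE) {
  purrr::pmap_dfr(
    regions[, c("contig", "start", "end", "strand", "seq", "tracts")],
    function(contig, start, end, strand, seq, tracts) {
      k <- nrow(tracts)
      if (k < 4L) return(NULL)
      combos <- if (extended) utils::combn(k, 4L, simplify = FALSE)
                else lapply(seq_len(k - 3L), function(i) i + 0:3)
      rows <- lapply(combos, function(ix) {
        st <- tracts$start[ix]
        en <- st + tracts$length[ix]
        loops <- st[-1L] - en[-4L]
        if (any(loops < params$loop_min | loops > params$loop_max)) return(NULL)
        tibble::tibble(
          contig = contig, strand = strand,
          region_start = start, region_end = end,
          tract_indices = list(ix),
          loop1 = loops[1L], loop2 = loops[2L], loop3 = loops[3L],
          span_start = st[1L], span_end = en[4L],
          seq = substr(seq, st[1L] + 1L, en[4L])
        )
      })
      dplyr::bind_rows(rows)
    })
}

#' Tetrad / placement count summary
#'
#' For each region reports the triple printed as `tetrads : total :
#' non-overlapping`: the tract count, the number of consecutive 4-tract
#' windows (`n_tracts - 3`), and the maximum number of disjoint windows
#' (greedy left-to-right, `floor(n_tracts / 4)` for a single chain).
#'
#' @param regions A region tibble from [detect_g4()].
#' @return `regions` with `n_tracts`, `total_matches` and
#'   `non_overlapping_matches` columns.
#' @examples
#' g4_count_summary(detect_g4("GGGTGGGTGGGTGGGTGGG"))
#' @export
g4_count_summary <- function(regions) {
  dplyr::mutate(
    dplyr::select(regions, -dplyr::any_of(c("tracts", "seq"))),
    total_matches = .data$n_tracts - 3L,
    non_overlapping_matches = .data$n_tracts %/% 4L
  )
}
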