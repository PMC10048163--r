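#' Read a FASTA file
#'
#' Plain and aligned (A2M-style, `-` gaps) FASTA are both supported;
#' sequences are uppercased. Malformed records raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @return A tibble with `seq_id` and `seq` (empty for an empty file).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(seq_id = character(), seq = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA: line ", lineno[1L], " is not a header", call. = FALSE)
  }
  bad <- which(!is_hdr & !grepl("^[A-Za-z.*-]+$", lines))
  if (length(bad)) {
    stop("malformed FASTA: unexpected characters on line ", lineno[bad[1L]],
         call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  seqs <- seqs[match(seq_along(ids), as.integer(names(seqs)))]
  seqs[is.na(seqs)] <- ""
  empty <- which(seqs == "")
  if (length(empty)) {
    stop("malformed FASTA: record on line ", lineno[is_hdr][empty[1L]],
         " has no sequence", call. = FALSE)
  }
  tibble::tibble(seq_id = ids, seq = toupper(unname(seqs)))
}

#' Write a FASTA file
#'
#' @param data A data frame with `seq_id` and `seq` (or named character).
#' @param path File path.
#' @param wrap Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, wrap = 60L) {
  data <- as_seq_tbl(data)
  out <- unlist(purrr::pmap(data[, c("seq_id", "seq")], function(seq_id, seq) {
    body <- substring(seq, seq(1L, max(nchar(seq), 1L), wrap),
                      pmin(seq(wrap, nchar(seq) + wrap - 1L, wrap), nchar(seq)))
    c(paste0(">", seq_id), body)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Write detected regions as BED6
#'
#' 0-based half-open intervals; name = region id, score = tract count.
#'
#' @param regions A tibble from [detect_g4()] (columns `contig`, `start`,
#'   `end`, `strand`, `n_tracts`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("contig", "start", "end", "strand") %in% names(regions)))
  if (any(regions$end <= regions$start)) stop("inverted interval in BED output")
  name <- if ("seq_id" %in% names(regions)) regions$seq_id else
    sprintf("g4_%d", seq_len(nrow(regions)))
  score <- if ("n_tracts" %in% names(regions)) regions$n_tracts else 0L
  df <- data.frame(regions$contig, regions$start, regions$end,
                   name, score, regions$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first 6 columns)
#'
#' @param path File path.
#' @return A tibble `contig`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  out <- tibble::tibble(
    contig = df[[1L]],
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    name = if (ncol(df) >= 4L) df[[4L]] else NA_character_,
    score = if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5L]])) else NA_real_,
    strand = if (ncol(df) >= 6L) df[[6L]] else "+"
  )
  if (any(out$end <= out$start)) stop("inverted interval in BED input")
  out
}

#' Parse a 1-based genomic region label
#'
#' Converts labels like `"chr19:43479561-43479598"` (1-based, inclusive, the
#' convention of genome-browser citations) to 0-based half-open coordinates.
#'
#' @param label Character vector of `chr:start-end` labels.
#' @return A tibble `contig`, `start`, `end` (0-based half-open).
#' @examples
#' parse_region_label("chr19:43479561-43479598")
#' @export
parse_region_label <- function(label) {
  m <- regmatches(label, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", label))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) stop("cannot parse region label: ", label[bad][1L], call. = FALSE)
  num <- function(i) as.integer(gsub(",", "", vapply(m, `[[`, character(1L), i)))
  tibble::tibble(contig = vapply(m, `[[`, character(1L), 2L),
                 start = num(3L) - 1L, end = num(4L))
}

FAMILY_BUNDLE_VERSION <- "1.0"

#' Write / read a family-set bundle
#'
#' One versioned JSON file carrying every accepted family: members,
#' alignment, consensus, gap score, serialized profile HMM and provenance.
#' The interchange artifact between the refine, merge and classify steps.
#'
#' @param family_set A `g4_family_set`.
#' @param path File path.
#' @return `write_family_set()` returns `path` invisibly; `read_family_set()`
#'   a `g4_family_set`.
#' @export
write_family_set <- function(family_set, path) {
  stopifnot(inherits(family_set, "g4_family_set"))
  payload <- list(
    version = FAMILY_BUNDLE_VERSION,
    converged = family_set$converged,
    iterations = family_set$iterations,
    families = lapply(unname(family_set$families), function(f) {
      list(id = f$id,
           members = as.list(f$members),
           alignment = as.list(f$alignment$rows),
           gap_score = f$gap_score,
           consensus = f$consensus,
           hmm = phmm_to_list(f$hmm),
           provenance = f$provenance)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_family_set
#' @export
read_family_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(as.character(x$version), FAMILY_BUNDLE_VERSION)) {
    stop("unsupported family bundle version: ", x$version, call. = FALSE)
  }
  fams <- lapply(x$families, function(f) {
    aln <- g4_alignment(tibble::tibble(seq_id = f$alignment$seq_id,
                                       aligned = f$alignment$aligned))
    structure(list(id = f$id,
                   members = tibble::as_tibble(f$members),
                   alignment = aln,
                   hmm = phmm_from_list(f$hmm),
                   gap_score = f$gap_score,
                   consensus = f$consensus,
                   provenance = f$provenance),
              class = "g4_family")
  })
  it <- suppressWarnings(as.integer(x$iterations))
  new_family_set(fams,
                 converged = if (is.null(x$converged) ||
                                 is.na(as.logical(x$converged))) NA
                             else as.logical(x$converged),
                 iterations = if (length(it) != 1L || is.na(it)) NA_integer_
                              else it)
}
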