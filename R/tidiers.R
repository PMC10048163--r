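#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an alignment into one row per (sequence, column)
#'
#' @param x A [g4_alignment()].
#' @param ... Unused.
#' @return A tibble `seq_id`, `column`, `char`.
#' @method tidy g4_alignment
#' @export
tidy.g4_alignment <- function(x, ...) {
  m <- aln_matrix(x)
  tibble::tibble(
    seq_id = rep(x$rows$seq_id, each = ncol(m)),
    column = rep(seq_len(ncol(m)), nrow(m)),
    char = as.vector(t(m))
  )
}

#' @rdname tidy.g4_alignment
#' @method glance g4_alignment
#' @export
glance.g4_alignment <- function(x, ...) {
  tibble::tibble(n_seqs = nrow(x$rows), n_cols = x$n_cols,
                 gap_score = gap_score(x),
                 consensus = iupac_consensus(x))
}

#' Plot an alignment as a base-colour tile map
#'
#' @param object A [g4_alignment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot g4_alignment
#' @export
autoplot.g4_alignment <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$seq_id,
                                  fill = .data$char)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::geom_text(ggplot2::aes(label = .data$char), size = 2.6) +
    ggplot2::scale_fill_manual(values = c(A = "#8dd3c7", C = "#80b1d3",
                                          G = "#fdb462", T = "#b3de69",
                                          "-" = "grey95"), guide = "none") +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a profile HMM into per-state emission rows
#'
#' @param x A [build_phmm()] model.
#' @param ... Unused.
#' @return A tibble `state`, `node`, `base`, `prob`.
#' @method tidy g4_phmm
#' @export
tidy.g4_phmm <- function(x, ...) {
  me <- tibble::tibble(state = "M",
                       node = rep(seq_len(x$m), each = 4L),
                       base = rep(BASES, x$m),
                       prob = as.vector(t(x$match_emis)))
  ie <- tibble::tibble(state = "I",
                       node = rep(0:x$m, each = 4L),
                       base = rep(BASES, x$m + 1L),
                       prob = as.vector(t(x$insert_emis)))
  dplyr::bind_rows(me, ie)
}

#' @rdname tidy.g4_phmm
#' @method glance g4_phmm
#' @export
glance.g4_phmm <- function(x, ...) {
  tibble::tibble(m = x$m, n_seqs = x$metadata$n_seqs,
                 pseudocount = x$metadata$pseudocount,
                 consensus = paste(BASES[apply(x$match_emis, 1L, which.max)],
                                   collapse = ""))
}

#' Plot profile HMM match emissions
#'
#' @param object A [build_phmm()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot g4_phmm
#' @export
autoplot.g4_phmm <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$state == "M")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$base,
                                  fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "match state", y = NULL, fill = "emission") +
    ggplot2::theme_minimal()
}

#' Tidy a family set into one row per family
#'
#' @param x A `g4_family_set`.
#' @param ... Unused.
#' @return A tibble `family`, `n_members`, `gap_score`, `consensus`,
#'   `model_length`.
#' @method tidy g4_family_set
#' @export
tidy.g4_family_set <- function(x, ...) {
  purrr::map_dfr(x$families, function(f) {
    tibble::tibble(family = f$id, n_members = nrow(f$members),
                   gap_score = f$gap_score, consensus = f$consensus,
                   model_length = f$hmm$m)
  })
}

#' @rdname tidy.g4_family_set
#' @method glance g4_family_set
#' @export
glance.g4_family_set <- function(x, ...) {
  tibble::tibble(n_families = length(x$families),
                 n_members = sum(vapply(x$families,
                                        function(f) nrow(f$members),
                                        integer(1L))),
                 converged = x$converged, iterations = x$iterations)
}

#' Plot family sizes and gap scores
#'
#' @param object A `g4_family_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot g4_family_set
#' @export
autoplot.g4_family_set <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$n_members,
                                  fill = .data$gap_score)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "#41ab5d", high = "#ef3b2c",
                                 limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = "members", fill = "gap score") +
    ggplot2::theme_minimal()
}

#' Tidy a distance matrix into long form
#'
#' @param x A [g4_dist()].
#' @param ... Unused.
#' @return A tibble `from`, `to`, `distance` (upper triangle only).
#' @method tidy g4_dist
#' @export
tidy.g4_dist <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(from = x$labels[ut[, 1L]], to = x$labels[ut[, 2L]],
                 distance = x$values[ut])
}

#' Plot the thermodynamic landscape of placements
#'
#' Energy of every quadruplex placement of a sequence against its span,
#' highlighting the MFE placement.
#'
#' @param seq A DNA sequence.
#' @param model A [energy_model()].
#' @return A ggplot object.
#' @export
plot_energy_landscape <- function(seq, model = energy_model()) {
  pl <- enumerate_placements(seq, model)
  if (nrow(pl) == 0L) stop("no quadruplex placements in sequence")
  pl$span <- pl$s4 + pl$layers - pl$s1
  pl$is_mfe <- pl$energy == min(pl$energy)
  ggplot2::ggplot(pl, ggplot2::aes(x = .data$span, y = .data$energy,
                                   colour = factor(.data$layers),
                                   shape = .data$is_mfe)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 17, `FALSE` = 16),
                                guide = "none") +
    ggplot2::labs(x = "placement span (nt)", y = "energy (kcal/mol)",
                  colour = "layers") +
    ggplot2::theme_minimal()
}
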