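#' Contact maps
#'
#' A contact map is a symmetric boolean map over residue pairs, stored as a
#' tibble of plotted pairs `(i, j)` with `i < j` plus the protein length.
#' An RDM (real distance map) is built from coordinates with a single
#' distance cutoff; an ADM (average distance map) is predicted from the
#' sequence alone via the distance-statistics table.
#'
#' @param pairs Tibble (or data frame) with integer columns `i` and `j`.
#' @param n Number of residues.
#' @param kind `"RDM"` or `"ADM"`.
#' @return An object of class `contact_map`: a list with elements `n`,
#'   `pairs` (tibble, `i < j`, sorted), `kind` and `density`.
#' @export
contact_map <- function(pairs, n, kind = c("ADM", "RDM")) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  pairs <- as_tibble(pairs)
  if (nrow(pairs) > 0) {
    ii <- pmin(pairs$i, pairs$j)
    jj <- pmax(pairs$i, pairs$j)
    pairs <- distinct(tibble(i = as.integer(ii), j = as.integer(jj)))
    if (any(pairs$i == pairs$j)) abort("self-pairs are not allowed on a contact map")
    if (any(pairs$i < 1) || any(pairs$j > n)) abort("pair indices outside 1..n")
    pairs <- arrange(pairs, .data$i, .data$j)
  } else {
    pairs <- tibble(i = integer(), j = integer())
  }
  total <- n * (n - 1) / 2
  structure(
    list(
      n = as.integer(n),
      pairs = pairs,
      kind = kind,
      density = if (total > 0) nrow(pairs) / total else 0
    ),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> kind=%s  n=%d  plotted=%d  density=%.4f\n",
    x$kind, x$n, nrow(x$pairs), x$density
  ))
  invisible(x)
}

#' @method tidy contact_map
#' @export
tidy.contact_map <- function(x, ...) x$pairs

#' @method glance contact_map
#' @export
glance.contact_map <- function(x, ...) {
  tibble(n = x$n, n_plotted = nrow(x$pairs), density = x$density, kind = x$kind)
}

#' Build a real distance map (RDM) from a C-alpha structure
#'
#' A residue pair is plotted when its Euclidean C-alpha distance is strictly
#' below the cutoff (default 15 Angstrom).
#'
#' @param structure C-alpha tibble from [read_calpha_structure()].
#' @param cutoff Distance cutoff in Angstrom.
#' @return A `contact_map` of kind `"RDM"`.
#' @export
build_rdm <- function(structure, cutoff = 15) {
  n <- nrow(structure)
  if (n < 2) abort("need at least 2 residues")
  d <- as.matrix(dist(as.matrix(structure[, c("x", "y", "z")])))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  contact_map(tibble(i = idx[, 1], j = idx[, 2]), n, kind = "RDM")
}

#' Predicted average contact density of an RDM
#'
#' Density law `rho = min(1, C / N)`: the expected overall contact density
#' of a 15-Angstrom RDM for a protein of `n` residues, with the constant
#' `C = 36.12` matching that cutoff.  The law is a configuration hook: any
#' function of `n` can be substituted via the `law` argument of
#' [calibrate_cutoffs()].
#'
#' @param n Number of residues (>= 2).
#' @param C Density-law constant.
#' @return Predicted density in (0, 1].
#' @export
predicted_rdm_density <- function(n, C = 36.12) {
  stopifnot(all(n >= 2), C > 0)
  pmin(1, C / n)
}

#' Map export / import as TSV of plotted pairs
#'
#' @param map A `contact_map`.
#' @param path File path.
#' @return `write_contact_map()` returns `path` invisibly;
#'   `read_contact_map()` the `contact_map`.
#' @export
write_contact_map <- function(map, path) {
  writeLines(
    c(
      sprintf("# n: %d", map$n),
      sprintf("# kind: %s", map$kind),
      "i\tj",
      sprintf("%d\t%d", map$pairs$i, map$pairs$j)
    ),
    path
  )
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("^# n:\\s*", "", grep("^# n:", lines, value = TRUE)[1]))
  kind <- sub("^# kind:\\s*", "", grep("^# kind:", lines, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  df <- readr::read_tsv(I(body), col_types = "ii")
  contact_map(df, n, kind = kind)
}

#' Plot a contact map
#'
#' Plotted pairs are mirrored across the diagonal, in the conventional
#' distance-map orientation.
#'
#' @param object A `contact_map`.
#' @param regions Optional tibble of compact regions (with `start`, `end`)
#'   to outline.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, regions = NULL, ...) {
  p <- object$pairs
  both <- bind_rows(p, tibble(i = p$j, j = p$i))
  g <- ggplot2::ggplot(both, ggplot2::aes(x = .data$j, y = .data$i)) +
    ggplot2::geom_point(shape = 15, size = 0.6) +
    ggplot2::scale_y_reverse(limits = c(object$n, 1)) +
    ggplot2::scale_x_continuous(limits = c(1, object$n), position = "top") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "residue j", y = "residue i",
      title = sprintf("%s (n = %d, density = %.3f)", object$kind, object$n, object$density)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    g <- g + ggplot2::annotate(
      "rect",
      xmin = regions$start, xmax = regions$end,
      ymin = regions$start, ymax = regions$end,
      fill = NA, colour = "red", linewidth = 0.4
    )
  }
  g
}
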