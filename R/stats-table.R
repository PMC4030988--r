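#' Build an inter-residue average-distance table from reference structures
#'
#' For every unordered residue-type pair and every separation range M, the
#' arithmetic mean of all observed C-alpha--C-alpha distances at separations
#' in that range is pooled over the supplied structures.  This table is the
#' sequence-to-map oracle: an ADM plots a residue pair when the table's mean
#' for its types and range falls below the calibrated cutoff.
#'
#' @param structures A list of C-alpha structures (tibbles as returned by
#'   [read_calpha_structure()]); a single tibble is also accepted.
#' @param scheme A [range_scheme()]; `NULL` uses the default.
#' @param min_obs Minimum observation count for a (type pair, range) entry
#'   to count as statistically significant.
#' @return A tibble of class `dist_stats` with columns `aa_a`, `aa_b`
#'   (sorted so `aa_a <= aa_b`), `m`, `mean_dist` (Angstrom) and `n_obs`;
#'   attributes `scheme` and `min_obs`.
#' @export
build_stats_table <- function(structures, scheme = NULL, min_obs = 10) {
  if (is.data.frame(structures)) structures <- list(structures)
  if (length(structures) == 0) abort("at least one structure is required")
  obs <- purrr::map_dfr(structures, function(st) {
    n <- nrow(st)
    if (n < 2) return(tibble())
    d <- as.matrix(dist(as.matrix(st[, c("x", "y", "z")])))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    tibble(
      aa_a = pmin(st$aa[i], st$aa[j]),
      aa_b = pmax(st$aa[i], st$aa[j]),
      k = abs(st$seq_index[j] - st$seq_index[i]),
      dist = d[idx]
    )
  })
  if (nrow(obs) == 0) abort("structures contain no residue pairs")
  obs$m <- range_of_separation(obs$k, scheme)
  tab <- obs |>
    group_by(.data$aa_a, .data$aa_b, .data$m) |>
    summarise(
      mean_dist = mean(.data$dist),
      n_obs = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$aa_a, .data$aa_b, .data$m)
  new_dist_stats(tab, scheme = scheme, min_obs = min_obs)
}

new_dist_stats <- function(tab, scheme = NULL, min_obs = 10) {
  attr(tab, "scheme") <- scheme
  attr(tab, "min_obs") <- min_obs
  class(tab) <- unique(c("dist_stats", class(tab)))
  tab
}

# significant entries only
significant_entries <- function(table) {
  min_obs <- attr(table, "min_obs") %||% 10
  table[table$n_obs >= min_obs, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a distance-statistics table as TSV
#'
#' Means are stored with 4 decimal places; the header records the range-bin
#' edges and the significance threshold so a loaded table carries its own
#' scheme (edited bin edges in the file override the defaults on read).
#'
#' @param table A `dist_stats` table.
#' @param path File path.
#' @return `write_stats_table()` returns `path` invisibly;
#'   `read_stats_table()` returns the `dist_stats` tibble.
#' @export
write_stats_table <- function(table, path) {
  scheme <- attr(table, "scheme")
  if (is.null(scheme)) scheme <- range_scheme(max(40, max(table$m) * 10))
  header <- c(
    sprintf(
      "# range_bins: %s",
      paste(sprintf("%d:%d-%d", scheme$m, scheme$k_min, scheme$k_max), collapse = ",")
    ),
    sprintf("# open_ended: %s", isTRUE(attr(scheme, "open_ended"))),
    sprintf("# min_obs: %d", attr(table, "min_obs") %||% 10)
  )
  body <- sprintf(
    "%s\t%s\t%d\t%.4f\t%d",
    table$aa_a, table$aa_b, table$m, table$mean_dist, table$n_obs
  )
  writeLines(c(header, "aa_a\taa_b\tm\tmean_dist\tn_obs", body), path)
  invisible(path)
}

#' @rdname write_stats_table
#' @export
read_stats_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  bins_line <- grep("^# range_bins:", hdr, value = TRUE)
  if (length(bins_line) != 1) abort("stats table header is missing its range_bins line")
  spec <- strsplit(sub("^# range_bins:\\s*", "", bins_line), ",")[[1]]
  parts <- do.call(rbind, strsplit(spec, "[:-]"))
  scheme <- tibble(
    m = as.integer(parts[, 1]),
    k_min = as.integer(parts[, 2]),
    k_max = as.integer(parts[, 3])
  )
  if (any(scheme$k_min[-1] != head(scheme$k_max, -1) + 1)) {
    abort("range bins in the stats table header are not contiguous")
  }
  open_line <- grep("^# open_ended:", hdr, value = TRUE)
  attr(scheme, "open_ended") <- length(open_line) == 1 &&
    sub("^# open_ended:\\s*", "", open_line) == "TRUE"
  class(scheme) <- c("range_scheme", class(scheme))
  min_obs_line <- grep("^# min_obs:", hdr, value = TRUE)
  min_obs <- if (length(min_obs_line) == 1) {
    as.integer(sub("^# min_obs:\\s*", "", min_obs_line))
  } else 10
  tab <- readr::read_tsv(
    I(lines[!grepl("^#", lines)]),
    col_types = readr::cols(
      aa_a = readr::col_character(), aa_b = readr::col_character(),
      m = readr::col_integer(), mean_dist = readr::col_double(),
      n_obs = readr::col_integer()
    )
  )
  new_dist_stats(as_tibble(tab), scheme = scheme, min_obs = min_obs)
}
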