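#' Contact-density-difference scanning profiles
#'
#' At each residue i the map is split into a triangular and a trapezoidal
#' part and the difference of their plot densities is recorded.  The
#' horizontal scan's triangle at i holds all pairs within residues 1..i;
#' the vertical scan's triangle holds all pairs within i..N; the trapezoid
#' is everything else.  A peak of `delta = rho_triangle - rho_trapezoid`
#' in the vertical scan marks a candidate region start, a horizontal peak a
#' candidate region end.
#'
#' @param map A `contact_map`.
#' @return A tibble of class `scan_profiles` with columns `axis`
#'   (`"horizontal"`/`"vertical"`), `i` (2..N-1), `rho_tri`, `rho_trap`,
#'   `delta`; attribute `n`.
#' @export
scan_profiles <- function(map) {
  n <- map$n
  if (n < 3) abort("scanning needs at least 3 residues")
  total_pairs <- n * (n - 1) / 2
  total_plotted <- nrow(map$pairs)
  # plotted-pair counts per triangle via cumulated max/min endpoint tallies
  cnt_by_max <- tabulate(map$pairs$j, nbins = n)
  cnt_by_min <- tabulate(map$pairs$i, nbins = n)
  is <- 2:(n - 1)
  tri_h <- cumsum(cnt_by_max)[is]                       # pairs within 1..i
  tri_v <- total_plotted - c(0, cumsum(cnt_by_min))[is] # pairs within i..N
  pairs_h <- choose(is, 2)
  pairs_v <- choose(n - is + 1, 2)
  prof <- function(axis, tri_cnt, tri_pairs) {
    rho_tri <- tri_cnt / tri_pairs
    rho_trap <- (total_plotted - tri_cnt) / (total_pairs - tri_pairs)
    tibble(
      axis = axis, i = is,
      rho_tri = rho_tri, rho_trap = rho_trap,
      delta = rho_tri - rho_trap
    )
  }
  out <- bind_rows(
    prof("horizontal", tri_h, pairs_h),
    prof("vertical", tri_v, pairs_v)
  )
  attr(out, "n") <- n
  class(out) <- c("scan_profiles", class(out))
  out
}

# one axis of a scan_profiles tibble, ordered by i
profile_axis <- function(profiles, axis) {
  p <- profiles[profiles$axis == axis, , drop = FALSE]
  p <- p[order(p$i), , drop = FALSE]
  attr(p, "n") <- attr(profiles, "n")
  p
}

#' Detect boundary peaks in a scanning profile
#'
#' Local maxima of `delta` with positive value and prominence at least the
#' threshold.  Prominence is the drop from the peak to the higher of the two
#' minima separating it from the nearest higher profile values (or the
#' profile ends).
#'
#' Positions near the profile ends are excluded by an edge guard: the
#' triangle there holds so few residue pairs that its density estimate is
#' dominated by sampling noise and spurious peaks appear.
#'
#' @param profile One axis of a [scan_profiles()] tibble (columns `i`,
#'   `delta`), or a full `scan_profiles` plus `axis`.
#' @param prominence Minimum prominence, in density units.
#' @param axis Axis to use when `profile` holds both.
#' @param edge_guard Minimum number of residues the triangular part must
#'   contain for its position to be eligible as a peak.
#' @return Sorted integer vector of peak residue indices.
#' @export
detect_boundary_peaks <- function(profile, prominence = 0.005, axis = NULL,
                                  edge_guard = 10) {
  if (!is.null(axis)) profile <- profile_axis(profile, axis)
  if ("axis" %in% names(profile) && length(unique(profile$axis)) > 1) {
    abort("profile holds both axes; pass `axis = \"horizontal\"` or \"vertical\"")
  }
  v <- profile$delta[order(profile$i)]
  idx <- sort(profile$i)
  m <- length(v)
  if (m < 3) return(integer())
  n <- attr(profile, "n") %||% (max(idx) + 1)
  eligible <- if (identical(profile$axis[1], "vertical")) {
    n - idx + 1 >= edge_guard
  } else {
    idx >= edge_guard
  }
  peaks <- integer()
  for (p in 2:(m - 1)) {
    if (!eligible[p]) next
    if (!(v[p] > v[p - 1] && v[p] >= v[p + 1])) next
    if (v[p] <= 0) next
    if (peak_prominence(v, p) < prominence) next
    peaks <- c(peaks, idx[p])
  }
  peaks
}

# prominence of a local maximum at position p of v
peak_prominence <- function(v, p) {
  left <- v[seq_len(p - 1)]
  higher_l <- which(left > v[p])
  base_l <- min(v[(if (length(higher_l)) max(higher_l) else 1):p])
  right <- v[(p + 1):length(v)]
  higher_r <- which(right > v[p])
  stop_r <- if (length(higher_r)) p + min(higher_r) else length(v)
  base_r <- min(v[p:stop_r])
  v[p] - max(base_l, base_r)
}

#' Predict compact regions from scanning profiles
#'
#' Each vertical peak (candidate start s) is paired with the nearest
#' horizontal peak e with `e > s + min_length - 1`; candidates are accepted
#' greedily in order of decreasing eta, skipping overlaps, and reported
#' sorted by start.  The compactness score is
#' `eta = (delta_v(s) + delta_h(e)) / 2`, the mean of the density contrasts
#' at the two boundaries.
#'
#' Because the whole-triangle density difference is nearly flat when a
#' boundary lies close to a chain terminus, each paired boundary is refined
#' within a small window by maximising a local band contrast (density of
#' the rows or columns kept inside the region minus the density of those
#' dropped); `refine_window = 0` disables this step.  Eta is evaluated at
#' the refined boundary positions.
#'
#' @param profiles A `scan_profiles` tibble (both axes).
#' @param map The `contact_map` the profiles came from; required for
#'   boundary refinement (pass `NULL` with `refine_window = 0` to skip).
#' @param min_length Minimum region length in residues.
#' @param prominence Peak prominence threshold.
#' @param edge_guard Edge guard passed to [detect_boundary_peaks()].
#' @param refine_window Half-width (residues) of the boundary-refinement
#'   search window.
#' @return Tibble of class `compact_regions` with columns `start`, `end`,
#'   `eta`, `peak_v`, `peak_h`, sorted by `start`.
#' @export
predict_regions <- function(profiles, map = NULL, min_length = 10,
                            prominence = 0.005, edge_guard = 10,
                            refine_window = 5) {
  h <- profile_axis(profiles, "horizontal")
  v <- profile_axis(profiles, "vertical")
  starts <- detect_boundary_peaks(v, prominence, edge_guard = edge_guard)
  ends <- detect_boundary_peaks(h, prominence, edge_guard = edge_guard)
  empty <- tibble(
    start = integer(), end = integer(), eta = numeric(),
    peak_v = integer(), peak_h = integer()
  )
  if (length(starts) == 0 || length(ends) == 0) {
    return(structure(empty, class = c("compact_regions", class(empty))))
  }
  dv <- setNames(v$delta, v$i)
  dh <- setNames(h$delta, h$i)
  delta_at <- function(d, i) {
    key <- as.character(i)
    if (key %in% names(d)) d[[key]] else d[[which.min(abs(as.integer(names(d)) - i))]]
  }
  cand <- purrr::map_dfr(starts, function(s) {
    es <- ends[ends > s + min_length - 1]
    if (length(es) == 0) return(tibble())
    e <- min(es)
    if (!is.null(map) && refine_window > 0) {
      refined <- refine_region(map, s, e, window = refine_window, min_length = min_length)
      s2 <- refined[1]; e2 <- refined[2]
    } else {
      s2 <- s; e2 <- e
    }
    tibble(
      start = s2, end = e2,
      eta = (delta_at(dv, s2) + delta_at(dh, e2)) / 2,
      peak_v = s, peak_h = e
    )
  })
  if (nrow(cand) == 0) {
    return(structure(empty, class = c("compact_regions", class(empty))))
  }
  cand <- cand[order(-cand$eta, cand$start), , drop = FALSE]
  chosen <- empty
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    overlaps <- nrow(chosen) > 0 &&
      any(row$start <= chosen$end & row$end >= chosen$start)
    if (!overlaps) chosen <- bind_rows(chosen, row)
  }
  chosen <- arrange(chosen, .data$start)
  structure(chosen, class = c("compact_regions", class(empty)))
}

#' Plot scanning profiles with detected peaks
#'
#' @param object A `scan_profiles` tibble.
#' @param prominence Peak prominence threshold for the overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scan_profiles
#' @export
autoplot.scan_profiles <- function(object, prominence = 0.005, ...) {
  pk <- bind_rows(lapply(c("horizontal", "vertical"), function(a) {
    p <- profile_axis(object, a)
    ix <- detect_boundary_peaks(p, prominence)
    p[p$i %in% ix, c("axis", "i", "delta")]
  }))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$i, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk, colour = "red") +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "residue i", y = expression(Delta * rho[i])) +
    ggplot2::theme_minimal()
}

# local band-contrast refinement of a candidate region's boundaries.
# For the start: choose s' in a window maximising (density of pairs inside
# [s', e]) minus (density of the row band dropped between the window floor
# and s'); symmetrically for the end with column bands.
refine_region <- function(map, s, e, window = 5, min_length = 10) {
  pr <- map$pairs
  n <- map$n
  region_density <- function(a, b) {
    len <- b - a + 1
    if (len < 2) return(0)
    sum(pr$i >= a & pr$j <= b) / choose(len, 2)
  }
  # start refinement
  lo <- max(1, s - window)
  hi <- min(s + window, e - min_length + 1)
  s2 <- s; best <- -Inf
  for (sp in lo:hi) {
    d_in <- region_density(sp, e)
    d_ex <- if (sp > lo) {
      cells <- sum(e - (lo:(sp - 1)))
      sum(pr$i >= lo & pr$i < sp & pr$j <= e) / cells
    } else 0
    jv <- d_in - d_ex
    if (jv > best) { best <- jv; s2 <- sp }
  }
  # end refinement
  lo_e <- max(s2 + min_length - 1, e - window)
  hi_e <- min(n, e + window)
  e2 <- e; best <- -Inf
  for (ep in lo_e:hi_e) {
    d_in <- region_density(s2, ep)
    d_ex <- if (ep < hi_e) {
      cells <- sum(((ep + 1):hi_e) - s2)
      sum(pr$j > ep & pr$j <= hi_e & pr$i >= s2) / cells
    } else 0
    jv <- d_in - d_ex
    if (jv > best) { best <- jv; e2 <- ep }
  }
  c(s2, e2)
}
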