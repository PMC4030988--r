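#' Calibrate per-range ADM cutoff distances
#'
#' The ADM cutoffs are chosen so that the predicted map's overall contact
#' density reproduces the density expected of the protein's RDM.  In each
#' separation range M the cutoff `c_M` is set so that the fraction of
#' statistically significant residue-type pairs with mean distance below
#' `c_M` equals a single global plotted-fraction parameter `D`
#' (`P(M)_C = D * P(M)_t`).  `D` is found by bisection on the resulting
#' whole-map ADM density until it matches the target within tolerance, or
#' saturates at `D = 1` when the target is unreachable.
#'
#' @param sequence Residues: a string, character vector, or one-row tibble
#'   with a `seq` column.
#' @param table A `dist_stats` table.
#' @param target_density Target overall density; `NULL` computes it from the
#'   density law at the sequence length.
#' @param tolerance Acceptable |achieved - target| (density units).
#' @param C Density-law constant, used when `target_density` is `NULL`.
#' @param law Density law, a function of the residue count; default
#'   [predicted_rdm_density()] with constant `C`.
#' @param max_iter Bisection iteration cap.
#' @return An object of class `adm_calibration`: list with `D`,
#'   `per_range_cutoff` (tibble `m`, `cutoff`), `achieved_density`,
#'   `target_density`, `saturated`.
#' @export
calibrate_cutoffs <- function(sequence, table, target_density = NULL,
                              tolerance = 0.005, C = 36.12,
                              law = NULL, max_iter = 60) {
  res <- as_residues(sequence)
  check_residues(res)
  n <- length(res)
  if (n < 2) abort("sequence must have at least 2 residues")
  if (is.null(target_density)) {
    target_density <- if (is.null(law)) predicted_rdm_density(n, C) else law(n)
  }
  sig <- significant_entries(table)
  scheme <- attr(table, "scheme")
  occupied <- sort(unique(range_of_separation(seq_len(n - 1), scheme)))
  means_by_m <- lapply(occupied, function(m) sort(sig$mean_dist[sig$m == m]))
  names(means_by_m) <- occupied
  empty <- occupied[lengths(means_by_m) == 0]
  if (length(empty) > 0) {
    abort(sprintf(
      "no statistically significant type pairs in occupied range(s): %s",
      paste(empty, collapse = ", ")
    ))
  }

  cutoffs_for_d <- function(d) {
    vapply(means_by_m, function(s) {
      nt <- length(s)
      kk <- round(d * nt)
      if (kk <= 0) return(0)
      if (kk >= nt) return(s[nt] + 1)
      (s[kk] + s[kk + 1]) / 2
    }, numeric(1))
  }
  cal_at <- function(d) {
    new_adm_calibration(
      D = d,
      per_range_cutoff = tibble(m = occupied, cutoff = unname(cutoffs_for_d(d))),
      achieved_density = NA_real_, target_density = target_density,
      saturated = FALSE
    )
  }
  density_at <- function(d) build_adm(sequence, table, cal_at(d))$density

  hi_density <- density_at(1)
  if (hi_density <= target_density) {
    cal <- cal_at(1)
    cal$achieved_density <- hi_density
    cal$saturated <- hi_density < target_density - tolerance
    return(cal)
  }
  lo <- 0; hi <- 1
  best_d <- 1; best_gap <- abs(hi_density - target_density)
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    dens <- density_at(mid)
    gap <- abs(dens - target_density)
    if (gap < best_gap) {
      best_gap <- gap
      best_d <- mid
    }
    if (gap <= tolerance) break
    if (dens > target_density) hi <- mid else lo <- mid
  }
  cal <- cal_at(best_d)
  cal$achieved_density <- density_at(best_d)
  cal$saturated <- FALSE
  cal
}

new_adm_calibration <- function(D, per_range_cutoff, achieved_density,
                                target_density, saturated) {
  structure(
    list(
      D = D, per_range_cutoff = per_range_cutoff,
      achieved_density = achieved_density, target_density = target_density,
      saturated = saturated
    ),
    class = "adm_calibration"
  )
}

#' Construct a calibration with fixed per-range cutoffs
#'
#' Bypasses density calibration; useful when cutoff distances are known or
#' planted (e.g. synthetic tables).
#'
#' @param cutoffs Either a single cutoff applied to every range, or a tibble
#'   with columns `m` and `cutoff`.
#' @param max_m When `cutoffs` is scalar, ranges 1..`max_m` get that cutoff.
#' @return An `adm_calibration`.
#' @export
fixed_calibration <- function(cutoffs, max_m = 50) {
  if (is.numeric(cutoffs) && length(cutoffs) == 1) {
    cutoffs <- tibble(m = seq_len(max_m), cutoff = cutoffs)
  }
  new_adm_calibration(
    D = NA_real_, per_range_cutoff = as_tibble(cutoffs),
    achieved_density = NA_real_, target_density = NA_real_, saturated = FALSE
  )
}

#' @export
print.adm_calibration <- function(x, ...) {
  cat(sprintf(
    "<adm_calibration> D=%.4g  achieved=%.4g  target=%.4g  saturated=%s\n",
    x$D, x$achieved_density, x$target_density, x$saturated
  ))
  invisible(x)
}

#' @method tidy adm_calibration
#' @export
tidy.adm_calibration <- function(x, ...) x$per_range_cutoff

#' @method glance adm_calibration
#' @export
glance.adm_calibration <- function(x, ...) {
  tibble(
    D = x$D, achieved_density = x$achieved_density,
    target_density = x$target_density, saturated = x$saturated
  )
}

#' Build an average distance map (ADM) from sequence alone
#'
#' A residue pair `(i, j)` is plotted when the table's mean distance for its
#' (type pair, range) entry is statistically significant and strictly below
#' the calibrated cutoff of range `M(|i - j|)`.  Pairs whose entry is absent
#' or insignificant are counted as non-contacts.
#'
#' @inheritParams calibrate_cutoffs
#' @param calibration An `adm_calibration` (from [calibrate_cutoffs()] or
#'   [fixed_calibration()]).
#' @return A `contact_map` of kind `"ADM"`.
#' @export
build_adm <- function(sequence, table, calibration) {
  res <- as_residues(sequence)
  check_residues(res)
  n <- length(res)
  if (n < 2) abort("sequence must have at least 2 residues")
  missing_types <- setdiff(unique(res), unique(c(table$aa_a, table$aa_b)))
  if (length(missing_types) > 0) {
    warn(sprintf(
      "residue type(s) %s absent from the statistics table; their pairs are counted as non-contacts",
      paste(missing_types, collapse = ", ")
    ))
  }
  sig <- significant_entries(table)
  scheme <- attr(table, "scheme")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- tibble(
    i = idx[, 1], j = idx[, 2],
    aa_a = pmin(res[idx[, 1]], res[idx[, 2]]),
    aa_b = pmax(res[idx[, 1]], res[idx[, 2]])
  )
  pairs$m <- range_of_separation(pairs$j - pairs$i, scheme)
  pairs <- left_join(
    pairs,
    select(sig, "aa_a", "aa_b", "m", "mean_dist"),
    by = c("aa_a", "aa_b", "m")
  )
  pairs <- left_join(pairs, calibration$per_range_cutoff, by = "m")
  plotted <- !is.na(pairs$mean_dist) & !is.na(pairs$cutoff) &
    pairs$mean_dist < pairs$cutoff
  contact_map(pairs[plotted, c("i", "j")], n, kind = "ADM")
}
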