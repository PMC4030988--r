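#' Find hydrophobic packing pairs between helices
#'
#' A packing pair is a pair of hydrophobic residues in different helices
#' whose side chains mutually bury more than `threshold` (default 10
#' Angstrom^2) of each other's solvent-accessible surface.  The F helix, if
#' annotated, is excluded from the analysis; intra-helix pairs are never
#' considered.  Each retained pair also records whether its closest
#' side-chain atom contact is within `contact_check` (approximately 5
#' Angstrom), a diagnostic rather than a second filter.
#'
#' @param structure Atom tibble (see [read_sidechain_structure()]).
#' @param helices Tibble with columns `label`, `start`, `end` (1-based
#'   inclusive residue numbers); labels must be unique and ranges
#'   non-overlapping.
#' @param hydrophobic Residue types considered hydrophobic.
#' @param threshold Buried-area threshold in Angstrom^2 (strict `>` on both
#'   sides of the pair).
#' @param contact_check Contact diagnostic distance in Angstrom.
#' @param n_points,probe SASA parameters, see [compute_sasa()].
#' @return Tibble of class `packing_pairs`: columns `res_a`, `aa_a`,
#'   `helix_a`, `res_b`, `aa_b`, `helix_b`, `delta_a`, `delta_b`,
#'   `min_sidechain_dist`, `contact_ok`.
#' @export
find_packing_pairs <- function(structure, helices,
                               hydrophobic = hydrophobic_residues,
                               threshold = 10, contact_check = 5,
                               n_points = 960, probe = 1.4) {
  helices <- as_tibble(helices)
  stopifnot(all(c("label", "start", "end") %in% names(helices)))
  if (anyDuplicated(helices$label)) abort("helix labels must be unique")
  hx <- arrange(helices, .data$start)
  if (nrow(hx) > 1 && any(hx$start[-1] <= head(hx$end, -1))) {
    abort("helix annotations overlap")
  }
  hx <- hx[hx$label != "F", , drop = FALSE]

  res_helix <- purrr::map_dfr(seq_len(nrow(hx)), function(r) {
    tibble(seq_index = hx$start[r]:hx$end[r], helix = hx$label[r])
  })
  res_info <- structure |>
    distinct(.data$seq_index, .data$aa) |>
    dplyr::inner_join(res_helix, by = "seq_index") |>
    filter(.data$aa %in% hydrophobic)
  # only residues that actually have side-chain atoms can bury surface
  has_sc <- unique(structure$seq_index[!structure$backbone])
  res_info <- res_info[res_info$seq_index %in% has_sc, , drop = FALSE]

  empty <- tibble(
    res_a = integer(), aa_a = character(), helix_a = character(),
    res_b = integer(), aa_b = character(), helix_b = character(),
    delta_a = numeric(), delta_b = numeric(),
    min_sidechain_dist = numeric(), contact_ok = logical()
  )
  out <- empty
  if (nrow(res_info) >= 2) {
    cand <- tidyr::crossing(a = seq_len(nrow(res_info)), b = seq_len(nrow(res_info))) |>
      filter(.data$a < .data$b)
    cand <- cand[res_info$helix[cand$a] != res_info$helix[cand$b], , drop = FALSE]
    sc <- structure[!structure$backbone, , drop = FALSE]
    max_reach <- 2 * max(sc$radius) + 2 * probe
    for (r in seq_len(nrow(cand))) {
      ra <- res_info$seq_index[cand$a[r]]
      rb <- res_info$seq_index[cand$b[r]]
      sa <- sc[sc$seq_index == ra, , drop = FALSE]
      sb <- sc[sc$seq_index == rb, , drop = FALSE]
      dmin <- min_interatom_dist(sa, sb)
      if (dmin >= max_reach) next  # no occlusion possible
      dd <- suppressWarnings(
        pair_delta_sasa(structure, ra, rb, n_points = n_points, probe = probe)
      )
      if (dd[["delta_a"]] > threshold && dd[["delta_b"]] > threshold) {
        out <- bind_rows(out, tibble(
          res_a = ra, aa_a = res_info$aa[cand$a[r]], helix_a = res_info$helix[cand$a[r]],
          res_b = rb, aa_b = res_info$aa[cand$b[r]], helix_b = res_info$helix[cand$b[r]],
          delta_a = dd[["delta_a"]], delta_b = dd[["delta_b"]],
          min_sidechain_dist = dmin,
          contact_ok = dmin <= contact_check
        ))
      }
    }
  }
  out <- arrange(out, .data$res_a, .data$res_b)
  base::structure(out, class = c("packing_pairs", class(empty)))
}

min_interatom_dist <- function(a, b) {
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  min(sqrt(pmax(0, outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * am %*% t(bm))))
}
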