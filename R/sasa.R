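# deterministic quasi-uniform unit-sphere point set (golden-spiral lattice)
fib_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# accessible area of each atom in `targets` (rows of the coordinate/radius
# tibble) against the occluding atoms in `occluders`
sasa_areas <- function(targets, occluders, n_points, probe) {
  pts <- fib_sphere_points(n_points)
  tc <- as.matrix(targets[, c("x", "y", "z")])
  oc <- as.matrix(occluders[, c("x", "y", "z")])
  tr <- targets$radius + probe
  or <- occluders$radius + probe
  areas <- numeric(nrow(targets))
  for (a in seq_len(nrow(targets))) {
    surf <- sweep(pts * tr[a], 2, tc[a, ], `+`)
    acc <- rep(TRUE, n_points)
    if (nrow(oc) > 0) {
      dc <- sqrt(colSums((t(oc) - tc[a, ])^2))
      self <- dc < 1e-9 & abs(or - tr[a]) < 1e-9
      near <- which(dc < tr[a] + or & !self)
      for (b in near) {
        d2 <- (surf[, 1] - oc[b, 1])^2 + (surf[, 2] - oc[b, 2])^2 +
          (surf[, 3] - oc[b, 3])^2
        acc <- acc & d2 >= or[b]^2
        if (!any(acc)) break
      }
    }
    areas[a] <- sum(acc) / n_points * 4 * pi * tr[a]^2
  }
  areas
}

#' Grid-count solvent-accessible surface area (SASA)
#'
#' For each heavy atom, quasi-uniform points are placed on the sphere of
#' radius vdW + probe; the accessible fraction (points not inside any other
#' atom's expanded sphere) times the sphere area is the atom's SASA.  The
#' probe radius defaults to 1.4 Angstrom, the van der Waals radius of a
#' water molecule.
#'
#' @param structure Atom tibble from [read_sidechain_structure()] (columns
#'   `seq_index`, `aa`, `atom`, `x`, `y`, `z`, `radius`, `backbone`).
#' @param n_points Sphere points per atom (>= 100; default 960).
#' @param probe Probe radius in Angstrom.
#' @return Object of class `sasa_result`: list with `atoms` (input tibble
#'   plus `area`), `residues` (per-residue side-chain area), `n_points`,
#'   `probe`.
#' @export
compute_sasa <- function(structure, n_points = 960, probe = 1.4) {
  if (nrow(structure) < 1) abort("structure has no atoms")
  if (n_points < 100) abort("n_points must be at least 100 for acceptable accuracy")
  atoms <- as_tibble(structure)
  atoms$area <- sasa_areas(atoms, atoms, n_points, probe)
  residues <- atoms |>
    group_by(.data$seq_index, .data$aa) |>
    summarise(
      sidechain_area = sum(.data$area[!.data$backbone]),
      total_area = sum(.data$area),
      .groups = "drop"
    )
  base::structure(
    list(atoms = atoms, residues = residues, n_points = n_points, probe = probe),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "<sasa_result> %d atoms, %d residues, n_points=%d, probe=%.2f A\n",
    nrow(x$atoms), nrow(x$residues), x$n_points, x$probe
  ))
  invisible(x)
}

#' @method tidy sasa_result
#' @export
tidy.sasa_result <- function(x, ...) x$residues

#' @method glance sasa_result
#' @export
glance.sasa_result <- function(x, ...) {
  tibble(
    n_atoms = nrow(x$atoms),
    total_area = sum(x$atoms$area),
    sidechain_area = sum(x$residues$sidechain_area),
    n_points = x$n_points,
    probe = x$probe
  )
}

# side-chain SASA of residue `res` with all atoms of residues in `exclude`
# removed from the structure
sidechain_sasa <- function(structure, res, exclude = integer(),
                           n_points = 960, probe = 1.4) {
  sc <- structure[structure$seq_index == res & !structure$backbone, , drop = FALSE]
  if (nrow(sc) == 0) return(0)
  occ <- structure[!(structure$seq_index %in% exclude), , drop = FALSE]
  # prune occluders beyond any possible overlap with the target atoms
  reach <- max(sc$radius) + max(occ$radius) + 2 * probe
  lo <- vapply(c("x", "y", "z"), function(d) min(sc[[d]]) - reach, numeric(1))
  hi <- vapply(c("x", "y", "z"), function(d) max(sc[[d]]) + reach, numeric(1))
  occ <- occ[occ$x >= lo[1] & occ$x <= hi[1] &
               occ$y >= lo[2] & occ$y <= hi[2] &
               occ$z >= lo[3] & occ$z <= hi[3], , drop = FALSE]
  sum(sasa_areas(sc, occ, n_points, probe))
}

#' Mutual buried side-chain surface of a residue pair
#'
#' `delta_a` is the side-chain SASA of residue `res_a` computed with all of
#' residue `res_b`'s atoms deleted, minus its side-chain SASA in the full
#' structure -- the surface area `res_b` buries on `res_a`.  Symmetrically
#' for `delta_b`.  Both are non-negative: removing an occluder cannot reduce
#' exposure.
#'
#' @inheritParams compute_sasa
#' @param res_a,res_b Residue numbers (`seq_index` values).
#' @return Named numeric vector `c(delta_a = , delta_b = )`, Angstrom^2.
#' @export
pair_delta_sasa <- function(structure, res_a, res_b, n_points = 960, probe = 1.4) {
  for (r in c(res_a, res_b)) {
    sc <- structure[structure$seq_index == r & !structure$backbone, , drop = FALSE]
    if (nrow(sc) == 0) {
      warn(sprintf("residue %d has no side-chain atoms; its delta is 0 by definition", r))
    }
  }
  delta_a <- sidechain_sasa(structure, res_a, exclude = res_b, n_points = n_points, probe = probe) -
    sidechain_sasa(structure, res_a, n_points = n_points, probe = probe)
  delta_b <- sidechain_sasa(structure, res_b, exclude = res_a, n_points = n_points, probe = probe) -
    sidechain_sasa(structure, res_b, n_points = n_points, probe = probe)
  c(delta_a = max(0, delta_a), delta_b = max(0, delta_b))
}
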