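#' Synthetic distance-statistics table with planted short-distance pairs
#'
#' Pairs involving only "attractor" residue types get short mean distances
#' in every range M >= 2; all other type pairs (and everything in the
#' near-diagonal range M = 1) get long means.  A deterministic linear
#' spread is added within each group so that calibration quantiles are
#' well defined.  Every entry carries `n_obs` observations, so all entries
#' are statistically significant by construction.
#'
#' @param attractors Attractor residue types (default `"L"`).
#' @param short,long Base mean distances (Angstrom) for attractor and
#'   non-attractor pairs.
#' @param spread Half-width of the deterministic within-group spread.
#' @param n_obs Observation count recorded for every entry.
#' @param max_m Largest range bin to tabulate.
#' @param min_obs Significance threshold stored on the table.
#' @return A `dist_stats` table covering all 210 type pairs in ranges
#'   1..`max_m`.
#' @export
make_stats_table <- function(attractors = "L", short = 5, long = 25,
                             spread = 2, n_obs = 100, max_m = 12,
                             min_obs = 10) {
  pairs <- tidyr::crossing(aa_a = AA20, aa_b = AA20) |>
    filter(.data$aa_a <= .data$aa_b)
  pairs$rank <- seq_len(nrow(pairs))
  tab <- tidyr::crossing(pairs, m = seq_len(max_m)) |>
    mutate(
      attract = .data$aa_a %in% attractors & .data$aa_b %in% attractors & .data$m >= 2,
      mean_dist = ifelse(.data$attract, short, long) +
        spread * (2 * (.data$rank - 1) / (max(.data$rank) - 1) - 1),
      n_obs = n_obs
    ) |>
    select("aa_a", "aa_b", "m", "mean_dist", "n_obs") |>
    arrange(.data$aa_a, .data$aa_b, .data$m)
  new_dist_stats(tab, scheme = range_scheme(10 * max_m), min_obs = min_obs)
}

#' Synthetic sequence whose ADM contains planted dense blocks
#'
#' Inside each planted region the attractor-type fraction is the square
#' root of the planted fill, so that attractor-attractor pairs -- the only
#' pairs the companion [make_stats_table()] plots at separations of 9 or
#' more -- approximate the planted block density; outside the regions the
#' composition follows `background_fill` the same way.  Block densities are
#' therefore defined (and should be measured) over pairs in ranges M >= 2.
#'
#' @param n Sequence length.
#' @param regions Tibble with `start`, `end`, `fill` for each planted
#'   region; `NULL` plants none.
#' @param background_fill Fill level outside the planted regions.
#' @param attractor Attractor residue type.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return One-row tibble (`id`, `seq`, `n`) with attribute `regions`.
#' @export
make_blocky_sequence <- function(n = 100, regions = NULL,
                                 background_fill = 0.05,
                                 attractor = "L", seed = 1) {
  pool <- setdiff(c("A", "S", "D", "E", "G", "K", "N", "Q", "R", "T"), attractor)
  withr::with_seed(seed, {
    res <- sample(pool, n, replace = TRUE)
    place <- function(lo, hi, fill) {
      len <- hi - lo + 1
      k <- round(sqrt(fill) * len)
      at <- sample(len, k)
      res[lo - 1 + at] <<- attractor
    }
    place(1, n, background_fill)
    if (!is.null(regions)) {
      for (r in seq_len(nrow(regions))) {
        seg <- regions$start[r]:regions$end[r]
        res[seg] <- sample(pool, length(seg), replace = TRUE)
        place(regions$start[r], regions$end[r], regions$fill[r])
      }
    }
  })
  out <- tibble(
    id = sprintf("synthetic_blocky_seed%d", seed),
    seq = paste(res, collapse = ""), n = n
  )
  attr(out, "regions") <- regions
  out
}

#' Synthetic contact map with planted dense diagonal blocks
#'
#' Each residue pair is plotted independently: with probability `fill`
#' when both residues lie in the same planted region, otherwise with
#' probability `background_fill`.
#'
#' @inheritParams make_blocky_sequence
#' @param kind Map kind label.
#' @return A `contact_map`.
#' @export
make_planted_map <- function(n = 100, regions = NULL, background_fill = 0.05,
                             seed = 1, kind = "ADM") {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- rep(background_fill, nrow(idx))
  if (!is.null(regions)) {
    for (r in seq_len(nrow(regions))) {
      inside <- idx[, 1] >= regions$start[r] & idx[, 2] <= regions$end[r]
      p[inside] <- regions$fill[r]
    }
  }
  plotted <- withr::with_seed(seed, runif(nrow(idx)) < p)
  contact_map(tibble(i = idx[plotted, 1], j = idx[plotted, 2]), n, kind = kind)
}

#' Synthetic helix bundle with planted side-chain contacts
#'
#' Ideal alpha-helical C-alpha traces (rise 1.5 Angstrom per residue, 100
#' degrees per residue, 2.3 Angstrom axis radius) run parallel along z with
#' the given inter-axis spacing.  Each residue carries a single-sphere
#' pseudo side chain (non-physical, radius `sc_radius`): planted contact
#' pairs are leucines whose side-chain spheres face each other across the
#' inter-helix midline at `contact_distance` apart; all other residues are
#' serines whose side chains point away from the bundle, so inter-helix
#' side chains of non-planted pairs stay at least ~8 Angstrom apart.
#'
#' @param n_helices Number of helices (default 3, labelled E, G, H).
#' @param helix_length Residues per helix.
#' @param spacing Inter-axis spacing in Angstrom.
#' @param n_contacts Number of planted contacts, distributed round-robin
#'   over adjacent helix pairs at residue slots 3, 7, 11, ...
#' @param contact_distance Centre distance of planted side-chain spheres.
#' @param sc_radius Pseudo side-chain sphere radius.
#' @param seed Integer seed (randomises helix phases).
#' @return List with `structure` (atom tibble), `helices` (annotation
#'   tibble) and `planted` (tibble of planted pairs, global residue
#'   numbering).
#' @export
make_helix_bundle <- function(n_helices = 3, helix_length = 18, spacing = 10,
                              n_contacts = 4, contact_distance = 3.5,
                              sc_radius = 1.9, seed = 1) {
  stopifnot(n_helices >= 2, n_helices <= 4)
  labels <- if (n_helices == 4) c("E", "F", "G", "H") else c("E", "G", "H")[seq_len(n_helices)]
  max_slots <- floor((helix_length - 3) / 4) + 1
  if (n_contacts > max_slots) {
    abort(sprintf("at most %d contacts fit %d-residue helices", max_slots, helix_length))
  }
  phases <- withr::with_seed(seed, runif(n_helices, 0, 2 * pi))
  rise <- 1.5; twist <- 100 * pi / 180; ca_radius <- 2.3

  planted <- tibble(
    slot = seq_len(n_contacts),
    res = 3L + 4L * (seq_len(n_contacts) - 1L),
    helix_a = ((seq_len(n_contacts) - 1L) %% (n_helices - 1L)) + 1L
  ) |>
    mutate(helix_b = .data$helix_a + 1L)

  atoms <- list()
  for (h in seq_len(n_helices)) {
    x0 <- (h - 1) * spacing
    for (i in seq_len(helix_length)) {
      gid <- (h - 1L) * helix_length + i
      theta <- phases[h] + twist * (i - 1)
      ca <- c(x0 + ca_radius * cos(theta), ca_radius * sin(theta), rise * (i - 1))
      in_a <- planted$res == i & planted$helix_a == h
      in_b <- planted$res == i & planted$helix_b == h
      if (any(in_a) || any(in_b)) {
        aa <- "L"
        mate <- if (any(in_a)) h + 1L else h - 1L
        midx <- (x0 + (mate - 1) * spacing) / 2
        dir <- if (any(in_a)) -1 else 1
        sc <- c(midx + dir * contact_distance / 2, 0, rise * (i - 1))
      } else {
        aa <- "S"
        side <- if (i %% 2 == 0) 1 else -1
        sc <- c(x0, side * (ca_radius + 2.2), rise * (i - 1))
      }
      atoms[[length(atoms) + 1]] <- tibble(
        seq_index = gid, aa = aa,
        atom = c("CA", "CB"),
        x = c(ca[1], sc[1]), y = c(ca[2], sc[2]), z = c(ca[3], sc[3]),
        radius = c(VDW_RADII[["C"]], sc_radius),
        backbone = c(TRUE, FALSE)
      )
    }
  }
  structure_tbl <- bind_rows(atoms)
  helices <- tibble(
    label = labels,
    start = (seq_len(n_helices) - 1L) * helix_length + 1L,
    end = seq_len(n_helices) * helix_length
  )
  planted_out <- planted |>
    mutate(
      res_a = (.data$helix_a - 1L) * helix_length + .data$res,
      res_b = (.data$helix_b - 1L) * helix_length + .data$res,
      label_a = labels[.data$helix_a],
      label_b = labels[.data$helix_b]
    ) |>
    select("res_a", "res_b", "label_a", "label_b") |>
    arrange(.data$res_a, .data$res_b)
  list(structure = structure_tbl, helices = helices, planted = planted_out)
}

#' Synthetic alignment evolved on a known tree with Poisson counts
#'
#' A random root sequence is evolved down the tree: in each column and along
#' each branch the number of substitution events is Poisson with mean
#' (column rate) x (branch length); each event replaces the residue with a
#' uniformly chosen different one.  Planted conserved columns have rate 0
#' and therefore stay invariant.
#'
#' @param n_taxa Number of leaves (used when `tree` is `NULL`).
#' @param n_cols Alignment columns.
#' @param tree_length Total tree length the random tree is rescaled to
#'   (expected substitutions per column at rate 1).
#' @param tree Optional `phylo` tree; overrides `n_taxa`/`tree_length`.
#' @param rates Per-column rates (recycled); default 1.
#' @param planted_conserved Columns whose rate is forced to 0.
#' @param seed Integer seed.
#' @return List with `alignment` (tibble `id`, `seq`), `tree` (the true
#'   tree), `planted_conserved` and `n_events` (true per-column event
#'   counts).
#' @export
make_alignment <- function(n_taxa = 24, n_cols = 300, tree_length = 6,
                           tree = NULL, rates = 1,
                           planted_conserved = integer(), seed = 1) {
  withr::with_seed(seed, {
    if (is.null(tree)) {
      tree <- ape::rtree(n_taxa)
      tree$edge.length <- tree$edge.length / sum(tree$edge.length) * tree_length
      tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
    }
    rates <- rep_len(rates, n_cols)
    rates[planted_conserved] <- 0
    root_seq <- sample(AA20, n_cols, replace = TRUE)
    n_tip <- length(tree$tip.label)
    seqs <- vector("list", n_tip + tree$Nnode)
    root_node <- n_tip + 1L
    seqs[[root_node]] <- root_seq
    n_events <- integer(n_cols)
    edges <- stats::reorder(tree, "cladewise")$edge
    lens <- stats::reorder(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      s <- seqs[[parent]]
      k <- rpois(n_cols, rates * lens[e])
      n_events <- n_events + k
      for (col in which(k > 0)) {
        for (ev in seq_len(k[col])) {
          s[col] <- sample(setdiff(AA20, s[col]), 1)
        }
      }
      seqs[[child]] <- s
    }
    alignment <- tibble(
      id = tree$tip.label,
      seq = vapply(seq_len(n_tip), function(t) paste(seqs[[t]], collapse = ""), character(1))
    )
  })
  attr(alignment, "n_cols") <- n_cols
  list(
    alignment = alignment, tree = tree,
    planted_conserved = sort(unique(as.integer(planted_conserved))),
    n_events = n_events
  )
}
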