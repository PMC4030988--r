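# Independent brute-force reference implementations and random fixtures.
# These deliberately use naive loops so they share no code path with the
# package internals they check.

random_calpha <- function(n, seed, box = 25) {
  withr::with_seed(seed, {
    tibble::tibble(
      seq_index = seq_len(n),
      aa = sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  n, replace = TRUE),
      x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)
    )
  })
}

random_atoms <- function(n_res, seed, box = 12) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_res), function(r) {
      ca <- runif(3, 0, box)
      sc <- ca + runif(3, -2, 2)
      tibble::tibble(
        seq_index = r,
        aa = sample(c("L", "V", "F", "S", "T"), 1),
        atom = c("CA", "CB"),
        x = c(ca[1], sc[1]), y = c(ca[2], sc[2]), z = c(ca[3], sc[3]),
        radius = c(1.7, 1.7),
        backbone = c(TRUE, FALSE)
      )
    })
    dplyr::bind_rows(rows)
  })
}

# contact map brute force: all-pairs distance comparison, strict <
oracle_rdm_pairs <- function(structure, cutoff) {
  n <- nrow(structure)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((structure$x[i] - structure$x[j])^2 +
                  (structure$y[i] - structure$y[j])^2 +
                  (structure$z[i] - structure$z[j])^2)
      if (d < cutoff) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(tibble::tibble(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

# scanning brute force: recount every triangle/trapezoid by enumeration
oracle_scan <- function(map) {
  n <- map$n
  key <- paste(map$pairs$i, map$pairs$j)
  plotted <- function(a, b) paste(a, b) %in% key
  all_pairs <- expand.grid(i = 1:n, j = 1:n)
  all_pairs <- all_pairs[all_pairs$i < all_pairs$j, ]
  rows <- list()
  for (i in 2:(n - 1)) {
    for (axis in c("horizontal", "vertical")) {
      in_tri <- if (axis == "horizontal") {
        all_pairs$j <= i
      } else {
        all_pairs$i >= i
      }
      tri <- all_pairs[in_tri, ]
      trap <- all_pairs[!in_tri, ]
      rho_tri <- mean(plotted(tri$i, tri$j))
      rho_trap <- mean(plotted(trap$i, trap$j))
      rows[[length(rows) + 1]] <- tibble::tibble(
        axis = axis, i = i, rho_tri = rho_tri, rho_trap = rho_trap,
        delta = rho_tri - rho_trap
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), axis, i)
}

# peak detection brute force: direct local-max scan with prominence walk
oracle_peaks <- function(delta, idx, n, axis, prominence, edge_guard) {
  m <- length(delta)
  res <- integer()
  for (p in 2:(m - 1)) {
    tri_res <- if (axis == "vertical") n - idx[p] + 1 else idx[p]
    if (tri_res < edge_guard) next
    if (!(delta[p] > delta[p - 1] && delta[p] >= delta[p + 1])) next
    if (delta[p] <= 0) next
    # walk left
    q <- p; base_l <- delta[p]
    while (q > 1 && delta[q - 1] <= delta[p]) {
      q <- q - 1
      base_l <- min(base_l, delta[q])
    }
    q <- p; base_r <- delta[p]
    while (q < m && delta[q + 1] <= delta[p]) {
      q <- q + 1
      base_r <- min(base_r, delta[q])
    }
    if (delta[p] - max(base_l, base_r) < prominence) next
    res <- c(res, idx[p])
  }
  res
}

# SASA brute force: naive point-in-sphere loops on the same deterministic
# golden-spiral lattice (the lattice itself is validated against closed
# forms elsewhere)
oracle_sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  ang <- k * pi * (3 - sqrt(5))
  cbind(r * cos(ang), r * sin(ang), z)
}

oracle_sidechain_sasa <- function(structure, res, exclude = integer(),
                                  n_points = 960, probe = 1.4) {
  sc_rows <- which(structure$seq_index == res & !structure$backbone)
  occ_rows <- which(!(structure$seq_index %in% exclude))
  pts <- oracle_sphere_points(n_points)
  total <- 0
  for (a in sc_rows) {
    R <- structure$radius[a] + probe
    n_acc <- 0
    for (k in seq_len(n_points)) {
      px <- structure$x[a] + R * pts[k, 1]
      py <- structure$y[a] + R * pts[k, 2]
      pz <- structure$z[a] + R * pts[k, 3]
      buried <- FALSE
      for (b in occ_rows) {
        if (b == a) next
        Rb <- structure$radius[b] + probe
        if ((px - structure$x[b])^2 + (py - structure$y[b])^2 +
              (pz - structure$z[b])^2 < Rb^2) {
          buried <- TRUE
          break
        }
      }
      if (!buried) n_acc <- n_acc + 1
    }
    total <- total + n_acc / n_points * 4 * pi * R^2
  }
  total
}

oracle_pair_delta <- function(structure, res_a, res_b, n_points = 960, probe = 1.4) {
  c(
    delta_a = oracle_sidechain_sasa(structure, res_a, res_b, n_points, probe) -
      oracle_sidechain_sasa(structure, res_a, integer(), n_points, probe),
    delta_b = oracle_sidechain_sasa(structure, res_b, res_a, n_points, probe) -
      oracle_sidechain_sasa(structure, res_b, integer(), n_points, probe)
  )
}

# positions whose extracted pattern equals a (singleton-length) pattern
positions_from_pattern <- function(pattern, offset = 1) {
  pos <- integer()
  cur <- offset
  for (r in seq_len(nrow(pattern$tokens))) {
    len <- pattern$tokens$lengths[[r]]
    stopifnot(length(len) == 1)
    if (pattern$tokens$type[r] == "phi") {
      pos <- c(pos, cur:(cur + len - 1))
      cur <- cur + len
    } else {
      cur <- cur + len
    }
  }
  pos
}

random_pattern <- function(seed) {
  withr::with_seed(seed, {
    n_phi <- sample(1:5, 1)
    types <- character(); lengths <- list()
    for (r in seq_len(n_phi)) {
      types <- c(types, "phi")
      lengths <- c(lengths, list(sample(1:4, 1)))
      if (r < n_phi) {
        types <- c(types, "x")
        lengths <- c(lengths, list(sample(1:6, 1)))
      }
    }
    spacing_pattern(tibble::tibble(type = types, lengths = lengths))
  })
}
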