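test_that("sequence separations map to the documented range bins", {
  expect_equal(range_of_separation(1), 1L)
  expect_equal(range_of_separation(8), 1L)
  expect_equal(range_of_separation(9), 2L)
  expect_equal(range_of_separation(20), 2L)
  expect_equal(range_of_separation(21), 3L)
  expect_equal(range_of_separation(30), 3L)
  expect_equal(range_of_separation(31), 4L)
  expect_equal(range_of_separation(35), 4L)
  expect_equal(range_of_separation(40), 4L)
  expect_equal(range_of_separation(41), 5L)
  expect_error(range_of_separation(0), "positive")

  sch <- range_scheme(100)
  expect_equal(range_of_separation(c(8, 9, 35, 95), sch), c(1L, 2L, 4L, 10L))
  # open-ended final bin absorbs larger separations
  expect_equal(range_of_separation(500, sch), max(sch$m))
})

test_that("distance statistics pool arithmetic means over structures", {
  st1 <- tibble::tibble(
    seq_index = 1:2, aa = c("A", "A"),
    x = c(0, 3.8), y = 0, z = 0
  )
  tab <- build_stats_table(st1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$m, 1L)
  expect_equal(tab$mean_dist, 3.8)
  expect_equal(tab$n_obs, 1L)

  st2 <- tibble::tibble(
    seq_index = 1:2, aa = c("A", "A"),
    x = c(0, 3.0), y = 0, z = 0
  )
  st3 <- tibble::tibble(
    seq_index = 1:2, aa = c("A", "A"),
    x = c(0, 5.0), y = 0, z = 0
  )
  tab2 <- build_stats_table(list(st2, st3))
  expect_equal(tab2$mean_dist, 4.0)
  expect_equal(tab2$n_obs, 2L)

  expect_error(build_stats_table(list()), "at least one")
})

test_that("distance statistics equal a brute-force recomputation", {
  structures <- lapply(1:6, function(s) random_calpha(15, seed = 100 + s))
  tab <- build_stats_table(structures)
  # brute force: accumulate every pair observation independently
  acc <- list()
  for (st in structures) {
    n <- nrow(st)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((st[i, c("x", "y", "z")] - st[j, c("x", "y", "z")])^2))
        m <- range_of_separation(j - i)
        key <- paste(min(st$aa[i], st$aa[j]), max(st$aa[i], st$aa[j]), m)
        acc[[key]] <- c(acc[[key]], d)
      }
    }
  }
  expect_equal(nrow(tab), length(acc))
  for (r in seq_len(nrow(tab))) {
    key <- paste(tab$aa_a[r], tab$aa_b[r], tab$m[r])
    expect_equal(tab$mean_dist[r], mean(acc[[key]]))
    expect_equal(tab$n_obs[r], length(acc[[key]]))
  }
})

test_that("density law: C/N with clamping and monotone decay", {
  expect_equal(predicted_rdm_density(100), 0.3612)
  expect_equal(predicted_rdm_density(36), 1)
  ns <- c(40, 80, 160, 320, 1000, 10000)
  rho <- predicted_rdm_density(ns)
  expect_true(all(diff(rho) < 0))
  expect_lt(predicted_rdm_density(1e6), 1e-4)
})

test_that("RDM plots strictly below the cutoff", {
  near <- tibble::tibble(seq_index = 1:2, aa = "A", x = c(0, 14.9), y = 0, z = 0)
  expect_equal(nrow(tidy(build_rdm(near))), 1L)
  at <- tibble::tibble(seq_index = 1:2, aa = "A", x = c(0, 15.0), y = 0, z = 0)
  expect_equal(nrow(tidy(build_rdm(at))), 0L)
})

test_that("RDM equals all-pairs brute force on random structures", {
  for (s in 1:25) {
    n <- withr::with_seed(s, sample(5:30, 1))
    st <- random_calpha(n, seed = 200 + s)
    expect_equal(tidy(build_rdm(st, 15)), oracle_rdm_pairs(st, 15))
  }
})

test_that("ADM plots significant pairs strictly below the range cutoff", {
  tab <- new_tab <- tibble::tibble(
    aa_a = "A", aa_b = "A", m = 1L, mean_dist = 5.0, n_obs = 50L
  )
  tab <- admscan:::new_dist_stats(tab, min_obs = 10)
  expect_equal(build_adm("AA", tab, fixed_calibration(6))$density, 1)
  expect_equal(build_adm("AA", tab, fixed_calibration(5))$density, 0)

  # insignificant entries are never plotted
  weak <- admscan:::new_dist_stats(
    tibble::tibble(aa_a = "A", aa_b = "A", m = 1L, mean_dist = 5.0, n_obs = 3L),
    min_obs = 10
  )
  expect_equal(build_adm("AA", weak, fixed_calibration(6))$density, 0)

  # residue types absent from the table are non-contacts, with a warning
  expect_warning(
    m <- build_adm("AW", tab, fixed_calibration(6)),
    "absent"
  )
  expect_equal(m$density, 0)
})

# all 210 type pairs in ranges 1..max_m with means spread linearly over
# (4, 30) Angstrom, so the density-vs-D curve has fine steps
uniform_stats_table <- function(max_m = 12) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  pairs <- tidyr::crossing(aa_a = aa, aa_b = aa)
  pairs <- pairs[pairs$aa_a <= pairs$aa_b, ]
  tab <- tidyr::crossing(pairs, m = seq_len(max_m))
  tab$mean_dist <- 4 + 26 * (seq_len(nrow(tab)) - 1) / (nrow(tab) - 1)
  tab$n_obs <- 100L
  admscan:::new_dist_stats(
    dplyr::select(tab, "aa_a", "aa_b", "m", "mean_dist", "n_obs"),
    min_obs = 10
  )
}

test_that("calibration reaches the target density or saturates honestly", {
  tab <- uniform_stats_table()
  sq <- paste(withr::with_seed(9, sample(unique(tab$aa_a), 100, replace = TRUE)),
              collapse = "")
  cal <- calibrate_cutoffs(sq, tab, target_density = 0.12, tolerance = 0.01)
  expect_false(cal$saturated)
  expect_lte(abs(cal$achieved_density - 0.12), 0.01)
  expect_equal(build_adm(sq, tab, cal)$density, cal$achieved_density)

  # with every pair significant the whole map can be plotted: D reaches 1
  # only for a target at the all-plotted density
  cal1 <- calibrate_cutoffs(sq, tab, target_density = 1, tolerance = 0.01)
  expect_equal(cal1$D, 1)
  expect_false(cal1$saturated)

  # a sequence rich in a residue type the table cannot score saturates:
  # even D = 1 cannot plot pairs without a significant table entry
  tab_no_w <- tab[tab$aa_a != "W" & tab$aa_b != "W", ]
  tab_no_w <- admscan:::new_dist_stats(tab_no_w, min_obs = 10)
  sq_w <- paste(rep(c("A", "W"), 40), collapse = "")
  sat <- suppressWarnings(
    calibrate_cutoffs(sq_w, tab_no_w, target_density = 0.9, tolerance = 0.01)
  )
  expect_equal(sat$D, 1)
  expect_true(sat$saturated)
  expect_lt(sat$achieved_density, 0.5)
})

test_that("a half-short planted table calibrates to D of about one half", {
  # 14 'short' residue types give 105 of the 210 unordered type pairs a
  # short mean distance in every range
  short_set <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q")
  pairs <- tidyr::crossing(
    aa_a = c(short_set, "R", "S", "T", "V", "W", "Y"),
    aa_b = c(short_set, "R", "S", "T", "V", "W", "Y")
  )
  pairs <- pairs[pairs$aa_a <= pairs$aa_b, ]
  tab <- tidyr::crossing(pairs, m = 1:6)
  tab$rank <- seq_len(nrow(tab))
  tab$mean_dist <- ifelse(tab$aa_a %in% short_set & tab$aa_b %in% short_set,
                          5, 25) + 0.001 * tab$rank
  tab$n_obs <- 100L
  tab <- admscan:::new_dist_stats(
    dplyr::select(tab, "aa_a", "aa_b", "m", "mean_dist", "n_obs"),
    min_obs = 10
  )
  # sequence drawn uniformly over all 20 types: the all-plotted density is
  # 1 and about half of the residue pairs are short-short
  sq <- paste(withr::with_seed(31, sample(c(short_set, "R", "S", "T", "V", "W", "Y"),
                                          60, replace = TRUE)), collapse = "")
  # the all-plotted density is 1; its half requires plotting the whole
  # short group (about half the sequence pairs) plus a sliver of the long
  # group, so the fitted D sits near one half
  cal <- calibrate_cutoffs(sq, tab, target_density = 0.5, tolerance = 0.01)
  expect_lte(abs(cal$achieved_density - 0.5), 0.01)
  expect_lt(abs(cal$D - 0.5), 0.1)
})

test_that("calibration density is non-decreasing in D", {
  tab <- make_stats_table(max_m = 12)
  sq <- make_blocky_sequence(60, seed = 4)
  dens <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1), function(d) {
    cutoffs <- admscan:::new_adm_calibration(
      D = d,
      per_range_cutoff = tibble::tibble(
        m = 1:12,
        cutoff = vapply(1:12, function(m) {
          s <- sort(tab$mean_dist[tab$m == m])
          kk <- round(d * length(s))
          if (kk <= 0) 0 else if (kk >= length(s)) s[length(s)] + 1
          else (s[kk] + s[kk + 1]) / 2
        }, numeric(1))
      ),
      achieved_density = NA, target_density = NA, saturated = FALSE
    )
    build_adm(sq, tab, cutoffs)$density
  }, numeric(1))
  expect_true(all(diff(dens) >= 0))
})

test_that("contact maps are canonical, symmetric and deterministic", {
  m <- contact_map(tibble::tibble(i = c(3, 1, 2), j = c(1, 3, 5)), 6, "ADM")
  expect_true(all(m$pairs$i < m$pairs$j))
  expect_equal(nrow(m$pairs), 2L)  # (3,1) and (1,3) collapse to one pair
  expect_error(contact_map(tibble::tibble(i = 2, j = 2), 4), "self-pairs")
  expect_error(contact_map(tibble::tibble(i = 0, j = 2), 4), "outside")

  tab <- make_stats_table(max_m = 12)
  sq <- make_blocky_sequence(50, seed = 8)
  a1 <- build_adm(sq, tab, fixed_calibration(10))
  a2 <- build_adm(sq, tab, fixed_calibration(10))
  expect_identical(tidy(a1), tidy(a2))
})
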