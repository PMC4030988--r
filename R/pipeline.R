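#' Screen predicted regions against a hit region
#'
#' Decides whether a structurally hit range (e.g. the four-helix E-to-H
#' unit found by a structure search) is predicted to be compact: `"full"`
#' when a predicted region covers at least `coverage` of the whole hit
#' range, `"gh_only"` when only the G--H sub-range is so covered, else
#' `"none"`.
#'
#' @param regions A `compact_regions` tibble (columns `start`, `end`).
#' @param hit_start,hit_end The hit range (1-based inclusive).
#' @param gh_start,gh_end Optional G--H sub-range.
#' @param coverage Required covered fraction (default 0.8).
#' @return One-row tibble with `decision`, `hit_coverage`, `gh_coverage`.
#' @export
region_overlap_screen <- function(regions, hit_start, hit_end,
                                  gh_start = NULL, gh_end = NULL,
                                  coverage = 0.8) {
  cov <- function(lo, hi) {
    if (nrow(regions) == 0) return(0)
    max(pmax(
      0,
      pmin(regions$end, hi) - pmax(regions$start, lo) + 1
    ) / (hi - lo + 1))
  }
  hit_cov <- cov(hit_start, hit_end)
  gh_cov <- if (!is.null(gh_start)) cov(gh_start, gh_end) else NA_real_
  decision <- if (hit_cov >= coverage) {
    "full"
  } else if (!is.na(gh_cov) && gh_cov >= coverage) {
    "gh_only"
  } else {
    "none"
  }
  tibble(decision = decision, hit_coverage = hit_cov, gh_coverage = gh_cov)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the workflow: sequence to ADM to compact regions; screening
#' of a configured hit region; hydrophobic packing between annotated
#' helices; conservation calling on a supplied alignment; helix spacing
#' patterns from the conserved hydrophobic positions.  Stages whose inputs
#' are missing from the config are skipped and noted in the summary.  The
#' run is deterministic given its inputs; logging goes to `message()`
#' (stderr), machine-readable TSV outputs to `out_dir`.
#'
#' @param config A named list or the path of a YAML file.  Recognised
#'   fields: `fasta`, `stats_table`, `pdb`, `chain`, `alignment`, `ref_id`,
#'   `hit_region` (list with `start`, `end`, optional `gh_start`,
#'   `gh_end`), `helices` (list of lists with `label`, `start`, `end`) and
#'   a `params` list (`C`, `tolerance`, `min_region_length`, `prominence`,
#'   `threshold`, `probe`, `n_points`, `alpha`, `coverage`, `lambda`).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params %||% list()
  par <- list(
    C = p$C %||% 36.12, tolerance = p$tolerance %||% 0.005,
    min_region_length = p$min_region_length %||% 10,
    prominence = p$prominence %||% 0.005,
    threshold = p$threshold %||% 10, probe = p$probe %||% 1.4,
    n_points = p$n_points %||% 960, alpha = p$alpha %||% 0.05,
    coverage = p$coverage %||% 0.8, lambda = p$lambda %||% "tree"
  )
  summary_rows <- list()
  note <- function(stage, status, detail = "") {
    message(sprintf("[%s] %s %s", stage, status, detail))
    summary_rows[[length(summary_rows) + 1]] <<-
      tibble(stage = stage, status = status, detail = detail)
  }
  results <- list()

  if (is.null(config$fasta) || is.null(config$stats_table)) {
    abort("config must provide `fasta` and `stats_table`")
  }
  seqs <- read_fasta(config$fasta)
  tab <- read_stats_table(config$stats_table)
  cal <- calibrate_cutoffs(seqs[1, ], tab, tolerance = par$tolerance, C = par$C)
  adm <- build_adm(seqs[1, ], tab, cal)
  regions <- predict_regions(
    scan_profiles(adm), adm,
    min_length = par$min_region_length, prominence = par$prominence
  )
  readr::write_tsv(tidy(adm), file.path(out_dir, "adm_map.tsv"))
  readr::write_tsv(as_tibble(regions), file.path(out_dir, "regions.tsv"))
  results$calibration <- cal
  results$adm <- adm
  results$regions <- regions
  note("adm", "ok", sprintf(
    "n=%d density=%.4f regions=%d", adm$n, adm$density, nrow(regions)
  ))

  if (!is.null(config$hit_region)) {
    hr <- config$hit_region
    screen <- region_overlap_screen(
      regions, hr$start, hr$end,
      gh_start = hr$gh_start, gh_end = hr$gh_end,
      coverage = par$coverage
    )
    readr::write_tsv(screen, file.path(out_dir, "screen.tsv"))
    results$screen <- screen
    note("screen", "ok", screen$decision)
  } else {
    note("screen", "skipped", "no hit_region configured")
  }

  if (!is.null(config$pdb) && !is.null(config$helices)) {
    helices <- bind_rows(lapply(config$helices, as_tibble))
    struct <- read_sidechain_structure(config$pdb, chain = config$chain)
    pairs <- find_packing_pairs(
      struct, helices,
      threshold = par$threshold, probe = par$probe, n_points = par$n_points
    )
    readr::write_tsv(as_tibble(pairs), file.path(out_dir, "packing.tsv"))
    results$packing <- pairs
    results$helices <- helices
    note("packing", "ok", sprintf("%d pairs", nrow(pairs)))
  } else {
    note("packing", "skipped", "no pdb/helices configured")
  }

  if (!is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    tree <- nj_tree(aln)
    counts <- count_substitutions(aln, tree)
    lambda <- if (identical(par$lambda, "tree")) sum(tree$edge.length) else par$lambda
    profile <- call_conserved(counts, lambda, alpha = par$alpha)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    readr::write_tsv(as_tibble(profile), file.path(out_dir, "conservation.tsv"))
    results$tree <- tree
    results$conservation <- profile
    note("conservation", "ok", sprintf(
      "lambda=%.3f q*=%d conserved=%d/%d",
      attr(profile, "lambda"), attr(profile, "q_star"),
      sum(profile$conserved), nrow(profile)
    ))

    ref_id <- config$ref_id %||% aln$id[1]
    if (ref_id %in% aln$id) {
      hyd <- conserved_hydrophobic(profile, ref_id, aln)
      readr::write_tsv(hyd, file.path(out_dir, "conserved_hydrophobic.tsv"))
      results$conserved_hydrophobic <- hyd
      if (!is.null(config$helices)) {
        helices <- bind_rows(lapply(config$helices, as_tibble))
        pats <- purrr::map_dfr(seq_len(nrow(helices)), function(r) {
          pos <- hyd$position[hyd$position >= helices$start[r] &
                                hyd$position <= helices$end[r]]
          if (length(pos) == 0) return(tibble())
          tibble(
            helix = helices$label[r],
            n_positions = length(pos),
            pattern = format(extract_pattern(pos, helices[r, ]))
          )
        })
        readr::write_tsv(pats, file.path(out_dir, "patterns.tsv"))
        results$patterns <- pats
        note("patterns", "ok", sprintf("%d helices with patterns", nrow(pats)))
      } else {
        note("patterns", "skipped", "no helices configured")
      }
    }
  } else {
    note("conservation", "skipped", "no alignment configured")
    note("patterns", "skipped", "no alignment configured")
  }

  readr::write_tsv(bind_rows(summary_rows), file.path(out_dir, "summary.tsv"))
  invisible(results)
}
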