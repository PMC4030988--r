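#' Neighbor-joining tree from a protein alignment
#'
#' Pairwise distances are Poisson-corrected p-distances,
#' `d = -ln(1 - p)`, computed over the sites where both rows are ungapped
#' (`model = "p"` uses the raw p-distance).  Negative NJ branch lengths are
#' set to zero with the length transferred to the sibling branch, so the
#' total tree length is preserved.
#'
#' @param alignment Tibble with `id` and `seq` columns (equal-length rows,
#'   gaps as `-`), as from [read_alignment()].
#' @param model `"poisson"` (default) or `"p"`.
#' @param p_cap Cap on the observed proportion of differences before the
#'   Poisson correction, to keep distances finite for near-saturated pairs.
#' @return An [ape::ape-package] `phylo` tree (unrooted for >= 4 taxa).
#' @export
nj_tree <- function(alignment, model = c("poisson", "p"), p_cap = 0.95) {
  model <- match.arg(model)
  if (nrow(alignment) < 3) abort("need at least 3 sequences")
  m <- alignment_matrix(alignment)
  nt <- nrow(m)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  for (a in seq_len(nt - 1)) {
    for (b in (a + 1):nt) {
      shared <- m[a, ] != "-" & m[b, ] != "-"
      if (!any(shared)) {
        abort(sprintf(
          "rows '%s' and '%s' share no ungapped sites", rownames(m)[a], rownames(m)[b]
        ))
      }
      p <- mean(m[a, shared] != m[b, shared])
      d[a, b] <- d[b, a] <- if (model == "poisson") -log(1 - min(p, p_cap)) else p
    }
  }
  tree <- if (nt == 3) nj3(d) else ape::nj(as.dist(d))
  fix_negative_branches(tree)
}

# closed-form three-taxon tree: terminal branches solve the three pairwise
# distance equations exactly
nj3 <- function(d) {
  ids <- rownames(d)
  x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ape::read.tree(text = sprintf(
    "(%s:%f,%s:%f,%s:%f);", ids[1], x, ids[2], y, ids[3], z
  ))
}

fix_negative_branches <- function(tree) {
  el <- tree$edge.length
  for (e in which(el < 0)) {
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_along(el) != e)
    if (length(sibs) > 0) el[sibs[1]] <- el[sibs[1]] + el[e]
    el[e] <- 0
  }
  tree$edge.length <- pmax(el, 0)
  tree
}

#' Per-column substitution counts by Fitch parsimony
#'
#' Counts the minimum number of substitutions per alignment column on the
#' tree topology (small-parsimony / Fitch counting after rooting the tree
#' along the first tip's edge; the count is independent of the rooting).
#' Gap characters are treated as missing data and contribute no state
#' constraint.
#'
#' @param alignment Tibble with `id` and `seq` columns.
#' @param tree A `phylo` tree whose tip labels match the alignment ids.
#' @return Integer vector of per-column counts.
#' @export
count_substitutions <- function(alignment, tree) {
  if (!setequal(tree$tip.label, alignment$id)) {
    abort("tree tip labels do not match alignment ids")
  }
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  tree <- stats::reorder(tree, "postorder")
  m <- alignment_matrix(alignment)[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_col <- ncol(m)
  masks <- matrix(0L, nrow = n_tip, ncol = n_col)
  code <- match(m, AA20)  # NA for gaps
  masks[] <- ifelse(is.na(code), 0L, bitwShiftL(1L, code - 1L))
  counts <- integer(n_col)
  sets <- matrix(0L, nrow = n_node, ncol = n_col)
  sets[seq_len(n_tip), ] <- masks
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    acc <- sets[parent, ]
    s <- sets[child, ]
    inter <- bitwAnd(acc, s)
    new_acc <- ifelse(
      acc == 0L, s,
      ifelse(s == 0L, acc, ifelse(inter != 0L, inter, bitwOr(acc, s)))
    )
    counts <- counts + as.integer(acc != 0L & s != 0L & inter == 0L)
    sets[parent, ] <- new_acc
  }
  counts
}

#' Poisson lower-tail conserved-residue call
#'
#' Approximating per-column substitution counts as Poisson with mean
#' `lambda` (the total tree length, i.e. the expected number of
#' substitutions averaged over residues), a column is called conserved when
#' its count falls within the lower 5% of that distribution: count <= q*,
#' where q* is the largest q with `ppois(q, lambda) <= alpha`.  If even a
#' count of 0 is not that improbable (`exp(-lambda) > alpha`), no column
#' can be called conserved.
#'
#' @param counts Integer vector of per-column substitution counts.
#' @param lambda Poisson mean; either a positive number, `"tree"` is not
#'   resolvable here so pass `sum(tree$edge.length)`, or the string
#'   `"mean"` to use the empirical mean of `counts` (useful because
#'   parsimony counts sit on a slightly different scale than branch-length
#'   sums).
#' @param alpha Lower-tail level (default 0.05).
#' @return Tibble of class `conservation_profile` with columns `column`,
#'   `count`, `conserved`; attributes `lambda`, `alpha`, `q_star`.
#' @export
call_conserved <- function(counts, lambda, alpha = 0.05) {
  if (identical(lambda, "mean")) lambda <- mean(counts)
  if (!is.numeric(lambda) || lambda <= 0) abort("lambda must be a positive number")
  if (ppois(0, lambda) > alpha) {
    q_star <- -1L
  } else {
    q_star <- qpois(alpha, lambda)
    while (q_star > 0 && ppois(q_star, lambda) > alpha) q_star <- q_star - 1L
    while (ppois(q_star + 1, lambda) <= alpha) q_star <- q_star + 1L
  }
  out <- tibble(
    column = seq_along(counts),
    count = as.integer(counts),
    conserved = counts <= q_star
  )
  attr(out, "lambda") <- lambda
  attr(out, "alpha") <- alpha
  attr(out, "q_star") <- as.integer(q_star)
  class(out) <- c("conservation_profile", class(out))
  out
}

#' @method glance conservation_profile
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(
    n_columns = nrow(x),
    lambda = attr(x, "lambda"),
    alpha = attr(x, "alpha"),
    q_star = attr(x, "q_star"),
    n_conserved = sum(x$conserved)
  )
}

#' Conserved hydrophobic positions on a reference sequence
#'
#' Filters the conserved columns to those whose reference residue is
#' hydrophobic and maps them through the reference row's gap pattern to
#' 1-based positions on the ungapped reference sequence.
#'
#' @param profile A `conservation_profile`.
#' @param ref_id Id of the reference row in the alignment.
#' @param alignment The alignment the profile was computed from.
#' @param hydrophobic Hydrophobic residue set.
#' @return Tibble with columns `column`, `position`, `residue`.
#' @export
conserved_hydrophobic <- function(profile, ref_id, alignment,
                                  hydrophobic = hydrophobic_residues) {
  row <- which(alignment$id == ref_id)
  if (length(row) != 1) abort(sprintf("reference id '%s' not found in alignment", ref_id))
  ref <- strsplit(alignment$seq[row], "")[[1]]
  pos <- cumsum(ref != "-")
  keep <- profile$conserved & ref[profile$column] != "-" &
    ref[profile$column] %in% hydrophobic
  tibble(
    column = profile$column[keep],
    position = pos[profile$column[keep]],
    residue = ref[profile$column[keep]]
  )
}

#' Plot a conservation profile
#'
#' @param object A `conservation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  q_star <- attr(object, "q_star")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$count)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$conserved), width = 1) +
    ggplot2::geom_hline(yintercept = q_star + 0.5, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "alignment column", y = "substitution count",
      title = sprintf(
        "lambda = %.2f, alpha = %.2f, q* = %d",
        attr(object, "lambda"), attr(object, "alpha"), q_star
      )
    ) +
    ggplot2::theme_minimal()
}
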