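#' Helix-local hydrophobic spacing patterns
#'
#' A spacing pattern describes conserved hydrophobic positions within a
#' helix as alternating runs: a phi-run of consecutive hydrophobic
#' positions, an x-run of intervening residues, and so on, always beginning
#' and ending with a phi-run.  The text notation writes a run of length 1
#' bare and longer runs with the length in parentheses, e.g.
#' `"φx(3)φ(2)x(2)φ"`; an x-run may carry alternative
#' lengths, `"x(2,3)"`, which any of those lengths matches.
#'
#' @param tokens Tibble with columns `type` (`"phi"`/`"x"`) and `lengths`
#'   (list column of allowed integer lengths).
#' @return An object of class `spacing_pattern`.
#' @export
spacing_pattern <- function(tokens) {
  tokens <- as_tibble(tokens)
  stopifnot(all(c("type", "lengths") %in% names(tokens)))
  if (nrow(tokens) == 0) abort("a pattern needs at least one phi-run")
  if (tokens$type[1] != "phi" || tail(tokens$type, 1) != "phi") {
    abort("a pattern must begin and end with a phi-run")
  }
  if (any(tokens$type[-1] == head(tokens$type, -1))) {
    abort("phi-runs and x-runs must alternate")
  }
  if (any(vapply(tokens$lengths, function(l) any(l < 1), logical(1)))) {
    abort("run lengths must be >= 1")
  }
  structure(list(tokens = tokens), class = "spacing_pattern")
}

#' @export
format.spacing_pattern <- function(x, ...) {
  paste(vapply(seq_len(nrow(x$tokens)), function(r) {
    sym <- if (x$tokens$type[r] == "phi") "φ" else "x"
    l <- x$tokens$lengths[[r]]
    if (length(l) == 1 && l == 1) sym else sprintf("%s(%s)", sym, paste(l, collapse = ","))
  }, character(1)), collapse = "")
}

#' @export
print.spacing_pattern <- function(x, ...) {
  cat("<spacing_pattern>", format(x), "\n")
  invisible(x)
}

#' Parse spacing-pattern notation
#'
#' Accepts the Greek phi or the ASCII alias `f`; whitespace inside
#' parenthesised length lists is tolerated.
#'
#' @param text Pattern text such as `"φx(2,3)φ(2)x(2,3)φ"`.
#' @return A `spacing_pattern`.
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  rest <- text
  pos <- 1
  types <- character()
  lengths <- list()
  token_re <- "^(φ|f|x)(\\(\\s*[0-9]+(\\s*,\\s*[0-9]+)*\\s*\\))?"
  while (nchar(rest) > 0) {
    m <- regexpr(token_re, rest, perl = TRUE)
    if (m == -1) {
      abort(sprintf("malformed pattern at position %d: '%s'", pos, substr(rest, 1, 8)))
    }
    tok <- regmatches(rest, m)
    sym <- substr(tok, 1, 1)
    types <- c(types, if (sym == "x") "x" else "phi")
    paren <- sub("^(φ|f|x)", "", tok)
    lengths <- c(lengths, list(
      if (nchar(paren) == 0) 1L
      else as.integer(strsplit(gsub("[()[:space:]]", "", paren), ",")[[1]])
    ))
    pos <- pos + nchar(tok)
    rest <- substr(rest, nchar(tok) + 1, nchar(rest))
  }
  spacing_pattern(tibble(type = types, lengths = lengths))
}

#' Extract the spacing pattern of positions within a helix
#'
#' Consecutive positions merge into phi-runs; gaps between them become
#' x-runs of the gap length.  Residues of the helix before the first and
#' after the last position are not encoded, so the pattern depends only on
#' the gap signature (it is translation-invariant within the helix).
#'
#' @param positions Sorted 1-based residue positions (e.g. conserved
#'   hydrophobic positions).
#' @param helix Optional helix annotation (one row with `start`, `end`);
#'   when given, positions outside it are an error.
#' @return A `spacing_pattern`.
#' @export
extract_pattern <- function(positions, helix = NULL) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0) abort("no positions to extract a pattern from")
  if (!is.null(helix)) {
    if (any(positions < helix$start[1] | positions > helix$end[1])) {
      abort("positions fall outside the helix range")
    }
  }
  gaps <- diff(positions) - 1L
  types <- "phi"
  lengths <- list()
  phi_len <- 1L
  for (g in gaps) {
    if (g == 0L) {
      phi_len <- phi_len + 1L
    } else {
      lengths <- c(lengths, list(phi_len), list(g))
      types <- c(types, "x", "phi")
      phi_len <- 1L
    }
  }
  lengths <- c(lengths, list(phi_len))
  spacing_pattern(tibble(type = types, lengths = lengths))
}

#' Match candidate positions against a spacing pattern
#'
#' True iff the pattern extracted from the candidate positions has the same
#' run structure and every run length is among the pattern's allowed
#' lengths (variant syntax such as `"x(2,3)"` matches an x-run of length 2
#' or 3).
#'
#' @param pattern A `spacing_pattern` or pattern text.
#' @param positions Candidate positions.
#' @param helix Optional helix annotation, as in [extract_pattern()].
#' @return Logical scalar.
#' @export
match_pattern <- function(pattern, positions, helix = NULL) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  cand <- extract_pattern(positions, helix)
  pt <- pattern$tokens
  ct <- cand$tokens
  if (nrow(pt) != nrow(ct)) return(FALSE)
  if (!all(pt$type == ct$type)) return(FALSE)
  all(vapply(seq_len(nrow(pt)), function(r) {
    ct$lengths[[r]] %in% pt$lengths[[r]]
  }, logical(1)))
}

#' Pattern equality up to notation
#'
#' @param a,b Patterns or pattern texts.
#' @return TRUE iff both have identical run structure and allowed lengths.
#' @export
patterns_equal <- function(a, b) {
  if (is.character(a)) a <- parse_pattern(a)
  if (is.character(b)) b <- parse_pattern(b)
  at <- a$tokens; bt <- b$tokens
  nrow(at) == nrow(bt) && all(at$type == bt$type) &&
    all(vapply(seq_len(nrow(at)), function(r) {
      identical(sort(at$lengths[[r]]), sort(bt$lengths[[r]]))
    }, logical(1)))
}
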