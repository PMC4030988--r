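#' Sequence-separation range scheme
#'
#' Distance statistics are pooled within "ranges" of sequence separation
#' k = |i - j|.  The default scheme is M = 1 for 1 <= k <= 8, M = 2 for
#' 9 <= k <= 20, M = 3 for 21 <= k <= 30, M = 4 for 31 <= k <= 40, and
#' width-10 bins continuing upward; the final listed bin may be flagged
#' open-ended so that any larger separation falls into it.
#'
#' @param max_k Largest separation the enumerated bins must cover.
#' @param open_ended Should the last bin absorb separations beyond `max_k`?
#' @return A tibble with columns `m`, `k_min`, `k_max` (class
#'   `range_scheme`), with an `open_ended` attribute.
#' @export
range_scheme <- function(max_k = 400, open_ended = TRUE) {
  stopifnot(max_k >= 1)
  k_min <- c(1, 9, 21)
  k_max <- c(8, 20, 30)
  while (tail(k_max, 1) < max_k) {
    k_min <- c(k_min, tail(k_max, 1) + 1)
    k_max <- c(k_max, tail(k_max, 1) + 10)
  }
  keep <- k_min <= max_k
  sch <- tibble(m = seq_along(k_min[keep]), k_min = k_min[keep], k_max = k_max[keep])
  attr(sch, "open_ended") <- open_ended
  class(sch) <- c("range_scheme", class(sch))
  sch
}

#' Map a sequence separation to its range bin
#'
#' @param k Positive integer separation(s) `|i - j|`.
#' @param scheme A [range_scheme()]; `NULL` uses the default scheme.
#' @return Integer bin id(s) `M`.
#' @export
range_of_separation <- function(k, scheme = NULL) {
  if (any(k <= 0) || any(k != round(k))) {
    abort("separation k must be a positive integer")
  }
  if (is.null(scheme)) {
    return(ifelse(k <= 8L, 1L, ifelse(k <= 20L, 2L, 2L + as.integer(ceiling((k - 20) / 10)))))
  }
  idx <- findInterval(k, scheme$k_min)
  m <- scheme$m[idx]
  over <- k > scheme$k_max[idx]
  if (any(over)) {
    if (isTRUE(attr(scheme, "open_ended"))) {
      m[over] <- tail(scheme$m, 1)
    } else {
      abort(sprintf("separation %d is beyond the scheme's last bin", max(k[over])))
    }
  }
  as.integer(m)
}
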