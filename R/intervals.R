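#' Overlap in base pairs between two inclusive intervals
#'
#' Coordinates are 1-based inclusive, so adjacency (`end + 1 == start`) is
#' not overlap. Vectorised over all arguments.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds.
#' @param a_chrom,b_chrom Optional chromosome labels; when given, differing
#'   chromosomes raise an error (overlap across chromosomes is undefined).
#' @return Integer bp shared; 0 when disjoint.
#' @export
overlap_bp <- function(a_start, a_end, b_start, b_end,
                       a_chrom = NULL, b_chrom = NULL) {
  if (!is.null(a_chrom) && !is.null(b_chrom) &&
      any(norm_chrom(a_chrom) != norm_chrom(b_chrom))) {
    abort("overlap_bp: intervals on different chromosomes")
  }
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
}

#' Overlap specification
#'
#' Defines when two calls are considered to hit the same locus. `"any"`
#' requires at least 1 bp shared; `"reciprocal"` additionally requires the
#' shared bp to be at least `min_fraction` of EACH interval's length.
#'
#' @param mode `"any"` or `"reciprocal"`.
#' @param min_fraction Fraction in (0, 1]; used for reciprocal mode.
#' @return An `overlap_spec` list.
#' @export
overlap_spec <- function(mode = c("any", "reciprocal"), min_fraction = 0.5) {
  mode <- match.arg(mode)
  if (mode == "reciprocal" &&
      (!is.finite(min_fraction) || min_fraction <= 0 || min_fraction > 1)) {
    abort("overlap_spec: min_fraction must be in (0, 1]")
  }
  structure(list(mode = mode, min_fraction = min_fraction),
            class = "overlap_spec")
}

#' Does a pair of intervals satisfy an overlap specification?
#'
#' @inheritParams overlap_bp
#' @param spec An [overlap_spec()].
#' @return Logical vector.
#' @export
overlap_satisfies <- function(a_start, a_end, b_start, b_end,
                              spec = overlap_spec()) {
  ov <- overlap_bp(a_start, a_end, b_start, b_end)
  if (spec$mode == "any") return(ov >= 1)
  fa <- ov / interval_size(a_start, a_end)
  fb <- ov / interval_size(b_start, b_end)
  # tiny tolerance so exact fractions like 50/100 pass f = 0.5 despite
  # floating-point division
  eps <- 1e-12
  ov >= 1 & fa >= spec$min_fraction - eps & fb >= spec$min_fraction - eps
}

# Connected components of the overlap graph, per chromosome.
# Returns an integer component id per row of `iv` (tibble chrom/start/end).
# mode "any": single sorted sweep (components are contiguous runs).
# mode "reciprocal": candidate pairs from the sweep, then union-find.
overlap_components <- function(iv, spec = overlap_spec()) {
  n <- nrow(iv)
  comp <- integer(n)
  if (!n) return(comp)
  next_id <- 0L
  for (ch in unique(iv$chrom)) {
    idx <- which(iv$chrom == ch)
    o <- idx[order(iv$start[idx], iv$end[idx])]
    s <- iv$start[o]; e <- iv$end[o]
    if (spec$mode == "any") {
      run_max <- cummax(c(-Inf, head(e, -1)))
      new_run <- s > run_max  # no overlap with anything before it in the run
      comp[o] <- next_id + cumsum(new_run)
      next_id <- next_id + sum(new_run)
    } else {
      parent <- seq_along(o)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (i in seq_along(o)) {
        j <- i + 1L
        while (j <= length(o) && s[j] <= e[i]) {
          if (overlap_satisfies(s[i], e[i], s[j], e[j], spec)) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
          j <- j + 1L
        }
      }
      roots <- vapply(seq_along(o), find, 1L)
      comp[o] <- next_id + as.integer(factor(roots, levels = unique(roots)))
      next_id <- next_id + length(unique(roots))
    }
  }
  comp
}

#' Merge CNV calls into CNV regions
#'
#' A CNV region (CNVR) is a connected component of the call overlap graph:
#' calls linked, directly or transitively, by overlaps satisfying `spec`.
#' The region envelope is the union of its members' intervals (min start,
#' max end).
#'
#' @param calls Call tibble; only `chrom`, `start`, `end` are required.
#'   `sample_id` and `copy_number`, when present, populate carrier and state
#'   summaries.
#' @param spec An [overlap_spec()]; default any-overlap.
#' @return Tibble of regions sorted by `(chrom, start)` with columns `chrom`,
#'   `start`, `end`, `n_calls`, `n_carriers`, `state`, `carriers` (list) and
#'   `members` (list of row indices into `calls`).
#' @export
merge_to_regions <- function(calls, spec = overlap_spec()) {
  calls <- as_tibble(calls)
  if (!nrow(calls)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_calls = integer(), n_carriers = integer(),
                  state = character(), carriers = list(), members = list()))
  }
  comp <- overlap_components(calls, spec)
  has_sample <- "sample_id" %in% names(calls)
  has_cn <- "copy_number" %in% names(calls)
  idx_by_comp <- split(seq_len(nrow(calls)), comp)
  rows <- purrr::map(idx_by_comp, function(ix) {
    carriers <- if (has_sample) sort(unique(calls$sample_id[ix])) else character()
    tibble(
      chrom = calls$chrom[ix[1]],
      start = min(calls$start[ix]),
      end = max(calls$end[ix]),
      n_calls = length(ix),
      n_carriers = length(carriers),
      state = if (has_cn) classify_state(calls$copy_number[ix]) else NA_character_,
      carriers = list(carriers),
      members = list(ix)
    )
  })
  out <- bind_rows(rows)
  out[order(chrom_rank(out$chrom), out$start, out$end), ]
}

#' Classify a set of copy numbers as loss, gain or both
#'
#' @param copy_numbers Integer vector of member copy numbers (never 2).
#' @return `"loss"` if all < 2, `"gain"` if all > 2, otherwise `"both"`.
#' @export
classify_state <- function(copy_numbers) {
  cn <- copy_numbers[!is.na(copy_numbers)]
  if (!length(cn)) abort("classify_state: no copy numbers")
  if (all(cn < 2)) "loss" else if (all(cn > 2)) "gain" else "both"
}
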