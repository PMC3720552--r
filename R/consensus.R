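#' Three-level multi-caller consensus
#'
#' Finds loci supported by every detection algorithm. A locus is a connected
#' component of the overlap graph over ALL callers' calls (under `spec`).
#' Support is then required from all callers:
#' \describe{
#'   \item{population}{each caller has at least one supporting call at the
#'     locus, in any samples;}
#'   \item{breed}{at least one breed exists in which every caller has a
#'     supporting call;}
#'   \item{individual}{at least one sample exists in which every caller has
#'     a supporting call.}
#' }
#' One row is returned per qualifying locus; `n_pairs` carries the
#' per-breed (resp. per-sample) multiplicity, i.e. the number of
#' (locus, breed) or (locus, sample) support pairs, matching the convention
#' under which breed-level counts can exceed the population-level locus
#' count.
#'
#' @param calls Call tibble covering all callers (column `caller`).
#' @param samples Sample tibble mapping `sample_id` to `breed`; required for
#'   breed level, optional otherwise.
#' @param level `"population"`, `"breed"` or `"individual"`.
#' @param spec An [overlap_spec()].
#' @param callers Character vector of required caller names; defaults to the
#'   callers present in `calls`, or the canonical three when `calls` spans
#'   them.
#' @return Tibble with one row per consensus locus: `level`, `chrom`,
#'   `start`, `end` (union envelope of supporting calls), `state`,
#'   `n_calls`, `n_pairs`, `carriers`, `breeds`, `units` (list of qualifying
#'   breeds or samples), and per-caller support counts.
#' @export
consensus <- function(calls, samples = NULL,
                      level = c("population", "breed", "individual"),
                      spec = overlap_spec(), callers = NULL) {
  level <- match.arg(level)
  calls <- as_tibble(calls)
  if (is.null(callers)) {
    callers <- sort(unique(calls$caller))
    canonical <- c("cnvpartition", "penncnv", "quantisnp")
    if (all(canonical %in% callers)) callers <- canonical
  }
  empty <- tibble(level = character(), chrom = character(), start = numeric(),
                  end = numeric(), state = character(), n_calls = integer(),
                  n_pairs = integer(), carriers = list(), breeds = list(),
                  units = list())
  for (cl in callers) empty[[paste0("n_", cl)]] <- integer()

  bad_chrom <- !calls$chrom %in% .autosomes
  if (any(bad_chrom)) {
    warn(paste0("dropping ", sum(bad_chrom),
                " call(s) on non-autosomal chromosome(s)"))
    calls <- calls[!bad_chrom, ]
  }
  missing_caller <- setdiff(callers, unique(calls$caller))
  if (length(missing_caller)) {
    warn(paste0("caller(s) with zero calls genome-wide: ",
                paste(missing_caller, collapse = ", "),
                "; consensus is empty"))
    return(empty)
  }
  if (!nrow(calls)) return(empty)

  breed_of <- NULL
  if (level %in% c("breed", "individual") || !is.null(samples)) {
    if (is.null(samples) && level == "breed") {
      abort("consensus: breed level requires a samples table")
    }
    if (!is.null(samples)) {
      breed_of <- setNames(samples$breed, samples$sample_id)
      if (level == "breed") {
        unknown <- setdiff(unique(calls$sample_id), samples$sample_id)
        if (length(unknown)) {
          abort(paste0("consensus: sample(s) without breed: ",
                       paste(head(unknown, 3), collapse = ", ")))
        }
      }
    }
  }

  comp <- overlap_components(calls, spec)
  rows <- purrr::map(split(seq_len(nrow(calls)), comp), function(ix) {
    sub <- calls[ix, ]
    support <- split(sub, factor(sub$caller, levels = callers))
    if (!all(vapply(support, nrow, 1L) > 0)) return(NULL)
    units <- switch(level,
      population = "population",
      breed = {
        per_caller <- lapply(support, function(s) unique(breed_of[s$sample_id]))
        Reduce(intersect, per_caller)
      },
      individual = {
        per_caller <- lapply(support, function(s) unique(s$sample_id))
        Reduce(intersect, per_caller)
      })
    if (!length(units)) return(NULL)
    carriers <- sort(unique(sub$sample_id))
    carrier_breeds <- if (!is.null(breed_of)) {
      sort(unique(unname(breed_of[carriers])))
    } else character()
    out <- tibble(
      level = level, chrom = sub$chrom[1],
      start = min(sub$start), end = max(sub$end),
      state = classify_state(sub$copy_number),
      n_calls = nrow(sub),
      n_pairs = if (level == "population") 1L else length(units),
      carriers = list(carriers),
      breeds = list(carrier_breeds),
      units = list(sort(units))
    )
    for (cl in callers) out[[paste0("n_", cl)]] <- nrow(support[[cl]])
    out
  })
  rows <- purrr::compact(rows)
  if (!length(rows)) return(empty)
  out <- bind_rows(rows)
  out[order(chrom_rank(out$chrom), out$start, out$end), ]
}

#' Directional pairwise caller overlap fraction
#'
#' Fraction of calls in `calls_a` that have at least one call in `calls_b`
#' satisfying `spec` on the same chromosome. Asymmetric by construction:
#' swap the arguments for the other direction.
#'
#' @param calls_a,calls_b Call tibbles.
#' @param spec An [overlap_spec()].
#' @return A single fraction in `[0, 1]`.
#' @export
pairwise_overlap_fraction <- function(calls_a, calls_b, spec = overlap_spec()) {
  if (!nrow(calls_a)) abort("pairwise_overlap_fraction: empty first call set")
  hit <- has_hit(calls_a, calls_b, spec)
  mean(hit)
}

# logical per row of `query`: does any row of `subject` on the same
# chromosome satisfy `spec` against it?
has_hit <- function(query, subject, spec = overlap_spec()) {
  hit <- logical(nrow(query))
  if (!nrow(subject)) return(hit)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    for (i in qi) {
      hit[i] <- any(overlap_satisfies(query$start[i], query$end[i],
                                      subject$start[si], subject$end[si], spec))
    }
  }
  hit
}

#' Compare regions against an external CNV list
#'
#' For each chromosome present in the external list, the percentage of
#' external regions overlapped (any-overlap) by at least one of `my_regions`,
#' plus a `total` row over all external regions.
#'
#' @param my_regions Region tibble (`chrom`, `start`, `end`).
#' @param external_regions External region tibble in the same 1-based
#'   inclusive convention (BED input is converted on read).
#' @return Tibble with `chrom`, `n_external`, `n_overlapped`, `pct_overlap`.
#' @export
compare_external <- function(my_regions, external_regions) {
  ext <- as_tibble(external_regions)
  if (!nrow(ext)) {
    return(tibble(chrom = "total", n_external = 0L, n_overlapped = 0L,
                  pct_overlap = NA_real_))
  }
  hit <- has_hit(ext, my_regions, overlap_spec("any"))
  per <- ext %>%
    mutate(.hit = hit) %>%
    group_by(chrom = .data$chrom) %>%
    summarise(n_external = dplyr::n(), n_overlapped = sum(.data$.hit),
              .groups = "drop") %>%
    mutate(pct_overlap = 100 * .data$n_overlapped / .data$n_external)
  per <- per[order(chrom_rank(per$chrom)), ]
  total <- tibble(chrom = "total", n_external = nrow(ext),
                  n_overlapped = sum(hit),
                  pct_overlap = 100 * sum(hit) / nrow(ext))
  bind_rows(per, total)
}

#' Breed sharing matrix of consensus CNVs
#'
#' Counts, for every pair of breeds, the consensus CNVs carried by at least
#' one animal of each breed. The diagonal counts CNVs private to a single
#' breed.
#'
#' @param consensus_tbl Output of [consensus()] (column `carriers`).
#' @param samples Sample tibble mapping carriers to breeds.
#' @return Symmetric integer matrix with breed dimnames.
#' @export
breed_share_matrix <- function(consensus_tbl, samples) {
  breed_of <- setNames(samples$breed, samples$sample_id)
  breeds <- sort(unique(samples$breed))
  m <- matrix(0L, length(breeds), length(breeds),
              dimnames = list(breeds, breeds))
  for (carriers in consensus_tbl$carriers) {
    unknown <- setdiff(carriers, names(breed_of))
    if (length(unknown)) {
      abort(paste0("breed_share_matrix: carrier(s) with unknown breed: ",
                   paste(head(unknown, 3), collapse = ", ")))
    }
    bs <- sort(unique(unname(breed_of[carriers])))
    if (length(bs) == 1) {
      m[bs, bs] <- m[bs, bs] + 1L
    } else {
      for (i in seq_len(length(bs) - 1)) {
        for (j in seq(i + 1, length(bs))) {
          m[bs[i], bs[j]] <- m[bs[i], bs[j]] + 1L
          m[bs[j], bs[i]] <- m[bs[j], bs[i]] + 1L
        }
      }
    }
  }
  m
}

#' Mean sizes of shared versus private CNV calls
#'
#' A call is "shared" when at least one other sample has an overlapping
#' (any-overlap) call; otherwise it is private to its sample. Reports the
#' mean size (bp) of each class; an empty class yields `NA` with a flag.
#'
#' @param calls Call tibble from at least two samples.
#' @return Tibble with one row: `shared_mean_bp`, `private_mean_bp`,
#'   `n_shared`, `n_private`, `shared_defined`, `private_defined`.
#' @export
sharing_size_stats <- function(calls) {
  if (length(unique(calls$sample_id)) < 2) {
    abort("sharing_size_stats: calls from at least two samples required")
  }
  shared <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    ix <- which(calls$chrom == ch)
    for (i in ix) {
      others <- ix[calls$sample_id[ix] != calls$sample_id[i]]
      if (length(others)) {
        shared[i] <- any(overlap_bp(calls$start[i], calls$end[i],
                                    calls$start[others], calls$end[others]) >= 1)
      }
    }
  }
  sz <- interval_size(calls$start, calls$end)
  tibble(
    shared_mean_bp = if (any(shared)) mean(sz[shared]) else NA_real_,
    private_mean_bp = if (any(!shared)) mean(sz[!shared]) else NA_real_,
    n_shared = sum(shared), n_private = sum(!shared),
    shared_defined = any(shared), private_defined = any(!shared)
  )
}

#' Summary statistics of a consensus CNV table
#'
#' Row count, size-column summaries and loss-only/gain-only/both
#' classification counts for a consensus table (e.g. a transcribed published
#' consensus list). Sizes are taken from a `size` column when present, else
#' computed as `end - start + 1`.
#'
#' @param tbl Tibble with `state` in `{loss, gain, both}` and either `size`
#'   or `start`/`end`.
#' @return One-row tibble: `n`, `mean_size`, `median_size`, `min_size`,
#'   `max_size`, `n_loss_only`, `n_gain_only`, `n_both`.
#' @export
consensus_table_stats <- function(tbl) {
  tbl <- as_tibble(tbl)
  size <- if ("size" %in% names(tbl)) tbl$size else
    interval_size(tbl$start, tbl$end)
  if (!"state" %in% names(tbl)) abort("consensus_table_stats: need a state column")
  tibble(
    n = nrow(tbl),
    mean_size = mean(size), median_size = stats::median(size),
    min_size = min(size), max_size = max(size),
    n_loss_only = sum(tbl$state == "loss"),
    n_gain_only = sum(tbl$state == "gain"),
    n_both = sum(tbl$state == "both")
  )
}
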