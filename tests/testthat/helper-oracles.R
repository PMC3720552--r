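# Brute-force oracles used to cross-check the interval algebra. These stay
# deliberately naive (per-base set arithmetic, O(n^2) pair scans) and
# independent of the package's sweep/union-find implementation.

# quick constructor for call tibbles
mk_calls <- function(start, end, sample_id = "s1", caller = "penncnv",
                     chrom = "1", copy_number = 1L, n_probes = 10L,
                     score = 50) {
  tibble::tibble(sample_id = sample_id, caller = caller, chrom = chrom,
                 start = start, end = end, copy_number = copy_number,
                 n_probes = n_probes, score = score)
}

# per-base overlap count by explicit enumeration (small coordinates only)
brute_overlap_bp <- function(a_start, a_end, b_start, b_end) {
  length(intersect(seq(a_start, a_end), seq(b_start, b_end)))
}

# connected components of the overlap graph by O(n^2) union-find
brute_components <- function(iv, spec = overlap_spec()) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && iv$chrom[i] == iv$chrom[j] &&
          overlap_satisfies(iv$start[i], iv$end[i], iv$start[j], iv$end[j],
                            spec)) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  split(seq_len(n), roots)
}

# canonical form of a partition (set of sorted member index sets)
canon_partition <- function(groups) {
  unname(lapply(groups, sort))[order(vapply(groups, min, 1))]
}

# consensus loci by triple loop: returns per-component qualification at
# the given level
brute_consensus_loci <- function(calls, samples, level,
                                 spec = overlap_spec(),
                                 callers = c("cnvpartition", "penncnv",
                                             "quantisnp")) {
  groups <- brute_components(calls, spec)
  keep <- vapply(groups, function(ix) {
    sub <- calls[ix, ]
    ok_all <- all(vapply(callers, function(cl) any(sub$caller == cl), TRUE))
    if (!ok_all) return(FALSE)
    switch(level,
      population = TRUE,
      breed = {
        breeds <- unique(samples$breed)
        any(vapply(breeds, function(b) {
          ids <- samples$sample_id[samples$breed == b]
          all(vapply(callers, function(cl) {
            any(sub$caller == cl & sub$sample_id %in% ids)
          }, TRUE))
        }, TRUE))
      },
      individual = {
        any(vapply(unique(sub$sample_id), function(sid) {
          all(vapply(callers, function(cl) {
            any(sub$caller == cl & sub$sample_id == sid)
          }, TRUE))
        }, TRUE))
      })
  }, TRUE)
  groups[keep]
}

# markers covered by intervals, by explicit per-marker scan
brute_marker_count <- function(starts, ends, pos) {
  sum(vapply(pos, function(p) any(p >= starts & p <= ends), TRUE))
}

# random small call sets on coordinates <= max_pos
random_calls <- function(n, n_samples = 4, max_pos = 10000, chroms = c("1", "2"),
                         callers = c("cnvpartition", "penncnv", "quantisnp")) {
  start <- sample.int(max_pos - 50, n, replace = TRUE)
  len <- sample.int(300, n, replace = TRUE)
  mk_calls(start = start, end = pmin(start + len, max_pos),
           sample_id = sample(paste0("s", seq_len(n_samples)), n, replace = TRUE),
           caller = sample(callers, n, replace = TRUE),
           chrom = sample(chroms, n, replace = TRUE),
           copy_number = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE))
}
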