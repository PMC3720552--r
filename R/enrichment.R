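#' Per-chromosome CNV-region coverage and enrichment
#'
#' For each autosome in the SNP map, counts the markers covered by CNV
#' regions and divides by the chromosome length (SNP density per bp). The
#' genome-wide density (total covered markers / total autosome length) is
#' the standard: a chromosome is flagged enriched when its density strictly
#' exceeds the genome density. The bp coverage percentage is reported
#' alongside for reference but does not drive the flag.
#'
#' @param regions Region tibble, disjoint per chromosome (see
#'   [merge_to_regions()]).
#' @param snp_map A [read_snp_map()] map with chromosome lengths.
#' @return Tibble with one row per chromosome (`chrom`, `n_regions`,
#'   `n_snps_in_cnvr`, `chrom_length`, `snp_density`, `bp_coverage_pct`,
#'   `genome_snp_density`, `enriched`) plus a `total` row.
#' @export
coverage_table <- function(regions, snp_map) {
  lens <- chrom_lengths(snp_map)
  chroms <- names(lens)
  regions <- as_tibble(regions)
  if (nrow(regions)) {
    len_of <- lens[regions$chrom]
    if (anyNA(len_of)) abort("coverage_table: region on chromosome absent from the SNP map")
    if (any(regions$end > len_of)) {
      abort("coverage_table: region extends beyond its chromosome length")
    }
  }
  rows <- purrr::map(chroms, function(ch) {
    reg <- regions[regions$chrom == ch, ]
    pos <- snp_map$pos[snp_map$chrom == ch]
    n_in <- count_markers_in(reg$start, reg$end, pos)
    tibble(chrom = ch, n_regions = nrow(reg), n_snps_in_cnvr = n_in,
           chrom_length = unname(lens[ch]),
           snp_density = n_in / unname(lens[ch]),
           bp_coverage_pct = 100 * sum(interval_size(reg$start, reg$end)) /
             unname(lens[ch]))
  })
  out <- bind_rows(rows)
  genome_density <- sum(out$n_snps_in_cnvr) / sum(out$chrom_length)
  out$genome_snp_density <- genome_density
  out$enriched <- out$snp_density > genome_density
  total <- tibble(chrom = "total", n_regions = sum(out$n_regions),
                  n_snps_in_cnvr = sum(out$n_snps_in_cnvr),
                  chrom_length = sum(out$chrom_length),
                  snp_density = genome_density,
                  bp_coverage_pct = 100 *
                    sum(out$bp_coverage_pct * out$chrom_length / 100) /
                    sum(out$chrom_length),
                  genome_snp_density = genome_density, enriched = NA)
  bind_rows(out, total)
}

# markers (sorted positions) covered by any of the inclusive intervals;
# intervals assumed disjoint on the chromosome
count_markers_in <- function(starts, ends, pos) {
  if (!length(starts) || !length(pos)) return(0L)
  pos <- sort(pos)
  sum(vapply(seq_along(starts), function(i) {
    findInterval(ends[i], pos) - findInterval(starts[i] - 1, pos)
  }, 1))
}

#' Permutation test for chromosomal CNV enrichment
#'
#' Empirical null for the per-chromosome SNP-density statistic: region
#' lengths are preserved, each region is reassigned to a chromosome with
#' probability proportional to chromosome length (among chromosomes it fits
#' on) and given a uniform start. The p-value per chromosome is the add-one
#' corrected fraction of placements whose SNP density reaches the observed
#' density.
#'
#' @inheritParams coverage_table
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (mandatory; the draw is fully reproducible).
#' @return Tibble `chrom`, `observed_density`, `perm_p`.
#' @export
permutation_enrichment <- function(regions, snp_map, n_perm = 1000, seed) {
  if (missing(seed)) abort("permutation_enrichment: seed is required")
  if (n_perm < 100) abort("permutation_enrichment: n_perm must be >= 100")
  lens <- chrom_lengths(snp_map)
  chroms <- names(lens)
  sizes0 <- interval_size(regions$start, regions$end)
  if (length(sizes0) && any(vapply(sizes0, function(s) all(s > lens), TRUE))) {
    abort("permutation_enrichment: a region is longer than every chromosome")
  }
  obs <- coverage_table(regions, snp_map)
  obs <- obs[obs$chrom != "total", ]
  pos_by_chrom <- lapply(chroms, function(ch) sort(snp_map$pos[snp_map$chrom == ch]))
  names(pos_by_chrom) <- chroms
  sizes <- sizes0
  exceed <- setNames(numeric(length(chroms)), chroms)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      counts <- setNames(numeric(length(chroms)), chroms)
      for (s in sizes) {
        fit <- lens >= s
        w <- lens * fit
        ch <- sample(chroms, 1, prob = w / sum(w))
        st <- floor(runif(1, min = 1, max = lens[[ch]] - s + 1 + 1))
        en <- st + s - 1
        pos <- pos_by_chrom[[ch]]
        counts[ch] <- counts[ch] +
          (findInterval(en, pos) - findInterval(st - 1, pos))
      }
      dens <- counts / lens[chroms]
      exceed <- exceed + (dens >= obs$snp_density[match(chroms, obs$chrom)])
    }
  })
  tibble(chrom = chroms,
         observed_density = unname(obs$snp_density[match(chroms, obs$chrom)]),
         perm_p = unname((1 + exceed) / (n_perm + 1)))
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
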