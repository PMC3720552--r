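#' Build a region-by-sample copy-number matrix
#'
#' Every sample defaults to the diploid copy number 2 at every region. Where
#' a sample has one or more calls overlapping a region (any-overlap), its
#' entry is the minimum copy number among those calls (the stated tie rule:
#' a homozygous deletion dominates a heterozygous one).
#'
#' @param regions Region tibble, disjoint per chromosome.
#' @param calls Filtered call tibble (one caller or a chosen set).
#' @param samples Sample tibble; its `sample_id` column fixes the matrix
#'   columns.
#' @return A `cnv_genotypes` list: `cn` (integer matrix regions x samples),
#'   `regions` (tibble with `region_id`, `chrom`, `start`, `end`).
#' @export
build_genotypes <- function(regions, calls, samples) {
  regions <- as_tibble(regions)
  sample_ids <- samples$sample_id
  region_id <- paste0(regions$chrom, ":", format(regions$start, scientific = FALSE, trim = TRUE),
                      "-", format(regions$end, scientific = FALSE, trim = TRUE))
  cn <- matrix(2L, nrow = nrow(regions), ncol = length(sample_ids),
               dimnames = list(region_id, sample_ids))
  if (nrow(calls) && nrow(regions)) {
    calls <- calls[calls$sample_id %in% sample_ids, ]
    for (i in seq_len(nrow(regions))) {
      same <- calls$chrom == regions$chrom[i]
      if (!any(same)) next
      ov <- same & overlap_bp(regions$start[i], regions$end[i],
                              calls$start, calls$end) >= 1
      if (!any(ov)) next
      mins <- tapply(calls$copy_number[ov], calls$sample_id[ov], min)
      cn[i, names(mins)] <- as.integer(mins)
    }
  }
  structure(list(cn = cn,
                 regions = tibble(region_id = region_id,
                                  chrom = regions$chrom,
                                  start = regions$start, end = regions$end)),
            class = "cnv_genotypes")
}

#' CNV-region association scan for a quantitative trait
#'
#' Per region, ordinary least squares of the trait on copy-number dosage
#' with breed fixed effects, computed by within-breed centering
#' (Frisch-Waugh), which is numerically identical to the full design. The
#' pointwise p comes from the t distribution of the dosage coefficient.
#' Family-wise significance uses max-statistic permutation: the trait is
#' shuffled WITHIN breed, and for each permutation the maximum |t| over all
#' regions (genome-wide) or over the region's chromosome (chromosome-wide)
#' forms the null. Permutation p-values are add-one corrected.
#'
#' @param genotypes A [build_genotypes()] object.
#' @param samples Sample tibble with `height_cm` (the trait) and `breed`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (mandatory).
#' @param min_carriers Regions with fewer non-diploid samples (among trait
#'   samples) are skipped and logged (default 5).
#' @param coding `"dosage"` (copy number 0-4, capped) or `"deletion"`
#'   (indicator of copy number < 2).
#' @return A `cnv_assoc` object; see [tidy.cnv_assoc()]. `beta` is the trait
#'   change in cm per copy-number unit; for a deletion that increases the
#'   trait, `beta` is negative and `direction` reads
#'   `"deletion-increases-trait"`.
#' @export
assoc_scan <- function(genotypes, samples, n_perm = 1000, seed,
                       min_carriers = 5, coding = c("dosage", "deletion")) {
  coding <- match.arg(coding)
  if (missing(seed)) abort("assoc_scan: seed is required")
  keep <- !is.na(samples$height_cm) & samples$sample_id %in% colnames(genotypes$cn)
  ss <- samples[keep, ]
  if (nrow(ss) < 3) abort("assoc_scan: too few samples with trait values")
  y <- ss$height_cm
  if (stats::var(y) == 0) abort("assoc_scan: zero-variance trait")
  breed <- factor(ss$breed)
  singletons <- names(which(table(breed) == 1))
  if (length(singletons)) {
    warn(paste0("assoc_scan: breed(s) with a single sample (",
                paste(singletons, collapse = ", "),
                "); their indicator is saturated and the sample carries no",
                " information on the dosage effect"))
  }
  cn <- genotypes$cn[, ss$sample_id, drop = FALSE]
  x <- switch(coding,
              dosage = pmin(cn, 4L),
              deletion = (cn < 2L) * 1L)
  n_carriers <- rowSums(cn != 2L)
  test <- n_carriers >= min_carriers
  skipped <- tibble(region_id = rownames(cn)[!test],
                    n_carriers = n_carriers[!test],
                    reason = "min_carriers")

  res <- genotypes$regions
  res$n_carriers <- n_carriers
  res$beta <- NA_real_; res$se <- NA_real_; res$t_stat <- NA_real_
  res$p_point <- NA_real_; res$p_chrom <- NA_real_; res$p_genome <- NA_real_
  res$direction <- NA_character_

  if (any(test)) {
    # within-breed centering == projecting out breed fixed effects
    center <- function(v) v - ave(v, breed)
    yc <- center(y)
    Xc <- t(apply(x[test, , drop = FALSE], 1, center))
    if (sum(test) == 1) Xc <- matrix(Xc, nrow = 1)
    n <- length(y)
    k <- nlevels(droplevels(breed))
    df <- n - k - 1
    if (df < 1) abort("assoc_scan: not enough residual degrees of freedom")
    Sxx <- rowSums(Xc^2)
    Syy <- sum(yc^2)
    degenerate <- Sxx < .Machine$double.eps  # dosage constant within breeds
    t_of <- function(yvec) {
      Sxy <- as.vector(Xc %*% yvec)
      beta <- Sxy / Sxx
      s2 <- pmax(Syy - beta * Sxy, 0) / df
      tt <- beta / sqrt(s2 / Sxx)
      tt[degenerate | !is.finite(tt)] <- 0
      list(beta = beta, t = tt, s2 = s2)
    }
    obs <- t_of(yc)
    res$beta[test] <- obs$beta
    res$se[test] <- sqrt(obs$s2 / Sxx)
    res$t_stat[test] <- obs$t
    res$p_point[test] <- 2 * pt(abs(obs$t), df = df, lower.tail = FALSE)
    res$direction[test] <- ifelse(
      obs$beta < 0, "deletion-increases-trait", "deletion-decreases-trait")
    if (coding == "deletion") {
      # deletion indicator: positive beta means carriers are larger
      res$direction[test] <- ifelse(
        obs$beta > 0, "deletion-increases-trait", "deletion-decreases-trait")
    }

    chrom_t <- res$chrom[test]
    abs_obs <- abs(obs$t)
    exceed_genome <- numeric(sum(test))
    exceed_chrom <- numeric(sum(test))
    idx_by_chrom <- split(seq_len(sum(test)), chrom_t)
    with_seed(seed, {
      # permute centered trait within breed: per-breed means stay exactly 0
      breed_idx <- split(seq_len(n), breed)
      Y <- matrix(0, n, n_perm)
      for (p in seq_len(n_perm)) {
        yp <- yc
        for (bi in breed_idx) if (length(bi) > 1) yp[bi] <- yc[sample(bi)]
        Y[, p] <- yp
      }
      Sxy <- Xc %*% Y                              # regions x perms
      Beta <- Sxy / Sxx
      S2 <- pmax(Syy - Beta * Sxy, 0) / df
      Tm <- abs(Beta / sqrt(S2 / Sxx))
      Tm[degenerate | !is.finite(Tm)] <- 0
      max_genome <- apply(Tm, 2, max)
      exceed_genome <- vapply(abs_obs, function(t0) sum(max_genome >= t0), 1)
      for (ch in names(idx_by_chrom)) {
        ix <- idx_by_chrom[[ch]]
        mx <- apply(Tm[ix, , drop = FALSE], 2, max)
        exceed_chrom[ix] <- vapply(abs_obs[ix], function(t0) sum(mx >= t0), 1)
      }
    })
    res$p_genome[test] <- (1 + exceed_genome) / (n_perm + 1)
    res$p_chrom[test] <- (1 + exceed_chrom) / (n_perm + 1)
  }

  structure(list(results = res[test, ],
                 all_regions = res, skipped = skipped,
                 n_samples = nrow(ss), n_perm = n_perm, seed = seed,
                 coding = coding, df = if (any(test)) df else NA_integer_),
            class = "cnv_assoc")
}

#' @export
print.cnv_assoc <- function(x, ...) {
  cat("CNV-trait association scan\n")
  cat("  samples:", x$n_samples, "  regions tested:",
      sum(!is.na(x$all_regions$p_point)), "  permutations:", x$n_perm,
      "  coding:", x$coding, "\n")
  tested <- x$all_regions[!is.na(x$all_regions$p_point), ]
  if (nrow(tested)) {
    top <- tested[order(tested$p_genome, tested$p_point), ][1, ]
    cat(sprintf("  top hit: %s  beta=%.2f  p_genome=%.4g (%s)\n",
                top$region_id, top$beta, top$p_genome, top$direction))
  }
  invisible(x)
}

#' Tidy an association scan
#'
#' @param x A `cnv_assoc` object.
#' @param ... Unused.
#' @return Tibble with one row per region (tested or skipped): coordinates,
#'   `n_carriers`, `beta`, `se`, `t_stat`, `p_point`, `p_chrom`, `p_genome`,
#'   `direction`.
#' @method tidy cnv_assoc
#' @export
tidy.cnv_assoc <- function(x, ...) as_tibble(x$all_regions)

#' One-row summary of an association scan
#'
#' @inheritParams tidy.cnv_assoc
#' @return Tibble: sample count, tested/skipped region counts, permutation
#'   count, smallest genome-wide p and its region.
#' @method glance cnv_assoc
#' @export
glance.cnv_assoc <- function(x, ...) {
  tested <- x$all_regions[!is.na(x$all_regions$p_point), ]
  top <- if (nrow(tested)) tested[order(tested$p_genome, tested$p_point), ][1, ] else NULL
  tibble(n_samples = x$n_samples,
         n_tested = nrow(tested),
         n_skipped = nrow(x$skipped),
         n_perm = x$n_perm,
         min_p_genome = if (!is.null(top)) top$p_genome else NA_real_,
         top_region = if (!is.null(top)) top$region_id else NA_character_)
}
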