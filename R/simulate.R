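#' Caller error profile
#'
#' Describes how one detection algorithm degrades the true CNV landscape:
#' per-event detection probability, Poisson rate of spurious calls per
#' sample, Gaussian breakpoint jitter, and the distribution of the emitted
#' confidence score (so quality filters have something to cut). The default
#' trio makes CNVPartition the low-yield caller and QuantiSNP the
#' high-yield one, mirroring the very different yields the three algorithms
#' produce on real array data.
#'
#' @param name Caller name.
#' @param sensitivity Detection probability per true (sample, locus) event.
#' @param fp_per_sample Mean count of spurious calls per sample.
#' @param jitter_sd Breakpoint noise sd in bp.
#' @param score_mean,score_sd Normal parameters of the emitted score;
#'   `NA` emits no score (PennCNV confidence is optional).
#' @return A `caller_profile` list.
#' @export
caller_profile <- function(name, sensitivity, fp_per_sample = 0,
                           jitter_sd = 0, score_mean = NA, score_sd = NA) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_per_sample >= 0,
            jitter_sd >= 0)
  structure(list(name = name, sensitivity = sensitivity,
                 fp_per_sample = fp_per_sample, jitter_sd = jitter_sd,
                 score_mean = score_mean, score_sd = score_sd),
            class = "caller_profile")
}

default_profiles <- function() {
  list(
    cnvpartition = caller_profile("cnvpartition", sensitivity = 0.2,
                                  fp_per_sample = 0.1, jitter_sd = 5000,
                                  score_mean = 55, score_sd = 15),
    penncnv = caller_profile("penncnv", sensitivity = 0.7,
                             fp_per_sample = 0.4, jitter_sd = 5000,
                             score_mean = NA, score_sd = NA),
    quantisnp = caller_profile("quantisnp", sensitivity = 0.8,
                               fp_per_sample = 0.6, jitter_sd = 5000,
                               score_mean = 30, score_sd = 12)
  )
}

#' Noiseless caller profiles
#'
#' Sensitivity 1, no false positives, no breakpoint jitter, scores far above
#' every filter threshold. With these profiles the pipeline must reproduce
#' the planted truth exactly.
#' @return Named list of three [caller_profile()]s.
#' @export
noiseless_profiles <- function() {
  list(
    cnvpartition = caller_profile("cnvpartition", 1, 0, 0, 60, 0),
    penncnv = caller_profile("penncnv", 1, 0, 0, NA, NA),
    quantisnp = caller_profile("quantisnp", 1, 0, 0, 50, 0)
  )
}

#' Simulation configuration
#'
#' Defines the synthetic study: a scaled genome (default 5 autosomes of
#' 10 Mb carrying 2,000 markers), a breed-structured cohort with
#' per-breed mean withers heights (Arabian 148 cm, Lusitano 160 cm,
#' Hanoverian 168 cm), a CNV landscape whose log-normal size distribution
#' is parameterised by its median (169,367 bp) and mean (487,562 bp), a
#' planted deletion that increases height, and the three caller error
#' profiles. [sim_config_paper_scale()] switches to a 31-autosome,
#' 48,860-marker, 717-sample layout for slow runs.
#'
#' @param seed Integer seed; mandatory, every generator is a pure function
#'   of (config, seed).
#' @param n_chrom Number of autosomes.
#' @param chrom_lengths Named numeric vector of lengths (bp); default
#'   `n_chrom` chromosomes of 10 Mb labelled `1..n_chrom`.
#' @param n_snps Total marker count, allocated proportionally to length.
#' @param breeds Tibble with `breed`, `n_samples`, `mean_height_cm`.
#' @param n_cnv_loci Number of disjoint true CNV loci.
#' @param size_median,size_mean Log-normal size parameters in bp.
#' @param loss_fraction Fraction of loci that are losses.
#' @param carrier_freq_min,carrier_freq_max Range of per-locus carrier
#'   frequencies; frequencies are rank-coupled to locus size (larger loci
#'   are carried more widely, so sharing correlates with length).
#' @param causal_locus List `(index, beta_cm, carrier_freq)`: the loss locus
#'   whose deletion increases height by `beta_cm` cm per lost copy;
#'   `carrier_freq` optionally pins its frequency.
#' @param trait_sd Within-breed residual sd of height (cm).
#' @param bad_sample_rate Fraction of samples given failing QC metrics.
#' @param caller_profiles Named list of three [caller_profile()]s.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chrom = 5,
                       chrom_lengths = NULL,
                       n_snps = 2000,
                       breeds = tibble(
                         breed = c("Arabian", "Hanoverian", "Lusitano"),
                         n_samples = c(60, 100, 40),
                         mean_height_cm = c(148, 168, 160)),
                       n_cnv_loci = 20,
                       size_median = 169367,
                       size_mean = 487562,
                       loss_fraction = 0.6,
                       carrier_freq_min = 0.05,
                       carrier_freq_max = 0.40,
                       causal_locus = list(index = 1, beta_cm = 4,
                                           carrier_freq = 0.15),
                       trait_sd = 3,
                       bad_sample_rate = 0.02,
                       caller_profiles = default_profiles()) {
  if (missing(seed)) abort("sim_config: seed is mandatory")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(rep(1e7, n_chrom), as.character(seq_len(n_chrom)))
  }
  stopifnot(n_snps >= length(chrom_lengths), n_cnv_loci >= 1,
            size_mean >= size_median, loss_fraction >= 0, loss_fraction <= 1,
            trait_sd >= 0)
  structure(list(seed = as.integer(seed), n_chrom = length(chrom_lengths),
                 chrom_lengths = chrom_lengths, n_snps = n_snps,
                 breeds = as_tibble(breeds), n_cnv_loci = n_cnv_loci,
                 size_median = size_median, size_mean = size_mean,
                 loss_fraction = loss_fraction,
                 carrier_freq_min = carrier_freq_min,
                 carrier_freq_max = carrier_freq_max,
                 causal_locus = causal_locus, trait_sd = trait_sd,
                 bad_sample_rate = bad_sample_rate,
                 caller_profiles = caller_profiles),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_paper_scale <- function(seed, ...) {
  sim_config(seed,
             chrom_lengths = setNames(round(seq(1.9e8, 2.5e7,
                                                length.out = 31)),
                                      as.character(1:31)),
             n_snps = 48860,
             breeds = tibble(
               breed = c("Arabian", "Hanoverian", "Lusitano", "Maremanno",
                         "Westphalian", "Thoroughbred", "Oldenburg",
                         "Holsteiner"),
               n_samples = c(87, 458, 47, 44, 29, 13, 11, 28),
               mean_height_cm = c(148, 168, 160, 160, 168, 163, 168, 168)),
             n_cnv_loci = 60, ...)
}

#' Draw CNV sizes from the configured log-normal
#'
#' Parameterised by the target median and mean (the statistics typically
#' reported for array CNV size distributions): meanlog = log(median),
#' sdlog^2 = 2 log(mean/median).
#'
#' @param n Number of draws.
#' @param size_median,size_mean Target median and mean in bp.
#' @return Numeric sizes (bp, >= 1).
#' @export
rcnv_sizes <- function(n, size_median = 169367, size_mean = 487562) {
  pmax(1, rlnorm(n, meanlog = log(size_median),
                 sdlog = sqrt(2 * log(size_mean / size_median))))
}

#' Generate a SNP map
#'
#' Markers are allocated to chromosomes proportionally to length (largest
#' remainder, deterministic) and placed uniformly at random within each
#' chromosome.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A `snp_map` (see [read_snp_map()]).
#' @export
gen_genome <- function(config, seed = config$seed) {
  lens <- config$chrom_lengths
  share <- config$n_snps * lens / sum(lens)
  n_per <- floor(share)
  rem <- config$n_snps - sum(n_per)
  if (rem > 0) {
    extra <- order(share - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1
  }
  with_seed(seed, {
    rows <- purrr::map(names(lens), function(ch) {
      k <- n_per[[ch]]
      pos <- sort(sample.int(lens[[ch]], k))
      tibble(name = sprintf("SNP_%s_%06d", ch, seq_len(k)),
             chrom = ch, pos = as.numeric(pos))
    })
    new_snp_map(bind_rows(rows), chrom_lengths = lens)
  })
}

#' Generate cohort sample records
#'
#' Sample ids, breeds per the configured breed table, and array QC metrics;
#' a `bad_sample_rate` fraction receives a failing metric (low call rate,
#' high SD(LRR) or high |GCWF|) so the QC stage has work to do.
#'
#' @inheritParams gen_genome
#' @return Sample tibble (heights `NA` until [gen_trait()]).
#' @export
gen_samples <- function(config, seed = config$seed + 1L) {
  br <- config$breeds
  n <- sum(br$n_samples)
  samples <- tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    breed = rep(br$breed, br$n_samples),
    height_cm = NA_real_
  )
  with_seed(seed, {
    samples$call_rate <- runif(n, 0.95, 0.999)
    samples$sd_lrr <- runif(n, 0.08, 0.25)
    samples$gcwf <- runif(n, -0.015, 0.015)
    bad <- runif(n) < config$bad_sample_rate
    which_rule <- sample(c("call_rate", "sd_lrr", "gcwf"), sum(bad),
                         replace = TRUE)
    samples$call_rate[bad][which_rule == "call_rate"] <- 0.85
    samples$sd_lrr[bad][which_rule == "sd_lrr"] <- 0.35
    samples$gcwf[bad][which_rule == "gcwf"] <- 0.03
  })
  samples
}

#' Generate the true CNV landscape
#'
#' Places `n_cnv_loci` disjoint loci: sizes from the configured log-normal,
#' chromosome chosen proportionally to length, uniform start, each locus
#' required to span at least 3 markers (so it is detectable under the
#' minimum-probe filter). Loci are losses with probability `loss_fraction`
#' (the causal locus is forced to be a loss). Carrier frequencies are
#' rank-coupled to size; carriers of a loss get copy number 1 (10%
#' homozygous 0), carriers of a gain get 3.
#'
#' @inheritParams gen_genome
#' @param snp_map A `snp_map` from [gen_genome()].
#' @param samples Sample tibble from [gen_samples()].
#' @return List with `loci` (tibble `locus_id`, `chrom`, `start`, `end`,
#'   `size`, `state`, `carrier_freq`, `n_markers`) and `carriers` (tibble
#'   `locus_id`, `sample_id`, `cn`).
#' @export
gen_truth <- function(config, snp_map, samples, seed = config$seed + 2L) {
  lens <- config$chrom_lengths
  pos_by_chrom <- lapply(names(lens),
                         function(ch) sort(snp_map$pos[snp_map$chrom == ch]))
  names(pos_by_chrom) <- names(lens)
  n_loci <- config$n_cnv_loci
  with_seed(seed, {
    loci <- vector("list", n_loci)
    placed <- tibble(chrom = character(), start = numeric(), end = numeric())
    attempts <- 0L
    i <- 1L
    while (i <= n_loci) {
      attempts <- attempts + 1L
      if (attempts > 200L * n_loci) {
        abort(paste0("gen_truth: cannot place ", n_loci, " disjoint loci; ",
                     "reduce n_cnv_loci or the size distribution"))
      }
      size <- round(rcnv_sizes(1, config$size_median, config$size_mean))
      fit <- lens >= size
      if (!any(fit)) next
      w <- lens * fit
      ch <- sample(names(lens), 1, prob = w / sum(w))
      st <- floor(runif(1, 1, lens[[ch]] - size + 2))
      en <- st + size - 1
      pos <- pos_by_chrom[[ch]]
      n_mark <- findInterval(en, pos) - findInterval(st - 1, pos)
      if (n_mark < 3) next
      same <- placed$chrom == ch
      if (any(same & overlap_bp(st, en, placed$start, placed$end) > 0)) next
      placed <- bind_rows(placed, tibble(chrom = ch, start = st, end = en))
      loci[[i]] <- tibble(chrom = ch, start = st, end = en, size = size,
                          n_markers = n_mark)
      i <- i + 1L
    }
    loci <- bind_rows(loci)
    loci <- loci[order(chrom_rank(loci$chrom), loci$start), ]
    loci$locus_id <- sprintf("L%03d", seq_len(n_loci))
    loci$state <- ifelse(runif(n_loci) < config$loss_fraction, "loss", "gain")
    ci <- config$causal_locus$index
    if (ci < 1 || ci > n_loci) abort("gen_truth: causal locus index out of range")
    loci$state[ci] <- "loss"
    # larger loci are carried more widely: frequency rank-coupled to size
    fr <- config$carrier_freq_min +
      (config$carrier_freq_max - config$carrier_freq_min) *
      (rank(loci$size, ties.method = "first") - 1) / max(1, n_loci - 1)
    loci$carrier_freq <- fr
    if (!is.null(config$causal_locus$carrier_freq)) {
      loci$carrier_freq[ci] <- config$causal_locus$carrier_freq
    }
    carriers <- purrr::map(seq_len(n_loci), function(j) {
      is_carrier <- runif(nrow(samples)) < loci$carrier_freq[j]
      if (!any(is_carrier)) return(NULL)
      ids <- samples$sample_id[is_carrier]
      cn <- if (loci$state[j] == "loss") {
        ifelse(runif(length(ids)) < 0.1, 0L, 1L)
      } else rep(3L, length(ids))
      tibble(locus_id = loci$locus_id[j], sample_id = ids, cn = cn)
    })
    list(loci = loci[c("locus_id", "chrom", "start", "end", "size", "state",
                       "carrier_freq", "n_markers")],
         carriers = bind_rows(purrr::compact(carriers)))
  })
}

#' Generate three caller-specific call sets from the truth
#'
#' Each true (sample, locus) event is detected with the profile's
#' sensitivity; detected breakpoints are jittered by Normal(0, jitter_sd)
#' and snapped back to the true interval whenever the jittered one would
#' span fewer than 3 markers. False positives are placed uniformly,
#' never overlapping true loci (so sensitivity and false-positive rate stay
#' identifiable). Copy number is preserved on true detections; scores are
#' drawn from the profile's score distribution.
#'
#' @param truth Output of [gen_truth()].
#' @param snp_map The `snp_map` used to generate the truth.
#' @param config A [sim_config()] (chromosome lengths, size distribution).
#' @param profiles Named list of [caller_profile()]s; defaults to
#'   `config$caller_profiles`.
#' @param seed Seed; defaults to `config$seed + 3`.
#' @return Call tibble spanning the three callers.
#' @export
gen_caller_calls <- function(truth, snp_map, config,
                             profiles = config$caller_profiles,
                             seed = config$seed + 3L) {
  lens <- config$chrom_lengths
  pos_by_chrom <- lapply(names(lens),
                         function(ch) sort(snp_map$pos[snp_map$chrom == ch]))
  names(pos_by_chrom) <- names(lens)
  loci <- truth$loci
  carriers <- truth$carriers %>% left_join(loci, by = "locus_id")
  samples_all <- unique(carriers$sample_id)
  with_seed(seed, {
    out <- purrr::map(profiles, function(pf) {
      det <- carriers[runif(nrow(carriers)) < pf$sensitivity, ]
      calls <- NULL
      if (nrow(det)) {
        st <- round(det$start + rnorm(nrow(det), 0, pf$jitter_sd))
        en <- round(det$end + rnorm(nrow(det), 0, pf$jitter_sd))
        st <- pmax(1, pmin(st, en))
        en <- pmin(pmax(en, st), unname(lens[det$chrom]))
        st <- pmin(st, en)
        n_mark <- vapply(seq_len(nrow(det)), function(i) {
          pos <- pos_by_chrom[[det$chrom[i]]]
          findInterval(en[i], pos) - findInterval(st[i] - 1, pos)
        }, 1)
        snap <- n_mark < 3
        st[snap] <- det$start[snap]
        en[snap] <- det$end[snap]
        n_mark[snap] <- det$n_markers[snap]
        calls <- tibble(sample_id = det$sample_id, caller = pf$name,
                        chrom = det$chrom, start = st, end = en,
                        copy_number = det$cn, n_probes = as.integer(n_mark),
                        score = if (is.na(pf$score_mean)) NA_real_ else
                          pmax(0, rnorm(nrow(det), pf$score_mean, pf$score_sd)))
      }
      n_fp <- rpois(length(samples_all), pf$fp_per_sample)
      fp_rows <- NULL
      if (sum(n_fp) > 0) {
        fp_sample <- rep(samples_all, n_fp)
        fp <- purrr::map(fp_sample, function(sid) {
          for (try in 1:50) {
            size <- round(rcnv_sizes(1, config$size_median / 3,
                                     config$size_mean / 3))
            fitc <- lens >= size
            if (!any(fitc)) next
            w <- lens * fitc
            ch <- sample(names(lens), 1, prob = w / sum(w))
            st <- floor(runif(1, 1, lens[[ch]] - size + 2))
            en <- st + size - 1
            same <- loci$chrom == ch
            if (any(same & overlap_bp(st, en, loci$start, loci$end) > 0)) next
            pos <- pos_by_chrom[[ch]]
            n_mark <- findInterval(en, pos) - findInterval(st - 1, pos)
            return(tibble(sample_id = sid, caller = pf$name, chrom = ch,
                          start = st, end = en,
                          copy_number = sample(c(1L, 3L), 1),
                          n_probes = as.integer(n_mark),
                          score = if (is.na(pf$score_mean)) NA_real_ else
                            pmax(0, rnorm(1, pf$score_mean, pf$score_sd))))
          }
          NULL
        })
        fp_rows <- bind_rows(purrr::compact(fp))
      }
      bind_rows(calls, fp_rows)
    })
    calls <- bind_rows(out)
    calls[order(chrom_rank(calls$chrom), calls$start, calls$end,
                calls$sample_id), ]
  })
}

#' Generate the height trait
#'
#' height = breed mean + beta_cm x (2 - copy number at the causal locus)
#' + Normal(0, trait_sd). A heterozygous deletion carrier (copy number 1)
#' is therefore `beta_cm` cm taller than its breed mean on average.
#'
#' @param truth Output of [gen_truth()].
#' @param samples Sample tibble from [gen_samples()].
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed + 4`.
#' @return `samples` with `height_cm` filled in.
#' @export
gen_trait <- function(truth, samples, config, seed = config$seed + 4L) {
  ci <- config$causal_locus$index
  if (ci < 1 || ci > nrow(truth$loci)) {
    abort("gen_trait: causal locus index out of range")
  }
  causal_id <- truth$loci$locus_id[ci]
  if (truth$loci$state[ci] != "loss") {
    abort("gen_trait: causal locus must be a loss locus")
  }
  cn <- setNames(rep(2L, nrow(samples)), samples$sample_id)
  cc <- truth$carriers[truth$carriers$locus_id == causal_id, ]
  cn[cc$sample_id] <- cc$cn
  mean_of <- setNames(config$breeds$mean_height_cm, config$breeds$breed)
  with_seed(seed, {
    samples$height_cm <- unname(mean_of[samples$breed] +
      config$causal_locus$beta_cm * (2 - cn[samples$sample_id]) +
      rnorm(nrow(samples), 0, config$trait_sd))
  })
  samples
}

#' Generate qPCR wells for one true locus
#'
#' Ct of the target assay follows the copy-number dose: Ct = base -
#' log2(cn / 2) + noise, with homozygous deletions (cn = 0) emitted as a
#' censored high Ct; the reference gene sits at a fixed base Ct. Two
#' replicates per well.
#'
#' @param truth Output of [gen_truth()].
#' @param locus_id True locus to assay.
#' @param sample_ids Samples to assay (should include the calibrator).
#' @param calibrator_sample A sample diploid at the locus.
#' @param noise_sd Ct noise sd in cycles (default 0.1).
#' @param seed Integer seed.
#' @param reference_assay Reference gene name (default `"GAPDH"`).
#' @return Well tibble (`sample_id`, `assay`, `replicate`, `ct`).
#' @export
gen_qpcr <- function(truth, locus_id, sample_ids, calibrator_sample,
                     noise_sd = 0.1, seed, reference_assay = "GAPDH") {
  if (missing(seed)) abort("gen_qpcr: seed is required")
  cc <- truth$carriers[truth$carriers$locus_id == locus_id, ]
  cn <- setNames(rep(2L, length(sample_ids)), sample_ids)
  hit <- intersect(cc$sample_id, sample_ids)
  cn[hit] <- cc$cn[match(hit, cc$sample_id)]
  if (cn[[calibrator_sample]] != 2L) {
    abort("gen_qpcr: calibrator sample is not diploid at this locus")
  }
  base_target <- 25; base_ref <- 20; censored_ct <- 38
  with_seed(seed, {
    rows <- purrr::map(sample_ids, function(sid) {
      ct_t <- if (cn[[sid]] == 0L) censored_ct else
        base_target - log2(cn[[sid]] / 2)
      tibble(sample_id = sid,
             assay = rep(c(locus_id, reference_assay), each = 2),
             replicate = rep(1:2, 2),
             ct = c(ct_t + rnorm(2, 0, noise_sd),
                    base_ref + rnorm(2, 0, noise_sd)))
    })
    bind_rows(rows)
  })
}

#' Copy-number matrix of the planted truth
#'
#' Builds the region-by-sample genotype matrix directly from the true CNV
#' genotypes (no caller noise), for parameter-recovery studies of the
#' association machinery.
#'
#' @param truth Output of [gen_truth()].
#' @param samples Sample tibble.
#' @return A `cnv_genotypes` object (see [build_genotypes()]).
#' @export
truth_genotypes <- function(truth, samples) {
  loci <- truth$loci
  region_id <- paste0(loci$chrom, ":",
                      format(loci$start, scientific = FALSE, trim = TRUE), "-",
                      format(loci$end, scientific = FALSE, trim = TRUE))
  cn <- matrix(2L, nrow(loci), nrow(samples),
               dimnames = list(region_id, samples$sample_id))
  for (j in seq_len(nrow(loci))) {
    cc <- truth$carriers[truth$carriers$locus_id == loci$locus_id[j], ]
    hit <- intersect(cc$sample_id, samples$sample_id)
    cn[j, hit] <- cc$cn[match(hit, cc$sample_id)]
  }
  structure(list(cn = cn,
                 regions = tibble(region_id = region_id, chrom = loci$chrom,
                                  start = loci$start, end = loci$end)),
            class = "cnv_genotypes")
}

#' Simulate a full study bundle
#'
#' Runs every generator in order under the config's seed: SNP map, cohort,
#' truth, three caller call sets and the height trait.
#'
#' @param config A [sim_config()].
#' @return List `config`, `snp_map`, `samples` (with heights), `truth`,
#'   `calls`.
#' @export
simulate_cohort <- function(config) {
  snp_map <- gen_genome(config)
  samples <- gen_samples(config)
  truth <- gen_truth(config, snp_map, samples)
  calls <- gen_caller_calls(truth, snp_map, config)
  samples <- gen_trait(truth, samples, config)
  list(config = config, snp_map = snp_map, samples = samples,
       truth = truth, calls = calls)
}
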