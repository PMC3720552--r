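test_that("genome generation is deterministic, length-proportional and degenerate-safe", {
  cfg <- sim_config(seed = 1, n_snps = 100,
                    chrom_lengths = c(`1` = 1e6, `2` = 1e6))
  sm1 <- gen_genome(cfg)
  sm2 <- gen_genome(cfg)
  expect_identical(as.data.frame(sm1), as.data.frame(sm2))
  # deterministic largest-remainder allocation: an even split here
  expect_equal(as.vector(table(sm1$chrom)[c("1", "2")]), c(50L, 50L))

  tiny <- sim_config(seed = 2, n_snps = 2, n_cnv_loci = 1,
                     chrom_lengths = c(`1` = 1e6, `2` = 1e6))
  sm <- gen_genome(tiny)
  expect_equal(as.vector(table(sm$chrom)), c(1L, 1L))
})

test_that("size distribution hits the configured median and mean within 5%", {
  set.seed(3)
  x <- rcnv_sizes(10000, 169367, 487562)
  expect_lt(abs(median(x) - 169367) / 169367, 0.05)
  expect_lt(abs(mean(x) - 487562) / 487562, 0.05)
})

test_that("truth generation respects loss fraction, marker floor and determinism", {
  cfg <- sim_config(seed = 4, loss_fraction = 1.0)
  sm <- gen_genome(cfg)
  samples <- gen_samples(cfg)
  truth <- gen_truth(cfg, sm, samples)
  expect_true(all(truth$loci$state == "loss"))
  expect_true(all(truth$loci$n_markers >= 3))
  expect_true(all(truth$carriers$cn < 2))
  truth2 <- gen_truth(cfg, sm, samples)
  expect_identical(truth, truth2)
  # loci are pairwise disjoint per chromosome
  by_chrom <- split(truth$loci, truth$loci$chrom)
  for (loc in by_chrom) {
    if (nrow(loc) > 1) {
      loc <- loc[order(loc$start), ]
      expect_true(all(loc$start[-1] > loc$end[-nrow(loc)]))
    }
  }
})

test_that("caller yields follow the configured sensitivity ordering", {
  ord_ok <- 0
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed)
    b <- simulate_cohort(cfg)
    yield <- table(factor(b$calls$caller,
                          levels = c("cnvpartition", "penncnv", "quantisnp")))
    if (yield[["cnvpartition"]] < yield[["penncnv"]] &&
        yield[["penncnv"]] < yield[["quantisnp"]]) ord_ok <- ord_ok + 1
  }
  expect_gte(ord_ok, 20 * 0.95)
})

test_that("noiseless profiles reproduce the planted truth exactly end to end", {
  cfg <- sim_config(seed = 6, caller_profiles = noiseless_profiles())
  b <- simulate_cohort(cfg)
  truth_keys <- paste(b$truth$loci$chrom, b$truth$loci$start, b$truth$loci$end)
  for (pf in names(noiseless_profiles())) {
    sub <- b$calls[b$calls$caller == pf, ]
    expect_true(all(paste(sub$chrom, sub$start, sub$end) %in% truth_keys))
    # every carrier event detected with its true copy number
    carr <- dplyr::left_join(
      b$truth$carriers,
      b$truth$loci[c("locus_id", "chrom", "start", "end")], by = "locus_id")
    expect_equal(nrow(sub), nrow(carr))
  }
  cons <- consensus(b$calls, b$samples, "individual")
  expect_equal(paste(cons$chrom, cons$start, cons$end), truth_keys)
  expect_equal(cons$state, b$truth$loci$state)
})

test_that("trait generation plants the breed structure and deletion effect", {
  cfg <- sim_config(seed = 7, trait_sd = 0)
  sm <- gen_genome(cfg)
  samples <- gen_samples(cfg)
  truth <- gen_truth(cfg, sm, samples)
  withh <- gen_trait(truth, samples, cfg)
  causal <- truth$loci$locus_id[cfg$causal_locus$index]
  carr <- truth$carriers[truth$carriers$locus_id == causal, ]
  means <- setNames(cfg$breeds$mean_height_cm, cfg$breeds$breed)
  het <- carr$sample_id[carr$cn == 1L]
  non <- setdiff(samples$sample_id, carr$sample_id)
  expect_equal(withh$height_cm[match(het, withh$sample_id)] -
                 means[withh$breed[match(het, withh$sample_id)]],
               rep(4, length(het)), ignore_attr = TRUE)
  expect_equal(withh$height_cm[match(non, withh$sample_id)],
               unname(means[withh$breed[match(non, withh$sample_id)]]))
  # breed means separated by the configured offsets
  cfg2 <- sim_config(seed = 8, trait_sd = 3)
  b2 <- simulate_cohort(cfg2)
  bm <- tapply(b2$samples$height_cm, b2$samples$breed, mean)
  expect_lt(abs((bm[["Hanoverian"]] - bm[["Arabian"]]) - 20), 2.5)
})

test_that("simulated qPCR wells reproduce exact rq levels without noise", {
  cfg <- sim_config(seed = 9)
  sm <- gen_genome(cfg)
  samples <- gen_samples(cfg)
  truth <- gen_truth(cfg, sm, samples)
  locus <- truth$loci$locus_id[1]
  carr <- truth$carriers[truth$carriers$locus_id == locus, ]
  het <- carr$sample_id[carr$cn == 1L][1]
  dip <- setdiff(samples$sample_id, carr$sample_id)[1:2]
  wells <- gen_qpcr(truth, locus, c(dip, het), calibrator_sample = dip[1],
                    noise_sd = 0, seed = 10)
  rq <- relative_quantity(wells, dip[1])
  expect_equal(rq$rq[rq$sample_id == het], 0.5)
  expect_equal(rq$rq[rq$sample_id == dip[2]], 1.0)
  expect_error(gen_qpcr(truth, locus, c(dip, het), calibrator_sample = het,
                        noise_sd = 0, seed = 10), "not diploid")
})
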