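mk_wells <- function(dct_by_sample, ref_ct = 20, assay = "L1") {
  rows <- lapply(names(dct_by_sample), function(sid) {
    tibble::tibble(sample_id = sid,
                   assay = rep(c(assay, "GAPDH"), each = 2),
                   replicate = rep(1:2, 2),
                   ct = c(rep(ref_ct + dct_by_sample[[sid]], 2),
                          rep(ref_ct, 2)))
  })
  dplyr::bind_rows(rows)
}

test_that("2^-ddCt closed forms: ddCt 0 / +1 / -1 give rq 1 / 0.5 / 2", {
  wells <- mk_wells(c(cal = 5, same = 5, up = 6, down = 4))
  rq <- relative_quantity(wells, "cal")
  expect_equal(rq$rq[rq$sample_id == "same"], 1.0)
  expect_equal(rq$rq[rq$sample_id == "up"], 0.5)
  expect_equal(rq$rq[rq$sample_id == "down"], 2.0)
  expect_equal(rq$called_cn[rq$sample_id == "cal"], 2L)
})

test_that("replicates are averaged and missing wells handled as specified", {
  wells <- dplyr::bind_rows(
    tibble::tibble(sample_id = "cal", assay = c("L1", "L1", "GAPDH", "GAPDH"),
                   replicate = c(1L, 2L, 1L, 2L), ct = c(24.8, 25.2, 20, 20)),
    tibble::tibble(sample_id = "s1", assay = c("L1", "L1", "GAPDH", "GAPDH"),
                   replicate = c(1L, 2L, 1L, 2L), ct = c(25.9, 26.1, 20, 20)),
    tibble::tibble(sample_id = "noref", assay = c("L1", "L1"),
                   replicate = c(1L, 2L), ct = c(25, 25)))
  expect_warning(rq <- relative_quantity(wells, "cal"), "noref")
  expect_equal(rq$rq[rq$sample_id == "s1"], 0.5)
  expect_false("noref" %in% rq$sample_id)
  expect_error(relative_quantity(wells, "missing_sample"), "calibrator")
})

test_that("ddCt is invariant to a constant shift of a sample's Ct values", {
  wells <- mk_wells(c(cal = 5, s1 = 6))
  shifted <- wells
  shifted$ct[shifted$sample_id == "s1"] <-
    shifted$ct[shifted$sample_id == "s1"] + 3.7
  expect_equal(relative_quantity(wells, "cal")$rq,
               relative_quantity(shifted, "cal")$rq)
})

test_that("copy-number classification uses midpoint bins with an out-of-range flag", {
  cls <- classify_copy_number(c(1.02, 0.48, 0.05, 1.45, 2.3))
  expect_equal(as.integer(cls), c(2L, 1L, 0L, 3L, 3L))
  expect_equal(attr(cls, "out_of_range"), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(classify_copy_number(0), "rq must be")
})

test_that("classification recovers the true copy number under realistic Ct noise", {
  set.seed(51)
  n <- 1000
  cn_true <- sample(0:3, n, replace = TRUE)
  hits <- 0
  base_t <- 25; base_r <- 20; noise_sd <- 0.1
  for (i in seq_len(n)) {
    ct_t <- if (cn_true[i] == 0) 38 else base_t - log2(cn_true[i] / 2)
    dct <- mean(ct_t + rnorm(2, 0, noise_sd)) -
      mean(base_r + rnorm(2, 0, noise_sd))
    ddct <- dct - (base_t - base_r)  # noiseless diploid calibrator
    cn_hat <- as.integer(classify_copy_number(2^(-ddct)))
    if (cn_hat == cn_true[i]) hits <- hits + 1
  }
  expect_gte(hits / n, 0.99)
})

test_that("caller concordance counts matches and false negatives per (sample, region)", {
  samples <- tibble::tibble(sample_id = sprintf("v%02d", 1:10),
                            breed = "Hanoverian", height_cm = 160,
                            call_rate = 0.99, sd_lrr = 0.1, gcwf = 0)
  regions <- tibble::tibble(region_id = "1:100-200", chrom = "1",
                            start = 100, end = 200)
  # truth: first 6 samples deleted (cn 1), rest diploid
  qpcr <- tibble::tibble(sample_id = samples$sample_id,
                         region_id = "1:100-200",
                         called_cn = c(rep(1L, 6), rep(2L, 4)))
  # caller A finds all six; caller B misses four of the six deletions
  calls <- dplyr::bind_rows(
    mk_calls(rep(100, 6), rep(200, 6), sample_id = samples$sample_id[1:6],
             caller = "quantisnp"),
    mk_calls(rep(100, 2), rep(200, 2), sample_id = samples$sample_id[1:2],
             caller = "penncnv"))
  out <- concordance(qpcr, calls, regions, samples)
  expect_equal(out$accuracy[out$caller == "quantisnp"], 1.0)
  expect_equal(out$fn_rate[out$caller == "quantisnp"], 0.0)
  expect_equal(out$accuracy[out$caller == "penncnv"], 0.6)
  expect_equal(out$fn_rate[out$caller == "penncnv"], 0.4)
  expect_equal(out$accuracy[out$caller == "any_caller"], 1.0)
  # any-caller accuracy dominates every per-caller accuracy
  expect_true(all(out$accuracy[out$caller == "any_caller"] >=
                    out$accuracy[out$caller != "any_caller"]))
  expect_error(concordance(qpcr[0, ], calls, regions, samples), "empty")
})
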