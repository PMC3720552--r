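three_samples <- tibble::tibble(
  sample_id = c("s1", "s2", "s3"),
  breed = "Hanoverian", height_cm = 168, call_rate = 0.99,
  sd_lrr = 0.1, gcwf = 0)

test_that("perfect three-caller agreement yields one locus at every level", {
  calls <- dplyr::bind_rows(
    mk_calls(100, 200, caller = "cnvpartition"),
    mk_calls(100, 200, caller = "penncnv"),
    mk_calls(100, 200, caller = "quantisnp"))
  for (lv in c("population", "breed", "individual")) {
    out <- consensus(calls, three_samples, level = lv)
    expect_equal(nrow(out), 1, info = lv)
    expect_equal(out$start, 100)
    expect_equal(out$end, 200)
  }
})

test_that("support split across samples of one breed passes breed but not individual level", {
  calls <- dplyr::bind_rows(
    mk_calls(100, 200, sample_id = "s1", caller = "cnvpartition"),
    mk_calls(110, 210, sample_id = "s2", caller = "penncnv"),
    mk_calls(120, 220, sample_id = "s3", caller = "quantisnp"))
  expect_equal(nrow(consensus(calls, three_samples, "population")), 1)
  expect_equal(nrow(consensus(calls, three_samples, "breed")), 1)
  expect_equal(nrow(consensus(calls, three_samples, "individual")), 0)
  # envelope is the union of all supporting calls
  expect_equal(consensus(calls, three_samples, "population")$end, 220)
})

test_that("a caller with zero calls genome-wide yields an empty result with a warning", {
  calls <- dplyr::bind_rows(
    mk_calls(100, 200, caller = "penncnv"),
    mk_calls(100, 200, caller = "quantisnp"))
  expect_warning(out <- consensus(calls, three_samples, "population",
                                  callers = c("cnvpartition", "penncnv",
                                              "quantisnp")),
                 "zero calls")
  expect_equal(nrow(out), 0)
})

test_that("consensus loci agree with the brute-force triple-loop oracle", {
  set.seed(31)
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    breed = c("Hanoverian", "Hanoverian", "Arabian", "Lusitano"),
    height_cm = 160, call_rate = 0.99, sd_lrr = 0.1, gcwf = 0)
  for (rep in 1:10) {
    calls <- random_calls(sample(10:50, 1))
    counts <- vapply(c("population", "breed", "individual"), function(lv) {
      nrow(consensus(calls, samples, lv))
    }, 1L)
    brute <- vapply(c("population", "breed", "individual"), function(lv) {
      length(brute_consensus_loci(calls, samples, lv))
    }, 1L)
    expect_equal(counts, brute)
    # distinct-locus monotonicity across levels
    expect_true(counts[["individual"]] <= counts[["breed"]])
    expect_true(counts[["breed"]] <= counts[["population"]])
  }
})

test_that("reciprocal-mode consensus agrees with the oracle and pairwise hits are monotone in f", {
  set.seed(32)
  samples <- tibble::tibble(sample_id = paste0("s", 1:4),
                            breed = rep(c("Hanoverian", "Arabian"), 2),
                            height_cm = 160, call_rate = 0.99,
                            sd_lrr = 0.1, gcwf = 0)
  for (rep in 1:5) {
    calls <- random_calls(40)
    for (f in c(0.25, 0.5, 0.9)) {
      n_rec <- nrow(consensus(calls, samples, "population",
                              spec = overlap_spec("reciprocal", f)))
      brute <- length(brute_consensus_loci(calls, samples, "population",
                                           overlap_spec("reciprocal", f)))
      expect_equal(n_rec, brute)
    }
    # tightening the pair criterion never adds pairwise overlap hits
    a <- random_calls(20, chroms = "1")
    b <- random_calls(20, chroms = "1")
    fr <- vapply(c(0, 0.25, 0.5, 0.9), function(f) {
      spec <- if (f == 0) overlap_spec("any") else overlap_spec("reciprocal", f)
      pairwise_overlap_fraction(a, b, spec)
    }, 1)
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("breed share matrix matches brute-force pair enumeration", {
  set.seed(33)
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    breed = rep(c("Hanoverian", "Arabian", "Lusitano", "Maremanno"), 3),
    height_cm = 160, call_rate = 0.99, sd_lrr = 0.1, gcwf = 0)
  cons <- tibble::tibble(
    carriers = replicate(20, sample(samples$sample_id,
                                    sample(1:6, 1)), simplify = FALSE))
  m <- breed_share_matrix(cons, samples)
  expect_true(isSymmetric(m))
  breed_of <- setNames(samples$breed, samples$sample_id)
  breeds <- sort(unique(samples$breed))
  for (i in breeds) {
    for (j in breeds) {
      want <- sum(vapply(cons$carriers, function(cc) {
        bs <- unique(unname(breed_of[cc]))
        if (i == j) identical(bs, i) else (i %in% bs) && (j %in% bs)
      }, TRUE))
      expect_equal(m[i, j], want, info = paste(i, j))
    }
  }
  # single-breed CNV hits only its diagonal
  solo <- tibble::tibble(carriers = list(c("s1", "s5")))  # both Hanoverian
  m2 <- breed_share_matrix(solo, samples)
  expect_equal(m2["Hanoverian", "Hanoverian"], 1L)
  expect_equal(sum(m2), 1L)
  expect_error(breed_share_matrix(tibble::tibble(carriers = list("zz")),
                                  samples), "unknown breed")
})

test_that("shared calls are longer than private calls when sharing is size-coupled", {
  # landscape: shared loci drawn longer than private ones
  wins <- 0
  for (seed in 1:100) {
    set.seed(seed)
    shared_len <- round(rlnorm(6, log(4e5), 0.3))
    shared_start <- seq(1e5, 6e6, length.out = 6)
    private_len <- round(rlnorm(8, log(2.5e5), 0.3))
    private_start <- seq(7e6, 9.5e6, length.out = 8)
    calls <- dplyr::bind_rows(
      mk_calls(rep(shared_start, 2), rep(shared_start + shared_len - 1, 2),
               sample_id = rep(c("s1", "s2"), each = 6)),
      mk_calls(private_start, private_start + private_len - 1,
               sample_id = rep(c("s1", "s2"), 4)))
    st <- sharing_size_stats(calls)
    if (isTRUE(st$shared_mean_bp > st$private_mean_bp)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("degenerate sharing classes are flagged undefined", {
  same <- mk_calls(c(100, 100), c(300, 300), sample_id = c("s1", "s2"))
  st <- sharing_size_stats(same)
  expect_true(is.na(st$private_mean_bp) && !st$private_defined)
  expect_equal(st$shared_mean_bp, 201)
  apart <- mk_calls(c(100, 1000), c(200, 1100), sample_id = c("s1", "s2"))
  st2 <- sharing_size_stats(apart)
  expect_true(is.na(st2$shared_mean_bp) && !st2$shared_defined)
})

test_that("consensus table statistics summarise size and state composition", {
  tbl <- tibble::tibble(size = c(100, 200, 300, 400),
                        state = c("loss", "loss", "gain", "both"))
  st <- consensus_table_stats(tbl)
  expect_equal(st$n, 4)
  expect_equal(st$mean_size, 250)
  expect_equal(st$median_size, 250)
  expect_equal(st$max_size, 400)
  expect_equal(c(st$n_loss_only, st$n_gain_only, st$n_both), c(2, 1, 1))
})
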