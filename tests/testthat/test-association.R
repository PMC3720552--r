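test_that("genotype matrix defaults to diploid and takes the minimum overlapping copy number", {
  regions <- tibble::tibble(chrom = "1", start = c(100, 500), end = c(200, 600))
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            breed = "Hanoverian", height_cm = 160,
                            call_rate = 0.99, sd_lrr = 0.1, gcwf = 0)
  calls <- dplyr::bind_rows(
    mk_calls(150, 180, sample_id = "s1", copy_number = 1L),
    mk_calls(120, 160, sample_id = "s3", copy_number = 1L),
    mk_calls(170, 210, sample_id = "s3", copy_number = 0L))
  g <- build_genotypes(regions, calls, samples)
  expect_equal(unname(g$cn[1, ]), c(1L, 2L, 0L))
  expect_equal(unname(g$cn[2, ]), c(2L, 2L, 2L))
})

sim_assoc_cohort <- function(seed, beta = 4, n = 120, carrier_freq = 0.2,
                             sd = 3) {
  set.seed(seed)
  breeds <- rep(c("Arabian", "Hanoverian", "Lusitano"), length.out = n)
  means <- c(Arabian = 148, Hanoverian = 168, Lusitano = 160)
  carrier <- runif(n) < carrier_freq
  cn <- ifelse(carrier, 1L, 2L)
  samples <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:n), breed = breeds,
    height_cm = means[breeds] + beta * (2 - cn) + rnorm(n, 0, sd),
    call_rate = 0.99, sd_lrr = 0.1, gcwf = 0)
  # two null regions plus the causal one
  null_cn1 <- ifelse(runif(n) < 0.2, 1L, 2L)
  null_cn2 <- ifelse(runif(n) < 0.2, 3L, 2L)
  cn_mat <- rbind(cn, null_cn1, null_cn2)
  rownames(cn_mat) <- c("1:100-200", "1:1000-1100", "2:500-600")
  colnames(cn_mat) <- samples$sample_id
  g <- structure(list(cn = cn_mat,
                      regions = tibble::tibble(
                        region_id = rownames(cn_mat),
                        chrom = c("1", "1", "2"),
                        start = c(100, 1000, 500), end = c(200, 1100, 600))),
                 class = "cnv_genotypes")
  list(g = g, samples = samples)
}

test_that("pointwise p equals the lm / t-test oracles", {
  co <- sim_assoc_cohort(1)
  fit <- assoc_scan(co$g, co$samples, n_perm = 200, seed = 2)
  td <- tidy(fit)
  for (i in 1:3) {
    d <- data.frame(y = co$samples$height_cm,
                    x = pmin(co$g$cn[i, co$samples$sample_id], 4),
                    br = co$samples$breed)
    m <- summary(stats::lm(y ~ x + br, d))
    expect_equal(td$beta[i], m$coefficients["x", "Estimate"], tolerance = 1e-10)
    expect_equal(td$p_point[i], m$coefficients["x", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
  # a balanced two-group single-breed case reduces to the two-sample t-test
  set.seed(3)
  n <- 60
  cn <- rep(c(1L, 2L), each = n / 2)
  samples <- tibble::tibble(sample_id = sprintf("u%02d", 1:n),
                            breed = "Hanoverian",
                            height_cm = 160 + 4 * (2 - cn) + rnorm(n, 0, 3),
                            call_rate = 0.99, sd_lrr = 0.1, gcwf = 0)
  g <- structure(list(cn = matrix(cn, 1, n, dimnames = list("1:1-10", samples$sample_id)),
                      regions = tibble::tibble(region_id = "1:1-10", chrom = "1",
                                               start = 1, end = 10)),
                 class = "cnv_genotypes")
  fit2 <- assoc_scan(g, samples, n_perm = 100, seed = 4)
  tt <- stats::t.test(height_cm ~ cn, data = cbind(samples, cn),
                      var.equal = TRUE)
  expect_equal(tidy(fit2)$p_point, tt$p.value, tolerance = 1e-10)
})

test_that("regions below the carrier floor are skipped and constant traits error", {
  co <- sim_assoc_cohort(5)
  co$g$cn["1:1000-1100", ] <- 2L  # no carriers
  fit <- assoc_scan(co$g, co$samples, n_perm = 100, seed = 6)
  expect_true("1:1000-1100" %in% fit$skipped$region_id)
  expect_true(is.na(tidy(fit)$p_point[tidy(fit)$region_id == "1:1000-1100"]))
  flat <- co$samples
  flat$height_cm <- 160
  expect_error(assoc_scan(co$g, flat, n_perm = 100, seed = 6), "zero-variance")
  single <- co$samples
  single$breed[1] <- "Shetland"
  expect_warning(assoc_scan(co$g, single, n_perm = 100, seed = 6),
                 "single sample")
})

test_that("within-breed permutation leaves per-breed means invariant", {
  co <- sim_assoc_cohort(7)
  breed <- factor(co$samples$breed)
  y <- co$samples$height_cm
  yc <- y - stats::ave(y, breed)
  set.seed(8)
  for (rep in 1:20) {
    yp <- yc
    for (bi in split(seq_along(yc), breed)) yp[bi] <- yc[sample(bi)]
    means <- tapply(yp, breed, mean)
    expect_true(all(abs(means) < 1e-9))
  }
})

test_that("the planted deletion is recovered with calibrated direction", {
  co <- sim_assoc_cohort(9, beta = 4, n = 300, sd = 3)
  fit <- assoc_scan(co$g, co$samples, n_perm = 1000, seed = 10)
  td <- tidy(fit)
  top <- td[order(td$p_genome, td$p_point), ][1, ]
  expect_equal(top$region_id, "1:100-200")
  expect_lt(top$p_genome, 0.05)
  # taller carriers at lower copy number: negative dosage coefficient
  expect_lt(top$beta, 0)
  expect_equal(top$direction, "deletion-increases-trait")
  # deletion-indicator coding flips the sign but not the direction label
  fit2 <- assoc_scan(co$g, co$samples, n_perm = 200, seed = 10,
                     coding = "deletion")
  td2 <- tidy(fit2)
  expect_gt(td2$beta[td2$region_id == "1:100-200"], 0)
  expect_equal(td2$direction[td2$region_id == "1:100-200"],
               "deletion-increases-trait")
  gl <- glance(fit)
  expect_equal(gl$top_region, "1:100-200")
  expect_equal(gl$n_tested, 3)
})
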