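#' Relative quantification by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (sample, assay). For each target
#' assay, dCt = Ct_target - Ct_reference per sample, ddCt = dCt_sample -
#' dCt_calibrator, and the relative quantity is rq = 2^(-ddCt). With a
#' diploid calibrator, rq of 0.5 / 1 / 1.5 corresponds to 1 / 2 / 3 copies.
#' Amplification efficiency is assumed to be exactly 2.
#'
#' @param wells Well tibble (`sample_id`, `assay`, `replicate`, `ct`).
#' @param calibrator_sample Sample id of the diploid calibrator.
#' @param reference_assay Reference-gene assay id (default `"GAPDH"`).
#' @return Tibble with one row per (sample, target assay): `delta_ct`,
#'   `delta_delta_ct`, `rq`, `called_cn`, `cn_out_of_range`.
#' @export
relative_quantity <- function(wells, calibrator_sample,
                              reference_assay = "GAPDH") {
  wells <- as_tibble(wells)
  avg <- wells %>%
    group_by(sample_id = .data$sample_id, assay = .data$assay) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- avg[avg$assay == reference_assay, ]
  targets <- avg[avg$assay != reference_assay, ]
  if (!calibrator_sample %in% avg$sample_id) {
    abort("relative_quantity: calibrator sample missing from wells")
  }
  no_ref <- setdiff(unique(targets$sample_id), ref$sample_id)
  if (length(no_ref)) {
    warn(paste0("skipping sample(s) without reference-gene wells: ",
                paste(no_ref, collapse = ", ")))
    targets <- targets[!targets$sample_id %in% no_ref, ]
  }
  ref_ct <- setNames(ref$ct, ref$sample_id)
  targets$delta_ct <- unname(targets$ct - ref_ct[targets$sample_id])
  cal <- targets[targets$sample_id == calibrator_sample, ]
  if (!nrow(cal)) abort("relative_quantity: calibrator has no target-assay wells")
  cal_dct <- setNames(cal$delta_ct, cal$assay)
  targets$delta_delta_ct <- unname(targets$delta_ct - cal_dct[targets$assay])
  targets$rq <- 2^(-targets$delta_delta_ct)
  cls <- classify_copy_number(targets$rq)
  targets$called_cn <- as.integer(cls)
  targets$cn_out_of_range <- attr(cls, "out_of_range")
  targets %>%
    select("sample_id", "assay", "delta_ct", "delta_delta_ct", "rq",
           "called_cn", "cn_out_of_range")
}

#' Classify a relative quantity into a copy-number class
#'
#' With a diploid calibrator, copy number k is expected at rq = k/2, so the
#' rq levels 0, 0.5, 1.0, 1.5 map to 0-3 copies. Classification is to the
#' nearest level with bin edges 0.25 / 0.75 / 1.25 (midpoints between
#' levels); rq beyond 1.75 would imply more than 3 copies and is reported
#' as 3 with an out-of-range flag.
#'
#' @param rq Positive relative quantities.
#' @param calibrator_cn Copy number of the calibrator (default 2).
#' @return Integer copy numbers in `{0,1,2,3}` with a logical
#'   `out_of_range` attribute.
#' @export
classify_copy_number <- function(rq, calibrator_cn = 2) {
  if (any(rq <= 0, na.rm = TRUE)) abort("classify_copy_number: rq must be > 0")
  r <- rq * calibrator_cn / 2  # normalise to a diploid calibrator
  cn <- as.integer(findInterval(r, c(0.25, 0.75, 1.25)))
  out_of_range <- r > 1.75
  cn[out_of_range] <- 3L
  structure(cn, out_of_range = out_of_range)
}

#' Caller concordance against qPCR copy numbers
#'
#' Compares, per (sample, region), each caller's copy number (diploid 2
#' where the caller has no overlapping call) with the qPCR-called copy
#' number. Accuracy is the fraction of validated (sample, region) pairs the
#' caller matches; the false-negative rate is the fraction with a
#' non-diploid qPCR copy number where the caller reports 2. A final
#' `any_caller` row uses the best match across callers.
#'
#' @param qpcr Tibble from [relative_quantity()] joined to regions: columns
#'   `sample_id`, `region_id`, `called_cn`.
#' @param calls Call tibble spanning all callers.
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`.
#' @param samples Sample tibble (defines the genotype-matrix columns).
#' @return Tibble with one row per caller plus `any_caller`: `n_validated`,
#'   `n_match`, `accuracy`, `fn_rate`.
#' @export
concordance <- function(qpcr, calls, regions, samples) {
  if (!nrow(qpcr)) abort("concordance: empty validation set")
  callers <- sort(unique(calls$caller))
  reg <- as_tibble(regions)
  cn_by_caller <- lapply(callers, function(cl) {
    g <- build_genotypes(reg, calls[calls$caller == cl, ], samples)
    rownames(g$cn) <- reg$region_id
    g$cn
  })
  names(cn_by_caller) <- callers
  match_mat <- matrix(FALSE, nrow(qpcr), length(callers),
                      dimnames = list(NULL, callers))
  fn_mat <- matrix(FALSE, nrow(qpcr), length(callers),
                   dimnames = list(NULL, callers))
  for (cl in callers) {
    cn <- cn_by_caller[[cl]]
    caller_cn <- cn[cbind(match(qpcr$region_id, rownames(cn)),
                          match(qpcr$sample_id, colnames(cn)))]
    match_mat[, cl] <- caller_cn == qpcr$called_cn
    fn_mat[, cl] <- qpcr$called_cn != 2 & caller_cn == 2
  }
  per_caller <- tibble(
    caller = callers,
    n_validated = nrow(qpcr),
    n_match = unname(colSums(match_mat)),
    accuracy = unname(colMeans(match_mat)),
    fn_rate = unname(colMeans(fn_mat))
  )
  any_row <- tibble(
    caller = "any_caller", n_validated = nrow(qpcr),
    n_match = sum(apply(match_mat, 1, any)),
    accuracy = mean(apply(match_mat, 1, any)),
    fn_rate = mean(apply(fn_mat, 1, all))
  )
  bind_rows(per_caller, any_row)
}
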