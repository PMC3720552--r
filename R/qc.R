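#' Quality-control thresholds
#'
#' Bundles the exclusion thresholds applied before any downstream analysis.
#' Defaults follow common SNP-array CNV practice: samples are kept only with
#' a call rate strictly above 90%, SD of the Log R Ratio at most 0.3 and
#' |GC wave factor| at most 0.02; calls need at least 3 probes, QuantiSNP
#' calls a Log Bayes Factor of at least 10 and CNVPartition calls a
#' confidence of at least 35.
#'
#' @param min_call_rate Keep samples with `call_rate >` this (default 0.90).
#' @param max_sd_lrr Keep samples with `sd_lrr <=` this (default 0.30).
#' @param max_abs_gcwf Keep samples with `|gcwf| <=` this (default 0.02).
#' @param min_probes Keep calls with `n_probes >=` this (default 3).
#' @param min_lbf Keep QuantiSNP calls with `score >=` this (default 10).
#' @param min_confidence Keep CNVPartition calls with `score >=` this
#'   (default 35).
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, max_sd_lrr = 0.30,
                          max_abs_gcwf = 0.02, min_probes = 3L,
                          min_lbf = 10, min_confidence = 35) {
  stopifnot(is.finite(min_call_rate), is.finite(max_sd_lrr),
            is.finite(max_abs_gcwf), is.finite(min_probes), min_probes >= 1,
            is.finite(min_lbf), is.finite(min_confidence))
  structure(list(min_call_rate = min_call_rate, max_sd_lrr = max_sd_lrr,
                 max_abs_gcwf = max_abs_gcwf, min_probes = as.integer(min_probes),
                 min_lbf = min_lbf, min_confidence = min_confidence),
            class = "qc_thresholds")
}

#' Filter samples on array quality metrics
#'
#' A sample is kept iff `call_rate > min_call_rate` AND
#' `sd_lrr <= max_sd_lrr` AND `|gcwf| <= max_abs_gcwf`. A missing `sd_lrr`
#' or `gcwf` skips that rule for that sample (recorded in the log).
#'
#' @param samples Sample tibble (see [read_samples()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `samples` (kept rows) and `log`, a tibble naming the
#'   first failing rule per removed sample plus any skipped rules.
#' @export
filter_samples <- function(samples, thresholds = qc_thresholds()) {
  if (!nrow(samples)) abort("filter_samples: empty sample list")
  th <- thresholds
  log_rows <- list()
  fail_rule <- rep(NA_character_, nrow(samples))
  fail_value <- rep(NA_real_, nrow(samples))
  fail_thr <- rep(NA_real_, nrow(samples))

  bad_cr <- !(samples$call_rate > th$min_call_rate)
  fail_rule[bad_cr] <- "call_rate"
  fail_value[bad_cr] <- samples$call_rate[bad_cr]
  fail_thr[bad_cr] <- th$min_call_rate

  open <- is.na(fail_rule)
  bad_sd <- open & !is.na(samples$sd_lrr) & samples$sd_lrr > th$max_sd_lrr
  fail_rule[bad_sd] <- "sd_lrr"
  fail_value[bad_sd] <- samples$sd_lrr[bad_sd]
  fail_thr[bad_sd] <- th$max_sd_lrr

  open <- is.na(fail_rule)
  bad_gc <- open & !is.na(samples$gcwf) & abs(samples$gcwf) > th$max_abs_gcwf
  fail_rule[bad_gc] <- "gcwf"
  fail_value[bad_gc] <- samples$gcwf[bad_gc]
  fail_thr[bad_gc] <- th$max_abs_gcwf

  removed <- !is.na(fail_rule)
  if (any(removed)) {
    log_rows$removed <- tibble(
      sample_id = samples$sample_id[removed],
      rule = fail_rule[removed],
      value = fail_value[removed],
      threshold = fail_thr[removed],
      action = "excluded"
    )
  }
  skipped <- samples[!removed & (is.na(samples$sd_lrr) | is.na(samples$gcwf)), ]
  if (nrow(skipped)) {
    log_rows$skipped <- tibble(
      sample_id = rep(skipped$sample_id,
                      times = is.na(skipped$sd_lrr) + is.na(skipped$gcwf)),
      rule = unlist(purrr::map2(is.na(skipped$sd_lrr), is.na(skipped$gcwf),
                                function(s, g) c(if (s) "sd_lrr", if (g) "gcwf"))),
      value = NA_real_, threshold = NA_real_, action = "rule_skipped_missing"
    )
  }
  log <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(sample_id = character(), rule = character(), value = numeric(),
           threshold = numeric(), action = character())
  list(samples = samples[!removed, ], log = log)
}

#' Filter CNV calls on probe count and caller score
#'
#' Keeps calls with `n_probes >= min_probes`; additionally requires
#' `score >= min_lbf` for QuantiSNP calls and `score >= min_confidence` for
#' CNVPartition calls (comparisons are boundary-inclusive for keeping). A
#' missing `n_probes` or score skips that rule for that call.
#'
#' @param calls Call tibble (see [read_calls()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `calls` (kept) and `removed`, a named integer count per
#'   rule (`n_probes`, `lbf`, `confidence`) summing to the number removed.
#' @export
filter_calls <- function(calls, thresholds = qc_thresholds()) {
  th <- thresholds
  if (!nrow(calls)) {
    return(list(calls = calls,
                removed = c(n_probes = 0L, lbf = 0L, confidence = 0L)))
  }
  bad_probes <- !is.na(calls$n_probes) & calls$n_probes < th$min_probes
  open <- !bad_probes
  bad_lbf <- open & calls$caller == "quantisnp" & !is.na(calls$score) &
    calls$score < th$min_lbf
  open <- open & !bad_lbf
  bad_conf <- open & calls$caller == "cnvpartition" & !is.na(calls$score) &
    calls$score < th$min_confidence
  removed <- c(n_probes = sum(bad_probes), lbf = sum(bad_lbf),
               confidence = sum(bad_conf))
  list(calls = calls[!(bad_probes | bad_lbf | bad_conf), ],
       removed = removed)
}
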