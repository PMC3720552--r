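# default resolved configuration; every key a config file may set
default_config <- function() {
  list(
    seed = 1L,
    sim = list(n_chrom = 5, n_snps = 2000, n_cnv_loci = 20,
               size_median = 169367, size_mean = 487562, loss_fraction = 0.6,
               trait_sd = 3, bad_sample_rate = 0.02,
               causal_index = 1, causal_beta_cm = 4, causal_carrier_freq = 0.15),
    qc = list(min_call_rate = 0.90, max_sd_lrr = 0.30, max_abs_gcwf = 0.02,
              min_probes = 3, min_lbf = 10, min_confidence = 35),
    consensus = list(mode = "any", min_fraction = 0.5),
    enrich = list(permutation = FALSE, n_perm = 1000),
    assoc = list(n_perm = 1000, min_carriers = 5, coding = "dosage"),
    qpcr = list(noise_sd = 0.1, n_samples = 20)
  )
}

validate_config <- function(cfg) {
  ref <- default_config()
  for (k in names(cfg)) {
    if (!k %in% names(ref)) abort(paste0("invalid config key: ", k))
    if (is.list(ref[[k]])) {
      for (k2 in names(cfg[[k]])) {
        if (!k2 %in% names(ref[[k]])) {
          abort(paste0("invalid config key: ", k, ".", k2))
        }
        ref[[k]][[k2]] <- cfg[[k]][[k2]]
      }
    } else ref[[k]] <- cfg[[k]]
  }
  ref
}

pipeline_stages <- c("simulate", "qc", "consensus", "enrich", "share",
                     "assoc", "qpcr", "report")

stage_outputs <- list(
  simulate = c("snp_map.tsv", "samples.tsv", "calls.tsv", "truth_loci.tsv",
               "truth_carriers.tsv", "qpcr_wells.tsv"),
  qc = c("samples_kept.tsv", "calls_kept.tsv", "qc_sample_log.tsv"),
  consensus = c("consensus_population.tsv", "consensus_breed.tsv",
                "consensus_individual.tsv", "regions.bed", "regions.tsv"),
  enrich = "enrichment.tsv",
  share = c("breed_share.tsv", "sharing_sizes.tsv"),
  assoc = "assoc.tsv",
  qpcr = c("qpcr_rq.tsv", "qpcr_concordance.tsv"),
  report = c("table1.tsv", "table4.tsv", "table5.tsv", "table7.tsv")
)

stage_deps <- list(simulate = character(), qc = "simulate",
                   consensus = "qc", enrich = "consensus",
                   share = "consensus", assoc = "consensus",
                   qpcr = "consensus",
                   report = c("enrich", "share", "assoc"))

#' Run the analysis pipeline
#'
#' Orchestrates the stages simulate -> qc -> consensus -> enrich -> share ->
#' assoc -> qpcr -> report. Each stage reads its upstream inputs from
#' `out_dir` (all cross-stage state flows through TSV files) and writes its
#' own outputs there; a `manifest.json` records the resolved configuration,
#' seed, stages executed, file MD5 digests and package version. Re-running
#' with an identical manifest reproduces byte-identical outputs.
#'
#' @param config `NULL` (defaults), a YAML file path, or a nested list with
#'   sections `sim`, `qc`, `consensus`, `enrich`, `assoc`, `qpcr` and a
#'   top-level `seed`. Unknown keys are errors.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, stages = pipeline_stages,
                         out_dir, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  p <- function(f) file.path(out_dir, f)
  say <- function(stage, t0, ...) {
    if (!quiet) {
      inform(sprintf("[%s] %.2fs %s", stage,
                     as.numeric(Sys.time()) - t0, paste0(...)))
    }
  }
  check_deps <- function(stage) {
    for (dep in stage_deps[[stage]]) {
      missing <- !file.exists(p(stage_outputs[[dep]]))
      if (any(missing)) {
        abort(paste0(stage, ": ", dep, " outputs missing (",
                     paste(stage_outputs[[dep]][missing], collapse = ", "),
                     "); run the '", dep, "' stage first"))
      }
    }
  }

  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    check_deps(stage)
    switch(stage,
      simulate = {
        sc <- sim_config(seed = cfg$seed,
                         n_chrom = cfg$sim$n_chrom, n_snps = cfg$sim$n_snps,
                         n_cnv_loci = cfg$sim$n_cnv_loci,
                         size_median = cfg$sim$size_median,
                         size_mean = cfg$sim$size_mean,
                         loss_fraction = cfg$sim$loss_fraction,
                         trait_sd = cfg$sim$trait_sd,
                         bad_sample_rate = cfg$sim$bad_sample_rate,
                         causal_locus = list(
                           index = cfg$sim$causal_index,
                           beta_cm = cfg$sim$causal_beta_cm,
                           carrier_freq = cfg$sim$causal_carrier_freq))
        b <- simulate_cohort(sc)
        write_table_tsv(as_tibble(b$snp_map), p("snp_map.tsv"))
        write_table_tsv(b$samples, p("samples.tsv"))
        write_table_tsv(b$calls, p("calls.tsv"))
        write_table_tsv(b$truth$loci, p("truth_loci.tsv"))
        write_table_tsv(b$truth$carriers, p("truth_carriers.tsv"))
        causal <- b$truth$loci$locus_id[sc$causal_locus$index]
        carriers_c <- b$truth$carriers$sample_id[
          b$truth$carriers$locus_id == causal]
        diploid <- setdiff(b$samples$sample_id, carriers_c)
        qn <- min(cfg$qpcr$n_samples, nrow(b$samples))
        assay_samples <- unique(c(diploid[1],
                                  head(c(carriers_c, diploid), qn)))
        wells <- gen_qpcr(b$truth, causal, assay_samples,
                          calibrator_sample = diploid[1],
                          noise_sd = cfg$qpcr$noise_sd,
                          seed = cfg$seed + 5L)
        write_table_tsv(wells, p("qpcr_wells.tsv"))
        say(stage, t0, nrow(b$calls), " calls, ", nrow(b$samples), " samples")
      },
      qc = {
        samples <- read_samples(p("samples.tsv"))
        calls <- read_calls(p("calls.tsv"), dialect = "tsv")
        th <- do.call(qc_thresholds, cfg$qc)
        fs <- filter_samples(samples, th)
        kept_calls <- filter_calls(
          calls[calls$sample_id %in% fs$samples$sample_id, ], th)
        write_table_tsv(fs$samples, p("samples_kept.tsv"))
        write_table_tsv(kept_calls$calls, p("calls_kept.tsv"))
        write_table_tsv(fs$log, p("qc_sample_log.tsv"))
        say(stage, t0, nrow(fs$samples), " samples, ",
            nrow(kept_calls$calls), " calls kept")
      },
      consensus = {
        calls <- read_calls(p("calls_kept.tsv"), dialect = "tsv")
        samples <- read_samples(p("samples_kept.tsv"))
        spec <- overlap_spec(cfg$consensus$mode, cfg$consensus$min_fraction)
        for (lv in c("population", "breed", "individual")) {
          cons <- consensus(calls, samples, level = lv, spec = spec)
          write_table_tsv(cons %>% select(-"carriers", -"breeds", -"units"),
                          p(paste0("consensus_", lv, ".tsv")))
          if (lv == "population") {
            write_regions_bed(cons, p("regions.bed"))
            write_table_tsv(cons %>% select("chrom", "start", "end", "state",
                                            "n_calls"),
                            p("regions.tsv"))
          }
        }
        say(stage, t0)
      },
      enrich = {
        snp_map <- read_snp_map(p("snp_map.tsv"))
        regions <- readr::read_tsv(p("regions.tsv"),
                                   col_types = readr::cols(chrom = "c"),
                                   progress = FALSE)
        cov <- coverage_table(regions, snp_map)
        if (isTRUE(cfg$enrich$permutation)) {
          pp <- permutation_enrichment(regions, snp_map,
                                       n_perm = cfg$enrich$n_perm,
                                       seed = cfg$seed + 6L)
          cov <- left_join(cov, pp[c("chrom", "perm_p")], by = "chrom")
        }
        write_table_tsv(cov, p("enrichment.tsv"))
        say(stage, t0, sum(cov$enriched, na.rm = TRUE), " chromosome(s) enriched")
      },
      share = {
        calls <- read_calls(p("calls_kept.tsv"), dialect = "tsv")
        samples <- read_samples(p("samples_kept.tsv"))
        spec <- overlap_spec(cfg$consensus$mode, cfg$consensus$min_fraction)
        cons <- consensus(calls, samples, level = "population", spec = spec)
        m <- breed_share_matrix(cons, samples)
        write_table_tsv(as_tibble(m, rownames = "breed"), p("breed_share.tsv"))
        write_table_tsv(sharing_size_stats(calls), p("sharing_sizes.tsv"))
        say(stage, t0)
      },
      assoc = {
        calls <- read_calls(p("calls_kept.tsv"), dialect = "tsv")
        samples <- read_samples(p("samples_kept.tsv"))
        regions <- readr::read_tsv(p("regions.tsv"),
                                   col_types = readr::cols(chrom = "c"),
                                   progress = FALSE)
        g <- build_genotypes(regions, calls, samples)
        fit <- assoc_scan(g, samples, n_perm = cfg$assoc$n_perm,
                          seed = cfg$seed + 7L,
                          min_carriers = cfg$assoc$min_carriers,
                          coding = cfg$assoc$coding)
        write_table_tsv(tidy(fit), p("assoc.tsv"))
        say(stage, t0, sum(!is.na(fit$all_regions$p_point)), " regions tested")
      },
      qpcr = {
        wells <- read_qpcr_wells(p("qpcr_wells.tsv"))
        calls <- read_calls(p("calls_kept.tsv"), dialect = "tsv")
        samples <- read_samples(p("samples_kept.tsv"))
        loci <- readr::read_tsv(p("truth_loci.tsv"),
                                col_types = readr::cols(chrom = "c"),
                                progress = FALSE)
        target <- setdiff(unique(wells$assay), "GAPDH")[1]
        locus <- loci[loci$locus_id == target, ]
        # calibrator: first assayed sample with dCt == modal dCt of diploids;
        # the simulate stage places a diploid sample first
        calib <- wells$sample_id[1]
        rq <- relative_quantity(wells, calibrator_sample = calib)
        reg <- tibble(region_id = target, chrom = locus$chrom,
                      start = locus$start, end = locus$end)
        qv <- rq %>% mutate(region_id = target) %>%
          filter(.data$sample_id %in% samples$sample_id)
        conc <- concordance(qv, calls, reg, samples)
        write_table_tsv(rq, p("qpcr_rq.tsv"))
        write_table_tsv(conc, p("qpcr_concordance.tsv"))
        say(stage, t0, "any-caller accuracy ",
            round(conc$accuracy[conc$caller == "any_caller"], 3))
      },
      report = {
        file.copy(p("enrichment.tsv"), p("table1.tsv"), overwrite = TRUE)
        samples <- read_samples(p("samples_kept.tsv"))
        calls <- read_calls(p("calls_kept.tsv"), dialect = "tsv")
        spec <- overlap_spec(cfg$consensus$mode, cfg$consensus$min_fraction)
        cons_b <- consensus(calls, samples, level = "breed", spec = spec)
        cons_i <- consensus(calls, samples, level = "individual", spec = spec)
        per_breed <- samples %>%
          group_by(breed = .data$breed) %>%
          summarise(n_animals = dplyr::n(), .groups = "drop") %>%
          mutate(
            n_calls = vapply(.data$breed, function(b) {
              sum(calls$sample_id %in% samples$sample_id[samples$breed == b])
            }, 1),
            n_consensus_breed = vapply(.data$breed, function(b) {
              sum(vapply(cons_b$units, function(u) b %in% u, TRUE))
            }, 1),
            n_consensus_same_horse = vapply(.data$breed, function(b) {
              ids <- samples$sample_id[samples$breed == b]
              sum(vapply(cons_i$units, function(u) any(u %in% ids), TRUE))
            }, 1))
        write_table_tsv(per_breed, p("table4.tsv"))
        file.copy(p("breed_share.tsv"), p("table5.tsv"), overwrite = TRUE)
        file.copy(p("assoc.tsv"), p("table7.tsv"), overwrite = TRUE)
        say(stage, t0)
      })
  }

  files <- list.files(out_dir, pattern = "\\.(tsv|bed)$", full.names = TRUE)
  manifest <- list(
    tool = "equicnv",
    version = as.character(utils::packageVersion("equicnv")),
    seed = cfg$seed,
    stages = stages,
    config = cfg,
    digests = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
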