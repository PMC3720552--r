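#' Read a SNP map
#'
#' Reads the marker map underlying the array: one row per SNP with its name,
#' chromosome and 1-based base-pair position. The map is the basis for probe
#' counting, enrichment statistics and the synthetic-data generator.
#'
#' @param path Path to a TSV with columns `name`, `chrom`, `pos` (header row).
#' @param chrom_lengths Optional named numeric vector of chromosome lengths in
#'   bp. When `NULL`, each chromosome's length defaults to its maximum marker
#'   position.
#' @return A `snp_map`: a tibble with columns `name`, `chrom`, `pos`, sorted
#'   by `(chrom, pos)` (ties broken by `name`), carrying a `chrom_lengths`
#'   attribute.
#' @export
read_snp_map <- function(path, chrom_lengths = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_double()
  ), progress = FALSE)
  new_snp_map(df, chrom_lengths = chrom_lengths)
}

#' Construct a SNP map from a data frame
#'
#' @param markers Data frame with columns `name`, `chrom`, `pos`.
#' @inheritParams read_snp_map
#' @return A `snp_map` tibble (see [read_snp_map()]).
#' @export
new_snp_map <- function(markers, chrom_lengths = NULL) {
  req <- c("name", "chrom", "pos")
  if (!all(req %in% names(markers))) {
    abort(paste0("SNP map needs columns: ", paste(req, collapse = ", ")))
  }
  m <- as_tibble(markers)[req]
  m$chrom <- norm_chrom(m$chrom)
  m$pos <- as.numeric(m$pos)
  if (anyNA(m$pos) || any(m$pos < 1)) {
    abort("SNP map format error: positions must be numeric and >= 1")
  }
  if (anyDuplicated(m$name)) {
    dup <- unique(m$name[duplicated(m$name)])
    abort(paste0("SNP map format error: duplicate marker name(s): ",
                 paste(head(dup, 3), collapse = ", ")))
  }
  m <- m[order(chrom_rank(m$chrom), m$pos, m$name), ]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(m$pos, m$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  } else {
    names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
    missing_len <- setdiff(unique(m$chrom), names(chrom_lengths))
    if (length(missing_len)) {
      abort(paste0("chrom_lengths missing chromosome(s): ",
                   paste(missing_len, collapse = ", ")))
    }
    too_far <- tapply(m$pos, m$chrom, max) > chrom_lengths[
      names(tapply(m$pos, m$chrom, max))]
    if (any(too_far)) abort("marker position beyond stated chromosome length")
  }
  structure(m, chrom_lengths = chrom_lengths[order(chrom_rank(names(chrom_lengths)))],
            class = c("snp_map", class(m)))
}

# numeric-aware chromosome ordering (1,2,...,10 not 1,10,...)
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(n), 1e6 + as.numeric(factor(chrom)), n)
}

#' @export
chrom_lengths <- function(snp_map) attr(snp_map, "chrom_lengths")

# column-mapping presets: each caller dialect is just a renaming of the
# generic TSV layout (sample_id, chrom, start, end, copy_number, n_probes, score)
caller_dialects <- list(
  tsv = c(sample_id = "sample_id", chrom = "chrom", start = "start",
          end = "end", copy_number = "copy_number", n_probes = "n_probes",
          score = "score"),
  penncnv = c(sample_id = "sample", chrom = "chr", start = "posStart",
              end = "posEnd", copy_number = "cn", n_probes = "numsnp",
              score = "conf"),
  quantisnp = c(sample_id = "Sample.Name", chrom = "Chromosome",
                start = "Start.Position..bp.", end = "End.Position..bp.",
                copy_number = "Copy.Number", n_probes = "No..Probes",
                score = "Max..Log.BF"),
  cnvpartition = c(sample_id = "Sample.ID", chrom = "Chromosome",
                   start = "Start", end = "End", copy_number = "CNV.Value",
                   n_probes = "Num.SNPs", score = "CNV.Confidence")
)

#' Read CNV calls
#'
#' Reads one caller's CNV call table. Caller-specific dialects are
#' column-mapping presets over a single tabular reader; `"bed"` reads a
#' 0-based half-open BED file and converts to the package's 1-based inclusive
#' convention. Records with `copy_number == 2` are not CNVs and are dropped
#' with a counted warning rather than an error so merged caller exports can
#' be ingested.
#'
#' @param path File path.
#' @param dialect One of `"tsv"`, `"penncnv"`, `"quantisnp"`,
#'   `"cnvpartition"`, `"bed"`.
#' @param caller Caller label to stamp on the calls; defaults to the dialect
#'   for the three caller dialects, otherwise taken from a `caller` column
#'   when present.
#' @return A tibble of calls with columns `sample_id`, `caller`, `chrom`,
#'   `start`, `end`, `copy_number`, `n_probes`, `score`. The number of
#'   diploid rows dropped is attached as attribute `n_rejected`.
#' @export
read_calls <- function(path, dialect = c("tsv", "penncnv", "quantisnp",
                                         "cnvpartition", "bed"),
                       caller = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") return(read_calls_bed(path, caller = caller))
  raw <- as.data.frame(readr::read_tsv(path, col_types = readr::cols(),
                                       progress = FALSE, name_repair = "minimal"))
  names(raw) <- make.names(names(raw))
  map <- caller_dialects[[dialect]]
  missing_cols <- setdiff(unname(map[c("sample_id", "chrom", "start", "end",
                                       "copy_number")]), names(raw))
  if (length(missing_cols)) {
    abort(paste0("call table format error (dialect ", dialect,
                 "): missing column(s) ", paste(missing_cols, collapse = ", ")))
  }
  df <- tibble(
    sample_id = as.character(raw[[map[["sample_id"]]]]),
    chrom = norm_chrom(raw[[map[["chrom"]]]]),
    start = as.numeric(raw[[map[["start"]]]]),
    end = as.numeric(raw[[map[["end"]]]]),
    copy_number = as.integer(raw[[map[["copy_number"]]]]),
    n_probes = if (map[["n_probes"]] %in% names(raw))
      as.integer(raw[[map[["n_probes"]]]]) else NA_integer_,
    score = if (map[["score"]] %in% names(raw))
      as.numeric(raw[[map[["score"]]]]) else NA_real_
  )
  if (is.null(caller)) {
    caller <- if (dialect == "tsv") {
      if ("caller" %in% names(raw)) as.character(raw[["caller"]]) else "unknown"
    } else dialect
  }
  df$caller <- caller
  validate_calls(df)
}

read_calls_bed <- function(path, caller = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(validate_calls(tibble(sample_id = character(), caller = character(),
                                 chrom = character(), start = numeric(),
                                 end = numeric(), copy_number = integer(),
                                 n_probes = integer(), score = numeric())))
  }
  parts <- strsplit(lines, "\t| +")
  chrom <- norm_chrom(vapply(parts, `[`, "", 1))
  bstart <- as.numeric(vapply(parts, `[`, "", 2))
  bend <- as.numeric(vapply(parts, `[`, "", 3))
  name <- vapply(parts, function(p) if (length(p) >= 4) p[4] else ".", "")
  # optional name field "sample=s1;cn=1;caller=penncnv"
  get_kv <- function(nm, key) {
    hit <- regmatches(nm, regexpr(paste0(key, "=[^;]+"), nm))
    if (length(hit)) sub(paste0(key, "="), "", hit) else NA_character_
  }
  sample_id <- vapply(name, get_kv, "", key = "sample")
  cn <- suppressWarnings(as.integer(vapply(name, get_kv, "", key = "cn")))
  call_lab <- vapply(name, get_kv, "", key = "caller")
  df <- tibble(
    sample_id = ifelse(is.na(sample_id), "unknown", sample_id),
    caller = if (!is.null(caller)) caller else
      ifelse(is.na(call_lab), "unknown", call_lab),
    chrom = chrom,
    start = bstart + 1,  # BED is 0-based half-open
    end = bend,
    copy_number = ifelse(is.na(cn), 1L, cn),
    n_probes = NA_integer_,
    score = NA_real_
  )
  validate_calls(df)
}

#' Validate and normalise a CNV call table
#'
#' Enforces the call invariants: `start <= end`, `copy_number >= 0` and not
#' equal to 2 (diploid rows are dropped, counted in attribute `n_rejected`).
#'
#' @param calls Data frame with at least `sample_id`, `caller`, `chrom`,
#'   `start`, `end`, `copy_number`; `n_probes` and `score` are added as `NA`
#'   when absent.
#' @return Validated tibble of calls.
#' @export
validate_calls <- function(calls) {
  calls <- as_tibble(calls)
  if (!"n_probes" %in% names(calls)) calls$n_probes <- NA_integer_
  if (!"score" %in% names(calls)) calls$score <- NA_real_
  if (!"caller" %in% names(calls)) calls$caller <- "unknown"
  calls <- calls[c("sample_id", "caller", "chrom", "start", "end",
                   "copy_number", "n_probes", "score")]
  calls$chrom <- norm_chrom(calls$chrom)
  if (nrow(calls)) {
    if (any(calls$start > calls$end)) {
      abort("call table format error: start > end")
    }
    if (any(calls$start < 1)) abort("call table format error: start < 1")
    if (any(calls$copy_number < 0, na.rm = TRUE)) {
      abort("call table format error: negative copy number")
    }
  }
  diploid <- !is.na(calls$copy_number) & calls$copy_number == 2L
  n_rejected <- sum(diploid)
  if (n_rejected > 0) {
    warn(paste0("dropped ", n_rejected, " diploid (copy_number = 2) record(s)"))
    calls <- calls[!diploid, ]
  }
  calls <- calls[order(chrom_rank(calls$chrom), calls$start, calls$end,
                       calls$sample_id), ]
  attr(calls, "n_rejected") <- n_rejected
  calls
}

#' Interval size in bp under the 1-based inclusive convention
#' @param start,end Interval bounds, 1-based inclusive.
#' @return `end - start + 1`.
#' @export
interval_size <- function(start, end) end - start + 1

#' Write CNV regions as BED
#'
#' Exports regions (1-based inclusive) as 0-based half-open BED. The name
#' column encodes the region state and carrier count as
#' `state=<loss|gain|both>;carriers=<n>`, so the file round-trips through
#' [read_calls()] with `dialect = "bed"` on coordinates.
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optionally `state`,
#'   `n_carriers`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (!nrow(regions)) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  state <- if ("state" %in% names(regions)) regions$state else "loss"
  carriers <- if ("n_carriers" %in% names(regions)) regions$n_carriers else 0L
  lines <- paste(regions$chrom, format(regions$start - 1, scientific = FALSE,
                                       trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 paste0("state=", state, ";carriers=", carriers),
                 sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `breed`, `height_cm`,
#'   `call_rate`, `sd_lrr`, `gcwf` (missing QC metrics allowed as `NA`).
#' @return Tibble of sample records.
#' @export
read_samples <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    breed = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  req <- c("sample_id", "breed", "call_rate")
  if (!all(req %in% names(df))) {
    abort(paste0("sample table needs columns: ", paste(req, collapse = ", ")))
  }
  for (col in c("height_cm", "sd_lrr", "gcwf")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (any(df$call_rate < 0 | df$call_rate > 1, na.rm = TRUE)) {
    abort("sample table format error: call_rate outside [0,1]")
  }
  df[c("sample_id", "breed", "height_cm", "call_rate", "sd_lrr", "gcwf")]
}

#' Read qPCR wells
#'
#' @param path TSV with columns `sample_id`, `assay`, `replicate`, `ct`.
#' @return Tibble of wells.
#' @export
read_qpcr_wells <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    assay = readr::col_character(),
    replicate = readr::col_integer(),
    ct = readr::col_double()
  ), progress = FALSE)
  if (any(df$ct <= 0, na.rm = TRUE)) {
    abort("qPCR table format error: Ct values must be positive")
  }
  df
}

#' Write a tibble as TSV
#' @param x Data frame. List-columns are collapsed to comma-separated strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  x <- as_tibble(x)
  is_list <- vapply(x, is.list, logical(1))
  for (col in names(x)[is_list]) {
    x[[col]] <- vapply(x[[col]], function(v) paste(v, collapse = ","), "")
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
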