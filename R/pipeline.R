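#' Run the quantification pipeline over a sample sheet
#'
#' Orchestrates quality filtering, alignment, classification and
#' summarization over a set of FASTQ files, one per (site, condition,
#' replicate). The config is a YAML file (or an equivalent list) with:
#'
#' ```yaml
#' amplicons: refs.fa          # FASTA of reference amplicons
#' sites: sites.tsv            # site config, see load_sites()
#' quality_threshold: 30
#' min_identity: 0.75
#' scoring: {match: 2, mismatch: -3, gap_open: -5, gap_extend: -1}
#' output_dir: out/
#' samples:
#'   - {site: s1, condition: treated, replicate: 1, fastq: s1_t_r1.fq}
#' ```
#'
#' Every referenced path is checked up front; a missing FASTQ is reported
#' with its (site, condition, replicate). Outputs (per-sample summary
#' files plus a run log recording read counts at every filter stage) are
#' deterministic: re-running on identical inputs reproduces identical
#' files.
#'
#' @param config path of a YAML config or a list with the same structure.
#' @return list with `summaries` (nested per sample, with `site`,
#'   `condition`, `replicate`, `summary`) and `run_log` (data.frame of
#'   stage counts `n_total >= n_pass_qc >= n_aligned >= n_covering`).
#' @export
run_quantify <- function(config) {
  if (is.character(config)) {
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  } else {
    base_dir <- "."
  }
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  for (field in c("amplicons", "sites", "samples")) {
    if (is.null(config[[field]])) stop("config missing '", field, "'")
  }
  amp_path <- resolve(config$amplicons)
  sites_path <- resolve(config$sites)
  for (p in c(amp_path, sites_path)) {
    if (!file.exists(p)) stop("config references missing file: ", p)
  }
  sites <- load_sites(sites_path, read_fasta(amp_path))
  names(sites) <- vapply(sites, `[[`, "", "site_id")

  qthr <- config$quality_threshold %||% 30
  scoring_cfg <- config$scoring %||% list()
  scoring <- align_scoring(
    match = scoring_cfg$match %||% 2,
    mismatch = scoring_cfg$mismatch %||% -3,
    gap_open = scoring_cfg$gap_open %||% -5,
    gap_extend = scoring_cfg$gap_extend %||% -1,
    min_identity = config$min_identity %||% 0.75)

  # validate the sample sheet before any work
  keys <- character(0)
  for (s in config$samples) {
    for (field in c("site", "condition", "replicate", "fastq")) {
      if (is.null(s[[field]])) stop("sample entry missing '", field, "'")
    }
    if (!s$site %in% names(sites)) {
      stop("sample references unknown site '", s$site, "'")
    }
    fq <- resolve(s$fastq)
    if (!file.exists(fq)) {
      stop("missing FASTQ for (site ", s$site, ", condition ", s$condition,
           ", replicate ", s$replicate, "): ", s$fastq)
    }
    keys <- c(keys, paste(s$site, s$condition, s$replicate, sep = "\r"))
  }
  if (anyDuplicated(keys)) {
    stop("duplicate (site, condition, replicate) in sample sheet")
  }

  out_dir <- config$output_dir
  results <- vector("list", length(config$samples))
  log_rows <- vector("list", length(config$samples))
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    reads <- read_fastq(resolve(s$fastq))
    summ <- quantify_site(reads, sites[[s$site]],
                          quality_threshold = qthr, scoring = scoring)
    if (!is.null(out_dir)) {
      write_summary(summ, resolve(out_dir),
                    prefix = paste(s$site, s$condition, s$replicate,
                                   sep = "_"))
    }
    results[[i]] <- list(site = s$site, condition = s$condition,
                         replicate = s$replicate, summary = summ)
    log_rows[[i]] <- data.frame(
      site = s$site, condition = s$condition, replicate = s$replicate,
      n_total = summ$n_total, n_pass_qc = summ$n_pass_qc,
      n_aligned = summ$n_aligned, n_covering = summ$n_covering,
      stringsAsFactors = FALSE)
  }
  run_log <- do.call(rbind, log_rows)
  if (!is.null(out_dir)) {
    utils::write.table(run_log,
                       file.path(resolve(out_dir), "run_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summaries = results, run_log = run_log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consolidated report over replicates
#'
#' Aggregates [run_quantify()] output (or any list of
#' `list(site, condition, replicate, summary)`) into site-by-condition
#' tables with mean +/- s.e.m. over replicates for every outcome category,
#' the dual same-strand frequency and the indel frequency, optional
#' user-specified substitution-pattern frequencies, and the cross-site
#' aggregate spectrum. A single replicate reports its value with an `NA`
#' s.e.m.
#'
#' @param results a [run_quantify()] result or its `summaries` element.
#' @param patterns optional named list: site_id -> character vector of
#'   pattern labels to quantify (superset semantics, see
#'   [pattern_frequency()]).
#' @param output_dir optional directory for TSV/JSON output.
#' @return list with `category_table`, `pattern_table` (NULL when no
#'   patterns requested), `spectrum` (per condition).
#' @export
run_report <- function(results, patterns = NULL, output_dir = NULL) {
  if (!is.null(results$summaries)) results <- results$summaries
  if (length(results) == 0) stop("no summaries to report")

  meta <- data.frame(
    site = vapply(results, `[[`, "", "site"),
    condition = vapply(results, `[[`, "", "condition"),
    stringsAsFactors = FALSE)

  groups <- split(seq_along(results),
                  paste(meta$site, meta$condition, sep = "\r"))
  cat_rows <- list()
  pat_rows <- list()
  for (g in groups) {
    site <- meta$site[g[1]]
    cond <- meta$condition[g[1]]
    summs <- lapply(results[g], `[[`, "summary")
    for (categ in EDIT_CATEGORIES) {
      vals <- vapply(summs, function(s) s$freq_by_category[[categ]], 1)
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        site = site, condition = cond, metric = categ,
        n_replicates = length(vals), mean = mean(vals), sem = sem(vals),
        stringsAsFactors = FALSE)
    }
    if (!is.null(patterns[[site]])) {
      for (lab in patterns[[site]]) {
        vals <- vapply(summs, pattern_frequency, 1, pattern = lab)
        pat_rows[[length(pat_rows) + 1]] <- data.frame(
          site = site, condition = cond, pattern = lab,
          n_replicates = length(vals), mean = mean(vals), sem = sem(vals),
          stringsAsFactors = FALSE)
      }
    }
  }
  category_table <- do.call(rbind, cat_rows)
  pattern_table <- if (length(pat_rows)) do.call(rbind, pat_rows) else NULL

  spectrum <- lapply(split(seq_along(results), meta$condition), function(g) {
    aggregate_window_spectrum(lapply(results[g], `[[`, "summary"))
  })

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(category_table,
                       file.path(output_dir, "category_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pattern_table)) {
      utils::write.table(pattern_table,
                         file.path(output_dir, "pattern_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (cond in names(spectrum)) {
      utils::write.table(spectrum[[cond]],
                         file.path(output_dir,
                                   paste0("spectrum_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(category_table = category_table, pattern_table = pattern_table,
       spectrum = spectrum)
}
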