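#' Summarize classified observations for one site
#'
#' Aggregates per-read outcome calls into the site-level quantities used to
#' report base-editing experiments: outcome-category frequencies (fractions
#' of reads covering the protospacer), the same-strand dual-editing
#' frequency, the indel frequency, an allele (haplotype) table, and the
#' per-position editing spectrum. The spectrum reports, for every
#' protospacer position whose reference base is C (resp. A), the fraction
#' of covering non-indel reads carrying T (resp. G) there; positions with a
#' different reference base are flagged undefined rather than coerced to 0.
#'
#' @param obs observation table from [align_observations()]; classified
#'   internally if the `category` column is absent.
#' @param site the [amplicon_site()].
#' @param n_total,n_pass_qc read counts before/after quality filtering, for
#'   the audit trail (default to the number of observations).
#' @param windows_only passed to the classifier.
#' @return object of class `site_summary` with fields `site_id`, `n_total`,
#'   `n_pass_qc`, `n_aligned`, `n_covering`, `freq_by_category`,
#'   `dual_same_strand_freq`, `indel_freq`, `allele_table`, `spectrum`.
#' @export
summarize_site <- function(obs, site, n_total = nrow(obs),
                           n_pass_qc = nrow(obs), windows_only = FALSE) {
  if (!"category" %in% names(obs)) {
    obs <- classify_observations(obs, site, windows_only = windows_only)
  }
  n_aligned <- sum(obs$aligned)
  cov <- obs[obs$covering, , drop = FALSE]
  n_cov <- nrow(cov)

  if (n_cov == 0) {
    freq <- setNames(rep(NA_real_, length(EDIT_CATEGORIES)), EDIT_CATEGORIES)
    allele <- data.frame(haplotype = character(0), count = integer(0),
                         frequency = numeric(0), category = character(0),
                         pattern = character(0), stringsAsFactors = FALSE)
  } else {
    counts <- table(factor(cov$category, levels = EDIT_CATEGORIES))
    freq <- as.numeric(counts) / n_cov
    names(freq) <- EDIT_CATEGORIES
    agg <- stats::aggregate(
      list(count = rep(1L, n_cov)),
      by = list(haplotype = cov$haplotype, category = cov$category,
                pattern = ifelse(is.na(cov$pattern), "", cov$pattern)),
      FUN = sum)
    ord <- order(-agg$count, agg$haplotype, method = "radix")
    allele <- data.frame(haplotype = agg$haplotype[ord],
                         count = agg$count[ord],
                         frequency = agg$count[ord] / n_cov,
                         category = agg$category[ord],
                         pattern = agg$pattern[ord],
                         stringsAsFactors = FALSE)
  }

  structure(list(
    site_id = site$site_id,
    site = site,
    n_total = as.integer(n_total),
    n_pass_qc = as.integer(n_pass_qc),
    n_aligned = as.integer(n_aligned),
    n_covering = as.integer(n_cov),
    freq_by_category = freq,
    dual_same_strand_freq = unname(freq["DUAL_SAME_STRAND"]),
    indel_freq = unname(freq["INDEL"]),
    allele_table = allele,
    spectrum = position_spectrum(cov, site)
  ), class = "site_summary")
}

# Per-position C>T / A>G frequencies over covering, non-indel reads.
position_spectrum <- function(cov, site, include_indel_reads = FALSE) {
  L <- site$spacer_length
  proto <- split1(site$protospacer_seq)
  samp <- proto_strand_seq(site)
  off <- site$protospacer_offset
  context <- vapply(seq_len(L), function(p) {
    prev <- if (p == 1) {
      if (off >= 1) substr(samp, off, off) else "N"
    } else proto[p - 1]
    paste0(prev, proto[p])
  }, "")

  use <- if (include_indel_reads) cov else cov[!cov$has_indel, , drop = FALSE]
  m <- nrow(use)
  ct <- rep(NA_real_, L)
  ag <- rep(NA_real_, L)
  if (m > 0) {
    callmat <- matrix(unlist(strsplit(use$calls, "", fixed = TRUE)),
                      nrow = m, ncol = L, byrow = TRUE)
    for (p in seq_len(L)) {
      if (proto[p] == "C") ct[p] <- mean(callmat[, p] == "T")
      if (proto[p] == "A") ag[p] <- mean(callmat[, p] == "G")
    }
  }
  data.frame(position = seq_len(L),
             ref_base = proto,
             context = context,
             ct_freq = ct,
             ag_freq = ag,
             ct_defined = proto == "C",
             ag_defined = proto == "A",
             n_reads = m,
             stringsAsFactors = FALSE)
}

#' @export
print.site_summary <- function(x, ...) {
  cat("<site_summary> ", x$site_id, "\n", sep = "")
  cat("  reads: total ", x$n_total, " -> passQC ", x$n_pass_qc,
      " -> aligned ", x$n_aligned, " -> covering ", x$n_covering, "\n",
      sep = "")
  f <- x$freq_by_category
  cat("  categories:", paste(sprintf("%s %.4f", names(f), f),
                             collapse = ", "), "\n")
  cat("  alleles: ", nrow(x$allele_table), "\n", sep = "")
  invisible(x)
}

#' Quantify one read set at one site
#'
#' End-to-end single-sample pipeline: mean-quality filter, orientation +
#' alignment, per-position observation, classification, and aggregation.
#'
#' @param reads a `QualityScaledDNAStringSet` (e.g. from [read_fastq()]).
#' @param site the [amplicon_site()].
#' @param quality_threshold minimum mean read Phred score, default 30.
#' @param scoring an [align_scoring()].
#' @param windows_only restrict classification to the reporting windows.
#' @return a `site_summary`.
#' @export
quantify_site <- function(reads, site, quality_threshold = 30,
                          scoring = align_scoring(), windows_only = FALSE) {
  qc <- filter_quality(reads, quality_threshold)
  obs <- align_observations(qc$kept, site, scoring)
  obs <- classify_observations(obs, site, windows_only = windows_only)
  summarize_site(obs, site, n_total = qc$n_total, n_pass_qc = qc$n_kept,
                 windows_only = windows_only)
}

#' Frequency of a substitution pattern
#'
#' Fraction of covering reads whose substitution set contains all calls of
#' `pattern` (superset semantics — the convention behind labels such as
#' "2C>2T,6A>6G", which count reads that may carry further substitutions;
#' reported separately, larger patterns overlap). Set `exact = TRUE` for
#' exact-set matching. Indel reads never match (their substitution content
#' is pooled).
#'
#' @param summary a `site_summary`.
#' @param pattern pattern label (`"2C>2T,6A>6G"`) or a data.frame from
#'   [parse_pattern()]. Referencing a position whose reference base differs
#'   from the pattern's is an error.
#' @param exact require the substitution set to equal the pattern.
#' @return fraction of covering reads.
#' @export
pattern_frequency <- function(summary, pattern, exact = FALSE) {
  stopifnot(inherits(summary, "site_summary"))
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  site <- summary$site
  proto <- split1(site$protospacer_seq)
  if (nrow(pattern) > 0) {
    if (any(pattern$position < 1 | pattern$position > site$spacer_length)) {
      stop("pattern position outside protospacer")
    }
    bad <- proto[pattern$position] != pattern$ref_base
    if (any(bad)) {
      stop("pattern ref base mismatch at position(s) ",
           paste(pattern$position[bad], collapse = ", "),
           ": protospacer has ",
           paste(proto[pattern$position[bad]], collapse = ", "))
    }
  }
  if (summary$n_covering == 0) return(NA_real_)
  at <- summary$allele_table
  at <- at[at$haplotype != "INDEL", , drop = FALSE]
  if (nrow(at) == 0) return(0)
  want <- sprintf("%d%s>%d%s", pattern$position, pattern$ref_base,
                  pattern$position, pattern$alt_base)
  match_row <- vapply(at$pattern, function(lab) {
    have <- if (nzchar(lab)) strsplit(lab, ",", fixed = TRUE)[[1]] else character(0)
    if (exact) setequal(have, want) else all(want %in% have)
  }, logical(1))
  sum(at$count[match_row]) / summary$n_covering
}

#' Indel frequency of a site summary
#'
#' @param summary a `site_summary`.
#' @return fraction of covering reads classified `INDEL`.
#' @export
indel_frequency <- function(summary) {
  stopifnot(inherits(summary, "site_summary"))
  summary$indel_freq
}

#' Cross-site mean editing spectrum
#'
#' Averages per-position C-to-T and A-to-G frequencies across sites in
#' PAM-relative protospacer coordinates (+1 PAM-distal .. +L; PAM at
#' +L+1..+L+3). Each position's mean is the unweighted arithmetic mean over
#' the sites where that position is defined (the site's protospacer has the
#' relevant reference base there); the number of contributing sites is
#' reported per position, and positions defined in no site stay `NA`.
#'
#' @param summaries list of `site_summary` objects.
#' @return data.frame with `position`, `ct_mean`, `ct_n_sites`, `ag_mean`,
#'   `ag_n_sites`.
#' @export
aggregate_window_spectrum <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  maxL <- max(vapply(summaries, function(s) nrow(s$spectrum), 1L))
  pos <- seq_len(maxL)
  ct_vals <- matrix(NA_real_, length(summaries), maxL)
  ag_vals <- matrix(NA_real_, length(summaries), maxL)
  for (i in seq_along(summaries)) {
    sp <- summaries[[i]]$spectrum
    ct_vals[i, sp$position] <- sp$ct_freq
    ag_vals[i, sp$position] <- sp$ag_freq
  }
  data.frame(
    position = pos,
    ct_mean = colMeans(ct_vals, na.rm = TRUE),
    ct_n_sites = colSums(!is.na(ct_vals)),
    ag_mean = colMeans(ag_vals, na.rm = TRUE),
    ag_n_sites = colSums(!is.na(ag_vals))
  )
}

#' Editing preference by 5' dinucleotide context
#'
#' Mean editing frequency of editable positions grouped by their 5'
#' dinucleotide context on the protospacer strand (AC/CC/GC/TC for C-to-T;
#' AA/CA/GA/TA for A-to-G). Each editable position of each site contributes
#' one value; position 1 takes its 5' base from the amplicon just upstream
#' of the protospacer. Cytidine deaminase domains often show such context
#' preference (e.g. a TC bias), which this table makes visible.
#'
#' @param summaries list of `site_summary` objects.
#' @return data.frame with `context`, `edit` (`"C>T"`/`"A>G"`), `mean_freq`,
#'   `n` (number of contributing positions), ordered by `edit` then
#'   decreasing mean frequency.
#' @export
motif_preference <- function(summaries) {
  rows <- list()
  for (s in summaries) {
    sp <- s$spectrum
    ctp <- sp[sp$ct_defined & !is.na(sp$ct_freq), , drop = FALSE]
    agp <- sp[sp$ag_defined & !is.na(sp$ag_freq), , drop = FALSE]
    if (nrow(ctp) > 0) {
      rows[[length(rows) + 1]] <- data.frame(context = ctp$context,
                                             edit = "C>T", freq = ctp$ct_freq,
                                             stringsAsFactors = FALSE)
    }
    if (nrow(agp) > 0) {
      rows[[length(rows) + 1]] <- data.frame(context = agp$context,
                                             edit = "A>G", freq = agp$ag_freq,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(context = character(0), edit = character(0),
                      mean_freq = numeric(0), n = integer(0)))
  }
  all <- do.call(rbind, rows)
  all <- all[!grepl("N", all$context), , drop = FALSE]  # edge contexts excluded
  agg <- stats::aggregate(freq ~ context + edit, data = all,
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(context = agg$context, edit = agg$edit,
                    mean_freq = agg$freq[, 1], n = as.integer(agg$freq[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$edit, -out$mean_freq), ]
}

#' Welch two-sample t test with significance tiers
#'
#' Two-tailed unequal-variance (Welch) t test between two groups of
#' per-replicate fractions, with the significance tier labels used in
#' figure legends: `N.S.` for p >= 0.05, `*` for 0.05 > p >= 0.001, `**`
#' for 0.001 > p >= 0.0001, `***` for p < 0.0001. Two groups with zero
#' variance and equal means return t = 0, p = 1.
#'
#' @param a,b numeric vectors of replicate values, each length >= 2.
#' @return list with `t`, `df` (Welch-Satterthwaite, fractional), `p`, and
#'   `tier`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 replicates")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  tier = significance_tier(1)))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0,
                tier = significance_tier(0)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, tier = significance_tier(ht$p.value))
}

#' @rdname compare_groups
#' @param p p value.
#' @export
significance_tier <- function(p) {
  if (p < 0.0001) "***"
  else if (p < 0.001) "**"
  else if (p < 0.05) "*"
  else "N.S."
}

#' Plot a per-position editing spectrum
#'
#' Simple barplot of C-to-T and A-to-G frequencies by protospacer position.
#'
#' @param summary a `site_summary` (or a data.frame like its `spectrum`).
#' @param main plot title.
#' @export
plot_spectrum <- function(summary, main = NULL) {
  sp <- if (inherits(summary, "site_summary")) summary$spectrum else summary
  if (is.null(main) && inherits(summary, "site_summary")) {
    main <- summary$site_id
  }
  h <- rbind(ifelse(is.na(sp$ct_freq), 0, sp$ct_freq),
             ifelse(is.na(sp$ag_freq), 0, sp$ag_freq))
  graphics::barplot(h, beside = TRUE, names.arg = sp$position,
                    col = c("firebrick", "grey30"), border = NA,
                    xlab = "protospacer position (PAM-distal = +1)",
                    ylab = "editing frequency", main = main,
                    legend.text = c("C>T", "A>G"))
  invisible(sp)
}
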