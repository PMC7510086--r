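#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-cased sequences, in file order.
#'   Duplicate record ids, empty files and non-nucleotide characters raise a
#'   format error.
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0) stop("FASTA '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("FASTA '", path, "' contains duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]*$", out)
  if (any(bad)) {
    stop("FASTA '", path, "' record(s) ", paste(ids[bad], collapse = ", "),
         " contain non-IUPAC-DNA characters")
  }
  names(out) <- ids
  out
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records with Phred+33 qualities into a
#' [Biostrings::QualityScaledDNAStringSet]. Records whose quality string
#' length differs from the read length raise a format error. Phred+64
#' encodings are not supported.
#'
#' @param path FASTQ file.
#' @return a `QualityScaledDNAStringSet`; per-read integer qualities are
#'   recoverable with [read_quals()].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) {
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character(0))))
  }
  if (length(lines) %% 4 != 0) {
    stop("FASTQ '", path, "': truncated record (line count not a multiple of 4)")
  }
  idx <- seq(1, length(lines), by = 4)
  heads <- lines[idx]
  seqs <- toupper(lines[idx + 1])
  quals <- lines[idx + 3]
  if (any(substr(heads, 1, 1) != "@")) {
    stop("FASTQ '", path, "': record header missing '@'")
  }
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop("FASTQ '", path, "': sequence/quality length mismatch in record(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  ids <- sub("\\s.*$", "", substring(heads, 2))
  dna <- tryCatch(Biostrings::DNAStringSet(seqs),
                  error = function(e) stop("FASTQ '", path,
                                           "': invalid sequence characters",
                                           call. = FALSE))
  names(dna) <- ids
  qmin <- min(utf8ToInt(paste(quals, collapse = "")))
  if (qmin < 33) stop("FASTQ '", path, "': quality character below Phred+33 range")
  Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(quals))
}

#' Integer Phred qualities of a read set
#'
#' @param reads a `QualityScaledDNAStringSet` from [read_fastq()].
#' @return an `IntegerList`, one vector of Phred scores per read.
#' @export
read_quals <- function(reads) {
  methods::as(Biostrings::quality(reads), "IntegerList")
}

#' Mean per-read Phred quality
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @return numeric vector of per-read mean Phred scores.
#' @export
mean_read_quality <- function(reads) {
  q <- read_quals(reads)
  as.numeric(sum(q)) / S4Vectors::elementNROWS(q)
}

#' Filter reads on mean Phred quality
#'
#' Implements the read-level quality filter used for amplicon libraries: a
#' read is kept iff its mean Phred score is at least `threshold` (default
#' Q30). The total and kept counts are returned so downstream frequency
#' denominators stay auditable.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param threshold minimum mean Phred score, default 30.
#' @return list with elements `kept` (filtered read set), `n_total`, `n_kept`.
#' @export
filter_quality <- function(reads, threshold = 30) {
  n_total <- length(reads)
  if (n_total == 0) {
    return(list(kept = reads, n_total = 0L, n_kept = 0L))
  }
  keep <- mean_read_quality(reads) >= threshold
  list(kept = reads[keep], n_total = n_total, n_kept = sum(keep))
}

#' Write a read set as Phred+33 FASTQ
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Write a site summary to disk
#'
#' Serializes a [summarize_site()] result as three files: the allele table
#' and the per-position spectrum as TSV, and the scalar counts/frequencies
#' as JSON. Numbers carry full precision (>= 6 significant digits); allele
#' rows are ordered by count descending, ties broken by haplotype string
#' (C-locale lexicographic), so output is deterministic.
#'
#' @param summary a `site_summary`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default the site id.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_summary <- function(summary, dir, prefix = summary$site_id) {
  stopifnot(inherits(summary, "site_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    alleles = file.path(dir, paste0(prefix, ".alleles.tsv")),
    spectrum = file.path(dir, paste0(prefix, ".spectrum.tsv")),
    scalars = file.path(dir, paste0(prefix, ".summary.json"))
  )
  at <- summary$allele_table
  at$frequency <- signif(at$frequency, 10)
  utils::write.table(at, paths[["alleles"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sp <- summary$spectrum
  sp$ct_freq <- signif(sp$ct_freq, 10)
  sp$ag_freq <- signif(sp$ag_freq, 10)
  utils::write.table(sp, paths[["spectrum"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  scalars <- list(
    site_id = summary$site_id,
    n_total = summary$n_total,
    n_pass_qc = summary$n_pass_qc,
    n_aligned = summary$n_aligned,
    n_covering = summary$n_covering,
    freq_by_category = as.list(summary$freq_by_category),
    dual_same_strand_freq = summary$dual_same_strand_freq,
    indel_freq = summary$indel_freq
  )
  jsonlite::write_json(scalars, paths[["scalars"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
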