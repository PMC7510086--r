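#' Define a target amplicon site
#'
#' An `amplicon_site` ties a reference amplicon to the protospacer targeted by
#' an sgRNA: where the protospacer sits, on which strand, its PAM, and the
#' position windows used for reporting editing spectra. Protospacer positions
#' are numbered 1 (PAM-distal, 5') to L on the protospacer strand; the PAM
#' occupies positions L+1..L+3, i.e. +21..+23 for a canonical 20-nt spacer.
#'
#' @param site_id character identifier.
#' @param amplicon_seq reference amplicon, 5'->3', A/C/G/T/N.
#' @param protospacer_seq protospacer sequence (A/C/G/T), length 15-31,
#'   given on the protospacer strand.
#' @param strand `"+"` if the protospacer reads off `amplicon_seq` directly,
#'   `"-"` if off its reverse complement.
#' @param protospacer_offset optional 0-based offset of protospacer position 1
#'   within the amplicon *on the protospacer strand*. Located automatically
#'   when `NULL`; an error is raised if the protospacer occurs more than once
#'   (ambiguous) or not at all.
#' @param pam_seq the 3-nt PAM immediately 3' of the protospacer. Checked
#'   against the amplicon; inferred from it when `NULL`.
#' @param ct_window,ag_window inclusive protospacer position ranges used for
#'   window-level reporting of C-to-T and A-to-G editing. Defaults `c(1, 7)`
#'   and `c(4, 6)`.
#' @param indel_flank number of nucleotides beyond the protospacer+PAM on
#'   each side inside which an insertion/deletion flags a read as indel.
#' @return an object of class `amplicon_site`.
#' @examples
#' amp <- paste0("GATTACAGATTACA", "GACGTACGTGCATGCATGCA", "TGGATTACAGATTACA")
#' site <- amplicon_site("ex1", amp, "GACGTACGTGCATGCATGCA")
#' site$protospacer_offset
#' @export
amplicon_site <- function(site_id, amplicon_seq, protospacer_seq,
                          strand = "+", protospacer_offset = NULL,
                          pam_seq = NULL, ct_window = c(1L, 7L),
                          ag_window = c(4L, 6L), indel_flank = 5L) {
  amplicon_seq <- toupper(amplicon_seq)
  protospacer_seq <- toupper(protospacer_seq)
  if (!is_dna(amplicon_seq)) {
    stop("site ", site_id, ": amplicon contains characters outside A/C/G/T/N")
  }
  if (!is_dna(protospacer_seq, allow_n = FALSE)) {
    stop("site ", site_id, ": protospacer must be A/C/G/T only")
  }
  L <- nchar(protospacer_seq)
  if (L < 15 || L > 31) {
    stop("site ", site_id, ": spacer length ", L, " outside [15, 31]")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")

  # Work on the protospacer-strand rendering of the amplicon.
  samp <- if (strand == "-") revcomp(amplicon_seq) else amplicon_seq
  if (is.null(protospacer_offset)) {
    hits <- gregexpr(protospacer_seq, samp, fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      stop("site ", site_id, ": protospacer not found in amplicon on '",
           strand, "' strand")
    }
    if (length(hits) > 1) {
      stop("site ", site_id, ": protospacer occurs ", length(hits),
           " times in amplicon; supply protospacer_offset to disambiguate")
    }
    protospacer_offset <- as.integer(hits[1]) - 1L
  }
  protospacer_offset <- as.integer(protospacer_offset)
  found <- substr(samp, protospacer_offset + 1L, protospacer_offset + L)
  if (!identical(found, protospacer_seq)) {
    stop("site ", site_id, ": amplicon does not contain the protospacer at ",
         "offset ", protospacer_offset, " on '", strand, "' strand")
  }
  pam_found <- substr(samp, protospacer_offset + L + 1L,
                      protospacer_offset + L + 3L)
  if (nchar(pam_found) < 3) {
    stop("site ", site_id, ": amplicon too short to contain a PAM 3' of ",
         "the protospacer")
  }
  if (is.null(pam_seq)) {
    pam_seq <- pam_found
  } else {
    pam_seq <- toupper(pam_seq)
    if (nchar(pam_seq) != 3) stop("site ", site_id, ": PAM must be 3 nt")
    ok <- all(mapply(iupac_match, split1(pam_found), split1(pam_seq)))
    if (!ok) {
      stop("site ", site_id, ": stated PAM '", pam_seq,
           "' does not match amplicon PAM '", pam_found, "'")
    }
  }
  ct_window <- as.integer(ct_window)
  ag_window <- as.integer(ag_window)
  for (win in list(ct_window, ag_window)) {
    if (length(win) != 2 || win[1] > win[2] || win[1] < 1 || win[2] > L) {
      stop("site ", site_id, ": window [", paste(win, collapse = ","),
           "] outside protospacer positions [1, ", L, "]")
    }
  }
  indel_flank <- as.integer(indel_flank)
  if (indel_flank < 0) stop("indel_flank must be >= 0")

  structure(list(
    site_id = site_id,
    amplicon_seq = amplicon_seq,
    protospacer_seq = protospacer_seq,
    spacer_length = L,
    strand = strand,
    protospacer_offset = protospacer_offset,
    pam_seq = pam_seq,
    ct_window = ct_window,
    ag_window = ag_window,
    indel_flank = indel_flank
  ), class = "amplicon_site")
}

#' @export
print.amplicon_site <- function(x, ...) {
  cat("<amplicon_site> ", x$site_id, "\n", sep = "")
  cat("  amplicon:    ", nchar(x$amplicon_seq), " nt\n", sep = "")
  cat("  protospacer: ", x$protospacer_seq, " (", x$spacer_length,
      " nt, strand ", x$strand, ", offset ", x$protospacer_offset, ")\n",
      sep = "")
  cat("  PAM: ", x$pam_seq, " at +", x$spacer_length + 1, "..+",
      x$spacer_length + 3, "\n", sep = "")
  cat("  windows: C>T +", x$ct_window[1], "..+", x$ct_window[2],
      ", A>G +", x$ag_window[1], "..+", x$ag_window[2], "\n", sep = "")
  invisible(x)
}

# Amplicon rendered on the protospacer strand.
proto_strand_seq <- function(site) {
  if (site$strand == "-") revcomp(site$amplicon_seq) else site$amplicon_seq
}

# 1-based amplicon (+ strand) coordinate of protospacer-strand position p.
# p may go beyond [1, L] (PAM positions, 5' context); values outside the
# amplicon come back as NA.
proto_to_amplicon_pos <- function(site, p) {
  A <- nchar(site$amplicon_seq)
  a <- if (site$strand == "+") site$protospacer_offset + p
       else A - site$protospacer_offset - p + 1L
  a[a < 1 | a > A] <- NA_integer_
  a
}

# Amplicon-coordinate range within which an indel flags a read:
# protospacer + PAM extended by indel_flank on both sides, clipped.
indel_window_range <- function(site) {
  coords <- proto_to_amplicon_pos(site, seq_len(site$spacer_length + 3L))
  coords <- coords[!is.na(coords)]
  lo <- max(1L, min(coords) - site$indel_flank)
  hi <- min(nchar(site$amplicon_seq), max(coords) + site$indel_flank)
  c(lo, hi)
}

#' Load amplicon sites from a TSV config
#'
#' Reads a tab-separated site table with header columns
#' `site_id amplicon_id protospacer pam strand ct_window ag_window`
#' (optional extra columns `protospacer_offset`, `indel_flank`) and resolves
#' each `amplicon_id` against the supplied reference sequences. Window
#' columns use the form `"1:7"`; empty or `NA` entries fall back to the
#' defaults (+1..+7 for C-to-T, +4..+6 for A-to-G). Every site is validated
#' on load; a protospacer that cannot be placed uniquely on the stated
#' strand raises an error naming the offending `site_id`.
#'
#' @param path TSV config file.
#' @param amplicons named character vector of amplicon sequences, or the
#'   path of a FASTA file to read them from.
#' @return list of [amplicon_site()] objects, in file order.
#' @export
load_sites <- function(path, amplicons) {
  if (is.character(amplicons) && length(amplicons) == 1 &&
      file.exists(amplicons) && is.null(names(amplicons))) {
    amplicons <- read_fasta(amplicons)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("site_id", "amplicon_id", "protospacer", "pam", "strand")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("site config is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  parse_window <- function(x, default) {
    if (is.na(x) || !nzchar(x)) return(default)
    parts <- as.integer(strsplit(x, "[:\\-]")[[1]])
    if (length(parts) != 2 || anyNA(parts)) stop("bad window spec: ", x)
    parts
  }
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (!row$amplicon_id %in% names(amplicons)) {
      stop("site ", row$site_id, ": unknown amplicon_id '", row$amplicon_id, "'")
    }
    offset <- if ("protospacer_offset" %in% names(tab) &&
                  !is.na(row$protospacer_offset) &&
                  nzchar(row$protospacer_offset)) {
      as.integer(row$protospacer_offset)
    } else NULL
    flank <- if ("indel_flank" %in% names(tab) && !is.na(row$indel_flank) &&
                 nzchar(row$indel_flank)) as.integer(row$indel_flank) else 5L
    amplicon_site(
      site_id = row$site_id,
      amplicon_seq = amplicons[[row$amplicon_id]],
      protospacer_seq = row$protospacer,
      strand = row$strand,
      protospacer_offset = offset,
      pam_seq = if (nzchar(row$pam) && !is.na(row$pam)) row$pam else NULL,
      ct_window = parse_window(if ("ct_window" %in% names(tab)) row$ct_window else NA, c(1L, 7L)),
      ag_window = parse_window(if ("ag_window" %in% names(tab)) row$ag_window else NA, c(4L, 6L)),
      indel_flank = flank
    )
  })
}
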