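#' Define an sgRNA guide design
#'
#' @param spacer spacer sequence 5'->3' (A/C/G/T), length 15-31.
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param name guide name.
#' @param require_leading_g enforce the G-N(L-1)-NGG design rule (the U6
#'   promoter wants a leading G). Set `FALSE` to handle arbitrary guides.
#' @return list of class `guide_design`.
#' @export
guide_design <- function(spacer, pam_pattern = "NGG", name = "guide",
                         require_leading_g = TRUE) {
  spacer <- toupper(spacer)
  if (!is_dna(spacer, allow_n = FALSE)) stop("spacer must be A/C/G/T")
  L <- nchar(spacer)
  if (L < 15 || L > 31) stop("spacer length ", L, " outside [15, 31]")
  if (require_leading_g && substr(spacer, 1, 1) != "G") {
    stop("spacer does not start with G (G-N", L - 1,
         "-NGG rule); set require_leading_g = FALSE to allow")
  }
  pam_pattern <- toupper(pam_pattern)
  if (!grepl("^[ACGTRYSWKMBDHVN]{3}$", pam_pattern)) {
    stop("pam_pattern must be a 3-character IUPAC string")
  }
  structure(list(spacer = spacer, length = L, pam_pattern = pam_pattern,
                 name = name), class = "guide_design")
}

#' Validate a guide against its target site
#'
#' Checks the design rules for an sgRNA at an amplicon site: leading G,
#' spacer length in [15, 31], 3'-anchored agreement with the protospacer
#' (variant-length spacers share the PAM-proximal end; spacers longer than
#' the protospacer must extend into the genomic 5' flank), and an NGG PAM.
#'
#' @param design a [guide_design()].
#' @param site an [amplicon_site()].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed checks, empty on pass).
#' @export
validate_guide <- function(design, site) {
  reasons <- character(0)
  sp <- design$spacer
  L <- nchar(sp)
  if (substr(sp, 1, 1) != "G") reasons <- c(reasons, "leading G")
  if (L < 15 || L > 31) reasons <- c(reasons, "spacer length outside [15, 31]")

  samp <- proto_strand_seq(site)
  Lp <- site$spacer_length
  off <- site$protospacer_offset
  # genomic sequence at the spacer's footprint: 3' ends of spacer and
  # protospacer coincide.
  start <- off + Lp - L + 1L
  if (start < 1) {
    reasons <- c(reasons, "amplicon lacks 5' flank for this spacer length")
  } else {
    genomic <- substr(samp, start, off + Lp)
    # Position 1 may be a designed (mismatched) G; compare the rest strictly.
    if (substr(genomic, 2, L) != substr(sp, 2, L) ||
        !(substr(genomic, 1, 1) == substr(sp, 1, 1) ||
          substr(sp, 1, 1) == "G")) {
      reasons <- c(reasons, "spacer does not match protospacer (3'-anchored)")
    }
  }
  pam <- substr(samp, off + Lp + 1L, off + Lp + 3L)
  if (nchar(pam) < 3 ||
      !all(mapply(iupac_match, split1(pam), split1(design$pam_pattern)))) {
    reasons <- c(reasons, paste0("PAM '", pam, "' does not match ",
                                 design$pam_pattern))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Generate PAM-anchored spacer-length variants
#'
#' Builds spacer variants of the requested lengths that all share the
#' PAM-proximal (3') end of the input 20-nt spacer, truncating from the 5'
#' end for shorter variants and extending 5'-ward with genomic sequence for
#' longer ones. The first base is reported as matching the genome or not
#' (a U6-driven guide usually wants a G there) but is never substituted
#' silently.
#'
#' @param spacer20 the canonical 20-nt spacer (must match the site).
#' @param site the [amplicon_site()].
#' @param lengths integer vector of requested spacer lengths in [15, 31].
#' @return data.frame with `name`, `length`, `spacer`,
#'   `leading_base_matches_genome`.
#' @export
spacer_variants <- function(spacer20, site,
                            lengths = c(15L, 18L, 20L, 24L, 27L, 31L)) {
  spacer20 <- toupper(spacer20)
  if (nchar(spacer20) != 20) stop("spacer20 must be 20 nt")
  lengths <- as.integer(lengths)
  if (any(lengths < 15 | lengths > 31)) stop("lengths must lie in [15, 31]")
  samp <- proto_strand_seq(site)
  Lp <- site$spacer_length
  off <- site$protospacer_offset
  proto_end <- off + Lp
  anchor20 <- substr(samp, proto_end - 19L, proto_end)
  if (substr(anchor20, 2, 20) != substr(spacer20, 2, 20)) {
    stop("spacer20 does not match the site's protospacer (3'-anchored)")
  }
  out <- lapply(lengths, function(Lv) {
    start <- proto_end - Lv + 1L
    if (start < 1) {
      stop("requested length ", Lv, " needs ", Lv - proto_end + off,
           " nt more 5' genomic flank than the amplicon provides")
    }
    genomic <- substr(samp, start, proto_end)
    # keep the user's (possibly designed) bases where the variant overlaps
    # the input spacer; genomic sequence beyond it.
    sp <- if (Lv <= 20) substr(spacer20, 20 - Lv + 1, 20)
          else paste0(substr(genomic, 1, Lv - 20), spacer20)
    data.frame(name = sprintf("%s-%d", site$site_id, Lv),
               length = Lv, spacer = sp,
               leading_base_matches_genome =
                 substr(sp, 1, 1) == substr(genomic, 1, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scan sequences for potential off-target sites
#'
#' Un-gapped scan of both strands for windows whose 3'-trailing 3 nt match
#' the PAM pattern exactly (no mismatch budget in the PAM) and whose spacer
#' portion differs from the guide at no more than `max_mismatches`
#' positions. `N` in the scanned sequence counts as a mismatch in the
#' spacer and never satisfies a PAM requirement. The on-target site itself
#' is reported with 0 mismatches.
#'
#' @param design a [guide_design()].
#' @param genome named character vector of sequences (e.g. [read_fasta()]).
#' @param max_mismatches maximum spacer mismatches, default 3.
#' @return data.frame sorted by (mismatch_count, sequence_id, start) with
#'   columns `sequence_id`, `start` (0-based, spacer+PAM footprint on the
#'   forward strand), `end` (exclusive), `strand`, `site_seq` (protospacer
#'   strand orientation), `mismatch_count`, `mismatch_positions`
#'   (comma-separated 1-based spacer positions).
#' @export
scan_offtargets <- function(design, genome, max_mismatches = 3L) {
  sp <- split1(design$spacer)
  L <- length(sp)
  W <- L + 3L
  pam_sets <- IUPAC_SETS[split1(design$pam_pattern)]
  hits <- list()

  scan_one_strand <- function(gchars, n) {
    npos <- n - W + 1L
    if (npos < 1) return(NULL)
    mm <- integer(npos)
    mm_pos <- vector("list", 0)
    for (j in seq_len(L)) {
      mm <- mm + (gchars[j:(j + npos - 1L)] != sp[j])
    }
    ok <- rep(TRUE, npos)
    for (k in 1:3) {
      ok <- ok & gchars[(L + k):(L + k + npos - 1L)] %in% pam_sets[[k]]
    }
    which(ok & mm <= max_mismatches)
  }

  for (sid in names(genome)) {
    seq_f <- toupper(genome[[sid]])
    n <- nchar(seq_f)
    gf <- split1(seq_f)
    gr <- split1(revcomp(seq_f))
    for (strand in c("+", "-")) {
      g <- if (strand == "+") gf else gr
      starts <- scan_one_strand(g, n)
      for (s in starts) {
        window <- g[s:(s + W - 1L)]
        spacer_part <- window[seq_len(L)]
        mpos <- which(spacer_part != sp)
        fstart <- if (strand == "+") s - 1L else n - (s - 1L) - W
        hits[[length(hits) + 1]] <- data.frame(
          sequence_id = sid,
          start = fstart,
          end = fstart + W,
          strand = strand,
          site_seq = paste(window, collapse = ""),
          mismatch_count = length(mpos),
          mismatch_positions = paste(mpos, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_seq = character(0), mismatch_count = integer(0),
                      mismatch_positions = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$mismatch_count, out$sequence_id, out$start,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write off-target hits as BED-like TSV
#'
#' Columns: sequence_id, start (0-based), end (exclusive), name,
#' mismatches, strand.
#'
#' @param hits result of [scan_offtargets()].
#' @param path output file.
#' @param name guide name used in the name column.
#' @return `path`, invisibly.
#' @export
write_offtargets_bed <- function(hits, path, name = "guide") {
  bed <- data.frame(hits$sequence_id, hits$start, hits$end,
                    paste0(name, "_mm", hits$mismatch_count),
                    hits$mismatch_count, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
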