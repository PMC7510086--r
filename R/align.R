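#' Alignment scoring parameters
#'
#' Scores for the semi-global (read end gaps free) affine alignment of reads
#' to their reference amplicon. A gap of length k costs
#' `-gap_open - (k - 1) * -gap_extend`, i.e. the opening penalty pays for the
#' first gapped column. N scores 0 against every base so ambiguous calls
#' neither reward nor punish the aligner.
#'
#' @param match match score (default +2).
#' @param mismatch mismatch score (default -3).
#' @param gap_open score of a 1-column gap (default -5).
#' @param gap_extend score of each additional gap column (default -1).
#' @param min_identity minimum alignment identity (matches / aligned
#'   columns) for a read to count as aligned, default 0.75.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -1, min_identity = 0.75) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            min_identity >= 0, min_identity <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "align_scoring")
}

# Substitution matrix over A/C/G/T/N for Biostrings.
subst_matrix <- function(scoring) {
  b <- c(DNA_BASES, "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# Biostrings' gap convention: cost(k) = gapOpening + k * gapExtension.
# Ours: cost(k) = -gap_open + (k - 1) * -gap_extend.
biostrings_gap <- function(scoring) {
  c(opening = -scoring$gap_open - (-scoring$gap_extend),
    extension = -scoring$gap_extend)
}

new_alignment <- function(read_id, pa, orientation, scoring) {
  ap <- as.character(Biostrings::alignedPattern(pa))
  as <- as.character(Biostrings::alignedSubject(pa))
  ncol <- nchar(ap)
  ident <- if (ncol == 0) 0 else Biostrings::nmatch(pa) / ncol
  structure(list(
    read_id = read_id,
    aligned_read = ap,
    aligned_ref = as,
    score = Biostrings::score(pa),
    identity = ident,
    orientation = orientation,
    ref_start = Biostrings::start(Biostrings::subject(pa)),
    ref_end = Biostrings::end(Biostrings::subject(pa)),
    aligned = ident >= scoring$min_identity
  ), class = "pairwise_alignment")
}

#' Semi-global pairwise alignment
#'
#' Optimal affine-gap alignment with the query aligned end-to-end and
#' reference overhangs free (appropriate when reads sit inside a longer
#' amplicon). Backed by [Biostrings::pairwiseAlignment()] with
#' `type = "global-local"`.
#'
#' @param query read sequence (character).
#' @param ref reference sequence (character).
#' @param scoring an [align_scoring()] object.
#' @param read_id identifier carried through to the result.
#' @return a `pairwise_alignment`: aligned strings with `-` gap characters,
#'   score, identity (matches / aligned columns), reference span, and an
#'   `aligned` flag (identity >= `min_identity`).
#' @examples
#' align_semiglobal("ACGT", "TTACGTTT")$score  # 8: reference overhangs free
#' @export
align_semiglobal <- function(query, ref, scoring = align_scoring(),
                             read_id = "query") {
  if (!nzchar(query) || !nzchar(ref)) stop("empty query or reference")
  gp <- biostrings_gap(scoring)
  pa <- Biostrings::pairwiseAlignment(
    query, ref, type = "global-local",
    substitutionMatrix = subst_matrix(scoring),
    gapOpening = gp[["opening"]], gapExtension = gp[["extension"]])
  new_alignment(read_id, pa, "forward", scoring)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$read_id, " (", x$orientation,
      ", score ", x$score, ", identity ", round(x$identity, 4),
      if (!x$aligned) ", UNALIGNED" else "", ")\n", sep = "")
  cat("  read: ", x$aligned_read, "\n  ref:  ", x$aligned_ref, "\n", sep = "")
  invisible(x)
}

#' Orient and align one read against an amplicon
#'
#' Aligns both the read and its reverse complement semi-globally against the
#' amplicon and keeps the orientation with the higher score (ties go to
#' forward). The result is flagged unaligned when its identity falls below
#' `scoring$min_identity`; an unaligned read is a value, not an error, and
#' is counted separately downstream.
#'
#' @param read read sequence (character), optionally named with the read id.
#' @param amplicon reference amplicon sequence.
#' @param scoring an [align_scoring()].
#' @param read_id read identifier (defaults to the name of `read`).
#' @return a `pairwise_alignment` with `orientation` `"forward"` or
#'   `"revcomp"`.
#' @export
orient_read <- function(read, amplicon, scoring = align_scoring(),
                        read_id = NULL) {
  if (is.null(read_id)) {
    read_id <- if (!is.null(names(read))) names(read)[1] else "read"
  }
  read <- unname(read)
  if (!nzchar(read)) stop("empty read")
  fwd <- align_semiglobal(read, amplicon, scoring, read_id)
  rev <- align_semiglobal(revcomp(read), amplicon, scoring, read_id)
  if (rev$score > fwd$score) {
    rev$orientation <- "revcomp"
    rev
  } else {
    fwd
  }
}

#' Extract per-position protospacer observations from an alignment
#'
#' Walks the alignment columns and reports, for every protospacer position,
#' the read base aligned to that reference position (`-` when the reference
#' base is deleted in the read; `N` for ambiguous calls). Calls and the 5'
#' context base are expressed on the protospacer strand, so downstream
#' classification is strand-free. `has_indel` is set when any deletion or
#' insertion touches the indel window (protospacer + PAM +/- `indel_flank`);
#' insertions at the window edge count as inside.
#'
#' @param aln a `pairwise_alignment` of the read against `site$amplicon_seq`.
#' @param site an [amplicon_site()].
#' @return list with `read_id`, `calls` (L-character string over
#'   `A/C/G/T/N/-`), `has_indel`, `context5`, and `covering` (`FALSE` when
#'   the aligned span does not contain the full protospacer, in which case
#'   the read is excluded from frequency denominators).
#' @export
extract_observation <- function(aln, site) {
  L <- site$spacer_length
  A <- nchar(site$amplicon_seq)
  coords <- proto_to_amplicon_pos(site, seq_len(L))

  if (!aln$aligned ||
      min(coords) < aln$ref_start || max(coords) > aln$ref_end) {
    return(list(read_id = aln$read_id, calls = NA_character_,
                has_indel = NA, context5 = NA_character_, covering = FALSE))
  }

  rchars <- split1(aln$aligned_ref)
  qchars <- split1(aln$aligned_read)
  ncol <- length(rchars)
  refpos <- cumsum(rchars != "-") + aln$ref_start - 1L

  base_at <- rep(NA_character_, A)
  non_gap <- rchars != "-"
  base_at[refpos[non_gap]] <- qchars[non_gap]

  win <- indel_window_range(site)
  # Deletions: reference positions aligned to a gap in the read.
  del_pos <- refpos[non_gap][qchars[non_gap] == "-"]
  has_indel <- any(del_pos >= win[1] & del_pos <= win[2])
  # Insertions: gap columns in the reference, at the junction after refpos.
  if (!has_indel && any(!non_gap)) {
    ins_after <- refpos[!non_gap]  # insertion sits between ins_after, ins_after+1
    has_indel <- any(ins_after + 1L >= win[1] & ins_after <= win[2])
  }

  calls <- base_at[coords]
  ctx_pos <- proto_to_amplicon_pos(site, 0L)
  context5 <- if (is.na(ctx_pos)) "N" else {
    cx <- substr(site$amplicon_seq, ctx_pos, ctx_pos)
    if (site$strand == "-") complement_chars(cx) else cx
  }
  if (site$strand == "-") {
    calls <- complement_chars(calls)
  }
  calls[is.na(calls)] <- "N"

  list(read_id = aln$read_id,
       calls = paste(calls, collapse = ""),
       has_indel = has_indel,
       context5 = context5,
       covering = TRUE)
}

# ---- batch engine ----------------------------------------------------------

# Align a whole read set against one site and extract observations.
#
# Reads whose length equals the amplicon's and whose best ungapped identity
# (over both orientations) reaches `fastpath_min_identity` are resolved by
# direct column comparison; everything else goes through the affine-gap
# aligner (both orientations, higher score wins, ties forward). The two
# routes produce identical observations for substitution-only reads; the
# fast path exists because in deep amplicon data the overwhelming majority
# of reads are full-length substitution-only copies.
#
# Returns a data.frame with one row per read:
#   read_id, orientation, identity, aligned, covering, calls, has_indel,
#   context5
align_observations <- function(reads, site, scoring = align_scoring(),
                               fastpath_min_identity = 0.95) {
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  out <- data.frame(
    read_id = ids,
    orientation = rep(NA_character_, n),
    identity = rep(NA_real_, n),
    aligned = rep(FALSE, n),
    covering = rep(FALSE, n),
    calls = rep(NA_character_, n),
    has_indel = rep(NA, n),
    context5 = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(out)

  amp <- site$amplicon_seq
  A <- nchar(amp)
  dna <- Biostrings::DNAStringSet(reads)
  widths <- Biostrings::width(dna)

  full <- which(widths == A)
  slow <- which(widths != A)

  if (length(full) > 0) {
    # Hamming screen on flat integer vectors (read-major blocks of A);
    # N never counts as a mismatch
    nfull <- length(full)
    s_f <- as.character(dna[full])
    s_r <- as.character(Biostrings::reverseComplement(dna[full]))
    refint <- utf8ToInt(amp)
    nint <- utf8ToInt("N")
    informative <- refint != nint
    mm_of <- function(strs) {
      m <- matrix(utf8ToInt(paste(strs, collapse = "")), nrow = A)
      colSums((m != refint) & (m != nint) & informative)
    }
    mm_f <- mm_of(s_f)
    mm_r <- mm_of(s_r)
    use_rev <- mm_r < mm_f
    mm <- ifelse(use_rev, mm_r, mm_f)
    ident <- 1 - mm / A
    fast <- ident >= fastpath_min_identity

    if (any(fast)) {
      idx <- full[fast]
      oriented <- ifelse(use_rev, s_r, s_f)[fast]
      coords <- proto_to_amplicon_pos(site, seq_len(site$spacer_length))
      ctx_pos <- proto_to_amplicon_pos(site, 0L)
      calls <- substring(oriented, min(coords), max(coords))
      if (site$strand == "-") calls <- revcomp(calls)
      ctx <- if (is.na(ctx_pos)) rep("N", length(idx)) else {
        cx <- substring(oriented, ctx_pos, ctx_pos)
        if (site$strand == "-") complement_chars(cx) else cx
      }
      out$orientation[idx] <- ifelse(use_rev[fast], "revcomp", "forward")
      out$identity[idx] <- ident[fast]
      out$aligned[idx] <- ident[fast] >= scoring$min_identity
      out$covering[idx] <- out$aligned[idx]
      out$has_indel[idx] <- FALSE
      out$calls[idx] <- ifelse(out$aligned[idx], calls, NA_character_)
      out$context5[idx] <- ctx
    }
    slow <- c(slow, full[!fast])
  }

  if (length(slow) > 0) {
    # Deduplicate identical sequences: observations depend only on sequence.
    seqs <- as.character(dna[slow])
    uniq <- unique(seqs)
    map <- match(seqs, uniq)
    gp <- biostrings_gap(scoring)
    smat <- subst_matrix(scoring)
    uset <- Biostrings::DNAStringSet(uniq)
    rset <- Biostrings::reverseComplement(uset)
    sc_f <- Biostrings::pairwiseAlignment(
      uset, amp, type = "global-local", substitutionMatrix = smat,
      gapOpening = gp[["opening"]], gapExtension = gp[["extension"]],
      scoreOnly = TRUE)
    sc_r <- Biostrings::pairwiseAlignment(
      rset, amp, type = "global-local", substitutionMatrix = smat,
      gapOpening = gp[["opening"]], gapExtension = gp[["extension"]],
      scoreOnly = TRUE)
    use_rev <- sc_r > sc_f
    best <- uset
    if (any(use_rev)) best[use_rev] <- rset[use_rev]
    pas <- Biostrings::pairwiseAlignment(
      best, amp, type = "global-local", substitutionMatrix = smat,
      gapOpening = gp[["opening"]], gapExtension = gp[["extension"]])
    # batch-extract alignment components once; per-element S4 subsetting
    # is prohibitively slow at scale
    ap_all <- as.character(Biostrings::pattern(pas))
    as_all <- as.character(Biostrings::subject(pas))
    sc_all <- Biostrings::score(pas)
    nm_all <- Biostrings::nmatch(pas)
    st_all <- Biostrings::start(Biostrings::subject(pas))
    en_all <- Biostrings::end(Biostrings::subject(pas))
    obs_u <- vector("list", length(uniq))
    for (k in seq_along(uniq)) {
      ncol_k <- nchar(ap_all[k])
      ident <- if (ncol_k == 0) 0 else nm_all[k] / ncol_k
      aln <- structure(list(
        read_id = "u", aligned_read = ap_all[k], aligned_ref = as_all[k],
        score = sc_all[k], identity = ident,
        orientation = if (use_rev[k]) "revcomp" else "forward",
        ref_start = st_all[k], ref_end = en_all[k],
        aligned = ident >= scoring$min_identity
      ), class = "pairwise_alignment")
      obs_u[[k]] <- extract_observation(aln, site)
      obs_u[[k]]$identity <- aln$identity
      obs_u[[k]]$aligned <- aln$aligned
      obs_u[[k]]$orientation <- aln$orientation
    }
    rows <- slow
    pick <- function(field) sapply(obs_u, `[[`, field)[map]
    out$orientation[rows] <- pick("orientation")
    out$identity[rows] <- pick("identity")
    out$aligned[rows] <- pick("aligned")
    out$covering[rows] <- pick("covering") & out$aligned[rows]
    out$calls[rows] <- pick("calls")
    out$has_indel[rows] <- pick("has_indel")
    out$context5[rows] <- pick("context5")
  }
  out
}
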