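#' Ground-truth parameters for a synthetic read set
#'
#' Describes how to generate amplicon reads with known editing structure.
#' Two generation modes:
#'
#' * `"class"` — each read is assigned an outcome class from `class_probs`
#'   (`WT`, `CT_ONLY`, `AG_ONLY`, `DUAL`, `INDEL`), and class-specific edits
#'   are applied: `CT_ONLY`/`DUAL` reads draw per-position C-to-T edits from
#'   `ct_profile` (Bernoulli per position, redrawn until at least one edit
#'   so the class is realized; a profile with probability 1 gives a fixed
#'   pattern), `AG_ONLY`/`DUAL` likewise from `ag_profile`.
#' * `"profile"` — every non-indel read draws independent per-position
#'   edits from both profiles and the outcome class is whatever results;
#'   the per-position marginal edit frequency then equals the profile
#'   exactly, which is what spectrum-recovery experiments need. Indel reads
#'   occur with probability `class_probs["INDEL"]`.
#'
#' Edits are applied on the protospacer strand; uniform sequencing errors
#' (each base miscalled with probability `error_rate`, uniformly to the 3
#' alternatives) come after editing, and each read is reverse-complemented
#' with probability `revcomp_prob`. Indels are deletions with lengths drawn
#' from `indel_len_weights` (1..10 nt, default geometrically decaying, the
#' small-deletion regime typical of nickase-based editors) starting
#' uniformly within the protospacer.
#'
#' @param n_reads number of reads.
#' @param class_probs named numeric over
#'   `c("WT","CT_ONLY","AG_ONLY","DUAL","INDEL")`, summing to 1. The default
#'   mirrors a strongly dual-edited amplicon sample: dual 0.2788 with a
#'   cytosine-skewed remainder and a 3% indel load.
#' @param ct_profile data.frame `position`, `prob`: per-read edit
#'   probability of C-to-T at each protospacer position (positions must
#'   carry C). Defaults, applied to a site's C positions inside +1..+7, are
#'   set per site by [default_ct_profile()].
#' @param ag_profile as `ct_profile` for A-to-G (A positions, +4..+6).
#' @param mode `"class"` or `"profile"`.
#' @param error_rate per-base miscall probability in [0, 0.02].
#' @param qual_constant constant Phred score given to every base.
#' @param revcomp_prob probability a read is emitted reverse-complemented.
#' @param indel_len_weights unnormalized weights for deletion lengths 1..10.
#' @param truncate_prob probability a read is 5'/3'-truncated so that it no
#'   longer covers the protospacer (exercises the not-covering path).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(n_reads = 20000,
                             class_probs = c(WT = 0.4912, CT_ONLY = 0.15,
                                             AG_ONLY = 0.05, DUAL = 0.2788,
                                             INDEL = 0.03),
                             ct_profile = NULL, ag_profile = NULL,
                             mode = c("class", "profile"),
                             error_rate = 0.001, qual_constant = 37L,
                             revcomp_prob = 0.5,
                             indel_len_weights = 0.5^(0:9),
                             truncate_prob = 0, seed = 1L) {
  mode <- match.arg(mode)
  classes <- c("WT", "CT_ONLY", "AG_ONLY", "DUAL", "INDEL")
  stopifnot(all(names(class_probs) %in% classes))
  probs <- setNames(numeric(5), classes)
  probs[names(class_probs)] <- class_probs
  if (abs(sum(probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (error_rate < 0 || error_rate > 0.02) {
    stop("error_rate outside [0, 0.02]")
  }
  if (length(indel_len_weights) != 10 || any(indel_len_weights < 0)) {
    stop("indel_len_weights must be 10 non-negative weights (lengths 1..10)")
  }
  structure(list(n_reads = as.integer(n_reads), class_probs = probs,
                 ct_profile = ct_profile, ag_profile = ag_profile,
                 mode = mode, error_rate = error_rate,
                 qual_constant = as.integer(qual_constant),
                 revcomp_prob = revcomp_prob,
                 indel_len_weights = indel_len_weights,
                 truncate_prob = truncate_prob, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Default editing profiles for a site
#'
#' Per-position edit probabilities emulating the canonical deaminase
#' windows: C-to-T active over protospacer positions +1..+7 with a
#' trapezoidal profile (0.11 at the edges rising to 0.29 mid-window,
#' matching the 10.92-29.00% range reported for cytosine editing windows),
#' A-to-G over +4..+6 (0.071, 0.117, 0.071, matching 7.07-11.68%). Only
#' positions whose reference base is editable are returned.
#'
#' @param site an [amplicon_site()].
#' @return list with `ct` and `ag` data.frames (`position`, `prob`).
#' @export
default_ct_profile <- function(site) {
  proto <- split1(site$protospacer_seq)
  ct_shape <- c(0.11, 0.18, 0.25, 0.29, 0.25, 0.18, 0.11)
  ag_shape <- c(0.071, 0.117, 0.071)
  ct_pos <- intersect(1:7, which(proto == "C"))
  ag_pos <- intersect(4:6, which(proto == "A"))
  list(
    ct = data.frame(position = ct_pos, prob = ct_shape[ct_pos]),
    ag = data.frame(position = ag_pos, prob = ag_shape[ag_pos - 3L])
  )
}

# Bernoulli edit matrix for m reads at the profile's positions; rows with no
# edit redrawn when force_one (class mode realizes its class).
draw_edits <- function(m, profile, force_one) {
  k <- nrow(profile)
  if (m == 0 || k == 0) return(matrix(FALSE, m, max(k, 0)))
  em <- matrix(runif(m * k) < rep(profile$prob, each = m), m, k)
  if (force_one) {
    for (iter in 1:100) {
      none <- rowSums(em) == 0
      if (!any(none)) break
      em[none, ] <- matrix(runif(sum(none) * k) < rep(profile$prob, each = sum(none)),
                           sum(none), k)
    }
    none <- rowSums(em) == 0
    if (any(none)) {  # degenerate all-zero profile: force the first position
      em[none, which.max(profile$prob)] <- TRUE
    }
  }
  em
}

#' Simulate an amplicon read set with known truth
#'
#' Generates full-amplicon reads according to `truth` (see
#' [simulation_truth()]) and returns them with a per-read ground-truth
#' manifest. Deterministic: the same `truth$seed` reproduces the same reads
#' byte for byte. The caller's RNG state is left untouched.
#'
#' @param site an [amplicon_site()].
#' @param truth a [simulation_truth()].
#' @return list with `reads` (a `QualityScaledDNAStringSet`), `manifest`
#'   (data.frame `read_id`, `class`, `n_ct`, `n_ag`, `indel_len`,
#'   `revcomp`), `class_counts` (realized per-class counts), and `truth`.
#' @export
simulate_read_set <- function(site, truth) {
  stopifnot(inherits(site, "amplicon_site"),
            inherits(truth, "simulation_truth"))
  with_seed(truth$seed, {
    n <- truth$n_reads
    samp <- proto_strand_seq(site)
    A <- nchar(samp)
    off <- site$protospacer_offset
    L <- site$spacer_length
    profs <- default_ct_profile(site)
    ctp <- if (is.null(truth$ct_profile)) profs$ct else truth$ct_profile
    agp <- if (is.null(truth$ag_profile)) profs$ag else truth$ag_profile
    proto <- split1(site$protospacer_seq)
    if (nrow(ctp) > 0 && any(proto[ctp$position] != "C")) {
      stop("ct_profile position without a reference C")
    }
    if (nrow(agp) > 0 && any(proto[agp$position] != "A")) {
      stop("ag_profile position without a reference A")
    }

    # reads held as one flat integer (UTF-8 code) vector in read-major
    # blocks of A; avoids large byrow character matrices
    ints <- rep.int(utf8ToInt(samp), n)
    lin <- function(rows, p) (rows - 1L) * A + off + p

    if (truth$mode == "class") {
      cls <- sample(names(truth$class_probs), n, replace = TRUE,
                    prob = truth$class_probs)
      ct_rows <- which(cls %in% c("CT_ONLY", "DUAL"))
      ag_rows <- which(cls %in% c("AG_ONLY", "DUAL"))
    } else {
      is_indel <- runif(n) < truth$class_probs[["INDEL"]]
      cls <- ifelse(is_indel, "INDEL", "EDITABLE")
      ct_rows <- which(!is_indel)
      ag_rows <- which(!is_indel)
    }
    force_one <- truth$mode == "class"

    n_ct <- integer(n)
    if (length(ct_rows) > 0 && nrow(ctp) > 0) {
      em <- draw_edits(length(ct_rows), ctp, force_one)
      for (j in seq_len(ncol(em))) {
        ints[lin(ct_rows[em[, j]], ctp$position[j])] <- utf8ToInt("T")
      }
      n_ct[ct_rows] <- rowSums(em)
    }
    n_ag <- integer(n)
    if (length(ag_rows) > 0 && nrow(agp) > 0) {
      em <- draw_edits(length(ag_rows), agp, force_one)
      for (j in seq_len(ncol(em))) {
        ints[lin(ag_rows[em[, j]], agp$position[j])] <- utf8ToInt("G")
      }
      n_ag[ag_rows] <- rowSums(em)
    }

    if (truth$mode == "profile") {
      # class determined by what was actually drawn
      cls[cls == "EDITABLE"] <-
        ifelse(n_ct[ct_rows] > 0 & n_ag[ct_rows] > 0, "DUAL",
        ifelse(n_ct[ct_rows] > 0, "CT_ONLY",
        ifelse(n_ag[ct_rows] > 0, "AG_ONLY", "WT")))
    }

    # sequencing errors: uniform, each to one of the 3 alternative bases
    eps <- truth$error_rate
    base_ints <- utf8ToInt(paste(DNA_BASES, collapse = ""))
    if (eps > 0) {
      err <- which(runif(n * A) < eps)
      err <- err[ints[err] %in% base_ints]  # N positions stay N
      if (length(err) > 0) {
        cur <- ints[err]
        shift <- sample.int(3, length(err), replace = TRUE)
        idx <- (match(cur, base_ints) - 1L + shift) %% 4L + 1L
        ints[err] <- base_ints[idx]
      }
    }

    big <- intToUtf8(ints)
    reads_chr <- substring(big, seq(1L, by = A, length.out = n),
                           seq(A, by = A, length.out = n))

    # deletions for indel reads (applied after errors; a deletion removes
    # the affected bases entirely)
    indel_rows <- which(cls == "INDEL")
    indel_len <- integer(n)
    if (length(indel_rows) > 0) {
      lens <- sample.int(10, length(indel_rows), replace = TRUE,
                         prob = truth$indel_len_weights)
      starts <- off + sample.int(L, length(indel_rows), replace = TRUE)
      ends <- pmin(starts + lens - 1L, A)
      reads_chr[indel_rows] <- paste0(
        substr(reads_chr[indel_rows], 1, starts - 1L),
        substr(reads_chr[indel_rows], ends + 1L, A))
      indel_len[indel_rows] <- ends - starts + 1L
    }

    # optional truncation: keep only sequence 5' of the protospacer, so the
    # read aligns but cannot cover the target
    trunc <- runif(n) < truth$truncate_prob
    if (any(trunc) && off > 20) {
      reads_chr[trunc] <- substr(reads_chr[trunc], 1, off - 1L)
    }

    rc <- runif(n) < truth$revcomp_prob
    if (any(rc)) reads_chr[rc] <- revcomp(reads_chr[rc])

    ids <- sprintf("r%06d", seq_len(n))
    dna <- Biostrings::DNAStringSet(reads_chr)
    names(dna) <- ids
    qchar <- rawToChar(as.raw(truth$qual_constant + 33L))
    quals <- Biostrings::PhredQuality(strrep(qchar, nchar(reads_chr)))
    reads <- Biostrings::QualityScaledDNAStringSet(dna, quals)

    manifest <- data.frame(read_id = ids, class = cls, n_ct = n_ct,
                           n_ag = n_ag, indel_len = indel_len,
                           revcomp = rc, truncated = trunc,
                           stringsAsFactors = FALSE)
    counts <- table(factor(manifest$class,
                           levels = c("WT", "CT_ONLY", "AG_ONLY", "DUAL",
                                      "INDEL")))
    list(reads = reads, manifest = manifest,
         class_counts = setNames(as.integer(counts), names(counts)),
         truth = truth)
  })
}

#' Simulate reads and write FASTQ + manifest files
#'
#' File-level wrapper around [simulate_read_set()]: writes the reads as
#' Phred+33 FASTQ and the ground truth as a JSON manifest (seed, generating
#' parameters, realized class counts, per-read classes).
#'
#' @param site an [amplicon_site()].
#' @param truth a [simulation_truth()].
#' @param fastq_path,manifest_path output files.
#' @return the [simulate_read_set()] result, invisibly.
#' @export
simulate_reads <- function(site, truth, fastq_path, manifest_path) {
  sim <- simulate_read_set(site, truth)
  write_fastq(sim$reads, fastq_path)
  jsonlite::write_json(list(
    site_id = site$site_id,
    seed = truth$seed,
    n_reads = truth$n_reads,
    mode = truth$mode,
    class_probs = as.list(truth$class_probs),
    error_rate = truth$error_rate,
    class_counts = as.list(sim$class_counts),
    reads = sim$manifest
  ), manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Generate a panel of synthetic amplicon sites
#'
#' Builds `n_sites` random amplicons (200-300 nt) with an embedded
#' G-N19-NGG protospacer on a random strand, each paired with a
#' profile-mode [simulation_truth()] drawing C-to-T edits over +1..+7 and
#' A-to-G edits over +4..+6 (see [default_ct_profile()]). Every protospacer
#' is guaranteed at least one C in +1..+7 and one A in +4..+6 so all sites
#' contribute to both spectra. Deterministic under `seed`.
#'
#' @param n_sites number of sites (a typical endogenous-locus panel runs to
#'   45 sgRNAs).
#' @param seed integer seed.
#' @param n_reads reads per site.
#' @param error_rate per-base sequencing error rate.
#' @param indel_prob per-read deletion probability.
#' @param tc_multiplier multiplier applied to the C-to-T edit probability
#'   of positions whose 5' neighbour is T, emulating a TC dinucleotide
#'   preference of the cytidine deaminase; 1 = no context effect.
#' @return list of `list(site, truth)` pairs.
#' @export
fixture_panel <- function(n_sites, seed = 1L, n_reads = 2000,
                          error_rate = 0.001, indel_prob = 0.03,
                          tc_multiplier = 1) {
  with_seed(seed, {
    lapply(seq_len(n_sites), function(i) {
      A <- sample(200:300, 1)
      chars <- sample(DNA_BASES, A, replace = TRUE)
      off <- sample(40:(A - 80), 1)  # room for flanks and PAM
      chars[off + 1] <- "G"                   # G-N19 rule
      chars[off + 22] <- "G"                  # NGG PAM
      chars[off + 23] <- "G"
      # guarantee editable bases inside the windows
      win_ct <- off + 1 + (1:6)   # positions 2..7 (keep position 1 = G)
      if (!any(chars[win_ct] == "C")) chars[sample(win_ct, 1)] <- "C"
      win_ag <- off + (4:6)
      if (!any(chars[win_ag] == "A")) chars[sample(win_ag, 1)] <- "A"
      samp <- paste(chars, collapse = "")
      strand <- sample(c("+", "-"), 1)
      amp <- if (strand == "-") revcomp(samp) else samp
      proto <- substr(samp, off + 1, off + 20)
      site <- amplicon_site(sprintf("panel%02d", i), amp, proto,
                            strand = strand, protospacer_offset = off)
      profs <- default_ct_profile(site)
      if (tc_multiplier != 1 && nrow(profs$ct) > 0) {
        prev <- ifelse(profs$ct$position == 1,
                       substr(samp, off, off),
                       substr(samp, off + profs$ct$position - 1,
                              off + profs$ct$position - 1))
        profs$ct$prob <- pmin(profs$ct$prob *
                                ifelse(prev == "T", tc_multiplier, 1), 0.95)
      }
      truth <- simulation_truth(
        n_reads = n_reads,
        class_probs = c(WT = 1 - indel_prob, INDEL = indel_prob),
        ct_profile = profs$ct, ag_profile = profs$ag,
        mode = "profile", error_rate = error_rate,
        seed = (seed * 1009L + i * 7L) %% .Machine$integer.max)
      list(site = site, truth = truth)
    })
  })
}
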