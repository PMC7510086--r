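EDIT_CATEGORIES <- c("WT", "C_TO_T_ONLY", "A_TO_G_ONLY", "DUAL_SAME_STRAND",
                     "INDEL", "OTHER")

#' Call substitutions in a protospacer observation
#'
#' One call per protospacer position where the observed base differs from
#' the reference protospacer base. `N` (ambiguous) and `-` (deleted)
#' observations never produce calls.
#'
#' @param obs an observation from [extract_observation()] (or any list with
#'   a `calls` string).
#' @param site the [amplicon_site()].
#' @return data.frame with columns `position` (1-based protospacer
#'   position), `ref_base`, `alt_base`; zero rows when the read matches the
#'   protospacer.
#' @export
call_substitutions <- function(obs, site) {
  calls <- split1(obs$calls)
  proto <- split1(site$protospacer_seq)
  hit <- calls != proto & calls %in% DNA_BASES
  data.frame(position = which(hit),
             ref_base = proto[hit],
             alt_base = calls[hit],
             stringsAsFactors = FALSE)
}

#' Classify a read into an editing outcome category
#'
#' Categories, in order of precedence: `INDEL` when any insertion/deletion
#' touches the indel window (indel reads are a standalone class even when
#' they also carry substitutions); `DUAL_SAME_STRAND` when the read carries
#' both a C-to-T and an A-to-G call anywhere in the protospacer — the
#' read-level co-occurrence that demonstrates same-strand dual editing;
#' `C_TO_T_ONLY` / `A_TO_G_ONLY` when only one of the two is present; `WT`
#' when there are no calls; `OTHER` when only unrelated substitutions are
#' present. Unrelated substitutions riding along with C-to-T / A-to-G calls
#' are recorded but never demote the category.
#'
#' @param obs observation (needs `has_indel`).
#' @param subs substitution calls from [call_substitutions()].
#' @param site the site (needed only when `windows_only = TRUE`).
#' @param windows_only when `TRUE`, only C-to-T calls inside `ct_window` and
#'   A-to-G calls inside `ag_window` drive the category (reporting windows
#'   as a classification gate; off by default).
#' @return one of `"WT"`, `"C_TO_T_ONLY"`, `"A_TO_G_ONLY"`,
#'   `"DUAL_SAME_STRAND"`, `"INDEL"`, `"OTHER"`.
#' @export
classify_read <- function(obs, subs, site = NULL, windows_only = FALSE) {
  if (isTRUE(obs$has_indel)) return("INDEL")
  ct <- subs$ref_base == "C" & subs$alt_base == "T"
  ag <- subs$ref_base == "A" & subs$alt_base == "G"
  if (windows_only) {
    stopifnot(!is.null(site))
    ct <- ct & subs$position >= site$ct_window[1] & subs$position <= site$ct_window[2]
    ag <- ag & subs$position >= site$ag_window[1] & subs$position <= site$ag_window[2]
  }
  if (any(ct) && any(ag)) return("DUAL_SAME_STRAND")
  if (any(ct)) return("C_TO_T_ONLY")
  if (any(ag)) return("A_TO_G_ONLY")
  if (nrow(subs) == 0) return("WT")
  "OTHER"
}

#' Haplotype (allele) key of an observation
#'
#' Non-indel reads are keyed by their full L-character calls string (N
#' retained, so reads differing only at an ambiguous position stay
#' distinct); all indel reads pool into the single key `"INDEL"`.
#'
#' @param obs observation with `calls` and `has_indel`.
#' @return character key.
#' @export
haplotype_key <- function(obs) {
  if (isTRUE(obs$has_indel)) "INDEL" else obs$calls
}

# Render a substitution set in the compact pattern style, e.g. "2C>2T,5A>5G".
format_pattern <- function(subs) {
  if (nrow(subs) == 0) return("")
  subs <- subs[order(subs$position), , drop = FALSE]
  paste(sprintf("%d%s>%d%s", subs$position, subs$ref_base,
                subs$position, subs$alt_base), collapse = ",")
}

#' Parse a substitution pattern label
#'
#' Inverse of the `"2C>2T,5A>5G"` rendering used in allele tables.
#'
#' @param label pattern string.
#' @return data.frame with `position`, `ref_base`, `alt_base`.
#' @export
parse_pattern <- function(label) {
  if (!nzchar(label)) {
    return(data.frame(position = integer(0), ref_base = character(0),
                      alt_base = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(label, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)([ACGT])>(\\d+)([ACGT])$", parts))
  bad <- vapply(m, length, 1L) != 5
  if (any(bad)) stop("unparseable pattern element(s): ",
                     paste(parts[bad], collapse = ", "))
  pos <- as.integer(vapply(m, `[[`, "", 2))
  pos2 <- as.integer(vapply(m, `[[`, "", 4))
  if (!all(pos == pos2)) stop("pattern positions disagree within an element")
  data.frame(position = pos,
             ref_base = vapply(m, `[[`, "", 3),
             alt_base = vapply(m, `[[`, "", 5),
             stringsAsFactors = FALSE)
}

# Vectorized classification of a batch observation table.
# Adds columns: category, haplotype, n_subs, pattern, n_ct, n_ag.
classify_observations <- function(obs, site, windows_only = FALSE) {
  n <- nrow(obs)
  obs$category <- rep(NA_character_, n)
  obs$haplotype <- rep(NA_character_, n)
  obs$n_subs <- rep(NA_integer_, n)
  obs$pattern <- rep(NA_character_, n)
  obs$n_ct <- rep(NA_integer_, n)
  obs$n_ag <- rep(NA_integer_, n)
  cov <- which(obs$covering)
  if (length(cov) == 0) return(obs)

  L <- site$spacer_length
  proto <- split1(site$protospacer_seq)
  callmat <- matrix(unlist(strsplit(obs$calls[cov], "", fixed = TRUE)),
                    nrow = length(cov), ncol = L, byrow = TRUE)
  protomat <- matrix(proto, nrow = length(cov), ncol = L, byrow = TRUE)
  is_base <- callmat %in% DNA_BASES
  dim(is_base) <- dim(callmat)
  sub <- (callmat != protomat) & is_base
  ct <- sub & protomat == "C" & callmat == "T"
  ag <- sub & protomat == "A" & callmat == "G"
  if (windows_only) {
    inwin <- function(win) {
      w <- matrix(FALSE, length(cov), L)
      w[, win[1]:win[2]] <- TRUE
      w
    }
    ct <- ct & inwin(site$ct_window)
    ag <- ag & inwin(site$ag_window)
  }
  n_ct <- rowSums(ct)
  n_ag <- rowSums(ag)
  n_subs <- rowSums(sub)
  indel <- obs$has_indel[cov]

  cat <- rep("OTHER", length(cov))
  cat[n_subs == 0] <- "WT"
  cat[n_ct > 0 & n_ag == 0] <- "C_TO_T_ONLY"
  cat[n_ag > 0 & n_ct == 0] <- "A_TO_G_ONLY"
  cat[n_ct > 0 & n_ag > 0] <- "DUAL_SAME_STRAND"
  cat[indel] <- "INDEL"

  # pattern labels per unique haplotype (few) rather than per read (many)
  pat <- character(length(cov))
  key <- obs$calls[cov]
  uu <- unique(key[n_subs > 0])
  if (length(uu) > 0) {
    upat <- vapply(uu, function(s) {
      cal <- split1(s)
      p <- which(cal != proto & cal %in% DNA_BASES)
      paste(sprintf("%d%s>%d%s", p, proto[p], p, cal[p]), collapse = ",")
    }, "", USE.NAMES = FALSE)
    mi <- match(key, uu)
    pat[!is.na(mi)] <- upat[mi[!is.na(mi)]]
  }

  obs$category[cov] <- cat
  obs$haplotype[cov] <- ifelse(indel, "INDEL", obs$calls[cov])
  obs$n_subs[cov] <- n_subs
  obs$pattern[cov] <- ifelse(indel & !nzchar(pat), "", pat)
  obs$n_ct[cov] <- n_ct
  obs$n_ag[cov] <- n_ag
  obs
}
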