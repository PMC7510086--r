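# Independent reference implementations used to validate the package's
# fast paths. These are deliberately written in the most transparent way
# possible (explicit loops, no shared code with the package).

# Affine-gap semi-global alignment score: query aligned end-to-end,
# reference overhangs free. Straightforward Gotoh dynamic program with
# three states; gap of length k costs -gap_open - (k-1) * -gap_extend.
oracle_semiglobal_score <- function(query, ref, match = 2, mismatch = -3,
                                    gap_open = -5, gap_extend = -1) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  m <- length(q)
  n <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)  # last column is (mis)match
  X <- matrix(NEG, m + 1, n + 1)  # last column is gap in query (ref consumed)
  Y <- matrix(NEG, m + 1, n + 1)  # last column is gap in ref (query consumed)
  B <- rep(0, n + 1)              # free leading reference overhang
  for (i in 1:m) {
    Y[i + 1, 1] <- gap_open + (i - 1) * gap_extend
    for (j in 1:n) {
      s <- if (q[i] == r[j]) match else mismatch
      prev <- if (i == 1) B[j] else max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- s + prev
      X[i + 1, j + 1] <- max(M[i + 1, j] + gap_open,
                             X[i + 1, j] + gap_extend,
                             Y[i + 1, j] + gap_open)
      ybase <- if (i == 1) B[j + 1] + gap_open
               else max(M[i, j + 1] + gap_open, Y[i, j + 1] + gap_extend,
                        X[i, j + 1] + gap_open)
      Y[i + 1, j + 1] <- ybase
    }
  }
  max(pmax(M[m + 1, ], Y[m + 1, ]))  # free trailing reference overhang
}

# Exhaustive un-gapped off-target scan: every window on both strands,
# position-by-position comparison.
oracle_scan <- function(spacer, pam_pattern, genome, max_mm) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  sp <- strsplit(spacer, "")[[1]]
  pam <- strsplit(pam_pattern, "")[[1]]
  L <- length(sp)
  W <- L + 3
  rows <- list()
  for (sid in names(genome)) {
    fwd <- toupper(genome[[sid]])
    n <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else dualedit::revcomp(fwd)
      ch <- strsplit(s, "")[[1]]
      if (n < W) next
      for (start in 1:(n - W + 1)) {
        win <- ch[start:(start + W - 1)]
        pam_ok <- TRUE
        for (k in 1:3) {
          if (!win[L + k] %in% iupac[[pam[k]]]) { pam_ok <- FALSE; break }
        }
        if (!pam_ok) next
        mm <- sum(win[1:L] != sp)
        if (mm <= max_mm) {
          fstart <- if (strand == "+") start - 1 else n - (start - 1) - W
          rows[[length(rows) + 1]] <- data.frame(
            sequence_id = sid, start = fstart, strand = strand,
            mismatch_count = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence_id = character(0), start = integer(0),
                      strand = character(0), mismatch_count = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$mismatch_count, out$sequence_id, out$start,
            method = "radix"), ]
}

# Plain-loop read classifier over a calls string: the category definition
# written as prose, position by position.
oracle_classify <- function(calls, proto, has_indel) {
  if (has_indel) return("INDEL")
  cal <- strsplit(calls, "")[[1]]
  ref <- strsplit(proto, "")[[1]]
  saw_ct <- FALSE; saw_ag <- FALSE; saw_other <- FALSE
  for (p in seq_along(ref)) {
    b <- cal[p]
    if (b %in% c("N", "-") || b == ref[p]) next
    if (ref[p] == "C" && b == "T") saw_ct <- TRUE
    else if (ref[p] == "A" && b == "G") saw_ag <- TRUE
    else saw_other <- TRUE
  }
  if (saw_ct && saw_ag) return("DUAL_SAME_STRAND")
  if (saw_ct) return("C_TO_T_ONLY")
  if (saw_ag) return("A_TO_G_ONLY")
  if (saw_other) return("OTHER")
  "WT"
}

# Textbook Welch t statistic / degrees of freedom / two-sided p.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
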