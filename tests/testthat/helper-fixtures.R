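# Shared toy fixtures, built in code.

# A plus-strand site whose protospacer has C at +2 and A at +5 (the classic
# dual-editing pattern positions) embedded in a 223-nt amplicon.
toy_proto <- "GCTGACGTACGTACGTACGT"

toy_site <- function(strand = "+") {
  flank5 <- paste(rep("GATTACAGAT", 10), collapse = "")
  flank3 <- paste(rep("TTACAGGATC", 10), collapse = "")
  samp <- paste0(flank5, toy_proto, "TGG", flank3)
  amp <- if (strand == "-") dualedit::revcomp(samp) else samp
  amplicon_site("toy", amp, toy_proto, strand = strand,
                protospacer_offset = 100L)
}

# Build a QualityScaledDNAStringSet from bare sequences, constant Q37.
as_reads <- function(seqs, qual = 37L) {
  dna <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) {
    names(dna) <- sprintf("r%03d", seq_along(seqs))
  } else {
    names(dna) <- names(seqs)
  }
  qch <- vapply(as.integer(qual), function(x) rawToChar(as.raw(x + 33L)), "")
  q <- Biostrings::PhredQuality(strrep(qch, nchar(seqs)))
  Biostrings::QualityScaledDNAStringSet(dna, q)
}

# Reverse-complement a quality-scaled read set (qualities reversed too).
revcomp_reads <- function(reads) {
  dna <- Biostrings::reverseComplement(
    methods::as(reads, "DNAStringSet"))
  q <- as.character(Biostrings::quality(reads))
  qrev <- vapply(q, function(s)
    intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
  out <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(qrev))
  names(out) <- names(reads)
  out
}

# Edit a read built from the site's amplicon at protospacer positions
# (on the protospacer strand). `edits` is a named vector position -> base.
edited_read <- function(site, edits = c(), delete = NULL) {
  samp <- dualedit:::proto_strand_seq(site)
  ch <- strsplit(samp, "")[[1]]
  off <- site$protospacer_offset
  for (p in names(edits)) {
    ch[off + as.integer(p)] <- edits[[p]]
  }
  if (!is.null(delete)) {
    ch <- ch[-(off + delete)]
  }
  paste(ch, collapse = "")
}
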