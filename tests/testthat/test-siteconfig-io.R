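test_that("read_fasta parses records in order and upper-cases", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">amp1", "acgt", ">amp2", "GGGG", "CCCC"), fa)
  out <- read_fasta(fa)
  expect_identical(out, c(amp1 = "ACGT", amp2 = "GGGGCCCC"))
})

test_that("read_fasta rejects empty files, duplicate ids and bad characters", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa))
  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(read_fasta(fa), "duplicate")
  writeLines(c(">a", "ACGU"), fa)
  expect_error(read_fasta(fa))
})

test_that("read_fastq decodes Phred+33 qualities", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "!!!!"), fq)
  reads <- read_fastq(fq)
  q <- read_quals(reads)
  expect_identical(as.integer(q[[1]]), rep(40L, 4))
  expect_identical(as.integer(q[[2]]), rep(0L, 4))
  expect_identical(names(reads), c("r1", "r2"))
})

test_that("read_fastq rejects length-mismatched quality strings", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "length mismatch")
})

test_that("filter_quality keeps reads by mean Phred >= threshold", {
  fq <- withr::local_tempfile(fileext = ".fq")
  # quals 40,40,20,18 -> mean 29.5, removed at threshold 30
  q1 <- intToUtf8(c(40, 40, 20, 18) + 33)
  writeLines(c("@hi", "ACGT", "+", "IIII",
               "@border", "ACGT", "+", q1,
               "@lo", "ACGT", "+", "5555"), fq)  # "5" = Q20
  reads <- read_fastq(fq)
  res <- filter_quality(reads, 30)
  expect_equal(res$n_total, 3L)
  expect_equal(res$n_kept, 1L)
  expect_identical(names(res$kept), "hi")
})

test_that("filter_quality counts are permutation-invariant and bounded", {
  set.seed(42)
  seqs <- replicate(30, random_dna(50))
  quals <- sample(20:45, 30, replace = TRUE)
  reads <- as_reads(setNames(seqs, sprintf("r%02d", seq_along(seqs))),
                    qual = quals)
  res <- filter_quality(reads, 30)
  perm <- sample(length(reads))
  res2 <- filter_quality(reads[perm], 30)
  expect_lte(res$n_kept, res$n_total)
  expect_setequal(names(res$kept), names(res2$kept))
})

test_that("filter_quality on empty input returns zero counts, no error", {
  empty <- as_reads(character(0))
  res <- filter_quality(empty, 30)
  expect_equal(res$n_total, 0L)
  expect_equal(res$n_kept, 0L)
  expect_length(res$kept, 0)
})

test_that("load_sites locates protospacers and validates invariants", {
  fa <- withr::local_tempfile(fileext = ".fa")
  cfg <- withr::local_tempfile(fileext = ".tsv")
  site <- toy_site("+")
  minus <- toy_site("-")
  writeLines(c(">ampP", site$amplicon_seq, ">ampM", minus$amplicon_seq), fa)
  writeLines(c("site_id\tamplicon_id\tprotospacer\tpam\tstrand\tct_window\tag_window",
               paste("p", "ampP", toy_proto, "NGG", "+", "1:7", "4:6", sep = "\t"),
               paste("m", "ampM", toy_proto, "NGG", "-", "", "", sep = "\t")),
             cfg)
  sites <- load_sites(cfg, fa)
  expect_length(sites, 2)
  expect_equal(sites[[1]]$protospacer_offset, 100L)
  expect_equal(sites[[2]]$strand, "-")
  expect_equal(sites[[2]]$ag_window, c(4L, 6L))
  # minus-strand invariant: revcomp(amplicon) carries the protospacer
  samp <- revcomp(sites[[2]]$amplicon_seq)
  expect_identical(substr(samp, 101, 120), toy_proto)
})

test_that("minus-strand offsets agree with a hand reverse complement", {
  # 60-nt toy: place proto+PAM on the minus strand by hand
  proto <- "GTACGTACGTACGTACGTAC"
  samp <- paste0(paste(rep("CT", 8), collapse = ""), proto, "CGG",
                 "GATTACAGATTACAGATTACA")
  amp <- revcomp(samp)
  site <- amplicon_site("hand", amp, proto, strand = "-")
  expect_equal(site$protospacer_offset, 16L)
  expect_identical(site$pam_seq, "CGG")
})

test_that("ambiguous and absent protospacers are config errors", {
  proto <- "GACGTACGTACGTACGTACG"
  amp2 <- paste0("AAA", proto, "TGGCCTT", proto, "AGGAAA")
  expect_error(amplicon_site("dup", amp2, proto), "twice|times")
  expect_error(amplicon_site("none", "GATTACAGATTACAGATTACA",
                             proto), "not found")
})

test_that("write_summary round-trips tables and orders allele rows", {
  site <- toy_site("+")
  reads <- as_reads(c(
    rep(edited_read(site), 4),
    rep(edited_read(site, c("2" = "T", "5" = "G")), 3),
    rep(edited_read(site, c("2" = "T")), 3)))
  summ <- quantify_site(reads, site)
  dir <- withr::local_tempdir()
  paths <- write_summary(summ, dir)
  at <- utils::read.delim(paths[["alleles"]], stringsAsFactors = FALSE)
  expect_equal(nrow(at), 3)
  expect_equal(at$count, sort(at$count, decreasing = TRUE))
  # tie between the two 3-count alleles broken lexicographically
  ties <- at$haplotype[at$count == 3]
  expect_identical(ties, sort(ties, method = "radix"))
  expect_equal(at$frequency, summ$allele_table$frequency, tolerance = 1e-9)
  sp <- utils::read.delim(paths[["spectrum"]], stringsAsFactors = FALSE)
  expect_equal(sp$ct_freq[2], 0.6, tolerance = 1e-9)
  js <- jsonlite::read_json(paths[["scalars"]])
  expect_equal(js$n_covering, 10)
  expect_equal(js$freq_by_category$DUAL_SAME_STRAND, 0.3, tolerance = 1e-12)
})
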