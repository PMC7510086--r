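test_that("summarize_site counts categories over covering reads", {
  site <- toy_site("+")
  reads <- as_reads(c(
    rep(edited_read(site), 50),
    rep(edited_read(site, c("2" = "T", "5" = "G")), 30),
    rep(edited_read(site, delete = 8:9), 20)))
  summ <- quantify_site(reads, site)
  expect_equal(summ$n_covering, 100L)
  expect_equal(unname(summ$freq_by_category["WT"]), 0.5)
  expect_equal(summ$dual_same_strand_freq, 0.3)
  expect_equal(summ$indel_freq, 0.2)
  expect_equal(indel_frequency(summ), 0.2)
  expect_equal(sum(summ$freq_by_category), 1, tolerance = 1e-9)
  expect_equal(sum(summ$allele_table$count), summ$n_covering)
  expect_equal(sum(summ$allele_table$frequency), 1, tolerance = 1e-9)
})

test_that("an all-WT read set gives a zero spectrum at defined positions", {
  site <- toy_site("+")
  summ <- quantify_site(as_reads(rep(edited_read(site), 20)), site)
  sp <- summ$spectrum
  expect_true(all(sp$ct_freq[sp$ct_defined] == 0))
  expect_true(all(sp$ag_freq[sp$ag_defined] == 0))
  # undefined positions are NA, never 0
  expect_true(all(is.na(sp$ct_freq[!sp$ct_defined])))
  expect_true(all(is.na(sp$ag_freq[!sp$ag_defined])))
})

test_that("spectrum excludes indel reads from its denominator", {
  site <- toy_site("+")
  reads <- as_reads(c(
    rep(edited_read(site, c("2" = "T")), 30),
    rep(edited_read(site), 30),
    rep(edited_read(site, delete = 2:4), 40)))
  summ <- quantify_site(reads, site)
  expect_equal(summ$spectrum$ct_freq[2], 0.5)  # 30 / 60 non-indel
  expect_equal(summ$spectrum$n_reads[1], 60L)
})

test_that("empty covering set yields flagged empty frequencies, not errors", {
  site <- toy_site("+")
  summ <- quantify_site(as_reads(character(0)), site)
  expect_equal(summ$n_covering, 0L)
  expect_true(all(is.na(summ$freq_by_category)))
  expect_equal(nrow(summ$allele_table), 0)
})

test_that("pattern_frequency uses superset semantics with an exact option", {
  site <- toy_site("+")
  reads <- as_reads(c(
    rep(edited_read(site, c("2" = "T", "5" = "G")), 3),
    rep(edited_read(site, c("2" = "T", "5" = "G", "10" = "T")), 2),
    rep(edited_read(site), 5)))
  summ <- quantify_site(reads, site)
  expect_equal(pattern_frequency(summ, "2C>2T,5A>5G"), 0.5)
  expect_equal(pattern_frequency(summ, "2C>2T,5A>5G", exact = TRUE), 0.3)
  expect_equal(pattern_frequency(summ, ""), 1)  # vacuous superset
  expect_error(pattern_frequency(summ, "1C>1T"), "mismatch")
})

test_that("pattern_frequency is monotone non-increasing in pattern size", {
  site <- toy_site("+")
  truth <- simulation_truth(n_reads = 500, error_rate = 0.002, seed = 12,
                            ct_profile = data.frame(position = c(2, 6, 10),
                                                    prob = c(0.5, 0.3, 0.2)),
                            ag_profile = data.frame(position = 5, prob = 0.5))
  summ <- quantify_site(simulate_read_set(site, truth)$reads, site)
  f1 <- pattern_frequency(summ, "2C>2T")
  f2 <- pattern_frequency(summ, "2C>2T,5A>5G")
  f3 <- pattern_frequency(summ, "2C>2T,5A>5G,6C>6T")
  expect_gte(f1, f2)
  expect_gte(f2, f3)
})

test_that("binomial recovery of a generated dual fraction", {
  site <- toy_site("+")
  p <- 0.2788
  truth <- simulation_truth(n_reads = 20000,
                            class_probs = c(WT = 1 - p, DUAL = p),
                            ct_profile = data.frame(position = 2, prob = 1),
                            ag_profile = data.frame(position = 5, prob = 1),
                            error_rate = 0.001, seed = 99)
  summ <- quantify_site(simulate_read_set(site, truth)$reads, site)
  tol <- 3 * sqrt(p * (1 - p) / 20000)
  expect_lt(abs(summ$dual_same_strand_freq - p), tol)
})

test_that("aggregate_window_spectrum averages only defined positions", {
  site <- toy_site("+")
  s1 <- quantify_site(as_reads(c(rep(edited_read(site, c("2" = "T")), 1),
                                 rep(edited_read(site), 9))), site)
  s2 <- quantify_site(as_reads(c(rep(edited_read(site, c("2" = "T")), 3),
                                 rep(edited_read(site), 7))), site)
  agg <- aggregate_window_spectrum(list(s1, s2))
  expect_equal(agg$ct_mean[2], 0.2)
  expect_equal(agg$ct_n_sites[2], 2L)
  # aggregating identical summaries reproduces the single-site spectrum
  agg1 <- aggregate_window_spectrum(list(s1, s1))
  expect_equal(agg1$ct_mean, s1$spectrum$ct_freq)
  # a position defined in no site stays flagged
  expect_true(all(is.na(agg$ct_mean[!s1$spectrum$ct_defined])))
  expect_equal(agg$ct_n_sites[1], 0L)  # position 1 is G in the toy proto
})

test_that("motif_preference separates constructed contexts", {
  # site with two Cs: one in TC context (edited), one in GC (never edited)
  proto <- "GTCAAGCTACGTACGTACGT"
  stopifnot(substr(proto, 3, 3) == "C", substr(proto, 2, 2) == "T",
            substr(proto, 7, 7) == "C", substr(proto, 6, 6) == "G")
  amp <- paste0(paste(rep("GATTATAGAT", 5), collapse = ""), proto, "TGG",
                paste(rep("TTATAGGATC", 5), collapse = ""))
  site <- amplicon_site("motif", amp, proto)
  reads <- as_reads(c(
    rep(edited_read(site, c("3" = "T")), 4),
    rep(edited_read(site), 6)))
  summ <- quantify_site(reads, site)
  mp <- motif_preference(list(summ))
  ct <- mp[mp$edit == "C>T", ]
  expect_equal(ct$mean_freq[ct$context == "TC"], 0.4)
  expect_equal(ct$mean_freq[ct$context == "GC"], 0)
  expect_gt(ct$mean_freq[ct$context == "TC"],
            max(ct$mean_freq[ct$context != "TC"]))
})

test_that("compare_groups matches the closed-form Welch computation", {
  a <- c(0.10, 0.12, 0.11)
  b <- c(0.30, 0.29, 0.31)
  res <- compare_groups(a, b)
  ref <- oracle_welch(a, b)
  expect_equal(res$t, ref$t, tolerance = 1e-10)
  expect_equal(res$df, ref$df, tolerance = 1e-10)
  expect_equal(res$p, ref$p, tolerance = 1e-10)
  expect_lt(res$p, 0.001)
  # symmetry: swapping groups negates t, keeps p
  res2 <- compare_groups(b, a)
  expect_equal(res2$t, -res$t, tolerance = 1e-12)
  expect_equal(res2$p, res$p, tolerance = 1e-12)
})

test_that("compare_groups handles degenerate inputs per contract", {
  res <- compare_groups(c(0.2, 0.2), c(0.2, 0.2))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_identical(res$tier, "N.S.")
  expect_error(compare_groups(0.1, c(0.2, 0.3)), "at least 2")
  # identical vectors elementwise -> t = 0, p = 1
  x <- c(0.1, 0.2, 0.3)
  res2 <- compare_groups(x, x)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("significance tiers follow the legend cut-points", {
  expect_identical(significance_tier(0.2), "N.S.")
  expect_identical(significance_tier(0.05), "N.S.")
  expect_identical(significance_tier(0.049), "*")
  expect_identical(significance_tier(0.001), "*")
  expect_identical(significance_tier(0.0009), "**")
  expect_identical(significance_tier(0.0001), "**")
  expect_identical(significance_tier(0.00009), "***")
})

test_that("sem follows sd/sqrt(n) with NA for single replicates", {
  expect_equal(sem(c(0.1, 0.2, 0.3)), sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(round(sem(c(0.1, 0.2, 0.3)), 4), 0.0577)
  expect_true(is.na(sem(0.5)))
})
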