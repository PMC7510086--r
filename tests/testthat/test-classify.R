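mk_obs <- function(calls, has_indel = FALSE) {
  list(read_id = "r", calls = calls, has_indel = has_indel,
       context5 = "T", covering = TRUE)
}

test_that("call_substitutions reports only real base changes", {
  site <- toy_site("+")
  expect_equal(nrow(call_substitutions(mk_obs(toy_proto), site)), 0)

  # C-to-T at position 2 of a GC-starting protospacer
  calls <- paste0("GT", substr(toy_proto, 3, 20))
  subs <- call_substitutions(mk_obs(calls), site)
  expect_equal(subs$position, 2L)
  expect_identical(subs$ref_base, "C")
  expect_identical(subs$alt_base, "T")

  # N and - never produce calls
  calls_n <- paste0(substr(toy_proto, 1, 2), "N", substr(toy_proto, 4, 20))
  expect_equal(nrow(call_substitutions(mk_obs(calls_n), site)), 0)
  calls_d <- paste0(substr(toy_proto, 1, 2), "-", substr(toy_proto, 4, 20))
  expect_equal(nrow(call_substitutions(mk_obs(calls_d), site)), 0)
})

test_that("classify_read applies the category precedence", {
  site <- toy_site("+")
  sub_ag <- data.frame(position = 5L, ref_base = "A", alt_base = "G")
  sub_dual <- data.frame(position = c(2L, 5L), ref_base = c("C", "A"),
                         alt_base = c("T", "G"))
  sub_other <- data.frame(position = 7L, ref_base = "G", alt_base = "T")

  expect_identical(classify_read(mk_obs(toy_proto, TRUE), sub_ag), "INDEL")
  expect_identical(classify_read(mk_obs(toy_proto), sub_dual),
                   "DUAL_SAME_STRAND")
  expect_identical(classify_read(mk_obs(toy_proto), sub_other), "OTHER")
  expect_identical(
    classify_read(mk_obs(toy_proto),
                  sub_ag[0, , drop = FALSE]), "WT")
  # unrelated substitutions do not demote the category
  expect_identical(classify_read(mk_obs(toy_proto),
                                 rbind(sub_dual, sub_other)),
                   "DUAL_SAME_STRAND")
  expect_identical(classify_read(mk_obs(toy_proto),
                                 rbind(sub_ag, sub_other)), "A_TO_G_ONLY")
})

test_that("haplotype keys are the calls string; indel reads pool", {
  expect_identical(haplotype_key(mk_obs(toy_proto)), toy_proto)
  expect_identical(haplotype_key(mk_obs(toy_proto, TRUE)), "INDEL")
  withN <- paste0("N", substr(toy_proto, 2, 20))
  expect_false(haplotype_key(mk_obs(withN)) == haplotype_key(mk_obs(toy_proto)))
})

test_that("classification matches an exhaustive oracle on a 4-nt toy site", {
  # L = 4 toy protospacer embedded with its own PAM; enumerate all 6^4
  # call strings
  proto4 <- "GCAT"
  alphabet <- c("A", "C", "G", "T", "N", "-")
  grid <- expand.grid(p1 = alphabet, p2 = alphabet, p3 = alphabet,
                      p4 = alphabet, stringsAsFactors = FALSE)
  calls_all <- do.call(paste0, grid)
  proto_chars <- strsplit(proto4, "")[[1]]

  # package route, vectorized over a fake observation table
  obs <- data.frame(read_id = sprintf("e%04d", seq_along(calls_all)),
                    orientation = "forward", identity = 1, aligned = TRUE,
                    covering = TRUE, calls = calls_all,
                    has_indel = grepl("-", calls_all, fixed = TRUE),
                    context5 = "T", stringsAsFactors = FALSE)
  fake_site <- structure(list(site_id = "L4", protospacer_seq = proto4,
                              spacer_length = 4L, ct_window = c(1L, 4L),
                              ag_window = c(1L, 4L)),
                         class = "amplicon_site")
  res <- dualedit:::classify_observations(obs, fake_site)
  expected <- vapply(seq_along(calls_all), function(i)
    oracle_classify(calls_all[i], proto4, obs$has_indel[i]), "")
  expect_identical(res$category, expected)
  # every read gets exactly one category; counts add up
  expect_false(anyNA(res$category))
  expect_equal(sum(table(res$category)), length(calls_all))
})

test_that("dual reads carry both edits in the same haplotype string", {
  site <- toy_site("+")
  truth <- simulation_truth(n_reads = 400,
                            class_probs = c(WT = 0.3, DUAL = 0.7),
                            ct_profile = data.frame(position = 2, prob = 1),
                            ag_profile = data.frame(position = 5, prob = 1),
                            error_rate = 0, seed = 10)
  sim <- simulate_read_set(site, truth)
  obs <- dualedit:::align_observations(sim$reads, site)
  res <- dualedit:::classify_observations(obs, site)
  duals <- res[res$category == "DUAL_SAME_STRAND", ]
  expect_gt(nrow(duals), 0)
  expect_true(all(substr(duals$haplotype, 2, 2) == "T" &
                    substr(duals$haplotype, 5, 5) == "G"))
})

test_that("pattern labels render and parse reversibly", {
  subs <- data.frame(position = c(5L, 2L), ref_base = c("A", "C"),
                     alt_base = c("G", "T"))
  lab <- dualedit:::format_pattern(subs)
  expect_identical(lab, "2C>2T,5A>5G")
  back <- parse_pattern(lab)
  expect_equal(back$position, c(2L, 5L))
  expect_identical(back$alt_base, c("T", "G"))
  expect_equal(nrow(parse_pattern("")), 0)
  expect_error(parse_pattern("2C>3T"), "disagree")
})

test_that("window-restricted classification is available behind the flag", {
  site <- toy_site("+")  # ct_window 1..7, ag_window 4..6
  # C>T at position 10 (outside window), A>G at 5 (inside)
  calls <- toy_proto
  substr(calls, 10, 10) <- "T"  # position 10 is C in toy_proto? ensure below
  stopifnot(substr(toy_proto, 10, 10) == "C")
  substr(calls, 5, 5) <- "G"
  obs <- mk_obs(calls)
  subs <- call_substitutions(obs, site)
  expect_identical(classify_read(obs, subs), "DUAL_SAME_STRAND")
  expect_identical(classify_read(obs, subs, site, windows_only = TRUE),
                   "A_TO_G_ONLY")
})
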