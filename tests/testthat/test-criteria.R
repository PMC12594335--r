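PLANT <- mode_config("plant")
ANIMAL <- mode_config("animal")

test_that("mode thresholds encode the published criteria", {
  expect_equal(PLANT$duplex_len_max, 24L)
  expect_equal(ANIMAL$duplex_len_max, 26L)
  expect_equal(PLANT$precursor_warn_len, 300L)
  expect_equal(ANIMAL$precursor_warn_len, 200L)
  expect_equal(PLANT$read_floor, 10L)
  expect_equal(PLANT$precision_min, 0.75)
  expect_error(mode_config("plant", nonsense = 1), "unknown config field")
})

test_that("flag severities follow the published table", {
  expect_equal(severity_of("No 2nt 3' overhang", PLANT), "fail")
  expect_equal(severity_of("No 2nt 3' overhang", ANIMAL), "fail")
  expect_equal(severity_of("More than 5 mismatches in duplex", PLANT), "fail")
  expect_equal(severity_of("More than 5 mismatches in duplex", ANIMAL),
               "warning")
  expect_equal(severity_of("More than 7 mismatches in duplex", ANIMAL), "fail")
  expect_equal(severity_of("Precursor > 300 nt", PLANT), "warning")
  expect_equal(severity_of("Precursor > 200 nt", ANIMAL), "warning")
  expect_equal(severity_of("23/24 nt miRNA", PLANT), "warning")
  expect_error(severity_of("not a flag", PLANT), "unknown flag code")
  expect_length(flag_codes(), 15L)
})

test_that("a clean locus passes with no flags, with or without user star", {
  fx <- eval_fixture(fixture_spec(seed = 51L))
  expect_equal(fx$result$verdict, "pass")
  expect_equal(nrow(fx$result$flags), 0L)
  expect_equal(fx$result$reported_libraries$precision, 1)

  fx2 <- eval_fixture(fixture_spec(seed = 51L), with_star = FALSE)
  expect_equal(fx2$result$verdict, "pass")
  expect_equal(fx2$result$star_source, "predicted")
  expect_equal(fx2$result$star_iv, fx$truth$star_iv)
})

test_that("23/24-nt duplex strands warn but pass", {
  fx <- eval_fixture(fixture_spec(seed = 52L, mature_len = 24L))
  expect_equal(fx$result$flags$code, "23/24 nt miRNA")
  expect_equal(fx$result$flags$severity, "warning")
  expect_equal(fx$result$verdict, "pass")
})

test_that("mismatch flags are mode-dependent", {
  # two 3+3 symmetric internal loops: 6 mismatches with stable helices
  spec6 <- fixture_spec(seed = 53L, planted_mismatches = c(5L, 6L, 7L,
                                                           12L, 13L, 14L))
  plant <- eval_fixture(spec6, "plant")
  expect_equal(plant$result$flags$code, "More than 5 mismatches in duplex")
  expect_equal(plant$result$verdict, "fail")

  animal <- eval_fixture(spec6, "animal")
  expect_equal(animal$result$flags$code, "More than 5 mismatches in duplex")
  expect_equal(animal$result$flags$severity, "warning")
  expect_equal(animal$result$verdict, "pass")
})

test_that("duplex strand length limits are mode-dependent", {
  # 25-nt strands: fail in plants, unflagged in animals
  spec25 <- fixture_spec(seed = 54L, mature_len = 25L)
  plant <- eval_fixture(spec25, "plant")
  expect_true(all(c("Mature miRNA length not met", "Star length not met")
                  %in% plant$result$flags$code))
  expect_equal(plant$result$verdict, "fail")

  animal <- eval_fixture(spec25, "animal")
  expect_false(any(grepl("length not met", animal$result$flags$code)))
  expect_equal(animal$result$verdict, "pass")
})

test_that("short hairpins fail and long precursors warn", {
  short <- eval_fixture(fixture_spec(seed = 55L, mature_len = 20L,
                                     loop_len = 5L, flank5_len = 2L,
                                     flank3_len = 2L))
  expect_equal(nchar(short$truth$hairpin), 49L)
  expect_equal(short$result$flags$code, "Hairpin is less than 50 nucleotides")
  expect_equal(short$result$verdict, "fail")

  long <- eval_fixture(fixture_spec(seed = 56L, flank5_len = 131L,
                                    flank3_len = 129L))
  expect_equal(nchar(long$truth$hairpin), 310L)
  expect_equal(long$result$flags$code, "Precursor > 300 nt")
  expect_equal(long$result$verdict, "pass")
})

test_that("multimapping or absent duplex strands stop evaluation", {
  tr <- make_hairpin(fixture_spec(seed = 57L))
  lib <- list(make_library(tr))

  dup_hp <- paste0(tr$hairpin, "AAAA", tr$mature_seq, "AACC")
  res <- evaluate_locus(locus_input("L1", dup_hp, tr$mature_seq), lib, PLANT)
  expect_equal(res$flags$code, "miRNA multimaps to hairpin")
  expect_equal(res$verdict, "fail")
  expect_null(res$all_metrics)  # expression skipped

  res2 <- evaluate_locus(
    locus_input("L2", tr$hairpin, "UUUUGGGGUUUUGGGGUUUUG"), lib, PLANT)
  expect_equal(res2$flags$code, "Hairpin structure invalid")
  expect_match(res2$flags$detail, "not found")

  # user-supplied star that does not locate
  res3 <- evaluate_locus(
    locus_input("L3", tr$hairpin, tr$mature_seq,
                star_seq = "UUUUGGGGUUUUGGGGUUUUG"), lib, PLANT)
  expect_equal(res3$flags$code, "Hairpin structure invalid")
  expect_match(res3$flags$detail, "star")
})

test_that("the predicted star is recorded even with a user-supplied star", {
  fx <- eval_fixture(fixture_spec(seed = 58L))
  expect_equal(fx$result$star_source, "user")
  expect_equal(fx$result$predicted_star_iv, fx$truth$star_iv)
})

test_that("verdict fails iff a fail-severity flag is present", {
  # warning-only combination: 23-nt strands + long plant precursor
  warn2 <- eval_fixture(fixture_spec(seed = 59L, mature_len = 23L,
                                     flank5_len = 131L, flank3_len = 131L))
  expect_setequal(warn2$result$flags$code,
                  c("23/24 nt miRNA", "Precursor > 300 nt"))
  expect_equal(warn2$result$flags$severity, c("warning", "warning"))
  expect_equal(warn2$result$verdict, "pass")

  # warning + fail: 24-nt strands with a 4-nt bulge
  mixed <- eval_fixture(fixture_spec(
    seed = 60L, mature_len = 24L,
    planted_bulge = list(side = "star", pos = 12L, size = 4L)))
  expect_true("Asymmetric bulge greater than 3" %in% mixed$result$flags$code)
  expect_true("23/24 nt miRNA" %in% mixed$result$flags$code)
  expect_equal(mixed$result$verdict, "fail")

  # structural warnings plus an expression fail
  tr <- make_hairpin(fixture_spec(seed = 61L, mature_len = 23L,
                                  mature_copies = 5L, star_copies = 3L))
  res <- evaluate_locus(fixture_locus(tr), list(make_library(tr)), PLANT)
  expect_setequal(res$flags$code,
                  c("23/24 nt miRNA", "Less than 10 reads in a single library"))
  expect_equal(res$verdict, "fail")

  for (r in list(warn2$result, mixed$result, res)) {
    expect_equal(r$verdict,
                 if (any(r$flags$severity == "fail")) "fail" else "pass")
  }
})

test_that("identical inputs give identical results", {
  a <- eval_fixture(fixture_spec(seed = 62L))$result
  b <- eval_fixture(fixture_spec(seed = 62L))$result
  expect_identical(a, b)
})
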