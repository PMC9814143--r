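test_that("zero noise and jitter reproduce the reference peak list", {
  sp <- parse_lipid_name("PC 18:0/18:1(n-9)")
  ref <- generate_reference_spectrum(sp)
  spec <- simulate_spectrum(sp, noise_free_sim())
  expect_equal(spec$mz, ref$mz, tolerance = 1e-12)
  expect_equal(spec$intensity / max(spec$intensity),
               ref$rel_intensity / max(ref$rel_intensity), tolerance = 1e-12)
})

test_that("a fixed seed gives identical spectra; different seeds differ", {
  sp <- parse_lipid_name("PE 16:0_20:4(n-6,9,12,15)")
  a <- simulate_spectrum(sp, seed = 99)
  b <- simulate_spectrum(sp, seed = 99)
  expect_identical(a, b)
  c <- simulate_spectrum(sp, seed = 100)
  expect_false(identical(a$mz, c$mz))
})

test_that("a 50/50 co-eluting isomer mixture carries both diagnostic pairs", {
  a <- parse_lipid_name("PC 16:0_18:1(n-9)")
  b <- parse_lipid_name("PC 16:0_18:1(n-7)")
  spec <- simulate_spectrum(a, noise_free_sim(), coeluting = b, mix_fraction = 0.5)
  prec <- precursor_mz(a)
  for (x in c(7L, 9L)) {
    nl <- lipidoad:::diagnostic_pair_nl(x, 1L)
    expect_true(any(abs(spec$mz - (prec - nl$nl03)) < 1e-4), label = sprintf("n-%d O3", x))
    expect_true(any(abs(spec$mz - (prec - nl$nl16)) < 1e-4), label = sprintf("n-%d 16", x))
  }
})

test_that("truth sets are reproducible, subclass-restricted, self-consistent", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  ts1 <- make_truthset(10, subclass_mix = c("PC", "TG"), seed = 3, dir = dir1)
  ts2 <- make_truthset(10, subclass_mix = c("PC", "TG"), seed = 3, dir = dir2)
  expect_identical(nrow(ts1$alignment), 10L)
  expect_identical(nrow(ts1$spectra), 10L)
  expect_identical(readr::read_file(ts1$paths$mgf), readr::read_file(ts2$paths$mgf))
  expect_identical(readr::read_file(ts1$paths$alignment), readr::read_file(ts2$paths$alignment))
  expect_true(all(grepl("^(PC|TG) ", ts1$truth$truth_name)))
  # files are consumable by the pipeline readers
  rec <- read_alignment_table(ts1$paths$alignment)
  spec <- read_spectra(ts1$paths$mgf)
  expect_identical(nrow(rec), 10L)
  expect_identical(nrow(spec), 10L)
})

test_that("PPV arithmetic and ambiguity accounting are exact", {
  truth <- tibble::tibble(
    record_id = 1:10,
    truth_name = c(rep("PC 16:0_18:1(n-9)", 9), "PC 16:0_18:1(n-7)"),
    n_unsaturated = rep(1L, 10)
  )
  results <- tibble::tibble(
    record_id = 1:10,
    resolved_name = rep("PC 16:0_18:1(n-9)", 10),
    status = rep("resolved", 10),
    score = rep(1, 10)
  )
  ev <- evaluate_ppv(results, truth)
  expect_equal(ev$summary$ppv, 90)
  expect_equal(ev$summary$n_correct_top, 9L)

  all_right <- dplyr::mutate(results, resolved_name = truth$truth_name)
  expect_equal(evaluate_ppv(all_right, truth)$summary$ppv, 100)

  # ambiguous output counts only when the truth is among the alternatives
  amb <- dplyr::mutate(results,
    resolved_name = "PC 16:0_18:1(n-7&9)", status = "ambiguous")
  ev_amb <- evaluate_ppv(amb, truth)
  expect_equal(ev_amb$summary$n_correct_top, 10L)
  amb2 <- dplyr::mutate(results,
    resolved_name = "PC 16:0_18:1(n-5&9)", status = "ambiguous")
  expect_equal(evaluate_ppv(amb2, truth)$summary$n_correct_top, 9L)

  # chain-unresolved records count at the species level: position multisets
  # may permute among equal-DBE chains, but must still agree
  swap <- tibble::tibble(
    record_id = 1L, resolved_name = "PC 16:1(n-9)_18:1(n-7)",
    status = "chain-unresolved", score = 1
  )
  truth_swap <- tibble::tibble(
    record_id = 1L, truth_name = "PC 16:1(n-7)_18:1(n-9)", n_unsaturated = 2L
  )
  expect_equal(evaluate_ppv(swap, truth_swap)$summary$n_correct_top, 1L)
  wrong_pos <- dplyr::mutate(swap, resolved_name = "PC 16:1(n-5)_18:1(n-7)")
  expect_equal(evaluate_ppv(wrong_pos, truth_swap)$summary$n_correct_top, 0L)
  # without the chain-unresolved flag the species-level relaxation is off
  claimed <- dplyr::mutate(swap, status = "resolved")
  expect_equal(evaluate_ppv(claimed, truth_swap)$summary$n_correct_top, 0L)

  expect_error(evaluate_ppv(dplyr::mutate(results, record_id = record_id + 100), truth),
               "record_id")
})

test_that("strata partition the evaluated set", {
  ts <- make_truthset(12, seed = 5)
  paired <- join_cid_oad(ts$alignment, ts$spectra)
  ev <- evaluate_ppv(annotate_batch(paired), ts$truth)
  expect_identical(sum(ev$strata$n_attempted), ev$summary$n_attempted)
  expect_identical(sum(ev$strata$n_annotated), ev$summary$n_annotated)
  expect_identical(sum(ev$strata$n_correct), ev$summary$n_correct_top)
  expect_identical(nrow(tidy(ev)), 12L)
  expect_identical(nrow(glance(ev)), 1L)
})

test_that("threshold sweep spans permissive to prohibitive floors", {
  ts <- make_truthset(8, seed = 21,
                      sim = simulation_config(noise_lambda = 40, mz_sigma_ppm = 2))
  sw <- threshold_sweep(ts, thresholds = c(0, 1e-4, 0.2))
  expect_setequal(unique(sw$stratum), c("total", "single", "multiple"))
  tot <- sw[sw$stratum == "total", ]
  expect_identical(nrow(tot), 3L)
  # a 20% floor rejects the genuine low-abundance pair ions
  expect_lt(tot$n_annotated[tot$threshold == 0.2],
            tot$n_annotated[tot$threshold == 1e-4])
})
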