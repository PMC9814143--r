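toy_measured <- function(mz, intensity) tibble::tibble(mz = mz, intensity = intensity)

test_that("reference peaks match the nearest measured peak within tolerance", {
  meas <- toy_measured(c(500.1, 933.6820), c(10, 50))
  ref <- tibble::tibble(mz = 933.6816, rel_intensity = 0.1)
  m <- match_peaks(meas, ref, tol_ppm = 15)
  expect_equal(m$matched_mz, 933.6820)
  expect_equal(m$ppm, 0.43, tolerance = 0.01)

  m2 <- match_peaks(toy_measured(933.6452, 50), ref, tol_ppm = 15)
  expect_true(is.na(m2$matched_mz)) # 38.99 ppm away
  m3 <- match_peaks(toy_measured(numeric(0), numeric(0)), ref, tol_ppm = 15)
  expect_true(is.na(m3$matched_mz))
})

test_that("essential pair verification needs both ions above threshold", {
  sp <- parse_lipid_name("PC 18:0/18:1(n-9)")
  prec <- precursor_mz(sp)
  full <- toy_measured(
    c(184.0733, prec - 139.1487, prec - 97.1381, prec),
    c(1e5, 30, 30, 5e4) # pair at 0.03% of base
  )
  v <- verify_essential_pair(full, sp)
  expect_identical(nrow(v), 1L)
  expect_true(v$pass)

  one_gone <- full[-2, ]
  expect_false(verify_essential_pair(one_gone, sp)$pass)

  faint <- full
  faint$intensity[2:3] <- 5 # 0.005% of base: below the 0.01% floor
  expect_false(verify_essential_pair(faint, sp)$pass)
})

test_that("the sphingoid delta-4 bond uses its lower intensity floor", {
  sm <- parse_lipid_name("SM 18:1(Δ4);O2/18:1(n-9)")
  prec <- precursor_mz(sm)
  nl <- lipidoad:::diagnostic_pair_nl(14L, 1L)
  meas <- toy_measured(
    c(184.0733, prec - nl$nl16, prec - nl$nl03,
      prec - 139.1487, prec - 97.1381),
    c(1e5, 7, 7, 100, 100) # delta-4 pair at 0.007% of base
  )
  v <- verify_essential_pair(meas, sm)
  d4row <- v[v$chain_index == 1, ]
  expect_true(d4row$delta4)
  expect_true(d4row$pass) # 0.007% >= 0.005% delta-4 floor
  strict <- verify_essential_pair(meas, sm, oad_config(min_rel_intensity_delta4 = 1e-4))
  expect_false(strict[strict$chain_index == 1, ]$pass) # fails the acyl floor
})

test_that("reverse dot product has the textbook fixed points", {
  ref <- generate_reference_spectrum(parse_lipid_name("PC 18:0/18:1(n-9)"))
  self <- toy_measured(ref$mz, ref$rel_intensity)
  expect_equal(reverse_dot_product(self, ref), 1)
  nothing <- toy_measured(2000, 1)
  expect_equal(reverse_dot_product(nothing, ref), 0)
  expect_error(reverse_dot_product(self, ref[0, ]), "Empty")
})

test_that("reverse dot product equals the hand-computed toy value", {
  # measured (4,1,0) vs reference (1,1,1): sqrt -> (2,1,0)/(1,1,1)
  # score = (2+1+0)^2 / ((4+1+0)*(1+1+1)) = 9/15
  ref <- tibble::tibble(mz = c(100, 200, 300), rel_intensity = c(1, 1, 1))
  meas <- toy_measured(c(100, 200), c(4, 1))
  expect_equal(reverse_dot_product(meas, ref), 9 / 15, tolerance = 1e-12)
})

test_that("score is scale-invariant and bounded", {
  set.seed(5)
  ref <- generate_reference_spectrum(parse_lipid_name("PE 18:1(n-9)_18:1(n-9)"))
  for (i in 1:10) {
    n <- sample(5:40, 1)
    meas <- toy_measured(sort(runif(n, 100, 750)), runif(n, 1, 100))
    meas <- dplyr::bind_rows(meas, toy_measured(ref$mz[1:5], runif(5, 1, 100)))
    s1 <- reverse_dot_product(meas, ref)
    meas2 <- meas
    meas2$intensity <- meas2$intensity * 1234.5
    expect_equal(reverse_dot_product(meas2, ref), s1, tolerance = 1e-12)
    expect_gte(s1, 0)
    expect_lte(s1, 1)
  }
})

test_that("removing a diagnostic ion never increases surviving candidates", {
  sp_true <- parse_lipid_name("PC 16:0_18:2(n-6,9)")
  meas <- simulate_spectrum(sp_true, noise_free_sim())
  cfg <- oad_config()
  cands <- enumerate_positions(18, 2)
  count_survivors <- function(m) {
    prec <- attr(meas, "precursor_mz")
    sum(lipidoad:::screen_candidates(cands, 18L, "ester", m, max(m$intensity), prec, cfg))
  }
  full <- count_survivors(meas)
  expect_gte(full, 1)
  nl <- lipidoad:::diagnostic_pair_nl(6L, 1L)
  drop_mz <- attr(meas, "precursor_mz") - nl$nl03
  pruned <- meas[abs(meas$mz - drop_mz) > 1e-4, ]
  attr(pruned, "precursor_mz") <- attr(meas, "precursor_mz")
  expect_lte(count_survivors(pruned), full)
})

test_that("candidate ranking returns the generator as top hit", {
  truth <- parse_lipid_name("PC 16:0_18:1(n-9)")
  meas <- simulate_spectrum(truth, noise_free_sim())
  cands <- lapply(c(7L, 9L, 11L), function(p) {
    sp <- parse_lipid_name("PC 16:0_18:1")
    sp$chains$positions[[2]] <- list(p)
    sp$chains$geometry[[2]] <- NA_character_
    sp
  })
  ranked <- rank_candidates(meas, cands)
  expect_identical(ranked$name[1], "PC 16:0_18:1(n-9)")
  expect_identical(ranked$rank[1], 1L)
  expect_true(all(ranked$score[ranked$survived] <= 1 + 1e-12))
})
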