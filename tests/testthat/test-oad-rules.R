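rule_by_id <- function(id) {
  r <- oad_rule_table()
  as.list(r[r$rule_id == id, ])
}

test_that("the rule table carries exactly one diagnostic pair", {
  rules <- oad_rule_table()
  diag <- rules[rules$diagnostic, ]
  expect_identical(nrow(diag), 2L)
  expect_setequal(diag$rule_id, c("OAD03", "OAD16"))
  expect_identical(sort(diag$bond_site), c(-1L, 1L))
  expect_true(all(rules$rel_intensity > 0 & rules$rel_intensity <= 1))
})

test_that("diagnostic neutral losses reproduce the printed n-9 values", {
  chain <- list(carbons = 18L, positions = 9L, linkage = "ester")
  nl03 <- fragment_neutral_loss(chain, 1L, rule_by_id("OAD03"))
  expect_equal(nl03$mass, 97.1381, tolerance = 5e-4)
  # the loss is an oxygen-deficient C8H17 radical: O stays on the ion
  expect_identical(nl03$delta, c(C = 8L, H = 17L, O = -1L))
  expect_equal(nl03$mass, oracle_formula_mass("C8H17") - ORACLE_MASSES[["O"]],
               tolerance = 1e-6)

  nl16 <- fragment_neutral_loss(chain, 1L, rule_by_id("OAD16"))
  expect_equal(nl16$mass, 139.1487, tolerance = 5e-4)
  expect_identical(nl16$delta, c(C = 10L, H = 19L))
  expect_equal(nl16$mass, oracle_formula_mass("C10H19"), tolerance = 1e-6)
})

test_that("double bonds inside the lost fragment reduce its hydrogen count", {
  chain <- list(carbons = 20L, positions = c(6L, 9L, 12L, 15L), linkage = "amide")
  nl <- fragment_neutral_loss(chain, 1L, rule_by_id("OAD16"))
  expect_identical(nl$delta, c(C = 7L, H = 13L)) # n-7_n-8 cleavage, one C=C lost
  expect_equal(nl$mass, oracle_formula_mass("C7H13"), tolerance = 1e-6)
  # third double bond: two C=C on the lost side of the methyl-side cleavage
  nl2 <- fragment_neutral_loss(chain, 3L, rule_by_id("OAD03"))
  expect_identical(nl2$delta, c(C = 11L, H = 19L, O = -1L))
})

test_that("pair neutral losses shift by CH2 per methyl-ward position step", {
  ch2 <- oracle_formula_mass("CH2")
  for (x in 3:15) {
    chain_lo <- list(carbons = 18L, positions = x, linkage = "ester")
    chain_hi <- list(carbons = 18L, positions = x + 1L, linkage = "ester")
    for (id in c("OAD03", "OAD16")) {
      expect_equal(
        fragment_neutral_loss(chain_hi, 1L, rule_by_id(id))$mass -
          fragment_neutral_loss(chain_lo, 1L, rule_by_id(id))$mass,
        ch2, tolerance = 1e-9
      )
    }
  }
})

test_that("vinyl-ether rules reject conventional chains", {
  chain <- list(carbons = 18L, positions = 9L, linkage = "ester")
  expect_error(fragment_neutral_loss(chain, 1L, rule_by_id("VE01")), "vinyl")
})

test_that("reference spectra contain the printed head-group and pair ions", {
  sp <- parse_lipid_name("PC 18:0/18:1(n-9)")
  ref <- generate_reference_spectrum(sp)
  prec <- attr(ref, "precursor_mz")
  expect_true(any(abs(ref$mz - 184.0734) < 5e-4))
  expect_true(any(abs(ref$mz - (prec - 97.1381)) < 5e-4))
  expect_true(any(abs(ref$mz - (prec - 139.1487)) < 5e-4))
  expect_true(all(diff(ref$mz) >= 0))
  expect_error(generate_reference_spectrum(parse_lipid_name("PC 18:0_18:1")),
               "unresolved")
})

test_that("PUFA-containing species give the near-isobaric fragment pair", {
  sp <- parse_lipid_name("PE-N(FA 20:4(n-6,9,12,15)) 18:1(n-9)/18:1(n-9)")
  ions <- attr(generate_reference_spectrum(sp), "ions")
  f_204 <- with(ions, mz[!is.na(rule_id) & rule_id == "OAD16" & chain_index == 1 & db_index == 1])
  f_181 <- with(ions, mz[!is.na(rule_id) & rule_id == "OAD03" & chain_index == 2 & db_index == 1])
  expect_equal(f_204, 933.6816, tolerance = 1e-3)
  expect_equal(f_181, 933.6452, tolerance = 1e-3)
  expect_equal(f_204 - f_181, 0.0364, tolerance = 5e-4)
})

test_that("saturated species produce only head-group and precursor ions", {
  ref <- generate_reference_spectrum(parse_lipid_name("PC 16:0_18:0"))
  expect_true(all(is.na(ref$chain_index)))
  expect_setequal(unique(sub(":.*", "", ref$label)), c("precursor", "head"))
})

test_that("mass conservation holds for every generated fragment peak", {
  species <- list(
    parse_lipid_name("PC 18:0/18:1(n-9)"),
    parse_lipid_name("PE-N(FA 20:4(n-6,9,12,15)) 18:1(n-9)/18:1(n-9)"),
    parse_lipid_name("TG 16:0_18:1(n-9)_18:3(n-3,6,9)"),
    parse_lipid_name("SM 18:1(Δ4);O2/18:1(n-9)"),
    parse_lipid_name("PE P-18:0/18:1(n-9)")
  )
  for (sp in species) {
    ions <- attr(generate_reference_spectrum(sp), "ions")
    prec <- precursor_mz(sp)
    frag <- ions[!is.na(ions$rule_id), ]
    expect_true(nrow(frag) > 0)
    expect_equal(frag$mz + frag$nl_mass, rep(prec, nrow(frag)), tolerance = 1e-6)
  }
})

test_that("special contexts select the documented rule subsets", {
  d4 <- special_case_rules("sphingoid_delta4")
  expect_true(all(c("OAD03", "OAD16") %in% d4$rule_id))
  expect_lt(max(d4$rel_intensity), min(oad_rule_table()$rel_intensity[oad_rule_table()$diagnostic]))
  d8 <- special_case_rules("sphingoid_delta_ge8")
  expect_identical(d8$rule_id, sprintf("OAD%02d", 1:20))
  ve <- special_case_rules("vinyl_ether")
  expect_true(all(ve$applicability == "vinyl_ether"))
})

test_that("sphingoid delta-4 ions are flagged and attenuated, delta-8 are standard", {
  sm <- parse_lipid_name("SM 18:1(Δ4);O2/18:1(n-9)")
  ions <- attr(generate_reference_spectrum(sm), "ions")
  base_ions <- ions[!is.na(ions$chain_index) & ions$chain_index == 1, ]
  acyl_ions <- ions[!is.na(ions$chain_index) & ions$chain_index == 2, ]
  expect_true(all(base_ions$delta4))
  expect_lt(max(base_ions$rel_intensity), max(acyl_ions$rel_intensity))

  cer <- parse_lipid_name("Cer 18:2;O2(Δ4,8)/24:1(n-9)")
  ions2 <- attr(generate_reference_spectrum(cer), "ions")
  d8 <- ions2[!is.na(ions2$chain_index) & ions2$chain_index == 1 & ions2$position == 10, ]
  expect_false(any(d8$delta4))
  expect_identical(sort(unique(d8$rule_id)), sort(sprintf("OAD%02d", 1:20)))
})

test_that("plasmalogens carry vinyl-ether cleavage ions near the printed values", {
  pe <- parse_lipid_name("PE P-18:0/18:1(n-9)")
  ions <- attr(generate_reference_spectrum(pe), "ions")
  ve <- ions[!is.na(ions$rule_id) & grepl("^VE", ions$rule_id), ]
  expect_identical(nrow(ve), 2L)
  expect_true(all(ve$position == 17L)) # the implicit delta-1' bond of P-18:0
  expect_true(any(abs(ve$mz - 521.31) < 0.05))
  expect_true(any(abs(ve$mz - 522.32) < 0.05))
})

test_that("spectrum generation is a pure function", {
  sp <- parse_lipid_name("PG 22:6(n-3,6,9,12,15,18)/22:6(n-3,6,9,12,15,18)")
  a <- generate_reference_spectrum(sp)
  b <- generate_reference_spectrum(sp)
  expect_identical(a, b)
})
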