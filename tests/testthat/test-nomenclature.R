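test_that("molecular-species names parse into chains without positions", {
  sp <- parse_lipid_name("PC 18:1_22:6")
  expect_identical(sp$subclass, "PC")
  expect_false(sp$chain_order_known)
  expect_identical(sp$chains$carbons, c(18L, 22L))
  expect_identical(sp$chains$db, c(1L, 6L))
  expect_true(all(lengths(sp$chains$positions) == 0))
})

test_that("linkage prefixes and declared positions parse", {
  sp <- parse_lipid_name("PE P-18:0/18:1(n-9)")
  expect_identical(sp$chains$linkage, c("vinyl", "ester"))
  expect_true(sp$chain_order_known)
  expect_identical(sp$chains$positions[[2]], list(9L))

  sp2 <- parse_lipid_name("PC O-16:0/20:4(n-6,9,12,15)")
  expect_identical(sp2$chains$linkage[1], "ether")
  expect_identical(unlist(sp2$chains$positions[[2]]), c(6L, 9L, 12L, 15L))
})

test_that("sphingolipids store delta-descriptions as n-positions", {
  sp <- parse_lipid_name("SM 18:1(Δ4);O2/18:1(n-9)")
  base <- sp$chains[1, ]
  expect_identical(base$linkage, "sphingoid")
  expect_identical(base$oh, 2L)
  expect_identical(base$positions[[1]], list(14L)) # delta-4 on C18 = n-14
  expect_identical(sp$chains$linkage[2], "amide")
  # ascii delta marker and post-hydroxyl position block both accepted
  sp2 <- parse_lipid_name("Cer 18:2;O2(d4,8)/24:1(n-9)")
  expect_identical(unlist(sp2$chains$positions[[1]]), c(10L, 14L))
})

test_that("N-acyl phosphoethanolamine names parse with the amide head chain", {
  sp <- parse_lipid_name("PE-N(FA 20:4(n-6,9,12,15)) 18:1(n-9)/18:1(n-9)")
  expect_identical(sp$subclass, "PE-N(FA)")
  expect_identical(sp$chains$linkage, c("amide", "ester", "ester"))
  expect_identical(unlist(sp$chains$positions[[1]]), c(6L, 9L, 12L, 15L))
})

test_that("serialization follows field conventions and round-trips", {
  sp <- parse_lipid_name("PC 18:1(n-9)_22:6(n-3,6,9,12,15,18)")
  expect_identical(serialize_lipid_name(sp), "PC 18:1(n-9)_22:6(n-3,6,9,12,15,18)")
  expect_identical(serialize_lipid_name(parse_lipid_name("PC 18:1_22:6")), "PC 18:1_22:6")
  expect_identical(
    serialize_lipid_name(parse_lipid_name("SM 18:1(Δ4);O2/18:1(n-9)")),
    "SM 18:1(Δ4);O2/18:1(n-9)"
  )
})

test_that("ambiguous position sets serialize with '&'", {
  sp <- parse_lipid_name("PC 16:0_38:5")
  sp$chains$positions[[2]] <- list(c(3L, 6L), 9L, 12L, 15L, 18L)
  sp$chains$geometry[[2]] <- rep(NA_character_, 5)
  out <- serialize_lipid_name(sp)
  expect_match(out, "38:5\\(n-3&6,9,12,15,18\\)", fixed = FALSE)
  back <- parse_lipid_name(out)
  expect_identical(back$chains$positions[[2]][[1]], c(3L, 6L))
})

test_that("round trip holds across a generated corpus of subclasses", {
  set.seed(11)
  cfg <- oad_config()
  for (subclass in c("PC", "PE", "PS", "PG", "PI", "TG", "DG", "LPC", "SM", "Cer", "HexCer", "CAR", "SPB")) {
    for (rep in 1:5) {
      sp <- lipidoad:::random_species(subclass, cfg)
      name <- serialize_lipid_name(sp)
      back <- parse_lipid_name(name, adduct = sp$adduct)
      expect_identical(serialize_lipid_name(back), name, label = name)
      expect_identical(back$chains$positions, sp$chains$positions, label = name)
    }
  }
})

test_that("n/delta conversion matches the published mapping and inverts", {
  expect_identical(n_to_delta(20, 6), 14)   # arachidonate n-6 <-> delta-14
  expect_identical(n_to_delta(18, 14), 4)   # sphingosine delta-4 <-> n-14
  expect_identical(n_to_delta(20, 10), 10)  # fixed point at C/2
  for (carbons in c(16, 18, 20, 22)) {
    for (p in seq_len(carbons - 1)) {
      expect_equal(delta_to_n(carbons, n_to_delta(carbons, p)), p)
    }
  }
  expect_error(n_to_delta(18, 18), "range")
  expect_error(n_to_delta(18, 0), "range")
})

test_that("malformed names fail informatively", {
  expect_error(parse_lipid_name("XX 18:1_18:1"), "subclass")
  expect_error(parse_lipid_name("PC 18:1_foo"), "chain token")
  expect_error(parse_lipid_name("PC 18:2(n-9)_16:0"), "position")
  expect_error(parse_lipid_name("PC 18:2(n-9,10)_16:0"), "conjugated")
  expect_error(parse_lipid_name("TG 18:1_18:1"), "3 chain")
  expect_error(parse_lipid_name(""), "Empty")
})

test_that("PC plasmalogen demotion to ether notation is opt-in", {
  sp <- parse_lipid_name("PC P-16:0/18:1(n-9)")
  expect_identical(serialize_lipid_name(sp), "PC P-16:0/18:1(n-9)")
  expect_identical(
    serialize_lipid_name(sp, pc_plasmalogen_as_ether = TRUE),
    "PC O-16:1/18:1(n-9)"
  )
})
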