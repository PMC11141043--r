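# Scoring functions: descriptors, penalised logP, consecutive rotatable
# bonds, similarity scorers, substructure scoring, applicability domain.

test_that("descriptors have the expected values and units", {
  expect_equal(unname(calc_descriptors("c1ccccc1", "HBD")), 0)
  expect_equal(unname(calc_descriptors("CCO", "MW")), 46.07, tolerance = 1e-3)
  expect_equal(unname(calc_descriptors("C", "FormalCharge")), 0)
  expect_equal(unname(calc_descriptors("C[N+](C)(C)C", "FormalCharge")), 1)
  expect_equal(unname(calc_descriptors("c1ccc2ccccc2c1", "AromaticRings")), 2)
  expect_equal(unname(calc_descriptors("c1ccccc1", "RingCount")), 1)
  expect_equal(unname(calc_descriptors("CCO", "HeavyAtoms")), 3)
  q <- unname(calc_descriptors("CC(=O)Nc1ccc(O)cc1", "QED"))
  expect_gt(q, 0); expect_lte(q, 1)
  expect_error(calc_descriptors("CCO", "NoSuchDescriptor"),
               "unknown descriptor")
  expect_error(calc_descriptors("C1CC"), "valid")
})

test_that("descriptor values are deterministic given the canonical form", {
  for (smi in c("CCO", "CC(=O)Nc1ccc(O)cc1")) {
    a <- calc_descriptors(smi)
    b <- calc_descriptors(parse_smiles(smi)$canonical_smiles)
    expect_identical(a, b)
  }
})

test_that("penalised logP = logP - SA - large-ring penalty", {
  # frozen regression value recorded once from this package's toolkit
  expect_equal(penalised_logp("CCO"), -1.6214, tolerance = 1e-6)
  # no ring larger than 6: the two scores differ by SA only
  lp <- unname(calc_descriptors("c1ccccc1", "logP"))
  expect_equal(penalised_logp("c1ccccc1"), lp - sa_score("c1ccccc1"))
  # one 8-ring costs one penalty unit relative to the same-size 6-ring case
  lp8 <- unname(calc_descriptors("C1CCCCCCC1", "logP"))
  expect_equal(penalised_logp("C1CCCCCCC1"),
               lp8 - sa_score("C1CCCCCCC1") - 1)
})

test_that("consecutive rotatable bonds match a brute-force path oracle", {
  expect_equal(max_consecutive_rotatable_bonds("c1ccccc1"), 0L)
  expect_equal(max_consecutive_rotatable_bonds("CCCCC"), 2L)
  expect_equal(max_consecutive_rotatable_bonds("CCCCCCCC"), 5L)
  for (smi in c("CCCCCCCC", "CC(CCC)CCCC", "c1ccccc1CCCCc1ccccc1",
                "CC(=O)NCCCC", "CCOC(=O)CCN(CC)CC")) {
    g <- genscore:::mol_graph(parse_smiles(smi)$canonical_smiles)
    rb <- genscore:::.rotatable_bonds(g)
    oracle <- brute_force_longest_path(g$bonds[rb, , drop = FALSE])
    expect_equal(max_consecutive_rotatable_bonds(smi), oracle, info = smi)
  }
})

test_that("fingerprint similarity reduces over the reference set", {
  expect_equal(fingerprint_similarity("CCO", c("CCO", "CCC")), 1)
  expect_equal(fingerprint_similarity("CCO", c("CCO", "CCO"),
                                      reduce = "mean"), 1)
  s1 <- fingerprint_similarity("CCO", "CCC")
  s2 <- fingerprint_similarity("CCO", "CCCC")
  expect_equal(fingerprint_similarity("CCO", c("CCC", "CCCC"),
                                      reduce = "mean"), mean(c(s1, s2)))
  expect_equal(fingerprint_similarity("CCO", c("CCC", "CCCC"),
                                      reduce = "max"), max(s1, s2))
  expect_error(fingerprint_similarity("CCO", character()), "empty reference")
})

test_that("isomer similarity scores formula agreement", {
  expect_equal(isomer_similarity("CCO", "C2H6O"), 1)
  # one element off by one: geometric mean includes a factor exp(-0.5)
  s <- isomer_similarity("CCO", "C3H6O")
  expect_lt(s, 1)
  # symmetric in deviation sign
  expect_equal(isomer_similarity("CCO", "C3H6O"),
               isomer_similarity("CCO", "C1H6O"), tolerance = 1e-12)
  # strictly decreasing with growing deviation
  expect_gt(isomer_similarity("CCO", "C3H6O"),
            isomer_similarity("CCO", "C4H6O"))
  expect_error(isomer_similarity("CCO", "??"), "formula")
})

test_that("substructure match and filter are complementary", {
  benzene <- "c1ccccc1"
  expect_equal(substructure_score(benzene, benzene, "match_any"), 1)
  expect_equal(substructure_score("C", benzene, "filter"), 1)
  expect_equal(substructure_score(benzene, benzene, "filter"), 0)
  pats <- c("c1ccccc1", "[OX2H]", "C(=O)N")
  for (smi in fixture_smiles()) {
    expect_equal(substructure_score(smi, pats, "filter"),
                 1 - substructure_score(smi, pats, "match_any"), info = smi)
  }
  expect_equal(substructure_score("CC(=O)Nc1ccc(O)cc1", pats, "match_all"), 1)
  expect_error(scorer_spec("x", "substructure_match", smarts = "[[["),
               "invalid SMARTS")
})

test_that("applicability domain scores similarity and descriptor coverage", {
  train <- c("CCO", "CCC", "CCCC", "CCCCO")
  dm <- domain_model(train, descriptors = c("MW", "logP", "TPSA", "HBD"))
  expect_equal(applicability("CCO", dm, "max_similarity"), 1)
  expect_equal(applicability("CCC", dm, "feature_range"), 1)
  # far outside on some but not all descriptors: a strict fraction
  frac <- applicability("CCCCCCCCCCCCCCCC", dm, "physchem_range")
  expect_gte(frac, 0); expect_lt(frac, 1)
  expect_equal(frac * 4, round(frac * 4)) # fraction of 4 descriptors
})

test_that("domain models survive a JSON round trip", {
  dm <- domain_model(c("CCO", "CCC", "c1ccccc1"))
  path <- tempfile(fileext = ".json")
  write_domain_model(dm, path)
  dm2 <- read_domain_model(path)
  expect_equal(dm$feature_mins, dm2$feature_mins)
  expect_equal(dm$feature_maxs, dm2$feature_maxs)
  for (probe in c("CCO", "CCCCO", "c1ccccc1C")) {
    expect_equal(applicability(probe, dm, "max_similarity"),
                 applicability(probe, dm2, "max_similarity"), info = probe)
  }
})

test_that("scorer errors name the offending configuration", {
  expect_error(scorer_spec("", "descriptors"), "nonempty")
  expect_error(scorer_spec("x", "no_such_kind"), "unknown scorer kind")
  expect_error(scorer_spec("x", "descriptors", names = "Bogus"),
               "unknown descriptor")
  expect_error(scorer_spec("x", "fingerprint_similarity",
                           ref_smiles = character()), "empty reference")
  expect_error(scorer_spec("x", "isomer_similarity"), "formula")
})
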