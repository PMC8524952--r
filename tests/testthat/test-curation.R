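test_that("DOI filter keeps exactly the records with >= 10 trimmed characters", {
  rec <- data.frame(
    id = paste0("r", 1:5),
    doi = c("10.5555/abcde", "", "12345678", "  10.1/ab  ", "10.1000/xyz9"),
    stringsAsFactors = FALSE)
  kept <- filter_by_doi(rec)
  expect_equal(kept$id, c("r1", "r5"))
  # missing column and NA entries are treated as empty
  expect_equal(nrow(filter_by_doi(data.frame(id = "a"))), 0)
  expect_equal(nrow(filter_by_doi(data.frame(doi = NA_character_))), 0)
})

test_that("origin resolution matches keywords with the documented priority", {
  expect_equal(resolve_origin("plants"), "plant")
  expect_equal(resolve_origin("plant"), "plant")
  expect_equal(resolve_origin("fungi"), "fungi")
  expect_equal(resolve_origin("aspergillus flavus"), "fungi")
  expect_equal(resolve_origin("bacteria"), "bacteria")
  expect_equal(resolve_origin("bacillus subtilis"), "bacteria")
  expect_equal(resolve_origin("actinobacta"), "bacteria")
  # priority: human > animal > bacteria > fungi > plant > marine
  expect_equal(resolve_origin("plants, bacteria"), "bacteria")
  expect_equal(resolve_origin("aspergillus, plant"), "fungi")
  expect_equal(resolve_origin("human, plants"), "human")
  expect_equal(resolve_origin("animal, fungi"), "animal")
  expect_equal(resolve_origin("marine, plant"), "plant")
  expect_equal(resolve_origin("coral reef"), "unresolved")
  expect_equal(resolve_origin(NA_character_), "unresolved")
})

test_that("origin resolution is case-insensitive and idempotent", {
  inputs <- c("Plants", "ASPERGILLUS, PLANT", "Bacillus Subtilis",
              "Coral Reef", "HUMAN, marine")
  expect_equal(resolve_origin(toupper(inputs)), resolve_origin(inputs))
  expect_equal(resolve_origin(tolower(inputs)), resolve_origin(inputs))
})

test_that("three-class subset keeps only plant/fungi/bacteria, order preserved", {
  rec <- data.frame(id = 1:5,
                    origin = c("plant", "marine", "bacteria", "human", "fungi"))
  expect_equal(select_three_class_subset(rec)$id, c(1, 3, 5))
  expect_equal(nrow(select_three_class_subset(
    data.frame(origin = rep("marine", 3)))), 0)
})

test_that("pipeline filters are monotone subsets", {
  fx <- generate_curation_fixture()
  step1 <- filter_by_doi(fx)
  step1$origin <- resolve_origin(step1$taxonomy)
  step2 <- select_three_class_subset(step1)
  expect_true(all(step1$id %in% fx$id))
  expect_true(all(step2$id %in% step1$id))
})

test_that("fixture records resolve to their expected labels", {
  fx <- generate_curation_fixture()
  kept <- filter_by_doi(fx)
  expect_identical(kept$id, fx$id[fx$expected_kept])
  expect_identical(resolve_origin(kept$taxonomy), kept$expected_origin)
})

test_that("molecular profiles reproduce worked descriptor values", {
  pr <- compute_profile(c("c1ccccc1", "C1CCCCC1", "C1C=CC=CN1", "CCO"))
  expect_equal(pr$fsp3, c(0, 1, 0.2, 1))
  expect_equal(round(pr$mw[3]), 81)        # 1,2-dihydropyridine
  expect_equal(pr$n_carbon, c(6, 6, 5, 2))
  expect_equal(pr$n_atoms, c(6, 6, 6, 3))
  expect_equal(pr$n_bonds, c(6, 6, 6, 2))
  expect_equal(pr$n_oxygen, c(0, 0, 0, 1))
  expect_equal(pr$n_nitrogen, c(0, 0, 1, 0))
  expect_true(all(pr$mw > 0))
  expect_true(all(pr$fsp3 >= 0 & pr$fsp3 <= 1))
  expect_error(compute_profile("not_a_smiles"), "position")
})

test_that("SMARTS flags agree with the independent-engine fixture", {
  # expected values frozen from an independent SMARTS engine (RDKit)
  cases <- data.frame(
    smiles = c("NCC(=O)NCC(=O)O",            # glycylglycine
               "COC1OC(CO)C(O)C(O)C1O",      # methyl glucopyranoside
               "c1ccccc1", "CCO", "CC(=O)NC", "C1CCOC1",
               "NCC(=O)NCC(=O)NCC(=O)O",     # triglycine
               "O=C1C=C(c2ccc(OC3OC(CO)C(O)C(O)C3O)cc2)Oc2cc(O)cc(O)c12"),
    peptide = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    glycoside = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(match_peptide(cases$smiles), cases$peptide)
  expect_equal(match_glycoside(cases$smiles), cases$glycoside)
})

test_that("categorization follows the priority order", {
  prof <- data.frame(
    is_glycoside = c(TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    is_peptide   = c(FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, TRUE),
    mw           = c(1200,  900,   900,   500,   150,   500,   150),
    fsp3         = c(0.5,   0.9,   0.9,   0.85,  0.5,   0.5,   0.1))
  expect_equal(categorize(prof),
               c("glycoside", "peptide", "high_MW", "high_Fsp3", "low_MW",
                 "none", "glycoside"))
  # boundary ties: thresholds are inclusive
  edge <- data.frame(is_glycoside = FALSE, is_peptide = FALSE,
                     mw = c(800, 200, 300, 300), fsp3 = c(0.5, 0.5, 0.8, 0.2))
  expect_equal(categorize(edge), c("high_MW", "low_MW", "high_Fsp3", "low_Fsp3"))
})

test_that("every category assignment survives an independent re-check", {
  pr <- small_profile()
  oracle <- vapply(seq_len(nrow(pr)), function(i) {
    p <- pr[i, ]
    if (p$is_glycoside) "glycoside"
    else if (p$is_peptide) "peptide"
    else if (p$mw >= 800) "high_MW"
    else if (p$fsp3 >= 0.8) "high_Fsp3"
    else if (p$fsp3 <= 0.2) "low_Fsp3"
    else if (p$mw <= 200) "low_MW"
    else "none"
  }, character(1))
  expect_equal(pr$category, oracle)
})

test_that("curate_records runs the fixture end to end and tracks skips", {
  fx <- generate_curation_fixture()
  # inject an unparseable structure that passes the text filters
  fx <- rbind(fx, data.frame(id = "BAD1", smiles = "xxqq((",
                             taxonomy = "plants", doi = "10.5555/fx.9999",
                             expected_kept = TRUE, expected_origin = "plant"))
  curated <- suppressWarnings(curate_records(fx))
  keep3 <- fx$expected_kept & fx$expected_origin %in% c("plant", "fungi", "bacteria")
  expect_equal(curated$id, setdiff(fx$id[keep3], "BAD1"))
  expect_equal(curated$origin, fx$expected_origin[match(curated$id, fx$id)])
  expect_equal(attr(curated, "n_skipped"), 1)
  expect_true(all(c("mw", "fsp3", "category") %in% names(curated)))
})

test_that("CSV round trip preserves records", {
  ds <- small_dataset()[1:10, ]
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_records(path)
  expect_equal(back$smiles, ds$smiles)
  expect_equal(back$taxonomy, ds$taxonomy)
  expect_error(read_records(path, columns = c(id = "nope", smiles = "smiles",
                                              taxonomy = "taxonomy", doi = "doi")),
               "lacks column")
})
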