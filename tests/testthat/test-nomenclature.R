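test_that("shorthand names parse to the expected structures", {
  s <- parse_lipid_name("CAR 12:0")
  expect_equal(s$lipid_class, "CAR")
  expect_equal(s$category, "FA")
  expect_equal(nrow(s$chains), 1L)
  expect_equal(s$chains$carbons, 12L)
  expect_equal(s$chains$double_bonds, 0L)

  s <- parse_lipid_name("SM 18:1;O2/26:0")
  expect_equal(s$lipid_class, "SM")
  expect_equal(s$chains$carbons, c(18L, 26L))
  expect_equal(s$chains$double_bonds, c(1L, 0L))
  expect_equal(s$chains$oxygens, c(2L, 0L))

  s <- parse_lipid_name("PC O-34:2")
  expect_equal(s$lipid_class, "PC O-")
  expect_true(s$ether_bond)
  expect_equal(sum(s$chains$ether_linked), 1L)
  expect_equal(s$chains$carbons, 34L)
  expect_equal(s$chains$double_bonds, 2L)

  # species-level PC stored as one aggregate chain
  expect_equal(nrow(parse_lipid_name("PC 36:0")$chains), 1L)
})

test_that("dialect glyphs normalize: unicode minus and ';2.0' oxygen suffix", {
  s <- parse_lipid_name("PC O−36:4;2.0")
  expect_equal(s$lipid_class, "PC O-")
  expect_equal(s$chains$oxygens, 2L)
  expect_equal(s$name, "PC O-36:4;O2")
  expect_length(s$notes, 2L)
  # same structure as the explicit spelling
  s2 <- parse_lipid_name("PC O-36:4;O2")
  expect_equal(s$chains, s2$chains)
})

test_that("unparseable and unsupported names raise informative errors", {
  expect_error(parse_lipid_name("XYZ 1:2"), "unsupported lipid class")
  expect_error(parse_lipid_name(""), "non-empty")
  expect_error(parse_lipid_name("PC 36:0:1"), "unparseable chain")
  expect_error(parse_lipid_name("PC 2:4"), "double bonds exceed carbons")
  expect_error(parse_lipid_name("CAR 12:0/14:0"), "exactly one chain")
  expect_error(parse_lipid_name("SM 18:1;Q2/26:0"), "modifier")
})

test_that("Total FA sums chains and formats the composite label", {
  a <- structural_annotation(parse_lipid_name("SM 18:1;O2/26:0"))
  expect_equal(a$total_c, 44L)
  expect_equal(a$total_db, 1L)
  expect_equal(a$total_oh, 2L)
  expect_equal(a$total_fa_label, "44:1;O2")

  a <- structural_annotation(parse_lipid_name("SM 18:1;O2/22:2;O"))
  expect_equal(a$total_c, 40L)
  expect_equal(a$total_db, 3L)
  expect_equal(a$total_oh, 3L)
  expect_equal(a$total_fa_label, "40:3;O3")

  a <- structural_annotation(parse_lipid_name("CAR 12:0"))
  expect_equal(a$total_fa_label, "12:0")
  expect_equal(a$total_oh, 0L)
})

test_that("classification codes follow the closed headgroup-class mapping", {
  expect_equal(classify_lipid(parse_lipid_name("PC 36:0")),
               list(category = "GP", subcategory_code = "GP01",
                    subclass_code = "GP0101"))
  expect_equal(classify_lipid(parse_lipid_name("PC O-36:5")),
               list(category = "GP", subcategory_code = "GP01",
                    subclass_code = "GP0102"))
  expect_equal(classify_lipid(parse_lipid_name("SM 18:1;O2/26:0")),
               list(category = "SP", subcategory_code = "SP03",
                    subclass_code = "SP0301"))
  expect_equal(classify_lipid(parse_lipid_name("CAR 10:0"))$category, "FA")
  expect_equal(classify_lipid(parse_lipid_name("LPC 18:0"))$subcategory_code,
               "GP01")
})

test_that("saturation classes are set by the species-level double-bond total", {
  expect_equal(saturation_class(c(0, 1, 2, 3, 6)),
               c("saturated", "monounsaturated", "diunsaturated",
                 "polyunsaturated", "polyunsaturated"))
})

test_that("round trip: canonical form re-parses structurally equal, panel-wide", {
  for (nm in default_panel()) {
    s <- parse_lipid_name(nm)
    s2 <- parse_lipid_name(s$name)
    expect_equal(s2$chains, s$chains, info = nm)
    expect_equal(s2$lipid_class, s$lipid_class, info = nm)
    expect_equal(s2$name, s$name, info = nm)
  }
})

test_that("structural totals are additive over chains (random chain tuples)", {
  set.seed(42)
  for (i in 1:50) {
    c1 <- sample(12:24, 1); d1 <- sample(0:3, 1); o1 <- sample(0:3, 1)
    c2 <- sample(12:26, 1); d2 <- sample(0:3, 1); o2 <- sample(0:2, 1)
    mod <- function(o) if (o == 0) "" else if (o == 1) ";O" else paste0(";O", o)
    nm <- sprintf("SM %d:%d%s/%d:%d%s", c1, d1, mod(o1), c2, d2, mod(o2))
    a <- structural_annotation(parse_lipid_name(nm))
    expect_equal(a$total_c, c1 + c2)
    expect_equal(a$total_db, d1 + d2)
    expect_equal(a$total_oh, o1 + o2)
  }
})

test_that("every panel species receives the complete annotation without error", {
  an <- annotate_lipids(default_panel())
  expect_equal(nrow(an), 124L)
  expect_false(anyNA(an))
  expect_setequal(unique(an$lipid_class), c("PC", "LPC", "SM", "PC O-", "CAR"))
  expect_true(all(an$category %in% c("FA", "GP", "SP")))
  expect_true(all(an$saturation_class %in%
    c("saturated", "monounsaturated", "diunsaturated", "polyunsaturated")))
  expect_true(all(an$bilayer_thickness %in%
    c("very low", "low", "average", "high", "very high")))
  expect_true(all(an$intrinsic_curvature %in% c("negative", "neutral", "positive")))
  expect_true(all(an$fn %in% c("membrane component", "lipid-mediated signaling")))
  expect_true(all(an$cellular_component %in%
    c("plasma membrane", "ER", "mitochondrion", "other")))
})

test_that("Total FA labels of the reported differential species match the study's composites", {
  # the species-level differential list and the Total FA composites it implies;
  # the ';2.0' dialect species is checked separately because its normalized
  # oxygens enter the label
  species <- c("SM 18:1;O2/22:2;O" = "40:3;O3", "SM 18:1;O2/26:0" = "44:1;O2",
               "PC O-40:1" = "40:1", "PC O-38:5" = "38:5", "PC 38:0" = "38:0",
               "PC O-36:3" = "36:3", "PC O-36:5" = "36:5", "PC O-34:2" = "34:2",
               "LPC 18:0" = "18:0", "PC 36:4" = "36:4", "LPC 17:0" = "17:0",
               "PC O-38:6" = "38:6", "PC O-34:3" = "34:3", "PC 34:4" = "34:4",
               "PC 36:6" = "36:6", "LPC 18:2" = "18:2", "PC 36:0" = "36:0",
               "CAR 12:0" = "12:0")
  for (nm in names(species))
    expect_equal(structural_annotation(parse_lipid_name(nm))$total_fa_label,
                 unname(species[nm]), info = nm)
  expect_equal(structural_annotation(parse_lipid_name("PC O-36:4;2.0"))$total_fa_label,
               "36:4;O2")
})
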