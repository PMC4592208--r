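# 2D pharmacophore surrogate: perception rules, merged shared-feature
# models, query-fit ranking.

test_that("feature perception follows the rules on reference molecules", {
  benz <- featureCounts(parseSmiles("c1ccccc1"))
  expect_equal(benz[["aromatic_ring"]], 1L)
  expect_equal(benz[["hydrophobic"]], 1L)
  expect_equal(sum(benz), 2L)   # nothing else

  ace <- featureCounts(parseSmiles("CC(=O)O"))
  expect_equal(ace[["HBD"]], 1L)
  expect_equal(ace[["HBA"]], 2L)
  expect_equal(ace[["neg_ionizable"]], 1L)
  expect_equal(ace[["aromatic_ring"]], 0L)

  # fused aromatic system: two rings, one hydrophobic patch
  naph <- featureCounts(parseSmiles("c1ccc2ccccc2c1"))
  expect_equal(naph[["aromatic_ring"]], 2L)
  expect_equal(naph[["hydrophobic"]], 1L)

  # sulfonamide: acidic N-H, no basic amine
  sulfa <- featureCounts(parseSmiles("NS(=O)(=O)c1ccccc1"))
  expect_equal(sulfa[["neg_ionizable"]], 1L)
  expect_equal(sulfa[["pos_ionizable"]], 0L)

  # aliphatic amine is positively ionizable; amide N is not
  expect_equal(featureCounts(parseSmiles("CCN"))[["pos_ionizable"]], 1L)
  expect_equal(featureCounts(parseSmiles("CC(=O)N"))[["pos_ionizable"]], 0L)
})

test_that("perception is stable across re-encodings and featureless input", {
  a <- featureCounts(parseSmiles("Cc1ccccc1O"))
  b <- featureCounts(parseSmiles("Oc1ccccc1C"))
  expect_identical(a, b)
  ethane <- featureCounts(parseSmiles("CC"))
  expect_equal(sum(ethane), 0L)
})

test_that("merging takes per-kind minima at f = 1 and errors on empty consensus", {
  m1 <- parseSmiles("NCCCC(=O)O", id = "m1")   # amine + acid
  model_same <- mergeFeatureModel(list(m1, m1))
  expect_identical(model_same@required, featureCounts(m1))

  # HBA counts 3 vs 5 -> required 3
  a <- parseSmiles("OCCO", id = "a")       # 2 HBA (+2 HBD)
  b <- parseSmiles("OCC(O)CO", id = "b")   # 3 HBA
  mod <- mergeFeatureModel(list(a, b))
  expect_equal(mod@required[["HBA"]], 2L)
  expect_equal(mod@required[["HBD"]], 2L)

  expect_error(mergeFeatureModel(list(parseSmiles("CC", id = "x"),
                                      parseSmiles("CCC", id = "y"))),
               "consensus")
})

test_that("sulfonamide-motif actives produce a donor/acceptor/ring model", {
  set.seed(1)
  actives <- lapply(1:10, function(k) {
    linker <- paste(rep("C", sample(2:5, 1)), collapse = "")
    parseSmiles(paste0("NS(=O)(=O)c1ccc(", linker, ")cc1"),
                id = sprintf("act%02d", k))
  })
  mod <- mergeFeatureModel(actives)
  expect_gte(mod@required[["HBA"]], 1L)
  expect_gte(mod@required[["HBD"]], 1L)
  expect_gte(mod@required[["aromatic_ring"]], 1L)
})

test_that("query fit is the capped-count ratio with the right endpoints", {
  train <- list(parseSmiles("NCCC(=O)O", id = "t1"),
                parseSmiles("NCCCC(=O)O", id = "t2"))
  mod <- mergeFeatureModel(train)
  # training molecules fit their own consensus fully
  expect_equal(queryFit(mod, train[[1]]), 1.0)
  expect_equal(queryFit(mod, train[[2]]), 1.0)
  # featureless molecule scores 0
  expect_equal(queryFit(mod, parseSmiles("CC")), 0.0)

  # hand-built model: require {HBA: 2, aromatic_ring: 1}
  req <- setNames(integer(6), hdacScreen:::FEATURE_KINDS)
  req["HBA"] <- 2L; req["aromatic_ring"] <- 1L
  mod2 <- new("PharmacophoreModel", required = req,
              training_ids = "hand", consensus_fraction = 1)
  # ethanol-like: 1 HBA, no ring -> 1/3
  expect_equal(queryFit(mod2, parseSmiles("CCOC")), 1 / 3)
  # 1 HBA + 1 ring -> 2/3
  expect_equal(queryFit(mod2, parseSmiles("COc1ccccc1")), 2 / 3)
})

test_that("adding a feature never lowers the fit; raising f never raises requirements", {
  req <- setNames(integer(6), hdacScreen:::FEATURE_KINDS)
  req["HBA"] <- 2L; req["HBD"] <- 1L; req["aromatic_ring"] <- 1L
  mod <- new("PharmacophoreModel", required = req,
             training_ids = "hand", consensus_fraction = 1)
  grow <- c("CCO", "OCCO", "OCCOc1ccccc1", "NCCOc1ccc(O)cc1")
  fits <- vapply(grow, function(s) queryFit(mod, parseSmiles(s)), numeric(1))
  expect_true(all(diff(fits) >= 0))
  expect_true(all(fits >= 0 & fits <= 1))

  set.seed(8)
  train <- lapply(1:6, function(k) {
    parseSmiles(paste0("N", paste(rep("C", k), collapse = ""), "C(=O)O"),
                id = paste0("t", k))
  })
  m_half <- mergeFeatureModel(train, f = 0.5)
  m_full <- mergeFeatureModel(train, f = 1.0)
  expect_true(all(m_full@required <= m_half@required))
})

test_that("library screening ranks by fit with deterministic tie-breaks", {
  train <- list(parseSmiles("NCCC(=O)O", id = "t1"),
                parseSmiles("NCCCC(=O)O", id = "t2"))
  mod <- mergeFeatureModel(train)
  lib <- c(train, list(parseSmiles("CCCC", id = "alkane")))
  ranked <- screenLibrary(mod, lib, min_fit = 1.0)
  expect_equal(ranked$id, c("t1", "t2"))       # ties keep input order
  expect_true(all(ranked$query_fit == 1.0))
  expect_equal(nrow(screenLibrary(mod, lib, min_fit = 1.1)), 0L)
})

test_that("planted feature-complete actives are retrieved exactly", {
  set.seed(30)
  planted <- lapply(1:50, function(k) {
    linker <- paste(rep("C", 2 + (k %% 4)), collapse = "")
    parseSmiles(paste0("c1ccccc1", linker, "C(=O)NO"),
                id = sprintf("ACT%03d", k))
  })
  fillers <- lapply(1:450, function(k) {
    # hydrocarbons: no donors/acceptors, so they cannot reach full fit
    parseSmiles(paste(rep("C", 4 + (k %% 7)), collapse = ""),
                id = sprintf("DEC%03d", k))
  })
  model <- mergeFeatureModel(planted)
  ranked <- screenLibrary(model, c(planted, fillers), min_fit = 0.99)
  expect_setequal(ranked$id, vapply(planted, function(m) m@id, character(1)))
  # end-to-end validation statistics: perfect screen by construction
  labels <- setNames(c(rep("active", 50), rep("decoy", 450)),
                     c(sprintf("ACT%03d", 1:50), sprintf("DEC%03d", 1:450)))
  met <- screenMetrics(tallyScreen(labels, ranked$id))
  expect_equal(met@sensitivity, 1.0)
  expect_equal(met@gh_score, 1.0)
})

test_that("pharmacophore model serialization round-trips", {
  train <- list(parseSmiles("NCCC(=O)O", id = "t1"),
                parseSmiles("NCCCC(=O)O", id = "t2"))
  mod <- mergeFeatureModel(train)
  path <- withr::local_tempfile()
  writePharmacophoreModel(mod, path)
  back <- readPharmacophoreModel(path)
  expect_identical(back@required, mod@required)
  expect_identical(back@training_ids, mod@training_ids)
  expect_identical(back@consensus_fraction, mod@consensus_fraction)
})
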