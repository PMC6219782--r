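# Pair counting, potential derivation, and interface scoring.

test_that("a single cross-interface pair lands in its half-open bin", {
  bn <- BinningScheme(0, 15, 0.5)
  ty <- AtomTypingScheme("residue")
  s <- twoGroupStructure(matrix(c(0, 0, 0), ncol = 3),
                         matrix(c(4.2, 0, 0), ncol = 3))
  cnt <- collectPairCounts(list(s), ty, bn, pmhcInterface())
  expect_equal(sum(cnt), 2)           # ALA-GLY recorded in both orders
  iA <- atomTypeIds(ty, "ALA", "CA")
  iG <- atomTypeIds(ty, "GLY", "CA")
  bin <- as.integer(4.2 / 0.5) + 1    # [4.0, 4.5)
  expect_equal(cnt[iA, iG, bin], 1)
  expect_equal(cnt[iG, iA, bin], 1)
  # a pair at exactly rMax is excluded (half-open binning)
  far <- twoGroupStructure(matrix(c(0, 0, 0), ncol = 3),
                           matrix(c(15, 0, 0), ncol = 3))
  expect_equal(sum(collectPairCounts(list(far), ty, bn, pmhcInterface())),
               0)
})

test_that("pair counts equal the brute-force double loop", {
  cs <- makeComplexSet(seed = 8, nBinder = 2, nNonbinder = 1)
  ty <- AtomTypingScheme("residue")
  bn <- BinningScheme(0, 15, 0.5)
  ifc <- pmhcInterface()
  got <- collectPairCounts(cs$binders, ty, bn, ifc)
  want <- oraclePairCounts(cs$binders[[1]], ty, bn, ifc) +
          oraclePairCounts(cs$binders[[2]], ty, bn, ifc)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("structures without interface roles are skipped, all-skipped errors", {
  cs <- makeComplexSet(seed = 9, nBinder = 1, nNonbinder = 1)
  tcrOnly <- cs$tcrModels[[1]]
  expect_warning(
    cnt <- collectPairCounts(c(cs$binders, list(tcrOnly)),
                             interface = pmhcInterface()),
    "skipped")
  expect_error(
    suppressWarnings(collectPairCounts(list(tcrOnly),
                                       interface = pmhcInterface())),
    "no usable structures")
})

test_that("potential derivation matches the log-odds formula cell by cell", {
  ty <- AtomTypingScheme("residue")
  bn <- BinningScheme(0, 1, 0.5)
  n <- nTypes(ty)
  obs <- array(0, dim = c(n, n, 2))
  ref <- array(1, dim = c(n, n, 2))
  # hand-set a symmetric 2-type x 2-bin block
  obs[1, 1, 1] <- 4; obs[1, 2, 1] <- 2; obs[2, 1, 1] <- 2
  obs[1, 1, 2] <- 1; obs[2, 2, 2] <- 3
  pot <- derivePotential(obs, ref, ty, bn, pseudocount = 1)
  P <- 1 * length(obs)
  cellScore <- function(o, r)
    -log(((o + 1) / (sum(obs) + P)) / ((r + 1) / (sum(ref) + P)))
  for (idx in list(c(1, 1, 1), c(1, 2, 1), c(2, 2, 1),
                   c(1, 1, 2), c(1, 2, 2), c(2, 2, 2))) {
    expect_equal(scores(pot)[idx[1], idx[2], idx[3]],
                 cellScore(obs[idx[1], idx[2], idx[3]],
                           ref[idx[1], idx[2], idx[3]]),
                 tolerance = 1e-12)
  }
  expect_error(derivePotential(obs, array(1, dim = c(n, n, 3)), ty, bn),
               "incompatible tensors")
})

test_that("observed identical to reference gives the zero-information table", {
  ty <- AtomTypingScheme("residue")
  bn <- BinningScheme(0, 15, 0.5)
  cnt <- array(runif(nTypes(ty)^2 * nBins(bn)),
               dim = c(nTypes(ty), nTypes(ty), nBins(bn)))
  cnt <- (cnt + aperm(cnt, c(2, 1, 3))) / 2
  pot <- derivePotential(cnt, cnt, ty, bn)
  expect_equal(max(abs(scores(pot))), 0)
  # and every interface then scores exactly 0
  cs <- makeComplexSet(seed = 10, nBinder = 1, nNonbinder = 1)
  expect_identical(scoreInterface(cs$binders[[1]], pmhcInterface(), pot),
                   0)
})

test_that("interface scoring sums table cells over pairs within the cutoff", {
  ty <- AtomTypingScheme("residue")
  bn <- BinningScheme(0, 15, 0.5)
  sc <- array(0, dim = c(nTypes(ty), nTypes(ty), nBins(bn)))
  iA <- atomTypeIds(ty, "ALA", "CA")
  iG <- atomTypeIds(ty, "GLY", "CA")
  bin <- as.integer(4.2 / 0.5) + 1
  sc[iA, iG, bin] <- -0.3
  sc[iG, iA, bin] <- -0.3
  pot <- new("PotentialTable", typing = ty, binning = bn, scores = sc,
             provenance = list())
  one <- twoGroupStructure(matrix(c(0, 0, 0), ncol = 3),
                           matrix(c(4.2, 0, 0), ncol = 3))
  expect_equal(scoreInterface(one, pmhcInterface(), pot), -0.3)
  # no pairs within cutoff -> 0
  apart <- twoGroupStructure(matrix(c(0, 0, 0), ncol = 3),
                             matrix(c(10, 0, 0), ncol = 3))
  expect_equal(scoreInterface(apart, pmhcInterface(6), pot), 0)
  expect_error(scoreInterface(one, pmhcInterface(20), pot),
               "distance range")
  tcrless <- one
  expect_error(scoreInterface(tcrless, tcrInterface(), pot),
               "interface incomplete")
})

test_that("scoring equals the brute-force double loop on 50-atom fixtures", {
  set.seed(12)
  cs <- makeComplexSet(seed = 12, nBinder = 3, nNonbinder = 3)
  pot <- trainPMHCPotential(
    c(cs$binders, cs$nonbinders),
    rep(c("binder", "nonbinder"), each = 3))
  ifc <- pmhcInterface()
  for (s in cs$binders) {
    expect_equal(scoreInterface(s, ifc, pot),
                 oracleInterfaceScore(s, ifc, pot), tolerance = 1e-9)
  }
})

test_that("interface score is symmetric under group swap and additive", {
  cs <- makeComplexSet(seed = 13, nBinder = 2, nNonbinder = 2)
  pot <- trainPMHCPotential(
    c(cs$binders, cs$nonbinders), rep(c("binder", "nonbinder"), each = 2))
  s <- cs$binders[[1]]
  fwd <- scoreInterface(s, pmhcInterface(), pot)
  swapped <- InterfaceDefinition(c("mhc_alpha", "mhc_beta"), "peptide", 6)
  expect_equal(scoreInterface(s, swapped, pot), fwd, tolerance = 1e-12)
  # peptide-alpha and peptide-beta partition the peptide-MHC interface
  partA <- InterfaceDefinition("peptide", "mhc_alpha", 6)
  partB <- InterfaceDefinition("peptide", "mhc_beta", 6)
  expect_equal(scoreInterface(s, partA, pot) + scoreInterface(s, partB, pot),
               fwd, tolerance = 1e-9)
})

test_that("training from planted cohorts recovers the planted preference", {
  cs <- makeComplexSet(seed = 14)
  pot <- trainPMHCPotential(
    c(cs$binders, cs$nonbinders),
    c(rep("binder", length(cs$binders)),
      rep("nonbinder", length(cs$nonbinders))))
  ty <- typing(pot)
  iK <- atomTypeIds(ty, "LYS", "CA")
  iD <- atomTypeIds(ty, "ASP", "CA")
  # short-range (< 6 A) Lys-Asp cells are favorable on average
  shortBins <- seq_len(as.integer(6 / 0.5))
  expect_lt(mean(scores(pot)[iK, iD, shortBins]), 0)
  # and binder complexes score lower than nonbinder complexes
  sb <- vapply(cs$binders, scoreInterface, numeric(1),
               interface = pmhcInterface(), potential = pot)
  sn <- vapply(cs$nonbinders, scoreInterface, numeric(1),
               interface = pmhcInterface(), potential = pot)
  expect_lt(mean(sb), mean(sn))
  expect_error(
    trainPMHCPotential(cs$binders, rep("binder", length(cs$binders))),
    "missing affinity class")
})

test_that("identical cohorts give the zero table", {
  cs <- makeComplexSet(seed = 15, nBinder = 2, nNonbinder = 2)
  pot <- trainPMHCPotential(c(cs$binders, cs$binders),
                            rep(c("binder", "nonbinder"), each = 2))
  expect_equal(max(abs(scores(pot))), 0)
})

test_that("potential tables round-trip through TSV + sidecar", {
  cs <- makeComplexSet(seed = 16, nBinder = 2, nNonbinder = 2)
  pot <- trainPMHCPotential(c(cs$binders, cs$nonbinders),
                            rep(c("binder", "nonbinder"), each = 2))
  f <- tempfile(fileext = ".tsv")
  writePotentialTable(pot, f)
  back <- readPotentialTable(f)
  expect_equal(scores(back), scores(pot), tolerance = 1e-9)
  expect_equal(typing(back)@name, typing(pot)@name)
  expect_equal(provenance(back)$pseudocount, 1)
})
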