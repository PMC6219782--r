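# Specificity-matrix construction, cleavage-site scoring and the
# candidate filter.

test_that("count -> probability -> log-odds chain matches hand computation", {
  # 4 events over a reduced {A,K} alphabet, all with K at P1
  ev <- data.frame(substrate_sequence = rep("KA", 4), scissile_index = 0,
                   enzyme = "cathepsin_S")
  bg <- c(A = 0.5, K = 0.5)
  m <- buildSpecificityMatrix(ev, WindowDefinition(1, 1), background = bg,
                              pseudocount = 1)
  expect_equal(probabilities(m)["K", "P1"], 5 / 6)
  expect_equal(logOdds(m)["K", "P1"], log((5 / 6) / 0.5))
  expect_equal(logOdds(m)["K", "P1"], 0.5108256, tolerance = 1e-6)
  # counts are exact tallies
  expect_equal(unname(residueCounts(m)["K", "P1"]), 4L)
  expect_equal(unname(residueCounts(m)["A", "P1p"]), 4L)
})

test_that("probabilities equal to background give all-zero log-odds", {
  ev <- data.frame(substrate_sequence = c("AK", "KA"), scissile_index = 0,
                   enzyme = "e")
  m <- buildSpecificityMatrix(ev, WindowDefinition(1, 1),
                              background = c(A = 0.5, K = 0.5),
                              pseudocount = 1)
  expect_equal(max(abs(logOdds(m))), 0)
})

test_that("matrix construction validates its inputs", {
  ev <- data.frame(substrate_sequence = "KA", scissile_index = 0,
                   enzyme = "e")
  expect_error(buildSpecificityMatrix(ev[0, ]), "no training data")
  expect_error(
    buildSpecificityMatrix(ev, background = c(A = 1, K = 0)),
    "degenerate background")
  bad <- data.frame(substrate_sequence = "KZ", scissile_index = 0,
                    enzyme = "e")
  expect_error(buildSpecificityMatrix(bad), "invalid residue")
  short <- data.frame(substrate_sequence = "K", scissile_index = 0,
                      enzyme = "e")
  expect_error(buildSpecificityMatrix(short), "invalid scissile bond")
})

test_that("events too short for the window contribute only where covered", {
  # P4-P4' window, 4-residue substrates covering P2..P2' only
  ev <- data.frame(substrate_sequence = rep("AKLS", 10),
                   scissile_index = 1, enzyme = "e")
  m <- buildSpecificityMatrix(ev, WindowDefinition(4, 4), pseudocount = 1)
  expect_equal(sum(residueCounts(m)[, "P4"]), 0)
  expect_equal(sum(residueCounts(m)[, "P1"]), 10)
  # uncovered positions fall back to uniform probabilities -> log-odds 0
  expect_equal(max(abs(logOdds(m)[, "P4"])), 0)
})

test_that("scoreSite equals the brute-force per-cell sum", {
  ev <- data.frame(substrate_sequence = rep("KA", 4), scissile_index = 0,
                   enzyme = "e")
  m2 <- buildSpecificityMatrix(ev, WindowDefinition(1, 1),
                               background = c(A = 0.5, K = 0.5))
  expect_equal(scoreSite(m2, "AKAA", 1),
               logOdds(m2)["K", "P1"] + logOdds(m2)["A", "P1p"])

  set.seed(42)
  for (trial in 1:20) {
    mat <- makePlantedMatrix(seed = trial)
    antigen <- paste(sample(rownames(logOdds(mat)), 30, replace = TRUE),
                     collapse = "")
    for (i in sample(0:28, 8)) {
      expect_equal(scoreSite(mat, antigen, i),
                   oracleScoreSite(mat, antigen, i), tolerance = 1e-12)
    }
  }
})

test_that("window positions beyond the termini contribute zero", {
  mat <- makePlantedMatrix(seed = 5)   # P4-P4'
  antigen <- paste(sample(rownames(logOdds(mat)), 12, replace = TRUE),
                   collapse = "")
  # bond 0: P4..P2 fall off the N-terminus
  expect_equal(scoreSite(mat, antigen, 0),
               oracleScoreSite(mat, antigen, 0))
  expect_error(scoreSite(mat, antigen, 11), "invalid scissile bond")
  expect_error(scoreSite(mat, antigen, -1), "invalid scissile bond")
})

test_that("confidence is score > threshold, and counts fall as threshold rises", {
  sc <- makePlantedEpitopeScenario(seed = 2)
  preds <- predictCleavageSites(sc$antigen, sc$cleavageMatrices,
                                threshold = 3.0)
  expect_identical(preds$confident, preds$cleavage_score > 3.0)
  # engineered motifs are the only confident cathepsin-S bonds
  confS <- preds$scissile_index[preds$confident &
                                preds$enzyme == "cathepsin_S"]
  expect_identical(sort(confS), sort(sc$cleavageMotifBonds))
  # no confident site at +Inf threshold; count monotone in threshold
  nConf <- vapply(c(-Inf, 0, 3, 5, Inf), function(th)
    sum(predictCleavageSites(sc$antigen, sc$cleavageMatrices,
                             threshold = th)$confident), numeric(1))
  expect_true(all(diff(nConf) <= 0))
  expect_equal(nConf[length(nConf)], 0)
})

test_that("prediction output is complete, ordered and validated", {
  sc <- makePlantedEpitopeScenario(seed = 3)
  m <- sc$cleavageMatrices
  preds <- predictCleavageSites("AK", m)
  expect_equal(sum(preds$enzyme == "cathepsin_S"), 1)
  expect_equal(sum(preds$enzyme == "cathepsin_B"), 1)
  expect_error(predictCleavageSites("AKL", m[c("cathepsin_S")]),
               "incomplete matrix set")
  full <- predictCleavageSites(sc$antigen, m)
  L <- nchar(sc$antigen)
  expect_equal(sum(full$enzyme == "cathepsin_S"), L - 1)
  expect_false(is.unsorted(full$scissile_index))
})

test_that("aminopeptidase trimming walks fragment N-termini", {
  # H matrix favoring Leu at P1 and P1' strongly enough to exceed 3
  probs <- matrix(1 / 20, nrow = 20, ncol = 5,
                  dimnames = list(Tripitope:::.AA1,
                                  c("P1", "P1p", "P2p", "P3p", "P4p")))
  spike <- rep(0.4 / 19, 20)
  names(spike) <- Tripitope:::.AA1
  spike["L"] <- 0.6
  probs[, "P1"] <- spike
  probs[, "P1p"] <- spike
  hMat <- flatBackgroundMatrix(probs, WindowDefinition(1, 4),
                               "cathepsin_H")
  mats <- list(cathepsin_S = Tripitope:::.flatMatrix("cathepsin_S",
                                                     WindowDefinition(4, 4)),
               cathepsin_B = Tripitope:::.flatMatrix("cathepsin_B",
                                                     WindowDefinition(4, 4)),
               cathepsin_H = hMat)
  antigen <- "LLLAAAAAAA"
  # default: one trim evaluated at the antigen N-terminus
  p1 <- predictCleavageSites(antigen, mats, maxTrims = 1)
  expect_equal(sum(p1$enzyme == "cathepsin_H"), 1)
  expect_true(p1$confident[p1$enzyme == "cathepsin_H"])
  # maxTrims 4: confident at bonds 0 and 1 (L|L), stops at bond 2 (L|A)
  p4 <- predictCleavageSites(antigen, mats, maxTrims = 4)
  h <- p4[p4$enzyme == "cathepsin_H", ]
  expect_equal(h$scissile_index, c(0L, 1L, 2L))
  expect_equal(h$confident, c(TRUE, TRUE, FALSE))
})

test_that("the filter removes exactly candidates with internal confident bonds", {
  antigen <- strrep("A", 20)
  cands <- enumerateCandidates(antigen)
  preds <- data.frame(antigen_id = "antigen", scissile_index = 5L,
                      enzyme = "cathepsin_S", cleavage_score = 4,
                      confident = TRUE)
  kept <- filterCandidates(cands[cands$start %in% c(0L, 6L), ], preds)
  expect_identical(kept$start, 6L)     # bond 5|6 not strictly internal
  # no confident predictions -> everything survives, order preserved
  none <- preds
  none$confident <- FALSE
  expect_identical(filterCandidates(cands, none), cands)
  expect_identical(filterCandidates(cands, preds[0, ]), cands)
})

test_that("filter survivors are a subset and never lose a clean candidate", {
  set.seed(7)
  for (trial in 1:10) {
    antigen <- paste(sample(Tripitope:::.AA1, 40, replace = TRUE),
                     collapse = "")
    cands <- enumerateCandidates(antigen)
    bonds <- sort(sample(0:38, 3))
    preds <- data.frame(antigen_id = "antigen", scissile_index = bonds,
                        enzyme = "cathepsin_S", cleavage_score = 4,
                        confident = TRUE)
    kept <- filterCandidates(cands, preds)
    expect_true(all(kept$start %in% cands$start))
    clean <- vapply(cands$start, function(s)
      !any(bonds >= s & bonds <= s + 10), logical(1))
    expect_setequal(kept$start, cands$start[clean])
  }
})

test_that("matrices rebuilt from planted events recover the ground truth", {
  planted <- makePlantedMatrix(seed = 99)
  ev <- makeCleavageDataset(planted, nEvents = 500, seed = 21)
  rebuilt <- buildSpecificityMatrix(ev, windowDef(planted),
                                    pseudocount = 1)
  pl <- logOdds(planted)
  rb <- logOdds(rebuilt)
  expect_gt(cor(as.vector(pl), as.vector(rb)), 0.9)
  strong <- abs(pl) > 0.5
  expect_true(all(sign(rb[strong]) == sign(pl[strong])))
})

test_that("matrix and event tables round-trip through files", {
  ev <- data.frame(substrate_sequence = c("KALS", "nALS"),
                   scissile_index = 1, enzyme = "cathepsin_B")
  f <- tempfile(fileext = ".tsv")
  utils::write.table(ev, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readCleavageEvents(f)
  # norleucine is mapped to Met on input
  expect_identical(back$substrate_sequence, c("KALS", "MALS"))

  m <- buildSpecificityMatrix(back, WindowDefinition(2, 2))
  fm <- tempfile(fileext = ".tsv")
  writeSpecificityMatrix(m, fm)
  m2 <- readSpecificityMatrix(fm)
  expect_equal(logOdds(m2), logOdds(m), tolerance = 1e-9)
  expect_equal(residueCounts(m2), residueCounts(m),
               ignore_attr = "class", tolerance = 0)
  expect_equal(enzyme(m2), "cathepsin_B")
})
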