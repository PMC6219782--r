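# Independent brute-force oracles and small constructors used across the
# test files. The oracles re-derive each quantity from first principles
# (explicit loops over cells / atom pairs) and never call the code path
# they check.

# Cleavage score: explicit per-cell loop over the window.
oracleScoreSite <- function(mat, antigen, scissile) {
  w <- windowDef(mat)
  lo <- logOdds(mat)
  up <- w@upstream
  dn <- w@downstream
  labs <- c(paste0("P", seq(up, 1)), paste0("P", seq_len(dn), "p"))
  offs <- c(seq(-up + 1, 0), seq_len(dn))
  total <- 0
  for (k in seq_along(offs)) {
    pos0 <- scissile + offs[k]
    if (pos0 < 0 || pos0 >= nchar(antigen)) next
    res <- substr(antigen, pos0 + 1, pos0 + 1)
    total <- total + lo[res, labs[k]]
  }
  total
}

# Interface score: explicit double loop over heavy-atom pairs.
oracleInterfaceScore <- function(structure, interface, potential) {
  at <- atoms(structure)
  at$role <- unname(roleMap(structure)[at$chain])
  A <- at[at$role %in% interface@groupA & toupper(at$element) != "H", ]
  B <- at[at$role %in% interface@groupB & toupper(at$element) != "H", ]
  sc <- scores(potential)
  bn <- binning(potential)
  ty <- typing(potential)
  total <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                (A$z[i] - B$z[j])^2)
      if (d >= interface@cutoff) next
      bin <- floor((d - bn@rMin) / bn@binWidth) + 1
      if (bin < 1 || bin > nBins(bn)) next
      ta <- atomTypeIds(ty, A$resname[i], A$atom[i])
      tb <- atomTypeIds(ty, B$resname[j], B$atom[j])
      if (is.na(ta) || is.na(tb)) next
      total <- total + sc[ta, tb, bin]
    }
  }
  total
}

# Pair counts: explicit double loop with the same symmetrization
# convention (each pair once per ordered type combination).
oraclePairCounts <- function(structure, ty, bn, interface) {
  at <- atoms(structure)
  at$role <- unname(roleMap(structure)[at$chain])
  A <- at[at$role %in% interface@groupA & toupper(at$element) != "H", ]
  B <- at[at$role %in% interface@groupB & toupper(at$element) != "H", ]
  n <- nTypes(ty)
  cnt <- array(0, dim = c(n, n, nBins(bn)))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                (A$z[i] - B$z[j])^2)
      if (d < bn@rMin || d >= bn@rMax) next
      bin <- floor((d - bn@rMin) / bn@binWidth) + 1
      ta <- atomTypeIds(ty, A$resname[i], A$atom[i])
      tb <- atomTypeIds(ty, B$resname[j], B$atom[j])
      if (is.na(ta) || is.na(tb)) next
      cnt[ta, tb, bin] <- cnt[ta, tb, bin] + 1
      if (ta != tb) cnt[tb, ta, bin] <- cnt[tb, ta, bin] + 1
    }
  }
  cnt
}

# Random proper rotation (uniform axis, given or random angle).
randomRotation <- function(angle = NULL) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  if (is.null(angle)) angle <- runif(1, 0.1, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Minimal structure from a coordinate matrix (one chain, CA atoms).
caStructure <- function(xyz, chain = "A", role = "other",
                        resname = "ALA") {
  ComplexStructure(
    data.frame(chain = chain, resno = seq_len(nrow(xyz)),
               resname = resname, atom = "CA", element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    stats::setNames(role, chain))
}

# Two-chain point structure for potential tests: one atom per row of
# each coordinate matrix, chains C (peptide) and A (mhc_alpha).
twoGroupStructure <- function(xyzA, xyzB, resA = "ALA", resB = "GLY") {
  atA <- data.frame(chain = "C", resno = seq_len(nrow(xyzA)),
                    resname = resA, atom = "CA", element = "C",
                    x = xyzA[, 1], y = xyzA[, 2], z = xyzA[, 3],
                    stringsAsFactors = FALSE)
  atB <- data.frame(chain = "A", resno = seq_len(nrow(xyzB)),
                    resname = resB, atom = "CA", element = "C",
                    x = xyzB[, 1], y = xyzB[, 2], z = xyzB[, 3],
                    stringsAsFactors = FALSE)
  ComplexStructure(rbind(atA, atB), c(C = "peptide", A = "mhc_alpha"))
}

# A deterministic uniform-background SpecificityMatrix whose log-odds
# are chosen directly (used where a specific score pattern is needed).
flatBackgroundMatrix <- function(probs, window, enzymeId = "test") {
  bg <- stats::setNames(rep(1 / 20, 20), rownames(probs))
  counts <- matrix(0L, nrow = nrow(probs), ncol = ncol(probs),
                   dimnames = dimnames(probs))
  new("SpecificityMatrix", enzyme = enzymeId, window = window,
      counts = counts, probabilities = probs, background = bg,
      logOdds = log(probs / bg), pseudocount = 0)
}
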