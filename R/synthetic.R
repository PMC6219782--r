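# Seeded synthetic-data generators. Every stage of the predictor can be
# exercised without downloads: cleavage-event sets sampled from planted
# specificity matrices, idealized mini pMHCII / TCR / ternary complexes
# with planted contact preferences, and a full planted-epitope scenario
# that runs end to end.
#
# Mini-structures use idealized geometry (backbone + C-beta stubs, no
# force field): a 12-residue extended peptide flanked by two MHC chains
# forming a groove, and two short TCR chains docked above the peptide.
# This is exactly the representation the default coarse scoring
# consumes; it does not emulate real groove chemistry.

#' Generate a planted specificity matrix
#'
#' Per-position residue probabilities are drawn from a symmetric
#' Dirichlet (small concentration = strong positional preferences),
#' giving a ground-truth matrix whose log-odds can later be compared
#' with matrices rebuilt from sampled events (parameter recovery).
#'
#' @param seed integer seed; the generator is a pure function of it.
#' @param window a \linkS4class{WindowDefinition}.
#' @param concentration Dirichlet concentration (default 0.3).
#' @param minProb floor on per-cell probabilities (default 0.004).
#'   Keeps planted log-odds within the range that is identifiable from
#'   a few hundred events under add-one smoothing (about +/- 3 nats);
#'   count-derived specificity matrices have the same property.
#' @param enzymeId identifier for the planted enzyme.
#' @return a \linkS4class{SpecificityMatrix} (counts all zero: the
#'   matrix is a ground truth, not a tally).
#' @export
makePlantedMatrix <- function(seed = 1, window = WindowDefinition(4, 4),
                              concentration = 0.3, minProb = 0.004,
                              enzymeId = "planted_enzyme") {
  set.seed(seed)
  bg <- uniformBackground()
  labs <- positionLabels(window)
  probs <- sapply(labs, function(p) {
    g <- stats::rgamma(length(.AA1), shape = concentration)
    g <- pmax(g / sum(g), minProb)
    g / sum(g)
  })
  rownames(probs) <- .AA1
  counts <- matrix(0L, nrow = length(.AA1), ncol = length(labs),
                   dimnames = list(.AA1, labs))
  new("SpecificityMatrix", enzyme = enzymeId, window = window,
      counts = counts, probabilities = probs, background = bg,
      logOdds = log(probs / bg), pseudocount = 0)
}

#' Sample a cleavage-event dataset from a planted matrix
#'
#' Each event is a substrate of exactly the window length with the
#' scissile bond at the P1|P1' position; residues are sampled
#' position-wise from the planted matrix, except that a
#' \code{decoyFraction} of events is drawn from the background
#' distribution instead. Identical seeds give identical datasets.
#'
#' @param matrix the planted \linkS4class{SpecificityMatrix}.
#' @param nEvents number of events (>= 1).
#' @param seed integer seed.
#' @param decoyFraction fraction of background-only events in [0, 1].
#' @return data.frame with columns \code{substrate_sequence},
#'   \code{scissile_index}, \code{enzyme}.
#' @export
makeCleavageDataset <- function(matrix, nEvents = 500, seed = 1,
                                decoyFraction = 0) {
  if (nEvents < 1) stop("nEvents must be >= 1")
  set.seed(seed)
  w <- matrix@window
  W <- w@upstream + w@downstream
  alphabet <- names(matrix@background)
  decoy <- stats::runif(nEvents) < decoyFraction
  res <- matrix(NA_character_, nrow = nEvents, ncol = W)
  for (p in seq_len(W)) {
    res[, p] <- sample(alphabet, nEvents, replace = TRUE,
                       prob = matrix@probabilities[, p])
  }
  if (any(decoy)) {
    for (p in seq_len(W)) {
      res[decoy, p] <- sample(alphabet, sum(decoy), replace = TRUE,
                              prob = matrix@background)
    }
  }
  data.frame(substrate_sequence = apply(res, 1, paste, collapse = ""),
             scissile_index = w@upstream - 1L,
             enzyme = matrix@enzyme, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------- geometry --

.CA_SPACING <- 3.8
.BB_OFFSETS <- list(N = c(-1.20, 0.70, 0.00),
                    C = c(1.20, 0.60, 0.00),
                    O = c(1.90, 1.60, 0.20))

# One idealized chain: extended backbone along x, C-beta stubs from the
# same ideal construction used by threading. Vectorized: one frame per
# chain, not per atom.
.syntheticChain <- function(chainId, seq1, origin, noiseSd = 0) {
  n <- length(seq1)
  res3 <- aaOneToThree(seq1)
  ca <- cbind(.CA_SPACING * (seq_len(n) - 1) + origin[1], origin[2],
              origin[3])
  Np <- sweep(ca, 2, .BB_OFFSETS$N, "+")
  Cp <- sweep(ca, 2, .BB_OFFSETS$C, "+")
  Op <- sweep(ca, 2, .BB_OFFSETS$O, "+")
  cb <- .idealCB(Np[1, ], ca[1, ], Cp[1, ]) - ca[1, ]  # same offset per residue
  CBp <- sweep(ca, 2, cb, "+")
  hasCB <- res3 != "GLY"
  atomNames <- c(rep(c("N", "CA", "C", "O"), n), rep("CB", sum(hasCB)))
  resnos <- c(rep(seq_len(n), each = 4), which(hasCB))
  xyz <- rbind(do.call(rbind, lapply(seq_len(n), function(i)
    rbind(Np[i, ], ca[i, ], Cp[i, ], Op[i, ]))),
    CBp[hasCB, , drop = FALSE])
  ord <- order(resnos, match(atomNames, c("N", "CA", "C", "O", "CB")))
  at <- data.frame(chain = chainId, resno = resnos[ord],
                   resname = res3[resnos[ord]], atom = atomNames[ord],
                   element = substr(atomNames[ord], 1, 1),
                   x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3],
                   stringsAsFactors = FALSE)
  if (noiseSd > 0) {
    at$x <- at$x + stats::rnorm(nrow(at), 0, noiseSd)
    at$y <- at$y + stats::rnorm(nrow(at), 0, noiseSd)
    at$z <- at$z + stats::rnorm(nrow(at), 0, noiseSd)
  }
  at
}

# Groove sequences: anchor-facing positions carry Asp, the rest Gly.
# Anchor positions have pairwise-distinct spacings (2, 5, 7), so no
# register shift of a peptide can align more than one anchor -- the
# planted binder register is unique.
.ANCHORS <- c(3L, 5L, 10L)              # peptide anchor positions (1-based)
.GROOVE_LEN <- 12L
.TCR_LEN <- 8L
.TCR_X_OFFSET <- 2L                     # TCR residue j faces peptide 2 + j

.grooveSeq <- function() {
  s <- rep("G", .GROOVE_LEN)
  s[.ANCHORS] <- "D"
  s
}

.tcrSeq <- function() {
  s <- rep("G", .TCR_LEN)
  s[.ANCHORS[.ANCHORS > .TCR_X_OFFSET] - .TCR_X_OFFSET] <- "D"
  s
}

#' Consensus binder peptide of the planted preference
#'
#' Lys at the three anchor positions facing the groove's planted Asp
#' residues; neutral filler elsewhere.
#'
#' @return a 12-residue sequence string.
#' @export
consensusBinderPeptide <- function() {
  s <- .splitSeq("ASAVTSLNVQAV")
  s[.ANCHORS] <- "K"
  paste(s, collapse = "")
}

.FILLER <- c("A", "S", "T", "V", "L", "N", "Q")

# Random binder peptide: Lys anchors, and the non-anchor positions a
# random permutation of a fixed filler multiset. Every binder (and
# hence every shuffled nonbinder) has exactly the same residue
# composition, so the binder/nonbinder contrast isolates positional
# contact structure rather than composition fluctuations.
.FILLER_MULTISET <- c(.FILLER, "A", "S")

.binderPeptide <- function() {
  s <- character(.GROOVE_LEN)
  s[.ANCHORS] <- "K"
  s[-.ANCHORS] <- sample(.FILLER_MULTISET)
  s
}

# Build one mini complex. `peptide` is a character vector of 12
# one-letter residues; `tcrShift` translates the TCR chains along x.
.miniComplex <- function(peptide, includeTcr = FALSE, tcrShift = 0,
                         noiseSd = 0) {
  groove <- .grooveSeq()
  parts <- list(
    .syntheticChain("A", groove, c(0, 5.2, 0), noiseSd),
    .syntheticChain("B", groove, c(0, -5.2, 0), noiseSd),
    .syntheticChain("C", peptide, c(0, 0, 0), noiseSd))
  roles <- c(A = "mhc_alpha", B = "mhc_beta", C = "peptide")
  if (includeTcr) {
    tcr <- .tcrSeq()
    x0 <- .CA_SPACING * .TCR_X_OFFSET + tcrShift
    parts <- c(parts, list(
      .syntheticChain("D", tcr, c(x0, 1.5, 5.2), noiseSd),
      .syntheticChain("E", tcr, c(x0, -1.5, 5.2), noiseSd)))
    roles <- c(roles, D = "tcr_alpha", E = "tcr_beta")
  }
  ComplexStructure(do.call(rbind, parts), roles)
}

# TCR-only structure (chains D/E), for use as a TCR model.
.miniTcr <- function(noiseSd = 0) {
  tcr <- .tcrSeq()
  x0 <- .CA_SPACING * .TCR_X_OFFSET
  at <- rbind(.syntheticChain("D", tcr, c(x0, 1.5, 5.2), noiseSd),
              .syntheticChain("E", tcr, c(x0, -1.5, 5.2), noiseSd))
  ComplexStructure(at, c(D = "tcr_alpha", E = "tcr_beta"))
}

#' Generate a synthetic complex set with planted contact preferences
#'
#' Produces everything the structural stages consume: a clean pMHCII
#' template, TCR models, ternary templates spanning distinct MHC-TCR
#' orientations with known pairwise TCR displacements, and
#' binder/nonbinder pMHCII cohorts. Binder peptides carry Lys at the
#' three anchor positions that face the groove's planted Asp residues
#' (realizing short-range Lys-Asp contacts); nonbinder peptides are
#' shuffles of binder peptides, which almost always move the Lys
#' residues off the anchors.
#'
#' @param seed integer seed.
#' @param nBinder,nNonbinder cohort sizes.
#' @param nTcrModels number of TCR models (loop-variability stand-ins,
#'   jittered copies of one TCR).
#' @param tcrShifts numeric vector of TCR x-displacements (Angstrom) for
#'   the ternary templates; the templates are noise-free so their
#'   pairwise MHC-anchored TCR RMSDs equal the displacement differences
#'   exactly.
#' @param noiseSd coordinate jitter (Angstrom) applied to cohort
#'   structures and TCR models.
#' @return list with \code{pmhcTemplate} (\linkS4class{TemplateEntry}),
#'   \code{tcrModels}, \code{ternaryTemplates}, \code{binders},
#'   \code{nonbinders}, \code{binderSequences},
#'   \code{nonbinderSequences}.
#' @export
makeComplexSet <- function(seed = 1, nBinder = 30, nNonbinder = 30,
                           nTcrModels = 2, tcrShifts = c(0, 5, 9),
                           noiseSd = 0.1) {
  if (nBinder < 1 || nNonbinder < 1) stop("cohorts must be non-empty")
  set.seed(seed)
  binderSeqs <- replicate(nBinder, .binderPeptide(), simplify = FALSE)
  nonbinderSeqs <- replicate(nNonbinder,
                             sample(.binderPeptide()), simplify = FALSE)
  binders <- lapply(binderSeqs, .miniComplex, noiseSd = noiseSd)
  nonbinders <- lapply(nonbinderSeqs, .miniComplex, noiseSd = noiseSd)
  tcrModels <- lapply(seq_len(nTcrModels), function(i)
    .miniTcr(noiseSd = noiseSd / 2))
  ternaryTemplates <- lapply(seq_along(tcrShifts), function(i)
    TemplateEntry(.miniComplex(.splitSeq(consensusBinderPeptide()),
                               includeTcr = TRUE,
                               tcrShift = tcrShifts[i], noiseSd = 0),
                  sourceId = sprintf("synthetic_ternary_%d", i),
                  kind = "ternary",
                  meta = list(coreStart = 1L, tcrShift = tcrShifts[i])))
  pmhcTemplate <- TemplateEntry(
    .miniComplex(.splitSeq(consensusBinderPeptide()), noiseSd = 0),
    sourceId = "synthetic_pmhc", kind = "pmhc",
    meta = list(coreStart = 1L))
  list(pmhcTemplate = pmhcTemplate, tcrModels = tcrModels,
       ternaryTemplates = ternaryTemplates, binders = binders,
       nonbinders = nonbinders,
       binderSequences = vapply(binderSeqs, paste, "", collapse = ""),
       nonbinderSequences = vapply(nonbinderSeqs, paste, "",
                                   collapse = ""))
}

# Specificity matrix with one planted dipeptide motif (P2, P1) and flat
# preferences elsewhere; motif sites score ~5.0, all others < 3.
.motifMatrix <- function(p2res, p1res, enzymeId,
                         window = WindowDefinition(4, 4)) {
  bg <- uniformBackground()
  labs <- positionLabels(window)
  probs <- matrix(1 / 20, nrow = 20, ncol = length(labs),
                  dimnames = list(.AA1, labs))
  spike <- function(col, res) {
    p <- rep(0.4 / 19, 20)
    names(p) <- .AA1
    p[res] <- 0.6
    probs[, col] <<- p
  }
  spike("P2", p2res)
  spike("P1", p1res)
  counts <- matrix(0L, nrow = 20, ncol = length(labs),
                   dimnames = list(.AA1, labs))
  new("SpecificityMatrix", enzyme = enzymeId, window = window,
      counts = counts, probabilities = probs, background = bg,
      logOdds = log(probs / bg), pseudocount = 0)
}

# Flat matrix: every site scores 0 (never confident).
.flatMatrix <- function(enzymeId, window = WindowDefinition(1, 4)) {
  bg <- uniformBackground()
  labs <- positionLabels(window)
  probs <- matrix(1 / 20, nrow = 20, ncol = length(labs),
                  dimnames = list(.AA1, labs))
  counts <- matrix(0L, nrow = 20, ncol = length(labs),
                   dimnames = list(.AA1, labs))
  new("SpecificityMatrix", enzyme = enzymeId, window = window,
      counts = counts, probabilities = probs, background = bg,
      logOdds = log(probs / bg), pseudocount = 0)
}

#' Generate a full planted-epitope scenario
#'
#' A ~100-residue antigen containing exactly one planted epitope -- the
#' consensus binder 12-mer, whose threaded model realizes the planted
#' favorable Lys-Asp contacts and which contains no internal cleavage
#' motif -- plus two planted cathepsin-S cleavage motifs elsewhere in the
#' sequence. The bundle (antigen, cleavage matrices, pMHCII template,
#' TCR models, ternary templates, trained potential) runs end to end
#' through \code{\link{runPipeline}}.
#'
#' @param seed integer seed.
#' @param antigenLength antigen length (default 100).
#' @return list with \code{antigen}, \code{antigenId},
#'   \code{epitopeStart} (0-based), \code{epitopeSequence},
#'   \code{cleavageMatrices}, \code{cleavageMotifBonds} (0-based
#'   scissile indices of the planted motifs), \code{pmhcTemplate},
#'   \code{tcrModels}, \code{ternaryTemplates}, \code{potential}, and
#'   \code{complexSet}.
#' @export
makePlantedEpitopeScenario <- function(seed = 1, antigenLength = 100) {
  cs <- makeComplexSet(seed = seed + 1)
  potential <- trainPMHCPotential(
    c(cs$binders, cs$nonbinders),
    c(rep("binder", length(cs$binders)),
      rep("nonbinder", length(cs$nonbinders))))

  set.seed(seed)
  bgAlpha <- setdiff(.AA1, c("K", "R", "F", "Y"))
  ant <- sample(bgAlpha, antigenLength, replace = TRUE)
  # planted cathepsin-S motifs (P2 = F, P1 = R): scissile bonds after
  # the R residues at 0-based positions 21 and 71
  motifP1 <- c(21L, 71L)
  ant[motifP1] <- "F"                    # P2 (0-based index motifP1 - 1)
  ant[motifP1 + 1L] <- "R"               # P1
  epitopeStart <- sample(33:58, 1)       # clear of both motifs
  epi <- .splitSeq(consensusBinderPeptide())
  ant[(epitopeStart + 1):(epitopeStart + 12)] <- epi
  antigen <- paste(ant, collapse = "")

  matrices <- list(cathepsin_S = .motifMatrix("F", "R", "cathepsin_S"),
                   cathepsin_B = .motifMatrix("Y", "R", "cathepsin_B"),
                   cathepsin_H = .flatMatrix("cathepsin_H"))

  list(antigen = antigen, antigenId = "planted_antigen",
       epitopeStart = epitopeStart,
       epitopeSequence = paste(epi, collapse = ""),
       cleavageMatrices = matrices, cleavageMotifBonds = motifP1,
       pmhcTemplate = cs$pmhcTemplate, tcrModels = cs$tcrModels,
       ternaryTemplates = cs$ternaryTemplates, potential = potential,
       complexSet = cs)
}
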