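# Distance-dependent interface statistical potentials: pair-count
# collection across an interface, negative-log-odds derivation against a
# reference state, interface scoring, and the two-stage training of the
# pMHC potential from binder/nonbinder model cohorts.
#
# Scores are "lower = more favorable" throughout, as usual for
# knowledge-based potentials.

.isHeavy <- function(element) {
  !(toupper(element) %in% c("H", "D"))
}

# Cross-interface heavy-atom pairs of one structure: type ids of each
# side and their distances. Returns NULL when a group role is missing.
.interfacePairs <- function(structure, interface, typingScheme) {
  roles <- structure@roleMap
  if (!any(interface@groupA %in% roles) ||
      !any(interface@groupB %in% roles))
    return(NULL)
  A <- .roledAtoms(structure, interface@groupA)
  B <- .roledAtoms(structure, interface@groupB)
  A <- A[.isHeavy(A$element), , drop = FALSE]
  B <- B[.isHeavy(B$element), , drop = FALSE]
  ta <- atomTypeIds(typingScheme, A$resname, A$atom)
  tb <- atomTypeIds(typingScheme, B$resname, B$atom)
  keepA <- !is.na(ta)
  keepB <- !is.na(tb)
  A <- A[keepA, , drop = FALSE]; ta <- ta[keepA]
  B <- B[keepB, , drop = FALSE]; tb <- tb[keepB]
  if (nrow(A) == 0 || nrow(B) == 0) return(NULL)
  xa <- as.matrix(A[, c("x", "y", "z")])
  xb <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  list(ta = rep(ta, times = length(tb)),
       tb = rep(tb, each = length(ta)),
       d = sqrt(as.vector(d2)))
}

#' Collect cross-interface atom-pair distance counts
#'
#' For each structure, every heavy-atom pair with one atom in each
#' interface group is assigned a distance bin (half-open, pairs at or
#' beyond \code{rMax} ignored) and tallied into a symmetric
#' \code{(type, type, bin)} tensor: each pair contributes one count to
#' \code{[ta, tb, bin]} and, when the types differ, one count to
#' \code{[tb, ta, bin]}.
#'
#' @param structures list of \linkS4class{ComplexStructure} objects;
#'   structures missing an interface role are skipped with a warning.
#' @param typingScheme an \linkS4class{AtomTypingScheme}.
#' @param binningScheme a \linkS4class{BinningScheme}.
#' @param interface an \linkS4class{InterfaceDefinition}.
#' @return numeric array \code{[nTypes, nTypes, nBins]} of counts.
#' @export
collectPairCounts <- function(structures, typingScheme = AtomTypingScheme(),
                              binningScheme = BinningScheme(),
                              interface = pmhcInterface()) {
  n <- nTypes(typingScheme)
  b <- nBins(binningScheme)
  acc <- numeric(n * n * b)
  used <- 0L
  for (s in structures) {
    pr <- .interfacePairs(templateStructure(s), interface, typingScheme)
    if (is.null(pr)) {
      warning("structure missing an interface role: skipped")
      next
    }
    used <- used + 1L
    bin <- binIndex(binningScheme, pr$d)
    keep <- !is.na(bin)
    ta <- pr$ta[keep]; tb <- pr$tb[keep]; bin <- bin[keep]
    if (length(bin) == 0) next
    lin1 <- ta + (tb - 1) * n + (bin - 1) * n * n
    off <- ta != tb
    lin2 <- tb[off] + (ta[off] - 1) * n + (bin[off] - 1) * n * n
    acc <- acc + tabulate(c(lin1, lin2), nbins = n * n * b)
  }
  if (used == 0L) stop("no usable structures")
  array(acc, dim = c(n, n, b))
}

#' Derive a potential from observed and reference counts
#'
#' The score of each cell is
#' \deqn{-\log\frac{(o + p)/(\sum o + P)}{(r + p)/(\sum r + P)}}
#' with per-cell pseudocount \eqn{p} and \eqn{P = p \times} number of
#' cells, so that identical tensors yield an all-zero (zero-information)
#' table. Lower scores mark type pairs enriched at that distance in the
#' observed set relative to the reference state.
#'
#' @param observed,reference count tensors of identical shape
#'   (from \code{\link{collectPairCounts}}).
#' @param typingScheme,binningScheme the schemes the tensors were
#'   collected under.
#' @param pseudocount per-cell smoothing constant (> 0, default 1).
#' @param provenance optional list of extra training metadata.
#' @return a \linkS4class{PotentialTable}.
#' @export
derivePotential <- function(observed, reference,
                            typingScheme = AtomTypingScheme(),
                            binningScheme = BinningScheme(),
                            pseudocount = 1, provenance = list()) {
  if (!all(dim(observed) == dim(reference)))
    stop("incompatible tensors")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  P <- pseudocount * length(observed)
  po <- (observed + pseudocount) / (sum(observed) + P)
  pr <- (reference + pseudocount) / (sum(reference) + P)
  sc <- -log(po / pr)
  sc <- (sc + aperm(sc, c(2, 1, 3))) / 2   # guard symmetry numerically
  prov <- c(list(observed_total = sum(observed),
                 reference_total = sum(reference),
                 pseudocount = pseudocount),
            provenance)
  new("PotentialTable", typing = typingScheme, binning = binningScheme,
      scores = sc, provenance = prov)
}

#' Score a complex interface with a potential
#'
#' Sums the potential over all cross-interface heavy-atom pairs closer
#' than the interface cutoff. Deterministic; lower is better; an
#' interface with no pairs within the cutoff scores 0.
#'
#' @param structure a \linkS4class{ComplexStructure}.
#' @param interface an \linkS4class{InterfaceDefinition}; its cutoff must
#'   not exceed the potential's binning ceiling.
#' @param potential a \linkS4class{PotentialTable}.
#' @return numeric score.
#' @export
scoreInterface <- function(structure, interface, potential) {
  if (interface@cutoff > potential@binning@rMax)
    stop("interface cutoff exceeds the potential's distance range")
  pr <- .interfacePairs(templateStructure(structure), interface,
                        potential@typing)
  if (is.null(pr)) stop("interface incomplete: a group role is missing")
  keep <- pr$d < interface@cutoff
  if (!any(keep)) return(0)
  bin <- binIndex(potential@binning, pr$d[keep])
  ok <- !is.na(bin)
  sum(potential@scores[cbind(pr$ta[keep][ok], pr$tb[keep][ok], bin[ok])])
}

#' Train a pMHC potential from affinity-labeled model cohorts
#'
#' Two-stage bootstrap: models of peptide-MHCII complexes with known
#' affinity class are built with a base potential (or any modeling
#' route), then a problem-specific potential is derived with the
#' binder-cohort pair counts as the observed state and the
#' nonbinder-cohort counts as the reference state.
#'
#' @param models list of \linkS4class{ComplexStructure} objects.
#' @param affinityClass character vector (\code{"binder"} /
#'   \code{"nonbinder"}), one per model.
#' @param typingScheme,binningScheme,interface counting schemes (defaults:
#'   residue typing, 0.5 A bins to 15 A, peptide vs MHC interface).
#' @param pseudocount per-cell smoothing constant.
#' @return a \linkS4class{PotentialTable} whose provenance records both
#'   cohorts.
#' @export
trainPMHCPotential <- function(models, affinityClass,
                               typingScheme = AtomTypingScheme(),
                               binningScheme = BinningScheme(),
                               interface = pmhcInterface(),
                               pseudocount = 1) {
  affinityClass <- as.character(affinityClass)
  stopifnot(length(models) == length(affinityClass))
  binders <- models[affinityClass == "binder"]
  nonbinders <- models[affinityClass == "nonbinder"]
  if (length(binders) == 0 || length(nonbinders) == 0)
    stop("missing affinity class")
  obs <- collectPairCounts(binders, typingScheme, binningScheme, interface)
  ref <- collectPairCounts(nonbinders, typingScheme, binningScheme,
                           interface)
  derivePotential(obs, ref, typingScheme, binningScheme, pseudocount,
                  provenance = list(reference_state = "nonbinder cohort",
                                    n_binder = length(binders),
                                    n_nonbinder = length(nonbinders)))
}
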