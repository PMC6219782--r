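# S4 classes for the three-stage epitope predictor.

#' @import methods
NULL

# ---------------------------------------------------------------- cleavage --

#' Scissile-bond window definition (Schechter-Berger positions)
#'
#' The residues flanking a protease scissile bond are numbered
#' P_n...P1 | P1'...P_m'; the bond is hydrolyzed between P1 and P1'.
#' A window definition fixes how many positions on each side of the bond
#' enter a specificity matrix, e.g. P4-P4' for an endopeptidase or
#' P1-P4' for an aminopeptidase.
#'
#' @slot upstream number of non-prime (P-side) positions, >= 1.
#' @slot downstream number of prime (P'-side) positions, >= 1.
#' @export
setClass("WindowDefinition",
  slots = c(upstream = "integer", downstream = "integer"))

setValidity("WindowDefinition", function(object) {
  if (length(object@upstream) != 1L || length(object@downstream) != 1L)
    return("upstream and downstream must be single integers")
  if (object@upstream < 1L || object@downstream < 1L)
    return("upstream and downstream must both be >= 1")
  TRUE
})

#' @param upstream number of P-side positions (P_n...P1).
#' @param downstream number of P'-side positions (P1'...P_m').
#' @rdname WindowDefinition-class
#' @return a \code{WindowDefinition} object.
#' @examples
#' WindowDefinition(4, 4)   # P4-P4'
#' WindowDefinition(1, 4)   # P1-P4' (aminopeptidase)
#' @export
WindowDefinition <- function(upstream = 4L, downstream = 4L) {
  new("WindowDefinition", upstream = as.integer(upstream),
      downstream = as.integer(downstream))
}

# Position labels, e.g. P4 P3 P2 P1 P1p P2p P3p P4p ("p" = prime).
positionLabels <- function(window) {
  c(paste0("P", seq(window@upstream, 1L)),
    paste0("P", seq_len(window@downstream), "p"))
}

# 0-based sequence offsets of the window positions relative to the P1
# index (the scissile bond lies between P1 and P1').
positionOffsets <- function(window) {
  c(seq(-window@upstream + 1L, 0L), seq_len(window@downstream))
}

#' Protease specificity matrix
#'
#' Position-specific residue statistics for one protease, built from
#' observed cleavage events. Counts are tallies of the residues observed
#' at each window position; probabilities are pseudocount-smoothed
#' per-position frequencies; log-odds compare those probabilities with a
#' background residue distribution. The cleavage score of a candidate
#' scissile bond is the sum of the (natural) log-odds across the window.
#'
#' @slot enzyme protease identifier (e.g. \code{"cathepsin_S"}).
#' @slot window a \linkS4class{WindowDefinition}.
#' @slot counts residue x position matrix of non-negative tallies.
#' @slot probabilities residue x position matrix; each column sums to 1.
#' @slot background named residue frequencies summing to 1; its names
#'   define the residue alphabet of the matrix.
#' @slot logOdds residue x position matrix,
#'   \code{log(probabilities / background)}.
#' @slot pseudocount non-negative smoothing constant used at the
#'   probability step.
#' @export
setClass("SpecificityMatrix",
  slots = c(enzyme = "character", window = "WindowDefinition",
            counts = "matrix", probabilities = "matrix",
            background = "numeric", logOdds = "matrix",
            pseudocount = "numeric"))

setValidity("SpecificityMatrix", function(object) {
  res <- names(object@background)
  labs <- positionLabels(object@window)
  for (m in c("counts", "probabilities", "logOdds")) {
    mm <- slot(object, m)
    if (!identical(rownames(mm), res))
      return(sprintf("rownames(%s) must match names(background)", m))
    if (!identical(colnames(mm), labs))
      return(sprintf("colnames(%s) must match the window positions", m))
  }
  if (any(object@background <= 0))
    return("degenerate background: all frequencies must be > 0")
  if (abs(sum(object@background) - 1) > 1e-6)
    return("background frequencies must sum to 1")
  if (any(object@counts < 0))
    return("counts must be non-negative")
  if (any(object@probabilities <= 0) || any(object@probabilities > 1))
    return("probabilities must lie in (0, 1]")
  colsum <- colSums(object@probabilities)
  if (any(abs(colsum - 1) > 1e-9))
    return("per-position probabilities must sum to 1 (tolerance 1e-9)")
  expect <- log(object@probabilities / object@background)
  if (max(abs(expect - object@logOdds)) > 1e-8)
    return("logOdds inconsistent with probabilities and background")
  if (object@pseudocount < 0)
    return("pseudocount must be non-negative")
  TRUE
})

# ----------------------------------------------------------------- structio --

#' Structure of an immunological complex
#'
#' Atoms grouped into chains, with each chain assigned an immunological
#' role: MHCII alpha or beta chain, peptide, TCR alpha or beta chain, or
#' "other". Coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname} (3-letter), \code{atom}, \code{element}, \code{x},
#'   \code{y}, \code{z}.
#' @slot roleMap named character vector mapping every chain identifier
#'   present in \code{atoms} to one of \code{mhc_alpha}, \code{mhc_beta},
#'   \code{peptide}, \code{tcr_alpha}, \code{tcr_beta}, \code{other};
#'   at most one chain per role except \code{other}.
#' @export
setClass("ComplexStructure",
  slots = c(atoms = "data.frame", roleMap = "character"))

setValidity("ComplexStructure", function(object) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@atoms) == 0)
    return("empty structure")
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    return("non-finite atom coordinates")
  chains <- unique(object@atoms$chain)
  if (!all(chains %in% names(object@roleMap)))
    return("roleMap must cover every chain present")
  if (!all(names(object@roleMap) %in% chains))
    return("unknown chain in roleMap")
  if (!all(object@roleMap %in% .ROLES))
    return(paste("roles must be among:", paste(.ROLES, collapse = ", ")))
  named <- object@roleMap[object@roleMap != "other"]
  if (anyDuplicated(named))
    return("at most one chain per role (except 'other')")
  TRUE
})

#' @param atoms atom table (see slot description).
#' @param roleMap named character vector, chain id -> role.
#' @rdname ComplexStructure-class
#' @return a \code{ComplexStructure}.
#' @export
ComplexStructure <- function(atoms, roleMap) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("ComplexStructure", atoms = atoms, roleMap = roleMap)
}

#' Rigid-body transform
#'
#' A proper rotation plus translation, applied to coordinates as
#' \code{x' = R x + t} (column-vector convention).
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector in Angstrom.
#' @export
setClass("RigidTransform",
  slots = c(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (RtR = I within 1e-8)")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det = +1 within 1e-8)")
  if (length(object@translation) != 3)
    return("translation must have length 3")
  TRUE
})

#' @param rotation,translation see slots.
#' @rdname RigidTransform-class
#' @return a \code{RigidTransform}.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

# ---------------------------------------------------------------- potential --

#' Atom typing scheme for statistical potentials
#'
#' Maps every canonical (residue, heavy atom) pair to a type identifier.
#' Two schemes are provided: \code{"residue"} (20 types, one per residue
#' -- the coarse default, adequate for backbone + C-beta-stub models) and
#' \code{"atom"} (backbone atoms N, CA, C, O and CB typed per residue,
#' any other heavy atom collapsed to a per-residue side-chain type).
#'
#' @slot name scheme name.
#' @slot labels type labels; \code{length(labels)} is the number of types.
#' @export
setClass("AtomTypingScheme",
  slots = c(name = "character", labels = "character"))

#' @param name \code{"residue"} or \code{"atom"}.
#' @rdname AtomTypingScheme-class
#' @return an \code{AtomTypingScheme}.
#' @examples
#' nTypes(AtomTypingScheme("residue"))
#' @export
AtomTypingScheme <- function(name = c("residue", "atom")) {
  name <- match.arg(name)
  labels <- switch(name,
    residue = .AA3,
    atom = as.vector(t(outer(.AA3, c("N", "CA", "C", "O", "CB", "SC"),
                             paste, sep = "."))))
  new("AtomTypingScheme", name = name, labels = labels)
}

#' @param scheme an \code{AtomTypingScheme}.
#' @rdname AtomTypingScheme-class
#' @export
nTypes <- function(scheme) length(scheme@labels)

#' Type identifiers for atoms
#'
#' @param scheme an \linkS4class{AtomTypingScheme}.
#' @param resname 3-letter residue names.
#' @param atom atom names (e.g. \code{"CA"}).
#' @return integer type ids (NA for non-canonical residues).
#' @export
atomTypeIds <- function(scheme, resname, atom) {
  if (scheme@name == "residue") {
    match(resname, scheme@labels)
  } else {
    a <- ifelse(atom %in% c("N", "CA", "C", "O", "CB"), atom, "SC")
    match(paste(resname, a, sep = "."), scheme@labels)
  }
}

#' Distance binning scheme
#'
#' Half-open bins \code{[lo, hi)} of equal width covering
#' \code{[rMin, rMax)}; pair distances at or beyond \code{rMax} are
#' ignored.
#'
#' @slot rMin,rMax range in Angstrom.
#' @slot binWidth bin width in Angstrom; \code{(rMax - rMin)/binWidth}
#'   must be a positive integer.
#' @export
setClass("BinningScheme",
  slots = c(rMin = "numeric", rMax = "numeric", binWidth = "numeric"))

setValidity("BinningScheme", function(object) {
  if (object@rMin < 0) return("rMin must be >= 0")
  if (object@rMax <= object@rMin) return("rMax must exceed rMin")
  n <- (object@rMax - object@rMin) / object@binWidth
  if (abs(n - round(n)) > 1e-9 || round(n) < 1)
    return("(rMax - rMin)/binWidth must be a positive integer")
  TRUE
})

#' @param rMin,rMax,binWidth see slots.
#' @rdname BinningScheme-class
#' @return a \code{BinningScheme}.
#' @export
BinningScheme <- function(rMin = 0, rMax = 15, binWidth = 0.5) {
  new("BinningScheme", rMin = rMin, rMax = rMax, binWidth = binWidth)
}

#' @param binning a \code{BinningScheme}.
#' @rdname BinningScheme-class
#' @export
nBins <- function(binning) {
  as.integer(round((binning@rMax - binning@rMin) / binning@binWidth))
}

# 1-based bin index for distances; NA outside [rMin, rMax).
binIndex <- function(binning, d) {
  idx <- floor((d - binning@rMin) / binning@binWidth) + 1
  idx[d < binning@rMin | d >= binning@rMax] <- NA_integer_
  as.integer(idx)
}

#' Distance-dependent interface potential
#'
#' Score per (type, type, distance bin), derived as negative log-odds of
#' observed versus reference pair counts. Lower scores are more
#' favorable. The table is symmetric in the two type indices.
#'
#' @slot typing an \linkS4class{AtomTypingScheme}.
#' @slot binning a \linkS4class{BinningScheme}.
#' @slot scores numeric array \code{[type, type, bin]}.
#' @slot provenance list of training metadata (count totals, pseudocount,
#'   reference state, cohort sizes).
#' @export
setClass("PotentialTable",
  slots = c(typing = "AtomTypingScheme", binning = "BinningScheme",
            scores = "array", provenance = "list"))

setValidity("PotentialTable", function(object) {
  n <- nTypes(object@typing)
  b <- nBins(object@binning)
  if (!all(dim(object@scores) == c(n, n, b)))
    return("scores must have dim (nTypes, nTypes, nBins)")
  if (!all(is.finite(object@scores)))
    return("scores must be finite")
  sw <- aperm(object@scores, c(2, 1, 3))
  if (max(abs(object@scores - sw)) > 1e-9)
    return("scores must be symmetric in the type indices")
  TRUE
})

#' Interface definition
#'
#' Two disjoint sets of chain roles whose cross pairs constitute the
#' interface, plus the distance cutoff (Angstrom) within which pairs are
#' scored.
#'
#' @slot groupA,groupB disjoint role sets.
#' @slot cutoff scoring cutoff in Angstrom.
#' @export
setClass("InterfaceDefinition",
  slots = c(groupA = "character", groupB = "character", cutoff = "numeric"))

setValidity("InterfaceDefinition", function(object) {
  if (length(intersect(object@groupA, object@groupB)) > 0)
    return("groupA and groupB must be disjoint")
  if (!all(c(object@groupA, object@groupB) %in% .ROLES))
    return("unknown role in interface definition")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' @param groupA,groupB,cutoff see slots.
#' @rdname InterfaceDefinition-class
#' @return an \code{InterfaceDefinition}.
#' @examples
#' pmhcInterface()
#' tcrInterface()
#' @export
InterfaceDefinition <- function(groupA, groupB, cutoff = 6) {
  new("InterfaceDefinition", groupA = groupA, groupB = groupB,
      cutoff = cutoff)
}

#' @rdname InterfaceDefinition-class
#' @export
pmhcInterface <- function(cutoff = 6) {
  InterfaceDefinition("peptide", .MHC_ROLES, cutoff)
}

#' @rdname InterfaceDefinition-class
#' @export
tcrInterface <- function(cutoff = 6) {
  InterfaceDefinition(.TCR_ROLES, c("peptide", .MHC_ROLES), cutoff)
}

# ----------------------------------------------------------------- modeling --

#' Template library entry
#'
#' A structure plus its bookkeeping: source identifier (typically a PDB
#' code), kind (\code{pmhc}, \code{tcr} or \code{ternary}), and metadata
#' such as the 1-based index, among the peptide-chain residues, where the
#' 12-residue groove core starts (\code{coreStart}), and allele or TCR
#' annotations.
#'
#' @slot structure a \linkS4class{ComplexStructure}.
#' @slot sourceId source identifier.
#' @slot kind one of \code{"pmhc"}, \code{"tcr"}, \code{"ternary"}.
#' @slot meta list of annotations (\code{coreStart}, \code{allele}, ...).
#' @export
setClass("TemplateEntry",
  slots = c(structure = "ComplexStructure", sourceId = "character",
            kind = "character", meta = "list"))

setValidity("TemplateEntry", function(object) {
  if (!object@kind %in% c("pmhc", "tcr", "ternary"))
    return("kind must be pmhc, tcr or ternary")
  roles <- object@structure@roleMap
  need <- switch(object@kind,
    pmhc = c(.MHC_ROLES, "peptide"),
    tcr = character(0),
    ternary = c(.MHC_ROLES, "peptide"))
  if (!all(need %in% roles))
    return(sprintf("%s template lacks required roles", object@kind))
  if (object@kind == "tcr" && !any(.TCR_ROLES %in% roles))
    return("tcr template lacks a TCR chain")
  if (object@kind == "ternary" && !any(.TCR_ROLES %in% roles))
    return("ternary template lacks a TCR chain")
  TRUE
})

#' @param structure,sourceId,kind,meta see slots.
#' @rdname TemplateEntry-class
#' @return a \code{TemplateEntry}.
#' @export
TemplateEntry <- function(structure, sourceId = "template",
                          kind = c("pmhc", "tcr", "ternary"),
                          meta = list()) {
  kind <- match.arg(kind)
  if (is.null(meta$coreStart)) meta$coreStart <- 1L
  new("TemplateEntry", structure = structure, sourceId = sourceId,
      kind = kind, meta = meta)
}
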