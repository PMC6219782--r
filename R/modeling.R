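# Candidate enumeration, fixed-backbone peptide threading onto pMHCII
# templates, and assembly of ternary pMHCII-TCR models on ternary
# templates.

#' Enumerate candidate epitope cores
#'
#' All overlapping windows of \code{coreLen} residues (default 12; this
#' 12-mer core starts two positions before the traditional 9-mer groove
#' register, recorded in \code{register_note}).
#'
#' @param antigen antigen sequence.
#' @param coreLen core length (default 12).
#' @param antigenId identifier carried into the output.
#' @return data.frame with columns \code{antigen_id}, \code{start}
#'   (0-based), \code{sequence}, \code{register_note}; ascending start.
#'   An antigen shorter than \code{coreLen} yields an empty frame with a
#'   warning.
#' @examples
#' nrow(enumerateCandidates(strrep("A", 317)))  # 306
#' @export
enumerateCandidates <- function(antigen, coreLen = 12L,
                                antigenId = "antigen") {
  L <- nchar(antigen)
  if (L < coreLen) {
    warning("antigen shorter than the core length: no candidates")
    return(data.frame(antigen_id = character(0), start = integer(0),
                      sequence = character(0), register_note = integer(0),
                      stringsAsFactors = FALSE))
  }
  starts <- 0:(L - coreLen)
  data.frame(antigen_id = antigenId, start = starts,
             sequence = substring(antigen, starts + 1, starts + coreLen),
             register_note = 2L, stringsAsFactors = FALSE)
}

# Ideal-geometry C-beta position from backbone N, CA, C (unit direction
# from the standard tetrahedral construction, scaled to 1.53 A).
.idealCB <- function(N, CA, C) {
  b <- CA - N
  c <- C - CA
  a <- c(b[2] * c[3] - b[3] * c[2],
         b[3] * c[1] - b[1] * c[3],
         b[1] * c[2] - b[2] * c[1])
  d <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c
  CA + 1.53 * d / sqrt(sum(d^2))
}

#' Thread a candidate peptide onto a pMHCII template
#'
#' Fixed-backbone threading: the MHC chains and all peptide backbone
#' atoms (N, CA, C, O) of the template's 12-residue core are kept
#' bit-identical; peptide residue identities are replaced by the
#' candidate sequence. In the default \code{"reduced"} mode every
#' non-glycine residue gets an ideal-geometry C-beta stub (Ca-Cb exactly
#' 1.53 A); in \code{"copy"} mode template side chains are kept where the
#' residue is unchanged and substituted residues get the stub. Peptide
#' residues outside the core (flanks) are not modeled.
#'
#' @param template a \linkS4class{TemplateEntry} of kind \code{pmhc}
#'   (or a \linkS4class{ComplexStructure}); \code{meta$coreStart} gives
#'   the 1-based index of the core's first residue among the peptide
#'   chain residues (default 1).
#' @param candidate a 12-residue sequence, or one row of
#'   \code{\link{enumerateCandidates}} output.
#' @param mode side-chain placement mode, \code{"reduced"} (default) or
#'   \code{"copy"}.
#' @return a \linkS4class{ComplexStructure} of the threaded pMHCII model.
#' @export
threadPeptide <- function(template, candidate, mode = c("reduced", "copy")) {
  mode <- match.arg(mode)
  if (is.data.frame(candidate)) candidate <- candidate$sequence[1]
  candidate <- normalizeSequence(candidate)
  coreLen <- nchar(candidate)
  struct <- templateStructure(template)
  coreStart <- 1L
  if (is(template, "TemplateEntry") && !is.null(template@meta$coreStart))
    coreStart <- as.integer(template@meta$coreStart)

  at <- struct@atoms
  at$role <- unname(struct@roleMap[at$chain])
  pep <- at[at$role == "peptide", , drop = FALSE]
  resnos <- sort(unique(pep$resno))
  if (length(resnos) < coreStart + coreLen - 1)
    stop("core mismatch: template peptide core shorter than ", coreLen)
  core <- resnos[coreStart:(coreStart + coreLen - 1)]

  newSeq <- .splitSeq(candidate)
  out <- list()
  for (j in seq_len(coreLen)) {
    rows <- pep[pep$resno == core[j], , drop = FALSE]
    bb <- rows[match(c("N", "CA", "C", "O"), rows$atom), , drop = FALSE]
    if (any(is.na(bb$atom)))
      stop("unusable template: incomplete backbone at peptide residue ",
           core[j])
    res3 <- aaOneToThree(newSeq[j])
    keep <- bb
    if (mode == "copy" && rows$resname[1] == res3) {
      keep <- rows
    } else if (res3 != "GLY") {
      cb <- .idealCB(as.numeric(bb[1, c("x", "y", "z")]),
                     as.numeric(bb[2, c("x", "y", "z")]),
                     as.numeric(bb[3, c("x", "y", "z")]))
      stub <- bb[2, , drop = FALSE]
      stub$atom <- "CB"
      stub$element <- "C"
      stub$x <- cb[1]; stub$y <- cb[2]; stub$z <- cb[3]
      keep <- rbind(bb, stub)
    }
    keep$resname <- res3
    out[[j]] <- keep
  }
  newPep <- do.call(rbind, out)
  rest <- at[at$role != "peptide", , drop = FALSE]
  atoms <- rbind(rest, newPep)
  atoms$role <- NULL
  ComplexStructure(atoms, struct@roleMap)
}

# Deterministically rename chains of `mobile` that clash with `taken`.
.resolveChainClash <- function(structure, taken) {
  clash <- intersect(names(structure@roleMap), taken)
  if (length(clash) == 0) return(structure)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)),
                  c(taken, names(structure@roleMap)))
  at <- structure@atoms
  rm <- structure@roleMap
  for (i in seq_along(clash)) {
    old <- clash[i]
    newId <- pool[i]
    at$chain[at$chain == old] <- newId
    names(rm)[names(rm) == old] <- newId
  }
  ComplexStructure(at, rm)
}

#' Assemble a ternary pMHCII-TCR model on a ternary template
#'
#' The pMHCII model is superposed onto the template via MHC-role C-alpha
#' atoms and the TCR model via TCR-role C-alpha atoms; the transformed
#' copies are combined into one complex, so the MHC-TCR relative
#' orientation of the output matches the template's within the
#' superposition residuals. Chain-identifier clashes between the two
#' models are resolved by deterministic renaming of the TCR chains.
#'
#' @param pmhcModel a \linkS4class{ComplexStructure} with MHC (and
#'   peptide) roles.
#' @param tcrModel a \linkS4class{ComplexStructure} with at least one TCR
#'   role (beta-only models are acceptable).
#' @param template a \linkS4class{TemplateEntry} of kind \code{ternary}
#'   (or a \linkS4class{ComplexStructure} with MHC and TCR roles).
#' @return the assembled \linkS4class{ComplexStructure}.
#' @export
assembleTernary <- function(pmhcModel, tcrModel, template) {
  tmpl <- templateStructure(template)
  tcrRoles <- intersect(.TCR_ROLES, tcrModel@roleMap)
  if (length(tcrRoles) == 0) stop("tcrModel has no TCR role")
  fitP <- superpose(pmhcModel, tmpl, roles = .MHC_ROLES, atomNames = "CA")
  pm <- applyTransform(pmhcModel, fitP$transform)
  fitT <- superpose(tcrModel, tmpl, roles = tcrRoles, atomNames = "CA")
  tc <- applyTransform(tcrModel, fitT$transform)
  tc <- .resolveChainClash(tc, names(pm@roleMap))
  ComplexStructure(rbind(pm@atoms, tc@atoms),
                   c(pm@roleMap, tc@roleMap))
}
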