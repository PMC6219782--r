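# PDB-format structure I/O, chain-role assignment, Kabsch superposition,
# and the MHC-anchored TCR RMSD used to compare pMHCII-TCR orientations.
#
# Parsing and writing of the PDB format are delegated to bio3d; chains
# are assigned immunological roles explicitly via a role map (no
# automatic MHC/TCR detection, avoiding silent misassignment on
# nonstandard chain identifiers).

#' Read a structure in PDB format and assign chain roles
#'
#' Atoms are kept in file order; for alternate locations only the first
#' altloc of each (chain, residue, atom) is kept, with a warning.
#'
#' @param file path to a PDB-format file.
#' @param roleMap named character vector mapping chain identifiers to
#'   roles (\code{mhc_alpha}, \code{mhc_beta}, \code{peptide},
#'   \code{tcr_alpha}, \code{tcr_beta}, \code{other}). Chains present in
#'   the file but absent from \code{roleMap} are assigned \code{other}.
#' @return a \linkS4class{ComplexStructure}.
#' @export
readComplex <- function(file, roleMap) {
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e) NULL)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure")
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  dup <- duplicated(key) & !is.na(at$alt) & at$alt != ""
  if (any(dup)) {
    warning(sum(dup), " alternate-location atoms dropped (first kept)")
    at <- at[!dup, , drop = FALSE]
  }
  chains <- unique(at$chain)
  missing <- setdiff(names(roleMap), chains)
  if (length(missing) > 0)
    stop("unknown chain: ", paste(missing, collapse = ", "))
  full <- stats::setNames(rep("other", length(chains)), chains)
  full[names(roleMap)] <- roleMap
  elem <- at$elesym
  if (is.null(elem) || length(elem) != nrow(at) || all(is.na(elem)))
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resname = at$resid, atom = at$elety,
                      element = elem, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  noncanon <- setdiff(unique(atoms$resname), .AA3)
  if (length(noncanon) > 0)
    message("non-canonical residues kept: ",
            paste(noncanon, collapse = ", "))
  ComplexStructure(atoms, full)
}

#' Write a structure in PDB format
#'
#' Round-trips coordinates to 3 decimals (the fixed-width PDB precision).
#'
#' @param structure a \linkS4class{ComplexStructure}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeComplex <- function(structure, file) {
  at <- structure@atoms
  n <- nrow(at)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = at$atom, resid = at$resname, chain = at$chain,
                   resno = at$resno, o = rep(1, n), b = rep(0, n))
  invisible(file)
}

# Atoms annotated with their chain role.
.roledAtoms <- function(structure, roles = NULL, atomNames = NULL) {
  at <- structure@atoms
  at$role <- unname(structure@roleMap[at$chain])
  if (!is.null(roles)) at <- at[at$role %in% roles, , drop = FALSE]
  if (!is.null(atomNames)) at <- at[at$atom %in% atomNames, , drop = FALSE]
  at
}

# Pair atoms of two structures by (role, residue number, atom name).
.pairAtoms <- function(a, b, roles = NULL, atomNames = "CA") {
  ta <- .roledAtoms(a, roles, atomNames)
  tb <- .roledAtoms(b, roles, atomNames)
  ka <- paste(ta$role, ta$resno, ta$atom)
  kb <- paste(tb$role, tb$resno, tb$atom)
  common <- intersect(ka, kb)
  list(a = as.matrix(ta[match(common, ka), c("x", "y", "z")]),
       b = as.matrix(tb[match(common, kb), c("x", "y", "z")]),
       n = length(common))
}

# Kabsch: least-squares proper rotation + translation taking P onto Q.
.kabsch <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc)
  Qc <- sweep(Q, 2, qc)
  sv <- svd(crossprod(Pc, Qc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = qc - as.vector(R %*% pc),
       singular = svd(Pc)$d)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Pairs atoms of \code{mobile} and \code{reference} by (role, residue
#' number, atom name), restricted to the requested roles and atom names
#' (default: C-alpha atoms of all shared roles), and returns the optimal
#' proper rigid transform together with the post-fit RMSD over the
#' selection. The input structures are not modified.
#'
#' @param mobile,reference \linkS4class{ComplexStructure} objects.
#' @param roles roles used for pairing (default: all).
#' @param atomNames atom-name filter (default \code{"CA"}).
#' @return list with elements \code{transform}
#'   (a \linkS4class{RigidTransform}) and \code{rmsd} (Angstrom).
#' @export
superpose <- function(mobile, reference, roles = NULL, atomNames = "CA") {
  pr <- .pairAtoms(mobile, reference, roles, atomNames)
  if (pr$n < 3) stop("underdetermined superposition: fewer than 3 pairs")
  k <- .kabsch(pr$a, pr$b)
  if (k$singular[2] < 1e-8 * max(k$singular[1], 1))
    stop("degenerate geometry: selection is collinear")
  moved <- sweep(pr$a %*% t(k$R), 2, k$t, "+")
  rmsd <- sqrt(mean(rowSums((moved - pr$b)^2)))
  list(transform = RigidTransform(k$R, k$t), rmsd = rmsd)
}

#' Apply a rigid transform to a structure
#'
#' @param structure a \linkS4class{ComplexStructure}.
#' @param transform a \linkS4class{RigidTransform}.
#' @return a new, transformed \linkS4class{ComplexStructure}.
#' @export
applyTransform <- function(structure, transform) {
  at <- structure@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(transform@rotation), 2,
                 transform@translation, "+")
  at$x <- moved[, 1]
  at$y <- moved[, 2]
  at$z <- moved[, 3]
  ComplexStructure(at, structure@roleMap)
}

#' TCR RMSD after MHC superposition
#'
#' Superposes \code{b} onto \code{a} using only MHC-role C-alpha atoms,
#' then returns the C-alpha RMSD over the TCR-role chains without any
#' further fitting. This is the metric used to compare pMHCII-TCR
#' orientations across a template library.
#'
#' @param a,b \linkS4class{ComplexStructure} objects with MHC and TCR
#'   roles.
#' @return RMSD in Angstrom.
#' @export
tcrRMSD <- function(a, b) {
  fit <- superpose(b, a, roles = .MHC_ROLES, atomNames = "CA")
  b2 <- applyTransform(b, fit$transform)
  pr <- .pairAtoms(a, b2, roles = .TCR_ROLES, atomNames = "CA")
  if (pr$n == 0) stop("incomparable TCRs: no pairable TCR C-alpha atoms")
  sqrt(mean(rowSums((pr$a - pr$b)^2)))
}

#' Closest template by MHC-anchored TCR RMSD
#'
#' @param model a \linkS4class{ComplexStructure}.
#' @param library list of \linkS4class{ComplexStructure} or
#'   \linkS4class{TemplateEntry} objects.
#' @return list with \code{index}, \code{template}, and \code{rmsd};
#'   ties broken by library order.
#' @export
closestTemplate <- function(model, library) {
  if (length(library) == 0) stop("no templates")
  rmsds <- vapply(library,
                  function(t) tcrRMSD(model, templateStructure(t)),
                  numeric(1))
  i <- which.min(rmsds)
  list(index = i, template = library[[i]], rmsd = rmsds[i])
}
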