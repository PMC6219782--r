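# Protease specificity matrices and cleavage-site prediction.
#
# Cathepsin S and B act as endopeptidases on the whole antigen; cathepsin
# H is a mono-aminopeptidase that trims single residues from fragment
# N-termini. A candidate scissile bond between residues i and i+1
# (0-based; i is the P1 residue) is scored as the sum over the window of
# the natural-log odds of the observed residue versus background, and is
# called confident when the score exceeds the threshold (default 3.0).

#' Default specificity windows per enzyme
#'
#' P4-P4' for the endopeptidases cathepsin S and cathepsin B (matching
#' the octapeptide cleavage-event sets they are trained from) and P1-P4'
#' for the aminopeptidase cathepsin H.
#'
#' @param enzyme enzyme identifier.
#' @return a \linkS4class{WindowDefinition}.
#' @export
defaultWindow <- function(enzyme) {
  switch(enzyme,
    cathepsin_H = WindowDefinition(1, 4),
    WindowDefinition(4, 4))
}

#' Build a protease specificity matrix from cleavage events
#'
#' Tallies the residues observed at each window position around the
#' scissile bond of each event, converts the tallies to
#' pseudocount-smoothed probabilities, and takes natural-log odds against
#' a background distribution. Events too short to cover a window
#' position simply do not contribute to that position (the per-position
#' denominator counts contributing events only).
#'
#' @param events data.frame with columns \code{substrate_sequence},
#'   \code{scissile_index} (0-based index of the P1 residue) and
#'   \code{enzyme}; see \code{\link{readCleavageEvents}}. Norleucine
#'   (lower-case \code{n}) is mapped to Met during normalization.
#' @param window a \linkS4class{WindowDefinition}; defaults to the
#'   enzyme's standard window (\code{\link{defaultWindow}}).
#' @param background named residue frequencies (strictly positive,
#'   summing to 1). Its names define the residue alphabet; default is
#'   uniform over the 20 canonical residues. A table of natural residue
#'   frequencies may be supplied instead.
#' @param pseudocount smoothing constant added to every count at the
#'   probability step (default 1, add-one); guarantees finite log-odds
#'   for small event sets.
#' @param enzymeId enzyme identifier; defaults to the single enzyme named
#'   in \code{events}.
#' @return a \linkS4class{SpecificityMatrix}.
#' @examples
#' ev <- data.frame(substrate_sequence = c("AKAA", "GKAS"),
#'                  scissile_index = 1, enzyme = "cathepsin_S")
#' m <- buildSpecificityMatrix(ev, WindowDefinition(1, 1))
#' logOdds(m)["K", "P1"]
#' @export
buildSpecificityMatrix <- function(events, window = NULL, background = NULL,
                                   pseudocount = 1, enzymeId = NULL) {
  if (is.null(events) || nrow(events) == 0)
    stop("no training data")
  if (is.null(background)) background <- uniformBackground()
  if (any(background <= 0))
    stop("degenerate background")
  background <- background / sum(background)
  alphabet <- names(background)
  if (is.null(enzymeId)) {
    enzymeId <- unique(as.character(events$enzyme))
    if (length(enzymeId) != 1)
      stop("events must concern a single enzyme (or pass enzymeId)")
  }
  if (is.null(window)) window <- defaultWindow(enzymeId)

  seqs <- normalizeSequence(as.character(events$substrate_sequence),
                            alphabet)
  idx <- as.integer(events$scissile_index)
  len <- nchar(seqs)
  if (any(idx < 0 | idx >= len - 1))
    stop("invalid scissile bond: scissile_index out of range")

  labs <- positionLabels(window)
  offs <- positionOffsets(window)
  counts <- matrix(0L, nrow = length(alphabet), ncol = length(labs),
                   dimnames = list(alphabet, labs))
  for (p in seq_along(offs)) {
    pos0 <- idx + offs[p]                  # 0-based residue index
    ok <- pos0 >= 0 & pos0 < len
    if (!any(ok)) next
    res <- substring(seqs[ok], pos0[ok] + 1, pos0[ok] + 1)
    tab <- table(factor(res, levels = alphabet))
    counts[, p] <- counts[, p] + as.integer(tab)
  }
  nA <- length(alphabet)
  denom <- colSums(counts) + nA * pseudocount
  if (any(denom <= 0))
    stop("no events cover one or more window positions and pseudocount is 0")
  probs <- sweep(counts + pseudocount, 2, denom, "/")
  lo <- log(probs / background)
  new("SpecificityMatrix", enzyme = enzymeId, window = window,
      counts = counts, probabilities = probs, background = background,
      logOdds = lo, pseudocount = pseudocount)
}

#' Score one candidate scissile bond
#'
#' Sums the matrix log-odds over the window centered on the bond between
#' antigen residues \code{scissileIndex} and \code{scissileIndex + 1}
#' (0-based). Window positions falling outside the antigen termini
#' contribute 0 (neutral padding), so near-terminal bonds remain
#' scoreable.
#'
#' @param matrix a \linkS4class{SpecificityMatrix}.
#' @param antigen antigen sequence (one-letter).
#' @param scissileIndex 0-based index of the P1 residue.
#' @return the cleavage score (numeric scalar).
#' @export
scoreSite <- function(matrix, antigen, scissileIndex) {
  antigen <- normalizeSequence(antigen, names(matrix@background))
  L <- nchar(antigen)
  if (scissileIndex < 0 || scissileIndex >= L - 1)
    stop("invalid scissile bond")
  offs <- positionOffsets(matrix@window)
  pos0 <- scissileIndex + offs
  ok <- pos0 >= 0 & pos0 < L
  if (!any(ok)) return(0)
  res <- substring(antigen, pos0[ok] + 1, pos0[ok] + 1)
  sum(matrix@logOdds[cbind(res, positionLabels(matrix@window)[ok])])
}

#' Predict cleavage sites in an antigen
#'
#' Every internal scissile bond is scored with the endopeptidase matrices
#' (cathepsins S and B). The aminopeptidase matrix (cathepsin H), when
#' supplied, is evaluated only at fragment N-termini: the antigen's own
#' N-terminus and each fragment start created by a confident
#' endopeptidase cut. Confident H cuts trim single residues; trimming is
#' iterated up to \code{maxTrims} times per fragment start and does not
#' create new endopeptidase evaluations.
#'
#' @param antigen antigen sequence (length >= 2).
#' @param matrices named list of \linkS4class{SpecificityMatrix} objects;
#'   \code{cathepsin_S} and \code{cathepsin_B} are required,
#'   \code{cathepsin_H} optional.
#' @param threshold confidence threshold on the cleavage score (default
#'   3.0, the method's operating point).
#' @param antigenId identifier carried into the output.
#' @param maxTrims maximum number of successive single-residue
#'   aminopeptidase trims evaluated per fragment N-terminus (default 1,
#'   at most 4).
#' @return data.frame with columns \code{antigen_id},
#'   \code{scissile_index}, \code{enzyme}, \code{cleavage_score},
#'   \code{confident}, ordered by ascending \code{scissile_index} then
#'   enzyme name.
#' @export
predictCleavageSites <- function(antigen, matrices, threshold = 3.0,
                                 antigenId = "antigen", maxTrims = 1L) {
  if (nchar(antigen) < 2) stop("antigen too short: no scissile bond")
  endo <- c("cathepsin_S", "cathepsin_B")
  if (!all(endo %in% names(matrices)))
    stop("incomplete matrix set: cathepsin_S and cathepsin_B are required")
  maxTrims <- min(as.integer(maxTrims), 4L)
  L <- nchar(antigen)
  bonds <- 0:(L - 2)

  out <- list()
  for (e in endo) {
    sc <- vapply(bonds, function(i) scoreSite(matrices[[e]], antigen, i),
                 numeric(1))
    out[[e]] <- data.frame(antigen_id = antigenId, scissile_index = bonds,
                           enzyme = e, cleavage_score = sc,
                           confident = sc > threshold,
                           stringsAsFactors = FALSE)
  }
  endoTab <- do.call(rbind, out)

  hTab <- NULL
  if ("cathepsin_H" %in% names(matrices)) {
    cuts <- sort(unique(endoTab$scissile_index[endoTab$confident]))
    starts <- unique(c(0L, cuts + 1L))      # fragment N-terminal residues
    rows <- list()
    for (s in starts) {
      bond <- s
      for (t in seq_len(maxTrims)) {
        if (bond > L - 2) break
        sc <- scoreSite(matrices$cathepsin_H, antigen, bond)
        rows[[length(rows) + 1]] <- data.frame(
          antigen_id = antigenId, scissile_index = bond,
          enzyme = "cathepsin_H", cleavage_score = sc,
          confident = sc > threshold, stringsAsFactors = FALSE)
        if (sc <= threshold) break
        bond <- bond + 1L
      }
    }
    if (length(rows)) {
      hTab <- do.call(rbind, rows)
      hTab <- hTab[!duplicated(hTab$scissile_index), , drop = FALSE]
    }
  }

  res <- rbind(endoTab, hTab)
  res <- res[order(res$scissile_index, res$enzyme), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter epitope candidates by confident cleavage sites
#'
#' A candidate is removed if and only if at least one confident scissile
#' bond lies strictly inside its span, i.e. the bond between residues i
#' and i+1 has both residues within the candidate. Bonds at a candidate
#' boundary (cutting just before its first or just after its last
#' residue) do not remove it. Survivor order is preserved.
#'
#' @param candidates data.frame from \code{\link{enumerateCandidates}}.
#' @param predictions data.frame from \code{\link{predictCleavageSites}}
#'   (for the same antigen).
#' @return the surviving subset of \code{candidates}.
#' @export
filterCandidates <- function(candidates, predictions) {
  if (is.null(candidates) || nrow(candidates) == 0) return(candidates)
  if (is.null(predictions) || nrow(predictions) == 0) return(candidates)
  conf <- predictions$scissile_index[predictions$confident]
  if (length(conf) == 0) return(candidates)
  len <- nchar(candidates$sequence)
  removed <- mapply(function(s, l) any(conf >= s & conf <= s + l - 2),
                    candidates$start, len)
  out <- candidates[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}
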