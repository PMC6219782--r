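# Orchestration of the three stages into the final epitope ranking:
# best-of-grid ternary scoring, Z-score integration, external-score
# merging, multi-TCR consensus, and benchmark-style evaluation.

#' Best ternary score over a TCR-model x template grid
#'
#' Assembles and scores every (TCR model, ternary template) combination
#' (the production grid is 10 models x 500 templates = 5000 ternary
#' models per candidate) and returns the minimum TCR-pMHC interface
#' score. Ties are broken deterministically by template order, then
#' model order. Combinations whose assembly fails are skipped with a
#' warning.
#'
#' @param pmhcModel a threaded pMHCII \linkS4class{ComplexStructure}.
#' @param tcrModels list of TCR \linkS4class{ComplexStructure} objects.
#' @param ternaryTemplates list of ternary \linkS4class{TemplateEntry}
#'   (or \linkS4class{ComplexStructure}) objects.
#' @param potential a \linkS4class{PotentialTable} for the TCR-pMHC
#'   interface.
#' @param interface the TCR-pMHC \linkS4class{InterfaceDefinition}.
#' @return list with \code{score}, \code{templateIndex},
#'   \code{modelIndex}.
#' @export
bestTernaryScore <- function(pmhcModel, tcrModels, ternaryTemplates,
                             potential, interface = tcrInterface()) {
  if (length(tcrModels) == 0 || length(ternaryTemplates) == 0)
    stop("no scorable ternary model: empty model or template list")
  best <- NULL
  for (ti in seq_along(ternaryTemplates)) {
    for (mi in seq_along(tcrModels)) {
      sc <- tryCatch({
        cx <- assembleTernary(pmhcModel, tcrModels[[mi]],
                              ternaryTemplates[[ti]])
        scoreInterface(cx, interface, potential)
      }, error = function(e) {
        warning("assembly failed (template ", ti, ", model ", mi, "): ",
                conditionMessage(e))
        NA_real_
      })
      if (!is.na(sc) && (is.null(best) || sc < best$score))
        best <- list(score = sc, templateIndex = ti, modelIndex = mi)
    }
  }
  if (is.null(best)) stop("no scorable ternary model")
  best
}

#' Z-score normalization
#'
#' Centers and scales with the sample (n-1) standard deviation so the
#' output has mean 0 and sample sd 1; order preserved. A constant input
#' yields all zeros with a warning.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector of Z-scores.
#' @examples
#' zscoreNormalize(c(1, 2, 3))  # -1 0 1
#' @export
zscoreNormalize <- function(x) {
  if (length(x) < 2) stop("insufficient scores")
  s <- stats::sd(x)
  if (s == 0) {
    warning("constant scores: all Z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Rank epitope candidates by the integrated final score
#'
#' The final score of each candidate is \code{pmhc_score +
#' tcr_pmhc_score} (both "lower = better"). Candidates spanning a
#' confident cleavage site are flagged \code{cleaved} and carry no rank
#' (the cleavage filter is optional: pass \code{NULL} to rank all
#' candidates). Survivors are ranked 1..K by ascending final score, ties
#' broken by ascending start offset. Z-scores are computed over ALL
#' candidates (the pre-filter population).
#'
#' @param candidates data.frame from \code{\link{enumerateCandidates}}.
#' @param cleavagePredictions data.frame from
#'   \code{\link{predictCleavageSites}}, or \code{NULL} to skip the
#'   filter.
#' @param pmhcScores,tcrScores numeric vectors aligned with
#'   \code{candidates}.
#' @return data.frame with columns \code{antigen_id}, \code{start},
#'   \code{sequence}, \code{pmhc_score}, \code{tcr_pmhc_score},
#'   \code{final_score}, \code{z_score}, \code{cleaved}, \code{rank}
#'   (NA for cleaved candidates); survivors first in rank order, then
#'   cleaved candidates by start.
#' @export
rankEpitopes <- function(candidates, cleavagePredictions = NULL,
                         pmhcScores, tcrScores) {
  K <- nrow(candidates)
  if (length(pmhcScores) != K || length(tcrScores) != K)
    stop("misaligned inputs")
  out <- data.frame(antigen_id = candidates$antigen_id,
                    start = candidates$start,
                    sequence = candidates$sequence,
                    pmhc_score = pmhcScores,
                    tcr_pmhc_score = tcrScores,
                    stringsAsFactors = FALSE)
  out$final_score <- out$pmhc_score + out$tcr_pmhc_score
  out$z_score <- if (K >= 2) zscoreNormalize(out$final_score) else 0
  out$cleaved <- FALSE
  if (!is.null(cleavagePredictions)) {
    kept <- filterCandidates(candidates, cleavagePredictions)
    out$cleaved <- !(candidates$start %in% kept$start)
  }
  out$rank <- NA_integer_
  surv <- which(!out$cleaved)
  if (length(surv) == 0) {
    warning("all candidates removed by the cleavage filter")
  } else {
    ord <- surv[order(out$final_score[surv], out$start[surv])]
    out$rank[ord] <- seq_along(ord)
  }
  ordAll <- order(is.na(out$rank), out$rank, out$start)
  out <- out[ordAll, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge external per-peptide affinity predictions into a ranking
#'
#' External predictions (e.g. a NetMHCIIpan-style affinity table) are
#' oriented so that lower = better, Z-score normalized over the ranked
#' candidates, and added to the Z-score of the final score; survivors are
#' re-ranked by the combined score.
#'
#' @param ranking data.frame from \code{\link{rankEpitopes}}.
#' @param external named numeric vector (names = peptide sequences) or
#'   data.frame with columns \code{sequence} and \code{score}.
#' @param type \code{"affinity_nM"} (log-transformed; lower nM = better),
#'   \code{"lower"} (used as-is) or \code{"higher"} (negated).
#' @param missing policy for ranked candidates absent from the table:
#'   \code{"error"} (default) or \code{"drop"}.
#' @return the re-ranked data.frame with extra columns
#'   \code{external_z} and \code{combined_score}.
#' @export
mergeExternalScores <- function(ranking, external,
                                type = c("affinity_nM", "lower", "higher"),
                                missing = c("error", "drop")) {
  type <- match.arg(type)
  missing <- match.arg(missing)
  if (is.data.frame(external))
    external <- stats::setNames(external$score, external$sequence)
  ext <- external[ranking$sequence]
  if (anyNA(ext)) {
    if (missing == "error") stop("missing external scores")
    keep <- !is.na(ext)
    ranking <- ranking[keep, , drop = FALSE]
    ext <- ext[keep]
  }
  ext <- switch(type,
    affinity_nM = log(as.numeric(ext)),
    lower = as.numeric(ext),
    higher = -as.numeric(ext))
  extZ <- if (stats::sd(ext) == 0) rep(0, length(ext)) else
    zscoreNormalize(ext)
  ranking$external_z <- extZ
  ranking$combined_score <- zscoreNormalize(ranking$final_score) + extZ
  surv <- which(!ranking$cleaved)
  ranking$rank <- NA_integer_
  ord <- surv[order(ranking$combined_score[surv], ranking$start[surv])]
  ranking$rank[ord] <- seq_along(ord)
  ranking <- ranking[order(is.na(ranking$rank), ranking$rank,
                           ranking$start), , drop = FALSE]
  rownames(ranking) <- NULL
  ranking
}

#' Consensus candidates across TCR rankings
#'
#' Returns the candidates ranked within the top k (default 100) for
#' every TCR, plus the near-consensus set (top k for all but one TCR) --
#' the repertoire-level filter that narrows thousands of overlapping
#' candidates to a handful of consensus epitopes.
#'
#' @param perTcrRankings named list (>= 2) of rankings from
#'   \code{\link{rankEpitopes}} over the same candidate set.
#' @param k top-rank cutoff.
#' @return object of class \code{ConsensusResult}: a list with
#'   \code{k}, \code{consensus} and \code{nearConsensus} (data.frames of
#'   candidate start/sequence with per-TCR ranks) and
#'   \code{perTcrTopK}.
#' @export
consensusAcrossTCRs <- function(perTcrRankings, k = 100) {
  if (length(perTcrRankings) < 2)
    stop("need at least two TCR rankings")
  keys <- lapply(perTcrRankings, function(r)
    sort(paste(r$antigen_id, r$start)))
  if (!all(vapply(keys[-1], identical, logical(1), keys[[1]])))
    stop("incompatible rankings: candidate sets differ")
  topk <- lapply(perTcrRankings, function(r)
    r$start[!is.na(r$rank) & r$rank <= k])
  nTcr <- length(topk)
  allStarts <- sort(unique(unlist(topk)))
  hits <- vapply(allStarts, function(s)
    sum(vapply(topk, function(t) s %in% t, logical(1))), integer(1))
  mkTable <- function(starts) {
    if (length(starts) == 0)
      return(data.frame(start = integer(0), sequence = character(0)))
    r1 <- perTcrRankings[[1]]
    df <- data.frame(start = starts,
                     sequence = r1$sequence[match(starts, r1$start)],
                     stringsAsFactors = FALSE)
    for (nm in names(perTcrRankings)) {
      r <- perTcrRankings[[nm]]
      df[[paste0("rank_", nm)]] <- r$rank[match(starts, r$start)]
    }
    df[order(df$start), , drop = FALSE]
  }
  out <- list(k = k,
              consensus = mkTable(allStarts[hits == nTcr]),
              nearConsensus = mkTable(allStarts[hits == nTcr - 1]),
              perTcrTopK = topk)
  class(out) <- "ConsensusResult"
  out
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult (k = %d, %d TCRs): %d consensus, %d near-consensus candidates\n",
              x$k, length(x$perTcrTopK), nrow(x$consensus),
              nrow(x$nearConsensus)))
  invisible(x)
}

#' Evaluate a ranking against a known epitope
#'
#' A candidate hits the true epitope if its span overlaps the epitope
#' span by at least \code{minOverlap} residues (5 for peptide-level
#' benchmarks; 12 for exact-register benchmarks). Returns the best
#' (smallest) rank among hitting candidates, or \code{NA} if none.
#'
#' @param ranking data.frame from \code{\link{rankEpitopes}}.
#' @param epitopeStart 0-based start of the true epitope span.
#' @param epitopeLength length of the true epitope span.
#' @param minOverlap minimum residue overlap, in [1, 12].
#' @return best hitting rank (integer) or \code{NA}.
#' @export
evaluatePrediction <- function(ranking, epitopeStart, epitopeLength = 12L,
                               minOverlap = 5L) {
  if (minOverlap < 1 || minOverlap > 12)
    stop("minOverlap must be in [1, 12]")
  candLen <- nchar(ranking$sequence)
  L <- max(ranking$start + candLen)
  if (epitopeStart < 0 || epitopeStart + epitopeLength > L)
    stop("invalid epitope span")
  e1 <- epitopeStart
  e2 <- epitopeStart + epitopeLength
  ov <- pmax(0, pmin(ranking$start + candLen, e2) -
                pmax(ranking$start, e1))
  hit <- !is.na(ranking$rank) & ov >= minOverlap
  if (!any(hit)) return(NA_integer_)
  min(ranking$rank[hit])
}

#' Run the full three-stage prediction for one TCR
#'
#' Enumerates 12-mer candidates, optionally applies the cathepsin
#' cleavage filter, threads every candidate onto the pMHCII template and
#' scores the peptide-MHC interface, finds the best ternary score over
#' the TCR-model x ternary-template grid, and returns the integrated
#' ranking.
#'
#' @param antigen antigen sequence.
#' @param pmhcTemplate \linkS4class{TemplateEntry} of kind \code{pmhc}.
#' @param tcrModels list of TCR \linkS4class{ComplexStructure} objects
#'   (the models for one TCR sequence).
#' @param ternaryTemplates list of ternary templates.
#' @param pmhcPotential,tcrPotential \linkS4class{PotentialTable}s for
#'   the two interfaces (default: the same table).
#' @param cleavageMatrices named list of specificity matrices, or
#'   \code{NULL} to skip the cleavage filter.
#' @param threshold cleavage confidence threshold.
#' @param pmhcTopN optional pre-filter: only the \code{pmhcTopN} best
#'   candidates by \code{pmhc_score} proceed to the ternary stage (the
#'   rest are dropped from the ranking); default \code{NULL} scores all
#'   survivors.
#' @param antigenId identifier carried through the outputs.
#' @param pmhcIface,tcrIface interface definitions.
#' @param threadMode side-chain placement mode for threading.
#' @return list with \code{ranking} (see \code{\link{rankEpitopes}}),
#'   \code{candidates}, \code{cleavage} (predictions or NULL), and
#'   \code{counts} (candidate counts per stage).
#' @export
runPipeline <- function(antigen, pmhcTemplate, tcrModels, ternaryTemplates,
                        pmhcPotential, tcrPotential = pmhcPotential,
                        cleavageMatrices = NULL, threshold = 3.0,
                        pmhcTopN = NULL, antigenId = "antigen",
                        pmhcIface = pmhcInterface(),
                        tcrIface = tcrInterface(),
                        threadMode = "reduced") {
  antigen <- normalizeSequence(antigen)
  cands <- enumerateCandidates(antigen, antigenId = antigenId)
  cleav <- NULL
  if (!is.null(cleavageMatrices))
    cleav <- predictCleavageSites(antigen, cleavageMatrices, threshold,
                                  antigenId)

  models <- vector("list", nrow(cands))
  pmhcScores <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    models[[i]] <- threadPeptide(pmhcTemplate, cands$sequence[i],
                                 mode = threadMode)
    pmhcScores[i] <- scoreInterface(models[[i]], pmhcIface, pmhcPotential)
  }

  keep <- seq_len(nrow(cands))
  if (!is.null(pmhcTopN) && pmhcTopN < length(keep))
    keep <- order(pmhcScores, cands$start)[seq_len(pmhcTopN)]

  tcrScores <- rep(NA_real_, nrow(cands))
  for (i in keep) {
    tcrScores[i] <- bestTernaryScore(models[[i]], tcrModels,
                                     ternaryTemplates, tcrPotential,
                                     tcrIface)$score
  }

  sel <- sort(keep)
  ranking <- rankEpitopes(cands[sel, , drop = FALSE], cleav,
                          pmhcScores[sel], tcrScores[sel])
  list(ranking = ranking, candidates = cands, cleavage = cleav,
       counts = c(candidates = nrow(cands),
                  ternary_stage = length(sel),
                  ranked = sum(!is.na(ranking$rank))))
}
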