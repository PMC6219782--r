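# Plain-text serialization: cleavage events, specificity matrices
# (TSV + JSON sidecar), cleavage predictions, potential tables
# (long TSV + JSON sidecar), rankings, and external affinity tables.

.sidecarPath <- function(file) paste0(file, ".json")

#' Read a cleavage-event table
#'
#' Expects columns \code{substrate_sequence}, \code{scissile_index}
#' (0-based index of the P1 residue) and \code{enzyme}, in CSV or TSV
#' depending on the file extension. Substrates are normalized
#' (upper-cased; norleucine \code{n} mapped to Met).
#'
#' @param file path.
#' @return data.frame of cleavage events.
#' @export
readCleavageEvents <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  ev <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("substrate_sequence", "scissile_index", "enzyme")
  if (!all(need %in% names(ev)))
    stop("cleavage-event table must have columns: ",
         paste(need, collapse = ", "))
  ev$substrate_sequence <- normalizeSequence(ev$substrate_sequence)
  ev
}

#' Write / read a specificity matrix
#'
#' The TSV holds the log-odds (one row per residue, one column per
#' window position); a JSON sidecar (\code{<file>.json}) carries the
#' enzyme, window, background, pseudocount, counts and probabilities so
#' the object round-trips losslessly.
#'
#' @param matrix a \linkS4class{SpecificityMatrix}.
#' @param file TSV path.
#' @return \code{writeSpecificityMatrix}: invisibly, \code{file};
#'   \code{readSpecificityMatrix}: the reconstructed matrix.
#' @export
writeSpecificityMatrix <- function(matrix, file) {
  utils::write.table(format(matrix@logOdds, digits = 12), file,
                     sep = "\t", quote = FALSE, col.names = NA)
  side <- list(enzyme = matrix@enzyme,
               upstream = matrix@window@upstream,
               downstream = matrix@window@downstream,
               background = as.list(matrix@background),
               pseudocount = matrix@pseudocount,
               counts = matrix@counts,
               probabilities = matrix@probabilities)
  jsonlite::write_json(side, .sidecarPath(file), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeSpecificityMatrix
#' @export
readSpecificityMatrix <- function(file) {
  side <- jsonlite::read_json(.sidecarPath(file), simplifyVector = TRUE)
  w <- WindowDefinition(side$upstream, side$downstream)
  labs <- positionLabels(w)
  bg <- unlist(side$background)
  counts <- matrix(as.numeric(side$counts), nrow = length(bg),
                   dimnames = list(names(bg), labs))
  probs <- matrix(as.numeric(side$probabilities), nrow = length(bg),
                  dimnames = list(names(bg), labs))
  new("SpecificityMatrix", enzyme = side$enzyme, window = w,
      counts = counts, probabilities = probs, background = bg,
      logOdds = log(probs / bg), pseudocount = side$pseudocount)
}

#' Write cleavage predictions as a BED-like TSV
#'
#' @param predictions data.frame from
#'   \code{\link{predictCleavageSites}}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writePredictions <- function(predictions, file) {
  utils::write.table(predictions, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write / read a potential table
#'
#' Long-format TSV (type1, type2, bin_lo, bin_hi, score; only the upper
#' type triangle is stored) plus a JSON sidecar with the typing scheme,
#' binning and provenance.
#'
#' @param potential a \linkS4class{PotentialTable}.
#' @param file TSV path.
#' @return \code{writePotentialTable}: invisibly, \code{file};
#'   \code{readPotentialTable}: the reconstructed table.
#' @export
writePotentialTable <- function(potential, file) {
  n <- nTypes(potential@typing)
  b <- nBins(potential@binning)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(b), function(bin) {
    lo <- potential@binning@rMin + (bin - 1) * potential@binning@binWidth
    data.frame(type1 = potential@typing@labels[idx[, 1]],
               type2 = potential@typing@labels[idx[, 2]],
               bin_lo = lo, bin_hi = lo + potential@binning@binWidth,
               score = potential@scores[cbind(idx[, 1], idx[, 2], bin)],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(typing = potential@typing@name,
               rMin = potential@binning@rMin,
               rMax = potential@binning@rMax,
               binWidth = potential@binning@binWidth,
               provenance = potential@provenance)
  jsonlite::write_json(side, .sidecarPath(file), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writePotentialTable
#' @export
readPotentialTable <- function(file) {
  side <- jsonlite::read_json(.sidecarPath(file), simplifyVector = TRUE)
  typ <- AtomTypingScheme(side$typing)
  bins <- BinningScheme(side$rMin, side$rMax, side$binWidth)
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  n <- nTypes(typ)
  b <- nBins(bins)
  sc <- array(0, dim = c(n, n, b))
  t1 <- match(tab$type1, typ@labels)
  t2 <- match(tab$type2, typ@labels)
  bin <- binIndex(bins, tab$bin_lo)
  sc[cbind(t1, t2, bin)] <- tab$score
  sc[cbind(t2, t1, bin)] <- tab$score
  prov <- as.list(side$provenance)
  new("PotentialTable", typing = typ, binning = bins, scores = sc,
      provenance = prov)
}

#' Write a ranking as TSV
#'
#' @param ranking data.frame from \code{\link{rankEpitopes}} (or
#'   \code{\link{mergeExternalScores}}).
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeRanking <- function(ranking, file) {
  utils::write.table(ranking, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read an external per-peptide affinity table
#'
#' Accepts a TSV with a peptide column (\code{sequence} or
#' \code{peptide}) and a score column (\code{score}, \code{affinity} or
#' \code{affinity_nM}), the shape of a NetMHCIIpan-style per-peptide
#' output.
#'
#' @param file path.
#' @return data.frame with columns \code{sequence} and \code{score}.
#' @export
readExternalScores <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  seqCol <- intersect(c("sequence", "peptide"), names(tab))[1]
  scoreCol <- intersect(c("score", "affinity", "affinity_nM"),
                        names(tab))[1]
  if (is.na(seqCol) || is.na(scoreCol))
    stop("external table needs a peptide column and a score column")
  data.frame(sequence = tab[[seqCol]], score = tab[[scoreCol]],
             stringsAsFactors = FALSE)
}

#' Read the first sequence of a FASTA file
#'
#' @param file FASTA path.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(file) {
  fa <- bio3d::read.fasta(file)
  stats::setNames(apply(fa$ali, 1, function(r)
    paste(r[r != "-"], collapse = "")), rownames(fa$ali))
}
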