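# Accessor generics and show methods.

#' Accessors for Tripitope S4 objects
#'
#' Accessor functions are preferred over direct slot access.
#'
#' @param object a Tripitope S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("logOdds", function(object) standardGeneric("logOdds"))

#' @rdname accessors
#' @export
setMethod("logOdds", "SpecificityMatrix", function(object) object@logOdds)

#' @rdname accessors
#' @export
setGeneric("residueCounts", function(object) standardGeneric("residueCounts"))

#' @rdname accessors
#' @export
setMethod("residueCounts", "SpecificityMatrix",
          function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))

#' @rdname accessors
#' @export
setMethod("probabilities", "SpecificityMatrix",
          function(object) object@probabilities)

#' @rdname accessors
#' @export
setGeneric("background", function(object) standardGeneric("background"))

#' @rdname accessors
#' @export
setMethod("background", "SpecificityMatrix",
          function(object) object@background)

#' @rdname accessors
#' @export
setGeneric("enzyme", function(object) standardGeneric("enzyme"))

#' @rdname accessors
#' @export
setMethod("enzyme", "SpecificityMatrix", function(object) object@enzyme)

#' @rdname accessors
#' @export
setGeneric("windowDef", function(object) standardGeneric("windowDef"))

#' @rdname accessors
#' @export
setMethod("windowDef", "SpecificityMatrix", function(object) object@window)

#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setMethod("atoms", "ComplexStructure", function(object) object@atoms)

#' @rdname accessors
#' @export
setMethod("atoms", "TemplateEntry", function(object) object@structure@atoms)

#' @rdname accessors
#' @export
setGeneric("roleMap", function(object) standardGeneric("roleMap"))

#' @rdname accessors
#' @export
setMethod("roleMap", "ComplexStructure", function(object) object@roleMap)

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setMethod("scores", "PotentialTable", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("provenance", "PotentialTable", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("typing", function(object) standardGeneric("typing"))

#' @rdname accessors
#' @export
setMethod("typing", "PotentialTable", function(object) object@typing)

#' @rdname accessors
#' @export
setGeneric("binning", function(object) standardGeneric("binning"))

#' @rdname accessors
#' @export
setMethod("binning", "PotentialTable", function(object) object@binning)

#' @rdname accessors
#' @export
setGeneric("templateStructure",
           function(object) standardGeneric("templateStructure"))

#' @rdname accessors
#' @export
setMethod("templateStructure", "TemplateEntry",
          function(object) object@structure)

#' @rdname accessors
#' @export
setMethod("templateStructure", "ComplexStructure", function(object) object)

# ------------------------------------------------------------------- show --

setMethod("show", "WindowDefinition", function(object) {
  cat(sprintf("WindowDefinition: P%d-P%d' (%d positions)\n",
              object@upstream, object@downstream,
              object@upstream + object@downstream))
})

setMethod("show", "SpecificityMatrix", function(object) {
  cat(sprintf("SpecificityMatrix for %s\n", object@enzyme))
  cat(sprintf("  window: P%d-P%d' | alphabet: %d residues | pseudocount: %g\n",
              object@window@upstream, object@window@downstream,
              length(object@background), object@pseudocount))
  cat(sprintf("  events tallied per position: %s\n",
              paste(colSums(object@counts), collapse = " ")))
})

setMethod("show", "ComplexStructure", function(object) {
  cat(sprintf("ComplexStructure: %d atoms, %d chains\n",
              nrow(object@atoms), length(object@roleMap)))
  for (ch in names(object@roleMap)) {
    sel <- object@atoms$chain == ch
    cat(sprintf("  chain %s [%s]: %d residues, %d atoms\n", ch,
                object@roleMap[[ch]],
                length(unique(object@atoms$resno[sel])), sum(sel)))
  }
})

setMethod("show", "PotentialTable", function(object) {
  cat(sprintf("PotentialTable: %s typing (%d types), %d bins of %g A over [%g, %g)\n",
              object@typing@name, nTypes(object@typing),
              nBins(object@binning), object@binning@binWidth,
              object@binning@rMin, object@binning@rMax))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})

setMethod("show", "TemplateEntry", function(object) {
  cat(sprintf("TemplateEntry %s (%s): %d atoms\n", object@sourceId,
              object@kind, nrow(object@structure@atoms)))
})
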