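#' @rdname HIGraph-class
#' @param x An object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname HIGraph-class
#' @export
setGeneric("hiEdges", function(x) standardGeneric("hiEdges"))

#' @rdname LineageChart-class
#' @param x An object.
#' @export
setGeneric("chartPoints", function(x) standardGeneric("chartPoints"))

#' @rdname LineageChart-class
#' @export
setGeneric("chartMembers", function(x) standardGeneric("chartMembers"))

#' @rdname LineageChart-class
#' @export
setGeneric("focalGene", function(x) standardGeneric("focalGene"))

#' @rdname SpeciesNetwork-class
#' @param x An object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname SpeciesNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname SpeciesNetwork-class
#' @export
setGeneric("highlightedSpecies",
           function(x) standardGeneric("highlightedSpecies"))

#' @rdname ProteinSet-class
#' @param x An object.
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))

#' @rdname ProteinSet-class
#' @export
setGeneric("speciesMap", function(x) standardGeneric("speciesMap"))
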