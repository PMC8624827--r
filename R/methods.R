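# Accessors and show methods for the S4 containers.

#' @rdname HIGraph-class
#' @export
setMethod("geneIds", "HIGraph", function(x) x@genes)

#' @rdname HIGraph-class
#' @export
setMethod("hiEdges", "HIGraph", function(x) x@edges)

#' @rdname ProteinSet-class
#' @export
setMethod("geneIds", "ProteinSet", function(x) names(x@seqs))

#' @rdname ProteinSet-class
#' @export
setMethod("proteinSeqs", "ProteinSet", function(x) x@seqs)

#' @rdname ProteinSet-class
#' @export
setMethod("speciesMap", "ProteinSet", function(x)
  data.frame(gene_id = names(x@seqs),
             species_id = unname(x@species[names(x@seqs)]),
             family_id = unname(x@family[names(x@seqs)]),
             stringsAsFactors = FALSE))

#' @rdname LineageChart-class
#' @export
setMethod("chartPoints", "LineageChart", function(x) x@counts)

#' @rdname LineageChart-class
#' @export
setMethod("chartMembers", "LineageChart", function(x) x@members)

#' @rdname LineageChart-class
#' @export
setMethod("focalGene", "LineageChart", function(x) x@focalGene)

#' @rdname SpeciesNetwork-class
#' @export
setMethod("networkNodes", "SpeciesNetwork", function(x) x@nodes)

#' @rdname SpeciesNetwork-class
#' @export
setMethod("networkEdges", "SpeciesNetwork", function(x) x@edges)

#' @rdname SpeciesNetwork-class
#' @export
setMethod("highlightedSpecies", "SpeciesNetwork", function(x) x@highlight)

setMethod("show", "ProteinSet", function(object) {
  cat("ProteinSet with", length(object@seqs), "proteins from",
      length(unique(object@species)), "species /",
      length(unique(object@family)), "families\n")
})

setMethod("show", "HIGraph", function(object) {
  cat("HIGraph with", length(object@genes), "genes and",
      nrow(object@edges), "edges")
  if (nrow(object@edges))
    cat(sprintf(" (HI range %.3f-%.3f)", min(object@edges$hi),
                max(object@edges$hi)))
  cat("\n")
})

setMethod("show", "LineageChart", function(object) {
  cat("LineageChart for gene", object@focalGene, "with",
      length(object@thresholds), "change points\n")
  if (length(object@thresholds)) {
    cn <- object@counts
    cat(sprintf("  thresholds %.4g .. %.4g; genes %d -> %d; species %d -> %d\n",
                min(cn$threshold), max(cn$threshold),
                cn$n_genes[1], cn$n_genes[nrow(cn)],
                cn$n_species[1], cn$n_species[nrow(cn)]))
  }
})

setMethod("show", "SpeciesNetwork", function(object) {
  cat("SpeciesNetwork with", nrow(object@nodes), "species and",
      nrow(object@edges), "CI edges;",
      length(object@highlight), "highlighted",
      if (!is.na(object@hiThreshold))
        sprintf("(HI threshold %.3g)", object@hiThreshold) else "", "\n")
})

setMethod("show", "RFResult", function(object) {
  cat(sprintf("RF = %d of max %d; percentile = %.1f (n_random = %d, seed = %d)\n",
              as.integer(object@rf), as.integer(object@maxRF),
              object@percentile, as.integer(object@nRandom),
              as.integer(object@seed)))
})
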