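#' ProteinSet: amino-acid sequences with species/family assignments
#'
#' Container pairing an [Biostrings::AAStringSet] of protein sequences with
#' the species and (optional) taxonomic family of each gene. Gene IDs are
#' the sequence names and must be unique.
#'
#' @slot seqs An `AAStringSet`; names are gene IDs.
#' @slot species Named character vector, gene ID -> species ID.
#' @slot family Named character vector, gene ID -> family ID. Genes without
#'   a family assignment carry their species ID, so family counts never
#'   exceed species counts.
#'
#' @seealso [readProteinSet()], [alignAllPairs()]
#' @export
setClass("ProteinSet",
  representation(seqs = "ANY", species = "character", family = "character"),
  validity = function(object) {
    ids <- names(object@seqs)
    if (is.null(ids) || anyDuplicated(ids))
      return("gene IDs (sequence names) must be present and unique")
    if (!setequal(ids, names(object@species)))
      return("species map must cover exactly the gene IDs")
    if (!setequal(ids, names(object@family)))
      return("family map must cover exactly the gene IDs")
    w <- Biostrings::width(object@seqs)
    if (any(w == 0)) return("sequences must be non-empty")
    bad <- setdiff(unique(strsplit(paste(as.character(object@seqs),
                                         collapse = ""), "")[[1]]),
                   .AA_ALPHABET)
    if (length(bad))
      return(paste0("non-IUPAC amino-acid codes in sequences: ",
                    paste(bad, collapse = ",")))
    TRUE
  })

#' HIGraph: symmetric homology-index graph over genes
#'
#' Undirected weighted graph whose vertices are gene IDs and whose edges
#' carry a homology index (HI) in (0, 1]. Edges are stored once with
#' `from < to` (lexicographic), so symmetry holds by construction; self
#' edges are never stored. Genes with no edges are retained as isolated
#' vertices.
#'
#' @slot genes Character vector of gene IDs (unique).
#' @slot edges `data.frame` with columns `from`, `to`, `hi`.
#' @slot hitCounts Named integer vector: number of raw hits per query seen
#'   when the graph was built from external tabular input; lets users
#'   detect truncated searches (e.g. a capped max-target-seqs). May be
#'   empty.
#'
#' @seealso [buildHIGraph()], [hiEdges()], [geneIds()]
#' @export
setClass("HIGraph",
  representation(genes = "character", edges = "data.frame",
                 hitCounts = "integer"),
  validity = function(object) {
    e <- object@edges
    if (!all(c("from", "to", "hi") %in% names(e)))
      return("edges must have columns from, to, hi")
    if (anyDuplicated(object@genes)) return("gene IDs must be unique")
    if (nrow(e)) {
      if (any(e$from == e$to)) return("self edges are not allowed")
      if (any(e$from > e$to)) return("edges must be stored with from < to")
      if (anyDuplicated(paste(e$from, e$to)))
        return("duplicate edges are not allowed")
      if (any(e$hi <= 0 | e$hi > 1)) return("edge hi must lie in (0, 1]")
      if (!all(c(e$from, e$to) %in% object@genes))
        return("edge endpoints must be listed in genes")
    }
    TRUE
  })

#' LineageChart: a focal gene's homologous groups across HI thresholds
#'
#' Ordered change points of the homologous group containing a focal gene as
#' the HI threshold increases. At each retained threshold the chart stores
#' the group membership and its gene / species / family counts (the three
#' line charts of the lineage display). Counts are non-increasing in the
#' threshold (single-linkage nestedness).
#'
#' @slot focalGene The focal gene ID.
#' @slot thresholds Strictly increasing HI thresholds of the change points.
#' @slot members List of character vectors, one per threshold; each
#'   contains `focalGene`.
#' @slot counts `data.frame` with columns `threshold`, `n_genes`,
#'   `n_species`, `n_families`.
#'
#' @seealso [sweepThresholds()], [classifyEvents()], [chartPoints()]
#' @export
setClass("LineageChart",
  representation(focalGene = "character", thresholds = "numeric",
                 members = "list", counts = "data.frame"),
  validity = function(object) {
    k <- length(object@thresholds)
    if (length(object@members) != k || nrow(object@counts) != k)
      return("thresholds, members and counts must have equal length")
    if (k && is.unsorted(object@thresholds, strictly = TRUE))
      return("thresholds must be strictly increasing")
    if (!all(vapply(object@members,
                    function(m) object@focalGene %in% m, logical(1))))
      return("focal gene must belong to every point's group")
    cn <- object@counts
    for (col in c("n_genes", "n_species", "n_families"))
      if (k > 1 && any(diff(cn[[col]]) > 0))
        return(paste0(col, " must be non-increasing with threshold"))
    if (any(cn$n_species > cn$n_genes) || any(cn$n_families > cn$n_species))
      return("count ordering violated (families <= species <= genes)")
    TRUE
  })

#' SpeciesNetwork: species nodes with CI-weighted edges
#'
#' Species--species network in which each edge weight is the CI index
#' (F-measure of one-to-one shared gene content) between two genomes, plus
#' an optional highlight set of species carrying a gene similar to a focal
#' gene at or above an HI threshold.
#'
#' @slot nodes `data.frame` with columns `species_id`, `n_genes`.
#' @slot edges `data.frame` with columns `species_a`, `species_b`, `ci`
#'   (`species_a < species_b`, ci in (0, 1]).
#' @slot highlight Character vector of highlighted species IDs.
#' @slot hiThreshold HI threshold used for the highlight (NA if none).
#'
#' @seealso [buildNetwork()], [highlightOrthologs()], [ciIndex()]
#' @export
setClass("SpeciesNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 highlight = "character", hiThreshold = "numeric"),
  validity = function(object) {
    e <- object@edges
    if (nrow(e)) {
      if (any(e$ci <= 0 | e$ci > 1)) return("edge ci must lie in (0, 1]")
      if (any(e$species_a >= e$species_b))
        return("edges must be stored with species_a < species_b")
      if (!all(c(e$species_a, e$species_b) %in% object@nodes$species_id))
        return("edge endpoints must be network nodes")
    }
    if (!all(object@highlight %in% object@nodes$species_id))
      return("highlight must be a subset of the nodes")
    TRUE
  })

#' RFResult: Robinson--Foulds distance with a Monte-Carlo percentile
#'
#' The RF distance between two leaf-labelled trees on the same leaf set,
#' the maximum attainable distance given each tree's resolved bipartitions,
#' and the percentile of the observed distance within a null of uniformly
#' random binary topologies (high percentile = more similar than random).
#'
#' @slot rf Observed RF distance (non-negative integer).
#' @slot maxRF Maximum attainable RF for the pair.
#' @slot percentile Percent of null trees at least as distant as observed.
#' @slot nRandom Number of random topologies sampled.
#' @slot seed Seed used for the null sample.
#'
#' @seealso [rfDistance()], [rfPercentile()], [rfCompare()]
#' @export
setClass("RFResult",
  representation(rf = "numeric", maxRF = "numeric", percentile = "numeric",
                 nRandom = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@rf < 0 || object@rf > object@maxRF)
      return("rf must satisfy 0 <= rf <= maxRF")
    if (object@percentile < 0 || object@percentile > 100)
      return("percentile must lie in [0, 100]")
    TRUE
  })
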