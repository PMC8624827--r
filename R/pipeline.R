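# End-to-end pipeline and ortholog exports.

#' Ortholog table for a focal gene
#'
#' Lists every gene with HI to the focal gene at or above `t` (the focal
#' gene itself included, with HI 1), with its species, sorted by HI
#' descending then gene ID. [exportOrthologFasta()] writes the same genes'
#' sequences in the same order.
#'
#' @param graph An [HIGraph-class].
#' @param focal Focal gene ID.
#' @param t HI threshold in `[0, 1]`.
#' @param map Species map `data.frame`.
#' @return `data.frame` with `gene_id`, `species_id`, `hi`.
#' @export
exportOrthologTable <- function(graph, focal, t, map) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  h <- hiTo(graph, focal)
  h <- h[h >= t | names(h) == focal]
  sp <- map$species_id[match(names(h), map$gene_id)]
  if (anyNA(sp))
    stop("gene(s) missing from the species map: ",
         paste(head(names(h)[is.na(sp)], 5), collapse = ", "))
  out <- data.frame(gene_id = names(h), species_id = sp, hi = unname(h),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hi, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Multi-FASTA export of a focal gene's orthologs
#'
#' @inheritParams exportOrthologTable
#' @param proteins A [ProteinSet-class] holding the sequences.
#' @param path Output FASTA path.
#' @return The ortholog table, invisibly.
#' @export
exportOrthologFasta <- function(graph, focal, t, map, proteins, path) {
  tab <- exportOrthologTable(graph, focal, t, map)
  writeProteinFasta(proteins, path, ids = tab$gene_id)
  invisible(tab)
}

.provenance <- function(cfg) {
  c(paste0("homolineage ", as.character(utils::packageVersion("homolineage"))),
    paste0("seed=", cfg$seed),
    paste0("edge_hi_threshold=", cfg$edgeHiThreshold),
    paste0("highlight_hi_threshold=", cfg$highlightHiThreshold),
    paste0("major_frac=", cfg$majorFrac),
    paste0("n_random=", cfg$nRandom))
}

#' Run the full analysis pipeline for one focal gene
#'
#' Stages: score (all-vs-all alignment, unless a precomputed hit table is
#' given) -> lineage sweep -> event classification -> orthology tree ->
#' taxonomy comparison (RF + percentile) -> species network with ortholog
#' highlighting -> ortholog table/FASTA export. Every output file carries
#' a provenance comment header (package version, seed, thresholds), and a
#' rerun with identical inputs and seed is byte-identical, including the
#' Monte-Carlo percentile.
#'
#' @param proteins A [ProteinSet-class].
#' @param focal Focal gene ID.
#' @param outDir Output directory (created if needed).
#' @param referenceTree Optional `ape::phylo` species/taxonomy tree for
#'   the RF comparison (skipped when `NULL` or too few shared leaves).
#' @param hits Optional precomputed hit `data.frame` (as from
#'   [readBlastTabular()]); when given, the internal aligner is skipped
#'   and the tabular input is authoritative.
#' @param edgeHiThreshold Network match threshold (default 0.3).
#' @param highlightHiThreshold Node highlight threshold (default 0.8).
#' @param orthologTableThreshold HI cut for the ortholog exports
#'   (defaults to `highlightHiThreshold`).
#' @param majorFrac Major-event fraction (default 0.25).
#' @param nRandom Null-sample size for the RF percentile (default 1000).
#' @param seed Integer seed (recorded in every output header).
#' @return Invisibly, a list with the in-memory artifacts (`graph`,
#'   `chart`, `events`, `orthologyTree`, `rf`, `network`, `orthologs`)
#'   and `files`, the paths written.
#' @export
runPipeline <- function(proteins, focal, outDir, referenceTree = NULL,
                        hits = NULL, edgeHiThreshold = 0.3,
                        highlightHiThreshold = 0.8,
                        orthologTableThreshold = highlightHiThreshold,
                        majorFrac = 0.25, nRandom = 1000, seed = 1) {
  cfg <- list(seed = seed, edgeHiThreshold = edgeHiThreshold,
              highlightHiThreshold = highlightHiThreshold,
              majorFrac = majorFrac, nRandom = nRandom)
  hdr <- .provenance(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  map <- speciesMap(proteins)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- list()
  if (is.null(hits))
    hits <- stage("score", alignAllPairs(proteins))
  files$hits <- file.path(outDir, "hits.tsv")
  writePairHits(hits, files$hits, header = hdr)
  graph <- stage("score", buildHIGraph(hits, genes = geneIds(proteins)))
  chart <- stage("lineage", sweepThresholds(graph, focal, map))
  files$chart <- file.path(outDir, "chart.tsv")
  writeLineageChart(chart, files$chart, header = hdr)
  events <- stage("events", classifyEvents(chart, map, majorFrac = majorFrac))
  files$events <- file.path(outDir, "events.tsv")
  writeEventTable(events, files$events, header = hdr)
  otree <- stage("orthotree", orthologyTree(graph, focal, map))
  rf <- NULL
  if (!is.null(otree)) {
    files$tree <- file.path(outDir, "tree.nwk")
    ape::write.tree(otree, files$tree)
    if (!is.null(referenceTree) &&
        length(intersect(otree$tip.label, referenceTree$tip.label)) >= 4) {
      rf <- stage("compare",
                  rfCompare(otree, referenceTree, nRandom = nRandom,
                            seed = seed))
      files$rf <- file.path(outDir, "rf.json")
      writeRFResult(rf, files$rf)
    }
  }
  net <- stage("network",
               buildNetwork(graph, map, edgeHiThreshold = edgeHiThreshold))
  net <- stage("network",
               highlightOrthologs(net, graph, focal, map,
                                  t = highlightHiThreshold))
  files$network <- file.path(outDir, "network.tsv")
  writeNetworkEdges(net, files$network, header = hdr)
  files$graphml <- file.path(outDir, "network.graphml")
  writeNetworkGraphML(net, files$graphml)
  orth <- stage("export",
                exportOrthologTable(graph, focal, orthologTableThreshold, map))
  files$orthologs <- file.path(outDir, "orthologs.tsv")
  con <- file(files$orthologs, "w")
  writeLines(paste0("# ", hdr), con)
  writeLines("gene_id\tspecies_id\thi", con)
  if (nrow(orth))
    writeLines(paste(orth$gene_id, orth$species_id,
                     format(orth$hi, digits = 17, trim = TRUE,
                            scientific = FALSE), sep = "\t"), con)
  close(con)
  files$orthologFasta <- file.path(outDir, "orthologs.faa")
  exportOrthologFasta(graph, focal, orthologTableThreshold, map, proteins,
                      files$orthologFasta)
  invisible(list(graph = graph, chart = chart, events = events,
                 orthologyTree = otree, rf = rf, network = net,
                 orthologs = orth, files = files))
}
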