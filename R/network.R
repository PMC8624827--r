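# Species-species CI network and ortholog highlighting.

#' CI index: F-measure of shared gene content between two genomes
#'
#' `CI = 2 * N_S / (N_C + N_D)` where `N_S` is the number of genes matched
#' between the two genomes and `N_C`, `N_D` are their total gene counts.
#' This is the harmonic mean of the two coverage ratios `N_S / N_C` and
#' `N_S / N_D`, i.e. the F-measure of the one-to-one correspondence.
#'
#' @param nShared Number of matched genes (`0 <= nShared <= min(nC, nD)`).
#' @param nC,nD Genome gene counts (>= 1).
#' @return Numeric in `[0, 1]`.
#' @examples
#' ciIndex(50, 100, 100)  # 0.5
#' @export
ciIndex <- function(nShared, nC, nD) {
  if (any(nC < 1) || any(nD < 1)) stop("genome gene counts must be >= 1")
  if (any(nShared < 0) || any(nShared > pmin(nC, nD)))
    stop("nShared must lie in [0, min(nC, nD)]")
  2 * nShared / (nC + nD)
}

.bestPerSpecies <- function(graph, map) {
  # for every gene, its best hit (max hi, ties by smallest gene id) in each
  # other species; long data.frame gene, other_species, best_gene, hi
  e <- hiEdges(graph)
  if (!nrow(e))
    return(data.frame(gene = character(0), other = character(0),
                      best = character(0), hi = numeric(0)))
  sp <- setNames(map$species_id, map$gene_id)
  long <- rbind(data.frame(gene = e$from, hit = e$to, hi = e$hi),
                data.frame(gene = e$to, hit = e$from, hi = e$hi))
  long$other <- sp[long$hit]
  long <- long[order(long$gene, long$other, -long$hi, long$hit), ]
  key <- paste(long$gene, long$other, sep = "\r")
  first <- !duplicated(key)
  data.frame(gene = long$gene[first], other = long$other[first],
             best = long$hit[first], hi = long$hi[first],
             stringsAsFactors = FALSE)
}

#' Build the species-species CI network
#'
#' For each ordered species pair, every gene's best match (maximum HI) in
#' the other species is determined; a gene pair is counted as shared
#' (`N_S`) when the two genes are each other's best match across the pair
#' and their HI is at least `edgeHiThreshold`. The edge weight is then
#' `ciIndex(N_S, N_C, N_D)` with `N_C`, `N_D` the species' total gene
#' counts. Alternatively (`method = "hit"`) `N_S` is the mean over the two
#' directions of the number of genes with at least one qualifying hit in
#' the other species. Zero-weight edges are omitted.
#'
#' @param graph An [HIGraph-class].
#' @param map Species map `data.frame` covering every graph gene.
#' @param edgeHiThreshold Minimum HI for a match to count (default 0.3).
#' @param method `"reciprocal"` (default; one-to-one reciprocal best
#'   matches) or `"hit"` (direction-averaged hit counts).
#' @return A [SpeciesNetwork-class] object (no highlight set).
#' @export
buildNetwork <- function(graph, map, edgeHiThreshold = 0.3,
                         method = c("reciprocal", "hit")) {
  method <- match.arg(method)
  genes <- geneIds(graph)
  miss <- setdiff(genes, map$gene_id)
  if (length(miss))
    stop("gene(s) missing from the species map: ",
         paste(head(miss, 5), collapse = ", "))
  sp <- setNames(map$species_id, map$gene_id)[genes]
  counts <- table(sp)
  nodes <- data.frame(species_id = names(counts),
                      n_genes = as.integer(counts),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$species_id), ]; rownames(nodes) <- NULL
  speciesIds <- nodes$species_id
  edges <- data.frame(species_a = character(0), species_b = character(0),
                      ci = numeric(0), stringsAsFactors = FALSE)
  if (length(speciesIds) >= 2) {
    best <- .bestPerSpecies(graph, map)
    best <- best[best$hi >= edgeHiThreshold, , drop = FALSE]
    best$from_sp <- unname(sp[best$gene])
    pairs <- utils::combn(speciesIds, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      A <- pairs[1, k]; B <- pairs[2, k]
      ab <- best[best$from_sp == A & best$other == B, , drop = FALSE]
      ba <- best[best$from_sp == B & best$other == A, , drop = FALSE]
      nS <- if (method == "reciprocal") {
        back <- setNames(ba$best, ba$gene)
        sum(!is.na(back[ab$best]) & back[ab$best] == ab$gene)
      } else {
        (nrow(ab) + nrow(ba)) / 2
      }
      nC <- nodes$n_genes[nodes$species_id == A]
      nD <- nodes$n_genes[nodes$species_id == B]
      data.frame(species_a = A, species_b = B,
                 ci = ciIndex(nS, nC, nD), stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
    edges <- edges[edges$ci > 0, , drop = FALSE]
    rownames(edges) <- NULL
  }
  methods::new("SpeciesNetwork", nodes = nodes, edges = edges,
               highlight = character(0), hiThreshold = NA_real_)
}

#' Highlight species carrying a homolog of a focal gene
#'
#' Sets the network's highlight to the species owning at least one gene
#' with `hi(focal, gene) >= t`, always including the focal gene's own
#' species. Raising `t` never adds species (nested highlight sets).
#'
#' @param net A [SpeciesNetwork-class].
#' @param graph The [HIGraph-class] the network was built from.
#' @param focal Focal gene ID.
#' @param map Species map `data.frame`.
#' @param t HI threshold in `[0, 1]` (default 0.8).
#' @return The network with its highlight set and threshold filled in.
#' @export
highlightOrthologs <- function(net, graph, focal, map, t = 0.8) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  h <- hiTo(graph, focal)
  sp <- setNames(map$species_id, map$gene_id)
  hot <- unique(unname(sp[names(h)[h >= t]]))
  hot <- union(hot, unname(sp[focal]))
  net@highlight <- sort(intersect(hot, net@nodes$species_id))
  net@hiThreshold <- t
  methods::validObject(net)
  net
}

#' Write a species network as an edge-list TSV
#'
#' Columns `species_a`, `species_b`, `ci`; edges with `ci < minCI`
#' (display threshold, default 0.05) are omitted to keep exports readable.
#'
#' @param net A [SpeciesNetwork-class].
#' @param path Output path.
#' @param minCI Minimum CI for an edge to be written.
#' @param header Optional comment lines.
#' @export
writeNetworkEdges <- function(net, path, minCI = 0.05, header = NULL) {
  e <- networkEdges(net)
  e <- e[e$ci >= minCI, , drop = FALSE]
  e$ci <- format(e$ci, digits = 17, trim = TRUE, scientific = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("species_a\tspecies_b\tci", con)
  if (nrow(e)) writeLines(do.call(paste, c(e, sep = "\t")), con)
  invisible(path)
}

#' Read a network edge list written by [writeNetworkEdges()]
#'
#' @param path Input path.
#' @return `data.frame` with `species_a`, `species_b`, `ci`.
#' @export
readNetworkEdges <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric"))
}

#' Export a species network as GraphML
#'
#' Node attributes: `n_genes` and `highlight` (0/1); edge attribute:
#' `ci`.
#'
#' @inheritParams writeNetworkEdges
#' @export
writeNetworkGraphML <- function(net, path, minCI = 0.05) {
  e <- networkEdges(net)
  e <- e[e$ci >= minCI, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = net@nodes$species_id,
                          n_genes = net@nodes$n_genes,
                          highlight = as.integer(
                            net@nodes$species_id %in% net@highlight)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
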