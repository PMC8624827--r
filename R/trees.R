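# HI-scale dendrograms, orthology and taxonomy trees, Robinson-Foulds
# discordance with a Monte-Carlo percentile.

#' Single-linkage dendrogram of genes on the HI scale
#'
#' Agglomerates the given genes by single linkage on the distance
#' `d = 1 - HI` (pairs with no recorded similarity are treated as HI 0,
#' i.e. d = 1). Merge heights are stored on the distance scale by
#' `hclust`; [mergeHI()] converts them back to HI. Cutting the dendrogram
#' at HI threshold `t` with [cutAtHI()] reproduces the single-linkage
#' groups of [groupsAtThreshold()] restricted to these genes, because both
#' are connected components of the `hi >= t` subgraph.
#'
#' @param graph An [HIGraph-class].
#' @param members Gene IDs to cluster (>= 2, all graph vertices).
#' @return An object of class `hclust` with labels set to the gene IDs.
#' @export
hiDendrogram <- function(graph, members) {
  members <- sort(unique(members))
  miss <- setdiff(members, geneIds(graph))
  if (length(miss))
    stop("member(s) absent from graph: ", paste(head(miss, 5), collapse = ", "))
  n <- length(members)
  if (n < 2) stop("need at least 2 members to build a dendrogram")
  d <- matrix(1, n, n, dimnames = list(members, members))
  e <- hiEdges(graph)
  e <- e[e$from %in% members & e$to %in% members, , drop = FALSE]
  if (nrow(e)) {
    d[cbind(e$from, e$to)] <- 1 - e$hi
    d[cbind(e$to, e$from)] <- 1 - e$hi
  }
  diag(d) <- 0
  stats::hclust(stats::as.dist(d), method = "single")
}

#' Merge heights of an HI dendrogram, on the HI scale
#'
#' @param dend An `hclust` object from [hiDendrogram()].
#' @return Numeric vector `1 - height`, one HI value per merge
#'   (non-increasing).
#' @export
mergeHI <- function(dend) 1 - dend$height

#' Cut an HI dendrogram at an HI threshold
#'
#' @param dend An `hclust` object from [hiDendrogram()].
#' @param t HI threshold; merges at HI >= `t` are kept together.
#' @return Named integer vector of cluster memberships (as [stats::cutree]).
#' @export
cutAtHI <- function(dend, t) stats::cutree(dend, h = 1 - t + 1e-9)

#' Orthology tree: one representative gene per species, on the HI scale
#'
#' For each species with at least one gene of positive HI to the focal
#' gene, the most homologous gene (maximum HI to the focal; ties broken by
#' lexicographically smallest gene ID) represents the species. The focal
#' species is always represented by the focal gene itself (self HI 1). A
#' single-linkage dendrogram over the representatives is built with
#' [hiDendrogram()] and its leaves are relabelled by species, yielding a
#' species tree as seen through this one gene family.
#'
#' @param graph An [HIGraph-class].
#' @param focal Focal gene ID.
#' @param map Species map `data.frame` (`gene_id`, `species_id`, ...).
#' @return An `ape::phylo` tree with species tip labels and attributes
#'   `representatives` (named character, species -> gene) and `mergeHI`
#'   (merge heights), or `NULL` (with a message) when no other species has
#'   a homolog.
#' @export
orthologyTree <- function(graph, focal, map) {
  h <- hiTo(graph, focal)
  sp <- map$species_id[match(names(h), map$gene_id)]
  if (anyNA(sp))
    stop("gene(s) missing from the species map: ",
         paste(head(names(h)[is.na(sp)], 5), collapse = ", "))
  keep <- h > 0
  reps <- vapply(split(names(h)[keep], sp[keep]), function(g) {
    g[order(-h[g], g)][1]
  }, "")
  focalSp <- map$species_id[match(focal, map$gene_id)]
  reps[focalSp] <- focal   # self HI 1 dominates
  if (length(reps) < 2) {
    message("no other species shares a homolog with ", focal,
            "; no orthology tree")
    return(NULL)
  }
  dend <- hiDendrogram(graph, unname(reps))
  phy <- ape::as.phylo(dend)
  gene2sp <- setNames(names(reps), reps)
  phy$tip.label <- unname(gene2sp[phy$tip.label])
  attr(phy, "representatives") <- reps
  attr(phy, "mergeHI") <- mergeHI(dend)
  phy
}

#' Read a taxonomy parent/child table
#'
#' Accepts either the `nodes.dmp` dialect (fields separated by `\t|\t`,
#' records terminated by `\t|`) or a plain 2-4 column TSV. Columns are
#' `child`, `parent`, and optionally `rank` and `name`. The root is the
#' record whose child equals its parent (NCBI convention) or whose parent
#' is absent from the child column.
#'
#' @param path Input path.
#' @return `data.frame` with columns `child`, `parent`, `rank`, `name`
#'   (missing names default to the child ID), validated to have exactly
#'   one root and no cycles.
#' @export
readTaxonomyTable <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw)) & !grepl("^\\s*#", raw)]
  dmp <- any(grepl("\t|\t", raw, fixed = TRUE))
  parts <- if (dmp) {
    strsplit(sub("\t\\|$", "", raw), "\t|\t", fixed = TRUE)
  } else {
    strsplit(raw, "\t", fixed = TRUE)
  }
  nf <- lengths(parts)
  if (any(nf < 2))
    stop("taxonomy line ", which(nf < 2)[1], ": need at least child, parent")
  get <- function(i) vapply(parts, function(p)
    if (length(p) >= i) trimws(p[i]) else NA_character_, "")
  tab <- data.frame(child = get(1), parent = get(2), rank = get(3),
                    name = get(4), stringsAsFactors = FALSE)
  tab$name[is.na(tab$name) | !nzchar(tab$name)] <-
    tab$child[is.na(tab$name) | !nzchar(tab$name)]
  if (anyDuplicated(tab$child)) stop("duplicate child taxid in taxonomy table")
  root <- tab$child[tab$child == tab$parent | !(tab$parent %in% tab$child)]
  if (length(root) != 1)
    stop("taxonomy table must have exactly one root, found ", length(root))
  # cycle check: every node must reach the root
  parent <- setNames(tab$parent, tab$child)
  for (v in tab$child) {
    seen <- character(0); u <- v
    while (u != root) {
      if (u %in% seen) stop("cycle in taxonomy table involving taxid ", u)
      seen <- c(seen, u); u <- parent[[u]]
    }
  }
  attr(tab, "root") <- root
  tab
}

.taxonomyToPhylo <- function(tab) {
  root <- attr(tab, "root")
  if (is.null(root)) root <- tab$child[tab$child == tab$parent |
                                       !(tab$parent %in% tab$child)]
  kids <- split(tab$child, tab$parent)
  label <- setNames(tab$name, tab$child)
  quote_lab <- function(x) {
    if (grepl("[^A-Za-z0-9_.-]", x)) paste0("'", x, "'") else x
  }
  rec <- function(id) {
    ch <- setdiff(kids[[id]], id)   # root lists itself as its own child
    if (is.null(ch) || !length(ch)) return(quote_lab(label[[id]]))
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")",
           quote_lab(label[[id]]))
  }
  phy <- ape::read.tree(text = paste0(rec(root), ";"))
  unquote <- function(x) sub("^'(.*)'$", "\\1", x)
  phy$tip.label <- unquote(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unquote(phy$node.label)
  ape::collapse.singles(phy)
}

#' Taxonomy tree induced on a set of species
#'
#' Converts a taxonomy parent/child table into a rooted tree, prunes it to
#' the requested species, and suppresses the internal nodes made unary by
#' the pruning. Multifurcations present in the taxonomy are preserved (no
#' resolution is invented).
#'
#' @param tab Taxonomy table from [readTaxonomyTable()] (or an equivalent
#'   `data.frame` with `child`, `parent`, `rank`, `name`).
#' @param keep Character vector of species labels to keep; each must match
#'   a leaf of the taxonomy (by `name` or taxid).
#' @return An `ape::phylo` tree with tip labels in `keep`.
#' @export
taxonomyTree <- function(tab, keep) {
  phy <- .taxonomyToPhylo(tab)
  lab <- phy$tip.label
  # allow keep to address leaves by taxid as well as by name
  byId <- setNames(tab$name, tab$child)
  keepLab <- ifelse(keep %in% lab, keep,
                    ifelse(keep %in% names(byId), unname(byId[keep]), NA))
  bad <- keep[is.na(keepLab) | !(keepLab %in% lab)]
  if (length(bad))
    stop("label(s) not resolvable to taxonomy leaves: ",
         paste(bad, collapse = ", "))
  ape::keep.tip(phy, unique(keepLab))
}

.nonTrivialSplits <- function(tree) {
  if (ape::Ntip(tree) < 4) return(0L)
  ur <- ape::unroot(tree)
  sum(ur$edge[, 2] > ape::Ntip(ur))
}

#' Robinson-Foulds distance between two leaf-labelled trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' unrooted trees (symmetric difference). Multifurcating trees contribute
#' only the bipartitions they resolve (generalized RF). The leaf label
#' sets must be identical; prune beforehand (see [rfCompare()]).
#'
#' @param a,b `ape::phylo` trees on the same leaf set.
#' @return Non-negative integer distance.
#' @export
rfDistance <- function(a, b) {
  la <- sort(a$tip.label); lb <- sort(b$tip.label)
  if (!identical(la, lb)) {
    d <- c(setdiff(la, lb), setdiff(lb, la))
    stop("leaf label sets differ: ", paste(head(d, 8), collapse = ", "))
  }
  if (length(la) < 2) stop("trees must have at least 2 leaves")
  as.integer(suppressMessages(suppressWarnings(
    phangorn::RF.dist(ape::unroot(a), ape::unroot(b),
                      check.labels = TRUE))))
}

#' Maximum attainable RF distance for a pair of trees
#'
#' The sum of the numbers of non-trivial bipartitions each tree resolves;
#' `2 * (n - 3)` when both trees are binary with `n` leaves.
#'
#' @inheritParams rfDistance
#' @return Non-negative integer.
#' @export
maxRFDistance <- function(a, b) .nonTrivialSplits(a) + .nonTrivialSplits(b)

#' Monte-Carlo percentile of an observed RF distance
#'
#' Samples `nRandom` uniformly random unrooted binary topologies on the
#' reference tree's leaf set, computes each one's RF distance to the
#' reference, and reports `100 * #{rf_random >= obs} / nRandom`: the
#' percent of random trees at least as distant as the observed tree, so a
#' tree more similar to the reference than random scores high (an observed
#' RF of 0 always scores 100). This makes discordance comparable across
#' gene trees with different species counts, since the raw RF grows with
#' the leaf count.
#'
#' @param obs Observed RF distance (integer >= 0).
#' @param reference `ape::phylo` reference tree (>= 4 leaves).
#' @param geneTreeLeaves Number of leaves of the (binary) gene tree that
#'   produced `obs`; used for the maximum attainable RF. Defaults to the
#'   reference leaf count.
#' @param nRandom Number of random topologies (default 1000).
#' @param seed Integer seed for the null sample (mandatory).
#' @return An [RFResult-class] object.
#' @export
rfPercentile <- function(obs, reference, geneTreeLeaves = ape::Ntip(reference),
                         nRandom = 1000, seed) {
  n <- ape::Ntip(reference)
  if (n < 4) stop("need at least 4 leaves for non-trivial bipartitions")
  if (missing(seed)) stop("a seed is required for the Monte-Carlo null")
  if (nRandom < 1) stop("nRandom must be >= 1")
  set.seed(seed)
  ref <- ape::unroot(reference)
  rfs <- vapply(seq_len(nRandom), function(i) {
    r <- ape::rtopology(n, rooted = FALSE, tip.label = reference$tip.label)
    as.integer(suppressMessages(suppressWarnings(
      phangorn::RF.dist(ref, r, check.labels = TRUE))))
  }, integer(1))
  maxRF <- .nonTrivialSplits(reference) + max(0L, geneTreeLeaves - 3L)
  methods::new("RFResult", rf = as.numeric(obs), maxRF = as.numeric(maxRF),
               percentile = 100 * mean(rfs >= obs),
               nRandom = as.numeric(nRandom), seed = as.numeric(seed))
}

#' Compare a gene tree with a reference species tree
#'
#' Prunes both trees to their common leaf set, computes the RF distance,
#' and situates it with [rfPercentile()].
#'
#' @param geneTree `ape::phylo`, leaves labelled by species (e.g. from
#'   [orthologyTree()]).
#' @param reference `ape::phylo` species/taxonomy tree.
#' @param nRandom,seed Passed to [rfPercentile()].
#' @return An [RFResult-class] object.
#' @export
rfCompare <- function(geneTree, reference, nRandom = 1000, seed) {
  common <- intersect(geneTree$tip.label, reference$tip.label)
  if (length(common) < 4)
    stop("fewer than 4 shared leaves between the trees")
  gt <- ape::keep.tip(geneTree, common)
  rt <- ape::keep.tip(reference, common)
  obs <- rfDistance(gt, rt)
  res <- rfPercentile(obs, rt, geneTreeLeaves = length(common),
                      nRandom = nRandom, seed = seed)
  res@maxRF <- as.numeric(maxRFDistance(gt, rt))
  methods::validObject(res)
  res
}

#' Write an RF comparison result as JSON
#'
#' @param res An [RFResult-class].
#' @param path Output path.
#' @export
writeRFResult <- function(res, path) {
  jsonlite::write_json(
    list(rf = res@rf, max_rf = res@maxRF, percentile = res@percentile,
         n_random = res@nRandom, seed = res@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
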