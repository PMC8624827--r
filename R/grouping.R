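# Threshold-sweep single-linkage grouping and lineage charts.

.componentsAt <- function(graph, t) {
  # list of character vectors: connected components of the subgraph hi >= t,
  # singletons included
  e <- hiEdges(graph)
  e <- e[e$hi >= t, , drop = FALSE]
  genes <- geneIds(graph)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = genes))
  cmp <- igraph::components(g)$membership
  unname(split(names(cmp), cmp))
}

.groupCounts <- function(members, map) {
  miss <- setdiff(members, map$gene_id)
  if (length(miss))
    stop("gene(s) missing from the species map: ",
         paste(head(miss, 5), collapse = ", "))
  i <- match(members, map$gene_id)
  fam <- map$family_id[i]
  fam[is.na(fam) | !nzchar(fam)] <- map$species_id[i][is.na(fam) | !nzchar(fam)]
  c(n_genes = length(members),
    n_species = length(unique(map$species_id[i])),
    n_families = length(unique(fam)))
}

#' Homologous gene groups at one HI threshold
#'
#' Groups are the connected components of the HI graph restricted to edges
#' with `hi >= t` (single linkage): every pair of members is connected by a
#' chain of pairwise similarities at or above the threshold. Genes with no
#' qualifying edge form singleton groups.
#'
#' @param graph An [HIGraph-class].
#' @param t HI threshold in `[0, 1]`.
#' @param map Species map `data.frame` with columns `gene_id`,
#'   `species_id` and optionally `family_id` (see [speciesMap()]).
#' @return `data.frame` with one row per group: `threshold`, `n_genes`,
#'   `n_species`, `n_families`, `members` (semicolon-joined, sorted).
#' @export
groupsAtThreshold <- function(graph, t, map) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  comps <- .componentsAt(graph, t)
  if (!length(comps))
    return(data.frame(threshold = numeric(0), n_genes = integer(0),
                      n_species = integer(0), n_families = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  rows <- lapply(comps, function(m) {
    cnt <- .groupCounts(m, map)
    data.frame(threshold = t, n_genes = cnt[["n_genes"]],
               n_species = cnt[["n_species"]],
               n_families = cnt[["n_families"]],
               members = paste(sort(m), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_genes, out$members), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sweep HI thresholds and chart the lineage of a focal gene
#'
#' Evaluates the group containing `focal` at every distinct edge HI value
#' (plus the endpoints 0 and 1) and keeps only the change points, giving
#' the ordered lineage of nested groups: reading from high threshold to
#' low, the group grows as more diverged homologs join; reading from low
#' to high, genes peel off at each divergence. The gene / species / family
#' counts of the retained points are the three lines of the lineage chart.
#'
#' @inheritParams groupsAtThreshold
#' @param focal Focal gene ID (must be a graph vertex).
#' @param grid Optional numeric vector of thresholds to use instead of the
#'   exact change points (e.g. a fixed grid for chart export); endpoints
#'   are added and change-point filtering still applies.
#' @return A [LineageChart-class] object.
#' @export
sweepThresholds <- function(graph, focal, map, grid = NULL) {
  if (!focal %in% geneIds(graph)) stop("focal gene not in graph: ", focal)
  e <- hiEdges(graph)
  ts <- if (is.null(grid)) sort(unique(c(0, e$hi, 1))) else
    sort(unique(c(0, grid, 1)))
  members <- list(); counts <- list(); keptT <- numeric(0)
  prev <- NULL
  for (t in ts) {
    comps <- .componentsAt(graph, t)
    grp <- sort(comps[[which(vapply(comps, function(m) focal %in% m,
                                    logical(1)))]])
    if (is.null(prev) || !identical(grp, prev)) {
      keptT <- c(keptT, t)
      members[[length(members) + 1L]] <- grp
      counts[[length(counts) + 1L]] <- .groupCounts(grp, map)
      prev <- grp
    }
  }
  cn <- as.data.frame(do.call(rbind, counts))
  cn <- cbind(data.frame(threshold = keptT), cn)
  methods::new("LineageChart", focalGene = focal, thresholds = keptT,
               members = members, counts = cn)
}

#' Census of distinct multi-gene groups across the full sweep
#'
#' Enumerates every distinct group (of size >= 2) formed at any threshold
#' during the sweep, deduplicated by member set, together with the number
#' of multi-gene groups present at each distinct threshold. Edges with
#' identical HI are processed atomically at that threshold.
#'
#' @param graph An [HIGraph-class].
#' @return List with `n_distinct_groups` (the census total) and
#'   `by_threshold`, a `data.frame` of `threshold`, `n_groups` (multi-gene
#'   groups present at that threshold).
#' @export
groupCensus <- function(graph) {
  e <- hiEdges(graph)
  if (!nrow(e))
    return(list(n_distinct_groups = 0L,
                by_threshold = data.frame(threshold = numeric(0),
                                          n_groups = integer(0))))
  ts <- sort(unique(e$hi))
  seen <- new.env(parent = emptyenv())
  byT <- data.frame(threshold = ts, n_groups = 0L)
  for (i in seq_along(ts)) {
    comps <- .componentsAt(graph, ts[i])
    multi <- comps[lengths(comps) >= 2]
    byT$n_groups[i] <- length(multi)
    for (m in multi) assign(paste(sort(m), collapse = ";"), TRUE, envir = seen)
  }
  list(n_distinct_groups = length(ls(seen)), by_threshold = byT)
}

#' Write a lineage chart as TSV
#'
#' Columns: `threshold`, `n_genes`, `n_species`, `n_families`,
#' `member_ids` (semicolon-joined). Comment header lines start with `#`.
#'
#' @param chart A [LineageChart-class].
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
writeLineageChart <- function(chart, path, header = NULL) {
  df <- chartPoints(chart)
  df$member_ids <- vapply(chartMembers(chart), paste, "", collapse = ";")
  df$threshold <- format(df$threshold, digits = 17, trim = TRUE,
                         scientific = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste0("# focal_gene=", focalGene(chart)), con)
  writeLines(paste(c("threshold", "n_genes", "n_species", "n_families",
                     "member_ids"), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Read a lineage chart written by [writeLineageChart()]
#'
#' @param path Input path.
#' @return A [LineageChart-class].
#' @export
readLineageChart <- function(path) {
  raw <- readLines(path)
  focal <- sub("^# focal_gene=", "", grep("^# focal_gene=", raw, value = TRUE))
  if (length(focal) != 1) stop("chart file lacks a focal_gene header line")
  body <- raw[!grepl("^#", raw)]
  df <- read.delim(text = paste(body, collapse = "\n"), header = TRUE,
                   stringsAsFactors = FALSE)
  members <- strsplit(df$member_ids, ";", fixed = TRUE)
  members <- lapply(members, sort)
  cn <- df[, c("threshold", "n_genes", "n_species", "n_families")]
  methods::new("LineageChart", focalGene = focal,
               thresholds = as.numeric(df$threshold),
               members = members, counts = cn)
}
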