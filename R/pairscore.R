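# Pairwise protein similarity -> homology index (HI) -> HI graph.

.BLAST_COLS <- c("query_id", "subject_id", "pident", "aln_len", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore", "qlen", "slen")

#' Homology index from one tabular alignment line
#'
#' Converts alignment statistics into the homology index
#' `HI = min(1, 2 * (pident/100) * aln_len / (qlen + slen))`:
#' the number of identical aligned residues normalised by the mean of the
#' two sequence lengths. A full-length identical match scores exactly 1;
#' partial or diverged matches score proportionally lower. All inputs are
#' available on a single line of tabular search output with query/subject
#' length columns, so the index can be computed streamingly.
#'
#' @param pident Percent identity in `[0, 100]`.
#' @param alnLen Number of aligned columns (>= 1).
#' @param qlen,slen Query and subject sequence lengths (>= 1).
#' @return Numeric vector of HI values in `[0, 1]`.
#' @examples
#' computeHI(50, 100, 100, 100)   # 0.5
#' computeHI(100, 50, 100, 100)   # half-length perfect match: 0.5
#' @export
computeHI <- function(pident, alnLen, qlen, slen) {
  if (any(!is.finite(pident)) || any(pident < 0 | pident > 100))
    stop("pident must lie in [0, 100]")
  if (any(alnLen < 1) || any(qlen < 1) || any(slen < 1))
    stop("alnLen, qlen and slen must be positive")
  pmin(1, 2 * (pident / 100) * alnLen / (qlen + slen))
}

#' Read tabular alignment hits (12 standard columns + qlen, slen)
#'
#' Parses the 14-column tab-separated dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore qlen slen`), computes the HI of every line with
#' [computeHI()], and flags self hits (query == subject). Lines starting
#' with `#` are ignored. Self hits are retained so callers can validate
#' them (a self hit should have HI 1); [buildHIGraph()] drops them.
#'
#' @param path Path to the tab-separated file.
#' @return `data.frame` with the 14 input columns plus `hi` and
#'   `self_hit`.
#' @export
readBlastTabular <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  raw <- raw[keep]
  if (!length(raw)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 14), .BLAST_COLS))
    out$hi <- numeric(0); out$self_hit <- logical(0)
    return(out)
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != 14))
    stop(sprintf("line %d: expected 14 tab-separated columns, found %d",
                 lineno[which(nfld != 14)[1]], nfld[nfld != 14][1]))
  m <- matrix(unlist(parts), ncol = 14, byrow = TRUE)
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    stringsAsFactors = FALSE)
  num_cols <- 3:14
  for (j in num_cols) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric value '%s' in column %d (%s)",
                   lineno[which(is.na(v))[1]], m[which(is.na(v))[1], j], j,
                   .BLAST_COLS[j]))
    out[[.BLAST_COLS[j]]] <- v
  }
  if (any(out$pident < 0 | out$pident > 100))
    stop(sprintf("line %d: pident outside [0, 100]",
                 lineno[which(out$pident < 0 | out$pident > 100)[1]]))
  out$hi <- computeHI(out$pident, out$aln_len, out$qlen, out$slen)
  out$self_hit <- out$query_id == out$subject_id
  out
}

#' Write alignment hits in the 14-column tabular dialect
#'
#' Numeric fields are written with full double precision so that re-reading
#' the file with [readBlastTabular()] reproduces each HI exactly.
#'
#' @param hits `data.frame` of hits (as from [readBlastTabular()] or
#'   [alignAllPairs()]).
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @export
writePairHits <- function(hits, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  if (nrow(hits)) {
    cols <- lapply(.BLAST_COLS, function(cl) {
      v <- hits[[cl]]
      if (is.numeric(v)) format(v, digits = 17, trim = TRUE,
                                scientific = FALSE) else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Construct a ProteinSet
#'
#' @param seqs Named character vector or `AAStringSet` of amino-acid
#'   sequences; names are gene IDs.
#' @param species Named character vector gene ID -> species ID (or a
#'   `data.frame` with columns `gene_id`, `species_id` and optionally
#'   `family_id`).
#' @param family Optional named character vector gene ID -> family ID.
#'   Missing assignments default to the species ID.
#' @return A [ProteinSet-class] object.
#' @export
proteinSet <- function(seqs, species, family = NULL) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(seqs)
  if (is.data.frame(species)) {
    df <- species
    species <- setNames(as.character(df$species_id), df$gene_id)
    if (is.null(family) && "family_id" %in% names(df))
      family <- setNames(as.character(df$family_id), df$gene_id)
  }
  ids <- names(seqs)
  missing <- setdiff(ids, names(species))
  if (length(missing))
    stop("no species assignment for gene(s): ",
         paste(head(missing, 5), collapse = ", "))
  species <- species[ids]
  if (is.null(family)) family <- setNames(rep(NA_character_, length(ids)), ids)
  family <- family[ids]
  names(family) <- ids
  na_fam <- is.na(family) | !nzchar(family)
  family[na_fam] <- species[na_fam]
  methods::new("ProteinSet", seqs = seqs, species = species, family = family)
}

#' Read proteins from FASTA plus a sidecar species/family table
#'
#' The sidecar is a tab-separated file with columns
#' `gene_id<TAB>species_id[<TAB>family_id]` (no header required; a header
#' row naming the columns is also accepted). Every FASTA record must be
#' mapped.
#'
#' @param fasta Path to a protein FASTA file. The gene ID is the first
#'   whitespace-delimited token of each header.
#' @param map Path to the sidecar TSV.
#' @return A [ProteinSet-class] object.
#' @export
readProteinSet <- function(fasta, map) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- read.delim(map, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(tab) && identical(tolower(tab[1, 1]), "gene_id"))
    tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2) stop("species map must have at least 2 columns")
  names(tab)[1:2] <- c("gene_id", "species_id")
  if (ncol(tab) >= 3) names(tab)[3] <- "family_id"
  proteinSet(seqs, tab)
}

#' Write the proteins of a ProteinSet (or a subset) as FASTA
#'
#' @param proteins A [ProteinSet-class].
#' @param path Output path.
#' @param ids Optional gene IDs to write, in order; default all.
#' @export
writeProteinFasta <- function(proteins, path, ids = NULL) {
  seqs <- proteinSeqs(proteins)
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(seqs))
    if (length(missing))
      stop("missing sequence for gene(s): ",
           paste(head(missing, 5), collapse = ", "))
    seqs <- seqs[ids]
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Align one protein pair and derive its homology index
#'
#' Smith-Waterman local alignment with the BLOSUM62 matrix and affine gap
#' penalties (open 11, extend 1). Percent identity is the number of
#' identical aligned residues over the alignment length (gap columns
#' included), as in tabular search output, and the HI follows from
#' [computeHI()]. If no alignment scores above zero the pair has HI 0 and
#' the hit records `aln_len = 0`.
#'
#' @param a,b Amino-acid sequences (character or `AAString`).
#' @param idA,idB Gene IDs for the output record.
#' @param gapOpening,gapExtension Affine gap penalties.
#' @param substitutionMatrix Name of the scoring matrix.
#' @return One-row `data.frame` in the layout of [readBlastTabular()]
#'   (no E-value model is implemented, so evalue is written as 0; bitscore
#'   carries the raw alignment score).
#' @export
alignPair <- function(a, b, idA = "query", idB = "subject",
                      gapOpening = 11, gapExtension = 1,
                      substitutionMatrix = "BLOSUM62") {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a), Biostrings::AAStringSet(b), type = "local",
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  qlen <- base::nchar(a); slen <- base::nchar(b)
  sc <- Biostrings::score(aln)
  alnLen <- Biostrings::nchar(aln)
  nid <- Biostrings::nmatch(aln)
  if (sc <= 0 || alnLen == 0) {
    pident <- 0; alnLen <- 0L; nid <- 0L; hi <- 0
  } else {
    pident <- 100 * nid / alnLen
    hi <- computeHI(pident, alnLen, qlen, slen)
  }
  data.frame(query_id = idA, subject_id = idB, pident = pident,
             aln_len = as.numeric(alnLen), mismatch = as.numeric(alnLen - nid),
             gapopen = 0, qstart = 1, qend = qlen, sstart = 1, send = slen,
             evalue = 0, bitscore = sc, qlen = qlen, slen = slen,
             hi = hi, self_hit = idA == idB, stringsAsFactors = FALSE)
}

#' All-vs-all pairwise alignment of a ProteinSet
#'
#' Aligns every unordered gene pair with [alignPair()] (the HI is symmetric
#' under this aligner, so one direction suffices) and returns the combined
#' hit table. Intended for desk-scale inputs; precomputed tabular input
#' from an external search is the route for large datasets.
#'
#' @param proteins A [ProteinSet-class].
#' @param ... Passed to [alignPair()].
#' @return `data.frame` of hits (one row per unordered pair).
#' @export
alignAllPairs <- function(proteins, ...) {
  ids <- geneIds(proteins)
  seqs <- as.character(proteinSeqs(proteins))
  if (length(ids) < 2)
    return(alignPair("A", "A")[0, ])
  idx <- utils::combn(length(ids), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    alignPair(seqs[i], seqs[j], ids[i], ids[j], ...)
  })
  do.call(rbind, rows)
}

#' Build the symmetric HI graph from alignment hits
#'
#' Drops self hits and zero-HI hits, collapses duplicate and reciprocal
#' hits for the same unordered pair by taking the maximum HI (the strongest
#' evidence; monotone under adding hits), and returns the undirected graph.
#'
#' @param hits Hit `data.frame` with columns `query_id`, `subject_id`,
#'   `hi` (e.g. from [readBlastTabular()] or [alignAllPairs()]).
#' @param genes Optional character vector of gene IDs to include as
#'   vertices even when isolated (defaults to the genes seen in `hits`).
#' @return An [HIGraph-class] object.
#' @export
buildHIGraph <- function(hits, genes = NULL) {
  hc <- table(hits$query_id)
  hitCounts <- setNames(as.integer(hc), names(hc))
  keep <- hits$query_id != hits$subject_id & hits$hi > 0
  h <- hits[keep, c("query_id", "subject_id", "hi")]
  from <- pmin(h$query_id, h$subject_id)
  to <- pmax(h$query_id, h$subject_id)
  key <- paste(from, to, sep = "\r")
  hi <- if (nrow(h)) as.numeric(tapply(h$hi, key, max)) else numeric(0)
  ukey <- if (nrow(h)) names(tapply(h$hi, key, max)) else character(0)
  sp <- strsplit(ukey, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(sp, `[`, "", 1),
                      to = vapply(sp, `[`, "", 2),
                      hi = hi, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  allGenes <- sort(unique(c(genes, hits$query_id, hits$subject_id)))
  methods::new("HIGraph", genes = allGenes, edges = edges,
               hitCounts = hitCounts)
}

#' HI of every gene relative to a focal gene
#'
#' @param graph An [HIGraph-class].
#' @param focal Focal gene ID (must be a vertex).
#' @return Named numeric vector over all genes: the edge HI to `focal`,
#'   1 for `focal` itself, 0 where no edge exists.
#' @export
hiTo <- function(graph, focal) {
  genes <- geneIds(graph)
  if (!focal %in% genes) stop("focal gene not in graph: ", focal)
  out <- setNames(numeric(length(genes)), genes)
  e <- hiEdges(graph)
  ia <- e$from == focal
  ib <- e$to == focal
  out[e$to[ia]] <- e$hi[ia]
  out[e$from[ib]] <- e$hi[ib]
  out[focal] <- 1
  out
}
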