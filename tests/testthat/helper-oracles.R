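# Fixture builders and independent brute-force oracles used across tests.

# random HI graph with a species/family map; hi values rounded so distinct
# thresholds are well separated
randomHIGraph <- function(nGenes = 12, pEdge = 0.3, nSpecies = 4, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  species <- paste0("s", sample(nSpecies, nGenes, replace = TRUE))
  fam <- paste0("f", (as.integer(sub("s", "", species)) + 1) %/% 2)
  map <- data.frame(gene_id = genes, species_id = species, family_id = fam,
                    stringsAsFactors = FALSE)
  pairs <- utils::combn(genes, 2)
  keep <- stats::runif(ncol(pairs)) < pEdge
  hits <- data.frame(query_id = pairs[1, keep], subject_id = pairs[2, keep],
                     hi = round(stats::runif(sum(keep), 0.05, 0.95), 3),
                     stringsAsFactors = FALSE)
  list(graph = buildHIGraph(hits, genes = genes), map = map, hits = hits)
}

# transitive-closure oracle: components of {edges with hi >= t} by repeated
# set merging (independent of igraph)
bruteComponents <- function(genes, edges, t) {
  comps <- lapply(genes, function(g) g)
  for (k in seq_len(nrow(edges))) {
    if (edges$hi[k] < t) next
    ia <- which(vapply(comps, function(cc) edges$from[k] %in% cc, TRUE))
    ib <- which(vapply(comps, function(cc) edges$to[k] %in% cc, TRUE))
    if (ia != ib) {
      comps[[ia]] <- c(comps[[ia]], comps[[ib]])
      comps[[ib]] <- NULL
    }
  }
  sort(vapply(comps, function(cc) paste(sort(cc), collapse = ";"), ""))
}

# non-trivial bipartitions of an unrooted tree, canonicalised as the sorted
# side not containing the alphabetically first label (path enumeration,
# independent of phangorn)
bipartitionSet <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- ape::Ntip(tree)
  if (nt < 4) return(character(0))
  labs <- tree$tip.label
  adj <- list()
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
    adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
  }
  anchor <- sort(labs)[1]
  splits <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    if (child <= nt) next   # trivial split
    # tips reachable from child without crossing this edge
    seen <- c(tree$edge[k, 1]); stack <- child; side <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      if (v <= nt) side <- c(side, v)
      else stack <- c(stack, adj[[as.character(v)]])
    }
    tipsIn <- sort(labs[side])
    if (anchor %in% tipsIn) tipsIn <- sort(setdiff(labs, tipsIn))
    splits <- c(splits, paste(tipsIn, collapse = ";"))
  }
  unique(splits)
}

rfOracle <- function(a, b) {
  sa <- bipartitionSet(a); sb <- bipartitionSet(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# Gotoh local alignment with affine gaps and full traceback; returns score,
# alignment length and identity count (independent of Biostrings)
gotohLocal <- function(a, b, open = 11, ext = 1) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- as.matrix(e$BLOSUM62)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)    # best ending at (i, j)
  E <- matrix(NEG, n + 1, m + 1)  # gap in B (deletion from A)
  F_ <- matrix(NEG, n + 1, m + 1) # gap in A
  ptrH <- matrix(0L, n + 1, m + 1)  # 0 stop, 1 diag, 2 fromE, 3 fromF
  ptrE <- matrix(0L, n + 1, m + 1)  # 1 open from H, 2 extend
  ptrF <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    eo <- H[i - 1, j] - open - ext; ee <- E[i - 1, j] - ext
    E[i, j] <- max(eo, ee); ptrE[i, j] <- if (eo >= ee) 1L else 2L
    fo <- H[i, j - 1] - open - ext; fe <- F_[i, j - 1] - ext
    F_[i, j] <- max(fo, fe); ptrF[i, j] <- if (fo >= fe) 1L else 2L
    diag <- H[i - 1, j - 1] + S[A[i - 1], B[j - 1]]
    h <- max(0, diag, E[i, j], F_[i, j])
    H[i, j] <- h
    ptrH[i, j] <- if (h == 0) 0L else if (h == diag) 1L else
      if (h == E[i, j]) 2L else 3L
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  if (best <= 0) return(list(score = 0, aln_len = 0L, nid = 0L))
  i <- bi; j <- bj; state <- "H"; len <- 0L; nid <- 0L
  repeat {
    if (state == "H") {
      p <- ptrH[i, j]
      if (p == 0L) break
      if (p == 1L) {
        len <- len + 1L
        if (A[i - 1] == B[j - 1]) nid <- nid + 1L
        i <- i - 1; j <- j - 1
      } else if (p == 2L) state <- "E" else state <- "F"
    } else if (state == "E") {
      len <- len + 1L
      if (ptrE[i, j] == 1L) { i <- i - 1; state <- "H" } else i <- i - 1
    } else {
      len <- len + 1L
      if (ptrF[i, j] == 1L) { j <- j - 1; state <- "H" } else j <- j - 1
    }
    if (i == 1 && j == 1) break
  }
  list(score = best, aln_len = len, nid = nid)
}

# random protein pair with controlled divergence, for round-trip panels
randomProteinPair <- function(len = 120, pMut = 0.2) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  a <- sample(aa, len, replace = TRUE)
  b <- a
  mut <- stats::runif(len) < pMut
  b[mut] <- sample(aa, sum(mut), replace = TRUE)
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# hand-built LineageChart
makeChart <- function(focal, thresholds, members, map) {
  counts <- do.call(rbind, lapply(members, function(m) {
    i <- match(m, map$gene_id)
    data.frame(n_genes = length(m),
               n_species = length(unique(map$species_id[i])),
               n_families = length(unique(map$family_id[i])))
  }))
  counts <- cbind(data.frame(threshold = thresholds), counts)
  methods::new("LineageChart", focalGene = focal, thresholds = thresholds,
               members = lapply(members, sort), counts = counts)
}
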