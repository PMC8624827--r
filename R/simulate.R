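# Seeded gene-family simulator: speciation, duplication, substitution.

#' Simulation configuration
#'
#' @param nSpecies Number of species (>= 2).
#' @param treeHeight Species-tree height in expected substitutions per
#'   site (root-to-tip). Speciation nodes are evenly spaced between
#'   `treeHeight / (nSpecies - 1)` and `treeHeight`, so each divergence is
#'   individually resolvable at the default sequence length; the join
#'   order (tree shape) is random.
#' @param duplications List of duplication events; each is
#'   `list(branch = <tip label or character vector of tip labels>,
#'   rtime = <fraction in (0,1)>)`. `branch` names the species-tree branch
#'   above the named tip (or above the MRCA of several tips); `rtime` is
#'   the position along that branch measured from the rootward end.
#' @param seqLength Protein length in residues (>= 50).
#' @param substitutionRate Multiplier on branch lengths (default 1: branch
#'   lengths are already substitutions per site).
#' @param familyCutFrac Species whose divergence height is below
#'   `familyCutFrac * treeHeight` are binned into the same synthetic
#'   taxonomic family (default 0.5), so family counts are exercised.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   the config.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(nSpecies = 8, treeHeight = 0.5,
                      duplications = list(list(branch = "sp1", rtime = 0.5)),
                      seqLength = 300, substitutionRate = 1,
                      familyCutFrac = 0.5, seed = 1) {
  if (nSpecies < 2) stop("nSpecies must be >= 2")
  if (seqLength < 50) stop("seqLength must be >= 50")
  if (treeHeight <= 0) stop("treeHeight must be positive")
  if (substitutionRate < 0) stop("substitutionRate must be non-negative")
  for (d in duplications) {
    if (is.null(d$branch) || is.null(d$rtime) ||
        d$rtime <= 0 || d$rtime >= 1)
      stop("each duplication needs a branch and an rtime in (0, 1)")
  }
  structure(list(nSpecies = nSpecies, treeHeight = treeHeight,
                 duplications = duplications, seqLength = seqLength,
                 substitutionRate = substitutionRate,
                 familyCutFrac = familyCutFrac, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Expected pairwise identity/HI under the substitution model
#'
#' Substitutions arrive per site as a Poisson process and replace the
#' residue with a uniform draw from the 20 amino acids. Two sequences
#' separated by a path of `pathLength` expected substitutions per site are
#' identical at a site with probability
#' `exp(-pathLength) + (1 - exp(-pathLength)) / 20`. Without indels the
#' alignment is full-length, so the expected HI equals this expected
#' identity.
#'
#' @param pathLength Total expected substitutions per site along the path
#'   between the two sequences (twice the divergence height for an
#'   ultrametric tree).
#' @return Expected identity (= expected HI) in `(0, 1]`.
#' @export
expectedHI <- function(pathLength) {
  exp(-pathLength) + (1 - exp(-pathLength)) / 20
}

# ---- internal nested-tree machinery -------------------------------------

.tipSet <- function(node) {
  if (node$kind == "tip") return(node$label)
  sort(unique(unlist(lapply(node$children, .tipSet))))
}

# duplicate the subtree below the branch above the clade `tips`, splitting
# the branch at fraction rtime from its rootward end
.applyDuplication <- function(node, tips, rtime) {
  hit <- FALSE
  rec <- function(nd) {
    nd$children <- lapply(nd$children, function(ch) {
      if (identical(.tipSet(ch), tips)) {
        hit <<- TRUE
        dupHeight <- nd$height - rtime * (nd$height - ch$height)
        return(list(kind = "duplication", label = NA_character_,
                    height = dupHeight, children = list(ch, ch)))
      }
      rec(ch)
    })
    nd
  }
  out <- rec(node)
  if (!hit)
    stop("duplication branch not found for clade: ",
         paste(tips, collapse = ","))
  out
}

.nameGenes <- function(node) {
  counter <- new.env(parent = emptyenv())
  rec <- function(nd) {
    if (nd$kind == "tip") {
      k <- (if (exists(nd$label, envir = counter))
        get(nd$label, envir = counter) else 0L) + 1L
      assign(nd$label, k, envir = counter)
      nd$gene <- paste0(nd$label, "_g", k)
      return(nd)
    }
    nd$children <- lapply(nd$children, rec)
    nd
  }
  rec(node)
}

.nestedToNewick <- function(node, useGene = FALSE) {
  rec <- function(nd, parentHeight) {
    bl <- format(parentHeight - nd$height, digits = 12, scientific = FALSE)
    if (nd$kind == "tip") {
      lab <- if (useGene) nd$gene else nd$label
      return(paste0(lab, ":", bl))
    }
    paste0("(", paste(vapply(nd$children, rec, "", nd$height),
                      collapse = ","), "):", bl)
  }
  inner <- paste(vapply(node$children, rec, "", node$height), collapse = ",")
  paste0("(", inner, ");")
}

.collectLeaves <- function(node) {
  if (node$kind == "tip")
    return(list(list(gene = node$gene, species = node$label)))
  do.call(c, lapply(node$children, .collectLeaves))
}

.focalPathEvents <- function(node, gene) {
  # ancestors (kind, height) of a gene leaf, leaf-to-root order
  rec <- function(nd) {
    if (nd$kind == "tip") {
      if (identical(nd$gene, gene)) return(list())
      return(NULL)
    }
    for (ch in nd$children) {
      sub <- rec(ch)
      if (!is.null(sub))
        return(c(sub, list(list(kind = nd$kind, height = nd$height))))
    }
    NULL
  }
  out <- rec(node)
  if (is.null(out)) stop("gene not found in gene tree: ", gene)
  out
}

.evolveSequences <- function(node, seqLength, rate) {
  leaves <- new.env(parent = emptyenv())
  rec <- function(nd, seq, parentHeight) {
    b <- rate * (parentHeight - nd$height)
    nev <- stats::rpois(seqLength, b)
    mut <- which(nev > 0)
    if (length(mut)) seq[mut] <- sample(.AA20, length(mut), replace = TRUE)
    if (nd$kind == "tip") {
      assign(nd$gene, paste(seq, collapse = ""), envir = leaves)
      return(invisible())
    }
    for (ch in nd$children) rec(ch, seq, nd$height)
  }
  root <- sample(.AA20, seqLength, replace = TRUE)
  for (ch in node$children) rec(ch, root, node$height)
  out <- mget(ls(leaves), envir = leaves)
  unlist(out)
}

.randomSpeciesTree <- function(nSpecies, treeHeight) {
  # coalescent-style construction: repeatedly join a uniformly random pair
  # of lineages; merge heights evenly spaced so every internode gap is
  # treeHeight / (nSpecies - 1) and no divergence is drowned by sequence
  # noise at realistic lengths
  active <- lapply(seq_len(nSpecies), function(i)
    list(kind = "tip", label = paste0("sp", i), height = 0,
         children = list()))
  for (k in seq_len(nSpecies - 1)) {
    pick <- sample(length(active), 2)
    node <- list(kind = "speciation", label = NA_character_,
                 height = k * treeHeight / (nSpecies - 1),
                 children = active[pick])
    active <- c(active[-pick], list(node))
  }
  active[[1]]
}

# ---- public simulator ----------------------------------------------------

#' Simulate a protein family with known speciation/duplication history
#'
#' Draws a random ultrametric species tree (coalescent-style random join
#' order, merge heights evenly spaced up to the configured height in
#' substitutions per site), grafts the configured duplications onto it to
#' obtain the gene tree, and evolves a random root protein down the gene
#' tree under Poisson substitution with uniform amino-acid replacement
#' (no indels, so alignments are full length and HI expectations are
#' analytic; see [expectedHI()]). Species are binned into synthetic
#' families by cutting the species tree at `familyCutFrac * treeHeight`.
#'
#' @param cfg A `SimConfig` from [simConfig()].
#' @return A list of class `GroundTruth`: `speciesTree` and `geneTree`
#'   (`ape::phylo`), `proteins` (a [ProteinSet-class]), `events`
#'   (`data.frame` of true events with `time` = height in substitutions
#'   per site and `kind` in speciation/duplication), `cfg`, and the
#'   internal `nested` gene tree (for expectation queries).
#' @export
simulateFamily <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  spNested <- .randomSpeciesTree(cfg$nSpecies, cfg$treeHeight)
  phy <- ape::read.tree(text = .nestedToNewick(spNested, useGene = FALSE))
  nested <- spNested
  for (d in cfg$duplications)
    nested <- .applyDuplication(nested, sort(unique(d$branch)), d$rtime)
  nested <- .nameGenes(nested)
  leaves <- .collectLeaves(nested)
  gene2sp <- setNames(vapply(leaves, `[[`, "", "species"),
                      vapply(leaves, `[[`, "", "gene"))
  seqs <- .evolveSequences(nested, cfg$seqLength, cfg$substitutionRate)
  seqs <- seqs[sort(names(seqs))]
  # synthetic families: single-linkage cut of the species tree
  coph <- ape::cophenetic.phylo(phy) / 2
  hc <- stats::hclust(stats::as.dist(coph), method = "single")
  famCut <- cfg$familyCutFrac * cfg$treeHeight
  famId <- stats::cutree(hc, h = famCut)
  fam <- setNames(paste0("fam", famId), names(famId))
  map <- data.frame(gene_id = names(seqs),
                    species_id = unname(gene2sp[names(seqs)]),
                    stringsAsFactors = FALSE)
  map$family_id <- unname(fam[map$species_id])
  proteins <- proteinSet(seqs, map)
  # true events: internal species-tree nodes plus grafted duplications
  evts <- list()
  walk <- function(nd) {
    if (nd$kind != "tip") {
      evts[[length(evts) + 1L]] <<- data.frame(
        time = nd$height, kind = nd$kind, stringsAsFactors = FALSE)
      for (ch in nd$children) walk(ch)
    }
  }
  walk(nested)
  events <- do.call(rbind, evts)
  events <- events[order(-events$time), ]; rownames(events) <- NULL
  geneTree <- ape::read.tree(text = .nestedToNewick(nested, useGene = TRUE))
  structure(list(speciesTree = phy, geneTree = geneTree,
                 proteins = proteins, events = events, cfg = cfg,
                 nested = nested),
            class = "GroundTruth")
}

#' Expected lineage events and trees from simulator ground truth
#'
#' Maps the true history onto what the pipeline should observe for a focal
#' gene: each ancestor of the focal gene in the gene tree is one expected
#' group-splitting event, at an expected HI given by [expectedHI()] of
#' twice the ancestor's height, with kind orthologous for speciation
#' ancestors and paralogous for duplication ancestors. The expected
#' orthology-tree topology (absent rate variation) is the true species
#' tree.
#'
#' @param gt A `GroundTruth` from [simulateFamily()].
#' @param focal Focal gene ID (default: first gene).
#' @return List with `events` (`data.frame` of `hi`, `kind`, `height`,
#'   root-ward order removed: sorted by decreasing `hi`), `speciesTree`,
#'   and `focal`.
#' @export
truthToExpectations <- function(gt, focal = NULL) {
  stopifnot(inherits(gt, "GroundTruth"))
  if (is.null(focal)) focal <- geneIds(gt$proteins)[1]
  rate <- gt$cfg$substitutionRate
  anc <- .focalPathEvents(gt$nested, focal)
  ev <- data.frame(
    height = vapply(anc, `[[`, 0, "height"),
    kind = ifelse(vapply(anc, `[[`, "", "kind") == "duplication",
                  "paralogous", "orthologous"),
    stringsAsFactors = FALSE)
  ev$hi <- expectedHI(2 * rate * ev$height)
  ev <- ev[order(-ev$hi), c("hi", "kind", "height")]
  rownames(ev) <- NULL
  list(events = ev, speciesTree = gt$speciesTree, focal = focal)
}

#' Score observed events against simulator expectations
#'
#' An observed lineage event spans the HI interval `(t_low, t_high]`
#' between two adjacent chart change points; the true merge HI of the
#' departing clade lies inside that interval by construction. An expected
#' event therefore matches the observed event whose interval (widened by
#' `resolution` on each side, to absorb per-pair identity noise) contains
#' its expected HI; when windows overlap the nearest interval wins, each
#' observed event matching at most one expected event. Kind labels are
#' scored only for expected events separated from their neighbours by at
#' least `resolution` (closer events cannot be told apart at the
#' simulator's noise level). Precision is the fraction of scored observed
#' events whose kind is correct; recall is the fraction of well-separated
#' expected events recovered with the correct kind.
#'
#' @param observed Event `data.frame` from [classifyEvents()].
#' @param expected Expectation list from [truthToExpectations()].
#' @param resolution Minimum HI separation between expected events for
#'   them to be scored, and the window tolerance. The default
#'   `3 * sqrt(0.25 / 300)` (about 0.087) is three binomial standard
#'   deviations of a per-pair identity estimate at 300 residues.
#' @return List with `tp`, `n_observed_matched`, `n_expected_scored`,
#'   `precision`, `recall`.
#' @export
scoreEventRecovery <- function(observed, expected, resolution = 0.0866) {
  exp_ev <- expected$events
  exp_ev <- exp_ev[order(-exp_ev$hi), , drop = FALSE]
  sep <- rep(TRUE, nrow(exp_ev))
  if (nrow(exp_ev) > 1) {
    d <- abs(outer(exp_ev$hi, exp_ev$hi, "-"))
    diag(d) <- Inf
    sep <- apply(d, 1, min) >= resolution
  }
  if (!any(sep))
    return(list(tp = 0L, n_observed_matched = 0L, n_expected_scored = 0L,
                precision = NA_real_, recall = NA_real_))
  obs <- observed
  tp <- 0L; matched <- 0L
  usedObs <- rep(FALSE, nrow(obs))
  for (i in which(sep)) {
    if (!nrow(obs)) break
    hi <- exp_ev$hi[i]
    # distance 0 inside the interval, else distance to the nearer end
    dd <- pmax(obs$t_low - hi, hi - obs$t_high, 0)
    dd[usedObs] <- Inf
    j <- which.min(dd)
    if (length(j) && is.finite(dd[j]) && dd[j] <= resolution) {
      usedObs[j] <- TRUE
      matched <- matched + 1L
      if (obs$kind[j] == exp_ev$kind[i]) tp <- tp + 1L
    }
  }
  list(tp = tp, n_observed_matched = matched,
       n_expected_scored = sum(sep),
       precision = if (matched) tp / matched else NA_real_,
       recall = tp / sum(sep))
}

#' Write a simulation bundle to a directory
#'
#' Writes `proteins.faa` (FASTA), `proteins.tsv` (gene/species/family
#' map), `species_tree.nwk`, `gene_tree.nwk`, and `events.tsv` (true
#' events). Outputs are byte-identical for identical configs.
#'
#' @param gt A `GroundTruth` from [simulateFamily()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSimulation <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeProteinFasta(gt$proteins, file.path(dir, "proteins.faa"))
  map <- speciesMap(gt$proteins)
  write.table(map, file.path(dir, "proteins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  ape::write.tree(gt$speciesTree, file.path(dir, "species_tree.nwk"))
  ape::write.tree(gt$geneTree, file.path(dir, "gene_tree.nwk"))
  ev <- gt$events
  ev$time <- format(ev$time, digits = 17, trim = TRUE, scientific = FALSE)
  write.table(ev, file.path(dir, "events.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
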