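# CI index, species network construction and ortholog highlighting.

test_that("ciIndex is the F-measure of shared gene content", {
  expect_equal(ciIndex(50, 100, 100), 0.5)
  expect_equal(ciIndex(10, 10, 10), 1)
  expect_equal(ciIndex(0, 5, 8), 0)
  # harmonic-mean identity on random triples
  set.seed(8)
  for (r in 1:1000) {
    nC <- sample(1:500, 1); nD <- sample(1:500, 1)
    nS <- sample(0:min(nC, nD), 1)
    ci <- ciIndex(nS, nC, nD)
    expect_equal(ci, ciIndex(nS, nD, nC))   # symmetric
    if (nS > 0) {
      prec <- nS / nC; rec <- nS / nD
      expect_equal(ci, 2 * prec * rec / (prec + rec))
    }
  }
  expect_error(ciIndex(6, 5, 10), "min")
  expect_error(ciIndex(1, 0, 10), ">= 1")
})

twoSpeciesFixture <- function() {
  # identical single-gene genomes
  hits <- data.frame(query_id = "a1", subject_id = "b1", hi = 1)
  map <- data.frame(gene_id = c("a1", "b1"), species_id = c("sA", "sB"))
  list(graph = buildHIGraph(hits), map = map)
}

test_that("identical single-gene genomes get one edge with ci 1", {
  fx <- twoSpeciesFixture()
  net <- buildNetwork(fx$graph, fx$map)
  expect_equal(nrow(networkEdges(net)), 1)
  expect_equal(networkEdges(net)$ci, 1)
  expect_equal(networkNodes(net)$n_genes, c(1, 1))
})

test_that("species without qualifying cross hits get no edge", {
  hits <- data.frame(query_id = "a1", subject_id = "b1", hi = 0.2)
  map <- data.frame(gene_id = c("a1", "b1"), species_id = c("sA", "sB"))
  net <- buildNetwork(buildHIGraph(hits), map, edgeHiThreshold = 0.3)
  expect_equal(nrow(networkEdges(net)), 0)
  expect_error(buildNetwork(buildHIGraph(hits), map[1, ]), "missing")
})

test_that("network edges equal a brute-force reciprocal-best enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    nGenes <- 12
    genes <- sprintf("g%02d", 1:nGenes)
    species <- paste0("s", sample(3, nGenes, replace = TRUE))
    map <- data.frame(gene_id = genes, species_id = species)
    pairs <- utils::combn(genes, 2)
    keep <- runif(ncol(pairs)) < 0.5
    hits <- data.frame(query_id = pairs[1, keep], subject_id = pairs[2, keep],
                       hi = round(runif(sum(keep)), 3))
    g <- buildHIGraph(hits, genes = genes)
    thr <- 0.3
    net <- buildNetwork(g, map, edgeHiThreshold = thr)
    # oracle: exhaustive best-match table then reciprocal pairing
    hiOf <- function(x, y) {
      e <- hiEdges(g)
      v <- e$hi[(e$from == min(x, y)) & (e$to == max(x, y))]
      if (length(v)) v else 0
    }
    bestIn <- function(gene, sp) {
      cand <- genes[species == sp & genes != gene]
      if (!length(cand)) return(NA_character_)
      his <- vapply(cand, function(y) hiOf(gene, y), 0)
      cand <- cand[order(-his, cand)]
      if (max(his) <= 0) NA_character_ else cand[1]
    }
    for (A in unique(species)) for (B in unique(species)) {
      if (A >= B) next
      nS <- 0
      for (ga in genes[species == A]) {
        gb <- bestIn(ga, B)
        if (is.na(gb) || hiOf(ga, gb) < thr) next
        back <- bestIn(gb, A)
        if (!is.na(back) && back == ga) nS <- nS + 1
      }
      ciOra <- ciIndex(nS, sum(species == A), sum(species == B))
      e <- networkEdges(net)
      got <- e$ci[e$species_a == A & e$species_b == B]
      expect_equal(if (length(got)) got else 0, ciOra,
                   label = paste(rep, A, B))
    }
  }
})

test_that("self-comparison of a genome under reciprocal best is perfect", {
  # two identical genomes: every gene reciprocally best-matches its copy
  genes <- c(paste0("a", 1:3), paste0("b", 1:3))
  map <- data.frame(gene_id = genes,
                    species_id = rep(c("sA", "sB"), each = 3))
  hits <- data.frame(query_id = paste0("a", 1:3),
                     subject_id = paste0("b", 1:3), hi = 1)
  net <- buildNetwork(buildHIGraph(hits, genes = genes), map)
  expect_equal(networkEdges(net)$ci, 1)
})

test_that("highlight sets are nested in the HI threshold", {
  set.seed(31)
  fx <- randomHIGraph(14, 0.5, nSpecies = 5, seed = 31)
  net <- buildNetwork(fx$graph, fx$map, edgeHiThreshold = 0)
  focal <- geneIds(fx$graph)[1]
  focalSp <- fx$map$species_id[fx$map$gene_id == focal]
  prev <- NULL
  for (t in c(0.9, 0.6, 0.3, 0)) {
    hl <- highlightedSpecies(
      highlightOrthologs(net, fx$graph, focal, fx$map, t = t))
    expect_true(focalSp %in% hl)
    if (!is.null(prev)) expect_true(all(prev %in% hl))  # monotone nesting
    prev <- hl
  }
  # t above every hit leaves only the focal species
  hiMax <- max(hiTo(fx$graph, focal)[names(hiTo(fx$graph, focal)) != focal])
  hl <- highlightedSpecies(
    highlightOrthologs(net, fx$graph, focal, fx$map,
                       t = min(1, hiMax + 1e-6)))
  expect_equal(hl, focalSp)
})

test_that("network exports round-trip and honour the display threshold", {
  fx <- randomHIGraph(10, 0.6, nSpecies = 4, seed = 13)
  net <- buildNetwork(fx$graph, fx$map, edgeHiThreshold = 0.2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeNetworkEdges(net, f, minCI = 0)
  back <- readNetworkEdges(f)
  expect_equal(back$ci, networkEdges(net)$ci)
  writeNetworkEdges(net, f, minCI = 0.5)
  expect_true(all(readNetworkEdges(f)$ci >= 0.5))
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetworkGraphML(highlightOrthologs(net, fx$graph,
                                         geneIds(fx$graph)[1], fx$map),
                      gml, minCI = 0)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::vertex_attr(g, "name")),
               sort(networkNodes(net)$species_id))
})
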