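# HI dendrograms, orthology/taxonomy trees, Robinson-Foulds comparison.

test_that("a single pair merges at its edge HI", {
  g <- buildHIGraph(data.frame(query_id = "a", subject_id = "b", hi = 0.8))
  d <- hiDendrogram(g, c("a", "b"))
  expect_equal(mergeHI(d), 0.8)
  expect_equal(sort(d$labels), c("a", "b"))
  expect_error(hiDendrogram(g, c("a", "zz")), "absent")
  expect_error(hiDendrogram(g, "a"), "at least 2")
})

test_that("dendrogram cuts reproduce threshold groups on random graphs", {
  for (seed in 1:8) {
    fx <- randomHIGraph(12, 0.45, seed = seed)
    comps0 <- strsplit(groupsAtThreshold(fx$graph, 0, fx$map)$members, ";")
    for (mem in comps0) {
      if (length(mem) < 2) next
      d <- hiDendrogram(fx$graph, mem)
      for (t in c(sort(unique(hiEdges(fx$graph)$hi)), 1)) {
        cut <- cutAtHI(d, t)
        got <- sort(unname(vapply(split(names(cut), cut),
                                  function(m) paste(sort(m), collapse = ";"),
                                  "")))
        sub <- hiEdges(fx$graph)
        sub <- sub[sub$from %in% mem & sub$to %in% mem, ]
        ora <- bruteComponents(mem, sub, t)
        expect_equal(got, ora, label = paste("seed", seed, "t", t))
      }
    }
  }
})

test_that("orthology tree picks per-species best homologs of the focal gene", {
  # star around the focal gene, one gene per species
  hits <- data.frame(query_id = "f1",
                     subject_id = c("b1", "c1", "d1"),
                     hi = c(0.9, 0.6, 0.3))
  g <- buildHIGraph(hits, genes = c("f1", "b1", "c1", "d1"))
  map <- data.frame(gene_id = c("f1", "b1", "c1", "d1"),
                    species_id = c("sF", "sB", "sC", "sD"))
  tr <- orthologyTree(g, "f1", map)
  expect_setequal(tr$tip.label, c("sF", "sB", "sC", "sD"))
  # caterpillar: sF joins sB first (0.9), then sC, then sD
  ora <- ape::read.tree(text = "(((sF,sB),sC),sD);")
  expect_equal(rfOracle(tr, ora), 0)
  reps <- attr(tr, "representatives")
  expect_equal(unname(reps["sF"]), "f1")   # focal represents its own species
  # ties broken by lexicographically smallest gene id
  hits2 <- rbind(hits, data.frame(query_id = "f1", subject_id = "b0",
                                  hi = 0.9))
  g2 <- buildHIGraph(hits2, genes = c(geneIds(g), "b0"))
  map2 <- rbind(map, data.frame(gene_id = "b0", species_id = "sB"))
  expect_equal(unname(attr(orthologyTree(g2, "f1", map2),
                           "representatives")["sB"]), "b0")
  # no homologous species -> empty-tree signal
  gIso <- buildHIGraph(data.frame(query_id = character(0),
                                  subject_id = character(0),
                                  hi = numeric(0)), genes = c("f1", "b1"))
  expect_message(expect_null(orthologyTree(gIso, "f1", map)), "no other")
})

test_that("taxonomy tables parse in both dialects and induce pruned trees", {
  dmp <- withr::local_tempfile(fileext = ".dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|\troot\t|",
               "2\t|\t1\t|\tphylum\t|\tPa\t|",
               "3\t|\t1\t|\tphylum\t|\tPb\t|",
               "4\t|\t2\t|\tspecies\t|\tsp one\t|",
               "5\t|\t2\t|\tspecies\t|\tsp two\t|",
               "6\t|\t2\t|\tspecies\t|\tsp three\t|",
               "7\t|\t3\t|\tspecies\t|\tsp four\t|",
               "8\t|\t3\t|\tspecies\t|\tsp five\t|"), dmp)
  tab <- readTaxonomyTable(dmp)
  expect_equal(attr(tab, "root"), "1")
  expect_equal(tab$name[tab$child == "4"], "sp one")
  # trifurcation under Pa is preserved, no resolution invented
  tr <- taxonomyTree(tab, c("sp one", "sp two", "sp three", "sp four"))
  expect_equal(ape::Ntip(tr), 4)
  expect_false(ape::is.binary(tr))
  # keep of 2 gives a cherry
  tr2 <- taxonomyTree(tab, c("sp one", "sp five"))
  expect_equal(ape::Ntip(tr2), 2)
  # taxids resolve too; unknown labels are listed
  tr3 <- taxonomyTree(tab, c("4", "5"))
  expect_setequal(tr3$tip.label, c("sp one", "sp two"))
  expect_error(taxonomyTree(tab, c("sp one", "nope")), "nope")
  # plain 2-column TSV dialect
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r\tr", "x\tr", "y\tr", "u\tx", "v\tx", "w\ty"), tsv)
  tab2 <- readTaxonomyTable(tsv)
  tr4 <- taxonomyTree(tab2, c("u", "v", "w"))
  expect_equal(rfOracle(tr4, ape::read.tree(text = "((u,v),w);")), 0)
})

test_that("taxonomy validation catches multiple roots and cycles", {
  f <- withr::local_tempfile()
  writeLines(c("1\t1", "2\t2", "3\t1"), f)
  expect_error(readTaxonomyTable(f), "exactly one root")
  writeLines(c("1\t1", "2\t3", "3\t2"), f)
  expect_error(readTaxonomyTable(f), "cycle")
})

test_that("rfDistance agrees with the bipartition oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  expect_equal(rfDistance(t1, t1), 0)
  t4a <- ape::read.tree(text = "((a,b),(c,d));")
  t4b <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rfDistance(t4a, t4b), 2)
  expect_equal(maxRFDistance(t4a, t4b), 2)
  # polytomies contribute only resolved bipartitions
  p <- ape::read.tree(text = "((a,b,c),d,e);")
  b <- ape::read.tree(text = "(((a,b),c),d,e);")
  expect_equal(rfDistance(p, b), rfOracle(p, b))
  expect_equal(rfDistance(p, b), 1)
  # random binary pairs, 5-8 leaves
  set.seed(4)
  for (n in 5:8) for (r in 1:10) {
    a <- ape::rtopology(n, rooted = FALSE, tip.label = letters[1:n])
    b2 <- ape::rtopology(n, rooted = FALSE, tip.label = letters[1:n])
    expect_equal(rfDistance(a, b2), rfOracle(a, b2))
    expect_true(rfDistance(a, b2) <= 2 * (n - 3))
  }
  expect_error(rfDistance(t4a, t1), "differ")
})

test_that("rf satisfies metric axioms on sampled triples", {
  set.seed(12)
  for (r in 1:10) {
    trs <- replicate(3, ape::rtopology(7, rooted = FALSE,
                                       tip.label = letters[1:7]),
                     simplify = FALSE)
    ab <- rfDistance(trs[[1]], trs[[2]])
    ba <- rfDistance(trs[[2]], trs[[1]])
    expect_equal(ab, ba)
    expect_true(ab <= rfDistance(trs[[1]], trs[[3]]) +
                  rfDistance(trs[[3]], trs[[2]]))
  }
})

test_that("rfPercentile is seeded, bounded and maximal for identity", {
  ref <- ape::rtopology(6, rooted = FALSE, tip.label = letters[1:6])
  r0 <- rfPercentile(0, ref, nRandom = 200, seed = 5)
  expect_equal(r0@percentile, 100)
  expect_equal(r0@rf, 0)
  r1 <- rfPercentile(4, ref, nRandom = 200, seed = 5)
  r2 <- rfPercentile(4, ref, nRandom = 200, seed = 5)
  expect_equal(r1@percentile, r2@percentile)  # deterministic under the seed
  expect_true(r1@percentile >= 0 && r1@percentile <= 100)
  expect_error(rfPercentile(0, ape::read.tree(text = "(a,b,c);"),
                            nRandom = 10, seed = 1), "4 leaves")
  expect_error(rfPercentile(0, ref, nRandom = 10), "seed")
})

test_that("rfCompare prunes to the shared leaf set before comparing", {
  gt <- ape::read.tree(text = "(((a,b),c),(d,e));")
  ref <- ape::read.tree(text = "(((a,b),(c,x)),(d,(e,y)));")
  res <- rfCompare(gt, ref, nRandom = 100, seed = 3)
  expect_equal(res@rf, 0)
  expect_equal(res@percentile, 100)
  expect_error(rfCompare(ape::read.tree(text = "((a,b),(c,q));"), ref,
                         nRandom = 10, seed = 1), "shared")
})
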