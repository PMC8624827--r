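# Homology-index computation, tabular I/O and HI-graph assembly.

test_that("computeHI matches hand arithmetic and enforces its domain", {
  expect_equal(computeHI(50, 100, 100, 100), 0.5)
  expect_equal(computeHI(100, 50, 100, 100), 0.5)
  expect_equal(computeHI(100, 120, 120, 120), 1)
  # capped at 1 even when the alignment overshoots the mean length
  expect_equal(computeHI(100, 150, 100, 100), 1)
  # vectorised
  expect_equal(computeHI(c(50, 100), c(100, 80), c(100, 80), c(100, 80)),
               c(0.5, 1))
  expect_error(computeHI(101, 10, 10, 10), "pident")
  expect_error(computeHI(50, 0, 10, 10), "positive")
  expect_error(computeHI(50, 10, 0, 10), "positive")
})

test_that("tabular hits round-trip with full HI precision", {
  withr::with_seed(7, {
    pairs <- replicate(20, randomProteinPair(len = 80, pMut = 0.3),
                       simplify = FALSE)
  })
  hits <- do.call(rbind, lapply(seq_along(pairs), function(i)
    alignPair(pairs[[i]][1], pairs[[i]][2], paste0("q", i), paste0("s", i))))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePairHits(hits, f, header = c("roundtrip panel"))
  back <- readBlastTabular(f)
  expect_equal(back$hi, hits$hi, tolerance = 0)
  expect_equal(back$query_id, hits$query_id)
  expect_false(any(back$self_hit))
})

test_that("malformed tabular input is rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ok <- paste(c("g1", "g2", "50", "100", "50", "0", "1", "100", "1", "100",
                "0", "200", "100", "100"), collapse = "\t")
  writeLines(c("# comment", ok, paste(c("g1", "g3", "1"), collapse = "\t")), f)
  expect_error(readBlastTabular(f), "line 3.*14")
  writeLines(c(ok, sub("^g1\tg2\t50", "g1\tg2\tfifty", ok)), f)
  expect_error(readBlastTabular(f), "non-numeric")
  writeLines(sub("^g1\tg2\t50", "g1\tg2\t150", ok), f)
  expect_error(readBlastTabular(f), "pident")
  # self hits retained and flagged
  writeLines(paste(c("g1", "g1", "100", "100", "0", "0", "1", "100", "1",
                     "100", "0", "200", "100", "100"), collapse = "\t"), f)
  got <- readBlastTabular(f)
  expect_true(got$self_hit)
  expect_equal(got$hi, 1)
})

test_that("alignPair satisfies the HI contract on identity and disjointness", {
  s <- "MKVLATQWERPLMNDSHHGF"
  expect_equal(alignPair(s, s)$hi, 1)
  # no residue pair scores positive between poly-P and poly-G under BLOSUM62
  expect_equal(alignPair("PPPPPPPPPP", "GGGGGGGGGG")$hi, 0)
  expect_error(alignPair("", s), "non-empty")
  # symmetry of the index
  withr::with_seed(11, {
    for (i in 1:10) {
      p <- randomProteinPair(len = 60, pMut = 0.4)
      expect_equal(alignPair(p[1], p[2])$hi, alignPair(p[2], p[1])$hi)
    }
  })
})

test_that("alignPair agrees with an exhaustive Gotoh DP oracle", {
  seqs <- c(a = "MKVLATQWERPLMNDS",
            b = "MKVLATQWERPLMNDSAGHT",
            c = "MKVAATQWERPLQNDS",
            d = "HHHCCWWYYFFMMLLK")
  ids <- names(seqs)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    got <- alignPair(seqs[i], seqs[j], ids[i], ids[j])
    ora <- gotohLocal(unname(seqs[i]), unname(seqs[j]))
    expect_equal(got$bitscore, ora$score,
                 label = paste("score", ids[i], ids[j]))
    if (ora$score > 0) {
      expect_equal(got$aln_len, ora$aln_len,
                   label = paste("aln_len", ids[i], ids[j]))
      hiOra <- computeHI(100 * ora$nid / ora$aln_len, ora$aln_len,
                         nchar(seqs[i]), nchar(seqs[j]))
      expect_equal(got$hi, hiOra, label = paste("hi", ids[i], ids[j]))
    } else {
      expect_equal(got$hi, 0)
    }
  }
})

test_that("buildHIGraph collapses duplicates by maximum and stays symmetric", {
  expect_equal(nrow(hiEdges(buildHIGraph(
    data.frame(query_id = character(0), subject_id = character(0),
               hi = numeric(0))))), 0)
  hits <- data.frame(query_id = c("g1", "g2", "g1", "g3"),
                     subject_id = c("g2", "g1", "g1", "g1"),
                     hi = c(0.4, 0.6, 1.0, 0.2))
  g <- buildHIGraph(hits)
  e <- hiEdges(g)
  expect_equal(nrow(e), 2)
  expect_equal(e$hi[e$from == "g1" & e$to == "g2"], 0.6)  # max collapse
  expect_false(any(e$from == e$to))                        # self hit dropped
  # feeding (q,s) or (s,q) gives identical graphs
  withr::with_seed(3, {
    fx <- randomHIGraph(10, 0.5, seed = 3)
    rev <- fx$hits[, c("subject_id", "query_id", "hi")]
    names(rev) <- c("query_id", "subject_id", "hi")
    g2 <- buildHIGraph(rev, genes = geneIds(fx$graph))
    expect_equal(hiEdges(g2), hiEdges(fx$graph))
  })
})

test_that("graph edges match a brute-force pair dictionary on random hits", {
  set.seed(21)
  for (rep in 1:5) {
    genes <- paste0("g", 1:8)
    n <- 40
    hits <- data.frame(query_id = sample(genes, n, replace = TRUE),
                       subject_id = sample(genes, n, replace = TRUE),
                       hi = round(runif(n), 3))
    g <- buildHIGraph(hits)
    dict <- new.env()
    for (k in seq_len(n)) {
      a <- hits$query_id[k]; b <- hits$subject_id[k]
      if (a == b || hits$hi[k] <= 0) next
      key <- paste(min(a, b), max(a, b))
      prev <- mget(key, dict, ifnotfound = 0)[[1]]
      assign(key, max(prev, hits$hi[k]), dict)
    }
    e <- hiEdges(g)
    expect_equal(nrow(e), length(ls(dict)))
    for (k in seq_len(nrow(e)))
      expect_equal(e$hi[k], get(paste(e$from[k], e$to[k]), dict))
  }
})

test_that("ProteinSet validates identity, alphabet and map coverage", {
  ps <- proteinSet(c(g1 = "MKV", g2 = "MKL"),
                   data.frame(gene_id = c("g1", "g2"),
                              species_id = c("s1", "s2")))
  expect_equal(geneIds(ps), c("g1", "g2"))
  # family defaults to species when absent
  expect_equal(speciesMap(ps)$family_id, c("s1", "s2"))
  expect_error(proteinSet(c(g1 = "MKV", g1 = "MKL"),
                          data.frame(gene_id = "g1", species_id = "s1")),
               "unique")
  expect_error(proteinSet(c(g1 = "MKV"),
                          data.frame(gene_id = "g2", species_id = "s1")),
               "species")
  f <- withr::local_tempfile(fileext = ".faa")
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">g1 some description", "MKVL", ">g2", "MKLI"), f)
  writeLines(c("g1\ts1\tfA", "g2\ts2\tfB"), m)
  ps2 <- readProteinSet(f, m)
  expect_equal(speciesMap(ps2)$family_id, c("fA", "fB"))
  expect_equal(as.character(proteinSeqs(ps2)[["g1"]]), "MKVL")
})

test_that("hiTo reports self as 1 and absent edges as 0", {
  g <- buildHIGraph(data.frame(query_id = "a", subject_id = "b", hi = 0.7),
                    genes = c("a", "b", "c"))
  h <- hiTo(g, "a")
  expect_equal(unname(h[c("a", "b", "c")]), c(1, 0.7, 0))
  expect_error(hiTo(g, "zz"), "not in graph")
})
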