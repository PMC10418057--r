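test_that("uniform tiling follows the start arithmetic and C-terminal rule", {
  t56 <- pepsynTile(strrep("A", 56))
  expect_equal(nrow(t56), 1L)
  expect_equal(c(t56$start, t56$end), c(0L, 56L))

  t112 <- pepsynTile(randomPeptides(1, 112, seed = 1))
  expect_equal(t112$start, c(0L, 28L, 56L))
  expect_equal(t112$end, c(56L, 84L, 112L))

  t70 <- pepsynTile(randomPeptides(1, 70, seed = 2))
  expect_equal(t70$start, c(0L, 14L))
  expect_equal(t70$end, c(56L, 70L))

  expect_error(pepsynTile(strrep("A", 40)), "tile length")
})

test_that("tiling matches the brute-force interval generator for lengths 56-400", {
  for (L in 56:400) {
    seq <- strrep("A", L)
    t <- pepsynTile(seq)
    expect_identical(t$start, bruteTile(L))
    expect_true(all(t$end - t$start == 56L))
    expect_equal(t$end[nrow(t)], L)   # all residues covered
    expect_true(all(nchar(t$seq) == 56L))
  }
})

test_that("k-mer scan window counts follow floor((56-k)/5)+1", {
  wt <- randomPeptides(1, 56, seed = 3)
  ks <- kmerScan(wt)
  for (k in seq(15, 45, by = 5))
    expect_equal(sum(ks$k == k), (56 - k) %/% 5 + 1)
  expect_equal(ks$start[ks$k == 45], c(0L, 5L, 10L))
  expect_true(all(mapply(function(s, kk, sq)
    substr(wt, s + 1, s + kk) == sq, ks$start, ks$k, ks$seq)))
  expect_error(kmerScan(strrep("A", 55)), "56")
})

test_that("alanine scan substitutes triplets, with A -> G", {
  wt <- paste0(strrep("C", 10), "CAT", strrep("C", 43))
  av <- alanineScan(wt)
  expect_equal(nrow(av), 54L)
  v <- av$seq[av$start == 10]
  expect_equal(substr(v, 11, 13), "AGA")        # C->A, A->G, T->A
  expect_equal(substr(v, 1, 10), strrep("C", 10))
  expect_equal(substr(v, 14, 56), strrep("C", 43))

  noAla <- chartr("A", "C", randomPeptides(1, 56, seed = 4))
  av2 <- alanineScan(noAla)
  diffs <- vapply(seq_len(54), function(i) {
    sum(strsplit(av2$seq[i], "")[[1]] != strsplit(noAla, "")[[1]])
  }, 0L)
  expect_true(all(diffs == 3L))
  expect_error(alanineScan("SHORT"), "56")
})

test_that("window enumeration is exhaustive with correct offsets", {
  expect_equal(nrow(enumerateWindows(randomPeptides(1, 15, seed = 5))), 1L)
  w <- enumerateWindows(randomPeptides(1, 56, seed = 6))
  expect_equal(nrow(w), 42L)
  expect_warning(w0 <- enumerateWindows("ACDEF", k = 15), "no windows")
  expect_equal(nrow(w0), 0L)
})

test_that("greedy epitope selection is non-overlapping, ranked, cutoff-gated", {
  w <- data.frame(start = c(0, 5, 20, 40, 41), seq = strrep("A", 15),
                  prob = c(0.9, 0.8, 0.7, 0.6, 0.95))
  sel <- selectEpitopes(w)
  expect_equal(sel$start, c(41, 0, 20))  # 0.95, 0.9, 0.7; 0.8 and 0.6 overlap
  expect_equal(sel$rank, 1:3)
  expect_equal(nrow(selectEpitopes(transform(w, prob = 0.4))), 0L)
  two <- data.frame(start = c(0, 5), seq = "x", prob = c(0.9, 0.8))
  expect_equal(selectEpitopes(two)$start, 0)
})

test_that("greedy selection equals the brute-force re-implementation", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(3:25, 1)
    w <- data.frame(start = sample(0:80, n), seq = "x",
                    prob = round(runif(n), 2))
    a <- selectEpitopes(w)
    b <- bruteSelect(w)
    expect_equal(a$start, b$start)
    expect_equal(a$prob, b$prob)
    if (nrow(a) > 1)
      expect_true(all(abs(diff(sort(a$start))) >= 15))
  }
})

test_that("deduplication takes unions of memberships and the max probability", {
  sel <- data.frame(
    seq = c("PEP1", "PEP1", "PEP1", "PEP2"),
    prob = c(0.6, 0.9, 0.7, 0.8),
    group_id = c("g1", "g2", "g3", "g1"),
    phages = c("p1", "p1;p2", "p2", "p1"))
  cat <- dedupeEpitopes(sel)
  e1 <- cat[cat$seq == "PEP1", ]
  expect_equal(e1$prob, 0.9)
  expect_equal(e1$groups, "g1;g2;g3")
  expect_equal(e1$phages, "p1;p2")
  expect_equal(e1$n_occurrences, 3L)
  allDistinct <- data.frame(seq = c("X", "Y"), prob = 0.6,
                            group_id = "g", phages = "p")
  expect_equal(nrow(dedupeEpitopes(allDistinct)), 2L)
})

test_that("rank layouts interleave the top epitopes across peptides", {
  expect_equal(assignPositions(3), list(c(1, 2, 3)))
  expect_equal(assignPositions(6), list(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(assignPositions(7), list(c(1, 3, 5), c(2, 4, 6)))  # 7 dropped
  expect_equal(assignPositions(2), list())
})

test_that("stitching yields 55-mers containing the epitopes at fixed offsets", {
  eps <- randomPeptides(3, 15, seed = 7)
  st <- stitchPeptides(eps)
  expect_equal(nchar(st), 55L)
  expect_equal(substr(st, 1, 15), eps[1])
  expect_equal(substr(st, 21, 35), eps[2])
  expect_equal(substr(st, 41, 55), eps[3])
  expect_equal(nchar(stitchPeptides(eps, linker = "")), 45L)
  expect_error(stitchPeptides(eps[1:2]), "three")
})

test_that("library design produces consistent manifests and coverage", {
  prot <- data.frame(id = "p1", seq = randomPeptides(1, 56, seed = 8),
                     group_id = "p1", phages = "ph1")
  lib <- designLibrary(prot, mode = "tiling")
  expect_equal(nrow(manifest(lib)), 1L)
  expect_equal(libraryCoverage(lib), 1.0)
  expect_error(designLibrary(prot[0, ], mode = "tiling"), "empty")
  expect_error(designLibrary(prot, mode = "stitched"), "model")
})

test_that("stitched designs compress the proteome relative to tiling", {
  cfg <- synthConfig(seed = 21, nPhages = 8, proteinsPerPhage = 5,
                     cohortSize = 8)
  pr <- generateProteome(cfg)
  sc <- generateScanDataset(synthConfig(seed = 22, cohortSize = 8),
                            nWildtypes = 150, lengths = 15L)
  ts <- buildTrainingSet(sc$kmer[, setdiff(names(sc$kmer), c("k", "start"))],
                         sc$bead)
  m <- trainEpitopeModel(ts)
  stitched <- designLibrary(pr$proteins, m, "stitched")
  tiled <- designLibrary(pr$proteins, mode = "tiling")
  expect_lt(nrow(manifest(stitched)) / nrow(manifest(tiled)), 0.5)
  man <- manifest(stitched)
  expect_true(all(nchar(man$aa_seq) == 55L))
  # every stitched peptide embeds three windows of its source protein
  for (i in seq_len(min(nrow(man), 20L))) {
    src <- pr$proteins$seq[pr$proteins$group_id == man$source_group[i]]
    st <- as.integer(strsplit(man$epitope_starts[i], ";")[[1]])
    eps <- substring(src, st + 1L, st + 15L)
    expect_equal(substr(man$aa_seq[i], 1, 15), eps[1])
    expect_equal(substr(man$aa_seq[i], 21, 35), eps[2])
    expect_equal(substr(man$aa_seq[i], 41, 55), eps[3])
  }
})
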