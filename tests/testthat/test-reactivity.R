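test_that("hit calling is the strict three-way threshold conjunction", {
  counts <- matrix(c(16, 15, 0, 100), 2, 2)
  log2fc <- matrix(log2(c(5.1, 100, 1, 6)), 2, 2)
  pvals <- matrix(c(9e-4, 1e-9, 0.5, 1e-4), 2, 2)
  h <- callHits(counts, log2fc, pvals)
  expect_true(h[1, 1])        # 16 / 5.1 / 0.0009
  expect_false(h[2, 1])       # count 15 fails the strict inequality
  expect_false(h[1, 2])
  expect_true(h[2, 2])
  expect_false(any(callHits(matrix(0, 2, 2), log2fc, pvals)))
  expect_error(callHits(counts, log2fc[1, , drop = FALSE], pvals), "dimensions")
})

test_that("simple fold test is centered at null and monotone in counts", {
  set.seed(51)
  mock <- matrix(rpois(400 * 4, 100), 400, 4)
  atNull <- matrix(rowMeans(mock), 400, 2)
  ft <- simpleFoldTest(atNull, mock)
  expect_lt(abs(median(ft$log2fc)), 0.2)          # fc ~ 1 at the null
  expect_true(all(ft$pvals[abs(ft$log2fc) < 0.01] >= 0.3))

  enriched <- atNull; enriched[1, ] <- 10 * atNull[1, ]
  ft2 <- simpleFoldTest(enriched, mock)
  expect_equal(2^ft2$log2fc[1, 1], 10, tolerance = 0.15)
  expect_lt(ft2$pvals[1, 1], 1e-6)
  # larger pseudocount shrinks |log fc| at low counts
  low <- matrix(c(9, 7), 2, 1)
  lowMock <- matrix(c(1, 1, 1, 9, 9, 9), 2, 3, byrow = TRUE)
  a <- abs(simpleFoldTest(low, lowMock, pseudocount = 1)$log2fc[1, 1])
  b <- abs(simpleFoldTest(low, lowMock, pseudocount = 2)$log2fc[1, 1])
  expect_lt(b, a)
  expect_error(simpleFoldTest(atNull, mock[, 0]), "mock")
})

test_that("reactive fraction counts peptides with any positive log-hfc", {
  lh <- matrix(0, 4, 3)
  lh[1, 3] <- 2.5
  rf <- reactiveFraction(lh)
  expect_true(rf$reactive[1])
  expect_equal(rf$fraction, 0.25)
  expect_equal(reactiveFraction(matrix(0, 5, 2))$fraction, 0)
  expect_error(reactiveFraction(matrix(0, 0, 0)), "empty")
})

test_that("ReactivitySet derives hits and exposes aligned assays", {
  set.seed(52)
  counts <- matrix(rpois(60, 50), 20, 3,
                   dimnames = list(sprintf("p%d", 1:20), c("a", "b", "c")))
  log2fc <- matrix(rnorm(60), 20, 3)
  pvals <- matrix(runif(60), 20, 3)
  rs <- ReactivitySet(counts, log2fc, pvals,
                      peptides = data.frame(peptide_id = rownames(counts),
                                            aa_seq = "X", phages = "ph"))
  expect_s4_class(rs, "ReactivitySet")
  expect_identical(hitMatrix(rs), callHits(counts, log2fc, pvals))
  expect_identical(unname(log2fcMatrix(rs)), unname(log2fc))
})

test_that("degenerate constant fold changes give zero scores everywhere", {
  lf <- matrix(1.3, 100, 2, dimnames = list(sprintf("p%d", 1:100), NULL))
  pm <- data.frame(peptide_id = rownames(lf),
                   phages = rep(c("A", "B"), each = 50))
  ph <- pharScore(lf, pm, minPeptides = 10, nDraws = 50, seed = 1)
  expect_true(all(scores(ph)[c("A", "B"), ] == 0))
})

test_that("a planted high-mean phage scores above 1, null phages stay moderate", {
  set.seed(53)
  n <- 2000
  lf <- matrix(rnorm(n * 2), n, 2,
               dimnames = list(sprintf("p%04d", 1:n), c("s1", "s2")))
  lf[1:30, ] <- lf[1:30, ] + 2.0
  pm <- data.frame(peptide_id = rownames(lf),
                   phages = c(rep("hot", 30),
                              rep(sprintf("null%d", 1:10), each = 100),
                              rep(sprintf("bg%02d", 1:97),
                                  each = 10)))  # small bg groups: ineligible
  ph <- pharScore(lf, pm, minPeptides = 25, nDraws = 500, seed = 2)
  s <- scores(ph)
  expect_true(all(s["hot", ] > 1))
  expect_true(all(abs(s[sprintf("null%d", 1:10), ]) < 4))
  expect_lte(ph@iterationsUsed, 7L)
  # removal log never re-removes a phage and the hot phage leaves first
  expect_true("hot" %in% ph@removalLog[[1]])
  expect_length(unlist(ph@removalLog), length(unique(unlist(ph@removalLog))))
})

test_that("PhARscore is deterministic under a fixed seed and errors on tiny pools", {
  set.seed(54)
  lf <- matrix(rnorm(200), 100, 2, dimnames = list(sprintf("p%d", 1:100), NULL))
  pm <- data.frame(peptide_id = rownames(lf),
                   phages = rep(c("A", "B"), each = 50))
  a <- pharScore(lf, pm, minPeptides = 10, nDraws = 100, seed = 7)
  b <- pharScore(lf, pm, minPeptides = 10, nDraws = 100, seed = 7)
  expect_identical(scores(a), scores(b))
  big <- data.frame(peptide_id = rownames(lf)[1:40], phages = "huge")
  expect_error(pharScore(lf[1:30, , drop = FALSE],
                         data.frame(peptide_id = rownames(lf)[1:30],
                                    phages = "huge"),
                         minPeptides = 25, nDraws = 10, seed = 1),
               NA)  # pool equals the set: allowed (sd ~ 0 guarded)
})

test_that("shared peptides stay in the pool until every owner is removed", {
  set.seed(55)
  n <- 600
  lf <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("p%03d", 1:n), "s"))
  lf[1:60, ] <- lf[1:60, ] + 3
  # peptides 1:30 serve both hot phages; 31:60 only hotB
  phs <- c(rep("hotA;hotB", 30), rep("hotB", 30), rep("bg", n - 60))
  pm <- data.frame(peptide_id = rownames(lf), phages = phs)
  ph <- pharScore(lf, pm, minPeptides = 20, nDraws = 200, seed = 3)
  s <- scores(ph)
  expect_true(s["hotA", 1] > 1 && s["hotB", 1] > 1)
  expect_true(all(c("hotA", "hotB") %in% unlist(ph@removalLog)))
  expect_lte(ph@iterationsUsed, 7L)
})

test_that("cost-effectiveness curves conserve the endpoint and are monotone", {
  set.seed(56)
  hits <- matrix(runif(80) < 0.2, 20, 4,
                 dimnames = list(sprintf("p%d", 1:20), NULL))
  fwd <- costEffectiveness(hits, 1:20)
  rev <- costEffectiveness(hits, 20:1)
  expect_equal(fwd[20], rev[20])
  expect_equal(fwd[20], sum(hits))
  expect_true(all(diff(fwd) >= 0))
  step <- matrix(c(rep(TRUE, 4), rep(FALSE, 76)), 20, 4, byrow = FALSE)
  expect_equal(costEffectiveness(cbind(c(4, rep(0, 19))) > 0, 1:20)[1],
               costEffectiveness(cbind(c(4, rep(0, 19))) > 0, 1:20)[20])
  expect_error(costEffectiveness(hits, c(1:19, 19)), "permutation")
})

test_that("probability-ordered curves dominate random order on correlated hits", {
  set.seed(57)
  wins <- 0L
  for (r in 1:20) {
    prob <- runif(200)
    hits <- matrix(runif(200 * 5) < prob * 0.5, 200, 5)
    rownames(hits) <- sprintf("p%d", 1:200)
    ordered <- costEffectiveness(hits, order(-prob))
    random <- costEffectiveness(hits, sample(200))
    if (sum(ordered) >= sum(random)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("protein recovery metrics behave on identical, degraded and empty truth", {
  set.seed(58)
  truth <- matrix(runif(40) < 0.4, 10, 4,
                  dimnames = list(sprintf("pr%d", 1:10), sprintf("s%d", 1:4)))
  pr <- proteinRecovery(truth, truth)
  expect_true(all(pr$perSample$accuracy == 1))
  expect_true(all(pr$perSample$recall == 1, na.rm = TRUE))
  expect_true(all(pr$perSample$precision == 1, na.rm = TRUE))

  half <- truth[1:5, , drop = FALSE]
  pr2 <- proteinRecovery(truth, half)
  expect_setequal(pr2$missingProteins, sprintf("pr%d", 6:10))
  expect_true(all(pr2$fullRecall <= pr2$perSample$recall, na.rm = TRUE))

  # invariance to row/column permutation of the test design
  perm <- truth[sample(10), sample(4)]
  pr3 <- proteinRecovery(truth, perm)
  expect_equal(sort(pr3$perSample$accuracy), sort(pr$perSample$accuracy))

  empty <- truth; empty[] <- FALSE
  expect_warning(pr4 <- proteinRecovery(empty, empty), "undefined")
  expect_true(all(is.na(pr4$perSample$recall)))
  expect_error(proteinRecovery(truth,
                               matrix(TRUE, 1, 4,
                                      dimnames = list("zz", colnames(truth)))),
               "shared")
})

test_that("alanine profiles recover the planted epitope width via the convolution oracle", {
  set.seed(59)
  w <- 14L
  nCurves <- 60L
  variantMat <- matrix(NA_real_, 54, nCurves)
  wtVals <- rep(3, nCurves)
  oracleCurves <- matrix(0, 109, nCurves)
  for (j in seq_len(nCurves)) {
    a <- sample(0:(56 - w), 1)
    d <- 3 * convolutionCurve(a, w)
    variantMat[, j] <- 3 - d + rnorm(54, 0, 0.1)
    idx <- which(d > 0)
    center <- round(mean(idx))
    oracleCurves[(1:54) - center + 55, j] <- d
  }
  prof <- alanineEpitopeProfile(variantMat, wtVals, noiseLevel = 1)
  expect_equal(prof$nUsed, nCurves)
  oracleMean <- rowMeans(oracleCurves)
  names(oracleMean) <- -54:54
  oracleWidth <- curveMassWidth(oracleMean, 0.8)
  expect_lte(abs(prof$width - oracleWidth), 2)

  # flat curves and two-epitope curves are excluded
  flat <- matrix(3 + rnorm(54 * 3, 0, 0.1), 54, 3)
  expect_message(p0 <- alanineEpitopeProfile(flat, rep(3, 3)), "no single")
  expect_true(is.na(p0$width))
  two <- matrix(3, 54, 1)
  two[5:10, 1] <- 0; two[40:45, 1] <- 0
  mix <- cbind(variantMat[, 1, drop = FALSE], two, flat[, 1, drop = FALSE])
  p2 <- alanineEpitopeProfile(mix, c(3, 3, 3), noiseLevel = 1)
  expect_equal(p2$nUsed, 1L)
  expect_equal(p2$nExcluded, 2L)
})
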