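#' PhIP-Seq reactivity container
#'
#' A \code{SummarizedExperiment} holding aligned peptide x sample matrices
#' from a PhIP-Seq screen: read counts, log2 fold changes over the mock-IP
#' background, p-values, and the derived boolean hit calls. Row metadata
#' carries the peptide sequences and semicolon-separated phage memberships;
#' column metadata flags mock (bead-only) columns.
#'
#' @exportClass ReactivitySet
setClass("ReactivitySet", contains = "SummarizedExperiment")

#' Construct a ReactivitySet
#'
#' @param counts peptide x sample integer matrix (serum samples only).
#' @param log2fc,pvals matrices aligned with \code{counts}.
#' @param peptides data.frame with columns \code{peptide_id}, \code{aa_seq},
#'   \code{phages} aligned with the rows.
#' @param countThreshold,fcThreshold,pThreshold hit-call thresholds
#'   (defaults: count > 15, fold change > 5, p < 0.001; all strict).
#' @return A \code{\linkS4class{ReactivitySet}} with assays \code{counts},
#'   \code{log2fc}, \code{pvals}, \code{hits}.
#' @export
ReactivitySet <- function(counts, log2fc, pvals, peptides,
                          countThreshold = 15, fcThreshold = 5,
                          pThreshold = 0.001) {
  hits <- callHits(counts, log2fc, pvals, countThreshold, fcThreshold,
                   pThreshold)
  rd <- S4Vectors::DataFrame(peptides)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, log2fc = log2fc, pvals = pvals,
                  hits = hits),
    rowData = rd)
  rownames(se) <- peptides$peptide_id
  new("ReactivitySet", se)
}

#' @describeIn ReactivitySet boolean hit matrix
#' @param x a \code{ReactivitySet}
#' @export
hitMatrix <- function(x) SummarizedExperiment::assay(x, "hits")

#' @describeIn ReactivitySet log2 fold-change matrix
#' @export
log2fcMatrix <- function(x) SummarizedExperiment::assay(x, "log2fc")

setMethod("show", "ReactivitySet", function(object) {
  h <- hitMatrix(object)
  cat("ReactivitySet:", nrow(object), "peptides x", ncol(object),
      "samples\n")
  cat("  hits:", sum(h), sprintf("(%.1f%% of cells)\n", 100 * mean(h)))
})

#' Call significant reactivity ("hits")
#'
#' A peptide is a hit in a sample when all three thresholds are exceeded
#' strictly: count > 15, fold change > 5 (i.e. log2 fold change >
#' log2(5)), and p < 0.001.
#'
#' @param counts,log2fc,pvals aligned peptide x sample matrices.
#' @param countThreshold,fcThreshold,pThreshold the thresholds.
#' @return Logical matrix of the same dimensions.
#' @export
callHits <- function(counts, log2fc, pvals, countThreshold = 15,
                     fcThreshold = 5, pThreshold = 0.001) {
  if (!all(dim(counts) == dim(log2fc)) || !all(dim(counts) == dim(pvals)))
    stop("counts, log2fc and pvals must share dimensions")
  counts > countThreshold & 2^log2fc > fcThreshold & pvals < pThreshold
}

#' Log hit-fold-change matrix
#'
#' log2 fold change where the peptide is a hit, 0 elsewhere; positive
#' entries mark reactivity.
#'
#' @param hits logical hit matrix.
#' @param log2fc aligned log2 fold-change matrix.
#' @return Numeric matrix.
#' @export
logHfc <- function(hits, log2fc) ifelse(hits, log2fc, 0)

#' Simple count-based fold test against mock IPs
#'
#' A pluggable stand-in for a full count-model analysis: per-sample fold
#' changes are the pseudocounted ratio of the observed count to the
#' expected background count, and p-values come from an upper-tail Poisson
#' test at that rate. The expected background is the mock-IP relative
#' abundance times a median-ratio size factor (robust to the composition
#' shift a strongly enriched peptide subset induces on total depth).
#' Larger counts at a fixed background give larger fold changes and
#' smaller p-values.
#'
#' @param counts peptide x sample matrix (serum samples).
#' @param mockCounts peptide x mock-replicate matrix (>= 1 column).
#' @param pseudocount added to numerator and denominator (default 1).
#' @return list with matrices \code{log2fc} and \code{pvals} aligned with
#'   \code{counts}.
#' @export
simpleFoldTest <- function(counts, mockCounts, pseudocount = 1) {
  if (is.null(dim(mockCounts)) || ncol(mockCounts) < 1L)
    stop("at least one mock column is required")
  if (nrow(counts) != nrow(mockCounts))
    stop("counts and mockCounts must have the same peptides")
  mockDepth <- mean(colSums(mockCounts))
  relAbund <- rowMeans(mockCounts) / mockDepth
  ok <- relAbund > 0
  sizeFactors <- apply(counts, 2L, function(x)
    stats::median(x[ok] / relAbund[ok]))
  expected <- outer(relAbund, sizeFactors)  # mock-estimated rate per cell
  fc <- (counts + pseudocount) / (expected + pseudocount)
  pv <- stats::ppois(counts - 1, lambda = pmax(expected, 1e-9),
                     lower.tail = FALSE)
  list(log2fc = log2(fc), pvals = pmin(pv, 1))
}

#' Reactive peptides and the library reactive fraction
#'
#' A peptide counts as reactive when its log hit-fold-change exceeds zero
#' in at least one sample; the fraction of such peptides is the headline
#' efficiency statistic of a library design.
#'
#' @param loghfc peptide x sample log-hfc matrix (see \code{\link{logHfc}}).
#' @return list with \code{reactive} (logical per peptide) and
#'   \code{fraction}.
#' @export
reactiveFraction <- function(loghfc) {
  if (!length(loghfc)) stop("empty reactivity matrix")
  reactive <- apply(loghfc > 0, 1L, any)
  list(reactive = reactive, fraction = mean(reactive))
}

#' Phage aggregate reactivity scores
#'
#' S4 container for the PhARscore permutation statistic: a phage x sample
#' score matrix (z-like, relative to random peptide sets of matching
#' size), per-phage eligibility, the number of iterations the reactive-
#' phage removal ran, and the per-iteration removal log.
#'
#' @slot scores phage x sample numeric matrix (NA for ineligible phages).
#' @slot eligible named logical per phage (>= minPeptides peptides).
#' @slot iterationsUsed integer, at most the configured maximum.
#' @slot removalLog list (one element per iteration) of phage ids newly
#'   removed from the null pool.
#' @exportClass PhARscoreTable
setClass("PhARscoreTable",
  representation(scores = "matrix", eligible = "logical",
                 iterationsUsed = "integer", removalLog = "list"))

setMethod("show", "PhARscoreTable", function(object) {
  cat("PhARscoreTable:", nrow(object@scores), "phages x",
      ncol(object@scores), "samples\n")
  cat("  eligible phages:", sum(object@eligible), "\n")
  cat("  iterations:     ", object@iterationsUsed, "\n")
})

#' @describeIn PhARscoreTable the phage x sample score matrix
#' @param object a \code{PhARscoreTable}
#' @export
scores <- function(object) object@scores

# one iteration of null z-scores for every eligible phage in one sample;
# null distributions are shared across phages of equal peptide-set size
.pharIteration <- function(x, phagePeps, pool, nDraws) {
  sizes <- vapply(phagePeps, length, 0L)
  out <- setNames(numeric(length(phagePeps)), names(phagePeps))
  nullStats <- list()
  for (m in sort(unique(sizes))) {
    if (m > length(pool))
      stop(sprintf("null pool (%d) smaller than phage peptide set (%d) for %s",
                   length(pool), m,
                   names(phagePeps)[which(sizes == m)[1]]))
    means <- vapply(seq_len(nDraws),
                    function(d) mean(x[pool[sample.int(length(pool), m)]]),
                    0)
    nullStats[[as.character(m)]] <- c(mean(means), stats::sd(means))
  }
  for (p in names(phagePeps)) {
    ns <- nullStats[[as.character(sizes[[p]])]]
    obs <- mean(x[phagePeps[[p]]])
    out[p] <- if (ns[2] < 1e-12) 0 else (obs - ns[1]) / ns[2]
  }
  out
}

#' Permutation-based phage aggregate reactivity score (PhARscore)
#'
#' For each phage represented by at least \code{minPeptides} peptides and
#' each sample, the observed mean log2 fold change of the phage's peptide
#' set is standardized against the empirical distribution of mean log2
#' fold changes of \code{nDraws} equally sized random peptide sets drawn
#' (without replacement within a draw) from the current null pool. The
#' procedure iterates: peptides of strongly reactive phages (score >
#' \code{scoreThreshold} in that sample; or in mean across samples with
#' \code{globalRemoval}) are removed from the pool, scores are recomputed,
#' and iteration stops when no new phage passes or after \code{maxIter}
#' rounds. A peptide serving several phages stays in the pool until every
#' owning phage has been removed.
#'
#' @param log2fc peptide x sample matrix with peptide ids as rownames.
#' @param phageMap data.frame with columns \code{peptide_id} and
#'   \code{phages} (semicolon-separated), or a named list mapping phage ->
#'   peptide ids.
#' @param minPeptides eligibility threshold (default 25).
#' @param nDraws random sets per null distribution (default 1000).
#' @param scoreThreshold removal threshold (default 1.0).
#' @param maxIter maximum removal iterations (default 7).
#' @param seed integer seed (default 1).
#' @param globalRemoval remove a phage's peptides from all samples' pools
#'   when its mean score across samples passes the threshold, instead of
#'   per-sample removal (default FALSE).
#' @return A \code{\linkS4class{PhARscoreTable}}.
#' @export
pharScore <- function(log2fc, phageMap, minPeptides = 25L, nDraws = 1000L,
                      scoreThreshold = 1.0, maxIter = 7L, seed = 1L,
                      globalRemoval = FALSE) {
  if (is.data.frame(phageMap)) {
    long <- strsplit(phageMap$phages, ";", fixed = TRUE)
    phageMap <- split(rep(phageMap$peptide_id, lengths(long)), unlist(long))
  }
  pepIds <- rownames(log2fc)
  if (is.null(pepIds)) stop("log2fc must carry peptide ids as rownames")
  phagePeps <- lapply(phageMap, function(p) match(intersect(p, pepIds), pepIds))
  eligible <- vapply(phagePeps, length, 0L) >= minPeptides
  elig <- phagePeps[eligible]
  nS <- ncol(log2fc)
  scoreMat <- matrix(NA_real_, nrow = length(phageMap), ncol = nS,
                     dimnames = list(names(phageMap), colnames(log2fc)))
  if (!length(elig))
    return(new("PhARscoreTable", scores = scoreMat,
               eligible = setNames(eligible, names(phageMap)),
               iterationsUsed = 0L, removalLog = list()))

  # peptide -> owning eligible phages (peptides leave a pool only when
  # every owner has been removed)
  owners <- vector("list", nrow(log2fc))
  for (p in names(elig))
    for (i in elig[[p]]) owners[[i]] <- c(owners[[i]], p)

  set.seed(seed)
  removedPerSample <- rep(list(character(0)), nS)
  removalLog <- list()
  iterationsUsed <- 0L
  for (iter in seq_len(maxIter)) {
    iterScores <- matrix(NA_real_, length(elig), nS,
                         dimnames = list(names(elig), colnames(log2fc)))
    for (s in seq_len(nS)) {
      rem <- removedPerSample[[s]]
      inPool <- vapply(seq_len(nrow(log2fc)), function(i) {
        ow <- owners[[i]]
        is.null(ow) || !all(ow %in% rem)
      }, TRUE)
      iterScores[, s] <- .pharIteration(log2fc[, s], elig, which(inPool),
                                        nDraws)
    }
    scoreMat[rownames(iterScores), ] <- iterScores
    iterationsUsed <- iter
    if (globalRemoval) {
      passing <- rownames(iterScores)[rowMeans(iterScores) > scoreThreshold]
      newly <- setdiff(passing, removedPerSample[[1]])
      if (!length(newly)) break
      removalLog[[iter]] <- newly
      removedPerSample <- lapply(removedPerSample, function(r) c(r, newly))
    } else {
      newlyAny <- character(0)
      for (s in seq_len(nS)) {
        passing <- rownames(iterScores)[iterScores[, s] > scoreThreshold]
        newly <- setdiff(passing, removedPerSample[[s]])
        newlyAny <- union(newlyAny, newly)
        removedPerSample[[s]] <- c(removedPerSample[[s]], newly)
      }
      if (!length(newlyAny)) break
      removalLog[[iter]] <- newlyAny
    }
  }
  new("PhARscoreTable", scores = scoreMat,
      eligible = setNames(eligible, names(phageMap)),
      iterationsUsed = iterationsUsed, removalLog = removalLog)
}

#' Cost-effectiveness accumulation curve
#'
#' Cumulative number of detected reactivities (hits summed over samples)
#' as peptides are added to the library in a given order; ordering
#' peptides by predicted epitope probability front-loads the detections.
#'
#' @param hits logical peptide x sample hit matrix.
#' @param peptideOrder permutation of the row indices (or rownames).
#' @return Integer vector: \code{curve[i]} = total hits over the first i
#'   peptides; non-decreasing.
#' @export
costEffectiveness <- function(hits, peptideOrder) {
  if (is.character(peptideOrder))
    peptideOrder <- match(peptideOrder, rownames(hits))
  if (length(peptideOrder) != nrow(hits) ||
      !setequal(peptideOrder, seq_len(nrow(hits))))
    stop("peptideOrder must be a permutation of the peptides")
  unname(cumsum(rowSums(hits)[peptideOrder]))
}

#' Protein-level recovery of a compressed design
#'
#' Treats protein-by-sample reactivity under the full tiling design as
#' ground truth (a protein is reactive when any of its peptides is a hit)
#' and computes confusion-matrix metrics for a compressed design over the
#' proteins represented in both; proteins absent from the compressed
#' design are reported separately, with a full-universe recall that counts
#' them as misses.
#'
#' @param truthHits logical protein x sample matrix (full design), protein
#'   ids as rownames.
#' @param testHits logical protein x sample matrix (compressed design).
#' @return list with \code{perSample} (data.frame of accuracy, recall,
#'   precision over shared proteins), \code{missingProteins}, and
#'   \code{fullRecall} (per-sample recall over the truth universe).
#' @export
proteinRecovery <- function(truthHits, testHits) {
  shared <- intersect(rownames(truthHits), rownames(testHits))
  if (!length(shared)) stop("no shared proteins between the designs")
  missing <- setdiff(rownames(truthHits), rownames(testHits))
  tru <- truthHits[shared, , drop = FALSE]
  tst <- testHits[shared, colnames(truthHits), drop = FALSE]
  perSample <- data.frame(
    sample = colnames(tru),
    accuracy = NA_real_, recall = NA_real_, precision = NA_real_)
  fullRecall <- numeric(ncol(tru))
  for (s in seq_len(ncol(tru))) {
    a <- tru[, s]; b <- tst[, s]
    tp <- sum(a & b); fn <- sum(a & !b); fp <- sum(!a & b)
    perSample$accuracy[s] <- mean(a == b)
    perSample$recall[s] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    perSample$precision[s] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    truthAll <- sum(truthHits[, s])
    fullRecall[s] <- if (truthAll > 0) tp / truthAll else NA_real_
  }
  if (all(is.na(perSample$recall)))
    warning("empty truth: recovery metrics undefined")
  list(perSample = perSample, missingProteins = missing,
       fullRecall = setNames(fullRecall, colnames(tru)))
}

#' Epitope localization profile from triple-alanine scans
#'
#' For each scan curve (one wildtype peptide in one reactive sample) the
#' difference wildtype - variant reactivity is computed over the 54
#' substitution positions. Curves with no above-noise disruption (flat)
#' or with more than one contiguous above-noise region (multiple epitopes)
#' are excluded; the remaining single-epitope curves are aligned on the
#' mass center of their disruption region and averaged. The epitope width
#' is summarized as the smallest centered span containing 80\% of the
#' positive mass of the mean curve.
#'
#' @param variantMat 54 x nCurves matrix of variant reactivities (rows =
#'   0-based substitution starts 0..53).
#' @param wildtypeVals numeric vector of length nCurves: the matching
#'   wildtype reactivity.
#' @param noiseLevel absolute disruption threshold separating signal from
#'   noise (default 1, log2 units).
#' @param massFraction mass fraction defining the width (default 0.8).
#' @return list with \code{meanCurve} (named by centered offset),
#'   \code{width} (positions), \code{nUsed}, \code{nExcluded}; empty
#'   result (width NA) with a diagnostic message when no single-epitope
#'   curve survives.
#' @export
alanineEpitopeProfile <- function(variantMat, wildtypeVals, noiseLevel = 1,
                                  massFraction = 0.8) {
  stopifnot(nrow(variantMat) == 54L,
            ncol(variantMat) == length(wildtypeVals))
  nPos <- 54L
  half <- nPos  # aligned grid: offsets -54..54
  grid <- matrix(NA_real_, nrow = 2L * half + 1L, ncol = 0L)
  excluded <- 0L
  for (j in seq_len(ncol(variantMat))) {
    d <- wildtypeVals[j] - variantMat[, j]
    above <- d > noiseLevel
    if (!any(above)) { excluded <- excluded + 1L; next }
    r <- rle(above)
    if (sum(r$values) != 1L) { excluded <- excluded + 1L; next }
    idx <- which(above)
    center <- round(sum(idx * d[idx]) / sum(d[idx]))
    shifted <- rep(NA_real_, 2L * half + 1L)
    shifted[(seq_len(nPos) - center) + half + 1L] <- d
    grid <- cbind(grid, shifted)
  }
  if (!ncol(grid)) {
    message("no single-epitope curves found")
    return(list(meanCurve = NULL, width = NA_real_, nUsed = 0L,
                nExcluded = excluded))
  }
  meanCurve <- rowMeans(grid, na.rm = TRUE)
  meanCurve[is.nan(meanCurve)] <- 0
  names(meanCurve) <- -half:half
  list(meanCurve = meanCurve,
       width = curveMassWidth(meanCurve, massFraction),
       nUsed = ncol(grid), nExcluded = excluded)
}

#' Width of the centered mass of a difference curve
#'
#' Smallest symmetric span around offset 0 containing at least
#' \code{massFraction} of the curve's positive mass.
#'
#' @param curve numeric vector named by centered integer offsets.
#' @param massFraction target mass fraction (default 0.8).
#' @return The span width in positions (2h + 1).
#' @export
curveMassWidth <- function(curve, massFraction = 0.8) {
  off <- as.integer(names(curve))
  pos <- pmax(curve, 0)
  total <- sum(pos)
  if (total <= 0) return(NA_real_)
  for (h in 0:max(abs(off))) {
    if (sum(pos[abs(off) <= h]) >= massFraction * total) return(2 * h + 1)
  }
  2 * max(abs(off)) + 1
}
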