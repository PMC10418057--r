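#' Synthetic study configuration
#'
#' Parameters of the synthetic-data generators, chosen to emulate the
#' structure of a gut-phage PhIP-Seq study: a proteome of homologous
#' proteins shared across phages, planted composition-biased linear
#' epitopes of about 14 residues, a scan library read out in a cohort, and
#' overdispersed sequencing counts with mock-IP background columns.
#'
#' @param seed integer master seed.
#' @param nPhages number of phages (default 50).
#' @param proteinsPerPhage proteins per phage (default 10).
#' @param sharedProteinFraction probability a phage protein is reused
#'   verbatim from an already generated one (default 0.05).
#' @param proteinLengthRange amino-acid length range (default 150--400).
#' @param epitopeRate expected planted epitopes per 100 aa (default 3).
#' @param epitopeWidth planted epitope width in aa (default 14, the span
#'   covering 80\% of the mean alanine-scan disruption curve).
#' @param compositionShift named per-amino-acid log-enrichments applied
#'   inside epitopes (default: elevated K, S/T/A and charged residues,
#'   depleted hydrophobics) and renormalized to a proper distribution.
#' @param cohortSize number of serum samples (default 20).
#' @param seroprevalence probability a sample reacts to a given planted
#'   epitope (default 0.3).
#' @param reactivePhageFraction fraction of phages whose epitopes are
#'   immunogenic at all (default 0.2); the rest form the null.
#' @param depth mean reads per peptide (default 100).
#' @param noiseDispersion negative-binomial overdispersion of counts
#'   (default 0.25; variance = mu + dispersion * mu^2).
#' @param enrichFold mean fold enrichment of a reactive peptide over
#'   background (default 20).
#' @param mockReplicates bead-only background columns (default 8).
#' @param effectMean,effectSd mean/sd of log-hfc for reactive scan
#'   peptides (defaults 3, 0.5).
#' @param scanNoiseSd sd of alanine-scan measurement noise (default 0.2).
#' @param falsePositiveRate per-cell probability of spurious scan
#'   reactivity (default 0.002).
#' @return A list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(seed = 1L, nPhages = 50L, proteinsPerPhage = 10L,
                        sharedProteinFraction = 0.05,
                        proteinLengthRange = c(150L, 400L),
                        epitopeRate = 3, epitopeWidth = 14L,
                        compositionShift = NULL, cohortSize = 20L,
                        seroprevalence = 0.3, reactivePhageFraction = 0.2,
                        depth = 100, noiseDispersion = 0.25,
                        enrichFold = 20, mockReplicates = 8L,
                        effectMean = 3, effectSd = 0.5, scanNoiseSd = 0.2,
                        falsePositiveRate = 0.002) {
  if (is.null(compositionShift)) {
    compositionShift <- c(
      K = 1.2, R = 0.6, D = 0.6, E = 0.6,
      S = 0.9, T = 0.9, A = 0.9, N = 0.3, Q = 0.3,
      I = -0.8, L = -0.8, V = -0.8, F = -0.8, M = -0.8, W = -0.8)
  }
  stopifnot(seroprevalence >= 0, seroprevalence <= 1,
            epitopeRate >= 0, epitopeWidth >= 1,
            proteinLengthRange[1] <= proteinLengthRange[2],
            epitopeWidth <= proteinLengthRange[1])
  structure(as.list(environment()), class = "SynthConfig")
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# background and epitope residue distributions implied by a config
.compositions <- function(config) {
  bg <- rep(1 / 20, 20); names(bg) <- .AA20
  shift <- rep(0, 20); names(shift) <- .AA20
  shift[names(config$compositionShift)] <- config$compositionShift
  epi <- bg * exp(shift)
  epi <- epi / sum(epi)
  list(background = bg, epitope = epi)
}

.sampleResidues <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a synthetic phage proteome with planted epitopes
#'
#' Proteins are drawn from a background residue composition; epitope
#' intervals with shifted composition are planted at non-overlapping
#' random offsets (Poisson number per protein at the configured rate); a
#' configurable fraction of proteins is shared verbatim across phages,
#' emulating the homology structure of metagenome-derived phage protein
#' sets. Each distinct protein is its own cluster (clusters are consumed
#' upstream, not computed here).
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list with \code{proteins} (data.frame \code{id}, \code{seq},
#'   \code{group_id}, \code{phages}) and \code{epitopes} (data.frame
#'   \code{epitope_id}, \code{group_id}, \code{start}, \code{end} 0-based
#'   half-open, \code{seq}).
#' @export
generateProteome <- function(config = synthConfig()) {
  set.seed(config$seed)
  comp <- .compositions(config)
  w <- config$epitopeWidth
  proteins <- list()
  epitopes <- list()
  for (ph in seq_len(config$nPhages)) {
    phage <- sprintf("phage_%03d", ph)
    for (k in seq_len(config$proteinsPerPhage)) {
      if (length(proteins) > 0 &&
          stats::runif(1) < config$sharedProteinFraction) {
        i <- sample.int(length(proteins), 1L)
        proteins[[i]]$phages <- union(proteins[[i]]$phages, phage)
        next
      }
      L <- sample(config$proteinLengthRange[1]:config$proteinLengthRange[2],
                  1L)
      seqCh <- strsplit(.sampleResidues(L, comp$background), "")[[1]]
      nEpi <- stats::rpois(1L, config$epitopeRate * L / 100)
      starts <- integer(0)
      attempts <- 0L
      while (length(starts) < nEpi && attempts < 50L * max(nEpi, 1L)) {
        s <- sample.int(L - w + 1L, 1L) - 1L
        if (!length(starts) || all(abs(s - starts) >= w))
          starts <- c(starts, s)
        attempts <- attempts + 1L
      }
      pid <- sprintf("prot_%05d", length(proteins) + 1L)
      for (s in sort(starts)) {
        eseq <- .sampleResidues(w, comp$epitope)
        seqCh[(s + 1L):(s + w)] <- strsplit(eseq, "")[[1]]
        epitopes[[length(epitopes) + 1L]] <- data.frame(
          epitope_id = sprintf("%s_e%d", pid, s), group_id = pid,
          start = s, end = s + w, seq = eseq, stringsAsFactors = FALSE)
      }
      proteins[[length(proteins) + 1L]] <- list(
        id = pid, seq = paste(seqCh, collapse = ""), phages = phage)
    }
  }
  prot <- data.frame(
    id = vapply(proteins, `[[`, "", "id"),
    seq = vapply(proteins, `[[`, "", "seq"),
    group_id = vapply(proteins, `[[`, "", "id"),
    phages = vapply(proteins, function(p)
      paste(sort(p$phages), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  epi <- if (length(epitopes)) do.call(rbind, epitopes) else
    data.frame(epitope_id = character(0), group_id = character(0),
               start = integer(0), end = integer(0), seq = character(0))
  rownames(epi) <- NULL
  list(proteins = prot, epitopes = epi)
}

#' Generate a synthetic scan-library reactivity dataset
#'
#' Emulates the readout of a public-epitope scan library: 56-mer wildtype
#' peptides each carrying one planted composition-shifted epitope at a
#' random offset, a k-mer scan (sub-peptides of lengths 15--45 starting
#' every 5 aa) and a triple-alanine scan, read out in a cohort. A scan
#' sub-peptide is reactive in a sample iff it fully contains the planted
#' epitope and the sample is seropositive for that wildtype (plus a small
#' false-positive rate); alanine variants lose reactivity iff the
#' substituted 3-mer intersects the epitope. Bead-background counts for
#' every k-mer come from the count model.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param nWildtypes number of wildtype 56-mers (default 357).
#' @param lengths k-mer scan lengths (default 15, 20, ..., 45).
#' @return list with \code{wildtypes} (id, seq, epitope_start),
#'   \code{seropositive} (wildtype x sample logical), \code{kmer}
#'   (data.frame: seq, wildtype_id, k, start, one log-hfc column per
#'   sample), \code{bead} (seq, count), and \code{alanine} (list:
#'   \code{variantMat} 54 x nCurves, \code{wildtypeVals},
#'   \code{curveInfo}).
#' @export
generateScanDataset <- function(config = synthConfig(), nWildtypes = 357L,
                                lengths = seq(15L, 45L, by = 5L)) {
  set.seed(config$seed)
  comp <- .compositions(config)
  w <- config$epitopeWidth
  nS <- config$cohortSize
  sampleIds <- sprintf("S%02d", seq_len(nS))

  wt <- data.frame(
    id = sprintf("wt_%05d", seq_len(nWildtypes)),
    seq = NA_character_, epitope_start = NA_integer_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nWildtypes)) {
    ch <- strsplit(.sampleResidues(56L, comp$background), "")[[1]]
    a <- sample.int(56L - w + 1L, 1L) - 1L
    ch[(a + 1L):(a + w)] <- strsplit(.sampleResidues(w, comp$epitope),
                                     "")[[1]]
    wt$seq[i] <- paste(ch, collapse = "")
    wt$epitope_start[i] <- a
  }
  seropos <- matrix(stats::runif(nWildtypes * nS) < config$seroprevalence,
                    nrow = nWildtypes,
                    dimnames = list(wt$id, sampleIds))

  kmerRows <- do.call(rbind, lapply(lengths, function(k) {
    starts <- seq.int(0L, 56L - k, by = 5L)
    data.frame(
      wildtype_id = rep(wt$id, each = length(starts)),
      k = k, start = rep(starts, times = nWildtypes),
      stringsAsFactors = FALSE)
  }))
  wtIdx <- match(kmerRows$wildtype_id, wt$id)
  kmerRows$seq <- substring(wt$seq[wtIdx], kmerRows$start + 1L,
                            kmerRows$start + kmerRows$k)
  a <- wt$epitope_start[wtIdx]
  contains <- kmerRows$start <= a & kmerRows$start + kmerRows$k >= a + w
  nR <- nrow(kmerRows)
  vals <- matrix(0, nrow = nR, ncol = nS, dimnames = list(NULL, sampleIds))
  reactive <- contains & seropos[cbind(rep(wtIdx, nS),
                                       rep(seq_len(nS), each = nR))]
  dim(reactive) <- c(nR, nS)
  fp <- matrix(stats::runif(nR * nS) < config$falsePositiveRate, nR, nS)
  react <- reactive | fp
  vals[react] <- stats::rnorm(sum(react), config$effectMean, config$effectSd)
  vals[vals < 0] <- 0
  kmer <- cbind(kmerRows[, c("seq", "wildtype_id", "k", "start")],
                as.data.frame(vals))

  bead <- data.frame(
    seq = kmer$seq,
    count = stats::rnbinom(nR, mu = config$depth,
                           size = 1 / config$noiseDispersion),
    stringsAsFactors = FALSE)
  bead <- bead[!duplicated(bead$seq), ]

  # alanine scan: one curve per seropositive (wildtype, sample) pair
  pairs <- which(seropos, arr.ind = TRUE)
  nC <- nrow(pairs)
  variantMat <- matrix(NA_real_, nrow = 54L, ncol = nC)
  wildtypeVals <- numeric(nC)
  for (j in seq_len(nC)) {
    i <- pairs[j, 1]
    wtVal <- stats::rnorm(1, config$effectMean, config$effectSd)
    aPos <- wt$epitope_start[i]
    disrupted <- (0:53) + 2L >= aPos & (0:53) <= aPos + w - 1L
    v <- wtVal + stats::rnorm(54L, 0, config$scanNoiseSd)
    v[disrupted] <- stats::rnorm(sum(disrupted), 0, config$scanNoiseSd)
    variantMat[, j] <- pmax(v, 0)
    wildtypeVals[j] <- wtVal
  }
  curveInfo <- data.frame(wildtype_id = wt$id[pairs[, 1]],
                          sample = sampleIds[pairs[, 2]],
                          stringsAsFactors = FALSE)

  list(wildtypes = wt, seropositive = seropos, kmer = kmer, bead = bead,
       alanine = list(variantMat = variantMat,
                      wildtypeVals = wildtypeVals, curveInfo = curveInfo))
}

# windows displayed by a manifest peptide, as (source group, start, width)
.peptideWindows <- function(man, proteins) {
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    mode <- man$mode[i]
    if (mode == "tiling") {
      out[[i]] <- data.frame(group = man$source_group[i],
                             start = man$start[i], width = 56L)
    } else if (mode == "stitched") {
      st <- as.integer(strsplit(man$epitope_starts[i], ";", fixed = TRUE)[[1]])
      out[[i]] <- data.frame(group = man$source_group[i], start = st,
                             width = 15L)
    } else {
      groups <- strsplit(man$groups[i], ";", fixed = TRUE)[[1]]
      rows <- list()
      for (g in groups) {
        rseq <- proteins$seq[match(g, proteins$group_id)]
        p <- regexpr(man$aa_seq[i], rseq, fixed = TRUE)
        if (p > 0) rows[[length(rows) + 1L]] <-
          data.frame(group = g, start = as.integer(p) - 1L,
                     width = nchar(man$aa_seq[i]))
      }
      out[[i]] <- if (length(rows)) do.call(rbind, rows) else
        data.frame(group = character(0), start = integer(0),
                   width = integer(0))
    }
  }
  out
}

#' Simulate a PhIP-Seq screen of a designed library
#'
#' Generates overdispersed (negative-binomial) sequencing counts for every
#' manifest peptide: bead-only mock columns at the background depth, and
#' serum columns in which peptides displaying a seropositive planted
#' epitope are enriched. A subset of phages (the planted reactive phages)
#' carries immunogenic epitopes; a peptide displays an epitope when one of
#' its windows overlaps the planted interval by at least
#' \code{minOverlap} residues. Fold changes and p-values then come from
#' \code{\link{simpleFoldTest}}, so the whole screening readout is
#' reproduced end to end.
#'
#' @param library a \code{\linkS4class{PeptideLibrary}} or manifest
#'   data.frame.
#' @param proteome output of \code{\link{generateProteome}} (ground
#'   truth).
#' @param config a \code{\link{synthConfig}}.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @param minOverlap minimum window/epitope overlap in aa (default 10).
#' @return list with \code{rset} (a \code{\linkS4class{ReactivitySet}}),
#'   \code{mockCounts}, \code{enriched} (peptide x sample truth),
#'   \code{seropositive} (epitope x sample), \code{reactivePhages}.
#' @export
simulatePhipseq <- function(library, proteome, config = synthConfig(),
                            seed = config$seed, minOverlap = 10L) {
  man <- if (is(library, "PeptideLibrary")) manifest(library) else library
  if (!nrow(man)) stop("empty library manifest")
  set.seed(seed)
  nS <- config$cohortSize
  sampleIds <- sprintf("S%02d", seq_len(nS))
  epi <- proteome$epitopes
  prot <- proteome$proteins

  phages <- sort(unique(unlist(strsplit(prot$phages, ";", fixed = TRUE))))
  nReactive <- max(1L, round(config$reactivePhageFraction * length(phages)))
  reactivePhages <- sort(sample(phages, nReactive))

  protPhages <- strsplit(prot$phages, ";", fixed = TRUE)
  groupReactive <- vapply(protPhages,
                          function(p) any(p %in% reactivePhages), TRUE)
  names(groupReactive) <- prot$group_id
  epiEligible <- groupReactive[epi$group_id]
  seropos <- matrix(FALSE, nrow = nrow(epi), ncol = nS,
                    dimnames = list(epi$epitope_id, sampleIds))
  if (any(epiEligible)) {
    n <- sum(epiEligible)
    seropos[epiEligible, ] <-
      stats::runif(n * nS) < config$seroprevalence
  }

  windows <- .peptideWindows(man, prot)
  epiByGroup <- split(seq_len(nrow(epi)), epi$group_id)
  enriched <- matrix(FALSE, nrow = nrow(man), ncol = nS,
                     dimnames = list(man$peptide_id, sampleIds))
  for (i in seq_len(nrow(man))) {
    wdf <- windows[[i]]
    if (!nrow(wdf)) next
    hitEpis <- integer(0)
    for (r in seq_len(nrow(wdf))) {
      cand <- epiByGroup[[wdf$group[r]]]
      if (is.null(cand)) next
      ov <- pmin(epi$end[cand], wdf$start[r] + wdf$width[r]) -
        pmax(epi$start[cand], wdf$start[r])
      hitEpis <- union(hitEpis, cand[ov >= minOverlap])
    }
    if (length(hitEpis))
      enriched[i, ] <- apply(seropos[hitEpis, , drop = FALSE], 2L, any)
  }

  nP <- nrow(man)
  size <- 1 / config$noiseDispersion
  mockCounts <- matrix(
    stats::rnbinom(nP * config$mockReplicates, mu = config$depth,
                   size = size),
    nrow = nP,
    dimnames = list(man$peptide_id,
                    sprintf("mock%d", seq_len(config$mockReplicates))))
  mu <- config$depth * (1 + config$enrichFold * enriched)
  counts <- matrix(stats::rnbinom(nP * nS, mu = mu, size = size),
                   nrow = nP, dimnames = list(man$peptide_id, sampleIds))
  ft <- simpleFoldTest(counts, mockCounts)
  rset <- ReactivitySet(counts, ft$log2fc, ft$pvals,
                        peptides = data.frame(peptide_id = man$peptide_id,
                                              aa_seq = man$aa_seq,
                                              phages = man$phages,
                                              stringsAsFactors = FALSE))
  list(rset = rset, mockCounts = mockCounts, enriched = enriched,
       seropositive = seropos, reactivePhages = reactivePhages)
}
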