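
#' Epitope classifier model
#'
#' S4 container for a trained per-length random-forest epitope classifier:
#' the forest itself, the peptide length it applies to, the training seed,
#' the 556-feature schema it expects and the out-of-bag AUC recorded at
#' training time.
#'
#' @slot forest the trained \code{\link[randomForest]{randomForest}} object.
#' @slot peptideLength integer; peptide length k the model scores.
#' @slot seed integer seed used for training.
#' @slot featureSchema character vector of the 556 feature names, in order.
#' @slot oobAUC numeric; out-of-bag AUC on the training data.
#' @exportClass EpitopeModel
setClass("EpitopeModel",
  representation(
    forest = "ANY",
    peptideLength = "integer",
    seed = "integer",
    featureSchema = "character",
    oobAUC = "numeric"
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@featureSchema) != 556L)
      msg <- c(msg, "featureSchema must have exactly 556 entries")
    if (length(object@peptideLength) != 1L || object@peptideLength < 2L)
      msg <- c(msg, "peptideLength must be a single integer >= 2")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "EpitopeModel", function(object) {
  cat("EpitopeModel (random forest,",
      object@forest$ntree, "trees)\n")
  cat("  peptide length:", object@peptideLength, "aa\n")
  cat("  features:      ", length(object@featureSchema), "\n")
  cat("  OOB AUC:       ", round(object@oobAUC, 3), "\n")
})

#' @describeIn EpitopeModel-class peptide length the model scores
#' @param object an \code{EpitopeModel}
#' @export
peptideLength <- function(object) object@peptideLength

#' @describeIn EpitopeModel-class out-of-bag AUC recorded at training
#' @export
oobAUC <- function(object) object@oobAUC

#' Build a balanced epitope training set from scan reactivity
#'
#' Positives are k-mers reactive (log hit-fold-change > 0) in at least two
#' samples; negatives are k-mers with no reactivity in any sample, ranked by
#' descending count on the empty-bead background samples (high bead count
#' guards against peptides that fail for technical display reasons) and
#' truncated to the number of positives, so the classes are balanced by
#' construction. K-mers reactive in exactly one sample belong to neither
#' class.
#'
#' @param kmerReactivity data.frame with columns \code{seq},
#'   \code{wildtype_id} and one numeric log-hfc column per sample.
#' @param beadCounts data.frame with columns \code{seq}, \code{count}
#'   (summed bead-background counts per k-mer).
#' @return data.frame with columns \code{seq}, \code{wildtype_id},
#'   \code{label} (1 = epitope, 0 = non-reactive),
#'   \code{n_reactive_samples}, \code{bead_count}.
#' @export
buildTrainingSet <- function(kmerReactivity, beadCounts) {
  stopifnot(all(c("seq", "wildtype_id") %in% names(kmerReactivity)),
            all(c("seq", "count") %in% names(beadCounts)))
  sampleCols <- setdiff(names(kmerReactivity), c("seq", "wildtype_id"))
  if (!length(sampleCols)) stop("kmerReactivity has no sample columns")
  vals <- as.matrix(kmerReactivity[, sampleCols, drop = FALSE])
  if (anyNA(vals)) stop("per-sample log-hfc values must be complete")
  nReact <- rowSums(vals > 0)

  pos <- kmerReactivity[nReact >= 2L, c("seq", "wildtype_id")]
  pos$label <- 1L
  pos$n_reactive_samples <- nReact[nReact >= 2L]

  negAll <- kmerReactivity[nReact == 0L, c("seq", "wildtype_id")]
  bead <- beadCounts$count[match(negAll$seq, beadCounts$seq)]
  bead[is.na(bead)] <- 0
  ord <- order(-bead, negAll$seq)  # bead count desc, ties lexicographic
  if (nrow(pos) > nrow(negAll))
    stop(sprintf("only %d eligible negatives for %d positives",
                 nrow(negAll), nrow(pos)))
  keep <- ord[seq_len(nrow(pos))]
  neg <- negAll[keep, ]
  neg$label <- 0L
  neg$n_reactive_samples <- 0L

  pos$bead_count <- beadCounts$count[match(pos$seq, beadCounts$seq)]
  pos$bead_count[is.na(pos$bead_count)] <- 0
  neg$bead_count <- bead[keep]
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Group-wise train/test split by wildtype parent
#'
#' Scan sub-peptides of one 56-mer wildtype are near-duplicates of each
#' other, so the split assigns whole wildtype groups: groups are taken in a
#' seeded random order and added to the test set until it covers at least
#' \code{testFraction} of the examples. Train and test wildtype sets are
#' disjoint for every seed.
#'
#' @param examples data.frame carrying a \code{wildtype_id} column.
#' @param testFraction target test share (default 0.05).
#' @param seed integer seed for the group order.
#' @return list with data.frames \code{train} and \code{test}.
#' @export
splitByWildtype <- function(examples, testFraction = 0.05, seed = 42) {
  stopifnot("wildtype_id" %in% names(examples))
  groups <- unique(examples$wildtype_id)
  if (testFraction <= 0)
    return(list(train = examples, test = examples[0, , drop = FALSE]))
  if (length(groups) < 2L)
    stop("cannot split: all examples share a single wildtype")
  set.seed(seed)
  ord <- sample(groups)
  sizes <- table(examples$wildtype_id)[ord]
  target <- testFraction * nrow(examples)
  cum <- cumsum(as.numeric(sizes))
  nTest <- which(cum >= target)[1]
  if (nTest >= length(groups)) nTest <- length(groups) - 1L
  testGroups <- ord[seq_len(nTest)]
  inTest <- examples$wildtype_id %in% testGroups
  list(train = examples[!inTest, , drop = FALSE],
       test = examples[inTest, , drop = FALSE])
}

#' Train a per-length epitope classifier
#'
#' Fits a 100-tree impurity-split random forest on the 556 composition
#' features of the training peptides. All forest hyperparameters are the
#' package defaults; only the tree count and the seed are pinned, so
#' retraining with the same data and seed reproduces identical predictions.
#'
#' @param examples data.frame with \code{seq} and binary \code{label}
#'   columns; all sequences must have length \code{k} and both classes must
#'   be present.
#' @param k peptide length the model applies to (default 15).
#' @param ntree number of trees (default 100).
#' @param seed RNG seed (default 42).
#' @param scheme an \code{\link{alphabetScheme}}.
#' @return An \code{\linkS4class{EpitopeModel}}.
#' @export
trainEpitopeModel <- function(examples, k = 15L, ntree = 100L, seed = 42L,
                              scheme = alphabetScheme()) {
  stopifnot(all(c("seq", "label") %in% names(examples)))
  if (length(unique(examples$label)) < 2L)
    stop("training data must contain both classes")
  if (any(table(examples$label) < 2L))
    stop("need at least 2 examples per class")
  if (!all(nchar(examples$seq) == k))
    stop(sprintf("all training sequences must have length %d", k))
  x <- featurizeMatrix(examples$seq, scheme)
  y <- factor(examples$label, levels = c(0, 1))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                   importance = FALSE, keep.forest = TRUE)
  oobProb <- rf$votes[, "1"]
  oob <- rocCurve(as.integer(as.character(y)), oobProb)$auc
  new("EpitopeModel", forest = rf, peptideLength = as.integer(k),
      seed = as.integer(seed), featureSchema = colnames(x), oobAUC = oob)
}

#' Epitope probability of peptides
#'
#' The fraction of forest trees voting "epitope" for each peptide; always in
#' [0, 1] and deterministic for a fixed model.
#'
#' @param model an \code{\linkS4class{EpitopeModel}}.
#' @param seqs character vector of peptides, each of the model's length.
#' @param scheme an \code{\link{alphabetScheme}}.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predictEpitopeProb <- function(model, seqs, scheme = alphabetScheme()) {
  bad <- nchar(seqs) != model@peptideLength
  if (any(bad))
    stop(sprintf("sequence length %d does not match model peptide length %d",
                 nchar(seqs[bad][1]), model@peptideLength))
  x <- featurizeMatrix(seqs, scheme)
  unname(predict(model@forest, x, type = "prob")[, "1"])
}

#' Score a long peptide as the mean over its k-mer windows
#'
#' For peptides longer than the model's length (e.g. 56-mers scored with a
#' 15-mer model) the epitope probability is the mean over all step-1
#' length-k windows.
#'
#' @inheritParams predictEpitopeProb
#' @param seq one amino-acid string with length >= the model's peptide
#'   length.
#' @return A single probability in [0, 1].
#' @export
scoreLongPeptide <- function(model, seq, scheme = alphabetScheme()) {
  k <- model@peptideLength
  L <- nchar(seq)
  if (L < k) stop(sprintf("sequence length %d < model peptide length %d", L, k))
  starts <- seq_len(L - k + 1L)
  windows <- substring(seq, starts, starts + k - 1L)
  mean(predictEpitopeProb(model, windows, scheme))
}

#' Impurity-based feature importance
#'
#' Mean decrease in node impurity per feature, normalized to sum to one and
#' returned in descending order.
#'
#' @param model an \code{\linkS4class{EpitopeModel}}.
#' @return data.frame with columns \code{feature}, \code{importance}
#'   (non-negative, summing to 1), sorted descending.
#' @export
featureImportance <- function(model) {
  if (is.null(model@forest$importance)) stop("model carries no forest")
  imp <- model@forest$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

#' Empirical ROC curve and AUC
#'
#' AUC equals the normalized Mann-Whitney U statistic (midranks for tied
#' scores); the curve is the empirical ROC over unique score thresholds.
#'
#' @param labels binary vector (0/1), both classes present.
#' @param scores numeric scores, higher = more positive.
#' @return list with \code{points} (data.frame of \code{fpr}, \code{tpr})
#'   and \code{auc}.
#' @export
rocCurve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), 0)
  list(points = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)),
       auc = auc)
}
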