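#' Names of the 556 composition features
#'
#' The feature layout is fixed so that serialized models remain stable:
#' 20 single amino-acid counts, 400 ordered adjacent amino-acid pair counts,
#' 11 DIAMOND-group counts, 121 ordered adjacent DIAMOND-pair counts and 4
#' side-chain-class counts (20 + 400 + 11 + 121 + 4 = 556), alphabetical
#' within each block. DIAMOND features carry a \code{d_} prefix, side-chain
#' features an \code{sc_} prefix, pair features join the two symbols with
#' \code{"."}.
#'
#' @param scheme an \code{\link{alphabetScheme}}.
#' @return Character vector of 556 feature names.
#' @export
featureNames556 <- function(scheme = alphabetScheme()) {
  aa <- scheme$natural
  dg <- scheme$diamondLabels
  sc <- scheme$sidechainLabels
  aaPairs <- as.vector(t(outer(aa, aa, paste, sep = ".")))
  dgPairs <- as.vector(t(outer(dg, dg, paste, sep = ".")))
  c(aa,
    sort(aaPairs),
    paste0("d_", dg),
    paste0("d_", sort(dgPairs)),
    paste0("sc_", sc))
}

.countBlock <- function(ch, labels) {
  tab <- tabulate(factor(ch, levels = labels), nbins = length(labels))
  names(tab) <- labels
  tab
}

.pairBlock <- function(ch, labels, sep = ".") {
  n <- length(ch)
  pairs <- paste(ch[-n], ch[-1], sep = sep)
  lev <- sort(as.vector(outer(labels, labels, paste, sep = sep)))
  tab <- tabulate(factor(pairs, levels = lev), nbins = length(lev))
  names(tab) <- lev
  tab
}

#' Composition feature vector of a peptide
#'
#' Converts a peptide amino-acid sequence into the 556-dimensional raw-count
#' composition vector used by the epitope classifier: single amino-acid
#' counts, ordered adjacent amino-acid pair counts, and the same two levels
#' for the 11-group DIAMOND reduced alphabet, plus 4 side-chain-class
#' counts. Counts are not normalized by peptide length (a single-letter
#' feature of a 15-mer maxes out at 15).
#'
#' @param seq a single amino-acid string, length >= 2, over the 20 standard
#'   letters. Non-standard letters (B, J, O, U, X, Z) are rejected with the
#'   offending position reported.
#' @param scheme an \code{\link{alphabetScheme}}.
#' @return Named integer vector of length 556 in the fixed
#'   \code{\link{featureNames556}} order. Single-letter blocks each sum to
#'   the peptide length; pair blocks sum to length - 1.
#' @examples
#' fv <- featurizePeptide("KSKSKSKSKSKSKSK")
#' fv[["K"]]; fv[["d_STA"]]
#' @export
featurizePeptide <- function(seq, scheme = alphabetScheme()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 2L) stop("peptide must have length >= 2")
  ch <- .splitValidate(seq, scheme$natural)[[1]]
  dch <- unname(scheme$diamondGroups[ch])
  sch <- unname(scheme$sidechainClasses[ch])
  out <- c(
    .countBlock(ch, scheme$natural),
    .pairBlock(ch, scheme$natural),
    .countBlock(dch, scheme$diamondLabels),
    .pairBlock(dch, scheme$diamondLabels),
    .countBlock(sch, scheme$sidechainLabels)
  )
  names(out) <- featureNames556(scheme)
  out
}

#' Featurize many peptides into a matrix
#'
#' Row-binds \code{\link{featurizePeptide}} over a character vector; the
#' workhorse for classifier training and window scoring.
#'
#' @param seqs character vector of peptides (all length >= 2).
#' @param scheme an \code{\link{alphabetScheme}}.
#' @return Integer matrix, one row per peptide, 556 named columns.
#' @export
featurizeMatrix <- function(seqs, scheme = alphabetScheme()) {
  stopifnot(length(seqs) >= 1L)
  fn <- featureNames556(scheme)
  m <- matrix(0L, nrow = length(seqs), ncol = length(fn),
              dimnames = list(names(seqs), fn))
  for (i in seq_along(seqs)) m[i, ] <- featurizePeptide(seqs[[i]], scheme)
  m
}
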