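#' Amino-acid alphabet schemes for composition features
#'
#' An alphabet scheme bundles the three alphabets the composition featurizer
#' counts over: the 20 natural amino acids, an 11-group reduced alphabet
#' (the DIAMOND reduction used for seed matching in homology search), and a
#' 4-class side-chain partition (positively charged, negatively charged,
#' polar uncharged, nonpolar).
#'
#' @section Reduced alphabets:
#' The 11 DIAMOND groups are \code{\{K,R,E,D,Q,N\}}, \code{\{S,T,A\}},
#' \code{\{I,L,V\}} and the singletons C, G, H, M, F, Y, W, P. Each group is
#' labelled by the concatenation of its members (e.g. \code{"KREDQN"},
#' \code{"STA"}).
#'
#' The side-chain classes are: positive \code{\{K,R,H\}}, negative
#' \code{\{D,E\}}, polar uncharged \code{\{S,T,N,Q,C,Y\}} and nonpolar
#' \code{\{G,A,V,L,I,P,F,M,W\}}. The assignment of C and Y to the polar
#' uncharged class is configurable via the \code{sidechainClasses} argument.
#'
#' @param sidechainClasses optional named character vector mapping each of
#'   the 20 amino-acid letters to one of \code{"positive"}, \code{"negative"},
#'   \code{"polar"}, \code{"nonpolar"}; defaults to the standard partition
#'   above.
#' @return A list of class \code{"AlphabetScheme"} with elements
#'   \code{natural} (ordered 20 letters), \code{diamondGroups} (named map
#'   letter -> group label), \code{sidechainClasses} (named map letter ->
#'   class label), and the ordered label sets \code{diamondLabels},
#'   \code{sidechainLabels}.
#' @examples
#' sch <- alphabetScheme()
#' sch$diamondGroups[["K"]]  # "KREDQN"
#' @export
alphabetScheme <- function(sidechainClasses = NULL) {
  natural <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  groups <- list(
    KREDQN = c("K", "R", "E", "D", "Q", "N"),
    C = "C", G = "G", H = "H",
    ILV = c("I", "L", "V"),
    M = "M", F = "F", Y = "Y", W = "W", P = "P",
    STA = c("S", "T", "A")
  )
  diamond <- character(0)
  for (g in names(groups)) diamond[groups[[g]]] <- g
  diamond <- diamond[natural]

  if (is.null(sidechainClasses)) {
    sidechainClasses <- c(
      K = "positive", R = "positive", H = "positive",
      D = "negative", E = "negative",
      S = "polar", T = "polar", N = "polar", Q = "polar",
      C = "polar", Y = "polar",
      G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
      I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
      W = "nonpolar"
    )
  }
  if (!setequal(names(sidechainClasses), natural))
    stop("sidechainClasses must cover exactly the 20 standard amino acids")
  sidechainClasses <- sidechainClasses[natural]

  structure(
    list(
      natural = natural,
      diamondGroups = diamond,
      sidechainClasses = sidechainClasses,
      diamondLabels = sort(names(groups)),
      sidechainLabels = sort(unique(sidechainClasses))
    ),
    class = "AlphabetScheme"
  )
}

#' @export
print.AlphabetScheme <- function(x, ...) {
  cat("AlphabetScheme: 20 natural letters,",
      length(x$diamondLabels), "DIAMOND groups,",
      length(x$sidechainLabels), "side-chain classes\n")
  invisible(x)
}

# Split peptides into per-position letter vectors, validating the alphabet.
# Reports the 1-based position of the first offending character.
.splitValidate <- function(seq, natural) {
  chars <- strsplit(seq, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!(chars[[i]] %in% natural))
    if (length(bad))
      stop(sprintf("non-standard amino acid '%s' at position %d of sequence %d",
                   chars[[i]][bad[1]], bad[1], i))
  }
  chars
}

#' Reduce an amino-acid sequence to DIAMOND group labels
#'
#' Maps each residue to its 11-group reduced-alphabet label. Useful for
#' inspecting which composition group a stretch of sequence falls in.
#'
#' @param seq character vector of amino-acid sequences.
#' @param scheme an \code{\link{alphabetScheme}}.
#' @return A list (one element per input sequence) of character vectors of
#'   group labels, same length as the input sequence.
#' @examples
#' reduceSequence("KR")[[1]]  # both "KREDQN"
#' @export
reduceSequence <- function(seq, scheme = alphabetScheme()) {
  chars <- .splitValidate(seq, scheme$natural)
  lapply(chars, function(ch) unname(scheme$diamondGroups[ch]))
}
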