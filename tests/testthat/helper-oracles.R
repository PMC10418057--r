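# Independent oracles and small fixture builders shared across tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomPeptides <- function(n, lengths, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- if (length(lengths) == 1L) lengths else sample(lengths, 1L)
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, "")
}

# naive double-loop feature counter, independent of featurizePeptide
naiveFeaturize <- function(seq, scheme = alphabetScheme()) {
  ch <- strsplit(seq, "")[[1]]
  fn <- featureNames556(scheme)
  out <- setNames(integer(length(fn)), fn)
  for (a in ch) {
    out[a] <- out[a] + 1L
    out[paste0("d_", scheme$diamondGroups[[a]])] <-
      out[paste0("d_", scheme$diamondGroups[[a]])] + 1L
    out[paste0("sc_", scheme$sidechainClasses[[a]])] <-
      out[paste0("sc_", scheme$sidechainClasses[[a]])] + 1L
  }
  for (i in seq_len(length(ch) - 1L)) {
    out[paste(ch[i], ch[i + 1L], sep = ".")] <-
      out[paste(ch[i], ch[i + 1L], sep = ".")] + 1L
    dp <- paste0("d_", scheme$diamondGroups[[ch[i]]], ".",
                 scheme$diamondGroups[[ch[i + 1L]]])
    out[dp] <- out[dp] + 1L
  }
  out
}

# brute-force uniform tiler: enumerate regular starts, then the catch-up tile
bruteTile <- function(L, tileLen = 56L, overlap = 28L) {
  step <- tileLen - overlap
  starts <- integer(0)
  s <- 0L
  while (s + tileLen <= L) { starts <- c(starts, s); s <- s + step }
  if (starts[length(starts)] + tileLen < L) starts <- c(starts, L - tileLen)
  starts
}

# greedy non-overlap selection, re-implemented directly from the rule
bruteSelect <- function(windows, probCutoff = 0.5, k = 15L) {
  cand <- windows[windows$prob > probCutoff, , drop = FALSE]
  picked <- windows[0, , drop = FALSE]
  while (nrow(cand)) {
    best <- which(cand$prob == max(cand$prob))
    best <- best[which.min(cand$start[best])]
    picked <- rbind(picked, cand[best, ])
    cand <- cand[abs(cand$start - cand$start[best]) >= k, , drop = FALSE]
  }
  picked
}

# expected alanine-scan disruption curve: convolution of the epitope
# indicator with the 3-residue substitution window
convolutionCurve <- function(epitopeStart, width, nPos = 54L) {
  starts <- 0:(nPos - 1L)
  as.numeric(starts + 2L >= epitopeStart &
               starts <= epitopeStart + width - 1L)
}

# stub model whose windows all score a constant (for mean-score contracts)
constantModel <- function(p, k = 15L) {
  structure(list(prob = p, k = k), class = "constantStub")
}
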