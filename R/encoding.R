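# Default synthesis dialect of the main (gut phage) library:
# 168-nt insert, 16-nt PCR adapters on both sides, 200-nt oligo.
.DEFAULT_PREFIX <- "AGGAATTCCGCTGCGT"
.DEFAULT_SUFFIX <- "ATGGTCACAGCTGTGC"
.FORBIDDEN <- c("GAATTC", "AAGCTT")  # EcoRI, HindIII cloning sites

# Fixed linker DNA used to pad variable-length inserts in the enterovirus
# dialect (its prefix of the required length is used).
.LINKER_DNA <- paste0(
  "GCAAGTCCTGCAGCTCCAGCCCCTGCAAGCCCAGCAGCTCCAGCACCAAGTGCACCTG",
  "CTGGCGGAGGAGGTTCTGGCGGGGGCGGGAGC")

#' Read a codon usage table
#'
#' Loads a per-amino-acid codon usage TSV (columns \code{aa}, \code{codon},
#' \code{fraction}; stop codons under aa \code{"*"}). Fractions must sum to
#' 1 within each amino acid. The package ships a standard E. coli K-12
#' usage table as the default.
#'
#' @param path path to the TSV; defaults to the shipped E. coli table.
#' @return list with \code{entries} (named list: amino acid ->
#'   data.frame(codon, fraction)) and \code{stopCodons}.
#' @export
readCodonTable <- function(path = system.file("extdata",
                                              "ecoli_codon_usage.tsv",
                                              package = "epistitch")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("aa", "codon", "fraction") %in% names(tab)))
  sums <- tapply(tab$fraction, tab$aa, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("per-amino-acid codon fractions must sum to 1")
  entries <- split(tab[, c("codon", "fraction")], tab$aa)
  stopCodons <- entries[["*"]]$codon
  entries[["*"]] <- NULL
  list(entries = entries, stopCodons = stopCodons)
}

# codons above the frequency threshold, renormalized
.allowedCodons <- function(table, aa, minFreq) {
  e <- table$entries[[aa]]
  if (is.null(e)) stop(sprintf("codon table has no entry for '%s'", aa))
  e <- e[e$fraction >= minFreq, , drop = FALSE]
  if (!nrow(e))
    stop(sprintf("no codon above frequency threshold for amino acid '%s'", aa))
  e$fraction <- e$fraction / sum(e$fraction)
  e
}

# precompute the allowed-codon lookup once per encoding pass
.allowedList <- function(table, minFreq) {
  out <- lapply(names(table$entries), function(aa)
    .allowedCodons(table, aa, minFreq))
  names(out) <- names(table$entries)
  out
}

# deterministic 31-bit hash of a string (per-peptide RNG stream seeds)
.stableHash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Codon-usage-weighted reverse translation
#'
#' Reverse-translates peptides into DNA by sampling, independently per
#' residue, among the codons whose usage fraction meets the threshold,
#' proportionally to their renormalized fractions. Deterministic under a
#' fixed seed; translating the result reproduces the peptide.
#'
#' @param peptides character vector of amino-acid sequences.
#' @param table a \code{\link{readCodonTable}} list.
#' @param minFreq codon usage threshold (default 0.1).
#' @param seed optional integer seed.
#' @return Character vector of coding DNA, 3x the peptide lengths.
#' @export
revTranslate <- function(peptides, table = readCodonTable(), minFreq = 0.1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  allowed <- .allowedList(table, minFreq)
  vapply(peptides, function(p) {
    ch <- strsplit(p, "")[[1]]
    codons <- character(length(ch))
    for (a in unique(ch)) {
      e <- allowed[[a]]
      if (is.null(e)) stop(sprintf("codon table has no entry for '%s'", a))
      idx <- which(ch == a)
      codons[idx] <- if (nrow(e) == 1L) e$codon else
        sample(e$codon, length(idx), replace = TRUE, prob = e$fraction)
    }
    paste(codons, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# translate in-frame coding DNA with the standard code (stops as "*")
.translateCoding <- function(dna) {
  n <- nchar(dna) %/% 3L
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

.findMotifs <- function(dna, motifs) {
  hits <- integer(0)
  for (m in motifs) {
    g <- gregexpr(m, dna, fixed = TRUE)[[1]]
    if (g[1] != -1L) hits <- c(hits, as.integer(g))
  }
  sort(hits)
}

#' Remove restriction sites from in-frame coding DNA
#'
#' Eliminates the cloning-enzyme recognition motifs (EcoRI GAATTC and
#' HindIII AAGCTT by default) by resampling synonymous codons that overlap
#' a motif occurrence, keeping the translation unchanged. Retries are
#' bounded; an unresolvable site raises an error with its coordinates.
#'
#' @param dna in-frame coding DNA (length divisible by 3).
#' @param forbidden motifs to eliminate.
#' @param table a \code{\link{readCodonTable}} list.
#' @param minFreq codon usage threshold for replacements.
#' @param maxAttempts resampling attempts per motif (default 100).
#' @param seed optional integer seed.
#' @return The recoded DNA, translation-identical, motif-free.
#' @export
recodeSites <- function(dna, forbidden = .FORBIDDEN, table = readCodonTable(),
                        minFreq = 0.1, maxAttempts = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nchar(dna) %% 3L != 0L) stop("coding DNA length must be divisible by 3")
  attempts <- 0L
  repeat {
    hits <- .findMotifs(dna, forbidden)
    if (!length(hits)) return(dna)
    if (attempts >= maxAttempts)
      stop(sprintf("unresolvable restriction site at nt position %d", hits[1]))
    pos <- hits[1]  # 1-based
    span <- pos:(pos + max(nchar(forbidden)) - 1L)
    codonIdx <- unique((pos:(pos + 5L) - 1L) %/% 3L + 1L)
    codonIdx <- codonIdx[codonIdx * 3L <= nchar(dna)]
    for (ci in codonIdx) {
      cur <- substr(dna, 3L * ci - 2L, 3L * ci)
      aa <- Biostrings::GENETIC_CODE[[cur]]
      e <- if (aa == "*")
        data.frame(codon = table$stopCodons,
                   fraction = rep(1 / length(table$stopCodons),
                                  length(table$stopCodons)))
      else .allowedCodons(table, aa, minFreq)
      alt <- setdiff(e$codon, cur)
      if (!length(alt)) next
      newCodon <- if (length(alt) == 1L) alt else
        sample(alt, 1L, prob = e$fraction[match(alt, e$codon)])
      substr(dna, 3L * ci - 2L, 3L * ci) <- newCodon
    }
    attempts <- attempts + 1L
  }
}

# random DNA avoiding forbidden motifs (checked in context) and
# homopolymer runs longer than maxRun
.randomFiller <- function(n, context = "", forbidden = .FORBIDDEN,
                          maxRun = 8L, maxAttempts = 100L) {
  if (n <= 0L) return("")
  for (i in seq_len(maxAttempts)) {
    filler <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    collapse = "")
    full <- paste0(context, filler)
    if (length(.findMotifs(full, forbidden))) next
    runs <- rle(strsplit(full, "")[[1]])
    if (max(runs$lengths) > maxRun) next
    return(filler)
  }
  stop("could not generate motif-free filler")
}

#' Pad coding DNA to a fixed insert length
#'
#' Two dialects are supported. \code{stop_random} (main library): three
#' stop codons followed by pseudo-random filler, placed 3' of the coding
#' region by default so the displayed peptide stays intact (a 45-nt 15-mer
#' coding region becomes a 168-nt insert); the filler avoids the cloning
#' motifs and homopolymer runs over 8 nt. \code{linker}: a fixed linker DNA
#' prefix appended to reach the target (enterovirus dialect, 120-nt
#' inserts).
#'
#' @param dna coding DNA.
#' @param targetNt target insert length.
#' @param dialect \code{"stop_random"} or \code{"linker"}.
#' @param table codon table (for stop codon identities).
#' @param padEnd \code{"3p"} (default) or \code{"5p"}: which side of the
#'   coding region receives the pad.
#' @param seed optional integer seed.
#' @return The padded DNA of length \code{targetNt}.
#' @export
padToLength <- function(dna, targetNt, dialect = c("stop_random", "linker"),
                        table = readCodonTable(), padEnd = c("3p", "5p"),
                        seed = NULL) {
  dialect <- match.arg(dialect)
  padEnd <- match.arg(padEnd)
  if (!is.null(seed)) set.seed(seed)
  need <- targetNt - nchar(dna)
  if (need < 0L) stop("coding DNA longer than the pad target")
  if (need == 0L) return(dna)
  if (dialect == "linker") {
    pad <- substr(strrep(.LINKER_DNA, ceiling(need / nchar(.LINKER_DNA))),
                  1L, need)
    return(if (padEnd == "3p") paste0(dna, pad) else paste0(pad, dna))
  }
  if (need %% 3L != 0L)
    stop("stop_random padding requires a length difference divisible by 3")
  if (need < 9L) stop("stop_random padding needs room for three stop codons")
  stops <- paste(sample(table$stopCodons, 3L, replace = TRUE), collapse = "")
  nFill <- need - 9L
  if (padEnd == "3p") {
    # the coding/stop junction can itself form a site (e.g. coding ending
    # AAGCT followed by any stop codon): recode in-frame before padding
    combined <- paste0(dna, stops)
    if (length(.findMotifs(combined, .FORBIDDEN)))
      combined <- recodeSites(combined, table = table)
    tail5 <- substr(combined, nchar(combined) - 4L, nchar(combined))
    filler <- .randomFiller(nFill, context = tail5)
    return(paste0(combined, filler))
  }
  # 5' padding: stops + filler precede the coding region
  att <- 0L
  repeat {
    filler <- .randomFiller(nFill, context = stops)
    out <- paste0(stops, filler, dna)
    if (!length(.findMotifs(out, .FORBIDDEN))) return(out)
    att <- att + 1L
    if (att >= 100L) stop("could not assemble a motif-free padded insert")
    stops <- paste(sample(table$stopCodons, 3L, replace = TRUE),
                   collapse = "")
  }
}

#' Add PCR amplification adapters
#'
#' @param dna insert DNA.
#' @param prefix 5' adapter (default the 16-nt main-library prefix).
#' @param suffix 3' adapter (default the 16-nt main-library suffix).
#' @return \code{prefix + dna + suffix}; a 168-nt insert with the default
#'   adapters yields a 200-nt oligo.
#' @export
addAdapters <- function(dna, prefix = .DEFAULT_PREFIX,
                        suffix = .DEFAULT_SUFFIX) {
  paste0(prefix, dna, suffix)
}

#' Encode a peptide library into synthesis-ready oligos
#'
#' For every manifest peptide: codon-sampled reverse translation,
#' restriction-site recoding, dialect-specific padding to the insert
#' length, then adapter addition. Stitched 55-mers get one terminal stop
#' codon (56 codons, 168 nt); uniform 56-mer tiles encode to 168 nt
#' directly; individual 15-mer epitopes are padded with three stops plus
#' random filler. Each peptide's random stream is seeded from the library
#' seed and a hash of its sequence, so identical manifests and seeds give
#' byte-identical output and duplicate peptide sequences encode to
#' identical coding DNA.
#'
#' @param library a \code{\linkS4class{PeptideLibrary}} or its manifest
#'   data.frame (columns \code{peptide_id}, \code{aa_seq}, \code{mode}).
#' @param table a \code{\link{readCodonTable}} list.
#' @param insertNt target insert length (default 168).
#' @param prefix,suffix PCR adapters.
#' @param minFreq codon usage threshold.
#' @param seed integer seed (default 0).
#' @return data.frame with columns \code{peptide_id}, \code{coding_dna},
#'   \code{insert}, \code{full_oligo}, \code{pad_spec}.
#' @export
encodeLibrary <- function(library, table = readCodonTable(), insertNt = 168L,
                          prefix = .DEFAULT_PREFIX, suffix = .DEFAULT_SUFFIX,
                          minFreq = 0.1, seed = 0L) {
  man <- if (is(library, "PeptideLibrary")) manifest(library) else library
  stopifnot(all(c("peptide_id", "aa_seq", "mode") %in% names(man)))
  n <- nrow(man)
  coding <- insert <- pad <- character(n)
  for (i in seq_len(n)) {
    aa <- man$aa_seq[i]
    set.seed((as.integer(seed) + .stableHash(paste0(man$mode[i], aa))) %%
               2147483647L)
    dna <- revTranslate(aa, table, minFreq)
    if (man$mode[i] == "stitched") {
      # terminal stop completes the 56-codon construct
      dna <- paste0(dna, sample(table$stopCodons, 1L))
    }
    dna <- recodeSites(dna, table = table, minFreq = minFreq)
    if (nchar(dna) == insertNt) {
      ins <- dna
      pad[i] <- "none"
    } else {
      ins <- padToLength(dna, insertNt, "stop_random", table)
      pad[i] <- sprintf("stop_random:%dnt", insertNt - nchar(dna))
    }
    coding[i] <- dna
    insert[i] <- ins
  }
  data.frame(peptide_id = man$peptide_id, coding_dna = coding,
             insert = insert, full_oligo = addAdapters(insert, prefix, suffix),
             pad_spec = pad, stringsAsFactors = FALSE)
}

#' Write encoded oligos to FASTA
#'
#' @param oligos data.frame from \code{\link{encodeLibrary}}.
#' @param fastaFile output path.
#' @return Invisibly, the path.
#' @export
writeOligoFasta <- function(oligos, fastaFile) {
  x <- Biostrings::DNAStringSet(oligos$full_oligo)
  names(x) <- oligos$peptide_id
  Biostrings::writeXStringSet(x, fastaFile)
  invisible(fastaFile)
}
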