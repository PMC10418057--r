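#' Peptide library manifest
#'
#' S4 container for a designed peptide library: the per-peptide manifest,
#' the design mode, and proteome bookkeeping used for the coverage
#' statistic. Coordinates in manifests are 0-based half-open internally;
#' display columns add 1-based starts.
#'
#' @slot manifest data.frame, one row per synthesized peptide.
#' @slot mode one of \code{"tiling"}, \code{"epitopes"}, \code{"stitched"}.
#' @slot proteomeLength total amino-acid length of the representative
#'   proteins the library was designed from.
#' @slot coverage (epitope-bearing residues in the library) /
#'   \code{proteomeLength}: 56 aa per uniform tile, 45 aa (3 x 15) per
#'   stitched peptide, 15 aa per individual epitope peptide.
#' @exportClass PeptideLibrary
setClass("PeptideLibrary",
  representation(
    manifest = "data.frame",
    mode = "character",
    proteomeLength = "numeric",
    coverage = "numeric"
  ),
  validity = function(object) {
    if (!object@mode %in% c("tiling", "epitopes", "stitched"))
      return("mode must be one of 'tiling', 'epitopes', 'stitched'")
    TRUE
  }
)

setMethod("show", "PeptideLibrary", function(object) {
  cat("PeptideLibrary (", object@mode, " mode)\n", sep = "")
  cat("  peptides:       ", nrow(object@manifest), "\n")
  cat("  proteome length:", object@proteomeLength, "aa\n")
  cat("  coverage:       ", round(object@coverage, 2), "x\n")
})

#' @describeIn PeptideLibrary-class the per-peptide manifest data.frame
#' @param object a \code{PeptideLibrary}
#' @export
manifest <- function(object) object@manifest

#' @describeIn PeptideLibrary-class library coverage of the proteome
#' @export
libraryCoverage <- function(object) object@coverage

.emptyManifest <- function() {
  data.frame(peptide_id = character(0), aa_seq = character(0),
             mode = character(0), groups = character(0),
             phages = character(0), source_group = character(0),
             start = integer(0), start1 = integer(0),
             epitope_starts = character(0), probs = character(0),
             rank_layout = character(0), stringsAsFactors = FALSE)
}

#' Proteome coverage ratio of a peptide library
#'
#' Coverage = (number of peptides x amino acids displayed per peptide) /
#' (total amino-acid length of the representative proteins). A uniform
#' 56-mer tiling with 28-aa overlap covers a proteome about 1.8x; a
#' stitched design displaying 45 aa of epitopes per peptide covers a
#' fraction of it.
#'
#' @param nPeptides number of peptides in the library.
#' @param aaPerPeptide amino acids displayed per peptide (56 for tiles, 45
#'   for stitched peptides, 15 for single epitopes).
#' @param proteomeAA summed representative protein length in amino acids.
#' @return The coverage ratio.
#' @export
coverageRatio <- function(nPeptides, aaPerPeptide, proteomeAA) {
  nPeptides * aaPerPeptide / proteomeAA
}

#' Recorded design statistics of the pilot phage libraries
#'
#' The published design statistics of the gut-phage pilot study this
#' package's algorithms reproduce: sub-library sizes, representative
#' proteome lengths and tile counts for the pilot (112 phages) and the
#' North American phageome designs, plus the enterovirus validation
#' sub-library. Used for bookkeeping checks (coverage and compression
#' arithmetic); the numbers are inputs, not outputs, of this package.
#'
#' @return A list with elements \code{pilot} (epitope/stitched/tiling
#'   sub-library sizes, proteome length), \code{northAmerican} (tile
#'   counts, proteome length) and \code{enterovirus} (base peptide count).
#' @export
pilotDesignStats <- function() {
  list(
    pilot = list(
      epitopePeptides = 19117,
      stitchedPeptides = 5266,
      tilingPeptides = 23745,
      proteomeAA = 750776
    ),
    northAmerican = list(
      tilingPeptides = 484761,
      stitchedPeptides = 106762,
      proteomeAA = 15637136
    ),
    enterovirus = list(basePeptides = 757)
  )
}

#' Read a protein set with group and phage membership
#'
#' Loads proteins from FASTA plus a membership TSV (columns \code{id},
#' \code{group_id}, \code{phages}; phage ids semicolon-separated). Proteins
#' without a membership row get a singleton group equal to their id.
#'
#' @param fastaFile path to a protein FASTA.
#' @param membershipFile optional path to the membership TSV.
#' @return data.frame with columns \code{id}, \code{seq}, \code{group_id},
#'   \code{phages}.
#' @export
readProteinSet <- function(fastaFile, membershipFile = NULL) {
  aa <- Biostrings::readAAStringSet(fastaFile)
  ids <- sub("\\s.*$", "", names(aa))
  out <- data.frame(id = ids, seq = as.character(aa),
                    group_id = ids, phages = ids,
                    stringsAsFactors = FALSE)
  if (!is.null(membershipFile)) {
    mem <- utils::read.delim(membershipFile, stringsAsFactors = FALSE)
    i <- match(out$id, mem$id)
    out$group_id[!is.na(i)] <- mem$group_id[i[!is.na(i)]]
    out$phages[!is.na(i)] <- mem$phages[i[!is.na(i)]]
  }
  rownames(out) <- NULL
  out
}

#' Uniform 56-mer tiling of a protein
#'
#' Tiles a protein with fixed-length peptides overlapping by half the tile
#' size: starts 0, 28, 56, ... (0-based). If the final regular tile does not
#' reach the C-terminus, one extra full-length tile ending exactly at the
#' C-terminus is appended, overlapping the previous tile by more than the
#' regular overlap.
#'
#' @param seq protein amino-acid string, length >= \code{tileLen}.
#' @param tileLen tile length in aa (default 56).
#' @param overlap overlap between consecutive tiles (default 28).
#' @return data.frame with 0-based half-open \code{start}, \code{end} and
#'   the tile \code{seq}.
#' @export
pepsynTile <- function(seq, tileLen = 56L, overlap = 28L) {
  L <- nchar(seq)
  if (L < tileLen)
    stop(sprintf("protein length %d < tile length %d", L, tileLen))
  step <- tileLen - overlap
  starts <- seq.int(0L, L - tileLen, by = step)
  if (starts[length(starts)] + tileLen < L) starts <- c(starts, L - tileLen)
  data.frame(start = starts, end = starts + tileLen,
             seq = substring(seq, starts + 1L, starts + tileLen),
             stringsAsFactors = FALSE)
}

#' k-mer scan of a 56-mer wildtype peptide
#'
#' Enumerates sub-peptides of lengths 15 to 45 starting every 5 residues,
#' the layout of a scan library used to localize epitopes within reactive
#' 56-mers.
#'
#' @param wildtype amino-acid string of length 56.
#' @param lengths sub-peptide lengths (default 15, 20, ..., 45).
#' @param step start spacing (default 5).
#' @return data.frame with columns \code{k}, \code{start} (0-based),
#'   \code{seq}.
#' @export
kmerScan <- function(wildtype, lengths = seq(15L, 45L, by = 5L), step = 5L) {
  if (nchar(wildtype) != 56L) stop("wildtype must be a 56-mer")
  out <- do.call(rbind, lapply(lengths, function(k) {
    starts <- seq.int(0L, 56L - k, by = step)
    data.frame(k = k, start = starts,
               seq = substring(wildtype, starts + 1L, starts + k),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Triple-alanine scan of a 56-mer wildtype peptide
#'
#' One variant per overlapping 3-mer (54 variants): the three targeted
#' residues are replaced by alanine, except a targeted residue that already
#' is alanine becomes glycine. Disruption of antibody reactivity localizes
#' the epitope.
#'
#' @param wildtype amino-acid string of length 56.
#' @return data.frame with \code{start} (0-based start of the substituted
#'   3-mer) and the variant \code{seq}.
#' @export
alanineScan <- function(wildtype) {
  if (nchar(wildtype) != 56L) stop("wildtype must be a 56-mer")
  ch <- strsplit(wildtype, "")[[1]]
  starts <- 0:53
  seqs <- vapply(starts, function(s) {
    v <- ch
    idx <- (s + 1):(s + 3)
    v[idx] <- ifelse(v[idx] == "A", "G", "A")
    paste(v, collapse = "")
  }, "")
  data.frame(start = starts, seq = seqs, stringsAsFactors = FALSE)
}

#' Enumerate all k-mer windows of a protein
#'
#' Step-1 windows, 0-based starts; the unit the epitope classifier scores.
#'
#' @param seq protein amino-acid string.
#' @param k window length (default 15).
#' @return data.frame with \code{start} and \code{seq}; zero rows (with a
#'   warning) if the protein is shorter than \code{k}.
#' @export
enumerateWindows <- function(seq, k = 15L) {
  L <- nchar(seq)
  if (L < k) {
    warning(sprintf("protein length %d < window length %d; no windows", L, k))
    return(data.frame(start = integer(0), seq = character(0)))
  }
  starts <- 0:(L - k)
  data.frame(start = starts, seq = substring(seq, starts + 1L, starts + k),
             stringsAsFactors = FALSE)
}

#' Greedy selection of non-overlapping epitope windows
#'
#' Repeatedly takes the highest-probability window above the cutoff that
#' does not overlap any already-selected window (ties broken by smaller
#' start). Returns windows ranked by probability descending; may be empty.
#'
#' @param windows data.frame with \code{start}, \code{seq}, \code{prob};
#'   all from one protein group.
#' @param probCutoff minimum epitope probability (default 0.5).
#' @param k window length (default 15; windows overlap iff their starts
#'   differ by less than \code{k}).
#' @return The selected rows of \code{windows}, probability-descending,
#'   with a \code{rank} column.
#' @export
selectEpitopes <- function(windows, probCutoff = 0.5, k = 15L) {
  stopifnot(all(c("start", "seq", "prob") %in% names(windows)))
  cand <- windows[windows$prob > probCutoff, , drop = FALSE]
  cand <- cand[order(-cand$prob, cand$start), , drop = FALSE]
  chosen <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(chosen) ||
        all(abs(cand$start[i] - cand$start[chosen]) >= k))
      chosen <- c(chosen, i)
  }
  out <- cand[chosen, , drop = FALSE]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  else out$rank <- integer(0)
  rownames(out) <- NULL
  out
}

#' Merge identical epitope 15-mers across protein groups
#'
#' Identical sequences selected from several proteins are collapsed to one
#' catalog entry whose protein-group and phage memberships are the unions
#' over occurrences; the merged probability is the maximum.
#'
#' @param selected data.frame with \code{seq}, \code{prob},
#'   \code{group_id}, \code{phages} (semicolon-separated).
#' @return data.frame with one row per distinct sequence: \code{seq},
#'   \code{prob} (max), \code{groups}, \code{phages} (sorted,
#'   semicolon-joined unions), \code{n_occurrences}.
#' @export
dedupeEpitopes <- function(selected) {
  stopifnot(all(c("seq", "prob", "group_id", "phages") %in% names(selected)))
  sp <- split(seq_len(nrow(selected)), selected$seq)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(
      seq = selected$seq[idx[1]],
      prob = max(selected$prob[idx]),
      groups = paste(sort(unique(selected$group_id[idx])), collapse = ";"),
      phages = paste(sort(unique(unlist(
        strsplit(selected$phages[idx], ";", fixed = TRUE)))), collapse = ";"),
      n_occurrences = length(idx),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Distribute ranked epitopes over stitched peptides
#'
#' With m ranked epitopes, n = floor(m/3) stitched peptides are formed;
#' peptide j holds ranks (j, n + j, 2n + j) at positions 1..3, so the
#' highest-probability epitopes occupy the first positions of successive
#' peptides and the library maximizes independently reactive peptides per
#' protein. Ranks beyond 3n are discarded.
#'
#' @param m number of ranked epitopes available for one protein group.
#' @return list of integer triples (one per stitched peptide), empty if
#'   m < 3.
#' @export
assignPositions <- function(m) {
  n <- m %/% 3L
  if (n == 0L) return(list())
  lapply(seq_len(n), function(j) c(j, n + j, 2L * n + j))
}

#' Stitch three epitope 15-mers into one peptide
#'
#' Joins the epitopes, probability order first, with a flexible inert
#' linker (default GGGGS), yielding a 55-mer; a terminal stop codon at
#' encoding time makes the synthesized construct span 56 codon positions.
#'
#' @param epitopes character vector of exactly three 15-mers, highest
#'   probability first.
#' @param linker linker amino acids between epitopes (default
#'   \code{"GGGGS"}).
#' @return The stitched amino-acid string (length 55 for the default
#'   linker).
#' @export
stitchPeptides <- function(epitopes, linker = "GGGGS") {
  if (length(epitopes) != 3L || any(nchar(epitopes) != 15L))
    stop("need exactly three 15-mer epitopes")
  paste(epitopes, collapse = linker)
}

#' Design a peptide library from a protein set
#'
#' Runs one of three designs over the group representatives (first protein
#' per \code{group_id}):
#' \describe{
#'   \item{tiling}{uniform 56-mer tiles with 28-aa overlap; proteins
#'     shorter than 56 aa are skipped with a warning.}
#'   \item{epitopes}{individual predicted epitope 15-mers (probability >
#'     cutoff, non-overlapping within a group), deduplicated across
#'     groups.}
#'   \item{stitched}{epitope selection as above, then three epitopes per
#'     synthesized peptide via \code{\link{stitchPeptides}}; groups with
#'     fewer than three selected epitopes are dropped; identical stitched
#'     sequences are synthesized once.}
#' }
#'
#' @param proteins data.frame with \code{id}, \code{seq}, \code{group_id},
#'   \code{phages} (see \code{\link{readProteinSet}}).
#' @param model an \code{\linkS4class{EpitopeModel}} (required for the two
#'   epitope modes).
#' @param mode \code{"tiling"}, \code{"epitopes"} or \code{"stitched"}.
#' @param probCutoff epitope probability cutoff (default 0.5).
#' @param linker stitching linker (default \code{"GGGGS"}).
#' @param scheme an \code{\link{alphabetScheme}}.
#' @return A \code{\linkS4class{PeptideLibrary}}.
#' @export
designLibrary <- function(proteins, model = NULL,
                          mode = c("tiling", "epitopes", "stitched"),
                          probCutoff = 0.5, linker = "GGGGS",
                          scheme = alphabetScheme()) {
  mode <- match.arg(mode)
  if (!nrow(proteins)) stop("empty protein set")
  reps <- proteins[!duplicated(proteins$group_id), , drop = FALSE]
  proteomeLength <- sum(nchar(reps$seq))

  if (mode == "tiling") {
    rows <- list()
    for (i in seq_len(nrow(reps))) {
      if (nchar(reps$seq[i]) < 56L) {
        warning(sprintf("protein group %s shorter than 56 aa; skipped",
                        reps$group_id[i]))
        next
      }
      t <- pepsynTile(reps$seq[i])
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = sprintf("%s_tile_%03d", reps$group_id[i],
                             seq_len(nrow(t))),
        aa_seq = t$seq, mode = "tiling",
        groups = reps$group_id[i], phages = reps$phages[i],
        source_group = reps$group_id[i],
        start = t$start, start1 = t$start + 1L,
        epitope_starts = NA_character_,
        probs = NA_character_, rank_layout = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) stop("no protein long enough to tile")
    man <- do.call(rbind, rows)
    cov <- coverageRatio(nrow(man), 56, proteomeLength)
    return(new("PeptideLibrary", manifest = man, mode = mode,
               proteomeLength = proteomeLength, coverage = cov))
  }

  if (is.null(model)) stop("epitope modes require a trained model")
  k <- model@peptideLength
  selections <- list()
  for (i in seq_len(nrow(reps))) {
    w <- suppressWarnings(enumerateWindows(reps$seq[i], k))
    if (!nrow(w)) next
    w$prob <- predictEpitopeProb(model, w$seq, scheme)
    sel <- selectEpitopes(w, probCutoff, k)
    if (!nrow(sel)) next
    sel$group_id <- reps$group_id[i]
    sel$phages <- reps$phages[i]
    selections[[length(selections) + 1L]] <- sel
  }
  if (!length(selections)) {
    return(new("PeptideLibrary", manifest = .emptyManifest(), mode = mode,
               proteomeLength = proteomeLength, coverage = 0))
  }
  allSel <- do.call(rbind, selections)
  catalog <- dedupeEpitopes(allSel)

  if (mode == "epitopes") {
    man <- data.frame(
      peptide_id = sprintf("epi_%05d", seq_len(nrow(catalog))),
      aa_seq = catalog$seq, mode = "epitopes",
      groups = catalog$groups, phages = catalog$phages,
      source_group = catalog$groups,
      start = NA_integer_, start1 = NA_integer_,
      epitope_starts = NA_character_,
      probs = sprintf("%.4f", catalog$prob),
      rank_layout = NA_character_, stringsAsFactors = FALSE)
    cov <- coverageRatio(nrow(man), k, proteomeLength)
    return(new("PeptideLibrary", manifest = man, mode = mode,
               proteomeLength = proteomeLength, coverage = cov))
  }

  # stitched: per-group ranked epitopes (catalog-merged membership),
  # distributed over peptides, identical constructs synthesized once
  rows <- list()
  for (sel in selections) {
    layouts <- assignPositions(nrow(sel))
    for (ranks in layouts) {
      eps <- sel[ranks, , drop = FALSE]
      aa <- stitchPeptides(eps$seq, linker)
      ci <- match(eps$seq, catalog$seq)
      rows[[length(rows) + 1L]] <- data.frame(
        aa_seq = aa, mode = "stitched",
        groups = paste(sort(unique(unlist(
          strsplit(catalog$groups[ci], ";", fixed = TRUE)))), collapse = ";"),
        phages = paste(sort(unique(unlist(
          strsplit(catalog$phages[ci], ";", fixed = TRUE)))), collapse = ";"),
        source_group = sel$group_id[1],
        start = eps$start[1], start1 = eps$start[1] + 1L,
        epitope_starts = paste(eps$start, collapse = ";"),
        probs = paste(sprintf("%.4f", eps$prob), collapse = ";"),
        rank_layout = paste(ranks, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(new("PeptideLibrary", manifest = .emptyManifest(), mode = mode,
               proteomeLength = proteomeLength, coverage = 0))
  }
  man <- do.call(rbind, rows)
  dup <- duplicated(man$aa_seq)
  man <- man[!dup, , drop = FALSE]
  man <- cbind(peptide_id = sprintf("stitch_%05d", seq_len(nrow(man))),
               man, stringsAsFactors = FALSE)
  rownames(man) <- NULL
  cov <- coverageRatio(nrow(man), 45, proteomeLength)
  new("PeptideLibrary", manifest = man, mode = mode,
      proteomeLength = proteomeLength, coverage = cov)
}

#' Write a peptide library manifest and FASTA
#'
#' @param library a \code{\linkS4class{PeptideLibrary}}.
#' @param manifestFile path for the TSV manifest.
#' @param fastaFile optional path for a FASTA of peptide amino-acid
#'   sequences.
#' @return Invisibly, the manifest data.frame.
#' @export
writeLibrary <- function(library, manifestFile, fastaFile = NULL) {
  man <- manifest(library)
  utils::write.table(man, manifestFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fastaFile)) {
    aa <- Biostrings::AAStringSet(man$aa_seq)
    names(aa) <- man$peptide_id
    Biostrings::writeXStringSet(aa, fastaFile)
  }
  invisible(man)
}
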