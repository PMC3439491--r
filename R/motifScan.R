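## CArG-box consensus scanning.
##
## The CArG box is the degenerate binding element of MADS-domain
## transcription factors. Four consensus classes are provided:
## the canonical decamer C(C/T)(A/T)6(A/G)G, the SRF/SRE class
## CC(A/T)6GG, the MEF2/N10 class CTA(A/T)4TAG, and the intermediate
## class C(A/T)6AG (an 8-mer). "Atypical" sites deviate from a class at
## up to maxAtypical positions.

.pat <- function(name, sets, maxAtypical) {
  new("MotifPattern", name = name, positions = sets,
      maxAtypical = as.integer(maxAtypical))
}

#' Built-in CArG-box consensus patterns
#'
#' Returns the four consensus classes used throughout the package:
#' `canonical` = C(C/T)(A/T)6(A/G)G, `srf_like` = CC(A/T)6GG,
#' `n10_like` = CTA(A/T)4TAG, and `intermediate` = C(A/T)6AG (8 bp, as
#' conventionally written; see the package vignette for why it is not
#' padded to a decamer).
#'
#' @param maxAtypical default mismatch budget attached to each pattern
#'   (used by [scanSequence()] when no explicit budget is given).
#' @return named list of [MotifPattern-class] objects, in priority order
#'   `canonical`, `srf_like`, `n10_like`, `intermediate`.
#' @examples
#' builtinPatterns()[["canonical"]]
#' @export
builtinPatterns <- function(maxAtypical = 2L) {
  AT <- c("A", "T")
  list(
    canonical = .pat("canonical",
      c(list("C", c("C", "T")), rep(list(AT), 6), list(c("A", "G"), "G")),
      maxAtypical),
    srf_like = .pat("srf_like",
      c(list("C", "C"), rep(list(AT), 6), list("G", "G")),
      maxAtypical),
    n10_like = .pat("n10_like",
      c(list("C", "T", "A"), rep(list(AT), 4), list("T", "A", "G")),
      maxAtypical),
    intermediate = .pat("intermediate",
      c(list("C"), rep(list(AT), 6), list("A", "G")),
      maxAtypical))
}

## Encode an upper-case ACGT string as integers 1..4; error otherwise.
.encodeDNA <- function(sequence) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(s, DNA_BASES4)
  if (anyNA(code))
    stop(sprintf("invalid alphabet: non-ACGT character '%s' in sequence",
                 s[which(is.na(code))[1]]))
  code
}

## 4 x k logical matrix of allowed bases; row order A,C,G,T.
.allowedMatrix <- function(pattern) {
  k <- length(pattern@positions)
  m <- matrix(FALSE, 4L, k)
  for (j in seq_len(k))
    m[match(pattern@positions[[j]], DNA_BASES4), j] <- TRUE
  m
}

## Allowed matrix for matching the forward strand against the pattern's
## reverse complement: complement bases (A<->T, C<->G), reverse positions.
.allowedMatrixRC <- function(pattern) {
  m <- .allowedMatrix(pattern)
  m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
}

## Mismatch count of every window of `code` against an allowed matrix.
.windowMismatches <- function(code, allowed) {
  k <- ncol(allowed)
  nwin <- length(code) - k + 1L
  if (nwin < 1L) return(integer(0))
  mm <- integer(nwin)
  for (j in seq_len(k))
    mm <- mm + !allowed[cbind(code[j:(j + nwin - 1L)], j)]
  mm
}

#' Classify a decamer against the CArG consensus classes
#'
#' Compares a 10-base window with the three decamer classes (`canonical`,
#' `srf_like`, `n10_like`) and returns the best match — fewest deviating
#' positions, ties broken in that priority order. A window deviating from
#' every class by more than `maxAtypical` positions is `"none"`.
#'
#' @param decamer a 10-character ACGT string (upper case).
#' @param maxAtypical mismatch budget for an "atypical" call (default 2).
#' @return list with elements `patternName` (`"none"` if unmatched) and
#'   `nAtypical` (`NA` for `"none"`).
#' @examples
#' classifyCarg("CCATATTAGG")  # canonical, 0 atypical bases
#' classifyCarg("CTAGTTAAAG")  # atypical canonical (1 deviation)
#' @export
classifyCarg <- function(decamer, maxAtypical = 2L) {
  if (nchar(decamer) != 10L)
    stop(sprintf("decamer must have length 10, got %d", nchar(decamer)))
  code <- .encodeDNA(decamer)
  pats <- builtinPatterns()[c("canonical", "srf_like", "n10_like")]
  mm <- vapply(pats, function(p)
    .windowMismatches(code, .allowedMatrix(p)), integer(1))
  best <- which.min(mm)  # ties resolved by priority order
  if (mm[best] > maxAtypical)
    return(list(patternName = "none", nAtypical = NA_integer_))
  list(patternName = names(pats)[best], nAtypical = unname(mm[best]))
}

#' Scan a sequence for CArG-box motifs
#'
#' Slides every pattern over the sequence (both strands by default — CArG
#' boxes are quasi-palindromic) and reports every window matching within
#' the mismatch budget. Coordinates are 0-based half-open on the forward
#' strand; for minus-strand hits `matchedSeq` is the reverse complement of
#' the forward-strand slice. Exact palindromic duplicates (same window,
#' identical matched sequence on both strands) are reported once with
#' strand `"+"`. Overlapping hits are all reported.
#'
#' @param seqId sequence identifier for the output table.
#' @param sequence ACGT string (case-insensitive).
#' @param patterns list of [MotifPattern-class] objects (default all four
#'   built-ins).
#' @param maxAtypical single mismatch budget overriding each pattern's own
#'   `maxAtypical`; `NULL` (default) uses the per-pattern budgets.
#' @param bothStrands scan the minus strand too (default `TRUE`).
#' @return data.frame with columns `seqId`, `start`, `end`, `strand`,
#'   `matchedSeq`, `patternName`, `nAtypical`, sorted by (start, strand).
#' @examples
#' scanSequence("N10probe", "AAAACTATTTATAGATCA",
#'              builtinPatterns()["n10_like"], maxAtypical = 0,
#'              bothStrands = FALSE)
#' @export
scanSequence <- function(seqId, sequence, patterns = builtinPatterns(),
                         maxAtypical = NULL, bothStrands = TRUE) {
  emptyHits <- data.frame(seqId = character(), start = integer(),
                          end = integer(), strand = character(),
                          matchedSeq = character(),
                          patternName = character(),
                          nAtypical = integer(),
                          stringsAsFactors = FALSE)
  if (nchar(sequence) == 0L) return(emptyHits)
  code <- .encodeDNA(sequence)
  out <- list()
  for (pat in patterns) {
    k <- length(pat@positions)
    budget <- if (is.null(maxAtypical)) pat@maxAtypical
              else as.integer(maxAtypical)
    mmF <- .windowMismatches(code, .allowedMatrix(pat))
    hitF <- which(mmF <= budget)
    for (i in hitF) {
      win <- substr(toupper(sequence), i, i + k - 1L)
      out[[length(out) + 1L]] <- data.frame(
        seqId = seqId, start = i - 1L, end = i + k - 1L, strand = "+",
        matchedSeq = win, patternName = pat@name,
        nAtypical = mmF[i], stringsAsFactors = FALSE)
    }
    if (bothStrands) {
      mmR <- .windowMismatches(code, .allowedMatrixRC(pat))
      hitR <- which(mmR <= budget)
      for (i in hitR) {
        win <- substr(toupper(sequence), i, i + k - 1L)
        rcwin <- revcomp(win)
        if (i %in% hitF && rcwin == win) next  # exact palindrome, keep "+"
        out[[length(out) + 1L]] <- data.frame(
          seqId = seqId, start = i - 1L, end = i + k - 1L, strand = "-",
          matchedSeq = rcwin, patternName = pat@name,
          nAtypical = mmR[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(emptyHits)
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start, hits$strand, hits$patternName), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan every record of a DNAStringSet (or FASTA file) for CArG motifs
#'
#' @param x a `DNAStringSet` or path to a FASTA file.
#' @inheritParams scanSequence
#' @return combined hit data.frame (see [scanSequence()]).
#' @export
scanFasta <- function(x, patterns = builtinPatterns(), maxAtypical = NULL,
                      bothStrands = TRUE) {
  if (is.character(x)) x <- readFasta(x)
  res <- lapply(seq_along(x), function(i)
    scanSequence(names(x)[i], as.character(x[[i]]), patterns,
                 maxAtypical, bothStrands))
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- scanSequence("x", "")  # canonical empty frame
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6
#'
#' Columns: seqId, start, end, name (`pattern/nAtypical`), score
#' (`nAtypical`), strand. Coordinates are 0-based half-open as in BED.
#'
#' @param hits hit data.frame from [scanSequence()]/[scanFasta()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeHitsBed <- function(hits, path) {
  bed <- data.frame(hits$seqId, hits$start, hits$end,
                    paste0(hits$patternName, "/", hits$nAtypical),
                    hits$nAtypical, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
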