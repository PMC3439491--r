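# Independent brute-force oracle for consensus scanning. Deliberately
# written against plain character vectors, without reusing any package
# internals, so it can stand as an independent check of scanSequence().

oracle_pattern_sets <- function(name) {
  AT <- c("A", "T")
  switch(name,
    canonical = c(list("C", c("C", "T")), rep(list(AT), 6),
                  list(c("A", "G"), "G")),
    srf_like = c(list("C", "C"), rep(list(AT), 6), list("G", "G")),
    n10_like = c(list("C", "T", "A"), rep(list(AT), 4),
                 list("T", "A", "G")),
    intermediate = c(list("C"), rep(list(AT), 6), list("A", "G")),
    stop("unknown pattern"))
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
        collapse = "")
}

oracle_count_mismatch <- function(window, sets) {
  ch <- strsplit(window, "")[[1]]
  sum(!mapply(function(b, s) b %in% s, ch, sets))
}

# Position-by-position scan of one sequence for the named patterns.
oracle_scan <- function(seqId, sequence, patternNames, budget,
                        bothStrands = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  rows <- list()
  for (pname in patternNames) {
    sets <- oracle_pattern_sets(pname)
    k <- length(sets)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      win <- substr(sequence, i, i + k - 1)
      mmF <- oracle_count_mismatch(win, sets)
      plusHit <- mmF <= budget
      if (plusHit)
        rows[[length(rows) + 1]] <- data.frame(
          seqId = seqId, start = i - 1L, end = i - 1L + k, strand = "+",
          matchedSeq = win, patternName = pname, nAtypical = mmF,
          stringsAsFactors = FALSE)
      if (bothStrands) {
        rcwin <- oracle_revcomp(win)
        mmR <- oracle_count_mismatch(rcwin, sets)
        if (mmR <= budget && !(plusHit && rcwin == win))
          rows[[length(rows) + 1]] <- data.frame(
            seqId = seqId, start = i - 1L, end = i - 1L + k,
            strand = "-", matchedSeq = rcwin, patternName = pname,
            nAtypical = mmR, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(seqId = character(), start = integer(),
                      end = integer(), strand = character(),
                      matchedSeq = character(), patternName = character(),
                      nAtypical = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand, out$patternName), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-replicate seed derivation shared by recovery tests and the
# acceptance protocol: block offsets keep replicate streams disjoint.
replicate_seed <- function(baseSeed, block, i) {
  as.integer((as.numeric(baseSeed) * 100000 + block + i) %%
               .Machine$integer.max)
}
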