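#' Scoring parameters for breakpoint-flank homology
#'
#' DNA local-alignment scoring used by [local_alignment_escore()]:
#' match/mismatch scores (+5/-4 by default, the classic DNA scoring), affine
#' gap costs (a gap of length L costs `gap_open + gap_extend * L`), and the
#' Karlin-Altschul parameters used to convert the optimal local score S into
#' an expectation-style E-score `E = K * m * n * exp(-lambda * S)` for
#' sequence lengths m and n.
#'
#' `lambda` is computed exactly for the ungapped score distribution under a
#' uniform base composition (the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`). `K` is a scale calibration
#' constant; it shifts all E-scores by a common factor and never changes
#' their ordering, which is how the score is used (descriptively, to flag
#' homology-driven artifacts — no hard threshold is applied).
#'
#' @param match,mismatch Match and mismatch scores.
#' @param gap_open,gap_extend Gap opening and per-base extension costs
#'   (positive numbers).
#' @param K Karlin-Altschul scale constant.
#' @return An object of class `homology_params`.
#' @export
homology_params <- function(match = 5, mismatch = -4,
                            gap_open = 12, gap_extend = 4, K = 0.1) {
  if (match <= 0 || mismatch >= 0) abort("need match > 0 and mismatch < 0")
  if (gap_open < 0 || gap_extend <= 0) abort("gap costs must be positive")
  lambda <- uniroot(
    function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1,
    lower = 1e-6, upper = 10, tol = 1e-12
  )$root
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 K = K, lambda = lambda),
            class = "homology_params")
}

#' Optimal Smith-Waterman local-alignment score
#'
#' Affine-gap Smith-Waterman between two DNA sequences. Ambiguity code `N`
#' scores 0 against everything (including itself).
#'
#' @param seq1,seq2 DNA sequences as single strings.
#' @param params A [homology_params()].
#' @return The optimal local alignment score (0 when nothing aligns).
#' @export
smith_waterman_score <- function(seq1, seq2, params = homology_params()) {
  s1 <- strsplit(toupper(seq1), "")[[1]]
  s2 <- strsplit(toupper(seq2), "")[[1]]
  n <- length(s1); m <- length(s2)
  if (n == 0 || m == 0) abort("sequences must be non-empty")
  gopen <- params$gap_open + params$gap_extend  # cost of the first gapped base
  gext <- params$gap_extend
  best <- 0
  Hprev <- numeric(m + 1)  # row i-1 of H
  Eprev <- numeric(m + 1)  # row i-1 of E (gap in seq2, vertical)
  for (i in seq_len(n)) {
    Hrow <- numeric(m + 1)
    Erow <- numeric(m + 1)
    Fcur <- 0  # gap in seq1 (horizontal), within current row
    a <- s1[i]
    for (j in seq_len(m)) {
      b <- s2[j]
      sub <- if (a == "N" || b == "N") 0 else if (a == b) params$match else params$mismatch
      Erow[j + 1] <- max(Hprev[j + 1] - gopen, Eprev[j + 1] - gext, 0)
      Fcur <- max(Hrow[j] - gopen, Fcur - gext, 0)
      h <- max(0, Hprev[j] + sub, Erow[j + 1], Fcur)
      Hrow[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- Hrow
    Eprev <- Erow
  }
  best
}

#' Local-alignment E-score of two sequences
#'
#' Aligns two sequences with [smith_waterman_score()] and converts the score
#' to an expectation-style E-score, `E = K * m * n * exp(-lambda * S)`.
#' Smaller E means stronger homology; the E-score behaves like a P-value for
#' the hypothesis that the sequences share no similarity.
#'
#' @inheritParams smith_waterman_score
#' @return A non-negative number; decreasing in the alignment score.
#' @export
#' @examples
#' p <- homology_params()
#' local_alignment_escore("ACGTACGTACGT", "ACGTACGTACGT", p)  # tiny: identity
#' local_alignment_escore("ACGTACGTACGT", "TTGCAATGCCTA", p)  # large: unrelated
local_alignment_escore <- function(seq1, seq2, params = homology_params()) {
  if (!nzchar(seq1) || !nzchar(seq2)) abort("sequences must be non-empty")
  S <- smith_waterman_score(seq1, seq2, params)
  params$K * nchar(seq1) * nchar(seq2) * exp(-params$lambda * S)
}

## Flank extraction ---------------------------------------------------------

load_reference <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (!methods::is(reference, "DNAStringSet")) {
    abort("'reference' must be a DNAStringSet or a FASTA path")
  }
  names(reference) <- sub("\\s.*$", "", names(reference))
  reference
}

# flanks of one breakpoint in transcription orientation
breakpoint_flanks <- function(reference, chrom, bp, strand, flank_len) {
  if (!chrom %in% names(reference)) abort("unknown contig '%s' in reference", chrom)
  contig <- reference[[chrom]]
  w <- length(contig)
  if (bp < 1 || bp > w) abort("breakpoint %d outside contig '%s'", bp, chrom)
  win <- function(from, to) {
    lo <- max(1L, from); hi <- min(w, to)
    list(seq = as.character(Biostrings::subseq(contig, lo, hi)),
         truncated = lo != from || hi != to)
  }
  if (strand == "+") {
    before <- win(bp - flank_len + 1L, bp)
    after <- win(bp + 1L, bp + flank_len)
    rc <- FALSE
  } else {
    # '-' strand: transcription runs toward lower coordinates on the
    # complement, so the mirrored genomic windows are reverse-complemented
    before <- win(bp, bp + flank_len - 1L)
    after <- win(bp - flank_len, bp - 1L)
    rc <- TRUE
  }
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  list(before = if (rc) revcomp(before$seq) else before$seq,
       after = if (rc) revcomp(after$seq) else after$seq,
       truncated = before$truncated || after$truncated)
}

#' Extract breakpoint flanking sequences for one fusion
#'
#' Retrieves the `flank_len` bases immediately before and after each
#' partner's breakpoint, read in transcription orientation (minus-strand
#' flanks are the reverse complement of the mirrored genomic window). The
#' before-flank ends at the breakpoint base; the after-flank starts at the
#' next transcribed base. Flanks running off a contig edge are truncated and
#' flagged with a warning.
#'
#' @param fusion One row of a consensus-fusion data.frame (caller-A
#'   breakpoint prediction).
#' @param reference A `DNAStringSet` or FASTA path.
#' @param flank_len Flank length in bases (default 20).
#' @return A list with elements `up5`, `up3` (before-flanks of the 5' and 3'
#'   partner), `down5`, `down3` (after-flanks) and `truncated`.
#' @export
extract_flanks <- function(fusion, reference, flank_len = 20L) {
  if (nrow(fusion) != 1) abort("extract_flanks works on a single fusion row")
  reference <- load_reference(reference)
  f5 <- breakpoint_flanks(reference, fusion$chrom5, fusion$bp5, fusion$strand5,
                          as.integer(flank_len))
  f3 <- breakpoint_flanks(reference, fusion$chrom3, fusion$bp3, fusion$strand3,
                          as.integer(flank_len))
  truncated <- f5$truncated || f3$truncated
  if (truncated) {
    warning("flank truncated at a contig edge", call. = FALSE)
  }
  list(up5 = f5$before, up3 = f3$before,
       down5 = f5$after, down3 = f3$after,
       truncated = truncated)
}

#' Homology score of one fusion's breakpoint flanks
#'
#' Aligns the two partners' before-flanks against each other and the two
#' after-flanks against each other, and returns the minimum of the two
#' E-scores as the fusion's homology score. A small score means the two
#' breakpoints sit in highly similar sequence, the signature of an
#' alignment-artifact "fusion" between paralogous or repetitive regions.
#'
#' @inheritParams extract_flanks
#' @param params A [homology_params()].
#' @return A list with `e_before`, `e_after` and `score = min(e_before,
#'   e_after)`.
#' @export
homology_score <- function(fusion, reference, params = homology_params(),
                           flank_len = 20L) {
  fl <- extract_flanks(fusion, reference, flank_len)
  e_before <- local_alignment_escore(fl$up5, fl$up3, params)
  e_after <- local_alignment_escore(fl$down5, fl$down3, params)
  list(e_before = e_before, e_after = e_after,
       score = min(e_before, e_after))
}

#' Score breakpoint-flank homology for a whole fusion table
#'
#' Fills the `homology_escore` column of a consensus-fusion table by running
#' [homology_score()] on every row (including rows already failed by the
#' read-support or gene-family filter, which are scored all the same).
#'
#' @param fusions Consensus-fusion data.frame.
#' @inheritParams homology_score
#' @return The data.frame with `homology_escore` filled.
#' @export
score_homology <- function(fusions, reference, params = homology_params(),
                           flank_len = 20L) {
  reference <- load_reference(reference)
  if (nrow(fusions) == 0) return(fusions)
  fusions$homology_escore <- vapply(seq_len(nrow(fusions)), function(i) {
    homology_score(fusions[i, , drop = FALSE], reference, params, flank_len)$score
  }, numeric(1))
  fusions
}
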