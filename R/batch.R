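# Set-level screening of a FASTA set of precursor sequences. Step 1 runs
# the per-sequence profile (and optionally the digest) exactly as the
# single-sequence tools would; step 2 aggregates, per target peptide:
#   a_T  = a_1 + ... + a_L      total occurrences over the set
#   a_S  = a_T / L              mean occurrences per sequence
#   A_S  = a_T / N_T            mean occurrence frequency
#   N_T  = N_1 + ... + N_L      total residues in the set
#   a_TE = a_1E + ... + a_LE    total release cases over the set
#   a_SE = a_TE / L             mean release cases per sequence
#   A_SE = a_TE / N_T           mean release frequency (also written A_TE)

.asSequenceSet <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- readFastaPeptides(x)
  if (is(x, "PeptideSequence")) x <- list(x)
  if (is.character(x)) x <- as.list(x)
  if (!length(x)) stop("the sequence set is empty", call. = FALSE)
  out <- lapply(x, asPeptideSequence)
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- paste0("seq", seq_along(out))
  out
}

#' Batch screening of a sequence set
#'
#' Runs the profile (and, when enzymes are given, the digest) on every
#' sequence of a FASTA set, then computes the set-level occurrence and
#' release parameters for each target peptide. Per-sequence outputs are
#' identical to running [buildProfile()]/[digestSequence()] on that
#' sequence alone.
#'
#' @param sequences a FASTA path, named list of
#'   [PeptideSequence-class]/strings, or character vector.
#' @param bundle a [DatabaseBundle-class].
#' @param activity one activity label or \code{"ALL"} (profiles and the
#'   candidate target list are restricted accordingly).
#' @param enzymeIds optional enzyme ids; when given, release parameters
#'   are computed from complete in-silico digests.
#' @param select optional character vector of target peptide sequences;
#'   default is every bioactive fragment found in the set (step 1 hits).
#' @param lengthCap advisory cap on the total set length in residues
#'   (mirrors the ~1500-residue web form limit); exceeding it warns but
#'   does not stop the analysis.
#' @return list with elements \code{profiles} (per-sequence
#'   [ActivityProfile-class]s), \code{digests} (per-sequence
#'   [DigestResult-class]s or NULL), and \code{report}: a data.frame with
#'   one row per target peptide (peptide, activity, L, N_T, a_T, a_S, A_S
#'   and -- with enzymes -- a_TE, a_SE, A_SE) plus list-columns \code{a_l}
#'   and \code{a_lE} of the per-sequence counts.
#' @examples
#' b <- generateFixture(seed = 5, nPeptides = 30, nEnzymes = 3)
#' res <- batchAnalyze(c(s1 = "RWAFAPGFAPGHIP", s2 = "APAP"), b)
#' res$report
#' @export
batchAnalyze <- function(sequences, bundle, activity = "ALL",
                         enzymeIds = NULL, select = NULL,
                         lengthCap = 1500L) {
  seqs <- .asSequenceSet(sequences)
  stopifnot(is(bundle, "DatabaseBundle"))
  L <- length(seqs)
  N_l <- vapply(seqs, function(s) length(s@tokens), 0L)
  N_T <- sum(N_l)
  if (N_T > lengthCap)
    warning(sprintf("set length %d residues exceeds the advisory cap of %d",
                    N_T, lengthCap), call. = FALSE)
  profiles <- lapply(seqs, buildProfile, bundle = bundle,
                     activity = activity)
  digests <- if (!is.null(enzymeIds))
    lapply(seqs, digestSequence, bundle = bundle, enzymeIds = enzymeIds)
  else NULL
  hitTab <- do.call(rbind, c(lapply(profiles, function(p)
    p@hits[c("fragment", "activity")]), make.row.names = FALSE))
  if (is.null(select)) {
    targets <- unique(hitTab)
  } else {
    targets <- unique(data.frame(fragment = select,
      activity = vapply(select, function(s) {
        a <- unique(hitTab$activity[hitTab$fragment == s])
        if (length(a)) a[1L] else NA_character_
      }, "")))
  }
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    frag <- targets$fragment[i]
    a_l <- vapply(seqs, function(s) nrow(findOccurrences(frag, s)), 0L)
    a_T <- sum(a_l)
    row <- data.frame(peptide = frag, activity = targets$activity[i],
                      L = L, N_T = N_T, a_T = a_T, a_S = a_T / L,
                      A_S = a_T / N_T)
    if (!is.null(digests)) {
      a_lE <- vapply(digests, function(d)
        sum(d@fragments$sequence == frag), 0L)
      a_TE <- sum(a_lE)
      row$a_TE <- a_TE; row$a_SE <- a_TE / L; row$A_SE <- a_TE / N_T
      row$a_lE <- list(a_lE)
    }
    row$a_l <- list(a_l)
    row
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), activity = character(),
               L = integer(), N_T = integer(), a_T = integer(),
               a_S = numeric(), A_S = numeric())
  rownames(report) <- NULL
  list(profiles = profiles, digests = digests, report = report)
}

#' Set-level release parameters for one peptide
#'
#' Digests every sequence of the set with the selected enzymes and counts
#' the cases in which a product fragment equals the target peptide
#' exactly: a_TE over the set, a_SE = a_TE/L and A_SE = a_TE/N_T (the
#' latter also written A_TE).
#'
#' @inheritParams batchAnalyze
#' @param peptide target peptide sequence (string or
#'   [PeptideSequence-class]).
#' @return list with a_TE, a_SE, A_SE, L, N_T and the per-sequence counts
#'   a_lE.
#' @export
setReleaseParameters <- function(sequences, bundle, enzymeIds, peptide) {
  seqs <- .asSequenceSet(sequences)
  frag <- as.character(asPeptideSequence(peptide))
  digests <- lapply(seqs, digestSequence, bundle = bundle,
                    enzymeIds = enzymeIds)
  a_lE <- vapply(digests, function(d) sum(d@fragments$sequence == frag), 0L)
  L <- length(seqs)
  N_T <- sum(vapply(seqs, function(s) length(s@tokens), 0L))
  list(a_TE = sum(a_lE), a_SE = sum(a_lE) / L, A_SE = sum(a_lE) / N_T,
       L = L, N_T = N_T, a_lE = a_lE)
}
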