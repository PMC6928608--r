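#' Parse an extended one-letter peptide sequence
#'
#' Tokenizes a sequence written in the extended one-letter code: the 20
#' standard amino acids in uppercase (L) with their D-enantiomers in
#' lowercase, \code{B}/\code{b} for L-/D-phosphoserine, and a single
#' trailing \code{"~"} marking a C-terminal amide. Lowercase \code{g} is
#' rejected because glycine is achiral.
#'
#' @param text non-empty character scalar, e.g. \code{"FhL"} for
#'   L-Phe-D-His-L-Leu or \code{"GHS"}.
#' @return a [PeptideSequence-class].
#' @examples
#' parseSequence("GHS")
#' parseSequence("FhL")
#' parseSequence("YPFP~")   # amidated
#' @export
parseSequence <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("sequence text must be a single non-empty string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  amid <- FALSE
  tilde <- which(chars == "~")
  if (length(tilde)) {
    if (length(tilde) > 1L || tilde != length(chars))
      stop("'~' (C-terminal amide) may appear only once, in final position",
           call. = FALSE)
    amid <- TRUE
    chars <- chars[-length(chars)]
  }
  if (!length(chars))
    stop("sequence must contain at least one residue", call. = FALSE)
  bad <- which(!chars %in% names(.RESIDUE_BASE))
  if (length(bad)) {
    what <- ifelse(chars[bad] == "g",
                   "'g' (glycine is achiral; use 'G')",
                   paste0("'", chars[bad], "'"))
    stop(sprintf("invalid residue character %s at position %s",
                 what[1L], bad[1L]), call. = FALSE)
  }
  new("PeptideSequence", tokens = chars, amidated = amid)
}

asPeptideSequence <- function(x) {
  if (is(x, "PeptideSequence")) x else parseSequence(x)
}

#' @describeIn parseSequence number of residues N (the amide marker is not
#'   a residue).
#' @param x a \code{PeptideSequence}.
#' @export
setMethod("length", "PeptideSequence", function(x) length(x@tokens))

#' Text form of a peptide sequence
#'
#' Inverse of [parseSequence()]: residue tokens concatenated, with a
#' trailing \code{"~"} if amidated.
#'
#' @param x a [PeptideSequence-class].
#' @param ... ignored.
#' @export
setMethod("as.character", "PeptideSequence", function(x, ...) {
  paste0(paste(x@tokens, collapse = ""), if (x@amidated) "~" else "")
})

setMethod("show", "PeptideSequence", function(object) {
  ch <- .tokenChirality(object@tokens)
  cat(sprintf("PeptideSequence: %s (%d residue%s%s%s)\n",
              as.character(object), length(object@tokens),
              if (length(object@tokens) == 1L) "" else "s",
              if (any(ch == "D")) ", contains D-residues" else "",
              if (object@amidated) ", C-terminal amide" else ""))
})

#' Residue token table
#'
#' One row per residue position: token, base residue letter and chirality.
#'
#' @param x a [PeptideSequence-class] or string.
#' @return data.frame with columns position, token, base, chirality.
#' @export
residueTokens <- function(x) {
  x <- asPeptideSequence(x)
  data.frame(position = seq_along(x@tokens), token = x@tokens,
             base = unname(.RESIDUE_BASE[x@tokens]),
             chirality = .tokenChirality(x@tokens))
}

#' Locate all occurrences of a fragment in a sequence
#'
#' Token-exact, case-sensitive search (a D-residue never matches its L
#' counterpart). Overlapping occurrences are all reported, sorted by start
#' position; coordinates are 1-based inclusive. An amidated fragment can
#' only occur at the C-terminus of an amidated sequence, since an internal
#' residue cannot carry a C-terminal amide.
#'
#' @param fragment,sequence [PeptideSequence-class] objects or strings.
#' @return data.frame with integer columns start, end (zero rows if the
#'   fragment does not occur).
#' @examples
#' findOccurrences("AP", "RWAFAPGFAPGHIP")  # positions 5-6 and 9-10
#' findOccurrences("AA", "AAA")             # overlapping: 1-2 and 2-3
#' @export
findOccurrences <- function(fragment, sequence) {
  fragment <- asPeptideSequence(fragment)
  sequence <- asPeptideSequence(sequence)
  m <- length(fragment@tokens); n <- length(sequence@tokens)
  empty <- data.frame(start = integer(), end = integer())
  if (m > n) return(empty)
  if (fragment@amidated) {
    if (!sequence@amidated) return(empty)
    tail_match <- identical(sequence@tokens[(n - m + 1L):n], fragment@tokens)
    return(if (tail_match)
             data.frame(start = n - m + 1L, end = n) else empty)
  }
  # overlap-counting scan via zero-width lookahead on the token string
  pat <- paste0("(?=", paste(fragment@tokens, collapse = ""), ")")
  hit <- gregexpr(pat, paste(sequence@tokens, collapse = ""),
                  perl = TRUE)[[1L]]
  if (hit[1L] == -1L) return(empty)
  data.frame(start = as.integer(hit), end = as.integer(hit) + m - 1L)
}

#' Read peptide sequences from a FASTA file
#'
#' Records are parsed and validated under the extended alphabet; a
#' malformed residue is reported with its record identifier and position.
#' Order is preserved and \code{writeFastaPeptides(readFastaPeptides(f))}
#' reproduces the content.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return named list of [PeptideSequence-class] objects; names are the
#'   FASTA identifiers (first whitespace-delimited word of each header).
#' @export
readFastaPeptides <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set))
    stop("no FASTA records found in '", path, "'", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- tryCatch(parseSequence(as.character(set[[i]])),
      error = function(e)
        stop(sprintf("record '%s': %s", ids[i], conditionMessage(e)),
             call. = FALSE))
  }
  names(out) <- ids
  out
}

#' Write peptide sequences to a FASTA file
#'
#' @param sequences named list of [PeptideSequence-class] objects (or
#'   strings); names become the FASTA identifiers.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastaPeptides <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every sequence needs a name for the FASTA header", call. = FALSE)
  txt <- vapply(sequences, function(s)
    as.character(asPeptideSequence(s)), "")
  set <- Biostrings::BStringSet(txt)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
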