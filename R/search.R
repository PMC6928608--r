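# Database search semantics. Text fields (name, activity, sequence,
# inchikey) support substring containment or whole-value equality
# ("exact"); id, mass and length ignore the exact flag. A peptide with k
# activity annotations is k records and can appear k times.

#' Search the peptide table
#'
#' @param bundle a [DatabaseBundle-class].
#' @param field one of \code{"id"}, \code{"name"}, \code{"activity"},
#'   \code{"mass"}, \code{"length"}, \code{"sequence"}, \code{"inchikey"}.
#' @param query the query: an id for \code{"id"}; text for the text
#'   fields; a closed numeric range \code{c(lo, hi)} in Da for
#'   \code{"mass"}; a positive residue count for \code{"length"}.
#' @param exact if \code{TRUE}, text fields match by whole-value equality
#'   instead of substring containment; ignored for id, mass and length.
#'   Name and activity matching is case-insensitive; sequence matching is
#'   case-sensitive (a D-residue is a different peptide from its L form).
#' @return data.frame of matching peptide records (possibly zero rows),
#'   in id order.
#' @examples
#' b <- generateFixture(seed = 1, nPeptides = 30, nEnzymes = 2)
#' searchPeptides(b, "activity", "inhibitor")               # substring
#' searchPeptides(b, "activity", "ACE inhibitor", exact = TRUE)
#' @export
searchPeptides <- function(bundle, field, query, exact = FALSE) {
  stopifnot(is(bundle, "DatabaseBundle"))
  p <- bundle@peptides
  field <- match.arg(field, c("id", "name", "activity", "mass", "length",
                              "sequence", "inchikey"))
  keep <- switch(field,
    id = {
      q <- as.integer(query)
      if (length(q) != 1L || is.na(q)) stop("id query must be one integer",
                                            call. = FALSE)
      p$id == q
    },
    mass = {
      q <- as.numeric(query)
      if (length(q) != 2L || anyNA(q) || q[1] > q[2])
        stop("mass query must be a closed range c(lo, hi)", call. = FALSE)
      m <- ifelse(is.na(p$chemical_mass_Da),
                  vapply(p$sequence,
                         function(s) peptideMasses(s)[["average"]], 0),
                  p$chemical_mass_Da)
      m >= q[1] & m <= q[2]
    },
    length = {
      q <- as.integer(query)
      if (length(q) != 1L || is.na(q) || q < 1L)
        stop("length query must be one positive integer", call. = FALSE)
      nchar(sub("~$", "", p$sequence)) == q
    },
    name = .textMatch(p$name, query, exact, ignore_case = TRUE),
    activity = .textMatch(p$activity, query, exact, ignore_case = TRUE),
    sequence = .textMatch(p$sequence, query, exact, ignore_case = FALSE),
    inchikey = .textMatch(p$inchikey, query, exact, ignore_case = FALSE))
  out <- p[which(keep), , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

.textMatch <- function(values, query, exact, ignore_case) {
  if (!is.character(query) || length(query) != 1L || is.na(query) ||
      !nzchar(query))
    stop("text query must be one non-empty string", call. = FALSE)
  v <- values
  q <- query
  if (ignore_case) { v <- tolower(v); q <- tolower(q) }
  hit <- if (exact) v == q else grepl(q, v, fixed = TRUE)
  !is.na(hit) & hit
}

#' Find records whose sequence contains a fragment
#'
#' Token-exact containment (the semantics of [findOccurrences()]): every
#' returned record's sequence contains the fragment as a contiguous,
#' case-matching subsequence.
#'
#' @param fragment a [PeptideSequence-class] or string.
#' @param bundle a [DatabaseBundle-class].
#' @param records optional data.frame with \code{sequence} (and ideally
#'   \code{id}, \code{name}) columns to scan instead of the bundle's
#'   peptide table -- e.g. a protein collection.
#' @return data.frame of matching records with an added integer column
#'   \code{n_occurrences}.
#' @export
findSequencesContaining <- function(fragment, bundle, records = NULL) {
  fragment <- asPeptideSequence(fragment)
  if (is.null(records)) {
    stopifnot(is(bundle, "DatabaseBundle"))
    records <- bundle@peptides
  }
  counts <- vapply(records$sequence,
                   function(s) nrow(findOccurrences(fragment, s)), 0L,
                   USE.NAMES = FALSE)
  out <- records[counts > 0L, , drop = FALSE]
  out$n_occurrences <- counts[counts > 0L]
  rownames(out) <- NULL
  out
}
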