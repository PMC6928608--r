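#' @import methods
NULL

#' Tokenized extended peptide sequence
#'
#' Ordered residue tokens in the extended one-letter alphabet: uppercase
#' letters are L-residues, lowercase letters their D-enantiomers (glycine,
#' being achiral, has no lowercase form), \code{B}/\code{b} are L-/D-
#' phosphoserine, and a C-terminal amide is carried as a flag (annotated
#' \code{"~"} in text form, which is not itself a residue).
#'
#' @slot tokens character vector of single-character residue tokens.
#' @slot amidated logical scalar; \code{TRUE} for a C-terminal amide.
#'
#' @seealso [parseSequence()], [composition()], [peptideMasses()]
#' @export
setClass("PeptideSequence",
  representation(tokens = "character", amidated = "logical"),
  prototype(tokens = character(), amidated = FALSE)
)

setValidity("PeptideSequence", function(object) {
  msg <- character()
  if (length(object@tokens) < 1L)
    msg <- c(msg, "sequence must contain at least one residue")
  if (length(object@amidated) != 1L || is.na(object@amidated))
    msg <- c(msg, "'amidated' must be TRUE or FALSE")
  bad <- setdiff(object@tokens, names(.RESIDUE_BASE))
  if (length(bad))
    msg <- c(msg, paste0("invalid residue token(s): ",
                         paste(unique(bad), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Peptide/enzyme database bundle
#'
#' In-memory representation of the peptide and enzyme databases: one
#' peptide record per (sequence, activity) annotation (a multifunctional
#' peptide appears once per activity, under distinct ids), enzyme records
#' with one or more cleavage specificity rules, and the controlled
#' activity vocabulary.
#'
#' @slot peptides data.frame of peptide records (id, name, sequence,
#'   activity, activity_code, fun_text, ec50_uM, chemical_mass_Da,
#'   monoisotopic_mass_Da, smiles, inchikey, references).
#' @slot enzymes data.frame of enzyme records (enzyme_id, name, ec_number,
#'   merops_id).
#' @slot rules data.frame of specificity rules (connection_id, enzyme_id,
#'   recognition_seq, cut_residue_index, side). \code{side = "after"}
#'   marks a bond formed by the carboxyl group of the cut residue
#'   (C-terminus annotation), \code{"before"} a bond formed by its amine
#'   group (N-terminus annotation).
#' @slot activities data.frame with columns activity, description.
#' @slot metadata list (version, provenance).
#'
#' @seealso [loadBundle()], [generateFixture()], [searchPeptides()]
#' @export
setClass("DatabaseBundle",
  representation(peptides = "data.frame", enzymes = "data.frame",
                 rules = "data.frame", activities = "data.frame",
                 metadata = "list")
)

setValidity("DatabaseBundle", function(object) {
  msg <- character()
  p <- object@peptides
  if (nrow(p)) {
    if (anyDuplicated(p$id))
      msg <- c(msg, "duplicate peptide id(s)")
    unknown <- setdiff(p$activity, object@activities$activity)
    if (length(unknown))
      msg <- c(msg, paste0("unknown activity label(s): ",
                           paste(unique(unknown), collapse = ", ")))
    if (any(!is.na(p$ec50_uM) & p$ec50_uM <= 0))
      msg <- c(msg, "ec50_uM values must be positive or NA")
    ik <- p$inchikey[!is.na(p$inchikey)]
    if (length(ik) && any(nchar(ik) != 27L | substr(ik, 15, 15) != "-" |
                          substr(ik, 26, 26) != "-"))
      msg <- c(msg, "inchikey must have 27 characters with hyphens at 15 and 26")
  }
  if (nrow(object@enzymes) && anyDuplicated(object@enzymes$enzyme_id))
    msg <- c(msg, "duplicate enzyme_id(s)")
  r <- object@rules
  if (nrow(r)) {
    if (anyDuplicated(r$connection_id))
      msg <- c(msg, "duplicate connection_id(s)")
    if (length(setdiff(r$enzyme_id, object@enzymes$enzyme_id)))
      msg <- c(msg, "rule refers to unknown enzyme_id")
    if (any(r$cut_residue_index < 1L |
            r$cut_residue_index > nchar(r$recognition_seq)))
      msg <- c(msg, "cut_residue_index outside recognition sequence")
    if (any(!r$side %in% c("after", "before")))
      msg <- c(msg, "rule side must be 'after' or 'before'")
    if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", r$recognition_seq)))
      msg <- c(msg, "recognition_seq must use the standard 20-letter alphabet")
  }
  if (nrow(object@enzymes) &&
      length(setdiff(object@enzymes$enzyme_id, r$enzyme_id)))
    msg <- c(msg, "every enzyme needs at least one specificity rule")
  if (anyDuplicated(object@activities$activity))
    msg <- c(msg, "duplicate activity label(s)")
  if (length(msg)) msg else TRUE
})

#' Profile of potential biological activity
#'
#' Located bioactive fragments in a query sequence: one hit per distinct
#' (fragment sequence, activity) pair, with its occurrence count and
#' 1-based inclusive locations.
#'
#' @slot query the query [PeptideSequence-class].
#' @slot activity the activity filter used (\code{"ALL"} or one label).
#' @slot hits data.frame (id, name, activity, fragment, a_i, ec50_uM,
#'   locations list-column of start/end matrices).
#'
#' @seealso [buildProfile()], [frequencyA()], [potencyB()]
#' @export
setClass("ActivityProfile",
  representation(query = "PeptideSequence", activity = "character",
                 hits = "data.frame")
)

#' Result of an in-silico digest
#'
#' Cleavage sites and product fragments of complete in-silico hydrolysis
#' of a precursor by the selected endopeptidases. Bond k joins residues k
#' and k+1; fragments tile the precursor.
#'
#' @slot precursor the digested [PeptideSequence-class].
#' @slot enzymeIds integer vector of enzyme ids used.
#' @slot sites data.frame (bond, contributors list-column of
#'   enzyme_id/connection_id data.frames).
#' @slot fragments data.frame (sequence, start, end).
#' @slot dBonds number of hydrolyzed bonds.
#' @slot DBonds total number of peptide bonds (N - 1).
#' @slot DHt theoretical degree of hydrolysis, percent.
#'
#' @seealso [digestSequence()], [releasedBioactive()]
#' @export
setClass("DigestResult",
  representation(precursor = "PeptideSequence", enzymeIds = "integer",
                 sites = "data.frame", fragments = "data.frame",
                 dBonds = "integer", DBonds = "integer", DHt = "numeric")
)

setValidity("DigestResult", function(object) {
  msg <- character()
  f <- object@fragments
  N <- length(object@precursor@tokens)
  if (nrow(f)) {
    if (f$start[1] != 1L || f$end[nrow(f)] != N ||
        (nrow(f) > 1L && any(f$start[-1] != f$end[-nrow(f)] + 1L)))
      msg <- c(msg, "fragments must tile the precursor")
  }
  if (object@DHt < 0 || object@DHt > 100)
    msg <- c(msg, "DHt must lie in [0, 100]")
  if (nrow(f) != object@dBonds + 1L)
    msg <- c(msg, "fragment count must equal dBonds + 1")
  if (length(msg)) msg else TRUE
})
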