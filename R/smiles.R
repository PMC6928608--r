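# Peptide-to-SMILES conversion by residue-block concatenation, producing
# aromatic SMILES for linear peptides. Each residue contributes one
# literal block (free alpha-amine through carbonyl, SwissSidechain/CycloPs
# layout, shipped as an editable JSON data file); the chain is the plain
# concatenation of blocks -- the leading N of the first block is the free
# alpha-amine -- closed by a one-atom terminal suffix: "O" for the free
# acid, "N" for a C-terminal amide. A D-residue block is the L block with
# every chirality tag inverted. Structure validation and InChI/InChIKey
# derivation are delegated to a standard InChI implementation (OpenBabel's
# obabel executable) behind a small backend contract; the converter itself
# has no external dependency.

.smilesTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "residue_smiles.json",
                          package = "biopepkit", mustWork = TRUE)
      cache <<- jsonlite::fromJSON(path)
    }
    cache
  }
})

.invertChirality <- function(block) {
  block <- gsub("@@", "\r", block, fixed = TRUE)
  block <- gsub("@", "@@", block, fixed = TRUE)
  gsub("\r", "@", block, fixed = TRUE)
}

#' Convert a peptide sequence to aromatic SMILES
#'
#' Deterministic residue-block concatenation: equal sequences always give
#' equal strings, and a D-residue differs from its L form only in
#' inverted chirality tags. Only linear peptides are supported.
#'
#' @param x a [PeptideSequence-class] or string in the extended alphabet.
#' @return a SMILES string.
#' @examples
#' toSmiles("GHS")
#' toSmiles("G~")   # glycinamide
#' @export
toSmiles <- function(x) {
  x <- asPeptideSequence(x)
  tab <- .smilesTable()
  blocks <- vapply(x@tokens, function(tok) {
    base <- .RESIDUE_BASE[[tok]]
    blk <- tab$blocks[[base]]
    if (.tokenChirality(tok) == "D") blk <- .invertChirality(blk)
    blk
  }, "")
  paste0(paste(blocks, collapse = ""),
         if (x@amidated) tab$terminal$amide else tab$terminal$acid)
}

#' Is the OpenBabel backend available?
#'
#' The InChI-dependent operations ([toInchiKey()], [toInchi()],
#' [validateStructure()]) shell out to the \code{obabel} executable. All
#' other functionality works without it.
#'
#' @return \code{TRUE} if \code{obabel} is on the PATH.
#' @export
obabelAvailable <- function() nzchar(Sys.which("obabel"))

.obabelConvert <- function(smiles, format) {
  if (!obabelAvailable())
    stop("unsupported operation: the 'obabel' executable (OpenBabel) is ",
         "required for InChI/InChIKey derivation but was not found",
         call. = FALSE)
  out <- suppressWarnings(system2("obabel",
    c(shQuote(paste0("-:", smiles)), paste0("-o", format)),
    stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(out)]
  if (!length(out))
    stop("OpenBabel could not convert the SMILES string: ", smiles,
         call. = FALSE)
  out[[1L]]
}

#' Standard InChI of a peptide sequence
#'
#' The InChI of the structure produced by [toSmiles()]: neutral acidic
#' and basic groups, all chirality centres defined, cysteines reduced.
#'
#' @inheritParams toSmiles
#' @return an InChI string (\code{"InChI=1S/..."}).
#' @export
toInchi <- function(x) .obabelConvert(toSmiles(x), "inchi")

#' Standard InChIKey of a peptide sequence
#'
#' @inheritParams toSmiles
#' @return a 27-character InChIKey with hyphens at positions 15 and 26.
#' @examples
#' \dontrun{toInchiKey("GHS")  # LPCKHUXOGVNZRS-YUMQZZPRSA-N}
#' @export
toInchiKey <- function(x) {
  key <- .obabelConvert(toSmiles(x), "inchikey")
  key <- trimws(key)
  if (nchar(key) != 27L || substr(key, 15, 15) != "-" ||
      substr(key, 26, 26) != "-")
    stop("backend returned a malformed InChIKey: ", key, call. = FALSE)
  key
}

#' Validate a generated structure against the sequence composition
#'
#' Re-parses the SMILES produced by [toSmiles()] with the external InChI
#' backend and checks that the parsed molecular formula equals the
#' formula computed independently from the residue composition table.
#'
#' @inheritParams toSmiles
#' @return list with elements \code{ok} (logical), \code{smiles},
#'   \code{formula_expected}, \code{formula_parsed} and \code{inchi}.
#'   A parse failure or formula mismatch has \code{ok = FALSE} and a
#'   \code{message} element naming the problem.
#' @export
validateStructure <- function(x) {
  x <- asPeptideSequence(x)
  smiles <- toSmiles(x)
  expected <- molecularFormula(composition(x))
  inchi <- tryCatch(.obabelConvert(smiles, "inchi"), error = identity)
  if (inherits(inchi, "error"))
    return(list(ok = FALSE, smiles = smiles, formula_expected = expected,
                formula_parsed = NA_character_, inchi = NA_character_,
                message = paste("SMILES parse failure:",
                                conditionMessage(inchi))))
  parsed <- strsplit(trimws(inchi), "/", fixed = TRUE)[[1L]][2L]
  ok <- identical(parsed, expected)
  out <- list(ok = ok, smiles = smiles, formula_expected = expected,
              formula_parsed = parsed, inchi = trimws(inchi))
  if (!ok)
    out$message <- sprintf("formula mismatch: SMILES parses to %s, %s",
                           parsed, paste0("composition gives ", expected))
  out
}
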