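# Database bundle I/O. Canonical on-disk form is JSON (UTF-8, fixed key
# order); TSV tables (peptides.tsv, enzymes.tsv, rules.tsv,
# activities.tsv) are provided for spreadsheet interchange.

.PEPTIDE_COLS <- c("id", "name", "sequence", "activity", "activity_code",
                   "fun_text", "ec50_uM", "chemical_mass_Da",
                   "monoisotopic_mass_Da", "smiles", "inchikey",
                   "references", "cross_refs")
.ENZYME_COLS <- c("enzyme_id", "name", "ec_number", "merops_id")
.RULE_COLS <- c("connection_id", "enzyme_id", "recognition_seq",
                "cut_residue_index", "side")

.emptyPeptides <- function() {
  data.frame(id = integer(), name = character(), sequence = character(),
             activity = character(), activity_code = character(),
             fun_text = character(), ec50_uM = numeric(),
             chemical_mass_Da = numeric(), monoisotopic_mass_Da = numeric(),
             smiles = character(), inchikey = character(),
             references = character(), cross_refs = character())
}

.emptyEnzymes <- function() {
  data.frame(enzyme_id = integer(), name = character(),
             ec_number = character(), merops_id = character())
}

.emptyRules <- function() {
  data.frame(connection_id = integer(), enzyme_id = integer(),
             recognition_seq = character(), cut_residue_index = integer(),
             side = character())
}

#' The shipped activity vocabulary
#'
#' Controlled vocabulary of bioactivity labels (ACE inhibitor,
#' antioxidative, opioid, ...) with short descriptions, shipped as an
#' editable TSV data file rather than hard code.
#'
#' @return data.frame with columns activity, description.
#' @export
defaultActivities <- function() {
  path <- system.file("extdata", "activities.tsv", package = "biopepkit",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
}

.coerceTable <- function(df, template, table, idcol) {
  if (is.null(df) || (is.list(df) && !length(df))) return(template)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(template), names(df))
  for (cc in missing_cols) df[[cc]] <- template[[cc]][NA_integer_][seq_len(nrow(df))]
  df <- df[names(template)]
  for (cc in names(template)) {
    target <- class(template[[cc]])[1L]
    df[[cc]] <- switch(target,
                       integer = as.integer(df[[cc]]),
                       numeric = as.numeric(df[[cc]]),
                       as.character(df[[cc]]))
  }
  if (anyNA(df[[idcol]]))
    stop(sprintf("table '%s': missing or non-numeric '%s'", table, idcol),
         call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Assemble and validate a database bundle
#'
#' Low-level constructor used by [loadBundle()], [importBundleTSV()] and
#' [generateFixture()]. Validates ids, activity labels, rule geometry and
#' InChIKey shape; non-positive EC50/IC50 values are demoted to absent
#' with a warning (a reciprocal-weighted potency cannot use them), and
#' duplicate (sequence, activity) pairs are flagged.
#'
#' @param peptides,enzymes,rules,activities data.frames in the documented
#'   schema; \code{activities} defaults to the shipped vocabulary.
#' @param metadata list of free-form bundle metadata.
#' @return a validated [DatabaseBundle-class].
#' @export
makeBundle <- function(peptides = NULL, enzymes = NULL, rules = NULL,
                       activities = defaultActivities(),
                       metadata = list()) {
  peptides <- .coerceTable(peptides, .emptyPeptides(), "peptides", "id")
  enzymes <- .coerceTable(enzymes, .emptyEnzymes(), "enzymes", "enzyme_id")
  rules <- .coerceTable(rules, .emptyRules(), "rules", "connection_id")
  activities <- as.data.frame(activities, stringsAsFactors = FALSE)
  bad <- !is.na(peptides$ec50_uM) & peptides$ec50_uM <= 0
  if (any(bad)) {
    warning(sprintf(
      "non-positive EC50/IC50 for peptide id(s) %s stored as absent",
      paste(peptides$id[bad], collapse = ", ")), call. = FALSE)
    peptides$ec50_uM[bad] <- NA_real_
  }
  for (s in peptides$sequence) parseSequence(s)
  dup <- duplicated(peptides[c("sequence", "activity")])
  if (any(dup))
    message(sprintf("note: %d duplicate (sequence, activity) record(s); %s",
                    sum(dup),
                    "profiles collapse duplicates to a single hit"))
  b <- new("DatabaseBundle", peptides = peptides, enzymes = enzymes,
           rules = rules, activities = activities, metadata = metadata)
  validObject(b)
  b
}

#' @describeIn makeBundle accessor for the peptide table.
#' @param bundle a [DatabaseBundle-class].
#' @export
peptides <- function(bundle) bundle@peptides

#' @describeIn makeBundle accessor for the enzyme table.
#' @export
enzymes <- function(bundle) bundle@enzymes

#' @describeIn makeBundle accessor for the specificity-rule table.
#' @export
specificityRules <- function(bundle) bundle@rules

#' @describeIn makeBundle accessor for the activity vocabulary.
#' @export
activities <- function(bundle) bundle@activities

setMethod("show", "DatabaseBundle", function(object) {
  cat(sprintf(paste0("DatabaseBundle: %d peptide record(s), %d enzyme(s) ",
                     "with %d rule(s), %d activity label(s)\n"),
              nrow(object@peptides), nrow(object@enzymes),
              nrow(object@rules), nrow(object@activities)))
})

.bundleAsList <- function(bundle) {
  df_rows <- function(df) {
    if (!nrow(df)) return(list())
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row[!vapply(row, is.na, NA)]
    })
  }
  list(activities = df_rows(bundle@activities),
       enzymes = df_rows(bundle@enzymes),
       metadata = bundle@metadata,
       peptides = df_rows(bundle@peptides),
       rules = df_rows(bundle@rules),
       schema_version = "1.0")
}

#' Save a database bundle as canonical JSON
#'
#' UTF-8 JSON with a fixed key order; absent optional fields are omitted,
#' so \code{saveBundle(loadBundle(f), g)} reproduces \code{f} byte for
#' byte.
#'
#' @param bundle a [DatabaseBundle-class].
#' @param path output file (conventionally \code{.json}).
#' @return \code{path}, invisibly.
#' @export
saveBundle <- function(bundle, path) {
  json <- jsonlite::toJSON(.bundleAsList(bundle), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a database bundle from canonical JSON
#'
#' @param path JSON file written by [saveBundle()] (or conforming to the
#'   documented schema).
#' @return a validated [DatabaseBundle-class].
#' @export
loadBundle <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e)
                    stop("cannot parse bundle JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(raw) || is.null(raw$peptides))
    stop("bundle JSON lacks a 'peptides' table", call. = FALSE)
  meta <- raw$metadata
  if (is.null(meta)) meta <- list()
  acts <- raw$activities
  if (is.null(acts) || !length(acts)) acts <- defaultActivities()
  makeBundle(peptides = raw$peptides, enzymes = raw$enzymes,
             rules = raw$rules, activities = acts, metadata = meta)
}

#' Export a bundle as TSV tables
#'
#' Writes peptides.tsv, enzymes.tsv, rules.tsv and activities.tsv
#' (tab-separated, header row, UTF-8) into a directory.
#'
#' @param bundle a [DatabaseBundle-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
exportBundleTSV <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
  wr(bundle@peptides, "peptides.tsv")
  wr(bundle@enzymes, "enzymes.tsv")
  wr(bundle@rules, "rules.tsv")
  wr(bundle@activities, "activities.tsv")
  invisible(dir)
}

#' Import a bundle from TSV tables
#'
#' @param dir directory holding peptides.tsv (required) and optionally
#'   enzymes.tsv, rules.tsv, activities.tsv as written by
#'   [exportBundleTSV()].
#' @return a validated [DatabaseBundle-class].
#' @export
importBundleTSV <- function(dir) {
  rd <- function(f, required = FALSE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing table '", f, "' in ", dir, call. = FALSE)
      return(NULL)
    }
    df <- utils::read.delim(p, stringsAsFactors = FALSE, quote = "",
                            comment.char = "", na.strings = "")
    if ("references" %in% names(df))
      df$references <- as.character(df$references)
    df
  }
  acts <- rd("activities.tsv")
  if (is.null(acts)) acts <- defaultActivities()
  makeBundle(peptides = rd("peptides.tsv", required = TRUE),
             enzymes = rd("enzymes.tsv"), rules = rd("rules.tsv"),
             activities = acts,
             metadata = list(provenance = paste0("TSV import: ", dir)))
}
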