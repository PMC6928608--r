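# In-silico proteolysis. Complete hydrolysis is assumed: every bond
# theoretically susceptible to a selected proteinase is cleaved. Bond k
# joins residues k and k+1 (k in [1, N-1]). A rule with recognition
# sequence R, cut residue index c and side "after" cleaves the bond formed
# by the carboxyl group of the cut residue (C-terminus annotation; cutting
# sequence rendered "X-"); side "before" cleaves the bond formed by its
# amine group (N-terminus annotation; rendered "X+").

.rowsForEnzymes <- function(bundle, enzymeIds) {
  enzymeIds <- as.integer(enzymeIds)
  missing_ids <- setdiff(enzymeIds, bundle@enzymes$enzyme_id)
  if (length(missing_ids))
    stop("unknown enzyme_id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  bundle@rules[bundle@rules$enzyme_id %in% enzymeIds, , drop = FALSE]
}

# bonds cleaved by one rule in a precursor token string
.ruleBonds <- function(rule, tokens, cleaveModified = FALSE) {
  N <- length(tokens)
  seqstr <- paste(tokens, collapse = "")
  pat <- paste0("(?=", rule$recognition_seq, ")")  # rules are L/uppercase
  w <- gregexpr(pat, seqstr, perl = TRUE)[[1L]]
  if (w[1L] == -1L) return(integer())
  off <- if (rule$side == "after") rule$cut_residue_index - 1L
         else rule$cut_residue_index - 2L
  bonds <- as.integer(w) + off
  bonds <- bonds[bonds >= 1L & bonds <= N - 1L]
  if (!cleaveModified && length(bonds)) {
    # D-residues and phosphoserine flanking a bond leave it resistant
    modified <- tokens != toupper(tokens) | toupper(tokens) == "B"
    bonds <- bonds[!(modified[bonds] | modified[bonds + 1L])]
  }
  sort(unique(bonds))
}

#' Cleavage sites of selected enzymes in a precursor
#'
#' Applies every specificity rule of the selected enzymes; the result is
#' the union of the single-enzyme bond sets, deduplicated with the
#' contributing (enzyme_id, connection_id) pairs merged per bond. By
#' default bonds flanked by a D-residue or phosphoserine are treated as
#' resistant (\code{cleaveModified = FALSE}).
#'
#' @param precursor a [PeptideSequence-class] or string.
#' @param bundle a [DatabaseBundle-class].
#' @param enzymeIds integer vector of enzyme ids (any number; the web-style
#'   front end restricts itself to 1--3).
#' @param cleaveModified set \code{TRUE} to let rules cleave bonds
#'   adjacent to D-residues/phosphoserine.
#' @return data.frame with integer column \code{bond} (sorted) and
#'   list-column \code{contributors} of data.frames (enzyme_id,
#'   connection_id).
#' @examples
#' b <- fAfterBundle <- makeBundle(
#'   peptides = data.frame(id = 1L, name = "AP", sequence = "AP",
#'                         activity = "ACE inhibitor"),
#'   enzymes = data.frame(enzyme_id = 1L, name = "Phe-C proteinase",
#'                        ec_number = "3.4.21.999", merops_id = NA),
#'   rules = data.frame(connection_id = 1L, enzyme_id = 1L,
#'                      recognition_seq = "F", cut_residue_index = 1L,
#'                      side = "after"))
#' cleavageSites("RWAFAPGFAPGHIP", b, 1L)   # bonds 4 and 8
#' @export
cleavageSites <- function(precursor, bundle, enzymeIds,
                          cleaveModified = FALSE) {
  precursor <- asPeptideSequence(precursor)
  stopifnot(is(bundle, "DatabaseBundle"))
  rules <- .rowsForEnzymes(bundle, enzymeIds)
  contrib <- list()
  for (i in seq_len(nrow(rules))) {
    bonds <- .ruleBonds(rules[i, ], precursor@tokens, cleaveModified)
    for (bnd in bonds) {
      key <- as.character(bnd)
      contrib[[key]] <- rbind(contrib[[key]],
        data.frame(enzyme_id = rules$enzyme_id[i],
                   connection_id = rules$connection_id[i]))
    }
  }
  bonds <- sort(as.integer(names(contrib)))
  out <- data.frame(bond = bonds)
  out$contributors <- lapply(as.character(bonds), function(k) {
    df <- contrib[[k]]
    df[order(df$enzyme_id, df$connection_id), , drop = FALSE]
  })
  out
}

#' Simulate complete proteolysis of a precursor
#'
#' Cleaves every susceptible bond (see [cleavageSites()]) and returns the
#' product fragments, which tile the precursor, together with the
#' theoretical degree of hydrolysis DH_T = d/D x 100, where d is the
#' number of hydrolyzed bonds and D = N - 1 the total number of peptide
#' bonds.
#'
#' @inheritParams cleavageSites
#' @return a [DigestResult-class].
#' @export
digestSequence <- function(precursor, bundle, enzymeIds,
                           cleaveModified = FALSE) {
  precursor <- asPeptideSequence(precursor)
  sites <- cleavageSites(precursor, bundle, enzymeIds, cleaveModified)
  N <- length(precursor@tokens)
  cuts <- sites$bond
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, N)
  frag <- data.frame(
    sequence = vapply(seq_along(starts), function(i) {
      s <- paste(precursor@tokens[starts[i]:ends[i]], collapse = "")
      # the C-terminal fragment of an amidated precursor keeps the amide
      if (precursor@amidated && ends[i] == N) s <- paste0(s, "~")
      s
    }, ""),
    start = starts, end = ends)
  D <- max(N - 1L, 0L)
  d <- length(cuts)
  new("DigestResult", precursor = precursor,
      enzymeIds = as.integer(enzymeIds), sites = sites, fragments = frag,
      dBonds = d, DBonds = D,
      DHt = if (D > 0L) 100 * d / D else 0)
}

#' @describeIn digestSequence accessor for the product-fragment table.
#' @param digest a \code{DigestResult}.
#' @export
digestFragments <- function(digest) digest@fragments

#' @describeIn digestSequence theoretical degree of hydrolysis (percent).
#' @export
degreeOfHydrolysis <- function(digest) digest@DHt

setMethod("show", "DigestResult", function(object) {
  cat(sprintf(paste0("DigestResult: %s, enzyme id(s) %s\n",
                     "  %d cleaved bond(s) of %d (DH_T = %.2f%%), ",
                     "%d fragment(s): %s\n"),
              as.character(object@precursor),
              paste(object@enzymeIds, collapse = ", "),
              object@dBonds, object@DBonds, object@DHt,
              nrow(object@fragments),
              paste(object@fragments$sequence, collapse = " / ")))
})

#' Bioactive peptides among proteolysis products
#'
#' Counts the digest fragments whose full sequence exactly matches a
#' database peptide with a given activity (a fragment merely containing a
#' bioactive subsequence does not count) and computes, per activity, the
#' release scores: A_E = d/N; W = A_E/A; B_E = [sum(d_j/EC50_j)]/N (uM^-1,
#' over released fragments with a known half-maximal concentration); and
#' V = B_E/B. A and B come from a profile of the same precursor, so
#' W and V fall in [0, 1]; they are reported NA when their denominator is
#' zero or absent.
#'
#' @param digest a [DigestResult-class].
#' @param bundle a [DatabaseBundle-class].
#' @param activity one activity label or \code{"ALL"}.
#' @return data.frame with one row per activity: activity, d_released, N,
#'   A_E, A, W, B_E, B, V.
#' @export
releasedBioactive <- function(digest, bundle, activity = "ALL") {
  stopifnot(is(digest, "DigestResult"), is(bundle, "DatabaseBundle"))
  profile <- buildProfile(digest@precursor, bundle, activity)
  pot <- precursorPotency(profile)
  h <- profile@hits
  N <- length(digest@precursor@tokens)
  released <- table(digest@fragments$sequence)
  acts <- sort(unique(pot$activity))
  rows <- lapply(acts, function(a) {
    g <- h[h$activity == a, , drop = FALSE]
    d_j <- ifelse(g$fragment %in% names(released),
                  as.integer(released[g$fragment]), 0L)
    d <- sum(d_j)
    A <- pot$A[pot$activity == a]
    B <- pot$B[pot$activity == a]
    withEC <- d_j > 0L & !is.na(g$ec50_uM)
    B_E <- if (!is.na(B)) sum(d_j[withEC] / g$ec50_uM[withEC]) / N
           else NA_real_
    data.frame(activity = a, d_released = d, N = N,
               A_E = d / N, A = A,
               W = if (A > 0) (d / N) / A else NA_real_,
               B_E = B_E, B = B,
               V = if (!is.na(B) && B > 0 && !is.na(B_E)) B_E / B
                   else NA_real_)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(activity = character(), d_released = integer(),
               N = integer(), A_E = numeric(), A = numeric(),
               W = numeric(), B_E = numeric(), B = numeric(),
               V = numeric())
  rownames(out) <- NULL
  out
}

#' Find enzymes with a given specificity
#'
#' Returns enzymes having at least one rule matching every provided query
#' field; omitted fields match anything. The cutting residue of a rule is
#' the residue of its recognition sequence at the cut index.
#'
#' @param bundle a [DatabaseBundle-class].
#' @param recognitionSeq optional recognition sequence (whole-value).
#' @param cuttingResidue optional single residue letter.
#' @param side optional \code{"after"} (bond on the carboxyl side,
#'   C-terminus annotation) or \code{"before"} (amine side, N-terminus).
#' @return data.frame of enzyme records with a list-column
#'   \code{matched_rules} of their matching rule tables.
#' @export
findEnzymesWithSpecificity <- function(bundle, recognitionSeq = NULL,
                                       cuttingResidue = NULL, side = NULL) {
  stopifnot(is(bundle, "DatabaseBundle"))
  r <- bundle@rules
  keep <- rep(TRUE, nrow(r))
  if (!is.null(recognitionSeq))
    keep <- keep & r$recognition_seq == recognitionSeq
  if (!is.null(cuttingResidue))
    keep <- keep & substr(r$recognition_seq, r$cut_residue_index,
                          r$cut_residue_index) == cuttingResidue
  if (!is.null(side)) {
    side <- match.arg(side, c("after", "before"))
    keep <- keep & r$side == side
  }
  r <- r[keep, , drop = FALSE]
  out <- bundle@enzymes[bundle@enzymes$enzyme_id %in% r$enzyme_id, ,
                        drop = FALSE]
  out$matched_rules <- lapply(out$enzyme_id, function(e)
    r[r$enzyme_id == e, , drop = FALSE])
  rownames(out) <- NULL
  out
}

.cuttingNotation <- function(rule) {
  res <- substr(rule$recognition_seq, rule$cut_residue_index,
                rule$cut_residue_index)
  # "X-": bond formed by the carboxyl group of X; "X+": by its amine group
  paste0(res, if (rule$side == "after") "-" else "+")
}

#' Enzymes able to release peptides from a precursor
#'
#' For each query peptide, locates its occurrences in the precursor and
#' enumerates the proteolytic events needed to release each occurrence:
#' an N-side event (cleavage of the bond preceding the occurrence) and a
#' C-side event (cleavage of the bond following it), labeled 1N, 1C, 2N,
#' 2C, ... in occurrence order. An occurrence abutting a precursor
#' terminus yields a TERMINAL event that requires no cleavage. Each
#' non-terminal event lists every (enzyme, connection) whose rule cleaves
#' exactly that bond in this precursor, with the cutting sequence rendered
#' in +/- notation; N- and C-side lists are kept separate.
#'
#' @param peptides named list of [PeptideSequence-class] objects or
#'   strings (e.g. from [readFastaPeptides()]), or a single
#'   sequence/string.
#' @param precursor a [PeptideSequence-class] or string.
#' @param bundle a [DatabaseBundle-class].
#' @param cleaveModified passed to the per-rule bond computation.
#' @return named list of reports, one per query peptide: list with
#'   elements \code{peptide}, \code{precursor}, \code{occurrences}
#'   (data.frame start/end) and \code{events} (data.frame label,
#'   occurrence, side, bond, terminal, plus list-column \code{enzymes} of
#'   data.frames name/ec_number/enzyme_id/connection_id/cutting_seq/
#'   recognition_seq). A peptide not found in the precursor yields a
#'   report with zero occurrences.
#' @examples
#' b <- generateFixture(seed = 3, nPeptides = 10, nEnzymes = 4)
#' enzymesForRelease("AP", "RWAFAPGFAPGHIP", b)[["AP"]]$events
#' @export
enzymesForRelease <- function(peptides, precursor, bundle,
                              cleaveModified = FALSE) {
  if (is(peptides, "PeptideSequence") ||
      (is.character(peptides) && length(peptides) == 1L &&
       is.null(names(peptides))))
    peptides <- stats::setNames(list(peptides),
                                as.character(asPeptideSequence(peptides)))
  precursor <- asPeptideSequence(precursor)
  stopifnot(is(bundle, "DatabaseBundle"))
  N <- length(precursor@tokens)
  rules <- bundle@rules
  bondRules <- vector("list", max(N - 1L, 0L))
  for (i in seq_len(nrow(rules))) {
    for (bnd in .ruleBonds(rules[i, ], precursor@tokens, cleaveModified)) {
      rl <- rules[i, ]
      enz <- bundle@enzymes[bundle@enzymes$enzyme_id == rl$enzyme_id, ]
      bondRules[[bnd]] <- rbind(bondRules[[bnd]], data.frame(
        name = enz$name, ec_number = enz$ec_number,
        enzyme_id = rl$enzyme_id, connection_id = rl$connection_id,
        cutting_seq = .cuttingNotation(rl),
        recognition_seq = rl$recognition_seq))
    }
  }
  noEnzymes <- data.frame(name = character(), ec_number = character(),
                          enzyme_id = integer(), connection_id = integer(),
                          cutting_seq = character(),
                          recognition_seq = character())
  enzymesAt <- function(bnd) {
    df <- bondRules[[bnd]]
    if (is.null(df)) noEnzymes else {
      df <- df[order(df$enzyme_id, df$connection_id), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
  }
  lapply(stats::setNames(peptides, vapply(peptides, function(p)
           as.character(asPeptideSequence(p)), "")), function(pep) {
    pep <- asPeptideSequence(pep)
    occ <- findOccurrences(pep, precursor)
    ev <- list(); k <- 0L
    for (i in seq_len(nrow(occ))) {
      for (sd in c("N", "C")) {
        bnd <- if (sd == "N") occ$start[i] - 1L else occ$end[i]
        terminal <- (sd == "N" && bnd == 0L) || (sd == "C" && bnd == N)
        k <- k + 1L
        ev[[k]] <- data.frame(label = paste0(i, sd), occurrence = i,
                              side = sd,
                              bond = if (terminal) NA_integer_ else bnd,
                              terminal = terminal)
        ev[[k]]$enzymes <- list(if (terminal) noEnzymes else enzymesAt(bnd))
      }
    }
    events <- if (k) do.call(rbind, ev) else
      data.frame(label = character(), occurrence = integer(),
                 side = character(), bond = integer(), terminal = logical(),
                 enzymes = I(list()))
    rownames(events) <- NULL
    list(peptide = pep, precursor = precursor, occurrences = occ,
         events = events)
  })
}
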