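# Profiles of potential biological activity and the precursor scores:
# A = a/N, the frequency of bioactive fragment occurrence, and
# B = [sum(a_i/EC50_i)]/N (uM^-1), the reciprocal-potency-weighted score.

#' Build a profile of potential biological activity
#'
#' Scans every database peptide against the query and reports one hit per
#' distinct (fragment sequence, activity) pair that occurs at least once,
#' with its occurrence count a_i (overlaps counted) and 1-based inclusive
#' locations. Duplicate database records with identical sequence and
#' activity collapse to a single hit; when duplicates disagree on EC50 the
#' lowest-id record with a known value supplies it.
#'
#' @param query a [PeptideSequence-class] or string.
#' @param bundle a [DatabaseBundle-class].
#' @param activity one vocabulary label, or \code{"ALL"} for all
#'   activities.
#' @return an [ActivityProfile-class].
#' @examples
#' b <- generateFixture(seed = 2, nPeptides = 40, nEnzymes = 2)
#' buildProfile("RWAFAPGFAPGHIP", b)
#' @export
buildProfile <- function(query, bundle, activity = "ALL") {
  query <- asPeptideSequence(query)
  stopifnot(is(bundle, "DatabaseBundle"))
  p <- bundle@peptides
  if (!identical(activity, "ALL")) {
    if (!activity %in% bundle@activities$activity)
      stop("unknown activity label: '", activity, "'", call. = FALSE)
    p <- p[p$activity == activity, , drop = FALSE]
  }
  if (nrow(p)) {
    p <- p[order(p$id), , drop = FALSE]
    dup <- duplicated(p[c("sequence", "activity")])
    # collapse duplicates; keep the first id, prefer a known EC50
    key <- paste(p$sequence, p$activity, sep = "\r")
    ec <- vapply(split(p$ec50_uM, key)[unique(key)],
                 function(v) { v <- v[!is.na(v)]
                               if (length(v)) v[1L] else NA_real_ }, 0)
    p <- p[!dup, , drop = FALSE]
    p$ec50_uM <- unname(ec[paste(p$sequence, p$activity, sep = "\r")])
  }
  hits <- vector("list", nrow(p))
  n_hit <- 0L
  for (i in seq_len(nrow(p))) {
    occ <- findOccurrences(p$sequence[i], query)
    if (!nrow(occ)) next
    n_hit <- n_hit + 1L
    hits[[n_hit]] <- data.frame(
      id = p$id[i], name = p$name[i], activity = p$activity[i],
      fragment = p$sequence[i], a_i = nrow(occ), ec50_uM = p$ec50_uM[i])
    hits[[n_hit]]$locations <- list(occ)
  }
  hits <- if (n_hit) do.call(rbind, hits[seq_len(n_hit)]) else
    data.frame(id = integer(), name = character(), activity = character(),
               fragment = character(), a_i = integer(),
               ec50_uM = numeric(), locations = I(list()))
  rownames(hits) <- NULL
  new("ActivityProfile", query = query, activity = activity, hits = hits)
}

#' @describeIn buildProfile accessor for the hit table.
#' @param profile an \code{ActivityProfile}.
#' @export
profileHits <- function(profile) profile@hits

setMethod("show", "ActivityProfile", function(object) {
  cat(sprintf("ActivityProfile for %s (activity: %s): %d hit(s)\n",
              as.character(object@query), object@activity,
              nrow(object@hits)))
  if (nrow(object@hits)) {
    h <- object@hits
    h$locations <- vapply(h$locations, function(m)
      paste(sprintf("%d-%d", m$start, m$end), collapse = ";"), "")
    print(h, row.names = FALSE)
  }
})

#' Frequency of bioactive fragment occurrence (A)
#'
#' A = a/N, where a is the total number of occurrences (with multiplicity
#' and overlap) of fragments with the given activity and N the query
#' length. Dimensionless; 0 for an empty profile.
#'
#' @param profile an [ActivityProfile-class].
#' @param activity one activity label; defaults to the profile's own
#'   filter when it is specific.
#' @return numeric scalar.
#' @export
frequencyA <- function(profile, activity = profile@activity) {
  if (identical(activity, "ALL"))
    stop("name one activity; precursorPotency() gives the per-activity breakdown",
         call. = FALSE)
  pr <- precursorPotency(profile)
  row <- pr[pr$activity == activity, , drop = FALSE]
  if (!nrow(row)) return(0)
  row$A
}

#' Reciprocal-potency score of a precursor (B)
#'
#' B = [sum over hits i with known EC50/IC50 of a_i/EC50_i]/N, in uM^-1.
#' Hits without a half-maximal concentration are skipped; when no hit has
#' one, B is absent (NA), not zero.
#'
#' @inheritParams frequencyA
#' @return numeric scalar in uM^-1, or NA when undefined.
#' @export
potencyB <- function(profile, activity = profile@activity) {
  if (identical(activity, "ALL"))
    stop("name one activity; precursorPotency() gives the per-activity breakdown",
         call. = FALSE)
  pr <- precursorPotency(profile)
  row <- pr[pr$activity == activity, , drop = FALSE]
  if (!nrow(row)) return(NA_real_)
  row$B
}

#' Per-activity precursor scores
#'
#' One row per activity present in the profile: total occurrence count a,
#' query length N, A = a/N, B (NA when no hit carries EC50/IC50) and the
#' number of hits skipped for lack of a half-maximal concentration.
#'
#' @param profile an [ActivityProfile-class].
#' @return data.frame with columns activity, a, N, A, B, n_skipped.
#' @export
precursorPotency <- function(profile) {
  h <- profile@hits
  N <- length(profile@query@tokens)
  if (!nrow(h))
    return(data.frame(activity = character(), a = integer(), N = integer(),
                      A = numeric(), B = numeric(), n_skipped = integer()))
  out <- lapply(split(h, h$activity), function(g) {
    withEC <- !is.na(g$ec50_uM)
    data.frame(activity = g$activity[1L], a = sum(g$a_i), N = N,
               A = sum(g$a_i) / N,
               B = if (any(withEC))
                     sum(g$a_i[withEC] / g$ec50_uM[withEC]) / N
                   else NA_real_,
               n_skipped = sum(!withEC))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$activity), , drop = FALSE]
}
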