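# Synthetic database fixture. A reproducible stand-in for hosted peptide
# database content: no record in a generated bundle corresponds to a real
# annotated peptide.

.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# largest-remainder apportionment of n among proportions p
.apportion <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  k <- floor(raw)
  short <- n - sum(k)
  if (short > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(short)]
    k[extra] <- k[extra] + 1L
  }
  as.integer(k)
}

#' Generate a synthetic peptide/enzyme database bundle
#'
#' Builds a reproducible random bundle for testing and demonstration:
#' peptide records 2--15 residues long over the standard L alphabet with
#' activities apportioned to \code{activityMix} (largest-remainder, so the
#' requested proportions are met within rounding), a fixed fraction of
#' records carrying a half-maximal concentration (log-uniform between 0.01
#' and 1000 uM), and enzymes bearing 1--3 specificity rules with single-
#' or multi-residue recognition sequences. The same seed always yields an
#' identical bundle.
#'
#' @param seed integer random seed.
#' @param nPeptides,nEnzymes numbers of records (each >= 1).
#' @param activityMix named numeric vector of label proportions (names
#'   from the activity vocabulary). The default mirrors the mix typical of
#'   food-derived bioactive peptide collections, where ACE and DPP-IV
#'   inhibitors dominate.
#' @param ec50Fraction fraction of peptide records with a known EC50/IC50,
#'   in [0, 1].
#' @return a validated [DatabaseBundle-class].
#' @examples
#' b <- generateFixture(seed = 7, nPeptides = 20, nEnzymes = 3)
#' b
#' @export
generateFixture <- function(seed, nPeptides = 50L, nEnzymes = 5L,
                            activityMix = c("ACE inhibitor" = 0.35,
                              "dipeptidyl peptidase IV inhibitor" = 0.2,
                              "antioxidative" = 0.15,
                              "antibacterial" = 0.1,
                              "hypotensive" = 0.1,
                              "opioid" = 0.1),
                            ec50Fraction = 0.5) {
  stopifnot(nPeptides >= 1L, nEnzymes >= 1L,
            ec50Fraction >= 0, ec50Fraction <= 1,
            !is.null(names(activityMix)), all(activityMix >= 0))
  vocab <- defaultActivities()
  unknown <- setdiff(names(activityMix), vocab$activity)
  if (length(unknown))
    stop("activityMix label(s) not in the vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  alphabet <- setdiff(rownames(.RESIDUE_COMPOSITION), "B")
  .withSeed(seed, {
    counts <- .apportion(nPeptides, activityMix)
    act <- rep(names(activityMix), counts)
    seqs <- character(nPeptides)
    seen <- character(0)
    for (i in seq_len(nPeptides)) {
      repeat {
        len <- sample(2:15, 1L)
        s <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
        key <- paste(s, act[i], sep = "\r")
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      seqs[i] <- s
    }
    nEC <- round(ec50Fraction * nPeptides)
    hasEC <- rep(FALSE, nPeptides)
    if (nEC > 0) hasEC[sample.int(nPeptides, nEC)] <- TRUE
    ec50 <- ifelse(hasEC, 10 ^ stats::runif(nPeptides, -2, 3), NA_real_)
    pep <- data.frame(
      id = seq_len(nPeptides),
      name = act,
      sequence = seqs,
      activity = act,
      activity_code = abbreviate(act, 4L, named = FALSE),
      fun_text = paste0("synthetic fixture record (", act, ")"),
      ec50_uM = ec50,
      chemical_mass_Da = NA_real_, monoisotopic_mass_Da = NA_real_,
      smiles = NA_character_, inchikey = NA_character_,
      references = "synthetic fixture; not a literature annotation",
      cross_refs = NA_character_)
    rules <- list(); conn <- 0L
    for (e in seq_len(nEnzymes)) {
      nr <- sample(1:3, 1L)
      for (r in seq_len(nr)) {
        conn <- conn + 1L
        len <- sample(c(1L, 1L, 1L, 2L, 3L), 1L)  # mostly single-residue
        rec <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
        rules[[conn]] <- data.frame(
          connection_id = conn, enzyme_id = e,
          recognition_seq = rec,
          cut_residue_index = sample.int(len, 1L),
          side = sample(c("after", "before"), 1L))
      }
    }
    enz <- data.frame(
      enzyme_id = seq_len(nEnzymes),
      name = sprintf("synthetic proteinase %d", seq_len(nEnzymes)),
      ec_number = sprintf("3.4.21.%d", 100L + seq_len(nEnzymes)),
      merops_id = sprintf("X%02d.%03d", seq_len(nEnzymes), seq_len(nEnzymes)))
    makeBundle(peptides = pep, enzymes = enz,
               rules = do.call(rbind, rules), activities = vocab,
               metadata = list(provenance = "synthetic fixture",
                               seed = seed, version = "1.0"))
  })
}
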