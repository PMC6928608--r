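# Residue-level chemistry: elemental composition and masses.
#
# Residue formulas are for the in-chain residue (amino acid minus water);
# a free peptide adds one H2O, a C-terminal amide replaces the terminal
# OH by NH2 (-O +N +H). Phosphoserine = serine + HPO3.

.ELEMENTS <- c("C", "H", "N", "O", "S", "P")

# IUPAC conventional atomic weights (Da)
.ATOMIC_WEIGHT <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.973761998)

# monoisotopic masses of the principal isotopes (Da)
.MONO_MASS <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069, P = 30.97376151)

# rows: residue (uppercase base token); columns C,H,N,O,S,P
.RESIDUE_COMPOSITION <- local({
  m <- rbind(
    A = c(3,  5, 1, 1, 0, 0),
    C = c(3,  5, 1, 1, 1, 0),
    D = c(4,  5, 1, 3, 0, 0),
    E = c(5,  7, 1, 3, 0, 0),
    F = c(9,  9, 1, 1, 0, 0),
    G = c(2,  3, 1, 1, 0, 0),
    H = c(6,  7, 3, 1, 0, 0),
    I = c(6, 11, 1, 1, 0, 0),
    K = c(6, 12, 2, 1, 0, 0),
    L = c(6, 11, 1, 1, 0, 0),
    M = c(5,  9, 1, 1, 1, 0),
    N = c(4,  6, 2, 2, 0, 0),
    P = c(5,  7, 1, 1, 0, 0),
    Q = c(5,  8, 2, 2, 0, 0),
    R = c(6, 12, 4, 1, 0, 0),
    S = c(3,  5, 1, 2, 0, 0),
    T = c(4,  7, 1, 2, 0, 0),
    V = c(5,  9, 1, 1, 0, 0),
    W = c(11, 10, 2, 1, 0, 0),
    Y = c(9,  9, 1, 2, 0, 0),
    B = c(3,  6, 1, 5, 0, 1)   # phosphoserine = Ser + HPO3
  )
  colnames(m) <- .ELEMENTS
  m
})

# token -> base residue letter (uppercase); lowercase g is NOT a token
.RESIDUE_BASE <- local({
  up <- rownames(.RESIDUE_COMPOSITION)
  lo <- tolower(setdiff(up, "G"))
  stats::setNames(c(up, toupper(lo)), c(up, lo))
})

.tokenChirality <- function(tokens) {
  ifelse(tokens == "G", "achiral",
         ifelse(tokens == toupper(tokens), "L", "D"))
}

#' Elemental composition of a peptide
#'
#' Sums the residue compositions over the token list and adds one water;
#' for a C-terminal amide the terminal hydroxyl is replaced by NH2
#' (net -O +N +H). D- and L-tokens of the same residue are isomers and
#' contribute identically.
#'
#' @param x a [PeptideSequence-class] or a string parseable by
#'   [parseSequence()].
#' @return named integer vector with elements C, H, N, O, S, P.
#' @examples
#' composition("GHS")   # C11 H17 N5 O5
#' composition("G~")    # glycinamide, C2 H6 N2 O
#' @export
composition <- function(x) {
  x <- asPeptideSequence(x)
  base <- .RESIDUE_BASE[x@tokens]
  counts <- colSums(.RESIDUE_COMPOSITION[base, , drop = FALSE])
  counts <- counts + c(C = 0, H = 2, N = 0, O = 1, S = 0, P = 0)  # + H2O
  if (x@amidated)
    counts <- counts + c(C = 0, H = 1, N = 1, O = -1, S = 0, P = 0)
  storage.mode(counts) <- "integer"
  counts
}

#' Molecular formula in Hill notation
#'
#' @param x a [PeptideSequence-class], string, or named element-count
#'   vector as returned by [composition()].
#' @return a string such as \code{"C11H17N5O5"}.
#' @export
molecularFormula <- function(x) {
  counts <- if (is.numeric(x)) x else composition(x)
  counts <- counts[c("C", "H", "N", "O", "P", "S")]  # Hill order, then alpha
  counts <- counts[!is.na(counts) & counts > 0]
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' Average and monoisotopic peptide mass
#'
#' Masses are computed from the elemental composition using IUPAC
#' conventional atomic weights (average) and principal-isotope masses
#' (monoisotopic); no mass table of whole residues is consulted.
#'
#' @inheritParams composition
#' @return named numeric vector \code{c(average = , monoisotopic = )} in Da.
#' @examples
#' peptideMasses("G")  # glycine: 75.07 average, 75.032 monoisotopic
#' @export
peptideMasses <- function(x) {
  counts <- composition(x)
  c(average = sum(counts * .ATOMIC_WEIGHT[names(counts)]),
    monoisotopic = sum(counts * .MONO_MASS[names(counts)]))
}
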