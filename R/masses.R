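# Monoisotopic and average mass constants and arithmetic.
# All masses in Da; monoisotopic unless suffixed _avg.

#' @keywords internal
PROTON_MASS <- 1.0072765

#' @keywords internal
WATER_MONO <- 18.010565

#' @keywords internal
C13_C12_DELTA <- 1.0033548

# Monoisotopic residue masses of the 20 standard amino acids
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (used for unresolved subunit isotope clusters)
AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

WATER_AVG <- 18.01528

# Monoisotopic atomic masses for elemental-formula arithmetic
ATOM_MONO <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163
)

# Monosaccharide residue masses (Oxford notation letters)
MONOSACCHARIDE_MONO <- c(
  H = 162.0528234,   # hexose (mannose/galactose), C6H10O5
  N = 203.0793725,   # HexNAc, C8H13NO5
  F = 146.0579088,   # deoxyhexose (fucose), C6H10O4
  Sa = 291.0954165   # NeuAc, C11H17NO8
)

# Carbamidomethylation of cysteine (iodoacetamide alkylation), fixed mod
CARBAMIDOMETHYL_MONO <- 57.021464

#' Monoisotopic mass of an elemental formula
#'
#' Parses a composition string such as `"C6O5H10"` (element symbols followed
#' by optional counts, in any order) and sums standard monoisotopic atomic
#' masses.
#'
#' @param formula Character elemental composition, e.g. `"C6H10O5"`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mono_mass("C6O5H10")  # hexose residue, the glycation adduct
#' @export
formula_mono_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  total <- 0
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[A-Za-z]", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(ATOM_MONO)) stop("unknown element in formula: ", el)
    total <- total + ATOM_MONO[[el]] * n
  }
  total
}

#' Monoisotopic mass of a peptide
#'
#' Sum of standard monoisotopic residue masses, one water, and any
#' modification delta masses.
#'
#' @param sequence One-letter amino-acid string.
#' @param mods Numeric vector of modification delta masses (Da), default none.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("GK")
#' peptide_mono_mass("G", mods = 15.994915)  # oxidised
#' @export
peptide_mono_mass <- function(sequence, mods = numeric()) {
  res <- residue_masses(sequence, AA_MONO)
  sum(res) + WATER_MONO + sum(mods)
}

#' Average mass of a polypeptide chain
#'
#' Used for subunit-level species where the isotope cluster is unresolved at
#' the working resolution.
#'
#' @inheritParams peptide_mono_mass
#' @return Neutral average mass in Da.
#' @export
peptide_avg_mass <- function(sequence, mods = numeric()) {
  res <- residue_masses(sequence, AA_AVG)
  sum(res) + WATER_AVG + sum(mods)
}

residue_masses <- function(sequence, table) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!letters %in% names(table))
  if (length(bad)) {
    stop("unknown residue '", letters[bad[1]], "' at position ", bad[1])
  }
  table[letters]
}

#' Convert neutral mass to m/z and back
#'
#' Standard protonation arithmetic: `mz = (M + z * m_p) / z` with the proton
#' mass 1.0072765 Da. `mass_from_mz` is the exact inverse.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param mz Observed m/z.
#' @param charge Positive integer charge state.
#' @return `mz_from_mass`: m/z; `mass_from_mz`: neutral mass in Da.
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' @rdname mz_from_mass
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  mz * charge - charge * PROTON_MASS
}

#' Define a glycan composition
#'
#' Oxford-notation N-glycan composition given as monosaccharide counts:
#' H = hexose (mannose/galactose), N = HexNAc, F = deoxyhexose (fucose),
#' Sa = N-acetylneuraminic acid.
#'
#' @param oxford_name Oxford-notation label, e.g. `"FA2"`.
#' @param H,N,F,Sa Non-negative integer monosaccharide counts.
#' @return A `glycan_composition` object with the additive monoisotopic mass.
#' @examples
#' glycan_composition("FA2", H = 3, N = 4, F = 1)
#' @export
glycan_composition <- function(oxford_name, H = 0, N = 0, F = 0, Sa = 0) {
  counts <- c(H = H, N = N, F = F, Sa = Sa)
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    stop("monosaccharide counts must be non-negative integers")
  }
  structure(
    list(oxford_name = oxford_name, counts = counts,
         mono_mass = sum(counts * MONOSACCHARIDE_MONO)),
    class = "glycan_composition"
  )
}

#' Monoisotopic mass of a glycan composition
#'
#' @param g A [glycan_composition()].
#' @return Mass in Da (sum of monosaccharide residue masses).
#' @export
glycan_mass <- function(g) {
  stopifnot(inherits(g, "glycan_composition"))
  g$mono_mass
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(sprintf("<glycan %s: H%d N%d F%d Sa%d, %0.5f Da>\n", x$oxford_name,
              x$counts[["H"]], x$counts[["N"]], x$counts[["F"]],
              x$counts[["Sa"]], x$mono_mass))
  invisible(x)
}

# Averagine model: average elemental composition per 111.1254 Da of peptide.
AVERAGINE <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
AVERAGINE_MASS <- 111.1254

# Isotope distributions per element as probability vectors over +0/+1/+2
# nominal mass offsets.
ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107, 0),
  H = c(0.999885, 0.000115, 0),
  N = c(0.99636, 0.00364, 0),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425)
)

# polynomial power with truncation: distribution of n iid copies of `d`
poly_pow <- function(d, n, len) {
  out <- c(1, rep(0, len - 1))
  base <- d[seq_len(min(length(d), len))]
  base <- c(base, rep(0, len - length(base)))
  while (n > 0) {
    if (n %% 2 == 1) out <- poly_mul(out, base, len)
    base <- poly_mul(base, base, len)
    n <- n %/% 2
  }
  out
}

poly_mul <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_len(len)) {
    j <- seq_len(len - i + 1)
    out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  }
  out
}

#' Averagine isotope envelope
#'
#' Approximate relative isotope abundances for a peptide of given
#' monoisotopic mass using the averagine composition model
#' (C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da).
#'
#' @param mass Monoisotopic mass in Da.
#' @param n_isotopes Number of isotope peaks returned (monoisotopic first).
#' @return Numeric vector of relative abundances summing to the retained
#'   envelope fraction (normalised over the returned peaks).
#' @export
averagine_envelope <- function(mass, n_isotopes = 5) {
  stopifnot(mass > 0, n_isotopes >= 1)
  units <- mass / AVERAGINE_MASS
  counts <- round(AVERAGINE * units)
  counts["H"] <- max(counts[["H"]], 1)
  dist <- c(1, rep(0, n_isotopes - 1))
  for (el in names(ELEMENT_ISOTOPES)) {
    if (counts[[el]] > 0) {
      dist <- poly_mul(dist, poly_pow(ELEMENT_ISOTOPES[[el]], counts[[el]],
                                      n_isotopes), n_isotopes)
    }
  }
  dist / sum(dist)
}
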