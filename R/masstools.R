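# Average-mass arithmetic for intact-protein mass spectrometry: compute the
# average (isotope-abundance-weighted) mass of a protein sequence and match a
# deconvoluted observed mass against the ladder of N-terminal truncation
# products, as used to locate proteolytic cleavage sites in the flexible
# N-terminal loop of L-asparaginase.

# ExPASy average residue masses (Da); a peptide mass is the residue sum plus
# one water (18.01524 Da)
AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_AVG_MASS <- 18.01524

#' Average molecular mass of a protein sequence
#'
#' @param seq one-letter amino-acid string (standard 20 residues).
#' @return average mass in Da (full precision; report at 1 decimal).
#' @export
average_mass <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  aa <- strsplit(toupper(seq), "")[[1L]]
  bad <- which(!aa %in% names(AA_AVG_MASS))
  if (length(bad))
    stop("non-standard amino acid '", aa[bad[1L]], "' at position ", bad[1L])
  sum(AA_AVG_MASS[aa]) + WATER_AVG_MASS
}

#' Masses of all N-terminal truncation products
#'
#' For each start position s in \code{start_range}, the average mass of the
#' suffix \code{s..end} (one water each).
#'
#' @param seq one-letter protein sequence.
#' @param start_range integer vector of 1-based start positions.
#' @return data.frame with columns \code{start}, \code{cleavage_after}
#'   (= start - 1), \code{mass} (Da).
#' @export
nterm_truncation_masses <- function(seq, start_range = seq_len(nchar(seq))) {
  n <- nchar(seq)
  if (length(start_range) < 1L) stop("empty start range")
  if (min(start_range) < 1L || max(start_range) > n)
    stop("start range outside sequence (1..", n, ")")
  aa <- strsplit(toupper(seq), "")[[1L]]
  full <- average_mass(seq)
  # cumulative residue mass removed ahead of each start
  removed <- c(0, cumsum(AA_AVG_MASS[aa]))[start_range]
  data.frame(start = start_range, cleavage_after = start_range - 1L,
             mass = full - removed)
}

#' Match an observed intact mass to N-terminal cleavage candidates
#'
#' Compares a deconvoluted average mass against every N-terminal truncation
#' product of the sequence and returns those within tolerance, closest first.
#'
#' @param seq one-letter protein sequence.
#' @param observed observed average mass (Da).
#' @param tolerance absolute matching tolerance (Da). Ignored when
#'   \code{relative_tolerance} is given.
#' @param relative_tolerance optional relative tolerance (e.g. 2e-4 for the
#'   0.02% mass accuracy of a linear ion-trap deconvolution).
#' @return data.frame of class \code{cleavage_candidates}: \code{start},
#'   \code{cleavage_after}, \code{calc_mass}, \code{delta}
#'   (observed - calculated), sorted by |delta|; zero rows when nothing
#'   matches.
#' @export
match_observed_mass <- function(seq, observed, tolerance = 5,
                                relative_tolerance = NULL) {
  if (!is.null(relative_tolerance)) tolerance <- relative_tolerance * observed
  stopifnot(tolerance > 0, observed > 0)
  ladder <- nterm_truncation_masses(seq)
  delta <- observed - ladder$mass
  keep <- abs(delta) <= tolerance
  out <- data.frame(start = ladder$start[keep],
                    cleavage_after = ladder$cleavage_after[keep],
                    calc_mass = ladder$mass[keep], delta = delta[keep])
  out <- out[order(abs(out$delta)), ]
  rownames(out) <- NULL
  structure(out, class = c("cleavage_candidates", "data.frame"))
}

#' Read a single protein sequence from a FASTA file
#'
#' @param path FASTA path (first record used; gaps stripped).
#' @return one-letter sequence string.
#' @export
read_protein_fasta <- function(path) {
  fa <- bio3d::read.fasta(path)
  seq <- fa$ali[1L, ]
  paste(toupper(seq[seq != "-"]), collapse = "")
}
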