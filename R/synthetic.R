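# Seeded generators for every input the pipeline consumes, with known ground
# truth recorded in the output metadata. Displacements are Gaussian and
# frame-independent: the downstream estimators are pure ensemble averages, so
# no autocorrelation structure is needed to exercise them.

#' Block-motion specification for synthetic ensembles
#'
#' Describes harmonic fluctuation about a reference structure: each block of
#' residues shares one isotropic Gaussian displacement per frame (coordinated
#' motion, sd \code{sigma_block}), on top of independent per-residue noise
#' (sd \code{sigma_local}). \code{scale} multiplies both amplitudes and is the
#' rigidification knob: a variant generated at scale 0.8 has RMSF 0.8x and
#' distance fluctuations 0.64x those of the scale-1 reference.
#'
#' @param blocks list of integer vectors partitioning residue positions
#'   1..n_res (order of the reference CA trace).
#' @param sigma_block per-coordinate sd of the shared block displacement (A).
#' @param sigma_local per-coordinate sd of the independent residue term (A).
#' @param scale multiplicative amplitude factor, > 0.
#' @return object of class \code{block_spec}.
#' @export
block_spec <- function(blocks, sigma_block, sigma_local, scale = 1) {
  stopifnot(sigma_block >= 0, sigma_local >= 0, scale > 0)
  idx <- as.integer(sort(unname(unlist(blocks))))
  if (any(duplicated(idx)) || !identical(idx, seq_along(idx)))
    stop("blocks must partition residues 1..n exactly once")
  structure(list(blocks = blocks, sigma_block = sigma_block,
                 sigma_local = sigma_local, scale = scale),
            class = "block_spec")
}

#' Deterministic multi-chain Calpha reference structure
#'
#' Builds an ideal alpha-helical CA trace per chain (1.5 A rise, 100 degree
#' turn, 2.3 A radius), with chains laid out on a 20 A grid and lightly
#' jittered (0.05 A, seeded) so distinct seeds give distinct but reproducible
#' geometries.
#'
#' @param n_chains number of chains (>= 1), labelled A, B, C, ...
#' @param n_res residues per chain (>= 3).
#' @param seed RNG seed.
#' @return a single-frame \code{Trajectory} of \code{n_chains * n_res} CA atoms.
#' @export
make_reference_structure <- function(n_chains, n_res, seed = 1L) {
  stopifnot(n_chains >= 1, n_res >= 3)
  set.seed(seed)
  coords <- NULL
  atoms <- NULL
  for (c_i in seq_len(n_chains)) {
    t <- (seq_len(n_res) - 1L)
    helix <- cbind(2.3 * cos(t * 100 * pi / 180),
                   2.3 * sin(t * 100 * pi / 180),
                   1.5 * t)
    offset <- c(20 * ((c_i - 1L) %% 2L), 20 * ((c_i - 1L) %/% 2L), 0)
    xyz <- sweep(helix, 2L, offset, "+")
    coords <- rbind(coords, xyz)
    atoms <- rbind(atoms, data.frame(
      serial = NA_integer_, name = "CA", element = "C", resname = "ALA",
      resno = seq_len(n_res), chain = LETTERS[c_i],
      stringsAsFactors = FALSE))
  }
  coords <- coords + matrix(stats::rnorm(length(coords), sd = 0.05),
                            ncol = 3L)
  atoms$serial <- seq_len(nrow(atoms))
  trajectory(atoms, as.vector(t(coords)),
             metadata = list(seed = seed, generator = "reference_structure"))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Simulate a block-coordinated harmonic ensemble
#'
#' Frame t has residue coordinates
#' \code{R_t (x_i + scale * (a_b(t) + e_i(t))) + T_t}, with \code{a_b} an
#' isotropic Gaussian shared by all residues of block b and \code{e_i}
#' independent per residue. The optional rigid motion (random rotation plus
#' uniform translation in [-10, 10] A) exercises the superposition and the
#' rigid-motion invariance of the distance-fluctuation statistic.
#'
#' @param ref single-frame \code{Trajectory} (CA trace), e.g. from
#'   \code{\link{make_reference_structure}}.
#' @param spec a \code{\link{block_spec}} covering the residues of \code{ref}.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param rigid_motion apply a random rigid motion per frame.
#' @return a \code{Trajectory}; ground truth in \code{$metadata$spec}.
#' @export
simulate_block_trajectory <- function(ref, spec, n_frames, seed = 1L,
                                      rigid_motion = FALSE) {
  stopifnot(inherits(spec, "block_spec"), n_frames >= 2)
  n_res <- nrow(ref$atoms)
  if (length(unlist(spec$blocks)) != n_res)
    stop("block partition covers ", length(unlist(spec$blocks)),
         " residues but reference has ", n_res)
  set.seed(seed)
  x0 <- frame_coords(ref)
  block_of <- integer(n_res)
  for (b in seq_along(spec$blocks)) block_of[spec$blocks[[b]]] <- b
  xyz <- matrix(0, n_frames, 3L * n_res)
  # internal displacements first, rigid motions after: the same seed then
  # yields identical internal coordinates with rigid_motion on or off, which
  # is what the rigid-motion invariance of DF/RMSF is tested against
  for (t in seq_len(n_frames)) {
    a_b <- matrix(stats::rnorm(3L * length(spec$blocks),
                               sd = spec$sigma_block), ncol = 3L)
    e_i <- matrix(stats::rnorm(3L * n_res, sd = spec$sigma_local), ncol = 3L)
    x <- x0 + spec$scale * (a_b[block_of, , drop = FALSE] + e_i)
    xyz[t, ] <- as.vector(t(x))
  }
  if (rigid_motion) {
    for (t in seq_len(n_frames)) {
      x <- matrix(xyz[t, ], ncol = 3L, byrow = TRUE) %*% t(random_rotation())
      x <- sweep(x, 2L, stats::runif(3L, -10, 10), "+")
      xyz[t, ] <- as.vector(t(x))
    }
  }
  trajectory(ref$atoms, xyz,
             metadata = list(seed = seed, spec = spec,
                             rigid_motion = rigid_motion,
                             generator = "block_trajectory"))
}

# two-alanine toy frame: res 1 donates its backbone N-H to the carbonyl O of
# res 2; all other polar pairs are kept out of detection range
hbond_toy_coords <- function(present) {
  u <- c(cos(10 * pi / 180), sin(10 * pi / 180), 0)  # H -> acceptor direction
  h <- c(1.01, 0, 0)
  a_on <- h + 1.9 * u     # N..O 2.90 A, D-H..A 170 deg
  a_off <- h + 4.5 * u    # N..O 5.49 A
  a <- if (present) a_on else a_off
  shift <- a - a_on
  rbind(
    c(0, 0, 0),                    # N   res1
    h,                             # H   res1
    c(-1.0, -1.0, 0),              # CA  res1
    c(-2.2, -0.5, 0),              # C   res1
    c(-3.2, -1.2, 0),              # O   res1
    c(6.5, 0.8, 0) + shift,        # N   res2
    c(7.3, 1.3, 0) + shift,        # H   res2
    c(5.2, 1.2, 0) + shift,        # CA  res2
    c(4.1, 0.33, 0) + shift,       # C   res2
    a)                             # O   res2
}

#' Simulate an intermittent hydrogen-bond trajectory
#'
#' A two-residue toy system whose single backbone N-H...O=C bond satisfies the
#' default detection criteria (2.9 A, 170 degrees) in each frame independently
#' with probability \code{p_present}, and is broken (5.5 A) otherwise.
#'
#' @param p_present per-frame presence probability in [0, 1].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a \code{Trajectory}; the realized presence vector is stored in
#'   \code{$metadata$present}.
#' @export
simulate_hbond_series <- function(p_present, n_frames, seed = 1L) {
  stopifnot(p_present >= 0, p_present <= 1, n_frames >= 1)
  set.seed(seed)
  present <- stats::runif(n_frames) < p_present
  atoms <- data.frame(
    serial = 1:10,
    name = rep(c("N", "H", "CA", "C", "O"), 2L),
    element = rep(c("N", "H", "C", "C", "O"), 2L),
    resname = "ALA", resno = rep(1:2, each = 5L), chain = "A",
    stringsAsFactors = FALSE)
  xyz <- t(vapply(present,
                  function(p) as.vector(t(hbond_toy_coords(p))),
                  numeric(30L)))
  trajectory(atoms, xyz,
             metadata = list(seed = seed, p_present = p_present,
                             present = present, generator = "hbond_series"))
}

#' Sigmoid (two-state) curve specification
#'
#' @param midpoint transition midpoint (degC).
#' @param k logistic steepness scale (degC, > 0); smaller k = sharper.
#' @param direction \code{"unfolding"} (signal rises with T, thermal-shift
#'   dye curve) or \code{"activity"} (residual activity falls with T).
#' @param baseline,amplitude signal units; an activity curve in percent uses
#'   baseline 0, amplitude 100.
#' @param noise_sd additive Gaussian noise sd, signal units.
#' @param T_grid temperature grid (degC); must span midpoint +/- 3k.
#' @return object of class \code{sigmoid_spec}.
#' @export
sigmoid_spec <- function(midpoint, k, direction = c("unfolding", "activity"),
                         baseline = 0, amplitude = 1, noise_sd = 0,
                         T_grid = seq(25, 95, by = 0.5)) {
  direction <- match.arg(direction)
  stopifnot(k > 0)
  if (min(T_grid) > midpoint - 3 * k || max(T_grid) < midpoint + 3 * k)
    stop("T_grid must span midpoint +/- 3k")
  structure(list(midpoint = midpoint, k = k, direction = direction,
                 baseline = baseline, amplitude = amplitude,
                 noise_sd = noise_sd, T_grid = T_grid),
            class = "sigmoid_spec")
}

#' Simulate a melting or thermal-inactivation curve
#'
#' \code{y = baseline + amplitude * L(T) + N(0, noise_sd)} with
#' \code{L(T) = 1 / (1 + exp((midpoint - T) / k))} for rising (unfolding)
#' curves and its mirror image for falling (residual-activity) curves.
#'
#' @param spec a \code{\link{sigmoid_spec}}.
#' @param seed RNG seed (only used when \code{noise_sd > 0}).
#' @return a \code{curve_table} of kind \code{"melting"} or
#'   \code{"activity"}; ground truth in its metadata.
#' @export
simulate_melting_curve <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sigmoid_spec"))
  set.seed(seed)
  T <- spec$T_grid
  L <- if (spec$direction == "unfolding")
    1 / (1 + exp((spec$midpoint - T) / spec$k))
  else
    1 / (1 + exp((T - spec$midpoint) / spec$k))
  y <- spec$baseline + spec$amplitude * L +
    stats::rnorm(length(T), sd = spec$noise_sd)
  curve_table(T, y,
              kind = if (spec$direction == "unfolding") "melting" else "activity",
              metadata = list(seed = seed, spec = spec))
}

#' Michaelis-Menten data specification
#'
#' @param Km Michaelis constant (mM).
#' @param kcat turnover number (per second).
#' @param E0_mg enzyme amount (mg) in the assay.
#' @param E0_nmol enzyme amount (nmol); linked to \code{E0_mg} by the monomer
#'   mass, supplied independently so unit conversions stay explicit.
#' @param S_grid substrate concentrations (mM); must span below and above Km.
#' @param cv relative (multiplicative) noise on rates.
#' @return object of class \code{kinetics_spec}.
#' @export
kinetics_spec <- function(Km, kcat, E0_mg, E0_nmol,
                          S_grid = NULL, cv = 0) {
  stopifnot(Km > 0, kcat > 0, E0_mg > 0, E0_nmol > 0, cv >= 0)
  if (is.null(S_grid))
    S_grid <- Km * c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16)
  if (min(S_grid) >= Km || max(S_grid) <= Km)
    stop("S_grid must span below and above Km")
  structure(list(Km = Km, kcat = kcat, E0_mg = E0_mg, E0_nmol = E0_nmol,
                 S_grid = S_grid, cv = cv), class = "kinetics_spec")
}

#' Simulate Michaelis-Menten rate data
#'
#' \code{v(S) = Vmax S / (Km + S) * (1 + N(0, cv))} with
#' \code{Vmax = kcat * E0_nmol * 60 / 1000} in umol/min (kcat in 1/s, E0 in
#' nmol), i.e. rates on the enzyme-Unit scale (1 U = 1 umol substrate
#' converted per minute).
#'
#' @param spec a \code{\link{kinetics_spec}}.
#' @param seed RNG seed (only used when \code{cv > 0}).
#' @return a \code{curve_table} of kind \code{"kinetics"} (x = mM, y =
#'   umol/min); ground truth in its metadata.
#' @export
simulate_kinetics <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "kinetics_spec"))
  set.seed(seed)
  Vmax <- spec$kcat * spec$E0_nmol * 60 / 1000
  S <- sort(spec$S_grid)
  v <- Vmax * S / (spec$Km + S) *
    (1 + stats::rnorm(length(S), sd = spec$cv))
  curve_table(S, v, kind = "kinetics",
              metadata = list(seed = seed, spec = spec, Vmax = Vmax))
}
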