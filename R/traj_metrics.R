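# Superposition, RMSD series, per-residue RMSF with cross-monomer averaging,
# and mutant-minus-wild-type difference profiles.

#' Indices of Calpha atoms
#' @param traj a \code{Trajectory}.
#' @return integer atom indices of CA atoms.
#' @export
select_calpha <- function(traj) which(traj$atoms$name == "CA")

# optimal proper rotation (Kabsch, via SVD) sending centred P onto centred Q;
# P, Q are N x 3
kabsch_rotation <- function(P, Q) {
  C <- crossprod(P, Q)
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

check_subset_geometry <- function(X) {
  if (nrow(X) < 3L) stop("superposition needs at least 3 subset atoms")
  sv <- svd(scale(X, scale = FALSE))$d
  if (sv[2L] < 1e-8) stop("subset atoms are collinear")
}

# superpose mobile coords (N x 3) onto ref coords on the rows in `sub`,
# returning the transformed full coordinate set and the minimized RMSD on sub
superpose_coords <- function(mobile, ref, sub) {
  mp <- mobile[sub, , drop = FALSE]
  rp <- ref[sub, , drop = FALSE]
  cm <- colMeans(mp); cr <- colMeans(rp)
  R <- kabsch_rotation(sweep(mp, 2L, cm), sweep(rp, 2L, cr))
  moved <- sweep(sweep(mobile, 2L, cm) %*% R, 2L, cr, "+")
  rmsd <- sqrt(mean(rowSums((moved[sub, , drop = FALSE] - rp)^2)))
  list(coords = moved, rmsd = rmsd)
}

#' Least-squares rigid superposition of one frame onto another
#'
#' Kabsch algorithm: the proper rotation (det = +1) and translation minimizing
#' the RMSD over the selected atoms are applied to the whole mobile frame.
#'
#' @param mobile,ref single-frame \code{Trajectory} objects with matching
#'   atom ordering.
#' @param subset integer atom indices used for the fit (default: all CA);
#'   needs >= 3 non-collinear atoms.
#' @return list with \code{frame} (transformed mobile) and \code{rmsd}
#'   (Angstrom, on the subset).
#' @export
kabsch_superpose <- function(mobile, ref, subset = select_calpha(ref)) {
  stopifnot(nrow(mobile$atoms) == nrow(ref$atoms))
  check_subset_geometry(frame_coords(ref)[subset, , drop = FALSE])
  fit <- superpose_coords(frame_coords(mobile), frame_coords(ref), subset)
  out <- mobile
  out$xyz <- matrix(as.vector(t(fit$coords)), nrow = 1L)
  list(frame = out, rmsd = fit$rmsd)
}

#' Per-frame minimized RMSD relative to a reference structure
#'
#' Each frame is independently superposed onto \code{ref} on \code{subset}
#' before the deviation is measured, so global drift and tumbling do not
#' contribute.
#'
#' @param traj a \code{Trajectory}.
#' @param ref single-frame reference with the same atom ordering.
#' @param subset atom indices (default CA).
#' @return numeric vector of RMSD values (Angstrom), one per frame.
#' @export
rmsd_series <- function(traj, ref, subset = select_calpha(traj)) {
  if (nrow(traj$atoms) != nrow(ref$atoms))
    stop("trajectory and reference have different atom counts")
  refc <- frame_coords(ref)
  check_subset_geometry(refc[subset, , drop = FALSE])
  vapply(seq_len(n_frames(traj)), function(i)
    superpose_coords(frame_coords(traj, i), refc, subset)$rmsd,
    numeric(1L))
}

# iterated mean structure: superpose all frames onto the running average of
# the selected atoms until the average moves by < tol
iterated_mean_coords <- function(traj, subset, tol = 1e-6, max_iter = 50L) {
  coords <- lapply(seq_len(n_frames(traj)),
                   function(i) frame_coords(traj, i)[subset, , drop = FALSE])
  mref <- coords[[1L]]
  sub_all <- seq_len(nrow(mref))
  for (it in seq_len(max_iter)) {
    fitted <- lapply(coords, function(x)
      superpose_coords(x, mref, sub_all)$coords)
    mnew <- Reduce(`+`, fitted) / length(fitted)
    delta <- max(abs(mnew - mref))
    mref <- mnew
    coords <- fitted
    if (delta < tol) break
  }
  list(mean = mref, fitted = coords)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the iteratively computed mean structure of the
#' selection (superpose, re-average, repeat until the mean moves < 1e-6 A),
#' then \code{RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2)} for each
#' selected atom.
#'
#' @param traj a \code{Trajectory} with >= 2 frames.
#' @param subset atom indices (default CA, one per residue).
#' @return data.frame of class \code{rmsf_profile} with columns \code{chain},
#'   \code{resno}, \code{rmsf} (Angstrom); attribute \code{averaged} is FALSE.
#' @export
rmsf_per_residue <- function(traj, subset = select_calpha(traj)) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  im <- iterated_mean_coords(traj, subset)
  dev2 <- Reduce(`+`, lapply(im$fitted,
                             function(x) rowSums((x - im$mean)^2)))
  prof <- data.frame(chain = traj$atoms$chain[subset],
                     resno = traj$atoms$resno[subset],
                     rmsf = sqrt(dev2 / length(im$fitted)))
  structure(prof, averaged = FALSE, n_chains_averaged = 1L,
            class = c("rmsf_profile", "data.frame"))
}

#' Average an RMSF profile over equivalent chains
#'
#' Corresponding residues of the listed chains (all chains by default, the
#' four monomers of a homotetramer in the motivating case) are averaged to a
#' single per-position profile, reducing sampling noise.
#'
#' @param profile an \code{rmsf_profile}.
#' @param chains character vector of chain ids to average; they must share an
#'   identical residue index set.
#' @return an \code{rmsf_profile} with one row per residue position, chain
#'   \code{"*"}, attribute \code{averaged = TRUE}.
#' @export
average_over_chains <- function(profile, chains = unique(profile$chain)) {
  sub <- profile[profile$chain %in% chains, ]
  res_sets <- lapply(split(sub$resno, sub$chain), sort)
  ref_set <- res_sets[[1L]]
  for (ch in names(res_sets)) {
    if (!identical(res_sets[[ch]], ref_set)) {
      off <- union(setdiff(res_sets[[ch]], ref_set),
                   setdiff(ref_set, res_sets[[ch]]))
      stop("chains have mismatched residue sets; offending positions: ",
           paste(off, collapse = ", "))
    }
  }
  m <- stats::aggregate(list(rmsf = sub$rmsf), list(resno = sub$resno), mean)
  out <- data.frame(chain = "*", resno = m$resno, rmsf = m$rmsf)
  structure(out, averaged = TRUE, n_chains_averaged = length(res_sets),
            class = c("rmsf_profile", "data.frame"))
}

#' Mutant-minus-wild-type RMSF difference profile
#'
#' Subtracts chain-averaged RMSF values at corresponding residue positions.
#' Negative values indicate positions rigidified in the mutant; the summary
#' reports the fraction of strictly negative positions (ties count as
#' non-negative) and a histogram of the differences.
#'
#' @param mutant,wildtype chain-averaged \code{rmsf_profile} objects.
#' @return list of class \code{delta_profile}: \code{resno}, \code{delta}
#'   (Angstrom), \code{fraction_negative}, and \code{histogram}
#'   (breaks/counts as from \code{hist}).
#' @export
delta_rmsf <- function(mutant, wildtype) {
  if (!isTRUE(attr(mutant, "averaged")) || !isTRUE(attr(wildtype, "averaged")))
    stop("both profiles must be chain-averaged (see average_over_chains)")
  common <- intersect(mutant$resno, wildtype$resno)
  if (length(common) < 1L) stop("profiles share no residue positions")
  common <- sort(common)
  d <- mutant$rmsf[match(common, mutant$resno)] -
    wildtype$rmsf[match(common, wildtype$resno)]
  h <- graphics::hist(d, breaks = "Sturges", plot = FALSE)
  structure(list(resno = common, delta = d,
                 fraction_negative = mean(d < 0),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf(
    "delta-RMSF profile: %d positions, %.1f%% rigidified (negative), median %.4f A\n",
    length(x$resno), 100 * x$fraction_negative, stats::median(x$delta)))
  invisible(x)
}
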