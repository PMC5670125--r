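# Geometric hydrogen-bond detection and persistence tabulation. The paper
# trail for this analysis reports residue-level bonds with a "percentage of
# presence" over the trajectory; criteria here are the common MD-analysis
# convention (donor-acceptor heavy distance and D-H...A angle cutoffs) and
# are configurable.

#' Default H-bond detection criteria
#' @param max_dist maximum donor-acceptor heavy-atom distance (Angstrom).
#' @param min_angle minimum D-H...A angle at the hydrogen (degrees).
#' @return named list of criteria.
#' @export
hbond_criteria <- function(max_dist = 3.5, min_angle = 135) {
  stopifnot(max_dist > 0, min_angle >= 0, min_angle <= 180)
  list(max_dist = max_dist, min_angle = min_angle)
}

angle_deg <- function(a, b, c) {
  # angle at b of the a-b-c triplet
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in a single frame
#'
#' Reports every donor-hydrogen-acceptor triplet with heavy-atom distance at
#' most \code{criteria$max_dist} and D-H...A angle at least
#' \code{criteria$min_angle}. Acceptors in the donor's own residue are
#' excluded.
#'
#' @param frame single-frame \code{Trajectory}.
#' @param topo topology from \code{\link{infer_topology}}.
#' @param criteria from \code{\link{hbond_criteria}}.
#' @return data.frame, one row per triplet: donor/acceptor chain, resno,
#'   resname, atom names, hydrogen name, distance, angle.
#' @export
detect_hbonds_frame <- function(frame, topo, criteria = hbond_criteria()) {
  X <- frame_coords(frame)
  a <- frame$atoms
  hyd <- which(topo$is_polar_hydrogen)
  acc <- which(topo$is_acceptor)
  if (!length(hyd)) {
    warning("no polar hydrogens in frame: no donors available")
    return(empty_hbond_frame())
  }
  rows <- list()
  for (h in hyd) {
    d <- topo$donor_parent[h]
    for (ac in acc) {
      if (ac == d) next
      if (a$chain[ac] == a$chain[d] && a$resno[ac] == a$resno[d]) next
      dist_da <- sqrt(sum((X[d, ] - X[ac, ])^2))
      if (dist_da > criteria$max_dist) next
      ang <- angle_deg(X[d, ], X[h, ], X[ac, ])
      if (ang < criteria$min_angle) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = a$chain[d], donor_resno = a$resno[d],
        donor_resname = a$resname[d], donor_atom = a$name[d],
        hydrogen = a$name[h],
        acceptor_chain = a$chain[ac], acceptor_resno = a$resno[ac],
        acceptor_resname = a$resname[ac], acceptor_atom = a$name[ac],
        distance = dist_da, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hbond_frame())
  do.call(rbind, rows)
}

empty_hbond_frame <- function() {
  data.frame(donor_chain = character(0), donor_resno = integer(0),
             donor_resname = character(0), donor_atom = character(0),
             hydrogen = character(0),
             acceptor_chain = character(0), acceptor_resno = integer(0),
             acceptor_resname = character(0), acceptor_atom = character(0),
             distance = numeric(0), angle = numeric(0),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond persistence over a trajectory
#'
#' Every donor-heavy/acceptor pair observed in at least one frame gets a
#' presence percentage: 100 x (frames detected) / (total frames), 1 decimal.
#' Equivalent hydrogens of one donor (e.g. the three of an NH3+ group) are
#' collapsed: a frame counts once per donor/acceptor pair. Records are sorted
#' by decreasing presence.
#'
#' @param traj a \code{Trajectory}.
#' @param topo topology from \code{\link{infer_topology}} (inferred from the
#'   first frame when NULL).
#' @param criteria from \code{\link{hbond_criteria}}.
#' @return data.frame of class \code{hbond_records}: donor and acceptor
#'   identity, representative hydrogen, \code{presence_pct},
#'   \code{intra_monomer} (donor and acceptor on the same chain), \code{n_frames}.
#' @export
hbond_persistence <- function(traj, topo = NULL,
                              criteria = hbond_criteria()) {
  if (is.null(topo))
    topo <- suppressWarnings(infer_topology(get_frame(traj, 1L)))
  nf <- n_frames(traj)
  counts <- list()
  if (!any(topo$is_polar_hydrogen))
    warning("no polar hydrogens in topology: no H-bonds reportable")
  else for (f in seq_len(nf)) {
    det <- detect_hbonds_frame(get_frame(traj, f), topo, criteria)
    if (!nrow(det)) next
    key <- paste(det$donor_chain, det$donor_resno, det$donor_atom,
                 det$acceptor_chain, det$acceptor_resno, det$acceptor_atom,
                 sep = "|")
    for (k in unique(key)) {
      if (is.null(counts[[k]])) {
        counts[[k]] <- list(n = 1L, row = det[match(k, key), ])
      } else counts[[k]]$n <- counts[[k]]$n + 1L
    }
  }
  if (!length(counts)) {
    out <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resname = character(0), donor_atom = character(0),
                      hydrogen = character(0), acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resname = character(0),
                      acceptor_atom = character(0),
                      presence_pct = numeric(0), intra_monomer = logical(0),
                      n_frames = integer(0))
    return(structure(out, class = c("hbond_records", "data.frame")))
  }
  out <- do.call(rbind, lapply(counts, function(cc) {
    r <- cc$row[, c("donor_chain", "donor_resno", "donor_resname",
                    "donor_atom", "hydrogen", "acceptor_chain",
                    "acceptor_resno", "acceptor_resname", "acceptor_atom")]
    r$presence_pct <- round(100 * cc$n / nf, 1)
    r$intra_monomer <- r$donor_chain == r$acceptor_chain
    r$n_frames <- nf
    r
  }))
  out <- out[order(-out$presence_pct), ]
  rownames(out) <- NULL
  structure(out, class = c("hbond_records", "data.frame"))
}

#' Filter hydrogen-bond records by minimum persistence
#'
#' @param records an \code{hbond_records} data.frame.
#' @param threshold_pct minimum presence percentage in [0, 100]; the default
#'   15 sits just under the smallest persistence worth reporting in the
#'   motivating study.
#' @return the records with \code{presence_pct >= threshold_pct}, order
#'   preserved.
#' @export
filter_persistent <- function(records, threshold_pct = 15) {
  stopifnot(threshold_pct >= 0, threshold_pct <= 100)
  records[records$presence_pct >= threshold_pct, , drop = FALSE]
}
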