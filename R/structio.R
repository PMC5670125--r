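# Structure and curve I/O: multi-model PDB ensembles, per-atom topology,
# and two-column curve tables.

#' Construct a Trajectory object
#'
#' A \code{Trajectory} bundles an ordered set of conformations (frames) of one
#' molecular system with its per-atom metadata. All frames share the same atom
#' ordering; coordinates are in Angstrom.
#'
#' @param atoms data.frame with one row per atom and columns \code{serial},
#'   \code{name}, \code{element}, \code{resname}, \code{resno} (1-based within
#'   chain), \code{chain}.
#' @param xyz numeric matrix, one row per frame, \code{3 * nrow(atoms)} columns
#'   in x1,y1,z1,x2,... order (the bio3d convention).
#' @param frame_interval optional time per frame (dimensionless by default).
#' @param metadata optional named list carried along (e.g. generator ground
#'   truth, seeds).
#' @return object of class \code{Trajectory}.
#' @export
trajectory <- function(atoms, xyz, frame_interval = NA_real_, metadata = list()) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns; expected ", 3L * nrow(atoms))
  if (nrow(xyz) < 1L) stop("a Trajectory needs at least one frame")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, name) atom: ", key[anyDuplicated(key)])
  structure(list(atoms = atoms, xyz = xyz,
                 frame_interval = frame_interval, metadata = metadata),
            class = "Trajectory")
}

#' Number of frames in a Trajectory
#' @param traj a \code{Trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a Trajectory
#' @param traj a \code{Trajectory}.
#' @param i frame index (1-based).
#' @return a single-frame \code{Trajectory} (a "Frame").
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  trajectory(traj$atoms, traj$xyz[i, , drop = FALSE],
             frame_interval = traj$frame_interval, metadata = traj$metadata)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s), %d atoms, chains %s\n",
              n_frames(x), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = "")))
  invisible(x)
}

# coordinates of frame i as an N x 3 matrix
frame_coords <- function(traj, i = 1L) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

# pre-scan MODEL blocks so a malformed multi-model file fails with an error
# naming the offending MODEL, which bio3d does not report
scan_model_blocks <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) return(invisible(NULL))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records (", length(model_starts),
         " MODEL vs ", length(model_ends), " ENDMDL)")
  counts <- mapply(function(a, b) {
    sum(grepl("^(ATOM  |HETATM)", lines[a:b]))
  }, model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    stop(sprintf(
      "MODEL %d has %d atom records but MODEL 1 has %d: all models must share one atom list",
      bad, counts[bad], counts[1L]))
  }
  invisible(NULL)
}

#' Read a (multi-model) PDB file as a Trajectory
#'
#' Each \code{MODEL}/\code{ENDMDL} block becomes one frame; a file without
#' \code{MODEL} records yields a single-frame Trajectory. Parsing is delegated
#' to \code{bio3d::read.pdb}; a pre-scan enforces that every model carries the
#' same atom records and names the first offending model otherwise.
#'
#' @param path path to a PDB file.
#' @return a \code{Trajectory}.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  scan_model_blocks(lines)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  element <- trimws(at$elesy)
  if (any(element == "" | is.na(element))) {
    # fall back on the leading letter(s) of the atom name
    nm <- trimws(at$elety)
    element <- ifelse(element == "" | is.na(element),
                      sub("^[0-9]*([A-Za-z]).*", "\\1", nm), element)
  }
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = element, resname = trimws(at$resid),
                      resno = at$resno, chain = at$chain,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  trajectory(atoms, unclass(pdb$xyz))
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Coordinates are written in the fixed-width PDB convention (3 decimals), so
#' a read/write round trip preserves them to 0.001 Angstrom.
#'
#' @param traj a \code{Trajectory}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  a <- traj$atoms
  bio3d::write.pdb(file = path, xyz = traj$xyz, resno = a$resno,
                   resid = a$resname, eleno = a$serial, elety = a$name,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

# residue-specific polar-hydrogen -> donor heavy atom map (standard PDB names);
# backbone amide H is handled generically
sidechain_donor_h <- list(
  ARG = c(HE = "NE", HH11 = "NH1", HH12 = "NH1", HH21 = "NH2", HH22 = "NH2"),
  LYS = c(HZ1 = "NZ", HZ2 = "NZ", HZ3 = "NZ"),
  HIS = c(HD1 = "ND1", HE2 = "NE2"),
  TRP = c(HE1 = "NE1"),
  ASN = c(HD21 = "ND2", HD22 = "ND2"),
  GLN = c(HE21 = "NE2", HE22 = "NE2"),
  SER = c(HG = "OG"),
  THR = c(HG1 = "OG1"),
  TYR = c(HH = "OH"),
  CYS = c(HG = "SG"),
  ASP = c(HD2 = "OD2"),
  GLU = c(HE2 = "OE2"))

sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2"), MET = character(0))

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Infer per-atom topology flags from atom and residue names
#'
#' Flags Calpha, backbone, donor heavy atoms (N/O/S bearing at least one
#' hydrogen actually present in the frame), polar hydrogens (with their
#' covalent donor-heavy partner), and lone-pair acceptors (backbone O,
#' side-chain O/N per standard residue chemistry). A pure function of atom
#' names and residue codes.
#'
#' @param frame a \code{Trajectory} (only its atom table is used).
#' @return data.frame, one row per atom, with logical columns
#'   \code{is_calpha}, \code{is_backbone}, \code{is_donor_heavy},
#'   \code{is_polar_hydrogen}, \code{is_acceptor} and integer
#'   \code{donor_parent} (row index of the heavy partner, NA otherwise).
#' @export
infer_topology <- function(frame) {
  a <- frame$atoms
  n <- nrow(a)
  known <- a$resname %in% AA3
  if (any(!known))
    warning("unknown residue code(s) ",
            paste(unique(a$resname[!known]), collapse = ", "),
            ": excluded from donor/acceptor flags")
  topo <- data.frame(
    is_calpha = a$name == "CA" & known,
    is_backbone = a$name %in% c("N", "CA", "C", "O", "OXT") & known,
    is_donor_heavy = FALSE, is_polar_hydrogen = FALSE,
    is_acceptor = FALSE, donor_parent = NA_integer_)

  reskey <- paste(a$chain, a$resno)
  heavy_index <- function(i, heavy_name) {
    j <- which(reskey == reskey[i] & a$name == heavy_name)
    if (length(j) == 1L) j else NA_integer_
  }
  for (i in seq_len(n)) {
    if (!known[i]) next
    nm <- a$name[i]
    if (grepl("^[0-9]*H", nm)) {
      parent <- NA_integer_
      if (nm %in% c("H", "HN", "H1", "H2", "H3")) {
        parent <- heavy_index(i, "N")
      } else {
        map <- sidechain_donor_h[[a$resname[i]]]
        if (!is.null(map) && nm %in% names(map))
          parent <- heavy_index(i, map[[nm]])
      }
      if (!is.na(parent)) {
        topo$is_polar_hydrogen[i] <- TRUE
        topo$donor_parent[i] <- parent
        topo$is_donor_heavy[parent] <- TRUE
      }
    } else if (nm %in% c("O", "OXT")) {
      topo$is_acceptor[i] <- TRUE
    } else {
      acc <- sidechain_acceptors[[a$resname[i]]]
      if (!is.null(acc) && nm %in% acc) topo$is_acceptor[i] <- TRUE
    }
  }
  if (!any(topo$is_polar_hydrogen))
    warning("no polar hydrogens found: donor set is empty")
  topo
}

#' Construct a curve table
#'
#' @param x ordered numeric vector (temperature in degC or substrate in mM).
#' @param y numeric signal / percent activity / rate vector.
#' @param kind one of \code{"melting"}, \code{"activity"}, \code{"kinetics"}.
#' @param metadata optional named list (e.g. generator ground truth).
#' @return data.frame of class \code{curve_table} with columns x, y.
#' @export
curve_table <- function(x, y, kind = c("melting", "activity", "kinetics"),
                        metadata = list()) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 points, got ", length(x))
  if (kind != "kinetics" && any(diff(x) <= 0))
    stop(kind, " curves need strictly increasing x")
  structure(data.frame(x = x, y = y), kind = kind, metadata = metadata,
            class = c("curve_table", "data.frame"))
}

curve_kind <- function(curve) attr(curve, "kind")

#' Read a two-column curve CSV
#'
#' Expects a header and two numeric columns (x, y). Rows are sorted by x and
#' duplicate x values are averaged (replicate wells).
#'
#' @param path CSV path.
#' @param kind curve kind tag; see \code{\link{curve_table}}.
#' @return a \code{curve_table}.
#' @export
read_curve_csv <- function(path, kind = c("melting", "activity", "kinetics")) {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected a 2-column CSV in ", path)
  xs <- suppressWarnings(as.numeric(raw[[1L]]))
  ys <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad))
    stop("non-numeric value at data row ", bad[1L], " of ", path)
  agg <- stats::aggregate(list(y = ys), list(x = xs), mean)
  agg <- agg[order(agg$x), ]
  curve_table(agg$x, agg$y, kind = kind)
}

#' Write a curve table as CSV
#' @param curve a \code{curve_table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(x = curve$x, y = curve$y), path,
                   row.names = FALSE)
  invisible(path)
}
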