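# Distance-fluctuation (DF) coordination analysis. The DF parameter for a
# residue pair is the time variance of its Calpha-Calpha distance:
#   DF_ij = < (d_ij - <d_ij>)^2 >
# with <.> the plain average over frames (population variance). Because it is
# built from internal distances it is invariant under rigid motion of each
# frame, so no superposition is applied.

#' Distance-fluctuation matrix of a trajectory
#'
#' @param traj a \code{Trajectory} with >= 2 frames and CA atoms.
#' @param scope \code{"tetramer"} (all chains; the name follows the motivating
#'   homotetramer, any chain count is accepted) or a single chain id.
#' @return object of class \code{df_matrix}: \code{labels} (data.frame chain,
#'   resno), \code{values} (symmetric matrix, Angstrom^2, zero diagonal),
#'   \code{n_frames}, \code{selection}.
#' @export
df_matrix <- function(traj, scope = "tetramer") {
  if (n_frames(traj) < 2L) stop("DF needs at least 2 frames")
  ca <- select_calpha(traj)
  if (length(ca) < 2L) stop("no CA atom pairs in trajectory")
  if (!identical(scope, "tetramer")) {
    keep <- traj$atoms$chain[ca] == scope
    if (!any(keep)) stop("chain not present: ", scope)
    ca <- ca[keep]
  }
  nf <- n_frames(traj)
  n <- length(ca)
  # two-pass: mean distance, then mean squared deviation (population)
  dsum <- 0
  dists <- vector("list", nf)
  for (f in seq_len(nf)) {
    dists[[f]] <- stats::dist(frame_coords(traj, f)[ca, , drop = FALSE])
    dsum <- dsum + dists[[f]]
  }
  dmean <- dsum / nf
  vsum <- 0
  for (f in seq_len(nf)) vsum <- vsum + (dists[[f]] - dmean)^2
  values <- matrix(0, n, n)
  values[lower.tri(values)] <- as.vector(vsum / nf)
  values <- values + t(values)
  labels <- data.frame(chain = traj$atoms$chain[ca],
                       resno = traj$atoms$resno[ca])
  rownames(values) <- colnames(values) <- paste0(labels$chain, labels$resno)
  structure(list(labels = labels, values = values, n_frames = nf,
                 selection = if (identical(scope, "tetramer")) "CA (all chains)"
                 else paste0("CA (chain ", scope, ")"),
                 units = "A^2"),
            class = "df_matrix")
}

#' @export
print.df_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("DF matrix: %d residues (%s), %d frames; mean %.4g A^2, max %.4g A^2\n",
              nrow(x$values), x$selection, x$n_frames, mean(off), max(off)))
  invisible(x)
}

check_block_partition <- function(n, blocks) {
  idx <- as.integer(sort(unname(unlist(blocks))))
  if (any(duplicated(idx)) || !identical(idx, seq_len(n)))
    stop("blocks must partition the matrix labels exactly once")
}

#' Within- and between-block summaries of a DF matrix
#'
#' @param dfm a \code{df_matrix}.
#' @param blocks list of integer vectors partitioning the matrix labels
#'   (e.g. one block per monomer).
#' @return list with \code{within} (data.frame block, mean, median),
#'   \code{between} (data.frame block_a, block_b, mean, median; empty for a
#'   single block), \code{within_mean}, \code{between_mean}.
#' @export
df_block_summary <- function(dfm, blocks) {
  n <- nrow(dfm$values)
  check_block_partition(n, blocks)
  nb <- length(blocks)
  within <- do.call(rbind, lapply(seq_len(nb), function(b) {
    v <- dfm$values[blocks[[b]], blocks[[b]]]
    off <- v[upper.tri(v)]
    if (!length(off)) off <- 0
    data.frame(block = b, mean = mean(off), median = stats::median(off))
  }))
  between <- NULL
  if (nb > 1L) {
    pairs <- utils::combn(nb, 2L)
    between <- do.call(rbind, apply(pairs, 2L, function(p) {
      v <- dfm$values[blocks[[p[1L]]], blocks[[p[2L]]], drop = FALSE]
      data.frame(block_a = p[1L], block_b = p[2L],
                 mean = mean(v), median = stats::median(v))
    }))
  } else {
    between <- data.frame(block_a = integer(0), block_b = integer(0),
                          mean = numeric(0), median = numeric(0))
  }
  all_within <- unlist(lapply(seq_len(nb), function(b) {
    v <- dfm$values[blocks[[b]], blocks[[b]]]
    v[upper.tri(v)]
  }))
  all_between <- if (nb > 1L)
    unlist(apply(utils::combn(nb, 2L), 2L, function(p)
      as.vector(dfm$values[blocks[[p[1L]]], blocks[[p[2L]]]])))
  else numeric(0)
  list(within = within, between = between,
       within_mean = if (length(all_within)) mean(all_within) else 0,
       between_mean = if (length(all_between)) mean(all_between) else NA_real_)
}

#' Element-wise difference of two DF matrices
#'
#' \code{a - b}; a negative entry means the pair is more coordinated (lower
#' distance fluctuation) in \code{a}.
#'
#' @param dfm_a,dfm_b \code{df_matrix} objects with identical labels.
#' @return list with \code{delta} (matrix, Angstrom^2) and \code{summary}
#'   (fraction of off-diagonal pairs strictly negative, mean delta).
#' @export
df_difference <- function(dfm_a, dfm_b) {
  if (!identical(dfm_a$labels, dfm_b$labels))
    stop("DF matrices have mismatched residue labels")
  delta <- dfm_a$values - dfm_b$values
  off <- delta[upper.tri(delta)]
  list(delta = delta,
       summary = list(fraction_negative = mean(off < 0),
                      mean_delta = mean(off)))
}

#' Write a DF matrix as labelled CSV
#' @param dfm a \code{df_matrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_df_csv <- function(dfm, path) {
  utils::write.csv(as.data.frame(dfm$values), path, row.names = TRUE)
  invisible(path)
}
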