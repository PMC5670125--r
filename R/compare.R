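# Full variant-vs-wild-type rigidity comparison: chain-averaged RMSF and its
# difference profile, distance-fluctuation matrices and their difference, and
# hydrogen-bond persistence for both ensembles.

#' Compare a mutant ensemble against a wild-type ensemble
#'
#' Runs the whole rigidity pipeline on two trajectories of the same system
#' and summarizes the evidence for (or against) rigidification of the mutant:
#' a negative-dominated delta-RMSF profile and a negative-dominated DF
#' difference both indicate a more rigid, more coordinated mutant.
#'
#' @param mutant,wildtype \code{Trajectory} objects with matching chains and
#'   residue numbering.
#' @param hbond_criteria H-bond detection criteria; see
#'   \code{\link{hbond_criteria}}.
#' @param hbond_threshold minimum persistence (%) retained in the report.
#' @return list of class \code{rigidity_comparison}: \code{delta_rmsf}
#'   (a \code{delta_profile}), \code{rmsf} (the two averaged profiles),
#'   \code{df_difference} (delta matrix and summary), \code{hbonds}
#'   (persistent records per ensemble), and a \code{verdict} list with the
#'   headline fractions.
#' @export
compare_ensembles <- function(mutant, wildtype,
                              hbond_criteria = rigidiscope::hbond_criteria(),
                              hbond_threshold = 15) {
  rmsf_mut <- average_over_chains(rmsf_per_residue(mutant))
  rmsf_wt <- average_over_chains(rmsf_per_residue(wildtype))
  drmsf <- delta_rmsf(rmsf_mut, rmsf_wt)
  dfd <- df_difference(df_matrix(mutant), df_matrix(wildtype))
  hb_mut <- filter_persistent(hbond_persistence(mutant, criteria = hbond_criteria),
                              hbond_threshold)
  hb_wt <- filter_persistent(hbond_persistence(wildtype, criteria = hbond_criteria),
                             hbond_threshold)
  structure(list(
    delta_rmsf = drmsf,
    rmsf = list(mutant = rmsf_mut, wildtype = rmsf_wt),
    df_difference = dfd,
    hbonds = list(mutant = hb_mut, wildtype = hb_wt),
    verdict = list(
      fraction_rmsf_negative = drmsf$fraction_negative,
      fraction_df_negative = dfd$summary$fraction_negative,
      median_delta_rmsf = stats::median(drmsf$delta),
      mean_delta_df = dfd$summary$mean_delta,
      rigidified = drmsf$fraction_negative > 0.5 &&
        dfd$summary$fraction_negative > 0.5)),
    class = "rigidity_comparison")
}

#' @export
print.rigidity_comparison <- function(x, ...) {
  v <- x$verdict
  cat(sprintf(paste0(
    "Rigidity comparison (mutant vs wild-type)\n",
    "  delta-RMSF: %.1f%% of positions negative (median %.4f A)\n",
    "  delta-DF:   %.1f%% of pairs negative (mean %.4g A^2)\n",
    "  verdict:    mutant %s\n"),
    100 * v$fraction_rmsf_negative, v$median_delta_rmsf,
    100 * v$fraction_df_negative, v$mean_delta_df,
    if (v$rigidified) "is rigidified" else "is not rigidified"))
  invisible(x)
}
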