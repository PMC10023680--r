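## Binding-energy-landscape representation and funnel selection.
##
## Each compatible docked pose yields an ensemble of design decoys, each
## with a backbone RMSD to the initial pose and an interface binding-energy
## change (ddg). A native-like pose shows a funnel: energy falls as the
## decoys approach the initial pose. Poses are filtered on four criteria
## (enough decoys; RMSD and ddg spreads in the top half of the cohort;
## energy minimum localized below the mean RMSD) and ranked by a
## closed-form 0-10 funnel score.

#' Design-decoy ensemble for one pose
#'
#' @param pose_id pose identifier shared by all decoys.
#' @param decoys data frame with columns `design_id`, `sequence`, `rmsd`
#'   (backbone RMSD to the initial pose, Angstrom, `>= 0`), `ddg` (binding
#'   energy change, engine units) and optionally `sasa`, `total_score`.
#' @return object of class `landscape_ensemble`.
#' @export
landscape_ensemble <- function(pose_id, decoys) {
  need <- c("design_id", "rmsd", "ddg")
  miss <- setdiff(need, names(decoys))
  if (length(miss))
    stop("decoy table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(decoys) > 0L && any(decoys$rmsd < 0))
    stop("decoy rmsd values must be nonnegative")
  decoys$pose_id <- as.character(pose_id)
  structure(list(pose_id = as.character(pose_id), decoys = decoys),
            class = "landscape_ensemble")
}

#' Funnel-filter criteria
#'
#' @param min_designs strict lower bound on the decoy count (criterion 1,
#'   default 50: an ensemble passes with more than 50 decoys).
#' @param spread_percentile cohort percentile defining "within the highest
#'   50\%" for the RMSD/ddg spreads (default 0.5; passing means `>=` that
#'   cohort quantile).
#' @param localization require the minimum-ddg decoy's RMSD below the
#'   ensemble mean RMSD (criterion 4, default `TRUE`).
#' @return list of class `funnel_criteria`.
#' @export
funnel_criteria <- function(min_designs = 50L, spread_percentile = 0.5,
                            localization = TRUE) {
  stopifnot(spread_percentile > 0, spread_percentile < 1)
  structure(list(min_designs = as.integer(min_designs),
                 spread_percentile = spread_percentile,
                 localization = localization),
            class = "funnel_criteria")
}

#' Summary statistics of a decoy ensemble
#'
#' Spreads are sample standard deviations (n - 1 denominator).
#' `rmsd_at_min_ddg` is the RMSD of the minimum-ddg decoy; ties on ddg
#' resolve to the lowest RMSD.
#'
#' @param ensemble a [landscape_ensemble()].
#' @return list with `n`, `rmsd_mean`, `rmsd_std`, `ddg_std`,
#'   `rmsd_at_min_ddg`, `min_ddg`.
#' @export
ensemble_stats <- function(ensemble) {
  d <- ensemble$decoys
  if (nrow(d) == 0L) stop("ensemble ", ensemble$pose_id, " has no decoys")
  ord <- order(d$ddg, d$rmsd)
  best <- d[ord[1L], ]
  list(n = nrow(d),
       rmsd_mean = mean(d$rmsd),
       rmsd_std = if (nrow(d) > 1L) stats::sd(d$rmsd) else 0,
       ddg_std = if (nrow(d) > 1L) stats::sd(d$ddg) else 0,
       rmsd_at_min_ddg = best$rmsd,
       min_ddg = best$ddg)
}

#' Funnel-shaped landscape filter over a pose cohort
#'
#' A pose is retained when (1) it has more than `min_designs` decoys,
#' (2) its RMSD spread and (3) its ddg spread are at or above the cohort
#' median (medians computed over the criterion-1 survivors), and (4) the
#' minimum-ddg decoy sits below the mean RMSD. The verdict table records
#' every criterion for every pose.
#'
#' @param cohort list of [landscape_ensemble()].
#' @param criteria a [funnel_criteria()] object.
#' @return list with `retained` (pose ids) and `verdicts` (data frame with
#'   per-pose stats and criterion columns `c1`..`c4`, `retained`).
#' @export
funnel_filter <- function(cohort, criteria = funnel_criteria()) {
  if (length(cohort) == 0L) stop("funnel_filter: empty cohort")
  st <- lapply(cohort, ensemble_stats)
  v <- data.frame(
    pose_id = vapply(cohort, `[[`, character(1), "pose_id"),
    n = vapply(st, `[[`, numeric(1), "n"),
    rmsd_mean = vapply(st, `[[`, numeric(1), "rmsd_mean"),
    rmsd_std = vapply(st, `[[`, numeric(1), "rmsd_std"),
    ddg_std = vapply(st, `[[`, numeric(1), "ddg_std"),
    rmsd_at_min_ddg = vapply(st, `[[`, numeric(1), "rmsd_at_min_ddg"),
    stringsAsFactors = FALSE)
  v$c1 <- v$n > criteria$min_designs
  if (!any(v$c1)) {
    warning("no ensemble passes the minimum-design-count criterion")
    v$c2 <- v$c3 <- v$c4 <- FALSE
    v$retained <- FALSE
    return(list(retained = character(0), verdicts = v))
  }
  q <- criteria$spread_percentile
  rmsd_cut <- stats::quantile(v$rmsd_std[v$c1], q, names = FALSE, type = 7)
  ddg_cut <- stats::quantile(v$ddg_std[v$c1], q, names = FALSE, type = 7)
  v$c2 <- v$rmsd_std >= rmsd_cut
  v$c3 <- v$ddg_std >= ddg_cut
  v$c4 <- if (criteria$localization) v$rmsd_at_min_ddg < v$rmsd_mean
          else TRUE
  v$retained <- v$c1 & v$c2 & v$c3 & v$c4
  list(retained = v$pose_id[v$retained], verdicts = v)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Quantitative funnel score (0-10)
#'
#' Closed-form surrogate for a visual funnel assessment, averaging three
#' equally weighted components scaled to `[0, 10]`:
#' \itemize{
#'   \item depth: `(median(ddg) - min(ddg)) / range(ddg)` clamped to
#'     `[0, 1]` (0 when the range is 0);
#'   \item slope: the Spearman correlation of (rmsd, ddg) over decoys with
#'     `rmsd < slope_rmsd_max` (5 Angstrom), clamped to `[0, 1]`, so that
#'     energy decreasing toward low RMSD scores high (0 when fewer than 3
#'     such decoys or either variable is constant);
#'   \item localization: 1 when the minimum-ddg decoy lies within
#'     `loc_cutoff` (2 Angstrom) of the initial pose, decaying as
#'     `exp(-(rmsd - loc_cutoff))` beyond it, and multiplied by the slope
#'     component. The gating matters: in a shallow featureless cloud the
#'     location of the energy minimum is noise, and an ungated
#'     localization term would hand roughly a quarter of flat landscapes
#'     (those whose accidental minimum lands below `loc_cutoff`) a
#'     misleadingly high score.
#' }
#'
#' @param ensemble a [landscape_ensemble()] with at least 5 decoys.
#' @param loc_cutoff localization cutoff in Angstrom (default 2).
#' @param slope_rmsd_max RMSD window for the slope component (default 5).
#' @return score in `[0, 10]`.
#' @export
funnel_score <- function(ensemble, loc_cutoff = 2, slope_rmsd_max = 5) {
  d <- ensemble$decoys
  if (nrow(d) < 5L)
    stop("funnel_score needs at least 5 decoys (got ", nrow(d), ")")
  st <- ensemble_stats(ensemble)
  rng <- max(d$ddg) - min(d$ddg)
  f_depth <- if (rng <= 0) 0 else
    clamp01((stats::median(d$ddg) - min(d$ddg)) / rng)
  r0 <- st$rmsd_at_min_ddg
  f_loc <- if (r0 <= loc_cutoff) 1 else exp(-(r0 - loc_cutoff))
  w <- d[d$rmsd < slope_rmsd_max, , drop = FALSE]
  f_slope <- 0
  if (nrow(w) >= 3L && stats::sd(w$rmsd) > 0 && stats::sd(w$ddg) > 0) {
    rho <- stats::cor(w$rmsd, w$ddg, method = "spearman")
    f_slope <- clamp01(rho)
  }
  (10 / 3) * (f_depth + f_slope * f_loc + f_slope)
}

#' Read/write decoy tables
#'
#' Long-format TSV with columns `design_id`, `pose_id`, `sequence`, `rmsd`,
#' `ddg` and optionally `sasa`, `total_score`, `mmpbsa`, `funnel_score`.
#'
#' @param path TSV file.
#' @return `read_decoy_table`: a data frame; `split_ensembles`: a list of
#'   [landscape_ensemble()] split by `pose_id` (input order of first
#'   appearance).
#' @export
read_decoy_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_decoy_table
#' @param decoys long-format decoy data frame.
#' @export
write_decoy_table <- function(decoys, path) {
  utils::write.table(decoys, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_decoy_table
#' @export
split_ensembles <- function(decoys) {
  ids <- unique(decoys$pose_id)
  lapply(ids, function(p)
    landscape_ensemble(p, decoys[decoys$pose_id == p, , drop = FALSE]))
}
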