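## MD post-processing: snapshot schedules, framework-anchored
## superposition, per-CDR backbone RMSD traces, multi-run aggregation and
## one-tailed significance testing of loop flexibility.

#' CDR / framework loop definition
#'
#' Residue ranges are inclusive on both ends and use author numbering.
#' Superposition is anchored on the framework so that loop motion is not
#' absorbed by the fit.
#'
#' @param cdr1,cdr2,cdr3 `c(lo, hi)` residue ranges of the three CDR
#'   loops.
#' @param framework list of `c(lo, hi)` ranges covering the framework;
#'   must not overlap the CDRs.
#' @param atom_filter atoms used for superposition and RMSD: `"CA"`
#'   (default) or the full backbone `c("N", "CA", "C", "O")`.
#' @return list of class `loop_definition`.
#' @export
loop_definition <- function(cdr1, cdr2, cdr3, framework = NULL,
                            atom_filter = "CA") {
  loops <- list(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3)
  loop_res <- unlist(lapply(loops, function(r) seq(r[1L], r[2L])))
  if (!is.null(framework)) {
    if (!is.list(framework)) framework <- list(framework)
    fw_res <- unlist(lapply(framework, function(r) seq(r[1L], r[2L])))
    if (length(intersect(loop_res, fw_res)))
      stop("framework and CDR residue ranges overlap")
  }
  structure(c(loops, list(framework = framework,
                          atom_filter = atom_filter)),
            class = "loop_definition")
}

#' Snapshot times for trajectory analysis
#'
#' Evenly spaced times `interval, 2*interval, ..., t_end`; the 0 ps frame
#' is excluded by default so a 10 ns run sampled every 200 ps yields
#' exactly 50 snapshots (and every 100 ps yields 100).
#'
#' @param t_end production length (ps).
#' @param interval spacing (ps), `> 0` and `<= t_end`.
#' @param include_t0 prepend time 0 (default `FALSE`).
#' @return numeric vector of times (ps). When `t_end` is not a multiple of
#'   `interval` the schedule stops at the last full multiple, with a
#'   warning.
#' @export
snapshot_schedule <- function(t_end, interval, include_t0 = FALSE) {
  stopifnot(interval > 0, t_end >= interval)
  n <- floor(t_end / interval + 1e-9)
  if (abs(n * interval - t_end) > 1e-9 * max(1, t_end))
    warning("t_end is not a multiple of interval; schedule stops at ",
            n * interval, " ps")
  times <- seq_len(n) * interval
  if (include_t0) times <- c(0, times)
  times
}

check_topology <- function(frame_atoms, ref_atoms) {
  key <- function(a) paste(a$chain_id, a$res_seq, a$atom_name)
  ka <- key(frame_atoms)
  kr <- key(ref_atoms)
  if (length(ka) != length(kr) || any(ka != kr)) {
    bad <- which(ka != kr)[1L]
    if (is.na(bad)) bad <- min(length(ka), length(kr)) + 1L
    stop("trajectory frame topology differs from reference at atom ",
         bad, " (", if (bad <= length(kr)) kr[bad] else "past end of",
         " reference)")
  }
}

frame_atoms <- function(frame) {
  if (inherits(frame, "complex_model")) frame$atoms
  else if (inherits(frame, "chain_model")) frame$atoms
  else frame
}

#' Per-CDR backbone RMSD trace over a trajectory
#'
#' Each frame is superposed onto the reference using the framework
#' atoms of the loop definition ([kabsch_superpose()]), then the
#' unsuperposed RMSD of each CDR's selected backbone atoms is recorded.
#'
#' @param frames list of trajectory frames (`complex_model`s sharing the
#'   reference topology), e.g. from [read_pdb()] on a multi-model file.
#' @param reference reference frame (same topology).
#' @param loopdef a [loop_definition()] with framework ranges.
#' @param times snapshot times (ps); default `1..n` frame index.
#' @param run_id identifier stored with the trace.
#' @return object of class `rmsd_trace`: data frame `time`, `cdr1`,
#'   `cdr2`, `cdr3` plus attribute `run_id`.
#' @export
cdr_rmsd_trace <- function(frames, reference, loopdef, times = NULL,
                           run_id = "run1") {
  ref <- frame_atoms(reference)
  if (is.null(loopdef$framework))
    stop("loop definition needs framework ranges for superposition")
  if (is.null(times)) times <- seq_along(frames)
  if (length(times) != length(frames))
    stop("times and frames differ in length")
  af <- loopdef$atom_filter
  ref_fw <- resolve_selection(ref, loopdef$framework, af)
  rows <- lapply(seq_along(frames), function(i) {
    at <- frame_atoms(frames[[i]])
    check_topology(at, ref)
    fw <- resolve_selection(at, loopdef$framework, af)
    fit <- kabsch_superpose(coords(fw), coords(ref_fw))
    fitted <- apply_superposition(at, fit)
    data.frame(time = times[i],
               cdr1 = selection_rmsd(fitted, ref, list(loopdef$cdr1), af),
               cdr2 = selection_rmsd(fitted, ref, list(loopdef$cdr2), af),
               cdr3 = selection_rmsd(fitted, ref, list(loopdef$cdr3), af))
  })
  out <- do.call(rbind, rows)
  if (is.unsorted(out$time, strictly = TRUE))
    stop("snapshot times must be strictly increasing")
  attr(out, "run_id") <- run_id
  class(out) <- c("rmsd_trace", "data.frame")
  out
}

#' Aggregate RMSD traces over independent runs
#'
#' Per time point and loop: mean and min/max envelope across runs (the
#' "mean and range" presentation for `n = 5` independent production
#' runs).
#'
#' @param traces list of [cdr_rmsd_trace()] results on a common time
#'   grid.
#' @param n_expected expected run count (default 5; a differing count
#'   only triggers a message).
#' @return data frame with `time`, then `<loop>_mean`, `<loop>_min`,
#'   `<loop>_max` for each loop column.
#' @export
aggregate_runs <- function(traces, n_expected = 5L) {
  stopifnot(length(traces) >= 1L)
  if (length(traces) != n_expected)
    message("aggregating ", length(traces), " runs (expected ",
            n_expected, ")")
  t0 <- traces[[1L]]$time
  for (tr in traces)
    if (length(tr$time) != length(t0) || any(tr$time != t0))
      stop("traces do not share a common time grid")
  loops <- setdiff(names(traces[[1L]]), "time")
  out <- data.frame(time = t0)
  for (lp in loops) {
    m <- vapply(traces, `[[`, numeric(length(t0)), lp)
    m <- matrix(m, nrow = length(t0))
    out[[paste0(lp, "_mean")]] <- rowMeans(m)
    out[[paste0(lp, "_min")]] <- apply(m, 1L, min)
    out[[paste0(lp, "_max")]] <- apply(m, 1L, max)
  }
  out
}

#' One-tailed two-sample flexibility comparison
#'
#' Pooled-variance (Student) independent two-sample t-test with a
#' one-tailed p-value in the stated direction. With zero pooled variance,
#' equal means give `t = 0, p = 0.5` by convention and unequal means are
#' an error.
#'
#' @param samplesA,samplesB numeric samples (e.g. per-snapshot loop RMSD),
#'   each of size >= 2.
#' @param alternative `"A_greater"` (default) or `"B_greater"`.
#' @return list with `t`, `df`, `p`.
#' @export
compare_flexibility <- function(samplesA, samplesB,
                                alternative = c("A_greater", "B_greater")) {
  alternative <- match.arg(alternative)
  na <- length(samplesA); nb <- length(samplesB)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 values")
  ma <- mean(samplesA); mb <- mean(samplesB)
  sp2 <- ((na - 1) * stats::var(samplesA) +
          (nb - 1) * stats::var(samplesB)) / (na + nb - 2)
  df <- na + nb - 2
  if (sp2 <= 0) {
    if (isTRUE(all.equal(ma, mb)))
      return(list(t = 0, df = df, p = 0.5))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  if (alternative == "B_greater") t_dir <- -t else t_dir <- t
  list(t = t, df = df, p = stats::pt(t_dir, df, lower.tail = FALSE))
}

#' Write an RMSD trace or aggregate to TSV
#' @param x data frame ([cdr_rmsd_trace()] or [aggregate_runs()] output).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
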