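## First-round design selection.
##
## The lowest-ddg decoys of each selected pose are pooled, designs with a
## small buried interface are discarded, and final candidates are picked in
## a cycled order over heterogeneous criteria sets until a fixed number of
## sequence-non-redundant designs is reached. Cycling over differently
## ranked and filtered views of the pool is what diversifies the picks.

#' Lowest-k decoys per pose
#'
#' For each ensemble, takes the `k` lowest-ddg decoys (ties: lower RMSD,
#' then `design_id`). Ensembles with fewer than `k` decoys contribute all
#' of them, with a warning.
#'
#' @param ensembles list of [landscape_ensemble()].
#' @param k decoys retained per pose (default 20).
#' @return pooled data frame of decoys, `pose_id` kept per row.
#' @export
per_pose_lowest_k <- function(ensembles, k = 20L) {
  stopifnot(k >= 1L)
  short <- character(0)
  picked <- lapply(ensembles, function(e) {
    d <- e$decoys
    if (nrow(d) < k) short <<- c(short, e$pose_id)
    ord <- order(d$ddg, d$rmsd, d$design_id)
    d[ord[seq_len(min(k, nrow(d)))], , drop = FALSE]
  })
  if (length(short))
    warning("ensemble(s) with fewer than k decoys contribute all: ",
            paste(short, collapse = ", "))
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Buried-SASA interface filter
#'
#' Discards designs whose interface buries less than `min_sasa` (kept when
#' `sasa >= min_sasa`; the boundary value is kept).
#'
#' @param designs data frame with a `sasa` column (Angstrom^2).
#' @param min_sasa cutoff (default 800).
#' @return the retained subset.
#' @export
sasa_filter <- function(designs, min_sasa = 800) {
  if (nrow(designs) == 0L) return(designs)
  if (is.null(designs$sasa) || anyNA(designs$sasa)) {
    bad <- if (is.null(designs$sasa)) designs$design_id else
      designs$design_id[is.na(designs$sasa)]
    stop("missing buried SASA for design(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- designs[designs$sasa >= min_sasa, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One selection criteria set
#'
#' @param set_id integer id.
#' @param keys list of ranking keys, each `list(column =, direction =)`
#'   with direction `"asc"` or `"desc"`; applied lexicographically.
#' @param filters optional named list of hard filters: `min_funnel_score`,
#'   `min_sasa`, `max_mmpbsa` (a number, or `"median"` for the pool
#'   median).
#' @return list of class `criteria_set`.
#' @export
criteria_set <- function(set_id, keys, filters = list()) {
  if (length(keys) == 0L) stop("criteria_set needs at least one ranking key")
  structure(list(set_id = as.integer(set_id), keys = keys,
                 filters = filters),
            class = "criteria_set")
}

#' Default 12-set selection scheme
#'
#' Cross product of three rankings (ddg ascending, mmpbsa ascending,
#' funnel score descending) with four hard filters (none; buried SASA at
#' least 900; funnel score at least 5; mmpbsa at or below the pool
#' median), giving criteria sets 1-12. Contents are a package default and
#' fully user-overridable.
#'
#' @param target_count number of non-redundant designs to select
#'   (default 16).
#' @return list of class `selection_scheme` with `sets` and
#'   `target_count`.
#' @export
default_selection_scheme <- function(target_count = 16L) {
  ranks <- list(list(list(column = "ddg", direction = "asc")),
                list(list(column = "mmpbsa", direction = "asc")),
                list(list(column = "funnel_score", direction = "desc")))
  filters <- list(list(), list(min_sasa = 900),
                  list(min_funnel_score = 5), list(max_mmpbsa = "median"))
  sets <- list()
  id <- 0L
  for (f in filters) for (r in ranks) {
    id <- id + 1L
    sets[[id]] <- criteria_set(id, r, f)
  }
  selection_scheme(sets, target_count)
}

#' Selection scheme container
#' @param sets ordered list of [criteria_set()].
#' @param target_count number of sequence-non-redundant designs to pick.
#' @return list of class `selection_scheme`.
#' @export
selection_scheme <- function(sets, target_count = 16L) {
  stopifnot(target_count >= 1L, length(sets) >= 1L)
  structure(list(sets = sets, target_count = as.integer(target_count)),
            class = "selection_scheme")
}

apply_filters <- function(pool, filters, pool_median_mmpbsa) {
  keep <- rep(TRUE, nrow(pool))
  if (!is.null(filters$min_funnel_score))
    keep <- keep & pool$funnel_score >= filters$min_funnel_score
  if (!is.null(filters$min_sasa))
    keep <- keep & pool$sasa >= filters$min_sasa
  if (!is.null(filters$max_mmpbsa)) {
    cut <- if (identical(filters$max_mmpbsa, "median"))
      pool_median_mmpbsa else filters$max_mmpbsa
    keep <- keep & pool$mmpbsa <= cut
  }
  keep
}

rank_order <- function(pool, keys) {
  args <- lapply(keys, function(k) {
    v <- pool[[k$column]]
    if (is.null(v)) stop("ranking column absent from pool: ", k$column)
    if (identical(k$direction, "desc")) -xtfrm(v) else xtfrm(v)
  })
  ## deterministic tie-break: rmsd then design_id
  if (!is.null(pool$rmsd)) args <- c(args, list(xtfrm(pool$rmsd)))
  args <- c(args, list(xtfrm(pool$design_id)))
  do.call(order, args)
}

#' Cycled multi-criteria design pick
#'
#' Iterates the scheme's criteria sets cyclically; each visit picks the
#' top-ranked not-yet-picked design (after that set's hard filters) whose
#' sequence differs from every already-picked design. Redundant designs
#' are skipped, not consumed. Stops at `target_count` picks or when a full
#' cycle adds nothing.
#'
#' @param pool design data frame with `design_id`, `sequence` and every
#'   column the scheme ranks or filters on.
#' @param scheme a [selection_scheme()].
#' @return data frame of picked designs, in pick order, with `picked_by_set`
#'   and (when the pool ran out) attribute `exhausted = TRUE`.
#' @export
cycled_pick <- function(pool, scheme = default_selection_scheme()) {
  if (nrow(pool) == 0L) stop("cycled_pick: empty pool")
  med_mmpbsa <- if (!is.null(pool$mmpbsa)) stats::median(pool$mmpbsa) else NA
  orders <- lapply(scheme$sets, function(s) {
    keep <- apply_filters(pool, s$filters, med_mmpbsa)
    ord <- rank_order(pool, s$keys)
    ord[keep[ord]]
  })
  picked <- integer(0)
  picked_by <- integer(0)
  seqs <- character(0)
  repeat {
    advanced <- FALSE
    for (si in seq_along(orders)) {
      if (length(picked) >= scheme$target_count) break
      for (i in orders[[si]]) {
        if (i %in% picked) next
        if (pool$sequence[i] %in% seqs) next   # skipped, not consumed
        picked <- c(picked, i)
        picked_by <- c(picked_by, scheme$sets[[si]]$set_id)
        seqs <- c(seqs, pool$sequence[i])
        advanced <- TRUE
        break
      }
    }
    if (length(picked) >= scheme$target_count || !advanced) break
  }
  out <- pool[picked, , drop = FALSE]
  out$picked_by_set <- picked_by
  rownames(out) <- NULL
  if (length(picked) < scheme$target_count) {
    warning("pool holds only ", length(picked),
            " non-redundant pickable sequences (target ",
            scheme$target_count, ")")
    attr(out, "exhausted") <- TRUE
  }
  out
}
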