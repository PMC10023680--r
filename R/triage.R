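## Steric triage of docked initial poses.
##
## A docked nanobody pose is kept when it (a) overlaps substantially with
## the competitor native binder it is meant to displace (clashscore >= 30),
## (b) leaves the flanking scaffold domain essentially untouched
## (clashscore < 10), and optionally (c) has all three CDR loops in contact
## with the antigen and (d) satisfies a two-anchor distance constraint that
## mirrors the docking-time restraint on CDR1/CDR2.

#' Docked pose container
#'
#' @param pose_id unique pose identifier.
#' @param atoms atom data frame of the nanobody placed in the antigen frame.
#' @param complementarity_score docking-engine score (optional).
#' @param engine_rank integer rank from the docking engine (optional).
#' @param source_chain provenance, e.g. `"5LMW_B"` (optional).
#' @return object of class `docked_pose`.
#' @export
docked_pose <- function(pose_id, atoms, complementarity_score = NA_real_,
                        engine_rank = NA_integer_,
                        source_chain = NA_character_) {
  validate_atoms(atoms)
  structure(list(pose_id = as.character(pose_id), atoms = atoms,
                 complementarity_score = complementarity_score,
                 engine_rank = engine_rank, source_chain = source_chain),
            class = "docked_pose")
}

#' Triage thresholds
#'
#' @param competitor_overlap_min minimum pose-vs-competitor clashscore
#'   (default 30, kept when `>=`).
#' @param scaffold_clash_max maximum pose-vs-scaffold clashscore (default
#'   10, kept when `<`).
#' @param contact_cutoff heavy-atom CDR-antigen contact distance (Angstrom,
#'   default 5).
#' @param anchor_residues residue numbers of the two docking anchors
#'   (default `c(38, 60)` on CDR1/CDR2).
#' @param anchor_distance_max maximum anchor-Calpha-to-epitope distance
#'   (Angstrom, default 12).
#' @return list of class `triage_thresholds`.
#' @export
triage_thresholds <- function(competitor_overlap_min = 30,
                              scaffold_clash_max = 10,
                              contact_cutoff = 5,
                              anchor_residues = c(38L, 60L),
                              anchor_distance_max = 12) {
  stopifnot(competitor_overlap_min > 0, scaffold_clash_max > 0,
            contact_cutoff > 0, anchor_distance_max > 0)
  structure(list(competitor_overlap_min = competitor_overlap_min,
                 scaffold_clash_max = scaffold_clash_max,
                 contact_cutoff = contact_cutoff,
                 anchor_residues = as.integer(anchor_residues),
                 anchor_distance_max = anchor_distance_max),
            class = "triage_thresholds")
}

pose_atoms <- function(pose) {
  if (inherits(pose, "docked_pose")) pose$atoms
  else if (inherits(pose, "chain_model")) pose$atoms
  else pose
}

#' Pose-vs-competitor overlap clashscore
#'
#' Clashscore of the pose against the competitor binder it should displace;
#' normalization is per 1000 pose atoms.
#'
#' @param pose a `docked_pose` (or atom data frame).
#' @param competitor_atoms competitor heavy atoms in the same frame.
#' @param overlap_threshold see [clash_metrics()].
#' @return clashscore (numeric).
#' @export
competitor_overlap_score <- function(pose, competitor_atoms,
                                     overlap_threshold = 0.4) {
  if (is.null(competitor_atoms) || nrow(competitor_atoms) == 0L)
    stop("competitor atom set is empty")
  clash_metrics(pose_atoms(pose), competitor_atoms,
                overlap_threshold)$clashscore
}

#' Pose-vs-scaffold steric clashscore
#'
#' @param pose a `docked_pose` (or atom data frame).
#' @param scaffold_atoms scaffold-region heavy atoms in the same frame.
#' @param overlap_threshold see [clash_metrics()].
#' @return clashscore (numeric).
#' @export
scaffold_clash_score <- function(pose, scaffold_atoms,
                                 overlap_threshold = 0.4) {
  if (is.null(scaffold_atoms) || nrow(scaffold_atoms) == 0L)
    stop("scaffold atom set is empty")
  clash_metrics(pose_atoms(pose), scaffold_atoms,
                overlap_threshold)$clashscore
}

#' CDR-loop contact check
#'
#' A CDR is in contact when any of its heavy atoms lies within `cutoff` of
#' any antigen heavy atom.
#'
#' @param pose a `docked_pose` (or atom data frame).
#' @param antigen_atoms antigen heavy atoms.
#' @param loopdef a [loop_definition()] giving CDR residue ranges.
#' @param cutoff contact distance (Angstrom, default 5).
#' @return list with logicals `cdr1`, `cdr2`, `cdr3`, `all_three`.
#' @export
cdr_contact_check <- function(pose, antigen_atoms, loopdef, cutoff = 5) {
  atoms <- drop_hydrogens(pose_atoms(pose))
  antigen <- drop_hydrogens(antigen_atoms)
  xb <- coords(antigen)
  one <- function(range) {
    sel <- resolve_selection(atoms, residues = list(range))
    if (nrow(sel) == 0L)
      stop("CDR range ", range[1L], "-", range[2L],
           " resolves to no residues on the pose")
    xa <- coords(sel)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
    any(d2 < cutoff^2)
  }
  res <- list(cdr1 = one(loopdef$cdr1), cdr2 = one(loopdef$cdr2),
              cdr3 = one(loopdef$cdr3))
  res$all_three <- res$cdr1 && res$cdr2 && res$cdr3
  res
}

#' Two-anchor distance constraint check
#'
#' Post-hoc surrogate for the docking-time two-point restraint: each anchor
#' residue's Calpha must lie within `dmax` of the nearest epitope heavy
#' atom.
#'
#' @param pose a `docked_pose` (or atom data frame).
#' @param epitope_atoms epitope heavy atoms.
#' @param anchors residue numbers of the anchors (default `c(38, 60)`).
#' @param dmax maximum allowed distance (Angstrom, default 12).
#' @return `TRUE`/`FALSE`.
#' @export
anchor_constraint_check <- function(pose, epitope_atoms,
                                    anchors = c(38L, 60L), dmax = 12) {
  atoms <- pose_atoms(pose)
  xb <- coords(drop_hydrogens(epitope_atoms))
  for (a in anchors) {
    ca <- atoms[atoms$res_seq == a & atoms$atom_name == "CA", , drop = FALSE]
    if (nrow(ca) == 0L)
      stop("anchor residue ", a, " (Calpha) absent from pose")
    d2 <- rowSums(sweep(xb, 2L, as.numeric(coords(ca)[1L, ]))^2)
    if (min(d2) > dmax^2) return(FALSE)
  }
  TRUE
}

#' Triage a set of docked poses
#'
#' Keeps poses with competitor overlap clashscore `>=`
#' `competitor_overlap_min`, scaffold clashscore `<` `scaffold_clash_max`,
#' and (when `loopdef` and `antigen_atoms` are given) all three CDRs in
#' antigen contact. When `epitope_atoms` is supplied the two-anchor
#' constraint is also required. The report covers every input pose.
#'
#' @param poses list of `docked_pose`.
#' @param competitor_atoms,scaffold_atoms heavy-atom sets in the pose frame.
#' @param thresholds a [triage_thresholds()] object.
#' @param loopdef optional [loop_definition()] enabling the CDR-contact
#'   test.
#' @param antigen_atoms antigen heavy atoms (needed with `loopdef`).
#' @param epitope_atoms optional epitope subset enabling the anchor test.
#' @return list with `retained` (list of retained poses) and `report`
#'   (data frame: `pose_id`, `overlap_score`, `scaffold_score`,
#'   `cdr1_contact`..`cdr3_contact`, `anchor_ok`, `retained`).
#' @export
triage_poses <- function(poses, competitor_atoms, scaffold_atoms,
                         thresholds = triage_thresholds(),
                         loopdef = NULL, antigen_atoms = NULL,
                         epitope_atoms = NULL) {
  if (!is.null(loopdef) && is.null(antigen_atoms))
    stop("CDR-contact triage needs antigen_atoms")
  rows <- lapply(poses, function(p) {
    ov <- competitor_overlap_score(p, competitor_atoms)
    sc <- scaffold_clash_score(p, scaffold_atoms)
    cdr <- if (!is.null(loopdef))
      cdr_contact_check(p, antigen_atoms, loopdef, thresholds$contact_cutoff)
    else list(cdr1 = NA, cdr2 = NA, cdr3 = NA, all_three = TRUE)
    anch <- if (!is.null(epitope_atoms))
      anchor_constraint_check(p, epitope_atoms, thresholds$anchor_residues,
                              thresholds$anchor_distance_max)
    else NA
    keep <- ov >= thresholds$competitor_overlap_min &&
      sc < thresholds$scaffold_clash_max &&
      isTRUE(cdr$all_three) &&
      (is.na(anch) || anch)
    data.frame(pose_id = p$pose_id, overlap_score = ov, scaffold_score = sc,
               cdr1_contact = cdr$cdr1, cdr2_contact = cdr$cdr2,
               cdr3_contact = cdr$cdr3, anchor_ok = anch, retained = keep,
               stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pose_id = character(0), overlap_score = numeric(0),
               scaffold_score = numeric(0), cdr1_contact = logical(0),
               cdr2_contact = logical(0), cdr3_contact = logical(0),
               anchor_ok = logical(0), retained = logical(0))
  list(retained = poses[report$retained], report = report)
}
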