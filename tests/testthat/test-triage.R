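test_that("competitor overlap and scaffold clashscores come from clash_metrics", {
  cm <- gen_clash_complex(200, 7, seed = 2)   # 1000 * 7 / 200 = 35
  lig <- model_atoms(cm, "ligand")
  comp <- model_atoms(cm, "competitor")
  pose <- docked_pose("p1", lig)
  expect_equal(competitor_overlap_score(pose, comp), 35)

  far <- comp; far$x <- far$x + 500
  expect_equal(competitor_overlap_score(pose, far), 0)
  expect_equal(scaffold_clash_score(pose, far), 0)
  expect_error(competitor_overlap_score(pose, comp[0, ]), "empty")
})

test_that("CDR contact check reflects constructed loop geometry", {
  ref <- gen_toy_structure()
  ld <- default_loop_definition()
  pose <- docked_pose("p1", ref$atoms)

  # epitope cloud hugging CDR1+CDR2 only: atoms 3 A from each loop residue
  loops12 <- resolve_selection(ref$atoms,
                               list(c(26L, 35L), c(50L, 59L)))
  epi12 <- loops12
  epi12$x <- epi12$x + 3
  epi12$chain_id <- "E"
  res12 <- cdr_contact_check(pose, epi12, ld, cutoff = 5)
  expect_true(res12$cdr1)
  expect_true(res12$cdr2)
  expect_false(res12$cdr3)
  expect_false(res12$all_three)

  # epitope hugging all three loops
  loops <- resolve_selection(ref$atoms,
                             list(c(26L, 35L), c(50L, 59L), c(97L, 111L)))
  epi <- loops; epi$x <- epi$x + 3; epi$chain_id <- "E"
  expect_true(cdr_contact_check(pose, epi, ld, cutoff = 5)$all_three)

  # pose displaced 100 A away contacts nothing
  off <- ref$atoms; off$x <- off$x + 100
  res_off <- cdr_contact_check(docked_pose("p2", off), epi, ld, 5)
  expect_false(res_off$cdr1 || res_off$cdr2 || res_off$cdr3)

  bad_ld <- loop_definition(c(900L, 910L), c(50L, 59L), c(97L, 111L))
  expect_error(cdr_contact_check(pose, epi, bad_ld, 5), "no residues")
})

test_that("anchor constraint agrees with brute-force nearest distances", {
  ref <- gen_toy_structure()
  epi <- carbon_atoms(matrix(rnorm(60, sd = 5), ncol = 3), chain = "E")
  set.seed(21)
  for (i in 1:20) {
    shift <- runif(3, -15, 15)
    pose_atoms <- ref$atoms
    pose_atoms$x <- pose_atoms$x + shift[1]
    pose_atoms$y <- pose_atoms$y + shift[2]
    pose_atoms$z <- pose_atoms$z + shift[3]
    got <- anchor_constraint_check(pose_atoms, epi, anchors = c(38L, 60L),
                                   dmax = 12)
    # brute force: per anchor, min distance over all epitope atoms
    ok <- TRUE
    for (a in c(38L, 60L)) {
      ca <- as.numeric(coords(pose_atoms[pose_atoms$res_seq == a &
                                           pose_atoms$atom_name == "CA", ]))
      dmin <- min(sqrt(rowSums(sweep(coords(epi), 2, ca)^2)))
      if (dmin > 12) ok <- FALSE
    }
    expect_identical(got, ok)
  }
  expect_error(anchor_constraint_check(ref$atoms[1:10, ], epi), "anchor")
})

test_that("pose triage equals brute-force predicate evaluation", {
  # 20 poses around a shared competitor/scaffold, scores straddling both
  # thresholds: pose i overlaps the competitor with i planted clashes out
  # of 100 atoms (clashscore 10 i) and the scaffold with (i %% 4) clashes
  poses <- list()
  reports <- list()
  comp_all <- NULL
  for (i in 1:20) {
    cm <- gen_clash_complex(100, i %% 8, seed = i)
    lig <- model_atoms(cm, "ligand")
    lig$x <- lig$x + 400 * i        # each pose in its own region
    cmp <- model_atoms(cm, "competitor")
    cmp$x <- cmp$x + 400 * i
    poses[[i]] <- docked_pose(sprintf("p%02d", i), lig)
    comp_all <- rbind(comp_all, cmp)
  }
  scaffold <- carbon_atoms(cbind(1:10 * 8, -500, 0), chain = "S")
  thr <- triage_thresholds(competitor_overlap_min = 30,
                           scaffold_clash_max = 10)
  res <- triage_poses(poses, comp_all, scaffold, thr)
  expect_equal(nrow(res$report), 20L)          # report is exhaustive
  for (i in 1:20) {
    ov <- clash_metrics(poses[[i]]$atoms, comp_all)$clashscore
    sc <- clash_metrics(poses[[i]]$atoms, scaffold)$clashscore
    expect_equal(res$report$overlap_score[i], ov)
    expect_identical(res$report$retained[i], ov >= 30 && sc < 10)
  }
  expect_equal(vapply(res$retained, `[[`, character(1), "pose_id"),
               res$report$pose_id[res$report$retained])
})

test_that("triage filters are monotone in their thresholds", {
  poses <- lapply(1:6, function(i) {
    cm <- gen_clash_complex(100, i, seed = i)
    lig <- model_atoms(cm, "ligand"); lig$x <- lig$x + 300 * i
    docked_pose(sprintf("p%d", i), lig)
  })
  comp <- do.call(rbind, lapply(1:6, function(i) {
    cmp <- model_atoms(gen_clash_complex(100, i, seed = i), "competitor")
    cmp$x <- cmp$x + 300 * i
    cmp
  }))
  scaffold <- carbon_atoms(cbind(0, -900, 0))
  kept_n <- function(min_ov) sum(triage_poses(
    poses, comp, scaffold,
    triage_thresholds(competitor_overlap_min = min_ov))$report$retained)
  expect_true(kept_n(10) >= kept_n(30))
  expect_true(kept_n(30) >= kept_n(60))
})
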