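test_that("read_pdb parses chains into groups and errors usefully", {
  atoms <- rbind(carbon_atoms(cbind(1:5, 0, 0), chain = "A"),
                 carbon_atoms(cbind(1:5, 10, 0), chain = "B"))
  atoms$group <- ifelse(atoms$chain_id == "A", "ligand", "receptor")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(complex_model(atoms), p)

  models <- read_pdb(p, c(A = "ligand", B = "receptor"))
  expect_length(models, 1L)
  expect_equal(nrow(models[[1]]$atoms), 10L)
  expect_equal(sum(models[[1]]$atoms$group == "ligand"), 5L)

  expect_error(read_pdb(p, c(A = "ligand", Z = "receptor")), "Z")

  bad <- readLines(p)
  substr(bad[3], 31, 38) <- "   xx.xx"
  pb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, pb)
  expect_error(read_pdb(pb, c(A = "ligand")), "line 3")
})

test_that("multi-model files give one complex model per MODEL", {
  ref <- gen_toy_structure()
  frames <- gen_toy_trajectory(ref, default_loop_definition(),
                               list(cdr3 = c(0, 1, 2)), seed = 1)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(frames, p)
  back <- read_pdb(p, c(A = "ligand"))
  expect_length(back, 3L)
  for (m in back) {
    expect_equal(m$atoms$res_seq, ref$atoms$res_seq)
    expect_equal(m$atoms$chain_id, ref$atoms$chain_id)
  }
  expect_equal(back[[2]]$model_no, 2L)
})

test_that("PDB round trip preserves identity and coordinates to 3 decimals", {
  ref <- gen_toy_structure()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ref, p)
  back <- read_pdb(p, c(A = "ligand"))[[1]]
  expect_equal(back$atoms$res_seq, ref$atoms$res_seq)
  expect_equal(back$atoms$chain_id, ref$atoms$chain_id)
  expect_equal(back$atoms$atom_name, ref$atoms$atom_name)
  expect_lt(max(abs(coords(back$atoms) - coords(ref$atoms))), 5e-4 + 1e-9)

  # independent reader agrees on the coordinates
  b3d <- suppressWarnings(bio3d::read.pdb(p))
  expect_equal(as.vector(t(coords(back$atoms))), as.vector(b3d$xyz),
               tolerance = 1e-6)
})

test_that("kabsch superposition recovers applied rigid transforms", {
  set.seed(11)
  ref <- matrix(rnorm(12), 4, 3)

  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-10)

  fit_t <- kabsch_superpose(sweep(ref, 2, c(-5, 0, 0)), ref)
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-10)

  th <- pi / 2
  rot90 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- ref %*% rot90
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation %*% rot90, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition rmsd is invariant to prior rigid motion of mobile", {
  set.seed(12)
  ref <- matrix(rnorm(30), 10, 3)
  mob <- ref + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- kabsch_superpose(mob, ref)$rmsd
  for (i in 1:5) {
    moved <- mob %*% random_rotation_matrix() +
      matrix(runif(3, -20, 20), 10, 3, byrow = TRUE)
    expect_equal(kabsch_superpose(moved, ref)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("degenerate superposition inputs error", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + 0.0, line), "collinear")
})

test_that("selection_rmsd matches hand arithmetic and honors the selection", {
  a <- carbon_atoms(cbind(c(0, 10), 0, 0))
  a$atom_name <- "CA"
  b <- a
  b$x <- b$x + c(3, 0)
  b$y <- b$y + c(0, 4)
  expect_equal(selection_rmsd(a, a), 0)
  expect_equal(selection_rmsd(a, b), sqrt((9 + 16) / 2), tolerance = 1e-12)

  # side-chain displacement invisible to a Calpha-only selection
  a2 <- rbind(a, transform(carbon_atoms(cbind(c(1, 11), 1, 0)),
                           atom_name = "CB", serial = 3:4))
  b2 <- a2
  b2$x[b2$atom_name == "CB"] <- b2$x[b2$atom_name == "CB"] + 50
  expect_equal(selection_rmsd(a2, b2, atom_names = "CA"), 0)
  expect_error(selection_rmsd(a, b, atom_names = "ZZ"), "0 atoms")
})

test_that("clash metrics count overlapping heavy-atom pairs", {
  far <- clash_metrics(carbon_atoms(c(0, 0, 0)), carbon_atoms(c(10, 0, 0)))
  expect_equal(far$clash_count, 0L)
  expect_equal(far$clashscore, 0)

  near <- clash_metrics(carbon_atoms(c(0, 0, 0)), carbon_atoms(c(2.9, 0, 0)))
  expect_equal(near$clash_count, 1L)  # overlap 0.5 >= 0.4 threshold

  cm <- gen_clash_complex(100, 3, seed = 5)
  res <- clash_metrics(model_atoms(cm, "ligand"),
                       model_atoms(cm, "competitor"))
  expect_equal(res$clash_count, 3L)
  expect_equal(res$clashscore, 30)

  expect_error(clash_metrics(carbon_atoms(c(0, 0, 0)),
                             atom_table(1, "X", "XX", "UNK", 1, "B",
                                        0, 0, 0)),
               "XX")
})

test_that("clash count equals O(n^2) brute force and is symmetric", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(50:250, 1)
    a <- carbon_atoms(matrix(runif(3 * n, 0, 25), ncol = 3))
    b <- carbon_atoms(matrix(runif(3 * n, 0, 25), ncol = 3), chain = "B")
    ab <- clash_metrics(a, b)
    expect_equal(ab$clash_count, brute_clash_count(a, b))
    expect_equal(clash_metrics(b, a)$clash_count, ab$clash_count)
  }
})

test_that("SASA matches closed-form sphere and two-sphere cap formulas", {
  lone <- sasa_atoms(carbon_atoms(c(0, 0, 0)))
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(lone - exact) / exact, 0.01)

  expect_lt(abs(buried_sasa(carbon_atoms(c(0, 0, 0)),
                            carbon_atoms(c(50, 0, 0)))), 1)

  # two identical spheres at center distance d each lose a cap of height
  # r - d/2: buried = 2 * 2*pi*r*(r - d/2)
  r <- 1.7 + 1.4
  for (d in c(1.0, 2.0, 3.0)) {
    bur <- buried_sasa(carbon_atoms(c(0, 0, 0)), carbon_atoms(c(d, 0, 0)))
    analytic <- 2 * 2 * pi * r * (r - d / 2)
    expect_lt(abs(bur - analytic) / analytic, 0.02)
  }
})

test_that("buried SASA is nonnegative and zero for distant groups", {
  set.seed(4)
  a <- carbon_atoms(matrix(runif(30, 0, 6), ncol = 3))
  b <- carbon_atoms(matrix(runif(30, 0, 6), ncol = 3) +
                      matrix(c(4, 0, 0), 10, 3, byrow = TRUE), chain = "B")
  expect_gte(buried_sasa(a, b), -1e-6)
  b_far <- b; b_far$x <- b_far$x + 100
  expect_equal(buried_sasa(a, b_far), 0, tolerance = 1e-9)
})

test_that("chain molecular weight uses average residue masses plus water", {
  expect_equal(chain_molecular_weight("GG"), 132.12, tolerance = 0.01)
  expect_equal(chain_molecular_weight("A"), 89.09, tolerance = 0.01)
  expect_lt(chain_molecular_weight(NB_TEMPLATE), 20000)
  expect_error(chain_molecular_weight(""), "nonempty")
  expect_error(chain_molecular_weight("AXZ"), "non-standard")
})
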