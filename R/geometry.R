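## Geometry primitives: Kabsch superposition, RMSD, heavy-atom clash
## counting, Shrake-Rupley solvent-accessible surface area, and protein
## molecular weight. All distances in Angstrom, areas in Angstrom^2,
## masses in Dalton.

#' Heavy-atom van der Waals radii (Angstrom)
#'
#' Element radii used by [clash_metrics()] and [buried_sasa()]:
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80. Hydrogens are not tabulated; both
#' consumers operate on heavy atoms only and drop H records.
#' @export
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

## average residue masses (Da); one water (18.0153 Da) is added per chain
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- coords(x)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected an n x 3 coordinate matrix")
  storage.mode(x) <- "double"
  x
}

atom_radii <- function(atoms, radii = VDW_RADII) {
  el <- atoms$element
  r <- radii[el]
  if (anyNA(r)) {
    unknown <- sort(unique(el[is.na(r)]))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  unname(r)
}

drop_hydrogens <- function(atoms) {
  atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a reference point set (paired by row order).
#'
#' @param mobile,reference n x 3 coordinate matrices (or atom data frames),
#'   n >= 3; the reference must not be collinear.
#' @return list of class `superposition` with `rotation` (3 x 3, det = +1),
#'   `translation` (length 3) and `rmsd` (Angstrom). The transform maps a
#'   row-vector coordinate matrix `X` to `X %*% rotation + translation`.
#' @seealso [apply_superposition()]
#' @export
kabsch_superpose <- function(mobile, reference) {
  m <- as_coord_matrix(mobile)
  r <- as_coord_matrix(reference)
  if (nrow(m) != nrow(r)) stop("point counts differ")
  if (nrow(m) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2L, cm); rc <- sweep(r, 2L, cr)
  sv_ref <- svd(rc)$d
  if (sv_ref[2L] < 1e-8 * max(sv_ref[1L], 1e-12))
    stop("reference points are (near-)collinear; superposition is degenerate")
  h <- crossprod(mc, rc)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- as.numeric(cr - cm %*% rot)
  fitted <- mc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param x n x 3 matrix or atom data frame.
#' @param fit a `superposition` from [kabsch_superpose()].
#' @return object of the same kind as `x` with transformed coordinates.
#' @export
apply_superposition <- function(x, fit) {
  xyz <- as_coord_matrix(x)
  new <- xyz %*% fit$rotation +
    matrix(fit$translation, nrow(xyz), 3L, byrow = TRUE)
  if (is.data.frame(x)) {
    x$x <- new[, 1L]; x$y <- new[, 2L]; x$z <- new[, 3L]
    x
  } else new
}

#' Plain (unsuperposed) RMSD over a selection
#'
#' Resolves the same selection on both structures and computes the
#' root-mean-square deviation of the paired atoms without refitting.
#'
#' @param atomsA,atomsB atom data frames with matching topology.
#' @param residues,atom_names,chains selection, see [resolve_selection()].
#' @return RMSD in Angstrom.
#' @export
selection_rmsd <- function(atomsA, atomsB, residues = NULL,
                           atom_names = "CA", chains = NULL) {
  a <- resolve_selection(atomsA, residues, atom_names, chains)
  b <- resolve_selection(atomsB, residues, atom_names, chains)
  if (nrow(a) == 0L) stop("selection resolves to 0 atoms")
  if (nrow(a) != nrow(b))
    stop("selection lengths differ: ", nrow(a), " vs ", nrow(b))
  sqrt(mean(rowSums((coords(a) - coords(b))^2)))
}

#' Inter-set steric clash count and clashscore
#'
#' A clash is an inter-set heavy-atom pair closer than
#' `r_vdw(i) + r_vdw(j) - overlap_threshold`. The clashscore normalizes the
#' count per 1000 atoms of the *first* argument (the pose being scored), a
#' heavy-atom variant of the MolProbity/PHENIX steric metric.
#'
#' @param atomsA atom data frame of the scored pose.
#' @param atomsB atom data frame of the partner set.
#' @param overlap_threshold clash overlap in Angstrom (default 0.4).
#' @param radii named element-radius table, default [VDW_RADII].
#' @return list with `clash_count` and `clashscore`
#'   (`1000 * clash_count / nrow(atomsA)`).
#' @export
clash_metrics <- function(atomsA, atomsB, overlap_threshold = 0.4,
                          radii = VDW_RADII) {
  atomsA <- drop_hydrogens(atomsA)
  atomsB <- drop_hydrogens(atomsB)
  if (nrow(atomsA) == 0L || nrow(atomsB) == 0L)
    stop("clash_metrics needs two nonempty heavy-atom sets")
  ra <- atom_radii(atomsA, radii)
  rb <- atom_radii(atomsB, radii)
  xa <- coords(atomsA); xb <- coords(atomsB)
  ## pairwise distances via |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  cut <- outer(ra, rb, `+`) - overlap_threshold
  count <- sum(sqrt(d2) < cut)
  list(clash_count = as.integer(count),
       clashscore = 1000 * count / nrow(atomsA))
}

## deterministic near-uniform sphere quadrature (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- (i - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral quadrature with `n_points` test points per
#' atom and a water-sized probe. Hydrogens are ignored.
#'
#' @param atoms atom data frame.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @param radii element radius table.
#' @return numeric vector of per-atom SASA (Angstrom^2).
#' @export
sasa_atoms <- function(atoms, probe = 1.4, n_points = 960L,
                       radii = VDW_RADII) {
  atoms <- drop_hydrogens(atoms)
  if (nrow(atoms) == 0L) return(numeric(0))
  r <- atom_radii(atoms, radii) + probe
  xyz <- coords(atoms)
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  ## neighbor pairs: centers closer than the sum of solvent-extended radii
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  vapply(seq_len(n), function(i) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    area_i <- 4 * pi * r[i]^2
    if (!length(nb)) return(area_i)
    p <- pts * r[i] + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      buried <- buried | dj2 < r[j]^2
      if (all(buried)) break
    }
    area_i * sum(!buried) / n_points
  }, numeric(1))
}

#' Buried solvent-accessible surface area of an interface
#'
#' `SASA(A) + SASA(B) - SASA(A union B)`; nonnegative up to quadrature
#' noise. Either pass two atom tables or a `complex_model` plus two group
#' names.
#'
#' @param a atom data frame of the first group, or a `complex_model`.
#' @param b atom data frame of the second group, or (when `a` is a complex
#'   model) a character vector of two group names, default
#'   `c("ligand", "receptor")`.
#' @inheritParams sasa_atoms
#' @return buried SASA in Angstrom^2.
#' @export
buried_sasa <- function(a, b = c("ligand", "receptor"), probe = 1.4,
                        n_points = 960L, radii = VDW_RADII) {
  if (inherits(a, "complex_model")) {
    atomsA <- model_atoms(a, b[[1L]])
    atomsB <- model_atoms(a, b[[2L]])
  } else {
    atomsA <- a; atomsB <- b
  }
  if (nrow(atomsA) == 0L || nrow(atomsB) == 0L)
    stop("buried_sasa needs two nonempty groups")
  sA <- sum(sasa_atoms(atomsA, probe, n_points, radii))
  sB <- sum(sasa_atoms(atomsB, probe, n_points, radii))
  sAB <- sum(sasa_atoms(rbind(atomsA[ATOM_COLS], atomsB[ATOM_COLS]),
                        probe, n_points, radii))
  sA + sB - sAB
}

#' Average molecular weight of a protein chain
#'
#' Sum of average residue masses plus one water (18.02 Da).
#'
#' @param sequence one-letter amino-acid string (standard 20 residues).
#' @return mass in Dalton.
#' @export
chain_molecular_weight <- function(sequence) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a nonempty string")
  aa <- strsplit(toupper(sequence), "")[[1L]]
  m <- RESIDUE_MASS[aa]
  if (anyNA(m))
    stop("non-standard residue letter(s): ",
         paste(sort(unique(aa[is.na(m)])), collapse = ", "))
  sum(m) + WATER_MASS
}
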