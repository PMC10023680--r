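## Seed-deterministic synthetic generators.
##
## These stand in for the upstream engines (docking, design, MD) so every
## decision stage is testable offline: decoy landscapes with funnel or
## flat structure, atom clouds with a planted clash count, pools of
## point-mutated variants with correlated scores and a planted cluster
## structure, and toy Calpha trajectories with scheduled loop
## displacements. Same spec + seed gives identical output; each generator
## seeds its own RNG state locally.

#' Toy nanobody-like template sequence (126 residues)
#'
#' A VHH-like single-domain sequence used as the default template of the
#' synthetic generators; its mass is under the 20 kDa curation bound.
#' @export
NB_TEMPLATE <- paste0(
  "QVQLVESGGGLVQAGGSLRLSCAASGRTFSSYAMGWFRQAPGKEREFVAAISWSGGSTYY",
  "ADSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYCAADRGSYYVDYWGQGTQVTVSS",
  "GGSSHHHH")

#' Default loop definition for the toy template
#'
#' CDR ranges on [NB_TEMPLATE] numbering (1-based, inclusive): CDR1 26-35,
#' CDR2 50-59, CDR3 97-111; framework = the remainder.
#' @return a [loop_definition()].
#' @export
default_loop_definition <- function() {
  loop_definition(cdr1 = c(26L, 35L), cdr2 = c(50L, 59L),
                  cdr3 = c(97L, 111L),
                  framework = list(c(1L, 25L), c(36L, 49L),
                                   c(60L, 96L), c(112L, 126L)))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

mutate_sequence <- function(template, positions, n_mut) {
  s <- strsplit(template, "")[[1L]]
  pos <- sample(positions, n_mut)
  for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1L)
  paste(s, collapse = "")
}

#' Generate a synthetic design-decoy ensemble
#'
#' `funnel` ensembles draw RMSD from |Normal(0, sigma_r)| truncated to
#' `[0, r_max]` and set `ddg = b - A * exp(-(rmsd / w)^2) + Normal(0, tau)`
#' -- energy falls into a well of depth `A` and width `w` near the initial
#' pose. `flat` ensembles draw RMSD uniformly on `[0, r_max]` and ddg from
#' `Normal(b, tau)` independently of RMSD. Buried SASA, an mmpbsa score
#' correlated with ddg, random mutant sequences of [NB_TEMPLATE], and the
#' ensemble's own [funnel_score()] (constant per pose) are attached so the
#' output feeds the downstream selection stages directly.
#'
#' @param kind `"funnel"` or `"flat"`.
#' @param n decoy count.
#' @param pose_id pose identifier.
#' @param seed RNG seed (required; the generator is deterministic in it).
#' @param sigma_r,r_max,A,w,tau,b generator parameters (defaults 2, 8, 10,
#'   1.5, 1, 0).
#' @param template template sequence for the decoy sequences.
#' @return a [landscape_ensemble()].
#' @export
gen_decoy_ensemble <- function(kind = c("funnel", "flat"), n, pose_id,
                               seed, sigma_r = 2, r_max = 8, A = 10,
                               w = 1.5, tau = 1, b = 0,
                               template = NB_TEMPLATE) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L, sigma_r > 0, r_max > 0, w > 0, tau >= 0)
  with_seed(seed, {
    if (kind == "funnel") {
      rmsd <- abs(stats::rnorm(n, 0, sigma_r))
      while (any(bad <- rmsd > r_max))
        rmsd[bad] <- abs(stats::rnorm(sum(bad), 0, sigma_r))
      ddg <- b - A * exp(-(rmsd / w)^2) + stats::rnorm(n, 0, tau)
    } else {
      rmsd <- stats::runif(n, 0, r_max)
      ddg <- stats::rnorm(n, b, tau)
    }
    sasa <- stats::rnorm(n, 1000, 80)
    mmpbsa <- 2 * ddg - 30 + stats::rnorm(n, 0, 3)
    seqs <- vapply(seq_len(n), function(i)
      mutate_sequence(template, 26:59, sample(2:3, 1L)), character(1))
    decoys <- data.frame(
      design_id = sprintf("%s_d%04d", pose_id, seq_len(n)),
      sequence = seqs, rmsd = rmsd, ddg = ddg, sasa = sasa,
      mmpbsa = mmpbsa, total_score = ddg - 100,
      stringsAsFactors = FALSE)
    ens <- landscape_ensemble(pose_id, decoys)
    if (n >= 5L) ens$decoys$funnel_score <- funnel_score(ens)
    ens
  })
}

#' Generate an atom-cloud complex with a planted clash count
#'
#' Carbon ligand atoms on an 8 Angstrom lattice (no internal contacts);
#' `planted_clashes` competitor atoms are placed 2.9 Angstrom from
#' distinct ligand atoms (a 0.5 Angstrom van der Waals overlap, one clash
#' each); the remaining competitor atoms sit at least 8 Angstrom from
#' every ligand atom. With `n_atoms = 100` and 3 planted clashes the
#' ligand clashscore is exactly 30.
#'
#' @param n_atoms atoms per group.
#' @param planted_clashes clash pairs to plant (`<= n_atoms`).
#' @param seed RNG seed (sub-Angstrom jitter of the safe positions).
#' @return a [complex_model()] with groups `ligand` and `competitor`.
#' @export
gen_clash_complex <- function(n_atoms = 100L, planted_clashes = 0L, seed = 1L) {
  if (planted_clashes > n_atoms)
    stop("cannot plant more clashes than atoms")
  side <- ceiling(n_atoms^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n_atoms), ,
                                                    drop = FALSE] * 8
  with_seed(seed, {
    comp <- matrix(0, n_atoms, 3L)
    k <- planted_clashes
    if (k > 0L)
      comp[seq_len(k), ] <- grid[seq_len(k), , drop = FALSE] +
        matrix(c(0, 0, 2.9), k, 3L, byrow = TRUE)
    if (k < n_atoms) {
      m <- n_atoms - k
      far <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                   z = seq_len(side)))[seq_len(m), ,
                                                       drop = FALSE] * 8
      far[, 1L] <- far[, 1L] + (side + 8) * 8   # shifted block, >= 8 A away
      comp[k + seq_len(m), ] <- far +
        matrix(stats::runif(3L * m, -0.05, 0.05), m, 3L)
    }
    lig <- atom_table(seq_len(n_atoms), "C", "C", "LIG",
                      seq_len(n_atoms), "A",
                      grid[, 1L], grid[, 2L], grid[, 3L])
    cmp <- atom_table(n_atoms + seq_len(n_atoms), "C", "C", "CMP",
                      seq_len(n_atoms), "B",
                      comp[, 1L], comp[, 2L], comp[, 3L])
    lig$group <- "ligand"
    cmp$group <- "competitor"
    complex_model(rbind(lig, cmp))
  })
}

#' Generate a pool of point-mutated variant records
#'
#' Unique variants are organized into `n_clusters` sequence clusters along
#' a mutation-load ladder: cluster `k` carries the first `3k` of a fixed
#' set of motif substitutions (so clusters differ in how far they have
#' drifted from the parent), plus one random extra mutation per variant.
#' The two lowest-load clusters - the ones nearest the parent - receive
#' markedly better (lower) mmpbsa and delta-FlexddG scores, emulating a
#' maturation pool whose score-selected designs concentrate in two
#' clusters while the rest supply diversification picks. mmpbsa and
#' delta-FlexddG are drawn with a planted correlation of 0.6. Duplicates
#' are injected by resampling unique sequences until `n` records exist.
#'
#' @param template template sequence.
#' @param mutable_positions 1-based designable positions (needs at least
#'   `3 * n_clusters + 1`).
#' @param n total record count.
#' @param duplicates_fraction fraction of records that are duplicates of
#'   an earlier sequence (ignored when `n_unique` is given).
#' @param seed RNG seed.
#' @param n_unique exact number of unique sequences (overrides
#'   `duplicates_fraction`).
#' @param n_clusters planted sequence clusters (default 5).
#' @param n_variations design-variation ids cycled over records (default
#'   16).
#' @param reference_flexddg FlexddG of the reference design (default 0).
#' @return data frame of variant records: `variant_id`, `sequence`,
#'   `variation_id`, `ddg`, `mmpbsa`, `flexddg`, `delta_flexddg`,
#'   `true_cluster` (generator label, for validation only).
#' @export
gen_variant_pool <- function(template = NB_TEMPLATE,
                             mutable_positions = c(26:35, 50:59, 97:111),
                             n = 1600L, duplicates_fraction = 0,
                             seed = 1L, n_unique = NULL, n_clusters = 6L,
                             n_variations = 16L, reference_flexddg = 0) {
  if (length(mutable_positions) == 0L)
    stop("gen_variant_pool needs mutable positions")
  if (length(mutable_positions) < 3L * n_clusters + 1L)
    stop("need at least ", 3L * n_clusters + 1L, " mutable positions for ",
         n_clusters, " clusters")
  if (is.null(n_unique))
    n_unique <- max(1L, n - as.integer(round(duplicates_fraction * n)))
  if (n_unique > n) stop("n_unique exceeds n")
  if (n_unique < 5L * n_clusters) n_clusters <- max(1L, n_unique %/% 5L)

  motif_pos <- utils::tail(mutable_positions, 3L * n_clusters)
  free_pos <- setdiff(mutable_positions, motif_pos)
  ## cluster sizes: first two take ~28% each, remainder split evenly
  if (n_clusters >= 3L) {
    s12 <- pmax(1L, as.integer(round(0.28 * n_unique)))
    rest <- n_unique - 2L * s12
    sizes <- c(s12, s12, rep(rest %/% (n_clusters - 2L), n_clusters - 2L))
    sizes[n_clusters] <- sizes[n_clusters] + rest %% (n_clusters - 2L)
  } else {
    sizes <- rep(n_unique %/% n_clusters, n_clusters)
    sizes[1L] <- sizes[1L] + n_unique %% n_clusters
  }

  with_seed(seed, {
    tmpl <- strsplit(template, "")[[1L]]
    ## one fixed substitution per motif position; cluster k applies the
    ## first 2k of them (mutation-load ladder)
    motif_sub <- vapply(motif_pos, function(p)
      sample(setdiff(AA20, tmpl[p]), 1L), character(1))
    uniq <- character(0)
    clus <- integer(0)
    for (cl in seq_len(n_clusters)) {
      base <- tmpl
      load <- seq_len(3L * cl)
      base[motif_pos[load]] <- motif_sub[load]
      made <- 0L
      attempts <- 0L
      while (made < sizes[cl]) {
        s <- base
        ## single extra mutation; double once singles grow scarce
        n_extra <- if (attempts > 20L * length(free_pos)) 2L else 1L
        for (p in sample(free_pos, n_extra))
          s[p] <- sample(setdiff(AA20, s[p]), 1L)
        sq <- paste(s, collapse = "")
        attempts <- attempts + 1L
        if (!(sq %in% uniq)) {
          uniq <- c(uniq, sq)
          clus <- c(clus, cl)
          made <- made + 1L
        }
      }
    }
    idx <- c(seq_len(n_unique),
             if (n > n_unique) sample(n_unique, n - n_unique,
                                      replace = TRUE))
    idx <- sample(idx)                       # shuffle record order
    good <- clus[idx] <= 2L
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    rho <- 0.6
    mmpbsa <- ifelse(good, -45, -25) + ifelse(good, 2, 3) * z1
    delta <- ifelse(good, -3, 1) +
      0.8 * (rho * z1 + sqrt(1 - rho^2) * z2)
    ddg <- ifelse(good, -7, -5) + stats::rnorm(n)
    data.frame(
      variant_id = sprintf("v%05d", seq_len(n)),
      sequence = uniq[idx],
      variation_id = (seq_len(n) - 1L) %% n_variations + 1L,
      ddg = ddg, mmpbsa = mmpbsa,
      flexddg = reference_flexddg + delta,
      delta_flexddg = delta,
      true_cluster = clus[idx],
      stringsAsFactors = FALSE)
  })
}

#' Build a toy Calpha-only nanobody structure
#'
#' Residues of [NB_TEMPLATE] (or any sequence) laid out on a helix-like
#' curve: a simple non-degenerate reference geometry for superposition and
#' trajectory fixtures.
#'
#' @param sequence one-letter sequence (default [NB_TEMPLATE]).
#' @param chain_id chain id.
#' @param group group label for the resulting complex model.
#' @return a [complex_model()] with one Calpha atom per residue.
#' @export
gen_toy_structure <- function(sequence = NB_TEMPLATE, chain_id = "A",
                              group = "ligand") {
  n <- nchar(sequence)
  i <- seq_len(n)
  aa3 <- AA_123[strsplit(sequence, "")[[1L]]]
  aa3[is.na(aa3)] <- "UNK"
  atoms <- atom_table(i, "CA", "C", aa3, i, chain_id,
                      2.3 * cos(i * 100 * pi / 180),
                      2.3 * sin(i * 100 * pi / 180),
                      1.5 * i)
  atoms$group <- group
  complex_model(atoms)
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3L, 3L)
}

#' Generate a toy trajectory with scheduled loop displacements
#'
#' Framework atoms stay fixed (up to an optional per-frame global rigid
#' motion, which superposition must cancel); each CDR loop is translated
#' along a fixed random direction by the scheduled per-frame magnitude,
#' plus optional isotropic noise on loop atoms.
#'
#' @param reference a `complex_model` (e.g. [gen_toy_structure()]).
#' @param loopdef a [loop_definition()].
#' @param displacement_schedule named list (`cdr1`, `cdr2`, `cdr3`;
#'   missing loops default to 0) of per-frame displacement magnitudes in
#'   Angstrom; all given vectors must share one length (= frame count).
#' @param noise_sd isotropic per-coordinate noise on loop atoms (default
#'   0).
#' @param rigid_motion apply a random global rotation + translation to
#'   every frame (default `FALSE`).
#' @param seed RNG seed.
#' @return list of `complex_model` frames.
#' @export
gen_toy_trajectory <- function(reference, loopdef, displacement_schedule,
                               noise_sd = 0, rigid_motion = FALSE,
                               seed = 1L) {
  lens <- unique(vapply(displacement_schedule, length, integer(1)))
  if (length(lens) != 1L)
    stop("displacement schedule vectors differ in length")
  n_frames <- lens
  sched <- lapply(c("cdr1", "cdr2", "cdr3"), function(lp)
    if (is.null(displacement_schedule[[lp]])) rep(0, n_frames)
    else displacement_schedule[[lp]])
  names(sched) <- c("cdr1", "cdr2", "cdr3")
  ref_atoms <- reference$atoms
  with_seed(seed, {
    dirs <- lapply(1:3, function(i) {
      v <- stats::rnorm(3L)
      v / sqrt(sum(v^2))
    })
    lapply(seq_len(n_frames), function(f) {
      at <- ref_atoms
      for (li in 1:3) {
        lp <- c("cdr1", "cdr2", "cdr3")[li]
        rows <- at$res_seq >= loopdef[[lp]][1L] &
          at$res_seq <= loopdef[[lp]][2L]
        shift <- dirs[[li]] * sched[[lp]][f]
        at$x[rows] <- at$x[rows] + shift[1L]
        at$y[rows] <- at$y[rows] + shift[2L]
        at$z[rows] <- at$z[rows] + shift[3L]
        if (noise_sd > 0) {
          m <- sum(rows)
          at$x[rows] <- at$x[rows] + stats::rnorm(m, 0, noise_sd)
          at$y[rows] <- at$y[rows] + stats::rnorm(m, 0, noise_sd)
          at$z[rows] <- at$z[rows] + stats::rnorm(m, 0, noise_sd)
        }
      }
      if (rigid_motion) {
        rot <- random_rotation()
        trans <- stats::runif(3L, -10, 10)
        xyz <- coords(at) %*% rot +
          matrix(trans, nrow(at), 3L, byrow = TRUE)
        at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
      }
      complex_model(at, f)
    })
  })
}
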