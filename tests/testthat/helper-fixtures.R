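# shared in-code fixtures and independent oracles

# atom table of carbons at given coordinates
carbon_atoms <- function(xyz, chain = "A", res_name = "LIG") {
  xyz <- matrix(xyz, ncol = 3L)
  atom_table(seq_len(nrow(xyz)), "C", "C", res_name,
             seq_len(nrow(xyz)), chain,
             xyz[, 1L], xyz[, 2L], xyz[, 3L])
}

# O(n^2) brute-force clash counter, independent of clash_metrics internals
brute_clash_count <- function(atomsA, atomsB, overlap = 0.4,
                              radii = VDW_RADII) {
  xa <- coords(atomsA); xb <- coords(atomsB)
  ra <- radii[atomsA$element]; rb <- radii[atomsB$element]
  count <- 0L
  for (i in seq_len(nrow(xa)))
    for (j in seq_len(nrow(xb))) {
      d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
      if (d < ra[i] + rb[j] - overlap) count <- count + 1L
    }
  count
}

# small ensemble straight from numbers
make_ensemble <- function(pose_id, rmsd, ddg, sasa = NULL, seqs = NULL) {
  n <- length(rmsd)
  d <- data.frame(design_id = sprintf("%s_d%02d", pose_id, seq_len(n)),
                  sequence = seqs %||% replicate(n, paste(
                    sample(LETTERS[1:20], 8, replace = TRUE), collapse = "")),
                  rmsd = rmsd, ddg = ddg,
                  stringsAsFactors = FALSE)
  if (!is.null(sasa)) d$sasa <- sasa
  landscape_ensemble(pose_id, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random proper rotation matrix
random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}
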