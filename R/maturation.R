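## Affinity maturation: design-parameter grid expansion, per-variation
## lowest-k retention, sequence deduplication, reference-relative FlexddG,
## residue-descriptor featurization, 2-component PCA, density clustering of
## sequence space, and the final dual-score + diversification selection.

#' Four-axis binary design-parameter grid
#'
#' The default axes mirror a maturation campaign around a first-round hit:
#' whether two interface hot-spot residues are forced into the design
#' (`force_L29_K59`), which CDRs are designable (`cdr_scope`), which
#' structure seeds the run (`start_structure`), and the radius of the
#' designable shell around the interface (`design_shell`, Angstrom).
#'
#' @param axes named list of length-2 vectors (axis levels, first level
#'   ordered first).
#' @return list of class `design_parameter_grid`.
#' @export
design_parameter_grid <- function(axes = list(
    force_L29_K59 = c("off", "on"),
    cdr_scope = c("all_CDRs", "H1_H2_only"),
    start_structure = c("parent_5LMW", "Nb01"),
    design_shell = c(10, 12))) {
  structure(list(axes = axes), class = "design_parameter_grid")
}

#' Expand a parameter grid into variation configs
#'
#' Cartesian product of the axes in deterministic order: the first declared
#' axis is the most significant (its first level covers the first half of
#' the variations).
#'
#' @param grid a [design_parameter_grid()].
#' @return data frame with `variation_id` (1-based) and one column per
#'   axis; `2^k` rows for `k` binary axes (one empty config for zero axes).
#' @export
expand_design_grid <- function(grid = design_parameter_grid()) {
  axes <- grid$axes
  if (length(axes) == 0L)
    return(data.frame(variation_id = 1L))
  ## first axis most significant -> reverse for expand.grid (first varies
  ## fastest there), then restore column order
  g <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(axes)), drop = FALSE]
  ord <- do.call(order, lapply(seq_along(axes), function(j)
    match(g[[j]], axes[[j]])))
  g <- g[ord, , drop = FALSE]
  rownames(g) <- NULL
  cbind(data.frame(variation_id = seq_len(nrow(g))), g)
}

#' Lowest-k variants per design variation
#'
#' For each `variation_id`, keeps the `k` lowest-ddg variants (ties: lower
#' `flexddg` if present, then `sequence`). Variations with fewer than `k`
#' variants contribute all of them, with a warning.
#'
#' @param variants data frame with `variation_id`, `sequence`, `ddg` and
#'   score columns.
#' @param k variants retained per variation (default 100).
#' @return pooled data frame.
#' @export
retain_lowest_k <- function(variants, k = 100L) {
  stopifnot(k >= 1L)
  short <- character(0)
  parts <- lapply(split(variants, variants$variation_id), function(d) {
    if (nrow(d) < k) short <<- c(short, as.character(d$variation_id[1L]))
    ord <- order(d$ddg, d$sequence)
    d[ord[seq_len(min(k, nrow(d)))], , drop = FALSE]
  })
  if (length(short))
    warning("variation(s) with fewer than k variants contribute all: ",
            paste(short, collapse = ", "))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Deduplicate a variant pool on exact sequence
#'
#' One representative per unique sequence: the record with the lowest
#' `ddg` (ties: first occurrence). Adds `n_duplicates` (copies seen).
#'
#' @param pool variant data frame with `sequence` and `ddg`.
#' @return non-redundant data frame, ordered by first appearance of each
#'   sequence.
#' @export
dedupe_variants <- function(pool) {
  if (nrow(pool) == 0L) return(pool)
  first_at <- match(unique(pool$sequence), pool$sequence)
  reps <- lapply(seq_along(first_at), function(i) {
    rows <- pool[pool$sequence == pool$sequence[first_at[i]], , drop = FALSE]
    r <- rows[which.min(rows$ddg), , drop = FALSE]
    r$n_duplicates <- nrow(rows)
    r
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

#' FlexddG relative to a reference design
#'
#' `variant - reference`: a negative value predicts improved binding over
#' the reference. The subtraction order is config-exposed because sign
#' conventions differ between engines.
#'
#' @param variant_flexddg numeric vector of variant FlexddG scores.
#' @param reference_flexddg FlexddG of the reference design (scalar).
#' @param sign `"variant_minus_reference"` (default) or
#'   `"reference_minus_variant"`.
#' @return numeric vector of differences.
#' @export
delta_flexddg <- function(variant_flexddg, reference_flexddg,
                          sign = c("variant_minus_reference",
                                   "reference_minus_variant")) {
  sign <- match.arg(sign)
  if (length(reference_flexddg) != 1L || !is.finite(reference_flexddg))
    stop("reference_flexddg must be a single finite value")
  if (any(!is.finite(variant_flexddg)))
    stop("variant FlexddG values must be finite")
  if (sign == "variant_minus_reference")
    variant_flexddg - reference_flexddg
  else reference_flexddg - variant_flexddg
}

#' Load the bundled per-residue descriptor table
#'
#' A 20 x 66 table: 66 descriptors per amino acid. Ten columns are standard
#' physicochemical scales (Kyte-Doolittle hydropathy, average residue mass,
#' Zamyatnin volume, net charge at pH 7, polarity/aromatic/aliphatic/tiny
#' indicators, H-bond donor and acceptor counts); the remaining 56 are
#' fixed, standardized synthetic axes that complete the 66-dimension
#' interface (see the package vignette). Any real 20 x 66 table (rownames =
#' one-letter residues) can be supplied to [featurize_sequences()] instead.
#'
#' @return numeric matrix, rownames the 20 residue letters, 66 columns.
#' @export
default_descriptor_table <- function() {
  path <- system.file("extdata", "aa_descriptors_synthetic.tsv",
                      package = "funneldock", mustWork = TRUE)
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Featurize equal-length sequences with per-residue descriptors
#'
#' Each sequence becomes the position-major concatenation of its residues'
#' descriptor vectors: row length `66 * L` for length-`L` sequences with
#' the default table.
#'
#' @param sequences character vector of equal-length sequences (or a
#'   variant data frame with a `sequence` column).
#' @param descriptor_table numeric matrix, one row per residue letter;
#'   default [default_descriptor_table()].
#' @return numeric matrix `length(sequences) x (ncol(table) * L)` with
#'   column names `pos<i>_<descriptor>`.
#' @export
featurize_sequences <- function(sequences,
                                descriptor_table = default_descriptor_table()) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  n <- length(sequences)
  if (n == 0L) stop("no sequences to featurize")
  L <- nchar(sequences[1L])
  if (any(nchar(sequences) != L))
    stop("sequences differ in length (expected ", L, ")")
  chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  unknown <- setdiff(unique(as.vector(chars)), rownames(descriptor_table))
  if (length(unknown))
    stop("residue letter(s) missing from the descriptor table: ",
         paste(unknown, collapse = ", "))
  nd <- ncol(descriptor_table)
  out <- matrix(0, n, nd * L)
  for (pos in seq_len(L))
    out[, (pos - 1L) * nd + seq_len(nd)] <-
      descriptor_table[chars[, pos], , drop = FALSE]
  colnames(out) <- as.vector(vapply(seq_len(L), function(pos)
    paste0("pos", pos, "_", colnames(descriptor_table)), character(nd)))
  out
}

#' Project a descriptor matrix onto its first principal components
#'
#' Columns are centered (not scaled) and projected onto the top right
#' singular directions. Component signs are fixed so that each component's
#' largest-magnitude loading is positive, making the projection
#' deterministic.
#'
#' @param mat numeric matrix (rows = variants), at least 2 rows.
#' @param n_components number of components (default 2).
#' @return list with `coords` (rows x components), `loadings`,
#'   `var_explained` (fraction per component).
#' @export
project_pca <- function(mat, n_components = 2L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("PCA needs at least 2 rows")
  if (any(!is.finite(mat))) stop("descriptor matrix has non-finite values")
  centered <- scale(mat, center = TRUE, scale = FALSE)
  s <- svd(centered)
  if (s$d[1L] < 1e-12) stop("descriptor matrix has zero variance")
  k <- min(n_components, length(s$d))
  load <- s$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- load[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2L, flip, `*`)
  coords <- centered %*% load
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, loadings = load,
       var_explained = (s$d^2 / sum(s$d^2))[seq_len(k)])
}

#' Build a sequence-space model of a variant pool
#'
#' Featurizes the sequences, projects onto the first two principal
#' components, and density-clusters the projection.
#'
#' @param variants variant data frame with `sequence` (unique sequences
#'   expected; see [dedupe_variants()]).
#' @param descriptor_table see [featurize_sequences()].
#' @param min_cluster_size see [cluster_density()].
#' @param n_components number of principal components (default 2).
#' @return object of class `sequence_space_model`: `descriptors`,
#'   `projection`, `labels`, `centroids`, `variant_ids`, `var_explained`.
#' @export
sequence_space_model <- function(variants,
                                 descriptor_table = default_descriptor_table(),
                                 min_cluster_size = 5L,
                                 n_components = 2L) {
  mat <- featurize_sequences(variants, descriptor_table)
  pca <- project_pca(mat, n_components)
  cl <- cluster_density(pca$coords, min_cluster_size)
  ids <- if (!is.null(variants$variant_id)) as.character(variants$variant_id)
         else as.character(seq_len(nrow(mat)))
  structure(list(descriptors = mat, projection = pca$coords,
                 labels = cl$labels, centroids = cl$centroids,
                 variant_ids = ids, var_explained = pca$var_explained),
            class = "sequence_space_model")
}

#' Cluster member nearest to its centroid
#'
#' @param model a [sequence_space_model()] (or any list with `projection`,
#'   `labels`, `centroids`, `variant_ids`).
#' @param cluster_label non-noise cluster label.
#' @return the variant id of the member closest to the cluster centroid
#'   (ties: lowest variant id).
#' @export
nearest_to_centroid <- function(model, cluster_label) {
  if (cluster_label < 0) stop("noise (-1) has no centroid")
  members <- which(model$labels == cluster_label)
  if (!length(members)) stop("no such cluster label: ", cluster_label)
  cen <- model$centroids[model$centroids$label == cluster_label, -1L]
  cen <- as.numeric(cen)
  d2 <- rowSums(sweep(model$projection[members, , drop = FALSE], 2L,
                      cen)^2)
  ids <- model$variant_ids[members]
  ord <- order(d2, ids)
  ids[ord[1L]]
}

#' Final affinity-maturation candidate selection
#'
#' Stage 1 alternates between the two score rankings (best remaining by
#' `mmpbsa`, then by `delta_flexddg`, both ascending) and accumulates
#' unique sequences until `n_score` designs are picked. Stage 2 adds, for
#' up to `n_cluster_picks` non-excluded clusters with no stage-1 member,
#' the variant nearest the cluster centroid. With the defaults this yields
#' 20 + 3 = 23 candidates.
#'
#' @param variants non-redundant variant data frame with `variant_id`,
#'   `sequence`, `mmpbsa`, `delta_flexddg` (row order matches `model`).
#' @param model a [sequence_space_model()] of the same variants.
#' @param n_score stage-1 pick count (default 20).
#' @param n_cluster_picks maximum stage-2 diversification picks (default
#'   3).
#' @param excluded_clusters cluster labels never picked from in stage 2
#'   (the score-dominated clusters; default none).
#' @return data frame of candidates in pick order with `picked_by`
#'   (`"mmpbsa"`, `"delta_flexddg"` or `"cluster_<label>"`).
#' @export
maturation_select <- function(variants, model, n_score = 20L,
                              n_cluster_picks = 3L,
                              excluded_clusters = integer(0)) {
  need <- c("variant_id", "sequence", "mmpbsa", "delta_flexddg")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  ord_mm <- order(variants$mmpbsa, variants$variant_id)
  ord_fx <- order(variants$delta_flexddg, variants$variant_id)
  picked <- integer(0)
  picked_by <- character(0)
  seqs <- character(0)
  take_next <- function(ord) {
    for (i in ord) {
      if (i %in% picked || variants$sequence[i] %in% seqs) next
      return(i)
    }
    NA_integer_
  }
  turn <- 0L
  while (length(picked) < n_score) {
    ord <- if (turn %% 2L == 0L) ord_mm else ord_fx
    by <- if (turn %% 2L == 0L) "mmpbsa" else "delta_flexddg"
    i <- take_next(ord)
    if (is.na(i)) {
      i <- take_next(if (turn %% 2L == 0L) ord_fx else ord_mm)
      if (is.na(i)) break
      by <- if (turn %% 2L == 0L) "delta_flexddg" else "mmpbsa"
    }
    picked <- c(picked, i)
    picked_by <- c(picked_by, by)
    seqs <- c(seqs, variants$sequence[i])
    turn <- turn + 1L
  }
  if (length(picked) < n_score)
    warning("only ", length(picked), " unique sequences available for the ",
            "score-based stage (requested ", n_score, ")")
  ## stage 2: diversification from unrepresented clusters
  added <- 0L
  for (lab in sort(unique(model$labels[model$labels >= 0L]))) {
    if (added >= n_cluster_picks) break
    if (lab %in% excluded_clusters) next
    if (any(model$labels[picked] == lab)) next
    vid <- nearest_to_centroid(model, lab)
    i <- match(vid, variants$variant_id)
    if (i %in% picked || variants$sequence[i] %in% seqs) next
    picked <- c(picked, i)
    picked_by <- c(picked_by, paste0("cluster_", lab))
    seqs <- c(seqs, variants$sequence[i])
    added <- added + 1L
  }
  out <- variants[picked, , drop = FALSE]
  out$picked_by <- picked_by
  out$cluster <- model$labels[picked]
  rownames(out) <- NULL
  out
}

#' Check that all mutations fall in allowed positions
#'
#' Validates a designed variant against its template: every differing
#' position must be in the whitelist (e.g. CDR loop positions; framework
#' beta-strand positions are excluded from design to protect stability).
#'
#' @param variant,template equal-length one-letter sequences.
#' @param allowed_positions integer vector of 1-based designable positions.
#' @return list with `ok` (logical) and `offending` (positions mutated
#'   outside the whitelist).
#' @export
validate_mutation_positions <- function(variant, template,
                                        allowed_positions) {
  if (nchar(variant) != nchar(template))
    stop("variant and template lengths differ")
  v <- strsplit(variant, "")[[1L]]
  t <- strsplit(template, "")[[1L]]
  diffs <- which(v != t)
  offending <- setdiff(diffs, allowed_positions)
  list(ok = length(offending) == 0L, offending = offending)
}

#' Read/write variant tables
#'
#' TSV with columns `variant_id`, `sequence`, `variation_id`, `ddg`,
#' `mmpbsa`, `flexddg` and optionally `delta_flexddg`.
#' @param path TSV file.
#' @return data frame.
#' @export
read_variant_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_variant_table
#' @param variants variant data frame.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
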