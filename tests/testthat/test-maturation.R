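test_that("design grid expansion enumerates all binary combinations", {
  g <- expand_design_grid(design_parameter_grid())
  expect_equal(nrow(g), 16L)
  expect_equal(g$variation_id, 1:16)
  # first declared axis most significant, first level first
  expect_equal(g$force_L29_K59, rep(c("off", "on"), each = 8))
  expect_equal(g$design_shell, rep(c(10, 12), 8))
  expect_equal(anyDuplicated(g[-1]), 0L)

  # zero axes -> one empty config
  expect_equal(nrow(expand_design_grid(design_parameter_grid(list()))), 1L)

  # three binary axes against a manual enumeration
  g3 <- expand_design_grid(design_parameter_grid(
    list(a = c("a0", "a1"), b = c("b0", "b1"), c = c("c0", "c1"))))
  expect_equal(nrow(g3), 8L)
  manual <- character(0)
  for (a in c("a0", "a1")) for (b in c("b0", "b1")) for (c in c("c0", "c1"))
    manual <- c(manual, paste(a, b, c))
  expect_equal(paste(g3$a, g3$b, g3$c), manual)
})

test_that("per-variation retention and pooling match the sort oracle", {
  pool <- gen_variant_pool(n = 16 * 150, n_unique = 16 * 150, seed = 3)
  kept <- retain_lowest_k(pool, 100)
  expect_equal(nrow(kept), 1600L)
  for (v in unique(pool$variation_id)) {
    want <- sort(pool$ddg[pool$variation_id == v])[1:100]
    expect_equal(sort(kept$ddg[kept$variation_id == v]), want)
  }

  toy <- data.frame(variation_id = 1L,
                    sequence = sprintf("S%d", 1:9),
                    ddg = c(3, -1, 4, 1, 5, -9, 2, 6, -5))
  expect_equal(sort(retain_lowest_k(toy, 4)$ddg), sort(toy$ddg)[1:4])
  expect_warning(all9 <- retain_lowest_k(toy, 20), "fewer than k")
  expect_equal(nrow(all9), 9L)
})

test_that("deduplication keeps the best-ddg representative per sequence", {
  pool <- data.frame(sequence = c("X", "Y", "X", "X", "Y"),
                     ddg = c(-1, -4, -3, -2, -1),
                     variant_id = sprintf("v%d", 1:5),
                     stringsAsFactors = FALSE)
  uq <- dedupe_variants(pool)
  expect_equal(uq$sequence, c("X", "Y"))
  expect_equal(uq$ddg, c(-3, -4))                 # group-by min oracle
  expect_equal(uq$n_duplicates, c(3L, 2L))

  five <- data.frame(sequence = rep("Z", 5), ddg = rnorm(5))
  expect_equal(nrow(dedupe_variants(five)), 1L)

  big <- gen_variant_pool(n = 1600, n_unique = 89, seed = 9)
  uq2 <- dedupe_variants(big)
  expect_equal(nrow(uq2), length(unique(big$sequence)))  # hash-set oracle
  expect_equal(nrow(uq2), 89L)
  expect_identical(dedupe_variants(uq2)$sequence, uq2$sequence)  # idempotent
})

test_that("delta FlexddG subtracts the reference with the stated sign", {
  expect_equal(delta_flexddg(-3.2, -1.0), -2.2)
  expect_equal(delta_flexddg(c(-1, -1), -1), c(0, 0))
  expect_equal(delta_flexddg(-3.2, -1.0, sign = "reference_minus_variant"),
               2.2)
  expect_error(delta_flexddg(1, NA_real_), "finite")
  expect_error(delta_flexddg(NaN, 0), "finite")
})

test_that("featurization is a position-major descriptor lookup", {
  tab <- default_descriptor_table()
  expect_equal(dim(tab), c(20L, 66L))

  one <- featurize_sequences("A", tab)
  expect_equal(dim(one), c(1L, 66L))
  expect_equal(as.numeric(one), unname(tab["A", ]))

  two <- featurize_sequences(c("ACD", "ACD"), tab)
  expect_equal(two[1, ], two[2, ])

  m <- featurize_sequences(c("ACD", "AWD", "CCD", "ACE", "GGG"), tab)
  expect_equal(dim(m), c(5L, 198L))
  # single-cell lookups: row 2, position 2 holds W's descriptors
  expect_equal(unname(m[2, 67:132]), unname(tab["W", ]))
  expect_equal(unname(m[5, 1:66]), unname(tab["G", ]))

  expect_error(featurize_sequences(c("AC", "ACD")), "length")
  expect_error(featurize_sequences("AZ"), "Z")
})

test_that("PCA projection matches an eigendecomposition oracle", {
  set.seed(51)
  # points on a line embedded in 66-D: PC2 coordinates vanish
  dirv <- rnorm(66)
  line <- outer(seq(-2, 2, length.out = 20), dirv)
  pl <- project_pca(line, 2)
  expect_lt(max(abs(pl$coords[, 2])), 1e-8)

  # planted 2-D Gaussian cloud in 66-D
  basis <- qr.Q(qr(matrix(rnorm(66 * 2), 66, 2)))
  scores <- cbind(rnorm(200, sd = 3), rnorm(200, sd = 1))
  x <- scores %*% t(basis)
  p <- project_pca(x, 2)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(p$var_explained, (ev / sum(ev))[1:2], tolerance = 1e-8)

  # deterministic sign: largest-|loading| entry positive
  expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(project_pca(matrix(1, 5, 3)), "zero variance")
})

test_that("nearest-to-centroid picks by brute-force minimum distance", {
  proj <- rbind(c(0, 0), c(1, 0), c(0.2, 0.1), c(5, 5), c(0.4, -0.2))
  model <- list(projection = proj,
                labels = c(0L, 0L, 0L, 1L, 0L),
                centroids = data.frame(label = 0:1,
                                       c1 = c(mean(proj[c(1:3, 5), 1]), 5),
                                       c2 = c(mean(proj[c(1:3, 5), 2]), 5)),
                variant_ids = sprintf("v%d", 1:5))
  cen <- as.numeric(model$centroids[1, -1])
  d2 <- rowSums(sweep(proj[c(1:3, 5), ], 2, cen)^2)
  want <- model$variant_ids[c(1:3, 5)][which.min(d2)]
  expect_equal(nearest_to_centroid(model, 0L), want)
  expect_equal(nearest_to_centroid(model, 1L), "v4")   # singleton cluster
  expect_error(nearest_to_centroid(model, -1L), "noise")
})

test_that("maturation selection alternates score rankings then diversifies", {
  # hand-ranked toy: mmpbsa order v1<v2<...<v6, delta order v6<v5<...<v1
  toy <- data.frame(variant_id = sprintf("v%d", 1:6),
                    sequence = sprintf("S%d", 1:6),
                    mmpbsa = c(-50, -40, -30, -20, -10, 0),
                    delta_flexddg = c(0, -1, -2, -3, -4, -5),
                    stringsAsFactors = FALSE)
  model <- list(projection = matrix(0, 6, 2), labels = rep(-1L, 6),
                centroids = data.frame(label = integer(0), c1 = numeric(0),
                                       c2 = numeric(0)),
                variant_ids = toy$variant_id)
  got <- maturation_select(toy, model, n_score = 4, n_cluster_picks = 0)
  expect_equal(got$variant_id, c("v1", "v6", "v2", "v5"))
  expect_equal(got$picked_by,
               c("mmpbsa", "delta_flexddg", "mmpbsa", "delta_flexddg"))

  # a duplicated sequence is skipped on the mmpbsa ranking
  toy2 <- toy
  toy2$sequence[2] <- "S1"
  got2 <- maturation_select(toy2, model, n_score = 4, n_cluster_picks = 0)
  expect_equal(got2$variant_id, c("v1", "v6", "v3", "v5"))

  # n_score = pool size returns the whole pool
  expect_warning(all6 <- maturation_select(toy2, model, n_score = 6,
                                           n_cluster_picks = 0),
                 "unique sequences")
  expect_equal(nrow(all6), 5L)
})

test_that("the full maturation pool yields 20 + 3 final candidates", {
  uq <- dedupe_variants(gen_variant_pool(n = 1600, n_unique = 89, seed = 7))
  model <- sequence_space_model(uq, min_cluster_size = 5)
  sel <- maturation_select(uq, model, n_score = 20, n_cluster_picks = 3)
  expect_equal(nrow(sel), 23L)
  expect_equal(anyDuplicated(sel$sequence), 0L)
  expect_equal(sum(sel$picked_by %in% c("mmpbsa", "delta_flexddg")), 20L)
  expect_equal(sum(startsWith(sel$picked_by, "cluster_")), 3L)
  # stage-2 picks come from clusters with no score-stage member
  score_cl <- unique(sel$cluster[sel$picked_by %in%
                                   c("mmpbsa", "delta_flexddg")])
  div_cl <- sel$cluster[startsWith(sel$picked_by, "cluster_")]
  expect_false(any(div_cl %in% score_cl))
})

test_that("mutation positions validate against a whitelist", {
  tmpl <- strsplit(NB_TEMPLATE, "")[[1]]
  v <- tmpl
  v[29] <- "L"; v[59] <- "K"          # two designed hot-spot mutations
  v <- paste(v, collapse = "")
  expect_true(validate_mutation_positions(v, NB_TEMPLATE, c(29, 59))$ok)
  res <- validate_mutation_positions(v, NB_TEMPLATE, 29)
  expect_false(res$ok)
  expect_equal(res$offending, 59L)
  expect_true(validate_mutation_positions(NB_TEMPLATE, NB_TEMPLATE,
                                          integer(0))$ok)
  expect_error(validate_mutation_positions("AA", "AAA", 1), "length")
})
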