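## Deterministic density-based clustering of the HDBSCAN family.
##
## Exact implementation for the small point sets this package sees
## (hundreds of variants in a 2-D projection): mutual-reachability
## distances, a Prim minimum spanning tree, a single-linkage hierarchy, a
## condensed tree at the requested minimum cluster size, and
## excess-of-mass cluster selection. No randomized initialization: the
## result is a pure function of the coordinates and the two size
## parameters.

#' Density clustering of a 2-D (or n-D) point set
#'
#' HDBSCAN-style hierarchical density clustering. Points in no selected
#' density cluster are labelled noise (`-1`); clusters are labelled
#' `0, 1, ...` in order of their appearance in the cluster hierarchy.
#' When the hierarchy contains no genuine split into two clusters of at
#' least `min_cluster_size` points (e.g. one compact blob, or all points
#' identical), the whole set is returned as a single cluster.
#'
#' @param coordinates numeric matrix, one point per row.
#' @param min_cluster_size smallest allowed cluster (default 5).
#' @param min_samples neighborhood size for core distances (default:
#'   `min_cluster_size`); the count includes the point itself.
#' @return list with `labels` (integer vector, `-1` = noise) and
#'   `centroids` (data frame `label`, one coordinate column per input
#'   dimension: mean of member coordinates).
#' @export
cluster_density <- function(coordinates, min_cluster_size = 5L,
                            min_samples = min_cluster_size) {
  x <- as.matrix(coordinates)
  n <- nrow(x)
  min_cluster_size <- as.integer(min_cluster_size)
  min_samples <- as.integer(min_samples)
  if (n < min_cluster_size) {
    warning("fewer points (", n, ") than min_cluster_size (",
            min_cluster_size, "): all points labelled noise")
    return(list(labels = rep(-1L, n), centroids = empty_centroids(x)))
  }

  d <- as.matrix(stats::dist(x))
  core <- apply(d, 1L, function(r) sort(r)[min(min_samples, n)])
  mreach <- pmax(d, outer(core, core, pmax))

  mst <- prim_mst(mreach)
  hier <- single_linkage(mst, n)
  cond <- condense_tree(hier, n, min_cluster_size)
  labels <- extract_labels(cond, n)
  list(labels = labels, centroids = label_centroids(x, labels))
}

empty_centroids <- function(x) {
  out <- data.frame(label = integer(0))
  for (j in seq_len(ncol(x))) out[[paste0("c", j)]] <- numeric(0)
  out
}

label_centroids <- function(x, labels) {
  labs <- sort(unique(labels[labels >= 0L]))
  out <- data.frame(label = labs)
  for (j in seq_len(ncol(x)))
    out[[paste0("c", j)]] <- vapply(labs, function(l)
      mean(x[labels == l, j]), numeric(1))
  out
}

## Prim MST on a full distance matrix; returns (from, to, weight) rows.
prim_mst <- function(w, n = nrow(w)) {
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best <- w[1L, ]
  from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (k in seq_len(n - 1L)) {
    cand <- best
    cand[in_tree] <- Inf
    j <- which.min(cand)
    edges[k, ] <- c(from[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & w[j, ] < best
    best[upd] <- w[j, upd]
    from[upd] <- j
  }
  edges[order(edges[, 3L]), , drop = FALSE]
}

## Single-linkage dendrogram from sorted MST edges (union-find).
## Node ids: 1..n leaves, n+k for the k-th merge.
single_linkage <- function(edges, n) {
  uf <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  node_of <- seq_len(n)          # component root -> current tree node
  children <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  for (k in seq_len(n - 1L)) {
    ra <- find(edges[k, 1L])
    rb <- find(edges[k, 2L])
    node <- n + k
    children[k, ] <- c(node_of[ra], node_of[rb])
    height[k] <- edges[k, 3L]
    size[node] <- size[node_of[ra]] + size[node_of[rb]]
    uf[ra] <- node
    uf[rb] <- node
    uf[node] <- node
    node_of[node] <- node
  }
  list(children = children, height = height, size = size, root = 2L * n - 1L)
}

subtree_leaves <- function(hier, node, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, hier$children[v - n, ])
  }
  out
}

## Condensed tree: clusters persist through splits that shed fewer than
## min_cluster_size points; a genuine split spawns two child clusters.
condense_tree <- function(hier, n, mcs) {
  lam <- function(h) 1 / max(h, 1e-10)
  parent_cluster <- integer(0)   # per cluster; 0 for root
  birth <- numeric(0)
  new_cluster <- function(parent, lambda) {
    parent_cluster[length(parent_cluster) + 1L] <<- parent
    birth[length(birth) + 1L] <<- lambda
    length(birth)
  }
  root <- new_cluster(0L, 0)
  pt_cluster <- integer(n)       # condensed cluster each point fell from
  pt_lambda <- numeric(n)
  stack <- list(list(node = hier$root, cluster = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    cl <- fr$cluster
    repeat {
      if (node <= n) {           # bare leaf (only when n == 1 subtree)
        pt_cluster[node] <- cl
        pt_lambda[node] <- Inf
        break
      }
      k <- node - n
      l <- lam(hier$height[k])
      a <- hier$children[k, 1L]
      b <- hier$children[k, 2L]
      sa <- hier$size[a]
      sb <- hier$size[b]
      if (sa >= mcs && sb >= mcs) {
        ca <- new_cluster(cl, l)
        cb <- new_cluster(cl, l)
        stack[[length(stack) + 1L]] <- list(node = b, cluster = cb)
        node <- a
        cl <- ca
      } else if (sa >= mcs || sb >= mcs) {
        small <- if (sa >= mcs) b else a
        for (p in subtree_leaves(hier, small, n)) {
          pt_cluster[p] <- cl
          pt_lambda[p] <- l
        }
        node <- if (sa >= mcs) a else b
      } else {
        for (p in subtree_leaves(hier, node, n)) {
          pt_cluster[p] <- cl
          pt_lambda[p] <- l
        }
        break
      }
    }
  }
  list(parent_cluster = parent_cluster, birth = birth,
       pt_cluster = pt_cluster, pt_lambda = pt_lambda)
}

## Excess-of-mass cluster selection, root excluded; falls back to one
## all-points cluster when the tree never split.
extract_labels <- function(cond, n) {
  ncl <- length(cond$birth)
  if (ncl == 1L) return(rep(0L, n))   # no split: single cluster
  ## stability: points leaving + child clusters detaching
  stability <- numeric(ncl)
  for (p in seq_len(n)) {
    c <- cond$pt_cluster[p]
    contrib <- min(cond$pt_lambda[p], 1e10) - cond$birth[c]
    stability[c] <- stability[c] + contrib
  }
  kids <- split(seq_len(ncl)[-1L], cond$parent_cluster[-1L])
  for (c in seq_len(ncl)) {
    ch <- kids[[as.character(c)]]
    if (!is.null(ch))
      for (cc in ch) {
        ## child detaches the child's points at the child's birth lambda
        sz <- sum(cond$pt_cluster %in% descendants(cond, cc))
        stability[c] <- stability[c] +
          sz * (cond$birth[cc] - cond$birth[c])
      }
  }
  selected <- logical(ncl)
  subtree_stab <- numeric(ncl)
  for (c in rev(seq_len(ncl))) {       # children have larger ids
    if (c == 1L) break
    ch <- kids[[as.character(c)]]
    if (is.null(ch)) {
      selected[c] <- TRUE
      subtree_stab[c] <- stability[c]
    } else if (stability[c] >= sum(subtree_stab[ch])) {
      selected[c] <- TRUE
      for (dd in descendants(cond, c)) if (dd != c) selected[dd] <- FALSE
      subtree_stab[c] <- stability[c]
    } else {
      subtree_stab[c] <- sum(subtree_stab[ch])
    }
  }
  labels <- rep(-1L, n)
  sel_ids <- which(selected)
  if (!length(sel_ids)) return(rep(0L, n))  # degenerate: one cluster
  relabel <- stats::setNames(seq_along(sel_ids) - 1L, sel_ids)
  for (p in seq_len(n)) {
    c <- cond$pt_cluster[p]
    while (c != 0L && !selected[c]) c <- cond$parent_cluster[c]
    if (c != 0L) labels[p] <- relabel[[as.character(c)]]
  }
  labels
}

descendants <- function(cond, c) {
  out <- c
  frontier <- c
  repeat {
    nxt <- which(cond$parent_cluster %in% frontier)
    if (!length(nxt)) return(out)
    out <- c(out, nxt)
    frontier <- nxt
  }
}
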