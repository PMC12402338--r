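# Embedding, neighbor graphs, Louvain clustering, cell-type labelling.

#' Normalize RNA counts
#'
#' Per-cell scaling to a fixed total followed by `log(1 + x)`; a cell's
#' normalized vector is invariant to uniform scaling of its counts.
#'
#' @param m Raw count matrix (genes x cells).
#' @param scale_factor Per-cell target total (default 10,000).
#' @return A sparse normalized matrix of the same shape.
#' @export
normalize_rna <- function(m, scale_factor = 1e4) {
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop_input("cell(s) with zero total counts: %s",
               paste(head(colnames(m)[tot == 0], 3), collapse = ", "))
  }
  out <- m %*% Diagonal(x = scale_factor / tot)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  as(out, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by a mean-binned standardized dispersion (variance/mean of the
#' normalized expression, z-scored within 20 bins of mean expression) and
#' returns the top `n`; ties and ranking are deterministic (gene order breaks
#' ties). Constant genes rank last.
#'
#' @param norm Normalized matrix from [normalize_rna()].
#' @param n Number of genes to select; if larger than the gene count, all
#'   genes are returned with a warning.
#' @param n_bins Number of mean-expression bins.
#' @return Character vector of selected gene identifiers.
#' @export
select_variable_genes <- function(norm, n = 2000L, n_bins = 20L) {
  score <- dispersion_score(norm, n_bins)
  if (n > nrow(norm)) {
    warn(sprintf("requested %d variable genes but only %d genes present; using all",
                 n, nrow(norm)))
    n <- nrow(norm)
  }
  ord <- order(-score, seq_along(score))
  rownames(norm)[ord[seq_len(n)]]
}

# standardized dispersion; -Inf-like floor for constant genes
dispersion_score <- function(norm, n_bins = 20L) {
  mu <- rowMeans(norm)
  v <- rowMeans(norm^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  score <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    s <- sd(disp[sel])
    score[sel] <- if (is.na(s) || s == 0) 0 else (disp[sel] - mean(disp[sel])) / s
  }
  score[v == 0] <- -Inf
  score
}

#' TF-IDF weighting of a binarized bin matrix
#'
#' `entry(i, j) = log(1 + 1e4 * tf(i, j) * idf(i))` where `tf(i, j)` is bin
#' i's share of cell j's total and `idf(i) = n_cells / n_cells_with_bin_i`.
#' (Features are rows, cells columns.)
#'
#' @param m Binary bin matrix (bins x cells) from [binarize()].
#' @param scale_factor Constant inside the logarithm (default 1e4).
#' @return A sparse weighted matrix.
#' @export
tfidf <- function(m, scale_factor = 1e4) {
  cell_tot <- colSums(m)
  bin_cells <- rowSums(m > 0)
  if (any(cell_tot == 0)) {
    stop_input("cell(s) with no bins after filtering: %s",
               paste(head(colnames(m)[cell_tot == 0], 3), collapse = ", "))
  }
  if (any(bin_cells == 0)) {
    stop_input("bin(s) present in no cell: %s",
               paste(head(rownames(m)[bin_cells == 0], 3), collapse = ", "))
  }
  idf <- ncol(m) / bin_cells
  out <- Diagonal(x = idf) %*% m %*% Diagonal(x = 1 / cell_tot)
  out@x <- log1p(scale_factor * out@x)
  dimnames(out) <- dimnames(m)
  as(out, "CsparseMatrix")
}

#' Reduce a matrix to a low-dimensional embedding
#'
#' `method = "pca"`: rows (features) are centered and unit-scaled, and the
#' first `n` principal components of the cells are returned (components
#' 1-30 by default). `method = "lsi"`: truncated SVD of the TF-IDF matrix
#' without centering; the first component, which tracks per-cell depth, is
#' dropped and components 2..n are returned. Component signs follow the
#' convention that the largest-magnitude feature loading is positive.
#'
#' @param m Normalized (pca) or TF-IDF (lsi) matrix, features x cells.
#' @param method `"pca"` or `"lsi"`.
#' @param n Highest component index to use (default 30).
#' @return A `pt_embedding`: list with `coords` (cells x components),
#'   `method`, `components`.
#' @export
reduce_dims <- function(m, method = c("pca", "lsi"), n = 30L) {
  method <- match.arg(method)
  x <- as.matrix(m)
  if (method == "pca") {
    x <- x - rowMeans(x)
    rs <- apply(x, 1, sd)
    rs[rs == 0] <- 1
    x <- x / rs
  }
  max_n <- min(dim(x)) - 1L
  if (n > max_n) {
    warn(sprintf("reducing n from %d to matrix rank limit %d", n, max_n))
    n <- max_n
  }
  sv <- svd(x, nu = 0L)            # x = features x cells; V holds cell scores
  keep <- seq_len(n)
  d <- sv$d[keep]
  v <- sv$v[, keep, drop = FALSE]
  u <- x %*% v %*% diag(1 / d, n)  # feature loadings
  # sign convention: largest |loading| positive
  for (k in seq_len(n)) {
    j <- which.max(abs(u[, k]))
    if (u[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  coords <- v %*% diag(d, n)
  rownames(coords) <- colnames(m)
  comps <- if (method == "lsi") 2:n else 1:n
  coords <- coords[, comps, drop = FALSE]
  colnames(coords) <- paste0(toupper(method), "_", comps)
  structure(list(coords = coords, method = method, components = comps,
                 sdev = d[comps] / sqrt(max(ncol(m) - 1, 1))),
            class = "pt_embedding")
}

#' Shared-nearest-neighbour graph
#'
#' k-nearest neighbours by Euclidean distance in the embedding (the cell
#' itself is included among its k neighbours), with edge weights
#' `|shared| / (2k - |shared|)` between cells whose neighbour sets overlap;
#' weights below `prune` are removed. The graph is undirected.
#'
#' @param embedding A `pt_embedding` (or a cells x dims matrix).
#' @param k Number of neighbours (default 20).
#' @param prune Minimum SNN weight to keep an edge (default 1/15).
#' @return An [igraph::graph] with `name` vertex attributes.
#' @export
knn_graph <- function(embedding, k = 20L, prune = 1 / 15) {
  coords <- if (is(embedding, "pt_embedding")) embedding$coords else embedding
  n <- nrow(coords)
  if (k >= n) stop_input("k (%d) must be smaller than the number of cells (%d)", k, n)
  d <- as.matrix(stats::dist(coords))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  adj <- sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn), x = 1,
                      dims = c(n, n))
  shared <- as(Matrix::tcrossprod(adj), "CsparseMatrix")  # |N(i) inter N(j)|
  w <- shared
  w@x <- w@x / (2 * k - w@x)
  w@x[w@x < prune] <- 0
  w <- drop0(w)
  Matrix::diag(w) <- 0
  w <- (w + Matrix::t(w)) / 2
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- rownames(coords)
  g
}

#' Blend two modality graphs with a fixed global weight
#'
#' Edge weights are `weight_rna * w_RNA + (1 - weight_rna) * w_DNA` over the
#' union of edges; `weight_rna = 1` reproduces the RNA graph exactly and 0 the
#' DNA graph. (A simplified stand-in for per-cell weighted-nearest-neighbour
#' integration, which is out of scope.)
#'
#' @param graph_rna,graph_dna Graphs over the same cells from [knn_graph()].
#' @param weight_rna RNA weight in `[0, 1]`.
#' @return An undirected weighted [igraph::graph].
#' @export
joint_graph <- function(graph_rna, graph_dna, weight_rna = 0.5) {
  if (weight_rna < 0 || weight_rna > 1) stop_config("weight_rna must be in [0, 1]")
  vr <- igraph::V(graph_rna)$name
  vd <- igraph::V(graph_dna)$name
  if (!setequal(vr, vd)) stop_input("graphs are over different cell sets")
  ar <- igraph::as_adjacency_matrix(graph_rna, attr = "weight", sparse = TRUE)
  ad <- igraph::as_adjacency_matrix(graph_dna, attr = "weight", sparse = TRUE)
  ad <- ad[vr, vr]
  w <- weight_rna * ar + (1 - weight_rna) * ad
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- vr
  g
}

#' Louvain clustering of a neighbour graph
#'
#' Modularity-based Louvain communities at the given resolution; clusters
#' smaller than `min_cells` (50 by default) are flagged `excluded`.
#'
#' @param graph Weighted undirected graph.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed (clustering is deterministic given it).
#' @param min_cells Minimum cluster size; smaller clusters are flagged.
#' @return A tibble `cell`, `cluster` (integer), `excluded`; cluster sizes in
#'   the `sizes` attribute.
#' @export
cluster_graph <- function(graph, resolution = 1, seed = 1L, min_cells = 50L) {
  if (igraph::vcount(graph) == 0L) stop_input("empty graph")
  memb <- withr::with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(graph, resolution = resolution))
  })
  out <- tibble(cell = igraph::V(graph)$name, cluster = as.integer(memb))
  sizes <- out |> count(.data$cluster, name = "size")
  out <- out |> left_join(sizes, by = "cluster") |>
    mutate(excluded = .data$size < min_cells) |> select(-"size")
  attr(out, "sizes") <- sizes
  out
}

#' Search the Louvain resolution for a target cluster count
#'
#' Utility for matching a predefined number of clusters; scans a resolution
#' grid and returns the clustering whose (non-excluded) cluster count is
#' closest to `target`.
#'
#' @inheritParams cluster_graph
#' @param target Desired number of clusters.
#' @param grid Resolutions to try.
#' @return As [cluster_graph()], with the chosen resolution in the
#'   `resolution` attribute.
#' @export
search_resolution <- function(graph, target, grid = seq(0.2, 3, by = 0.2),
                              seed = 1L, min_cells = 50L) {
  best <- NULL; best_gap <- Inf
  for (r in grid) {
    cl <- cluster_graph(graph, resolution = r, seed = seed, min_cells = min_cells)
    k <- length(unique(cl$cluster[!cl$excluded]))
    if (abs(k - target) < best_gap) {
      best <- cl; best_gap <- abs(k - target)
      attr(best, "resolution") <- r
    }
  }
  best
}

#' Score and label clusters by marker expression
#'
#' Each marker gene's mean normalized expression is computed per cluster
#' (the cluster centroid) and z-scored across clusters, so scores do not
#' depend on cluster sizes or on a type being the majority; each cluster then
#' scores each cell type by the mean centroid z-score of that type's markers.
#' The label is the argmax type when its score exceeds `margin`, otherwise
#' `"unresolved"`.
#'
#' @param clusters Tibble from [cluster_graph()].
#' @param norm Normalized RNA matrix (genes x cells).
#' @param markers Named list: cell type -> character vector of marker genes.
#'   Missing genes are warned about and skipped.
#' @param margin Minimum top score required to assign a label.
#' @return A tibble `cluster`, `label`, `score` (top score), with the full
#'   cluster x type score matrix in the `scores` attribute.
#' @export
label_clusters <- function(clusters, norm, markers, margin = 0.25) {
  if (!length(markers)) stop_input("empty marker configuration")
  missing <- setdiff(unlist(markers), rownames(norm))
  if (length(missing)) {
    warn(sprintf("marker gene(s) absent from the matrix: %s",
                 paste(missing, collapse = ", ")))
    markers <- lapply(markers, intersect, rownames(norm))
  }
  x <- as.matrix(norm[unique(unlist(markers)), clusters$cell, drop = FALSE])
  cl_ids <- sort(unique(clusters$cluster))
  centroids <- vapply(cl_ids, function(cl) {
    rowMeans(x[, clusters$cell[clusters$cluster == cl], drop = FALSE])
  }, numeric(nrow(x)))
  centroids <- matrix(centroids, nrow = nrow(x),
                      dimnames = list(rownames(x), as.character(cl_ids)))
  mu <- rowMeans(centroids)
  s <- apply(centroids, 1, sd); s[s == 0] <- 1
  z <- (centroids - mu) / s
  scores <- matrix(NA_real_, length(cl_ids), length(markers),
                   dimnames = list(as.character(cl_ids), names(markers)))
  for (i in seq_along(cl_ids)) {
    for (t in names(markers)) {
      scores[i, t] <- if (length(markers[[t]])) mean(z[markers[[t]], i]) else -Inf
    }
  }
  top <- apply(scores, 1, which.max)
  top_score <- scores[cbind(seq_along(cl_ids), top)]
  out <- tibble(
    cluster = cl_ids,
    label = if_else(top_score >= margin, colnames(scores)[top], "unresolved"),
    score = top_score
  )
  attr(out, "scores") <- scores
  out
}

#' Flag clusters expressing markers of multiple major types as doublets
#'
#' @param labelled Tibble from [label_clusters()] (carries the score matrix).
#' @param threshold Centroid z-score above which a type counts as "highly
#'   expressed" (default 0.4: pure clusters sit far above it on their own type
#'   and well below on every other).
#' @return `labelled` with a logical `doublet` column.
#' @export
flag_doublet_clusters <- function(labelled, threshold = 0.4) {
  scores <- attr(labelled, "scores")
  if (is.null(scores)) stop_input("labelled clusters lack a score matrix")
  n_high <- rowSums(scores > threshold)
  out <- mutate(labelled, doublet = n_high >= 2)
  attr(out, "scores") <- scores
  out
}
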