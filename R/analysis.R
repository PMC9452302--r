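## TF-IDF transform pinned for reproducibility:
##   tf  = count / pixel total
##   idf = log(1 + N_pixels / (1 + n_pixels_with_feature))
##   x   = log1p(tf * idf * 1e4)
tfidf_transform <- function(mat) {
  depth <- Matrix::rowSums(mat)
  depth[depth == 0] <- 1
  tf <- Matrix::Diagonal(x = 1 / depth) %*% mat
  nnz <- Matrix::colSums(mat > 0)
  idf <- log(1 + nrow(mat) / (1 + nnz))
  x <- tf %*% Matrix::Diagonal(x = idf)
  x@x <- log1p(x@x * 1e4)
  dimnames(x) <- dimnames(mat)
  x
}

svd_embed <- function(x, dims, seed) {
  dims <- min(dims, ncol(x) - 1L, nrow(x) - 1L)
  set.seed(seed)
  sv <- tryCatch(irlba::irlba(x, nv = dims),
                 error = function(e) {
                   s <- svd(as.matrix(x), nu = dims, nv = dims)
                   list(u = s$u, d = s$d[seq_len(dims)], v = s$v)
                 })
  emb <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(emb) <- rownames(x)
  colnames(emb) <- paste0("LSI", seq_len(ncol(emb)))
  emb
}

## drop components whose |Pearson r| with log depth exceeds the cutoff
filter_depth_components <- function(emb, depth, cutoff = 0.75) {
  ld <- log1p(depth)
  r <- suppressWarnings(apply(emb, 2L, function(v)
    if (sd(v) == 0) 0 else cor(v, ld)))
  r[is.na(r)] <- 0
  list(emb = emb[, abs(r) <= cutoff, drop = FALSE], depth_cor = r)
}

#' Iterative latent semantic indexing of a tile matrix
#'
#' Iteration 1 selects the `var_features` most accessible tiles (by total
#' count), applies the TF-IDF transform and a truncated SVD to `dims`
#' components, drops components correlated with sequencing depth
#' (|Pearson r| > `depth_cor_cutoff` vs log depth), and clusters the
#' result at `cluster_resolution`. Iteration 2 (and beyond) re-selects
#' features by their variability across the cluster pseudo-bulk profiles
#' and repeats the transform. Fully deterministic given `seed`.
#'
#' @param mat pixels x tiles sparse count matrix.
#' @param iterations LSI iterations (default 2).
#' @param var_features number of features to keep per iteration (default
#'   25000; when fewer tiles exist all are used, with a warning).
#' @param dims SVD components to compute (default 30).
#' @param cluster_resolution resolution of the interim clustering
#'   (default 0.2).
#' @param depth_cor_cutoff depth-correlation cutoff (default 0.75).
#' @param seed RNG seed.
#' @return object of class `lsi_embedding`: list with `coords` (pixels x
#'   retained dims), `depth_cor`, `features` (selected tile ids),
#'   `interim_clusters`, `degenerate` flag, and the parameters.
#' @export
iterative_lsi <- function(mat, iterations = 2L, var_features = 25000L,
                          dims = 30L, cluster_resolution = 0.2,
                          depth_cor_cutoff = 0.75, seed = 1L) {
  stopifnot(nrow(mat) >= 2L)
  if (ncol(mat) < var_features) {
    warning("only ", ncol(mat), " tiles available (< var_features = ",
            var_features, "); using all")
    var_features <- ncol(mat)
  }
  depth <- Matrix::rowSums(mat)
  degenerate <- FALSE
  feats <- order(Matrix::colSums(mat), decreasing = TRUE)[seq_len(var_features)]
  emb <- NULL; clusters <- NULL; depth_cor <- NULL
  for (it in seq_len(iterations)) {
    x <- tfidf_transform(mat[, feats, drop = FALSE])
    emb_full <- svd_embed(x, dims, seed + it)
    if (all(abs(emb_full[, -1, drop = FALSE]) < 1e-8)) degenerate <- TRUE
    fl <- filter_depth_components(emb_full, depth, depth_cor_cutoff)
    emb <- fl$emb; depth_cor <- fl$depth_cor
    if (ncol(emb) == 0L) {  # everything depth-like: keep all, flag it
      emb <- emb_full
      degenerate <- TRUE
    }
    if (it < iterations) {
      clusters <- cluster_graph(emb, resolution = cluster_resolution,
                                seed = seed + 100L + it)$label
      ## pseudo-bulk per cluster, depth-normalised log counts
      pb <- vapply(sort(unique(clusters)), function(cl) {
        v <- Matrix::colSums(mat[clusters == cl, , drop = FALSE])
        log1p(v / max(1, sum(v)) * 1e4)
      }, numeric(ncol(mat)))
      vvar <- apply(pb, 1L, var)
      feats <- order(vvar, decreasing = TRUE)[seq_len(var_features)]
    }
  }
  structure(list(coords = emb, depth_cor = depth_cor,
                 features = colnames(mat)[feats],
                 interim_clusters = clusters, degenerate = degenerate,
                 params = list(iterations = iterations,
                               var_features = var_features, dims = dims,
                               cluster_resolution = cluster_resolution,
                               depth_cor_cutoff = depth_cor_cutoff,
                               seed = seed)),
            class = "lsi_embedding")
}

coords_of <- function(x) {
  if (inherits(x, "lsi_embedding")) x$coords else as.matrix(x)
}

## cosine k-nearest neighbours by exact search (row-normalise + crossprod);
## adequate for grids of a few thousand pixels
cosine_knn <- function(emb, k) {
  n <- nrow(emb)
  k <- min(k, n - 1L)
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  e <- emb / nrm
  sim <- tcrossprod(e)
  diag(sim) <- -Inf
  t(apply(sim, 1L, function(v) order(v, decreasing = TRUE)[seq_len(k)]))
}

#' Graph clustering of an LSI embedding
#'
#' Builds a shared-nearest-neighbour graph (cosine kNN, Jaccard edge
#' weights over neighbourhoods including the point itself, weak edges
#' pruned) and partitions it with seeded Leiden modularity optimisation.
#'
#' @param emb an `lsi_embedding` or a numeric matrix (pixels x dims).
#' @param resolution Leiden resolution parameter.
#' @param n_neighbors kNN size (default 30; shrunk with a warning when
#'   there are fewer pixels).
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @param seed RNG seed (clustering is deterministic given it).
#' @return data.table `barcode`, `label` (contiguous integers from 0,
#'   ordered by decreasing cluster size), with attributes `resolution`,
#'   `seed`.
#' @export
cluster_graph <- function(emb, resolution = 0.8, n_neighbors = 30L,
                          prune = 1 / 15, seed = 1L) {
  emb <- coords_of(emb)
  n <- nrow(emb)
  stopifnot(n >= 2L)
  if (n_neighbors >= n) {
    warning("n_neighbors >= pixels; shrinking k to ", n - 1L)
    n_neighbors <- n - 1L
  }
  nn <- cosine_knn(emb, n_neighbors)
  k <- ncol(nn)
  ## neighbourhood sets include self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                              j = c(as.vector(nn), seq_len(n)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1L) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cm <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10L)
  memb <- igraph::membership(cm)
  ## relabel 0-based by decreasing size (ties: first occurrence)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- data.table(barcode = rownames(emb) %||% as.character(seq_len(n)),
                    label = unname(relab[as.character(memb)]))
  setattr(out, "resolution", resolution)
  setattr(out, "seed", seed)
  out[]
}

#' Seeded 2-D UMAP of an LSI embedding
#'
#' @param emb `lsi_embedding` or matrix.
#' @param n_neighbors neighbourhood size (default 30; shrunk when needed).
#' @param metric distance metric (default cosine).
#' @param min_dist UMAP minimum distance (default 0.5).
#' @param seed RNG seed; fixed seed gives identical coordinates.
#' @return matrix (pixels x 2) with rownames.
#' @export
umap_embed <- function(emb, n_neighbors = 30L, metric = "cosine",
                       min_dist = 0.5, seed = 1L) {
  emb <- coords_of(emb)
  stopifnot(ncol(emb) >= 2L)
  if (nrow(emb) >= 2L && all(apply(emb, 2L, sd) == 0))
    stop("degenerate embedding: all points identical")
  if (n_neighbors >= nrow(emb)) {
    warning("n_neighbors >= pixels; shrinking k to ", nrow(emb) - 1L)
    n_neighbors <- nrow(emb) - 1L
  }
  set.seed(seed)
  coords <- uwot::umap(emb, n_neighbors = n_neighbors, metric = metric,
                       min_dist = min_dist, n_threads = 1L,
                       n_sgd_threads = 0L, batch = FALSE)
  rownames(coords) <- rownames(emb)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

#' Wilcoxon marker features per cluster
#'
#' For every cluster, each feature is compared between in-cluster and
#' out-of-cluster pixels with a two-sided Wilcoxon rank-sum test;
#' p-values are Benjamini-Hochberg adjusted per cluster, and
#' `log2FC = log2((mean_in + eps) / (mean_out + eps))` with a pseudo-mean
#' of 1 unit. The returned table is filtered at `FDR <= fdr_max` and
#' `log2FC >= log2fc_min` (0.25 is the usual gene-score cutoff, 0.1 the
#' usual peak/motif cutoff).
#'
#' @param mat pixels x features matrix (tile counts or gene scores).
#' @param labels cluster labels: a [cluster_graph()] table or a vector
#'   aligned with `rownames(mat)`.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param log2fc_min log2 fold-change cutoff (default 0.25).
#' @param eps pseudo-mean added to both means (default 1).
#' @param min_cluster_size clusters smaller than this are skipped with a
#'   warning (default 3).
#' @return data.table (`cluster`, `feature`, `mean_in`, `mean_out`,
#'   `log2FC`, `p`, `FDR`), filtered; the unfiltered table is attached as
#'   attribute `full`.
#' @export
marker_features <- function(mat, labels, fdr_max = 0.05, log2fc_min = 0.25,
                            eps = 1, min_cluster_size = 3L) {
  if (is.data.frame(labels)) {
    lab <- labels$label[match(rownames(mat), labels$barcode)]
  } else lab <- labels
  stopifnot(length(lab) == nrow(mat))
  ulab <- sort(unique(lab))
  if (length(ulab) < 2L) stop("marker detection needs >= 2 clusters")
  dense <- as.matrix(mat)
  res <- list()
  for (cl in ulab) {
    inc <- lab == cl
    if (sum(inc) < min_cluster_size) {
      warning("cluster ", cl, " has fewer than ", min_cluster_size,
              " pixels; skipped")
      next
    }
    m_in <- colMeans(dense[inc, , drop = FALSE])
    m_out <- colMeans(dense[!inc, , drop = FALSE])
    pv <- vapply(seq_len(ncol(dense)), function(j) {
      x <- dense[inc, j]; y <- dense[!inc, j]
      if (all(x == x[1]) && all(y == x[1])) return(1)
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    }, numeric(1))
    pv[is.na(pv)] <- 1
    res[[as.character(cl)]] <- data.table(
      cluster = cl, feature = colnames(dense),
      mean_in = m_in, mean_out = m_out,
      log2FC = log2((m_in + eps) / (m_out + eps)),
      p = pv, FDR = p.adjust(pv, "BH"))
  }
  full <- rbindlist(res)
  out <- full[FDR <= fdr_max & log2FC >= log2fc_min]
  setorder(out, cluster, FDR, -log2FC)
  setattr(out, "full", full)
  out[]
}

#' Backbone pseudotime over ordered clusters
#'
#' A trajectory backbone is an ordered vector of cluster labels. Cluster
#' centroids are computed in the (depth-filtered) LSI space; every pixel
#' of backbone cluster `j` is projected onto the segment from centroid
#' `j` to centroid `j+1` (pixels of the final cluster project onto the
#' preceding segment, continuing past its end), and pseudotime is the
#' backbone position plus the clamped normalised projection, min-max
#' rescaled to `[0, 100]`. Pixels outside backbone clusters get `NA`
#' pseudotime and `in_backbone = FALSE`.
#'
#' @param emb `lsi_embedding` or matrix.
#' @param labels cluster labels ([cluster_graph()] table or vector).
#' @param backbone ordered vector of cluster labels (>= 2, all present).
#' @return data.table `barcode`, `label`, `in_backbone`, `pseudotime`.
#' @export
backbone_pseudotime <- function(emb, labels, backbone) {
  emb <- coords_of(emb)
  if (is.data.frame(labels)) {
    lab <- labels$label[match(rownames(emb), labels$barcode)]
  } else lab <- labels
  stopifnot(length(lab) == nrow(emb))
  backbone <- as.vector(backbone)
  if (length(backbone) < 2L) stop("backbone needs >= 2 clusters")
  if (!all(backbone %in% lab))
    stop("backbone references cluster(s) with no pixels: ",
         paste(setdiff(backbone, lab), collapse = ", "))
  cent <- t(vapply(backbone, function(cl)
    colMeans(emb[lab == cl, , drop = FALSE]), numeric(ncol(emb))))
  K <- length(backbone)
  raw <- rep(NA_real_, nrow(emb))
  for (j in seq_len(K)) {
    px <- which(lab == backbone[j])
    if (j < K) { a <- cent[j, ]; b <- cent[j + 1L, ] } else {
      a <- cent[K - 1L, ]; b <- cent[K, ]
    }
    seg <- b - a
    len2 <- sum(seg^2)
    u <- if (len2 == 0) rep(0, length(px)) else
      as.vector((emb[px, , drop = FALSE] -
                   matrix(a, length(px), ncol(emb), byrow = TRUE)) %*% seg) / len2
    raw[px] <- if (j < K) (j - 1L) + pmin(pmax(u, 0), 1)
               else (K - 1L) + pmin(pmax(u - 1, 0), 1)
  }
  inb <- !is.na(raw)
  rng <- range(raw[inb])
  pt <- if (diff(rng) == 0) ifelse(inb, 0, NA_real_) else
    (raw - rng[1]) / diff(rng) * 100
  data.table(barcode = rownames(emb) %||% as.character(seq_along(lab)),
             label = lab, in_backbone = inb, pseudotime = pt)
}

#' Feature dynamics along pseudotime
#'
#' Backbone pixels are split into `n_bins` equal-occupancy pseudotime
#' bins; per-bin means are reported together with a rolling-mean smoothed
#' curve (window of 3 bins, shrinking at the edges).
#'
#' @param mat pixels x features matrix.
#' @param trajectory a [backbone_pseudotime()] table.
#' @param feature feature (column) name.
#' @param n_bins number of bins (default 20; must not exceed backbone
#'   pixels).
#' @return data.table `bin`, `pseudotime_mid`, `n`, `mean`, `smoothed`.
#' @export
feature_along_pseudotime <- function(mat, trajectory, feature, n_bins = 20L) {
  tr <- as.data.table(trajectory)[in_backbone == TRUE]
  if (n_bins > nrow(tr))
    stop("n_bins (", n_bins, ") exceeds backbone pixels (", nrow(tr), ")")
  if (!feature %in% colnames(mat)) stop("unknown feature: ", feature)
  vals <- mat[match(tr$barcode, rownames(mat)), feature]
  ord <- order(tr$pseudotime)
  ## equal-occupancy bins by rank
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  dt <- data.table(bin = bin, pt = tr$pseudotime[ord], value = as.numeric(vals)[ord])
  out <- dt[, .(pseudotime_mid = median(pt), n = .N, mean = mean(value)),
            by = bin]
  out[, smoothed := roll_mean_partial(mean, 3L)]
  out[]
}
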