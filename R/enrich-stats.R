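#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated members when drawing
#' `n` items without replacement from a universe of `N` items of which `K`
#' are annotated:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Terms are accumulated in log space for numerical stability at genome
#' scale.
#'
#' @param k Observed annotated count in the selection.
#' @param K Annotated count in the universe.
#' @param n Selection size.
#' @param N Universe size.
#' @return The upper-tail probability, in (0, 1].
#' @examples
#' hypergeomUpperTail(4, 5, 5, 20)
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric arguments (need 0 <= k <= min(K, n), K <= N, n <= N)")
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logTerms)
  p <- exp(m) * sum(exp(logTerms - m))
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with order statistics \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} (p_{(j)} \cdot m / j)} clamped to
#' at most 1, returned in the input order. Thresholding the result at
#' \eqn{\alpha} reproduces the Benjamini-Hochberg step-up rejection set.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / seq.int(m, 1L)))
  q[ro]
}

#' Gene-set enrichment by hypergeometric test
#'
#' Tests each annotation term for over-representation in a selected gene
#' set relative to a gene universe, with Benjamini-Hochberg correction
#' across the tested terms. Terms with no selected gene are not tested
#' (they cannot be enriched and excluding them reduces the number of
#' tests), matching common enrichment-tool behaviour.
#'
#' @param selected Character vector of selected genes (must lie in
#'   `universe`).
#' @param universe Character vector: the gene universe.
#' @param annotation Named list mapping term id to a character vector of
#'   genes; genes outside the universe are dropped with a warning.
#' @param alpha Significance threshold on the adjusted q-value
#'   (default 0.01).
#' @return A data frame with one row per tested term: `term`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `significant`, ordered by increasing `p`.
#' @export
geneSetEnrichment <- function(selected, universe, annotation, alpha = 0.01) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (length(selected) == 0L) stop("empty selected gene set")
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  annotation <- lapply(annotation, unique)
  outside <- sum(vapply(annotation, function(g) sum(!g %in% universe), 0L))
  if (outside > 0) {
    warning(outside, " annotated gene(s) outside the universe dropped")
    annotation <- lapply(annotation, function(g) g[g %in% universe])
  }
  n <- length(selected)
  N <- length(universe)
  k <- vapply(annotation, function(g) sum(selected %in% g), 0L)
  K <- lengths(annotation)
  keep <- k >= 1L
  res <- data.frame(term = names(annotation)[keep], k = k[keep], K = K[keep],
                    n = n, N = N, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (nrow(res) == 0L) {
    res$p <- numeric(0); res$q <- numeric(0); res$significant <- logical(0)
    return(res)
  }
  res$p <- mapply(hypergeomUpperTail, res$k, res$K, res$n, res$N)
  res$q <- bhAdjust(res$p)
  res$significant <- res$q < alpha
  res[order(res$p, res$term), , drop = FALSE]
}

#' Venn partition of named gene lists
#'
#' Exact partition counts for two or three named gene sets, plus a
#' membership table over the union.
#'
#' @param lists Named list of character vectors (2 or 3 sets).
#' @return A list with `counts` (named integer vector keyed by
#'   membership pattern, e.g. `"A&B"`) and `membership` (logical data frame,
#'   one row per gene in the union).
#' @export
geneListOverlap <- function(lists) {
  if (length(lists) < 2L || length(lists) > 3L)
    stop("need 2 or 3 gene lists")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop("lists must be named")
  lists <- lapply(lists, unique)
  genes <- sort(unique(unlist(lists)))
  memb <- as.data.frame(lapply(lists, function(l) genes %in% l),
                        row.names = genes, optional = TRUE)
  names(memb) <- names(lists)
  pattern <- apply(memb, 1L, function(r)
    paste(names(lists)[as.logical(r)], collapse = "&"))
  # enumerate all non-empty membership patterns so absent regions report 0
  keys <- unlist(lapply(seq_along(lists), function(sz)
    utils::combn(names(lists), sz, paste, collapse = "&")))
  counts <- setNames(integer(length(keys)), keys)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, membership = memb)
}

# Jaccard distance between the rows of a binary matrix; pairs of all-zero
# rows are defined to have distance 0.
jaccardDistance <- function(m) {
  m <- (m != 0) * 1
  inter <- tcrossprod(m)
  sz <- rowSums(m)
  uni <- outer(sz, sz, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  d
}

#' Hierarchical clustering of binary profiles (Jaccard + Ward)
#'
#' Agglomerative clustering of binary presence/absence profiles using the
#' Jaccard distance (1 - |intersection|/|union|; 0 for two all-zero
#' profiles) and Ward's minimum-variance criterion applied through the
#' Lance-Williams update. Ties in the minimum inter-cluster distance are
#' broken toward the pair whose smallest original leaf indices are
#' lexicographically smallest, so the dendrogram is deterministic.
#'
#' @param mat Binary matrix (0/1) with row and column names.
#' @param axis Cluster `"rows"` or `"cols"`.
#' @return An object of class `hclust` (merge matrix, heights, leaf order,
#'   labels), directly plottable.
#' @export
binaryWardCluster <- function(mat, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") mat <- t(mat)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 items to cluster")
  labels <- rownames(mat)
  D <- jaccardDistance(mat)
  size <- rep(1L, n)
  minLeaf <- seq_len(n)          # smallest original leaf in each cluster
  id <- -seq_len(n)              # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    bestD <- Inf
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        i <- act[ii]; j <- act[jj]
        dij <- D[i, j]
        key <- sort(c(minLeaf[i], minLeaf[j]))
        if (dij < bestD - 1e-12 ||
            (abs(dij - bestD) <= 1e-12 && !is.null(best) &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          bestD <- min(bestD, dij)
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    a <- id[i]; b <- id[j]
    merge[step, ] <- if (minLeaf[i] <= minLeaf[j]) c(a, b) else c(b, a)
    height[step] <- D[i, j]
    # Lance-Williams Ward update onto cluster i
    for (k in act) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        ((size[i] + size[k]) * D[i, k] + (size[j] + size[k]) * D[j, k] -
         size[k] * D[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    minLeaf[i] <- min(minLeaf[i], minLeaf[j])
    id[i] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height,
                 order = hclustLeafOrder(merge), labels = labels,
                 method = "ward.jaccard", call = match.call(),
                 dist.method = "jaccard"),
            class = "hclust")
}

# leaf order from an hclust-style merge matrix (left-to-right traversal)
hclustLeafOrder <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}
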