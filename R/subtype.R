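# Disease-subtype detection: conditional-closeness feature matrix over
# (adjacent nodes x prioritized genes), two-way hierarchical clustering
# into sub-modules, and the Fisher-exact subgroup separation test.

#' Conditional-closeness feature matrix
#'
#' Row `u_i`, column `g` holds `c_p(g, u_i)`: the scaled conditional mean
#' hitting time from gene `g` to the adjacent node `u_i`, conditioned on
#' not passing any other adjacent node of the phenotype. Every walk
#' reaching `p` must cross its adjacency set, so avoiding the other
#' adjacent nodes already restricts the closeness to the channel through
#' `u_i`. Entries are `NA` where the gene cannot reach `u_i` while
#' avoiding the rest.
#'
#' @param net a `cipher_hetnet`.
#' @param p phenotype label.
#' @param genes character vector of gene labels (the prioritized set).
#' @return Matrix of class `cipher_features`, rows = adjacency-set node
#'   ids, columns = genes.
#' @export
feature_matrix <- function(net, p, genes) {
  stopifnot(length(genes) > 0)
  pid <- resolve_node(net, p, "phenotype")
  gid <- resolve_node(net, genes, "gene")
  U <- adjacency_set(net, p)$id
  if (length(U) < 2)
    stop("adjacency set of ", p, " has fewer than 2 members; no contrast possible")
  P <- transition_matrix(net)
  C <- matrix(NA_real_, nrow = length(U), ncol = length(genes),
              dimnames = list(U, genes))
  for (i in seq_along(U)) {
    ch <- conditional_mht(P, target = U[i], avoid = U[-i])
    C[i, ] <- as.numeric(ch$scaled[gid])
  }
  structure(C, class = c("cipher_features", "matrix"),
            phenotype = p)
}

#' Two-way hierarchical clustering of the feature matrix
#'
#' Clusters the gene columns (and the adjacent-node rows) of the
#' conditional-closeness matrix by agglomerative clustering - Euclidean
#' distance on the bounded \[0, 1\] features, average linkage, undefined
#' entries imputed to 1 (maximally distant). The two-way reordering is the
#' "diagonalization" that exposes block structure; the default cut gives 2
#' gene groups, or `n_groups = "auto"` picks the cut in `2..min(6, k-1)`
#' with the best average silhouette width.
#'
#' @param C a `cipher_features` matrix (rows adjacent nodes, columns
#'   genes).
#' @param n_groups integer number of gene groups, or `"auto"`.
#' @param method linkage passed to [stats::hclust()].
#' @param impute value substituted for undefined entries.
#' @return A `cipher_subtypes` object: `gene_groups` and `node_groups`
#'   (named membership vectors), the dendrograms, the reordered imputed
#'   matrix, and the cross-block mean closeness.
#' @export
cluster_subtypes <- function(C, n_groups = 2, method = "average",
                             impute = 1) {
  phen <- attr(C, "phenotype")
  C <- unclass(C)
  C <- C[rowSums(!is.na(C)) > 0, colSums(!is.na(C)) > 0, drop = FALSE]
  if (ncol(C) < 2) stop("fewer than 2 usable gene columns")
  if (nrow(C) < 2) stop("fewer than 2 usable adjacent-node rows")
  Ci <- C
  Ci[is.na(Ci)] <- impute

  hc_genes <- stats::hclust(stats::dist(t(Ci)), method = method)
  hc_nodes <- stats::hclust(stats::dist(Ci), method = method)

  if (identical(n_groups, "auto")) {
    if (!requireNamespace("cluster", quietly = TRUE))
      stop("the 'cluster' package is required for n_groups = \"auto\"")
    ks <- 2:min(6, ncol(Ci) - 1)
    d <- stats::dist(t(Ci))
    sil <- vapply(ks, function(k) {
      mean(cluster::silhouette(stats::cutree(hc_genes, k), d)[, "sil_width"])
    }, numeric(1))
    n_groups <- ks[which.max(sil)]
  }
  stopifnot(n_groups >= 2, n_groups <= ncol(Ci))
  gene_groups <- stats::cutree(hc_genes, n_groups)
  node_groups <- stats::cutree(hc_nodes, min(n_groups, nrow(Ci) - 1L))

  # mean closeness of each (node group, gene group) block; reported in
  # place of any pairing rule between row and column groups
  cross <- matrix(NA_real_, max(node_groups), max(gene_groups))
  for (a in seq_len(max(node_groups)))
    for (b in seq_len(max(gene_groups)))
      cross[a, b] <- mean(Ci[node_groups == a, gene_groups == b,
                             drop = FALSE])
  structure(list(gene_groups = gene_groups, node_groups = node_groups,
                 hclust_genes = hc_genes, hclust_nodes = hc_nodes,
                 C = Ci[hc_nodes$order, hc_genes$order, drop = FALSE],
                 cross_block = cross, n_groups = n_groups,
                 method = method, impute = impute,
                 phenotype = phen),
            class = "cipher_subtypes")
}

#' @export
print.cipher_subtypes <- function(x, ...) {
  cat("Sub-module clustering", if (!is.null(x$phenotype))
    paste0("(phenotype ", x$phenotype, ")"), "\n")
  tab <- table(x$gene_groups)
  cat(sprintf("  %d gene groups (%s genes); %d adjacent-node groups\n",
              length(tab), paste(tab, collapse = "/"),
              length(table(x$node_groups))))
  for (g in seq_along(tab))
    cat(sprintf("  G%d: %s\n", g,
                paste(names(x$gene_groups)[x$gene_groups == g],
                      collapse = ", ")))
  invisible(x)
}

#' Heatmap of the reordered feature matrix
#'
#' @param x a `cipher_subtypes` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.cipher_subtypes <- function(x, ...) {
  C <- x$C
  graphics::image(seq_len(ncol(C)), seq_len(nrow(C)), t(C)[, rev(seq_len(nrow(C))), drop = FALSE],
                  col = grDevices::grey.colors(64, start = 0, end = 1),
                  xlab = "prioritized genes (clustered)",
                  ylab = "adjacent nodes (clustered)", axes = FALSE,
                  main = "Conditional closeness c_p(g, u)", ...)
  graphics::axis(1, seq_len(ncol(C)), colnames(C), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(C)), rev(rownames(C)), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Pairwise gene closeness on the heterogeneous network
#'
#' Scaled mean hitting time between every unordered pair of the given
#' genes, symmetrized as the minimum (default) or mean of the two directed
#' values.
#'
#' @param net a `cipher_hetnet`.
#' @param genes gene labels.
#' @param pair_stat `"min"` or `"mean"`.
#' @return Symmetric matrix of pair statistics (diagonal 0).
#' @export
pairwise_gene_mht <- function(net, genes, pair_stat = c("min", "mean")) {
  pair_stat <- match.arg(pair_stat)
  gid <- resolve_node(net, genes, "gene")
  P <- transition_matrix(net)
  n <- length(genes)
  S <- matrix(NA_real_, n, n, dimnames = list(genes, genes))  # S[i,j] = MHT(i -> j)
  for (j in seq_len(n)) {
    mh <- mean_hitting_time(P, gid[j])
    S[, j] <- as.numeric(mh$scaled[gid])
  }
  M <- if (pair_stat == "min") pmin(S, t(S)) else (S + t(S)) / 2
  diag(M) <- 0
  M
}

#' Topological separation test for gene subgroups
#'
#' For every unordered pair of genes in the given groups the pair is
#' called topologically similar when its scaled pairwise mean hitting time
#' is below `theta_r`. Per subgroup, a 2x2 table \[within-similar,
#' within-dissimilar; between-similar, between-dissimilar\] is tested by a
#' one-sided Fisher's exact test for enrichment of similar pairs within
#' the subgroup.
#'
#' @param net a `cipher_hetnet`.
#' @param groups named integer vector: gene label -> group id; at least 2
#'   groups of at least 2 genes.
#' @param theta_r similarity threshold; `NULL` (default) selects the
#'   critical point of the ECDF of the pair statistics themselves via
#'   [select_theta_r()] - a label-independent cut, so the Fisher
#'   conditioning remains exact. An explicit value (e.g. the
#'   prioritization threshold) overrides.
#' @param pair_stat symmetrization of the directed pair values, see
#'   [pairwise_gene_mht()].
#' @return Data frame with one row per subgroup: contingency counts and
#'   one-sided p-value; the threshold used is in the `theta_r` attribute.
#' @export
subgroup_separation_test <- function(net, groups, theta_r = NULL,
                                     pair_stat = c("min", "mean")) {
  pair_stat <- match.arg(pair_stat)
  gl <- names(groups)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least 2 groups of at least 2 genes")
  M <- pairwise_gene_mht(net, gl, pair_stat)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  val <- M[idx]
  if (is.null(theta_r)) theta_r <- select_theta_r(val)
  same <- groups[idx[, 1]] == groups[idx[, 2]]
  high <- !is.na(val) & val < theta_r
  if (!any(!same)) stop("no between-group gene pairs")
  bh <- sum(high & !same); bl <- sum(!high & !same)
  out <- lapply(sort(unique(groups)), function(g) {
    within <- same & groups[idx[, 1]] == g
    wh <- sum(high & within); wl <- sum(!high & within)
    p <- fisher_exact_2x2(matrix(c(wh, wl, bh, bl), 2, byrow = TRUE),
                          alternative = "greater")
    data.frame(group = g, within_high = wh, within_low = wl,
               between_high = bh, between_low = bl, p_value = p)
  })
  res <- do.call(rbind, out)
  attr(res, "theta_r") <- theta_r
  attr(res, "pair_stat") <- pair_stat
  res
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Thin validated wrapper around [stats::fisher.test()], exposing the
#' exact hypergeometric test used by the subgroup separation statistic.
#'
#' @param table 2x2 matrix of nonnegative integer counts (row 1 = within,
#'   row 2 = between; column 1 = similar, column 2 = dissimilar).
#' @param alternative `"greater"` (default: enrichment of column 1 in row
#'   1), `"less"` or `"two.sided"`.
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(table, alternative = "greater") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("expected a 2x2 table")
  if (any(is.na(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8))
    stop("table entries must be nonnegative integers")
  if (sum(table) == 0) stop("table has no observations")
  stats::fisher.test(round(table), alternative = alternative)$p.value
}

#' Full subtype analysis of a phenotype
#'
#' Runs the subtype pipeline: builds the conditional-closeness
#' [feature_matrix()] over the candidate genes, keeps the genes (and
#' adjacent nodes) attached to the adjacency structure, clusters the
#' retained matrix two-way with [cluster_subtypes()], derives the gene
#' sub-modules from the adjacent-node groups (each node group leads to
#' the gene group attached to it; genes with comparable closeness to
#' several node groups stay unassigned), and applies the
#' [subgroup_separation_test()] to the resulting sub-modules.
#'
#' By default the candidate genes are all non-adjacent genes of the
#' network; genes associated with `p` are their own degenerate columns
#' (every other adjacent node is in their avoid set), so they carry no
#' contrast and are excluded. Passing an explicit `genes` vector (e.g.
#' the prioritized set of a [cipher_hit()] fit) overrides the default.
#'
#' @param net a `cipher_hetnet`.
#' @param p phenotype label.
#' @param genes gene labels to analyse; `NULL` uses every gene not
#'   adjacent to `p`.
#' @param n_groups passed to [cluster_subtypes()].
#' @param theta_r similarity threshold for the separation test; `NULL`
#'   lets the test select the critical point of its own pair-statistic
#'   ECDF (see [subgroup_separation_test()]).
#' @param min_attachment attachment filter in (0, 1\]; genes are kept for
#'   clustering only when their conditional closeness is below this level
#'   for at least a quarter of the adjacent nodes (default 0.3, the
#'   modularity threshold) - the column-wise analogue of a high
#'   modularity level. `NULL` disables the filter.
#' @return A `cipher_subtypes` object whose `gene_groups` are the
#'   node-group-led assignments (`gene_groups_all` keeps the raw column
#'   clustering, `unassigned` the ambiguous genes), with an extra
#'   `separation` table; or an empty result with a `status` note when
#'   fewer than 4 attached genes exist (no subtype structure
#'   detectable).
#' @export
cipher_subtypes <- function(net, p, genes = NULL, n_groups = 2,
                            theta_r = NULL, min_attachment = 0.3) {
  if (is.null(genes)) {
    adj <- adjacency_set(net, p)
    genes <- setdiff(net$nodes$label[net$nodes$kind == "gene"],
                     adj$label[adj$kind == "gene"])
  }
  C <- feature_matrix(net, p, genes)
  if (!is.null(min_attachment)) {
    # keep genes attached to a substantial part of the adjacency set:
    # close (below min_attachment) to at least a quarter of its members
    nclose <- colSums(!is.na(unclass(C)) & unclass(C) < min_attachment)
    keep <- nclose >= ceiling(nrow(C) / 4)
    if (sum(keep) < 4) {
      keep_rows <- TRUE
    } else {
      # symmetric rule for the adjacent nodes: a row carrying no
      # attached gene (e.g. a loosely associated disease gene) holds no
      # sub-module information and is dropped from the clustering
      rclose <- rowSums(!is.na(unclass(C)[, keep, drop = FALSE]) &
                          unclass(C)[, keep, drop = FALSE] < min_attachment)
      keep_rows <- rclose >= ceiling(sum(keep) / 4)
    }
    if (sum(keep) < 4 || sum(keep_rows) < 2) {
      out <- structure(list(gene_groups = integer(0), separation = NULL,
                            theta_r = theta_r,
                            status = sprintf(
                              "no subtype structure: %d gene(s) attached below %.2f",
                              sum(keep), min_attachment)),
                       class = "cipher_subtypes_empty")
      return(out)
    }
    C <- structure(unclass(C)[keep_rows, keep, drop = FALSE],
                   class = c("cipher_features", "matrix"),
                   phenotype = attr(C, "phenotype"))
  }
  cl <- cluster_subtypes(C, n_groups = n_groups)
  # Each adjacent-node group leads to a gene sub-group: genes are
  # assigned to the row group they are attached to (smallest mean
  # closeness); genes whose best and second-best group closeness are
  # comparable (ratio above `ambiguity`) are left unassigned rather
  # than forced into a sub-module.
  ambiguity <- 0.5
  Ci <- unclass(C)
  Ci[is.na(Ci)] <- 1
  row_groups <- cl$node_groups
  grp_means <- vapply(sort(unique(row_groups)), function(a)
    colMeans(Ci[names(row_groups)[row_groups == a], , drop = FALSE]),
    numeric(ncol(Ci)))
  if (is.null(dim(grp_means)))
    grp_means <- matrix(grp_means, nrow = 1)
  best <- apply(grp_means, 1, which.min)
  sorted <- t(apply(grp_means, 1, sort))
  assigned <- sorted[, 1] / pmax(sorted[, 2], 1e-12) <= ambiguity
  cl$gene_groups_all <- cl$gene_groups        # raw two-way clustering
  cl$gene_groups <- stats::setNames(best[assigned],
                                    colnames(Ci)[assigned])
  cl$unassigned <- colnames(Ci)[!assigned]
  sizes <- table(cl$gene_groups)
  cl$separation <- if (length(sizes) >= 2 && all(sizes >= 2))
    subgroup_separation_test(net, cl$gene_groups, theta_r) else NULL
  cl$theta_r <- if (!is.null(cl$separation))
    attr(cl$separation, "theta_r") else theta_r
  cl$status <- "ok"
  cl
}

#' @export
print.cipher_subtypes_empty <- function(x, ...) {
  cat("Sub-module clustering:", x$status, "\n")
  invisible(x)
}
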