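# Candidate-gene prioritization for a target phenotype: scaled-MHT
# ranking, the modularity level of adjacent nodes, the U_high/U_low
# partition, and the credible-prediction rank-ratio rule.

# Modularity level of each adjacent node: the minimum, over its companions
# in U(p), of the scaled conditional mean hitting time from the node to
# the companion, conditioned on not passing through p.
modularity_from_P <- function(P, U, pid) {
  m <- length(U)
  M <- stats::setNames(rep(NA_real_, m), U)
  if (m < 2) return(M)
  for (j in seq_len(m)) {
    ch <- conditional_mht(P, target = U[j], avoid = pid)
    others <- U[-j]
    v <- ch$scaled[others]
    better <- !is.na(v) & (is.na(M[others]) | v < M[others])
    M[others][better] <- v[better]
  }
  M
}

#' Modularity level of a phenotype's adjacent nodes
#'
#' For each adjacent node `u` of the target phenotype, the minimum scaled
#' conditional mean hitting time from `u` to any other adjacent node,
#' conditioned on not passing through the phenotype itself. Small values
#' mean `u` sits in a tight module with the other references; values are
#' in \[0, 1\], or `NA` when undefined (single-member adjacency set, or no
#' companion reachable without crossing `p`).
#'
#' @param net a `cipher_hetnet`.
#' @param p phenotype label.
#' @return Named numeric vector over the adjacency-set node ids.
#' @export
modularity_level <- function(net, p) {
  pid <- resolve_node(net, p, "phenotype")
  U <- adjacency_set(net, p)$id
  if (length(U) < 2)
    warning("adjacency set of ", p, " has fewer than 2 members; ",
            "modularity undefined")
  modularity_from_P(transition_matrix(net), U, pid)
}

partition_from_M <- function(M, theta_m, phenotype = NULL) {
  high <- names(M)[!is.na(M) & M < theta_m]
  low <- setdiff(names(M), high)
  structure(list(phenotype = phenotype, theta_m = theta_m, M = M,
                 U_high = high, U_low = low),
            class = "cipher_partition")
}

#' Partition the adjacency set by modularity level
#'
#' `U_high` holds the adjacent nodes with modularity level strictly below
#' `theta_m` (the credible references); `U_low` the rest, including nodes
#' whose modularity level is undefined.
#'
#' @inheritParams modularity_level
#' @param theta_m modularity threshold in (0, 1); default 0.3.
#' @return A `cipher_partition`: the level vector `M`, `U_high`, `U_low`.
#' @export
partition_adjacency <- function(net, p, theta_m = 0.3) {
  stopifnot(theta_m > 0, theta_m <= 1)
  M <- modularity_level(net, p)
  part <- partition_from_M(M, theta_m, phenotype = p)
  if (length(part$U_high) == 0)
    message("U_high is empty for ", p, " at theta_m = ", theta_m)
  part
}

#' @export
print.cipher_partition <- function(x, ...) {
  cat("Adjacency partition", if (!is.null(x$phenotype))
    paste0("of ", x$phenotype), "at theta_m =", x$theta_m, "\n")
  cat(sprintf("  U_high: %d node(s); U_low: %d node(s); %d undefined level(s)\n",
              length(x$U_high), length(x$U_low), sum(is.na(x$M))))
  invisible(x)
}

# deterministic ascending rank: ties by label, NA last
rank_by_value <- function(value, label) {
  ord <- order(is.na(value), value, label)
  r <- integer(length(value))
  r[ord] <- seq_along(value)
  r
}

#' Threshold selection from the empirical distribution of scaled MHT
#'
#' Builds the ECDF of the scores and returns its critical point,
#' operationalized as the knee: the abscissa maximizing the perpendicular
#' distance from the ECDF curve to the chord joining its endpoints. Errors
#' when the ECDF is degenerate (all scores equal, or indistinguishable
#' from the chord), in which case a manual threshold should be supplied.
#'
#' @param scores numeric vector of scaled mean hitting times (one per
#'   candidate gene); at least 10 values.
#' @return The selected threshold.
#' @export
select_theta_r <- function(scores) {
  x <- sort(scores[is.finite(scores)])
  n <- length(x)
  if (n < 10) stop("need at least 10 finite scores to select theta_R")
  if (x[n] == x[1])
    stop("degenerate score distribution; supply theta_R manually")
  F <- seq_len(n) / n
  dx <- x[n] - x[1]; dF <- F[n] - F[1]
  d <- abs(dx * (F - F[1]) - dF * (x - x[1])) / sqrt(dx^2 + dF^2)
  if (max(d) < 1e-3)
    stop("ECDF indistinguishable from its chord (uniform scores); ",
         "supply theta_R manually")
  x[which.max(d)]
}

#' Prioritize candidate genes for a target phenotype
#'
#' The main inference routine. Computes the scaled mean hitting time
#' MHT(g, \{p\}) for every gene and ranks it ascending (`rank`); selects
#' or accepts the prioritization threshold `theta_r`; scores the
#' modularity of the adjacency set and partitions it into `U_high` /
#' `U_low` at `theta_m`; computes the scaled conditional mean hitting time
#' of every gene to `U_high` avoiding `U_low` and ranks it
#' (`rank_prime`); and flags as credible the prioritized genes whose rank
#' strictly improves (`rank / rank_prime > 1`).
#'
#' Degenerate cases are carried in `status`: with an empty `U_high` no
#' credible set exists; with an empty `U_low` the second ranking falls
#' back to the unconditional hitting time to `U_high`.
#'
#' @param net a `cipher_hetnet`.
#' @param phenotype target phenotype label.
#' @param theta_m modularity threshold, default 0.3.
#' @param theta_r `"auto"` (ECDF knee via [select_theta_r()]) or a numeric
#'   threshold in (0, 1\].
#' @return A `cipher_hit` object: per-gene table (`gene`, `mht`, `rank`,
#'   `cmht_high`, `rank_prime`, `ratio`, `prioritized`, `credible`), the
#'   adjacency partition, resolved thresholds and status.
#' @export
cipher_hit <- function(net, phenotype, theta_m = 0.3, theta_r = "auto") {
  stopifnot(inherits(net, "cipher_hetnet"))
  pid <- resolve_node(net, phenotype, "phenotype")
  P <- transition_matrix(net)
  gene_rows <- net$nodes$kind == "gene"
  gids <- net$nodes$id[gene_rows]
  glabs <- net$nodes$label[gene_rows]

  mh <- mean_hitting_time(P, pid)
  mht <- as.numeric(mh$scaled[gids])
  rank <- rank_by_value(mht, glabs)

  theta_r_mode <- if (identical(theta_r, "auto")) "auto" else "manual"
  if (theta_r_mode == "auto") theta_r <- select_theta_r(mht)
  stopifnot(is.numeric(theta_r), theta_r > 0, theta_r <= 1)
  prioritized <- !is.na(mht) & mht < theta_r

  U <- adjacency_set(net, phenotype)$id
  M <- modularity_from_P(P, U, pid)
  part <- partition_from_M(M, theta_m, phenotype = phenotype)

  status <- "ok"
  cmht <- rep(NA_real_, length(gids))
  if (length(part$U_high) == 0) {
    status <- "no_credible_set: U_high empty"
  } else if (length(part$U_low) == 0) {
    status <- "degenerate: U_low empty, unconditional MHT to U_high used"
    ch <- mean_hitting_time(P, part$U_high)
    cmht <- as.numeric(ch$scaled[gids])
  } else {
    ch <- conditional_mht(P, target = part$U_high, avoid = part$U_low)
    cmht <- as.numeric(ch$scaled[gids])
  }
  rank_prime <- if (length(part$U_high) > 0)
    rank_by_value(cmht, glabs) else rep(NA_integer_, length(gids))
  ratio <- rank / rank_prime
  credible <- prioritized & !is.na(ratio) & !is.na(cmht) & ratio > 1

  genes <- data.frame(gene = glabs, mht = mht, rank = rank,
                      cmht_high = cmht, rank_prime = rank_prime,
                      ratio = ratio, prioritized = prioritized,
                      credible = credible, stringsAsFactors = FALSE)
  genes <- genes[order(genes$rank), ]
  rownames(genes) <- NULL
  structure(list(phenotype = phenotype, genes = genes, partition = part,
                 theta_m = theta_m, theta_r = theta_r,
                 theta_r_mode = theta_r_mode, status = status),
            class = "cipher_hit")
}

#' @export
print.cipher_hit <- function(x, ...) {
  cat("CIPHER-HIT prioritization for phenotype", x$phenotype, "\n")
  cat(sprintf("  theta_r = %.4g (%s), theta_m = %.2f\n",
              x$theta_r, x$theta_r_mode, x$theta_m))
  cat(sprintf("  %d candidate genes: %d prioritized, %d credible\n",
              nrow(x$genes), sum(x$genes$prioritized),
              sum(x$genes$credible)))
  cat(sprintf("  adjacency: |U_high| = %d, |U_low| = %d",
              length(x$partition$U_high), length(x$partition$U_low)))
  if (x$status != "ok") cat("  [", x$status, "]")
  cat("\n  top genes:\n")
  print(utils::head(x$genes, 5), digits = 4)
  invisible(x)
}

#' @export
summary.cipher_hit <- function(object, ...) {
  x <- object
  res <- list(phenotype = x$phenotype,
              n_genes = nrow(x$genes),
              n_prioritized = sum(x$genes$prioritized),
              n_credible = sum(x$genes$credible),
              theta_r = x$theta_r, theta_m = x$theta_m,
              U_high = x$partition$U_high, U_low = x$partition$U_low,
              M = x$partition$M, status = x$status)
  class(res) <- "summary.cipher_hit"
  res
}

#' @export
print.summary.cipher_hit <- function(x, ...) {
  cat("Prioritization summary:", x$phenotype, "\n")
  cat(sprintf("  genes %d | prioritized %d | credible %d | theta_r %.4g | theta_m %.2f\n",
              x$n_genes, x$n_prioritized, x$n_credible, x$theta_r,
              x$theta_m))
  cat("  modularity levels:\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Plot the score ECDF and the selected threshold
#'
#' Empirical distribution of scaled MHT(g, \{p\}) over all candidate
#' genes, with the resolved `theta_r` marked; the knee of this curve is
#' the automatic threshold.
#'
#' @param x a `cipher_hit` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cipher_hit <- function(x, ...) {
  s <- sort(x$genes$mht)
  graphics::plot(s, seq_along(s) / length(s), type = "s",
                 xlab = "scaled MHT(g, {p})", ylab = "ECDF",
                 main = paste("Score distribution:", x$phenotype), ...)
  graphics::abline(v = x$theta_r, lty = 2, col = "red")
  graphics::mtext(sprintf("theta_r = %.3f", x$theta_r), side = 3,
                  line = 0, adj = 1, cex = 0.8)
  invisible(x)
}

#' Rank candidate genes by scaled mean hitting time only
#'
#' The first stage of [cipher_hit()]: scaled MHT(g, {p}) for every gene
#' with ascending ranks, optionally flagging genes below a prioritization
#' threshold, without the modularity partition or credibility analysis.
#'
#' @inheritParams cipher_hit
#' @param theta_r optional numeric threshold; genes with `mht < theta_r`
#'   are flagged `prioritized`.
#' @return Data frame with columns `gene`, `mht`, `rank` (and
#'   `prioritized` when `theta_r` is given).
#' @export
rank_candidates <- function(net, phenotype, theta_r = NULL) {
  pid <- resolve_node(net, phenotype, "phenotype")
  P <- transition_matrix(net)
  gene_rows <- net$nodes$kind == "gene"
  mh <- mean_hitting_time(P, pid)
  mht <- as.numeric(mh$scaled[net$nodes$id[gene_rows]])
  out <- data.frame(gene = net$nodes$label[gene_rows], mht = mht,
                    rank = rank_by_value(mht, net$nodes$label[gene_rows]),
                    stringsAsFactors = FALSE)
  if (!is.null(theta_r)) out$prioritized <- !is.na(out$mht) & out$mht < theta_r
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}
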