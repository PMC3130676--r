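# Genome-wide leave-one-out cross-validation with ROC summaries, and the
# random-walk-with-restart baseline used as a comparison curve.

# Rebuild W and P after dropping one association edge. Association weights
# are recomputed (the per-endpoint association counts change). Nodes whose
# degree drops to zero are excluded from the walk; if the held-out gene or
# the phenotype is among them the case is censored.
drop_association <- function(net, p_label, g_label) {
  ed <- net$sub$association$edges
  hit <- which(ed$phenotype == p_label & ed$gene == g_label)
  if (length(hit) != 1) stop("association not found: ", p_label, " - ", g_label)
  asub <- new_assoc_subnet(ed$phenotype[-hit], ed$gene[-hit])
  asub <- suppressMessages(
    assign_association_weights(net$sub$gene, net$sub$phenotype, asub))

  nodes <- net$nodes
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  in_net <- function(kind, lab) paste(substr(kind, 1, 1), lab, sep = ":") %in% nodes$id
  ge <- net$sub$gene$edges
  ge <- ge[in_net("gene", ge$from) & in_net("gene", ge$to), ]
  pe <- net$sub$phenotype$edges
  pe <- pe[in_net("phenotype", pe$from) & in_net("phenotype", pe$to), ]
  ae <- asub$edges
  ae <- ae[in_net("gene", ae$gene) & in_net("phenotype", ae$phenotype), ]
  nid <- function(k1, x) if (length(x) == 0) integer(0) else
    idx[paste(k1, x, sep = ":")]
  i <- c(nid("g", ge$from), nid("p", pe$from), nid("g", ae$gene))
  j <- c(nid("g", ge$to), nid("p", pe$to), nid("p", ae$phenotype))
  w <- c(ge$weight, pe$weight, ae$weight)
  n <- nrow(nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n),
                            dimnames = list(nodes$id, nodes$id))
  deg <- Matrix::rowSums(W)
  keep <- deg > 0
  P <- W[keep, keep, drop = FALSE] / deg[keep]
  list(P = P, W = W, kept = nodes$id[keep])
}

# Score all genes under one inference mode on a (possibly modified)
# transition matrix. Returns scaled scores named by gene id plus flags.
mode_scores <- function(P, pid, gids, mode, theta_m, restart_rate = 0.7) {
  fallback <- FALSE
  present <- intersect(gids, rownames(P))
  score <- stats::setNames(rep(NA_real_, length(gids)), gids)
  if (!(pid %in% rownames(P)))
    return(list(score = score, fallback = FALSE, censored_net = TRUE))
  if (mode == "all_adjacent") {
    mh <- mean_hitting_time(P, pid)
    score[present] <- mh$scaled[present]
  } else if (mode == "rwr_baseline") {
    rw <- rwr_scores(P, pid, restart_rate)
    v <- rw[present]
    # convert to a [0,1] loss: rank percentile, best (highest mass) -> 0
    r <- rank_by_value(-v, present)
    score[present] <- (r - 1) / max(1, length(present) - 1)
  } else {
    U <- rownames(P)[which(P[pid, ] > 0)]
    M <- modularity_from_P(P, U, pid)
    part <- partition_from_M(M, theta_m)
    subset <- if (mode == "modular_high") part$U_high else part$U_low
    other <- setdiff(U, subset)
    if (length(subset) == 0 || length(other) == 0) {
      # trivial partition: no modularity contrast exists, so neither
      # partition mode makes a prediction (symmetric for both modes) and
      # the case fails at every threshold
      fallback <- TRUE
    } else {
      ch <- conditional_mht(P, target = subset, avoid = other)
      score[present] <- ch$scaled[present]
    }
  }
  list(score = score, fallback = fallback, censored_net = FALSE)
}

#' Leave-one-out cross-validation of disease-gene recovery
#'
#' For every gene-phenotype association (each association is its own
#' validation sample): remove that edge, recompute the association weights
#' and the walk, re-score all genes under each requested inference mode,
#' and record the held-out gene's scaled score and rank. A held-out score
#' below the threshold counts as a successful prediction; sweeping the
#' threshold over `theta_grid` yields the ROC, whose abscissa is the
#' threshold itself.
#'
#' Modes: `"all_adjacent"` (scaled MHT to the phenotype),
#' `"modular_high"` / `"low_only"` (scaled conditional MHT to the
#' modularity partition's U_high / U_low, avoiding the complement; when
#' the chosen subset is empty the score falls back to the plain MHT to
#' the phenotype, identically for both modes, and the case is flagged),
#' and `"rwr_baseline"` (random walk with restart, rank-percentile loss).
#'
#' @param net a `cipher_hetnet`.
#' @param modes character vector of inference modes.
#' @param theta_m modularity threshold for the partition modes.
#' @param theta_grid thresholds for the ROC sweep.
#' @param phenotypes restrict validation to these phenotype labels
#'   (default: all with associations).
#' @param max_cases optional subsample size of validation cases.
#' @param seed seed for the subsample (required with `max_cases`).
#' @param restart_rate restart probability of the RWR baseline.
#' @return A `cipher_cv` object: per-case table and per-mode ROC with AUC.
#' @export
loocv <- function(net, modes = "all_adjacent", theta_m = 0.3,
                  theta_grid = seq(0, 1, by = 0.01), phenotypes = NULL,
                  max_cases = NULL, seed = NULL, restart_rate = 0.7) {
  valid <- c("all_adjacent", "modular_high", "low_only", "rwr_baseline")
  stopifnot(all(modes %in% valid))
  ed <- net$sub$association$edges
  keep <- paste("g", ed$gene, sep = ":") %in% net$nodes$id &
    paste("p", ed$phenotype, sep = ":") %in% net$nodes$id
  ed <- ed[keep, c("phenotype", "gene")]
  if (!is.null(phenotypes)) ed <- ed[ed$phenotype %in% phenotypes, ]
  if (nrow(ed) == 0) stop("no associations to validate")
  if (!is.null(max_cases) && max_cases < nrow(ed)) {
    if (is.null(seed)) stop("seed required when subsampling cases")
    set.seed(seed)
    ed <- ed[sort(sample.int(nrow(ed), max_cases)), ]
  }
  gids <- net$nodes$id[net$nodes$kind == "gene"]
  glabs <- net$nodes$label[net$nodes$kind == "gene"]

  rows <- vector("list", nrow(ed) * length(modes))
  k <- 0L
  for (ci in seq_len(nrow(ed))) {
    p_label <- ed$phenotype[ci]; g_label <- ed$gene[ci]
    pid <- paste("p", p_label, sep = ":")
    gid <- paste("g", g_label, sep = ":")
    mod <- drop_association(net, p_label, g_label)
    censored <- !(gid %in% mod$kept) || !(pid %in% mod$kept)
    for (mode in modes) {
      k <- k + 1L
      if (censored) {
        rows[[k]] <- data.frame(phenotype = p_label, gene = g_label,
                                mode = mode, score = NA_real_,
                                rank = NA_integer_, censored = TRUE,
                                fallback = FALSE)
        next
      }
      ms <- mode_scores(mod$P, pid, gids, mode, theta_m, restart_rate)
      sc <- ms$score
      r <- rank_by_value(as.numeric(sc), glabs)
      gi <- match(gid, gids)
      rows[[k]] <- data.frame(phenotype = p_label, gene = g_label,
                              mode = mode,
                              score = as.numeric(sc[gid]),
                              rank = r[gi],
                              censored = ms$censored_net,
                              fallback = ms$fallback)
    }
  }
  cases <- do.call(rbind, rows)
  roc <- lapply(stats::setNames(modes, modes), function(m) {
    sub <- cases[cases$mode == m, ]
    roc_curve(ifelse(sub$censored, NA, sub$score), theta_grid)
  })
  structure(list(cases = cases, roc = roc, theta_m = theta_m,
                 modes = modes), class = "cipher_cv")
}

#' ROC curve over a threshold grid
#'
#' Sensitivity at threshold `theta` is the fraction of held-out scores
#' strictly below `theta` (at the grid maximum `theta >= 1` the boundary
#' is inclusive, so every finite scaled score counts); censored cases
#' (`NA`) fail at every threshold. The abscissa (1 - specificity) is the
#' threshold itself, matching a sweep of the prioritization cutoff; the
#' AUC is the trapezoid area of sensitivity over it.
#'
#' @param scores numeric held-out scores (`NA` = censored).
#' @param theta_grid increasing thresholds in \[0, 1\].
#' @return A `cipher_roc` object: data frame (`theta`, `sensitivity`,
#'   `one_minus_specificity`) and `auc`.
#' @export
roc_curve <- function(scores, theta_grid = seq(0, 1, by = 0.01)) {
  if (length(scores) == 0) stop("no validation cases")
  theta_grid <- sort(theta_grid)
  sens <- vapply(theta_grid, function(th) {
    ok <- !is.na(scores) & (scores < th | (th >= 1 & scores <= th))
    mean(ok)
  }, numeric(1))
  df <- data.frame(theta = theta_grid, sensitivity = sens,
                   one_minus_specificity = theta_grid)
  auc <- sum(diff(theta_grid) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(curve = df, auc = auc, n = sum(!is.na(scores)),
                 n_censored = sum(is.na(scores))), class = "cipher_roc")
}

#' @export
print.cipher_roc <- function(x, ...) {
  cat(sprintf("ROC over %d threshold(s): AUC = %.4f (%d cases, %d censored)\n",
              nrow(x$curve), x$auc, x$n + x$n_censored, x$n_censored))
  invisible(x)
}

#' @export
print.cipher_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation:",
      length(unique(paste(x$cases$phenotype, x$cases$gene))), "cases\n")
  for (m in x$modes)
    cat(sprintf("  %-13s AUC = %.4f\n", m, x$roc[[m]]$auc))
  invisible(x)
}

#' @export
plot.cipher_cv <- function(x, ...) {
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity (threshold)",
                 ylab = "sensitivity", main = "LOOCV ROC", ...)
  graphics::abline(0, 1, col = "grey", lty = 3)
  for (i in seq_along(x$modes)) {
    cv <- x$roc[[x$modes[i]]]$curve
    graphics::lines(cv$one_minus_specificity, cv$sensitivity, col = i,
                    lwd = 2, lty = if (x$modes[i] == "modular_high") 1 else 2)
  }
  graphics::legend("bottomright", legend = x$modes,
                   col = seq_along(x$modes), lwd = 2, cex = 0.8)
  invisible(x)
}

rwr_scores <- function(P, pid, restart_rate = 0.7, tol = 1e-10,
                       max_iter = 10000) {
  n <- nrow(P)
  e <- stats::setNames(numeric(n), rownames(P))
  e[pid] <- 1
  x <- e
  Pt <- Matrix::t(P)
  for (it in seq_len(max_iter)) {
    x_new <- restart_rate * e + (1 - restart_rate) * as.numeric(Pt %*% x)
    names(x_new) <- names(x)
    if (sum(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  stop("RWR failed to converge in ", max_iter, " iterations")
}

#' Random-walk-with-restart baseline scores
#'
#' Stationary distribution of the restart-at-`p` walk on the same
#' transition matrix; used only as a comparison method (it requires the
#' restart-rate parameter that hitting-time inference avoids).
#'
#' @param net a `cipher_hetnet`.
#' @param p phenotype label.
#' @param restart_rate restart probability in (0, 1), default 0.7.
#' @return Named probability vector over all nodes (sums to 1).
#' @export
rwr_baseline <- function(net, p, restart_rate = 0.7) {
  stopifnot(restart_rate > 0, restart_rate < 1)
  pid <- resolve_node(net, p, "phenotype")
  rwr_scores(transition_matrix(net), pid, restart_rate)
}
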