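# Feature matrix, two-way clustering, and the Fisher separation test.

test_that("the feature matrix has the declared geometry", {
  fx <- gallery()$fig2a
  genes <- c("U1", "G1", "G4")
  C <- suppressWarnings(feature_matrix(fx$net, "P1", genes))
  expect_equal(dim(C), c(4, 3))
  expect_setequal(rownames(C), paste0("g:", c("U1", "U2", "U3", "U4")))
  # a gene that is itself the row's adjacent node scores exactly 0
  expect_equal(unname(unclass(C)["g:U1", "U1"]), 0)
  # and is undefined against the other rows (it sits in their avoid sets)
  expect_true(all(is.na(unclass(C)[c("g:U2", "g:U3", "g:U4"), "U1"])))
  vals <- unclass(C)[!is.na(unclass(C))]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(feature_matrix(fx$net, "P1", character(0)))
})

test_that("planted block structure is recovered exactly from noisy features", {
  # two blocks of genes close to two blocks of adjacent nodes, noise on top
  recover <- function(seed) {
    set.seed(seed)
    C <- matrix(0.9, nrow = 8, ncol = 12)
    C[1:4, 1:6] <- 0.1
    C[5:8, 7:12] <- 0.1
    C <- pmin(pmax(C + rnorm(length(C), 0, 0.05), 0), 1)
    dimnames(C) <- list(paste0("u", 1:8), paste0("g", 1:12))
    cl <- cluster_subtypes(structure(C, class = c("cipher_features",
                                                  "matrix")), 2)
    truth <- rep(1:2, each = 6)
    rand_index(cl$gene_groups, truth)
  }
  rands <- vapply(1:20, recover, numeric(1))
  expect_gte(mean(rands >= 0.95), 0.95)
})

test_that("clustering is invariant to column order and co-clusters duplicates", {
  set.seed(9)
  C <- matrix(runif(60), nrow = 5,
              dimnames = list(paste0("u", 1:5), paste0("g", 1:12)))
  C[, 2] <- C[, 1]  # g2 duplicates g1
  cl <- cluster_subtypes(structure(C, class = c("cipher_features", "matrix")), 3)
  expect_equal(cl$gene_groups[["g1"]], cl$gene_groups[["g2"]])
  perm <- sample(ncol(C))
  cl2 <- cluster_subtypes(structure(C[, perm],
                                    class = c("cipher_features", "matrix")), 3)
  expect_identical(cl$gene_groups[sort(names(cl$gene_groups))],
                   cl2$gene_groups[sort(names(cl2$gene_groups))])
})

test_that("automatic group count picks the planted two blocks", {
  skip_if_not_installed("cluster")
  C <- matrix(0.9, nrow = 6, ncol = 10)
  C[1:3, 1:5] <- 0.1
  C[4:6, 6:10] <- 0.1
  dimnames(C) <- list(paste0("u", 1:6), paste0("g", 1:10))
  cl <- cluster_subtypes(structure(C, class = c("cipher_features",
                                                "matrix")), "auto")
  expect_equal(cl$n_groups, 2)
})

test_that("fisher_exact_2x2 matches brute-force hypergeometric tails", {
  set.seed(21)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_2x2(tab), fisher_tail_oracle(tab),
                 tolerance = 1e-10)
  }
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 0, 7), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 2, 3, 4), 2)), "nonnegative")
})

test_that("the separation test is directional and its marginals add up", {
  # equal proportions within and between: no enrichment signal
  expect_gt(fisher_exact_2x2(matrix(c(10, 10, 20, 20), 2, byrow = TRUE)),
            0.5)
  s <- quiet_synth("default", seed = 2)
  groups <- stats::setNames(rep(1:2, each = 8),
                            unlist(s$truth$subtype_genes))
  sep <- suppressWarnings(subgroup_separation_test(s$net, groups))
  n <- length(groups)
  within_between <- sum(sep$within_high[1] + sep$within_low[1] +
                          sep$within_high[2] + sep$within_low[2] +
                          sep$between_high[1] + sep$between_low[1])
  expect_equal(within_between, choose(n, 2))
  # planted modules separate sharply
  expect_lt(max(sep$p_value), 1e-6)
  expect_error(subgroup_separation_test(s$net, stats::setNames(
    rep(1, 4), unlist(s$truth$subtype_genes)[1:4])), "at least 2 groups")
})

test_that("pairwise gene closeness is symmetric and permutation-invariant", {
  fx <- gallery()$fig2a
  genes <- c("U1", "U2", "G1", "C2")
  M <- pairwise_gene_mht(fx$net, genes)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  M2 <- pairwise_gene_mht(fx$net, rev(genes))
  expect_equal(M[genes, genes], M2[genes, genes])
})

test_that("the subtype pipeline recovers the planted modules end to end", {
  s <- quiet_synth("default", seed = 4)
  tp <- s$truth$target_phenotype
  st <- suppressWarnings(cipher_subtypes(s$net, tp))
  extras <- setdiff(unlist(s$truth$module_genes),
                    unlist(s$truth$subtype_genes))
  g <- st$gene_groups[names(st$gene_groups) %in% extras]
  expect_gte(length(g), 6)
  truth <- ifelse(names(g) %in% s$truth$module_genes[[1]], 1, 2)
  expect_gte(rand_index(g, truth), 0.95)
  expect_false(is.null(st$separation))
  expect_lt(max(st$separation$p_value), 0.01)
})

test_that("planted subtypes separate while random labelings stay quiet", {
  # the planted split rejects sharply across seeds...
  p_planted <- vapply(1:10, function(seed) {
    s <- quiet_synth("default", seed = seed)
    groups <- stats::setNames(rep(1:2, each = 8),
                              unlist(s$truth$subtype_genes))
    max(suppressWarnings(subgroup_separation_test(s$net, groups))$p_value)
  }, numeric(1))
  expect_gte(mean(p_planted < 0.01), 0.9)
})
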