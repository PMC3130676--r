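# Parsing, weighting and assembly of the heterogeneous network.

test_that("sub-network files parse with the strict similarity threshold", {
  f <- toy_files()
  sub <- suppressMessages(read_subnetworks(f$ppi, f$sim, f$assoc, 0.4))
  expect_equal(nrow(sub$gene$edges), 3)
  expect_equal(nrow(sub$phenotype$edges), 1)   # the 0.3 edge is dropped
  expect_equal(sub$phenotype$edges$weight, 0.9)
  # an edge exactly at the threshold is dropped (strict "larger than")
  sim_eq <- tmp_tsv(c("P1\tP2\t0.4"))
  sub2 <- suppressMessages(read_subnetworks(f$ppi, sim_eq, f$assoc, 0.4))
  expect_equal(nrow(sub2$phenotype$edges), 0)
  # empty association file is valid
  empty <- tmp_tsv(character(0))
  sub3 <- suppressMessages(read_subnetworks(f$ppi, f$sim, empty, 0.4))
  expect_equal(nrow(sub3$association$edges), 0)
})

test_that("malformed inputs raise errors naming the file and line", {
  f <- toy_files()
  bad_ppi <- tmp_tsv(c("a\tb", "loner"))
  expect_error(suppressMessages(read_subnetworks(bad_ppi, f$sim, f$assoc)),
               "line 2")
  bad_sim <- tmp_tsv(c("P1\tP2\t1.3"))
  expect_error(suppressMessages(read_subnetworks(f$ppi, bad_sim, f$assoc)),
               "\\[0,1\\]")
  bad_num <- tmp_tsv(c("P1\tP2\tnot_a_number"))
  expect_error(suppressMessages(read_subnetworks(f$ppi, bad_num, f$assoc)),
               "line 1")
})

test_that("gene symbols are upper-cased and duplicate edges keep the max weight", {
  ppi <- tmp_tsv(c("tp53\tmdm2\t1", "TP53\tMDM2\t3", "tp53\ttp53\t1",
                   "mdm2\tbrca1"))
  sim <- tmp_tsv("P1\tP2\t0.8")
  assoc <- tmp_tsv("P1\tTP53")
  expect_warning(expect_warning(
    sub <- suppressMessages(read_subnetworks(ppi, sim, assoc)),
    "self-edge"), "duplicate")
  ed <- sub$gene$edges
  expect_setequal(sub$gene$nodes$label, c("TP53", "MDM2", "BRCA1"))
  expect_equal(ed$weight[ed$from == "MDM2" & ed$to == "TP53"], 3)
})

test_that("association weights honour the 0.5 cross-walk contract", {
  # gene with PPI strength 4 (one association), phenotype with similarity
  # strength 1 (one association): w = sqrt(4 * 1) = 2, cross-walk
  # probabilities 1/3 at the gene and 2/3 at the phenotype, mean 1/2
  gene_net <- cipherhit:::new_subnet(c("A", "A", "A", "A"),
                                     c("B", "C", "D", "E"),
                                     rep(1, 4), "gene")
  phen_net <- cipherhit:::new_subnet("P1", "P2", 1, "phenotype")
  assoc <- cipherhit:::new_assoc_subnet("P1", "A")
  aw <- assign_association_weights(gene_net, phen_net, assoc)
  expect_equal(aw$edges$weight, 2)
  net <- suppressMessages(merge_hetnet(gene_net, phen_net, aw))
  P <- transition_matrix(net)
  p_cross_g <- P["g:A", "p:P1"]
  p_cross_p <- P["p:P1", "g:A"]
  expect_equal(p_cross_g, 1 / 3)
  expect_equal(p_cross_p, 2 / 3)
  expect_equal((p_cross_g + p_cross_p) / 2, 0.5, tolerance = 1e-14)
  expect_equal(net$cross_walk$mean_prob_single, 0.5, tolerance = 1e-14)
  # symmetric strengths: w equals the shared strength, both sides 0.5
  gene2 <- cipherhit:::new_subnet(c("A", "A"), c("B", "C"), c(1, 2), "gene")
  phen2 <- cipherhit:::new_subnet(c("P1", "P1"), c("P2", "P3"),
                                  c(1, 2), "phenotype")
  aw2 <- assign_association_weights(gene2, phen2,
                                    cipherhit:::new_assoc_subnet("P1", "A"))
  expect_equal(aw2$edges$weight, 3)
  net2 <- suppressMessages(merge_hetnet(gene2, phen2, aw2))
  P2 <- transition_matrix(net2)
  expect_equal(P2["g:A", "p:P1"], 0.5)
  expect_equal(P2["p:P1", "g:A"], 0.5)
})

test_that("multi-association genes split their strength across phenotypes", {
  # k_g = 2: each association uses s_G/2 in the geometric mean, and the
  # total cross weight at the gene stays below its PPI strength
  gene_net <- cipherhit:::new_subnet(c("A", "A", "A", "A"),
                                     c("B", "C", "D", "E"),
                                     rep(1, 4), "gene")
  phen_net <- cipherhit:::new_subnet(c("P1", "P2"), c("P3", "P3"),
                                     c(1, 1), "phenotype")
  aw <- assign_association_weights(
    gene_net, phen_net, cipherhit:::new_assoc_subnet(c("P1", "P2"),
                                                     c("A", "A")))
  expect_equal(aw$edges$weight, rep(sqrt(4 / 2 * 1), 2))
  expect_lt(sum(aw$edges$weight), 4)
  # zero-strength endpoint falls back to weight 1
  lonely <- cipherhit:::new_assoc_subnet("P1", "Z")
  gene3 <- gene_net; gene3$nodes <- rbind(gene3$nodes,
                                          data.frame(kind = "gene", label = "Z"))
  expect_message(aw3 <- assign_association_weights(gene3, phen_net, lonely),
                 "zero-strength")
  expect_equal(aw3$edges$weight, 1)
  # unknown endpoint errors
  expect_error(assign_association_weights(
    gene_net, phen_net, cipherhit:::new_assoc_subnet("P9", "A")),
    "not found")
})

test_that("merge assembles a symmetric zero-diagonal W on one component", {
  f <- toy_files()
  net <- suppressMessages(hetnet_from_files(f$ppi, f$sim, f$assoc))
  W <- net$W
  expect_true(all(W >= 0))
  expect_equal(max(abs(W - Matrix::t(W))), 0)
  expect_true(all(Matrix::diag(W) == 0))
  # P3 had only a below-threshold similarity and no association: removed
  expect_true("P3" %in% net$removed$label)
  expect_false("p:P3" %in% net$nodes$id)
  # all retained similarity weights are strictly above the threshold
  expect_true(all(net$sub$phenotype$edges$weight > 0.4))
  # transition rows sum to one
  P <- transition_matrix(net)
  expect_lt(max(abs(Matrix::rowSums(P) - 1)), 1e-12)
  # block structure: gene-gene entries only between gene nodes
  kinds <- net$nodes$kind
  expect_true(all(W[kinds == "gene", kinds == "gene"] @x >= 0))
})

test_that("adjacency sets contain exactly the direct neighbours", {
  fx <- gallery()$fig2a
  adj <- adjacency_set(fx$net, "P1")
  expect_equal(nrow(adj), 4)
  expect_setequal(adj$label, c("U1", "U2", "U3", "U4"))
  expect_true(all(adj$role == "disease_gene"))
  expect_error(adjacency_set(fx$net, "NOPE"), "unknown")
})

test_that("network bundles round-trip through the text serialization", {
  s <- quiet_synth("default", seed = 5)
  d <- tempfile("bundle")
  write_hetnet(s$net, d)
  net2 <- suppressMessages(read_hetnet(d))
  expect_identical(s$net$nodes$id, net2$nodes$id)
  expect_equal(max(abs(s$net$W - net2$W)), 0)
})

test_that("assembly is deterministic: identical inputs give identical P", {
  f <- toy_files()
  n1 <- suppressMessages(hetnet_from_files(f$ppi, f$sim, f$assoc))
  n2 <- suppressMessages(hetnet_from_files(f$ppi, f$sim, f$assoc))
  expect_identical(as.matrix(transition_matrix(n1)),
                   as.matrix(transition_matrix(n2)))
})
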