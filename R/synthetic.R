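# Seeded generator of heterogeneous phenotype-gene networks with planted
# disease modules and subtypes, plus the small deterministic fixture graphs
# used throughout the test-suite.

#' Specification of a synthetic heterogeneous network
#'
#' Defines the generative conditions: a planted-partition PPI layer, a
#' clustered phenotype-similarity layer (truncated-normal scores so the 0.4
#' retention threshold separates the two score populations imperfectly),
#' and associations wiring each planted subtype's gene module to its own
#' companion phenotypes of the target phenotype.
#'
#' Presets: `"default"` (alias `"two-subtype"`) plants two 8-gene subtype
#' modules around the target phenotype; `"null"` keeps the same sizes but
#' ablates the planted structure entirely (module edge probability equal to
#' background and association wiring randomized), giving the calibration
#' condition under which subtype separation should not be detected.
#'
#' @param preset `"default"`, `"two-subtype"` or `"null"`.
#' @param seed mandatory integer seed; all randomness flows through it.
#' @param n_genes,n_phenotypes network size.
#' @param p_background,p_within background / within-module PPI edge
#'   probabilities.
#' @param sim_background_mean,sim_within_mean,sim_sd phenotype-similarity
#'   score distribution (normal, clipped to \[0, 1\]).
#' @param phenotype_cluster_size phenotypes per similarity cluster.
#' @param n_subtypes,genes_per_subtype planted subtype structure of the
#'   target phenotype: each subtype contributes `genes_per_subtype` disease
#'   genes (associated with the target) drawn from its own dense PPI
#'   module of `module_size` genes.
#' @param module_size genes per planted module (at least
#'   `genes_per_subtype + genes_per_companion`); the module members beyond
#'   the disease genes are not associated with the target.
#' @param companions_per_subtype companion phenotypes (drawn from the
#'   target's similarity cluster) wired to each subtype's module.
#' @param genes_per_companion module genes associated to each companion;
#'   these are taken from the non-disease members of the module, so the
#'   companion is their only association (the single-association geometry
#'   under which the cross-walk probability is 0.5 at both endpoints).
#' @param n_noise_disease_genes extra disease genes of the target drawn at
#'   random outside the planted modules (the loosely-attached adjacent
#'   nodes).
#' @param assoc_per_phenotype mean association count of background
#'   phenotypes (each draws uniformly from `1..assoc_per_phenotype + 1`
#'   genes, so single-association pairs occur).
#' @return A `cipher_synth_spec` list.
#' @export
synthetic_spec <- function(preset = c("default", "two-subtype", "null"),
                           seed,
                           n_genes = 200, n_phenotypes = 40,
                           p_background = 0.01, p_within = 0.9,
                           sim_background_mean = 0.2,
                           sim_within_mean = 0.6, sim_sd = 0.1,
                           phenotype_cluster_size = 10,
                           n_subtypes = 2, genes_per_subtype = 8,
                           module_size = 12,
                           companions_per_subtype = 4,
                           genes_per_companion = 2,
                           n_noise_disease_genes = 4,
                           assoc_per_phenotype = 2) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(p_background >= 0, p_background <= 1,
            p_within >= 0, p_within <= 1,
            module_size > genes_per_subtype,
            1 + n_subtypes * companions_per_subtype <= phenotype_cluster_size)
  planted <- preset != "null"
  if (!planted) p_within <- p_background
  if (planted && p_within <= p_background)
    stop("within-module edge probability must exceed background")
  structure(list(preset = preset, seed = as.integer(seed),
                 n_genes = n_genes, n_phenotypes = n_phenotypes,
                 p_background = p_background, p_within = p_within,
                 sim_background_mean = sim_background_mean,
                 sim_within_mean = sim_within_mean, sim_sd = sim_sd,
                 phenotype_cluster_size = phenotype_cluster_size,
                 n_subtypes = n_subtypes,
                 genes_per_subtype = genes_per_subtype,
                 module_size = module_size,
                 companions_per_subtype = companions_per_subtype,
                 genes_per_companion = genes_per_companion,
                 n_noise_disease_genes = n_noise_disease_genes,
                 assoc_per_phenotype = assoc_per_phenotype,
                 planted = planted),
            class = "cipher_synth_spec")
}

#' Generate a synthetic heterogeneous network
#'
#' Samples the three sub-network files described by a [synthetic_spec()]
#' and writes them (plus the ground truth) to `dir`. Generation is
#' deterministic given the spec: the same spec produces byte-identical
#' files. If the target phenotype ends up disconnected from the main
#' component, the draw is retried (up to 10 times) by continuing the same
#' random stream.
#'
#' @param spec a `cipher_synth_spec`.
#' @param dir output directory (created if needed).
#' @return List with `files` (paths of `ppi.tsv`,
#'   `phenotype_similarity.tsv`, `associations.tsv`, `ground_truth.json`)
#'   and `truth` (planted subtype membership, companions, target).
#' @export
generate_network <- function(spec, dir = tempfile("synthnet")) {
  stopifnot(inherits(spec, "cipher_synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  for (attempt in 1:10) {
    draw <- draw_network(spec)
    if (draw$target_connected) break
    if (attempt == 10)
      stop("target phenotype disconnected after 10 attempts; revise spec")
  }
  files <- list(
    ppi = file.path(dir, "ppi.tsv"),
    phensim = file.path(dir, "phenotype_similarity.tsv"),
    assoc = file.path(dir, "associations.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  hdr <- sprintf("# cipherhit synthetic network, preset=%s seed=%d",
                 spec$preset, spec$seed)
  write_tsv_with_header(draw$ppi, files$ppi, hdr)
  write_tsv_with_header(draw$sim, files$phensim, hdr)
  write_tsv_with_header(draw$assoc, files$assoc, hdr)
  jsonlite::write_json(draw$truth, files$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(files = files, truth = draw$truth)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

# One draw from the generative model (uses the current RNG stream).
draw_network <- function(spec) {
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  phens <- sprintf("PH%02d", seq_len(spec$n_phenotypes))
  target <- phens[1]

  # Phenotype clusters: groups of mutually similar phenotypes (the
  # target's cluster holds its companion phenotypes).
  clus <- (seq_len(spec$n_phenotypes) - 1) %/% spec$phenotype_cluster_size
  n_clusters <- max(clus) + 1

  # Planted geometry, emulating a globally modular interactome: every
  # phenotype cluster owns one dense PPI gene module (functionally
  # related genes causing similar phenotypes); the target's cluster owns
  # one module per subtype. A subtype module's first `genes_per_subtype`
  # members are disease genes of the target; the following members are
  # associated only with the subtype's companion phenotypes. Under the
  # null nothing is planted: disease genes are random, modules absent.
  n_modules <- if (spec$planted) spec$n_subtypes + (n_clusters - 1) else 0
  if (spec$planted) {
    if (n_modules * spec$module_size > spec$n_genes)
      stop("n_genes too small for the planted modules")
    all_modules <- lapply(seq_len(n_modules), function(s)
      genes[((s - 1) * spec$module_size + 1):(s * spec$module_size)])
    module_genes <- all_modules[seq_len(spec$n_subtypes)]
    cluster_module <- c(list(NULL),  # cluster 1: the subtype modules
                        all_modules[spec$n_subtypes + seq_len(n_clusters - 1)])
    subtype_genes <- lapply(module_genes, function(m)
      m[seq_len(spec$genes_per_subtype)])
  } else {
    all_modules <- list()
    cluster_module <- rep(list(NULL), n_clusters)
    n_disease <- spec$n_subtypes * spec$genes_per_subtype
    disease <- sort(sample(genes, n_disease))
    subtype_genes <- split(disease, rep(seq_len(spec$n_subtypes),
                                        each = spec$genes_per_subtype))
    module_genes <- subtype_genes
  }
  disease_genes <- unlist(subtype_genes)

  # PPI: sparse Erdos-Renyi background with dense planted modules. The
  # degree contrast (module genes ~p_within*module_size, background genes
  # ~p_background*n_genes) makes modules topologically tight relative to
  # the rest of the network.
  pair <- utils::combn(spec$n_genes, 2)
  p_edge <- rep(spec$p_background, ncol(pair))
  if (spec$planted) {
    mod_of <- rep(NA_integer_, spec$n_genes)
    for (s in seq_len(n_modules))
      mod_of[match(all_modules[[s]], genes)] <- s
    in_mod <- !is.na(mod_of[pair[1, ]]) &
      mod_of[pair[1, ]] == mod_of[pair[2, ]]
    p_edge[in_mod] <- spec$p_within
  }
  on <- stats::runif(ncol(pair)) < p_edge
  ppi <- data.frame(a = genes[pair[1, on]], b = genes[pair[2, on]])

  # phenotype similarities: clustered scores, clipped to [0,1]
  ppair <- utils::combn(spec$n_phenotypes, 2)
  same <- clus[ppair[1, ]] == clus[ppair[2, ]]
  mu <- ifelse(same, spec$sim_within_mean, spec$sim_background_mean)
  score <- pmin(pmax(stats::rnorm(ncol(ppair), mu, spec$sim_sd), 0), 1)
  sim <- data.frame(a = phens[ppair[1, ]], b = phens[ppair[2, ]],
                    s = sprintf("%.6f", score))

  # associations
  assoc <- data.frame(phenotype = target, gene = disease_genes)
  if (spec$n_noise_disease_genes > 0) {
    noise <- sample(setdiff(genes, unlist(all_modules)),
                    spec$n_noise_disease_genes)
    assoc <- rbind(assoc, data.frame(phenotype = target, gene = noise))
  } else noise <- character(0)
  # companion phenotypes: members of the target's similarity cluster,
  # each associated with module genes that carry no other association
  cluster_mates <- phens[clus == clus[1]][-1]
  companions <- list()
  used <- character(0)
  for (s in seq_len(spec$n_subtypes)) {
    comp <- utils::head(setdiff(cluster_mates, used),
                        spec$companions_per_subtype)
    used <- c(used, comp)
    companions[[s]] <- comp
    extra <- setdiff(module_genes[[s]], subtype_genes[[s]])
    for (ci in seq_along(comp)) {
      cg <- if (spec$planted) {
        # each companion shares a block of the subtype's disease genes
        # (genes associated with both the target and the companion) and
        # adopts a block of module-only genes as its own disease genes
        take <- ((ci - 1) * spec$genes_per_companion + 1):
          (ci * spec$genes_per_companion)
        c(subtype_genes[[s]][((take - 1) %% length(subtype_genes[[s]])) + 1],
          if (length(extra) > 0) extra[((take - 1) %% length(extra)) + 1])
      } else {
        sample(genes, min(2 * spec$genes_per_companion, length(genes)))
      }
      assoc <- rbind(assoc, data.frame(phenotype = comp[ci], gene = cg))
    }
  }
  # background phenotypes associate with genes from their own cluster's
  # module (functionally related genes for similar phenotypes); under the
  # null, or for leftover target-cluster phenotypes, with random genes
  background_phens <- setdiff(phens, c(target, used))
  for (bp in background_phens) {
    k <- clus[match(bp, phens)] + 1
    pool <- if (spec$planted && !is.null(cluster_module[[k]]))
      cluster_module[[k]] else genes
    n_draw <- sample(seq_len(spec$assoc_per_phenotype + 1), 1)
    bg <- sample(pool, min(n_draw, length(pool)))
    assoc <- rbind(assoc, data.frame(phenotype = bp, gene = bg))
  }
  assoc <- assoc[!duplicated(paste(assoc$phenotype, assoc$gene)), ]

  # connectivity check for the target phenotype on the merged graph
  gsub <- new_subnet(ppi$a, ppi$b, rep(1, nrow(ppi)), "gene",
                     all_labels = genes)
  keep <- as.numeric(sim$s) > 0.4
  psub <- new_subnet(sim$a[keep], sim$b[keep], as.numeric(sim$s[keep]),
                     "phenotype", all_labels = phens)
  asub <- new_assoc_subnet(assoc$phenotype, assoc$gene)
  net <- suppressMessages(merge_hetnet(gsub, psub,
    suppressMessages(assign_association_weights(gsub, psub, asub))))
  ok <- paste("p", target, sep = ":") %in% net$nodes$id &&
    all(paste("g", disease_genes, sep = ":") %in% net$nodes$id)

  truth <- list(target_phenotype = target,
                planted = spec$planted,
                subtype_genes = subtype_genes,
                module_genes = module_genes,
                noise_disease_genes = noise,
                companions = companions,
                preset = spec$preset, seed = spec$seed)
  list(ppi = ppi, sim = sim, assoc = assoc, truth = truth,
       target_connected = ok)
}

#' Generate and load a synthetic network in one step
#'
#' @inheritParams generate_network
#' @return List with `net` (a `cipher_hetnet` loaded back through the TSV
#'   parsers, so files round-trip), `truth` and `files`.
#' @export
synth_hetnet <- function(spec, dir = tempfile("synthnet")) {
  g <- generate_network(spec, dir)
  net <- suppressMessages(hetnet_from_files(g$files$ppi, g$files$phensim,
                                            g$files$assoc))
  list(net = net, truth = g$truth, files = g$files)
}

#' Deterministic fixture graphs
#'
#' Small named graphs used across the test-suite: `path3` (a-b-c), `ruin4`
#' (gambler's-ruin path 0-1-2-3), `cycle4`, `k4` (complete graph),
#' `star4` (weighted star), `oracle8` (8-node irregular weighted graph for
#' path-space enumeration checks) and `fig2a` (heterogeneous toy: a target
#' phenotype whose adjacency set holds a tight gene triangle u1-u3 plus a
#' distant outlier u4, with candidate genes hanging off the triangle).
#'
#' @return Named list; each entry has a transition matrix `P`, and `fig2a`
#'   additionally the `cipher_hetnet` and node bookkeeping.
#' @export
fixture_gallery <- function() {
  walk <- function(edges, nodes = NULL) {
    labs <- if (is.null(nodes)) sort(unique(c(edges$a, edges$b))) else nodes
    n <- length(labs)
    W <- matrix(0, n, n, dimnames = list(labs, labs))
    for (k in seq_len(nrow(edges))) {
      W[edges$a[k], edges$b[k]] <- W[edges$a[k], edges$b[k]] + edges$w[k]
      W[edges$b[k], edges$a[k]] <- W[edges$b[k], edges$a[k]] + edges$w[k]
    }
    P <- W / rowSums(W)
    Matrix::Matrix(P, sparse = TRUE)
  }
  ed <- function(a, b, w = 1) data.frame(a = a, b = b, w = w)

  out <- list()
  out$path3 <- list(P = walk(ed(c("a", "b"), c("b", "c"))))
  out$ruin4 <- list(P = walk(ed(c("0", "1", "2"), c("1", "2", "3")),
                             nodes = c("0", "1", "2", "3")))
  out$cycle4 <- list(P = walk(ed(c("a", "b", "c", "d"),
                                 c("b", "c", "d", "a"))))
  out$k4 <- list(P = walk(ed(c("a", "a", "a", "b", "b", "c"),
                             c("b", "c", "d", "c", "d", "d"))))
  out$star4 <- list(P = walk(ed(c("x", "x"), c("a", "b"), w = c(1, 3))))
  out$oracle8 <- list(P = walk(ed(
    a = c("n1", "n2", "n3", "n4", "n5", "n6", "n7", "n2", "n3", "n1"),
    b = c("n2", "n3", "n4", "n5", "n6", "n7", "n8", "n5", "n6", "n8"),
    w = c(1, 2, 1, 1, 2, 1, 1, 1, 2, 1))))

  # fig2a heterogeneous toy: tight triangle u1-u2-u3 adjacent to p (heavy
  # mutual interactions), outlier u4 reachable from the triangle only
  # through a long chain of weak links.
  gsub <- new_subnet(
    from = c("U1", "U1", "U2", "G1", "G1", "G2", "G2", "G3", "G3", "G4",
             "U4", "C1", "C2", "C3", "C4"),
    to   = c("U2", "U3", "U3", "U1", "U2", "U2", "U3", "U1", "U3", "G1",
             "C1", "C2", "C3", "C4", "U1"),
    weight = c(4, 4, 4, rep(1, 12)), kind = "gene")
  psub <- new_subnet(character(0), character(0), numeric(0),
                     kind = "phenotype", all_labels = "P1")
  asub <- new_assoc_subnet(rep("P1", 4), c("U1", "U2", "U3", "U4"))
  net <- suppressMessages(merge_hetnet(gsub, psub,
    suppressMessages(assign_association_weights(gsub, psub, asub))))
  out$fig2a <- list(net = net, P = transition_matrix(net),
                    phenotype = "P1",
                    triangle = c("U1", "U2", "U3"), outlier = "U4",
                    candidates = c("G1", "G2", "G3", "G4"))
  out
}
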