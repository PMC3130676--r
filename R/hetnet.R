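# Assembly of the phenotype-gene heterogeneous network from its three
# sub-networks: PPI (gene-gene), phenotype similarity, gene-phenotype
# associations.

#' Read the three sub-networks from tab-separated files
#'
#' Parses a protein-protein interaction edge list, a phenotype-phenotype
#' similarity edge list and a gene-phenotype association list. Similarity
#' edges are kept only when their score is strictly larger than
#' `sim_threshold`; PPI edges default to weight 1. Gene symbols are
#' upper-cased; phenotype identifiers are kept verbatim. Duplicate edges are
#' collapsed keeping the maximum weight.
#'
#' @param ppi_path TSV with columns `geneA geneB [weight]`; lines starting
#'   with `#` are ignored.
#' @param phensim_path TSV with columns `phenA phenB score`, score in
#'   \[0, 1\].
#' @param assoc_path TSV with columns `phenotype gene`.
#' @param sim_threshold similarity cutoff in \[0, 1\]; edges with score
#'   `<= sim_threshold` are dropped (strict "larger than" retention).
#'   Default 0.4.
#' @return A list with elements `gene`, `phenotype`, `association`, each a
#'   `cipher_subnet` (edge table + node table), plus per-block counts in
#'   attributes.
#' @export
read_subnetworks <- function(ppi_path, phensim_path, assoc_path,
                             sim_threshold = 0.4) {
  stopifnot(is.numeric(sim_threshold), length(sim_threshold) == 1L,
            sim_threshold >= 0, sim_threshold <= 1)

  ppi <- parse_edge_file(ppi_path, min_cols = 2L, max_cols = 3L)
  if (nrow(ppi) > 0) {
    ppi$V1 <- toupper(ppi$V1)
    ppi$V2 <- toupper(ppi$V2)
    w <- if (ncol(ppi) >= 3L) parse_numeric_col(ppi, 3L, ppi_path) else rep(1, nrow(ppi))
    w[is.na(w)] <- 1
    if (any(w < 0)) stop("negative PPI edge weight in ", ppi_path)
  } else w <- numeric(0)
  gene_net <- new_subnet(ppi$V1, ppi$V2, w, kind = "gene", symmetric = TRUE)

  sim <- parse_edge_file(phensim_path, min_cols = 3L, max_cols = 3L)
  s <- parse_numeric_col(sim, 3L, phensim_path)
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("similarity score outside [0,1] in ", phensim_path)
  keep <- s > sim_threshold
  phen_net <- new_subnet(sim$V1[keep], sim$V2[keep], s[keep],
                         kind = "phenotype", symmetric = TRUE,
                         all_labels = unique(c(sim$V1, sim$V2)))

  asc <- parse_edge_file(assoc_path, min_cols = 2L, max_cols = 2L)
  asc_gene <- toupper(asc$V2)
  assoc_net <- new_assoc_subnet(asc$V1, asc_gene)

  orphan_genes <- setdiff(assoc_net$nodes$label[assoc_net$nodes$kind == "gene"],
                          gene_net$nodes$label)
  orphan_phens <- setdiff(assoc_net$nodes$label[assoc_net$nodes$kind == "phenotype"],
                          phen_net$nodes$label)
  if (length(orphan_genes) > 0) {
    gene_net$nodes <- rbind(gene_net$nodes,
                            data.frame(kind = "gene", label = orphan_genes))
    message(length(orphan_genes),
            " association gene(s) absent from the PPI file; added without PPI edges")
  }
  if (length(orphan_phens) > 0) {
    phen_net$nodes <- rbind(phen_net$nodes,
                            data.frame(kind = "phenotype", label = orphan_phens))
    message(length(orphan_phens),
            " association phenotype(s) absent from the similarity file; added without similarity edges")
  }

  message(sprintf("loaded: %d PPI edges / %d genes; %d similarity edges retained (of %d) / %d phenotypes; %d associations",
                  nrow(gene_net$edges), nrow(gene_net$nodes),
                  nrow(phen_net$edges), nrow(sim), nrow(phen_net$nodes),
                  nrow(assoc_net$edges)))
  list(gene = gene_net, phenotype = phen_net, association = assoc_net,
       sim_threshold = sim_threshold)
}

# Read a whitespace/tab separated edge file, dropping comments and blanks,
# erroring with file and line number on malformed rows.
parse_edge_file <- function(path, min_cols, max_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(parts)
  bad <- nf < min_cols | nf > max_cols
  if (any(bad))
    stop("malformed line ", idx[which(bad)[1]], " in ", path,
         " (expected ", min_cols, "-", max_cols, " fields, got ",
         nf[which(bad)[1]], ")")
  if (length(parts) == 0)
    return(data.frame(V1 = character(0), V2 = character(0)))
  ncol_out <- max(nf)
  out <- lapply(seq_len(ncol_out), function(j)
    vapply(parts, function(p) if (length(p) >= j) p[j] else NA_character_,
           character(1)))
  names(out) <- paste0("V", seq_len(ncol_out))
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(df, "line_numbers") <- idx
  df
}

parse_numeric_col <- function(df, j, path) {
  x <- suppressWarnings(as.numeric(df[[j]]))
  bad <- which(is.na(x) & !is.na(df[[j]]))
  if (length(bad) > 0) {
    ln <- attr(df, "line_numbers")
    stop("malformed numeric field on line ",
         if (!is.null(ln)) ln[bad[1]] else bad[1], " in ", path)
  }
  x
}

# Construct a single-kind symmetric sub-network: drops self-edges,
# deduplicates undirected edges keeping the maximum weight.
new_subnet <- function(from, to, weight, kind, symmetric = TRUE,
                       all_labels = NULL) {
  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped in ", kind, " sub-network")
    from <- from[!self]; to <- to[!self]; weight <- weight[!self]
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edges in ", kind,
            " sub-network collapsed (max weight kept)")
    w <- tapply(weight, key, max)
    ord <- !duplicated(key)
    keep_key <- key[ord]
    from <- lo[ord]; to <- hi[ord]; weight <- as.numeric(w[keep_key])
  } else {
    from <- lo; to <- hi
  }
  labels <- sort(unique(c(from, to, all_labels)))
  structure(list(
    kind = kind,
    edges = data.frame(from = from, to = to, weight = weight,
                       stringsAsFactors = FALSE),
    nodes = data.frame(kind = kind, label = labels,
                       stringsAsFactors = FALSE),
    symmetric = symmetric), class = "cipher_subnet")
}

new_assoc_subnet <- function(phenotype, gene, weight = NULL) {
  key <- paste(phenotype, gene, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate association edges collapsed")
    if (!is.null(weight)) {
      w <- tapply(weight, key, max)
      ord <- !duplicated(key)
      phenotype <- phenotype[ord]; gene <- gene[ord]
      weight <- as.numeric(w[key[ord]])
    } else {
      ord <- !duplicated(key)
      phenotype <- phenotype[ord]; gene <- gene[ord]
    }
  }
  nodes <- rbind(
    data.frame(kind = rep("gene", length(unique(gene))),
               label = sort(unique(gene)), stringsAsFactors = FALSE),
    data.frame(kind = rep("phenotype", length(unique(phenotype))),
               label = sort(unique(phenotype)), stringsAsFactors = FALSE))
  edges <- data.frame(phenotype = phenotype, gene = gene,
                      stringsAsFactors = FALSE)
  if (!is.null(weight)) edges$weight <- weight
  structure(list(kind = "association", edges = edges, nodes = nodes,
                 symmetric = FALSE), class = "cipher_subnet")
}

#' Assign cross-network weights to the association edges
#'
#' Each association edge between gene `g` and phenotype `p` receives the
#' weight `w(g,p) = sqrt((s_G(g)/k_g) * (s_P(p)/k_p))`, where `s_G(g)` is
#' the total PPI weight at `g`, `s_P(p)` the total similarity weight at
#' `p`, and `k_g`, `k_p` the numbers of associations at each endpoint. When
#' both endpoints carry a single association this makes the average
#' probability of stepping onto the other sub-network at `g` and at `p`
#' exactly 0.5. When an endpoint has zero within-block strength the weight
#' falls back to 1 (logged).
#'
#' @param gene_net,phen_net,assoc_net sub-networks as returned by
#'   [read_subnetworks()].
#' @return The association `cipher_subnet` with a `weight` column filled in.
#' @export
assign_association_weights <- function(gene_net, phen_net, assoc_net) {
  ed <- assoc_net$edges
  if (nrow(ed) == 0) return(assoc_net)
  known_g <- gene_net$nodes$label
  known_p <- phen_net$nodes$label
  miss <- !(ed$gene %in% known_g) | !(ed$phenotype %in% known_p)
  if (any(miss))
    stop("association endpoint not found among sub-network nodes: ",
         paste(unique(c(ed$gene[miss & !(ed$gene %in% known_g)],
                        ed$phenotype[miss & !(ed$phenotype %in% known_p)])),
               collapse = ", "))
  sg <- block_strength(gene_net)
  sp <- block_strength(phen_net)
  s_g <- ifelse(ed$gene %in% names(sg), sg[ed$gene], 0)
  s_p <- ifelse(ed$phenotype %in% names(sp), sp[ed$phenotype], 0)
  k_g <- table(ed$gene)[ed$gene]
  k_p <- table(ed$phenotype)[ed$phenotype]
  w <- sqrt((s_g / as.numeric(k_g)) * (s_p / as.numeric(k_p)))
  fallback <- s_g == 0 | s_p == 0
  if (any(fallback)) {
    w[fallback] <- 1
    message(sum(fallback),
            " association(s) with a zero-strength endpoint given weight 1")
  }
  assoc_net$edges$weight <- as.numeric(w)
  assoc_net
}

# Total within-block edge weight per node, named numeric vector.
block_strength <- function(subnet) {
  ed <- subnet$edges
  if (nrow(ed) == 0) return(stats::setNames(numeric(0), character(0)))
  s <- tapply(c(ed$weight, ed$weight), c(ed$from, ed$to), sum)
  stats::setNames(as.numeric(s), names(s))
}

#' Merge the three sub-networks into one heterogeneous network
#'
#' Assembles the block weight matrix (gene-gene, phenotype-phenotype, and
#' the association blocks) over a fixed node ordering (genes first, then
#' phenotypes, lexicographic within kind) and restricts the result to its
#' largest connected component, so that every hitting time is finite.
#'
#' @param gene_net,phen_net PPI and similarity `cipher_subnet`s.
#' @param assoc_net association `cipher_subnet` with weights already
#'   assigned (see [assign_association_weights()]); unweighted associations
#'   are weighted on the fly.
#' @return A `cipher_hetnet`: node table (`id`, `kind`, `label`), sparse
#'   symmetric weight matrix `W`, the retained sub-networks (for
#'   re-assembly), the removed-node log and cross-walk diagnostics.
#' @export
merge_hetnet <- function(gene_net, phen_net, assoc_net) {
  if (is.null(assoc_net$edges$weight) && nrow(assoc_net$edges) > 0)
    assoc_net <- assign_association_weights(gene_net, phen_net, assoc_net)

  nodes <- rbind(gene_net$nodes[order(gene_net$nodes$label), ],
                 phen_net$nodes[order(phen_net$nodes$label), ])
  nodes$id <- paste(substr(nodes$kind, 1, 1), nodes$label, sep = ":")
  if (anyDuplicated(nodes$id)) stop("duplicate node identity after merge")
  rownames(nodes) <- NULL
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)

  gid <- function(x) if (length(x) == 0) integer(0) else
    idx[paste("g", x, sep = ":")]
  pid <- function(x) if (length(x) == 0) integer(0) else
    idx[paste("p", x, sep = ":")]
  i <- c(gid(gene_net$edges$from), pid(phen_net$edges$from),
         gid(assoc_net$edges$gene))
  j <- c(gid(gene_net$edges$to), pid(phen_net$edges$to),
         pid(assoc_net$edges$phenotype))
  w <- c(gene_net$edges$weight, phen_net$edges$weight,
         if (nrow(assoc_net$edges) > 0) assoc_net$edges$weight else numeric(0))
  n <- nrow(nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n), dimnames = list(nodes$id, nodes$id))

  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  keep <- comp$membership == main
  removed <- nodes[!keep, c("kind", "label")]
  if (sum(keep) == 0) stop("merged network is empty")
  if (nrow(removed) > 0)
    message(nrow(removed),
            " node(s) outside the largest connected component removed")
  nodes <- nodes[keep, ]
  rownames(nodes) <- NULL
  W <- W[keep, keep, drop = FALSE]

  net <- structure(list(
    nodes = nodes,
    W = W,
    sub = list(gene = gene_net, phenotype = phen_net,
               association = assoc_net),
    removed = removed,
    cross_walk = cross_walk_stats(gene_net, phen_net, assoc_net)
  ), class = "cipher_hetnet")
  net
}

# Realized probability of stepping onto the other sub-network at each
# association endpoint; the single-association mean is the design contract.
cross_walk_stats <- function(gene_net, phen_net, assoc_net) {
  ed <- assoc_net$edges
  if (nrow(ed) == 0 || is.null(ed$weight))
    return(list(mean_prob_single = NA_real_, mean_prob_all = NA_real_,
                n_single = 0L, n_fallback = 0L))
  sg <- block_strength(gene_net)
  sp <- block_strength(phen_net)
  s_g <- ifelse(ed$gene %in% names(sg), sg[ed$gene], 0)
  s_p <- ifelse(ed$phenotype %in% names(sp), sp[ed$phenotype], 0)
  cross_g <- tapply(ed$weight, ed$gene, sum)[ed$gene]
  cross_p <- tapply(ed$weight, ed$phenotype, sum)[ed$phenotype]
  prob_g <- as.numeric(cross_g) / (as.numeric(cross_g) + s_g)
  prob_p <- as.numeric(cross_p) / (as.numeric(cross_p) + s_p)
  pair_mean <- (prob_g + prob_p) / 2
  k_g <- table(ed$gene)[ed$gene]
  k_p <- table(ed$phenotype)[ed$phenotype]
  single <- as.numeric(k_g) == 1 & as.numeric(k_p) == 1 & s_g > 0 & s_p > 0
  list(mean_prob_single = if (any(single)) mean(pair_mean[single]) else NA_real_,
       pair_mean_single = pair_mean[single],
       mean_prob_all = mean(pair_mean),
       n_single = sum(single),
       n_fallback = sum(s_g == 0 | s_p == 0))
}

#' Build a heterogeneous network directly from the three files
#'
#' Convenience wrapper: [read_subnetworks()], then
#' [assign_association_weights()], then [merge_hetnet()].
#'
#' @inheritParams read_subnetworks
#' @return A `cipher_hetnet`.
#' @export
hetnet_from_files <- function(ppi_path, phensim_path, assoc_path,
                              sim_threshold = 0.4) {
  sub <- read_subnetworks(ppi_path, phensim_path, assoc_path, sim_threshold)
  assoc <- assign_association_weights(sub$gene, sub$phenotype,
                                      sub$association)
  net <- merge_hetnet(sub$gene, sub$phenotype, assoc)
  net$sim_threshold <- sub$sim_threshold
  net
}

#' Row-stochastic transition matrix of the random walk
#'
#' `P(i,j) = W(i,j) / sum_j' W(i,j')`. Every node of a merged network has
#' positive degree, so all rows are well defined and sum to one.
#'
#' @param net a `cipher_hetnet`.
#' @return A sparse row-stochastic matrix aligned to `net$nodes$id`.
#' @export
transition_matrix <- function(net) {
  stopifnot(inherits(net, "cipher_hetnet"))
  deg <- Matrix::rowSums(net$W)
  if (any(deg <= 0)) stop("node with zero weighted degree: ",
                          paste(net$nodes$id[deg <= 0], collapse = ", "))
  P <- net$W / deg
  stopifnot(max(abs(Matrix::rowSums(P) - 1)) < 1e-12)
  P
}

#' Adjacent nodes of a target phenotype
#'
#' The adjacency set U(p): known disease genes of `p` plus phenotypes linked
#' to `p` by a retained similarity edge.
#'
#' @param net a `cipher_hetnet`.
#' @param p phenotype label.
#' @return A data frame with columns `id`, `kind`, `label`, `role`
#'   (`disease_gene` or `similar_phenotype`) and the connecting weight.
#' @export
adjacency_set <- function(net, p) {
  pid <- resolve_node(net, p, "phenotype")
  w <- net$W[, pid]
  hit <- which(w > 0)
  members <- net$nodes[hit, c("id", "kind", "label")]
  members$role <- ifelse(members$kind == "gene", "disease_gene",
                         "similar_phenotype")
  members$weight <- as.numeric(w[hit])
  rownames(members) <- NULL
  attr(members, "phenotype") <- p
  members
}

# Map a user-facing (kind, label) to the internal node id, erroring when
# absent from the merged network.
resolve_node <- function(net, label, kind) {
  id <- paste(substr(kind, 1, 1), label, sep = ":")
  ok <- id %in% net$nodes$id
  if (!all(ok))
    stop("unknown ", kind, " node(s): ", paste(label[!ok], collapse = ", "))
  id
}

#' @export
print.cipher_hetnet <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat("Phenotype-gene heterogeneous network\n")
  cat(sprintf("  nodes: %d genes, %d phenotypes\n",
              kinds[["gene"]], kinds[["phenotype"]]))
  cat(sprintf("  edges: %d PPI, %d similarity, %d association\n",
              nrow(x$sub$gene$edges), nrow(x$sub$phenotype$edges),
              nrow(x$sub$association$edges)))
  if (nrow(x$removed) > 0)
    cat(sprintf("  %d node(s) removed outside the main component\n",
                nrow(x$removed)))
  if (!is.na(x$cross_walk$mean_prob_single))
    cat(sprintf("  mean cross-walk probability (single-association pairs): %.6f\n",
                x$cross_walk$mean_prob_single))
  invisible(x)
}

#' Write / read a heterogeneous network bundle
#'
#' The bundle is a plain-text directory: `nodes.tsv`, `edges.tsv` (one row
#' per undirected edge, tagged by block) and `meta.json`. Reading re-runs
#' weight assignment and the component restriction, so a round trip
#' reproduces the network exactly.
#'
#' @param net a `cipher_hetnet`.
#' @param dir directory to create/read.
#' @return `write_hetnet` returns `dir` invisibly; `read_hetnet` a
#'   `cipher_hetnet`.
#' @export
write_hetnet <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$nodes[, c("kind", "label")],
                     file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- rbind(
    data.frame(block = "gene", from = net$sub$gene$edges$from,
               to = net$sub$gene$edges$to,
               weight = net$sub$gene$edges$weight),
    data.frame(block = "phenotype", from = net$sub$phenotype$edges$from,
               to = net$sub$phenotype$edges$to,
               weight = net$sub$phenotype$edges$weight),
    if (nrow(net$sub$association$edges) > 0)
      data.frame(block = "association",
                 from = net$sub$association$edges$phenotype,
                 to = net$sub$association$edges$gene,
                 weight = NA_real_))
  utils::write.table(ed, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(format = "cipherhit-net/1",
               sim_threshold = net$sim_threshold,
               n_nodes = nrow(net$nodes))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_hetnet
#' @export
read_hetnet <- function(dir) {
  ed <- utils::read.table(file.path(dir, "edges.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  nodes <- utils::read.table(file.path(dir, "nodes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  ge <- ed[ed$block == "gene", ]
  pe <- ed[ed$block == "phenotype", ]
  ae <- ed[ed$block == "association", ]
  gene_net <- new_subnet(ge$from, ge$to, ge$weight, kind = "gene",
                         all_labels = nodes$label[nodes$kind == "gene"])
  phen_net <- new_subnet(pe$from, pe$to, pe$weight, kind = "phenotype",
                         all_labels = nodes$label[nodes$kind == "phenotype"])
  assoc_net <- new_assoc_subnet(ae$from, ae$to)
  assoc_net <- assign_association_weights(gene_net, phen_net, assoc_net)
  net <- merge_hetnet(gene_net, phen_net, assoc_net)
  net$sim_threshold <- meta$sim_threshold
  net
}
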