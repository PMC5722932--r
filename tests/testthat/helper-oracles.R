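# Independent oracles and fixture builders used across the test files.
# Each oracle recomputes a quantity by a different route than the package
# implementation (explicit enumeration, path intersection, direct
# simulation), so agreement is a genuine cross-check.

make_gene <- function(gene_id, start, end, strand = "+", scaffold = "s1",
                      species = "toy", group = gene_id, family = "other") {
  data.frame(gene_id = gene_id, species = species, scaffold = scaffold,
             start = as.integer(start), end = as.integer(end),
             strand = strand, group = group, family = family,
             stringsAsFactors = FALSE)
}

make_annotation <- function(...) {
  genome_annotation(do.call(rbind, list(...)))
}

# minimum base-to-base distance between two gene intervals, by explicit
# base sets (small coordinates only)
oracle_gap <- function(g1, g2) {
  b1 <- seq(g1$start, g1$end)
  b2 <- seq(g2$start, g2$end)
  min(abs(outer(b1, b2, "-")))
}

# interposed genes by a literal scan over every other gene's midpoint
oracle_interposed <- function(g1, g2, ann) {
  lo <- min(g1$end, g2$end)
  hi <- max(g1$start, g2$start)
  n <- 0L
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    if (g$gene_id %in% c(g1$gene_id, g2$gene_id)) next
    if (g$scaffold != g1$scaffold) next
    mid <- (g$start + g$end) / 2
    if (mid > lo && mid < hi) n <- n + 1L
  }
  n
}

tree_tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tree_tips_below, tree = tree))
}

tree_nodes_below <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  c(node, unlist(lapply(kids, tree_nodes_below, tree = tree)))
}

# minimal loss count under a single gain, by exhaustive search over every
# admissible gain placement and every loss-edge subset of increasing size
oracle_dollo_min_losses <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  present <- names(states)[states == "present"]
  absent <- names(states)[states == "absent"]
  best <- Inf
  for (g in seq_len(nnode)) {
    below_g <- tree_tips_below(tree, g)
    if (!all(present %in% below_g)) next
    cand <- setdiff(tree_nodes_below(tree, g), g)
    a_in <- intersect(absent, below_g)
    max_k <- min(length(cand), length(a_in))
    found <- NA
    for (k in 0:max_k) {
      subsets <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(cand, k), 2)
      for (L in subsets) {
        lost_tips <- unique(unlist(lapply(L, tree_tips_below, tree = tree)))
        ok <- all(a_in %in% lost_tips) && !any(present %in% lost_tips)
        if (ok) { found <- k; break }
      }
      if (!is.na(found)) break
    }
    if (!is.na(found)) best <- min(best, found)
  }
  best
}

# LCA reconciliation by ancestor-path intersection (independent of the
# postorder mapping in the implementation)
oracle_reconcile <- function(cluster_tree, species_tree, map) {
  anc_path <- function(tree, node) {
    ntip <- length(tree$tip.label)
    root <- ntip + 1
    path <- node
    while (node != root) {
      node <- tree$edge[tree$edge[, 2] == node, 1]
      path <- c(path, node)
    }
    path
  }
  sp_lca <- function(species) {
    nodes <- match(species, species_tree$tip.label)
    paths <- lapply(nodes, anc_path, tree = species_tree)
    common <- Reduce(intersect, paths)
    common[1]  # paths are ordered node -> root; first common is deepest
  }
  ntip <- length(cluster_tree$tip.label)
  internal <- sort(unique(cluster_tree$edge[, 1]))
  image <- function(node) {
    sp_lca(unique(map[tree_tips_below(cluster_tree, node)]))
  }
  dup <- integer(0)
  for (nd in internal) {
    kids <- cluster_tree$edge[cluster_tree$edge[, 1] == nd, 2]
    if (any(vapply(kids, image, numeric(1)) == image(nd))) {
      dup <- c(dup, nd)
    }
  }
  dup
}

# state propagation of an event history down the tree, written as a plain
# recursive walk (independent of the per-leaf path replay)
oracle_replay <- function(truth, tree) {
  clusters <- attr(truth, "clusters")
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  out <- matrix("absent", nrow = length(clusters), ncol = ntip,
                dimnames = list(clusters, tree$tip.label))
  fld <- function(x) if (is.na(x) || x == "") character(0) else
    strsplit(x, ",")[[1]]
  walk <- function(node, linked) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (k in kids) {
      lk <- linked
      rows <- truth[truth$node == k, , drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        lk <- union(setdiff(lk, fld(rows$disrupts[j])),
                    fld(rows$restores[j]))
      }
      if (k <= ntip) out[lk, k] <<- "present" else walk(k, lk)
    }
  }
  walk(root, character(0))
  out
}

# all labelled rooted binary topologies on the given tips, as newick text
all_rooted_topologies <- function(tips) {
  if (length(tips) == 1) return(tips)
  out <- character(0)
  n <- length(tips)
  # split the first tip from every non-empty proper subset of the rest
  rest <- tips[-1]
  for (k in 0:(length(rest) - 1)) {
    combos <- if (k == 0) list(character(0)) else
      asplit(utils::combn(rest, k), 2)
    for (left_extra in combos) {
      left <- c(tips[1], left_extra)
      right <- setdiff(tips, left)
      if (length(right) == 0) next
      for (lt in all_rooted_topologies(left)) {
        for (rt in all_rooted_topologies(right)) {
          out <- c(out, paste0("(", lt, ",", rt, ")"))
        }
      }
    }
  }
  out
}

random_binary_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

fig1_defs <- list(
  "PDIA1-RhoGDIa" = c("PDIA1", "RhoGDIa"),
  "PDIA2-RhoGDIg" = c("PDIA2", "RhoGDIg"),
  "PDIA8-RhoGDIb" = c("PDIA8", "RhoGDIb"))
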