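# Evolutionary operations on cluster presence/absence: Dollo reconstruction
# of gains and losses, duplication counting by LCA reconciliation, and
# auditing of "absent" states into loss vs. unlinking.

# a tree edge, identified by its child node and reported by the leaf set
# that node subtends
edge_ref <- function(tree, node) {
  list(node = as.integer(node),
       tips = sort(tree$tip.label[descendant_tips(tree, node)]))
}

#' Build a cluster presence matrix from detected pairs
#'
#' @param pairs_by_species named list: species -> `syntenic_pairs` data
#'   frame as returned by [detect_pairs()] (possibly empty).
#' @param cluster_defs named list: cluster label -> character vector of the
#'   two member ortholog-group labels, e.g.
#'   `list("PDIA1-RhoGDIa" = c("PDIA1", "RhoGDIa"))`.
#' @param missing_policy state recorded for a species without the pair:
#'   `"absent"` (default) or `"unknown"` (e.g. for species with patchy
#'   annotations where a missing pair must not be read as a loss).
#' @return A [presence_matrix()] over `names(cluster_defs)` x
#'   `names(pairs_by_species)`.
#' @export
build_presence_matrix <- function(pairs_by_species, cluster_defs,
                                  missing_policy = c("absent", "unknown")) {
  missing_policy <- match.arg(missing_policy)
  species <- names(pairs_by_species)
  if (is.null(species)) stop("pairs_by_species must be a named list")
  m <- matrix(missing_policy, nrow = length(cluster_defs),
              ncol = length(species),
              dimnames = list(names(cluster_defs), species))
  for (sp in species) {
    pr <- pairs_by_species[[sp]]
    if (is.null(pr) || nrow(pr) == 0L) next
    for (i in seq_len(nrow(pr))) {
      groups <- c(pr$group_pdi[i], pr$group_gdi[i])
      hit <- vapply(cluster_defs, function(def) setequal(def, groups),
                    logical(1))
      if (!any(hit)) {
        stop("pair (", groups[1], ", ", groups[2], ") in species ", sp,
             " maps to no cluster label")
      }
      m[names(cluster_defs)[which(hit)[1L]], sp] <- "present"
    }
  }
  presence_matrix(m)
}

#' Dollo-parsimony reconstruction of a cluster's history
#'
#' The cluster is constrained to a single gain; the gain branch is the edge
#' above the last common ancestor of all `present` leaves, and losses are
#' the minimal set of edges explaining every `absent` leaf inside the gain
#' subtree (each loss edge subtends a maximal clade containing no `present`
#' leaf and at least one `absent` leaf). `unknown` leaves constrain
#' nothing. This minimal loss set is unique and provably optimal for the
#' single-gain constraint.
#'
#' @param matrix a [presence_matrix()] whose species are a subset of the
#'   tree leaves. Tree leaves not in the matrix are treated as `unknown`.
#' @param tree rooted [ape::phylo] species tree.
#' @param cluster cluster label (row of `matrix`).
#' @return List of class `dollo_reconstruction`: `cluster`; `gain` (edge:
#'   `node` id and subtended `tips`); `losses` (list of edges);
#'   `ancestral_state` (character vector "present"/"absent" named by node
#'   id, covering every node of the tree).
#' @examples
#' pm <- builtin_fixture("species_presence_fig1")
#' tr <- builtin_fixture("species_tree_fig1")
#' dollo_reconstruct(pm, tr, "primordial")$gain$tips
#' @export
dollo_reconstruct <- function(matrix, tree, cluster) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!cluster %in% rownames(matrix)) stop("unknown cluster: ", cluster)
  extra <- setdiff(colnames(matrix), tree$tip.label)
  if (length(extra) > 0L) {
    stop("matrix species not in tree: ", paste(extra, collapse = ", "))
  }
  states <- setNames(rep("unknown", length(tree$tip.label)), tree$tip.label)
  states[colnames(matrix)] <- matrix[cluster, ]
  present <- names(states)[states == "present"]
  if (length(present) == 0L) stop("no present leaf for cluster ", cluster)

  gain_node <- if (length(present) == 1L) {
    match(present, tree$tip.label)
  } else {
    ape::getMRCA(tree, present)
  }

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # per-node counts of constrained (present/absent) leaves below
  n_present <- integer(nnode)
  n_absent <- integer(nnode)
  n_present[seq_len(ntip)] <- as.integer(states == "present")
  n_absent[seq_len(ntip)] <- as.integer(states == "absent")
  for (nd in sort(unique(tree$edge[, 1L]), decreasing = TRUE)) {
    kids <- node_children(tree, nd)
    n_present[nd] <- sum(n_present[kids])
    n_absent[nd] <- sum(n_absent[kids])
  }

  in_gain <- rep(FALSE, nnode)
  mark <- function(nd) {
    in_gain[nd] <<- TRUE
    for (k in node_children(tree, nd)) mark(k)
  }
  mark(gain_node)

  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  # maximal clades inside the gain subtree with no present and >=1 absent
  # leaf; maximality <=> the parent still has a present leaf below it
  loss_nodes <- which(in_gain & n_present == 0L & n_absent > 0L &
                      seq_len(nnode) != gain_node)
  loss_nodes <- loss_nodes[n_present[parent_of[loss_nodes]] > 0L]

  state <- rep("absent", nnode)
  lost <- rep(FALSE, nnode)
  for (ln in loss_nodes) {
    below <- c(ln, if (ln > ntip) {
      kids_all <- integer(0)
      stack <- ln
      while (length(stack) > 0L) {
        nd <- stack[[1L]]; stack <- stack[-1L]
        kd <- node_children(tree, nd)
        kids_all <- c(kids_all, kd)
        stack <- c(stack, kd[kd > ntip])
      }
      kids_all
    })
    lost[below] <- TRUE
  }
  state[in_gain & !lost] <- "present"

  structure(list(
    cluster = cluster,
    gain = edge_ref(tree, gain_node),
    losses = lapply(loss_nodes, edge_ref, tree = tree),
    ancestral_state = setNames(state, as.character(seq_len(nnode)))),
    class = "dollo_reconstruction")
}

#' Count cluster duplications by LCA reconciliation
#'
#' Standard last-common-ancestor mapping of a rooted binary cluster
#' (paralog) tree into a rooted binary species tree: each cluster-tree node
#' maps to the species-tree LCA of the species of its descendant leaves; an
#' internal node is a duplication if and only if its image equals the image
#' of at least one of its children.
#'
#' @param cluster_tree rooted binary [ape::phylo] tree of cluster lineages.
#' @param species_tree rooted binary [ape::phylo] species tree.
#' @param leaf_species_map named character vector: cluster-tree leaf label
#'   -> species-tree leaf label.
#' @return List of class `reconciliation_result`: `duplication_nodes`
#'   (cluster-tree internal node ids), `duplication_count`, and `lca_map`
#'   (integer vector, cluster-tree node id -> species-tree node id).
#' @examples
#' fx <- builtin_fixture("cluster_tree_fig2")
#' sp <- builtin_fixture("species_tree_fig1")
#' reconcile_duplications(fx$tree, sp, fx$species_map)$duplication_count  # 2
#' @export
reconcile_duplications <- function(cluster_tree, species_tree,
                                   leaf_species_map) {
  validate_tree(cluster_tree)
  validate_tree(species_tree)
  if (!ape::is.binary(cluster_tree)) {
    stop("cluster tree has polytomies; resolve them before reconciliation")
  }
  if (!ape::is.binary(species_tree)) {
    stop("species tree has polytomies; resolve them before reconciliation")
  }
  unmapped <- setdiff(cluster_tree$tip.label, names(leaf_species_map))
  if (length(unmapped) > 0L) {
    stop("cluster-tree leaf without species mapping: ",
         paste(unmapped, collapse = ", "))
  }
  sp_of_leaf <- leaf_species_map[cluster_tree$tip.label]
  bad <- setdiff(unique(sp_of_leaf), species_tree$tip.label)
  if (length(bad) > 0L) {
    stop("mapped species not a species-tree leaf: ",
         paste(bad, collapse = ", "))
  }

  ntip <- length(cluster_tree$tip.label)
  nnode <- ntip + cluster_tree$Nnode
  lca_map <- integer(nnode)
  lca_map[seq_len(ntip)] <- match(sp_of_leaf, species_tree$tip.label)
  for (nd in sort(unique(cluster_tree$edge[, 1L]), decreasing = TRUE)) {
    tips_below <- descendant_tips(cluster_tree, nd)
    sp <- unique(sp_of_leaf[tips_below])
    lca_map[nd] <- if (length(sp) == 1L) {
      match(sp, species_tree$tip.label)
    } else {
      ape::getMRCA(species_tree, sp)
    }
  }
  internal <- sort(unique(cluster_tree$edge[, 1L]))
  is_dup <- vapply(internal, function(nd) {
    any(lca_map[node_children(cluster_tree, nd)] == lca_map[nd])
  }, logical(1))
  structure(list(
    duplication_nodes = internal[is_dup],
    duplication_count = sum(is_dup),
    lca_map = lca_map),
    class = "reconciliation_result")
}

#' Audit a cluster's absence in one species into loss vs. unlinking
#'
#' Decouples disruption classification from the presence matrix so that an
#' "absent" cell can be explained: both or one member gene genuinely
#' missing from the annotation, both present but separated beyond the
#' criteria on one scaffold (e.g. the >1 Mb Drosophila arrangement), or
#' residing on different scaffolds.
#'
#' @param species species label.
#' @param cluster cluster label (carried through into the call).
#' @param annotation the species' [genome_annotation()].
#' @param groups character vector of the cluster's two member
#'   ortholog-group labels.
#' @param criteria a [pair_criteria()].
#' @param missing_policy with `"absent"` (default) an unannotated member
#'   counts as lost; with `"unknown"` a missing member yields mode
#'   `"unknown"` so patchy annotations are not read as losses.
#' @return List of class `disruption_call` with `species`, `cluster` and
#'   `mode` (one of `intact`, `both_genes_lost`, `one_gene_lost`,
#'   `unlinked_same_scaffold`, `unlinked_different_scaffold`, or
#'   `"unknown"` under the `"unknown"` policy).
#' @export
classify_disruption <- function(species, cluster, annotation, groups,
                                criteria = pair_criteria(),
                                missing_policy = c("absent", "unknown")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(groups) == 2L)
  ann <- annotation[annotation$species == species, , drop = FALSE]
  g1 <- ann[ann$group == groups[1L], , drop = FALSE]
  g2 <- ann[ann$group == groups[2L], , drop = FALSE]
  n_missing <- (nrow(g1) == 0L) + (nrow(g2) == 0L)
  mode <- if (n_missing > 0L) {
    if (missing_policy == "unknown") "unknown"
    else if (n_missing == 2L) "both_genes_lost"
    else "one_gene_lost"
  } else {
    same_scaffold <- FALSE
    intact <- FALSE
    for (i in seq_len(nrow(g1))) {
      for (j in seq_len(nrow(g2))) {
        a <- g1[i, , drop = FALSE]
        b <- g2[j, , drop = FALSE]
        if (a$scaffold != b$scaffold) next
        same_scaffold <- TRUE
        if (intergenic_distance(a, b) > criteria$max_intergenic_bp) next
        if (criteria$require_same_orientation && a$strand != b$strand) next
        if (interposed_count(a, b, annotation) > criteria$max_interposed) next
        intact <- TRUE
      }
    }
    if (intact) "intact"
    else if (same_scaffold) "unlinked_same_scaffold"
    else "unlinked_different_scaffold"
  }
  structure(list(species = species, cluster = cluster, mode = mode),
            class = "disruption_call")
}

#' Retrieve a node's age annotation
#'
#' Ages are user-supplied annotations (see [set_node_age()]); no inference
#' is performed.
#'
#' @param tree an [ape::phylo] tree.
#' @param node integer node id, or character vector of leaf labels
#'   addressing the node via [node_by_tips()].
#' @return Numeric age in million years, or the string `"unknown"` if the
#'   node carries no annotation.
#' @examples
#' tr <- builtin_fixture("species_tree_fig1")
#' date_node(tr, setdiff(tr$tip.label, "A_queenslandica"))  # 820
#' @export
date_node <- function(tree, node) {
  if (is.character(node)) {
    node <- node_by_tips(tree, node)
  } else {
    node <- as.integer(node)
    if (node < 1L || node > length(tree$tip.label) + tree$Nnode) {
      stop("node ", node, " not in tree")
    }
  }
  ages <- attr(tree, "node_ages")
  if (is.null(ages) || is.na(ages[as.character(node)]) ||
      !as.character(node) %in% names(ages)) {
    return("unknown")
  }
  unname(ages[as.character(node)])
}
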