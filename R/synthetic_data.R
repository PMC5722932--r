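# Forward simulator of gene-order evolution along a species tree: a root
# genome of background genes evolves by cluster gain, en-bloc cluster
# duplication, gene loss, inversion, translocation and background gene
# insertion. Every stochastic draw comes from R's RNG seeded once from
# SimParams, so a fixed seed reproduces the output exactly. The simulator
# emits per-species annotations, an ortholog table, a true event log, and
# the implied presence matrix — ground truth for recovery tests of the
# detection and reconstruction operations.

#' Simulation parameters
#'
#' Branches are addressed by the leaf set of the clade below them (see
#' [node_by_tips()]); the gain branch is the edge above that clade's
#' ancestor. Rates are events per unit branch length (branches without
#' lengths count as length 1); event counts per branch are Poisson with
#' mean rate x branch length. A loss event deletes one randomly chosen
#' cluster gene; an inversion reverses a random window of a scaffold
#' (flipping strands); a translocation moves a single randomly chosen gene
#' to a random position, unlinking without loss; an insertion adds a new
#' background gene.
#'
#' @param gain_tips leaf labels addressing the cluster-gain branch.
#' @param duplication_tips list of leaf-label vectors, one per duplication
#'   event, each addressing a branch at or below the gain branch. Repeat a
#'   branch for successive duplications on it.
#' @param loss_rate,inversion_rate,translocation_rate,background_insertion_rate
#'   non-negative event rates per unit branch length.
#' @param n_background_genes background genes in the root genome.
#' @param n_scaffolds scaffolds in the root genome.
#' @param seed integer RNG seed.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(gain_tips, duplication_tips = list(),
                       loss_rate = 0, inversion_rate = 0,
                       translocation_rate = 0,
                       background_insertion_rate = 0,
                       n_background_genes = 20L, n_scaffolds = 2L,
                       seed = 1L) {
  rates <- c(loss_rate, inversion_rate, translocation_rate,
             background_insertion_rate)
  if (any(rates < 0)) stop("rates must be non-negative")
  stopifnot(n_background_genes >= 0L, n_scaffolds >= 1L)
  structure(list(gain_tips = gain_tips,
                 duplication_tips = duplication_tips,
                 loss_rate = loss_rate, inversion_rate = inversion_rate,
                 translocation_rate = translocation_rate,
                 background_insertion_rate = background_insertion_rate,
                 n_background_genes = as.integer(n_background_genes),
                 n_scaffolds = as.integer(n_scaffolds),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# --- internal genome representation -----------------------------------
# genome$scaffolds: named list, scaffold -> ordered character vector of ids
# genome$genes: data frame keyed by id with strand, group, family, cluster
#   (label or NA) and role ("PDI"/"GDI"/NA)

new_gene_row <- function(id, strand, group, family,
                         cluster = NA_character_, role = NA_character_) {
  n <- length(id)
  data.frame(id = id, strand = strand, group = group, family = family,
             cluster = rep_len(cluster, n), role = rep_len(role, n),
             stringsAsFactors = FALSE)
}

genome_insert <- function(genome, scaffold, at, rows) {
  vec <- genome$scaffolds[[scaffold]]
  genome$scaffolds[[scaffold]] <- append(vec, rows$id, after = at)
  genome$genes <- rbind(genome$genes, rows)
  genome
}

genome_remove <- function(genome, id) {
  for (s in names(genome$scaffolds)) {
    genome$scaffolds[[s]] <- setdiff(genome$scaffolds[[s]], id)
  }
  genome$genes <- genome$genes[genome$genes$id != id, , drop = FALSE]
  genome
}

gene_scaffold <- function(genome, id) {
  for (s in names(genome$scaffolds)) {
    if (id %in% genome$scaffolds[[s]]) return(s)
  }
  NA_character_
}

# a cluster is intact when both members exist on one scaffold, same strand,
# with at most 3 genes between them (mirrors the default detection criteria)
cluster_intact <- function(genome, cluster) {
  rows <- genome$genes[!is.na(genome$genes$cluster) &
                       genome$genes$cluster == cluster, , drop = FALSE]
  if (nrow(rows) != 2L) return(FALSE)
  s1 <- gene_scaffold(genome, rows$id[1L])
  s2 <- gene_scaffold(genome, rows$id[2L])
  if (is.na(s1) || is.na(s2) || s1 != s2) return(FALSE)
  if (rows$strand[1L] != rows$strand[2L]) return(FALSE)
  vec <- genome$scaffolds[[s1]]
  abs(match(rows$id[1L], vec) - match(rows$id[2L], vec)) - 1L <= 3L
}

intact_clusters <- function(genome, clusters) {
  clusters[vapply(clusters, cluster_intact, logical(1), genome = genome)]
}

random_site <- function(genome) {
  scaffold <- sample(names(genome$scaffolds), 1L)
  list(scaffold = scaffold,
       at = sample.int(length(genome$scaffolds[[scaffold]]) + 1L, 1L) - 1L)
}

#' Simulate gene-order evolution along a species tree
#'
#' See [sim_params()] for the generative model. On the gain branch a linked
#' two-gene cluster (one PDI-family, one RhoGDI-family gene, adjacent, same
#' strand) is inserted; each duplication copies a randomly chosen intact
#' cluster en bloc (both genes, their order and strands) to a random
#' position, founding a new paralogous cluster.
#'
#' @param tree rooted [ape::phylo] species tree.
#' @param params a [sim_params()].
#' @return List of class `sim_output`:
#'   `annotations` (species -> [genome_annotation()]),
#'   `ortholog_table` (data frame gene_id -> group),
#'   `truth` (event log with per-event linkage effects; class
#'   `event_history` carrying the cluster labels as an attribute),
#'   `truth_matrix` ([presence_matrix()] of intact clusters per species),
#'   plus the `tree` and `params` used.
#' @export
simulate_gene_order <- function(tree, params) {
  stopifnot(inherits(params, "sim_params"))
  validate_tree(tree)
  set.seed(params$seed)

  gain_node <- node_by_tips(tree, params$gain_tips)
  if (gain_node == length(tree$tip.label) + 1L) {
    stop("gain branch must be a proper branch of the tree; ",
         "the root has no stem edge")
  }
  dup_nodes <- vapply(params$duplication_tips, node_by_tips,
                      integer(1), tree = tree)
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  under_gain <- function(nd) {
    while (nd != 0L) {
      if (nd == gain_node) return(TRUE)
      if (nd == root) return(FALSE)
      nd <- parent_of[nd]
    }
    FALSE
  }
  if (!all(vapply(dup_nodes, under_gain, logical(1)))) {
    stop("duplication branches must be at or below the gain branch")
  }

  # root genome
  scaffolds <- paste0("S", seq_len(params$n_scaffolds))
  genome0 <- list(
    scaffolds = setNames(vector("list", length(scaffolds)), scaffolds),
    genes = new_gene_row(character(0), character(0), character(0),
                         character(0)))
  for (s in scaffolds) genome0$scaffolds[[s]] <- character(0)
  if (params$n_background_genes > 0L) {
    for (i in seq_len(params$n_background_genes)) {
      id <- sprintf("bg%03d", i)
      site <- random_site(genome0)
      genome0 <- genome_insert(
        genome0, site$scaffold, site$at,
        new_gene_row(id, sample(c("+", "-"), 1L), paste0("BG", i), "other"))
    }
  }

  events <- list()
  clusters <- character(0)
  bg_counter <- params$n_background_genes

  record <- function(type, node, cluster = NA, gene = NA,
                     before, after) {
    disrupted <- setdiff(before, after)
    restored <- setdiff(after, before)
    events[[length(events) + 1L]] <<- data.frame(
      type = type, node = as.integer(node),
      cluster = as.character(cluster), gene = as.character(gene),
      disrupts = paste(disrupted, collapse = ","),
      restores = paste(restored, collapse = ","),
      stringsAsFactors = FALSE)
  }

  branch_length <- function(child) {
    if (is.null(tree$edge.length)) return(1)
    tree$edge.length[match(child, tree$edge[, 2L])]
  }

  apply_branch <- function(genome, child) {
    bl <- branch_length(child)
    if (child == gain_node) {
      lab <- sprintf("C%d", length(clusters) + 1L)
      clusters <<- c(clusters, lab)
      strand <- sample(c("+", "-"), 1L)
      site <- random_site(genome)
      rows <- rbind(
        new_gene_row(paste0(lab, "_pdi"), strand, paste0("PDI_", lab),
                     "PDI", lab, "PDI"),
        new_gene_row(paste0(lab, "_gdi"), strand, paste0("GDI_", lab),
                     "RhoGDI", lab, "GDI"))
      before <- intact_clusters(genome, clusters)
      genome <- genome_insert(genome, site$scaffold, site$at, rows)
      record("gain", child, cluster = lab,
             before = before, after = intact_clusters(genome, clusters))
    }
    for (k in which(dup_nodes == child)) {
      sources <- intact_clusters(genome, clusters)
      # a cluster already destroyed upstream cannot duplicate; the
      # scheduled event silently does not happen (only possible when
      # stochastic rates are non-zero)
      if (length(sources) == 0L) next
      src <- if (length(sources) == 1L) sources else sample(sources, 1L)
      lab <- sprintf("C%d", length(clusters) + 1L)
      clusters <<- c(clusters, lab)
      src_rows <- genome$genes[!is.na(genome$genes$cluster) &
                               genome$genes$cluster == src, , drop = FALSE]
      src_scaffold <- gene_scaffold(genome, src_rows$id[1L])
      vec <- genome$scaffolds[[src_scaffold]]
      src_rows <- src_rows[order(match(src_rows$id, vec)), , drop = FALSE]
      rows <- src_rows
      rows$id <- paste0(lab, "_", tolower(rows$role))
      rows$group <- paste0(rows$role, "_", lab)
      rows$cluster <- lab
      site <- random_site(genome)
      before <- intact_clusters(genome, clusters)
      genome <- genome_insert(genome, site$scaffold, site$at, rows)
      record("duplication", child, cluster = lab, gene = src,
             before = before, after = intact_clusters(genome, clusters))
    }
    n_ev <- c(loss = rpois(1L, params$loss_rate * bl),
              inversion = rpois(1L, params$inversion_rate * bl),
              translocation = rpois(1L, params$translocation_rate * bl),
              insertion = rpois(1L, params$background_insertion_rate * bl))
    queue <- rep(names(n_ev), n_ev)
    if (length(queue) > 1L) queue <- sample(queue)
    for (ev in queue) {
      before <- intact_clusters(genome, clusters)
      if (ev == "loss") {
        cl_genes <- genome$genes$id[!is.na(genome$genes$cluster)]
        if (length(cl_genes) == 0L) next
        victim <- if (length(cl_genes) == 1L) cl_genes
                  else sample(cl_genes, 1L)
        cl <- genome$genes$cluster[genome$genes$id == victim]
        genome <- genome_remove(genome, victim)
        record("loss", child, cluster = cl, gene = victim,
               before = before, after = intact_clusters(genome, clusters))
      } else if (ev == "inversion") {
        sizes <- vapply(genome$scaffolds, length, integer(1))
        cand <- names(sizes)[sizes >= 2L]
        if (length(cand) == 0L) next
        s <- if (length(cand) == 1L) cand else sample(cand, 1L)
        n <- length(genome$scaffolds[[s]])
        ij <- sort(sample.int(n, 2L))
        seg <- seq(ij[1L], ij[2L])
        ids <- genome$scaffolds[[s]][seg]
        genome$scaffolds[[s]][seg] <- rev(ids)
        flip <- genome$genes$id %in% ids
        genome$genes$strand[flip] <-
          ifelse(genome$genes$strand[flip] == "+", "-", "+")
        record("inversion", child, gene = paste(ids, collapse = ","),
               before = before, after = intact_clusters(genome, clusters))
      } else if (ev == "translocation") {
        ids <- genome$genes$id
        if (length(ids) == 0L) next
        id <- if (length(ids) == 1L) ids else sample(ids, 1L)
        row <- genome$genes[genome$genes$id == id, , drop = FALSE]
        genome <- genome_remove(genome, id)
        site <- random_site(genome)
        genome <- genome_insert(genome, site$scaffold, site$at, row)
        record("translocation", child,
               cluster = if (is.na(row$cluster)) NA else row$cluster,
               gene = id,
               before = before, after = intact_clusters(genome, clusters))
      } else {
        bg_counter <<- bg_counter + 1L
        id <- sprintf("bg%03d", bg_counter)
        site <- random_site(genome)
        genome <- genome_insert(
          genome, site$scaffold, site$at,
          new_gene_row(id, sample(c("+", "-"), 1L),
                       paste0("BG", bg_counter), "other"))
        record("insertion", child, gene = id,
               before = before, after = intact_clusters(genome, clusters))
      }
    }
    genome
  }

  leaf_genomes <- vector("list", ntip)
  descend <- function(node, genome) {
    for (child in node_children(tree, node)) {
      g <- apply_branch(genome, child)
      if (child <= ntip) leaf_genomes[[child]] <<- g else descend(child, g)
    }
  }
  # events on the root's own stem are not modelled; evolution starts at root
  descend(root, genome0)

  annotations <- list()
  ortho <- list()
  tm <- matrix("absent", nrow = max(1L, length(clusters)), ncol = ntip,
               dimnames = list(if (length(clusters)) clusters else "none",
                               tree$tip.label))
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    g <- leaf_genomes[[i]]
    rows <- list()
    for (s in names(g$scaffolds)) {
      ids <- g$scaffolds[[s]]
      if (length(ids) == 0L) next
      info <- g$genes[match(ids, g$genes$id), , drop = FALSE]
      start <- (seq_along(ids) - 1L) * 10000L + 1L
      rows[[s]] <- data.frame(
        gene_id = paste0(sp, "_", ids), species = sp, scaffold = s,
        start = start, end = start + 999L, strand = info$strand,
        group = info$group,
        family = ifelse(info$family %in% c("PDI", "RhoGDI"),
                        info$family, "other"),
        stringsAsFactors = FALSE)
    }
    ann <- if (length(rows) == 0L) empty_annotation() else
      genome_annotation(do.call(rbind, c(rows, list(
        make.row.names = FALSE))))
    annotations[[sp]] <- ann
    ortho[[sp]] <- data.frame(gene_id = ann$gene_id, group = ann$group,
                              stringsAsFactors = FALSE)
    for (cl in intact_clusters(g, clusters)) tm[cl, sp] <- "present"
  }

  truth <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), node = integer(), cluster = character(),
               gene = character(), disrupts = character(),
               restores = character(), stringsAsFactors = FALSE)
  attr(truth, "clusters") <- clusters
  class(truth) <- c("event_history", "data.frame")

  structure(list(
    annotations = annotations,
    ortholog_table = do.call(rbind, c(ortho, list(make.row.names = FALSE))),
    truth = truth,
    truth_matrix = if (length(clusters)) presence_matrix(tm) else NULL,
    tree = tree, params = params),
    class = "sim_output")
}

#' Replay an event history into a presence matrix
#'
#' Walks the root-to-leaf path of every species and propagates cluster
#' state through the logged events: a gain or duplication introduces its
#' cluster; an event's `disrupts`/`restores` fields toggle linkage. The
#' result is the presence matrix the history implies, independent of the
#' simulated coordinates.
#'
#' @param truth an `event_history` (see [simulate_gene_order()]). Events
#'   must be logged in evolutionary order (as the simulator does).
#' @param tree the species tree the history is anchored to.
#' @return A [presence_matrix()] (all states known: present/absent).
#' @export
replay_truth <- function(truth, tree) {
  clusters <- attr(truth, "clusters")
  if (is.null(clusters)) {
    clusters <- sort(unique(truth$cluster[truth$type %in%
                                          c("gain", "duplication")]))
  }
  if (length(clusters) == 0L) stop("history contains no cluster gain")
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  m <- matrix("absent", nrow = length(clusters), ncol = ntip,
              dimnames = list(clusters, tree$tip.label))
  split_field <- function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ",")[[1L]]
  }
  for (i in seq_len(ntip)) {
    path <- i
    nd <- i
    while (nd != root) {
      nd <- parent_of[nd]
      path <- c(nd, path)
    }
    alive <- character(0)   # clusters that exist (genes extant)
    linked <- character(0)  # clusters currently intact
    rows <- truth[truth$node %in% path, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      ev <- rows[j, ]
      if (ev$type %in% c("gain", "duplication")) {
        alive <- union(alive, ev$cluster)
      }
      if (ev$type == "loss") {
        if (!ev$cluster %in% alive) {
          stop("inconsistent history: loss of non-existent cluster ",
               ev$cluster)
        }
        alive <- setdiff(alive, ev$cluster)
      }
      dis <- split_field(ev$disrupts)
      res <- split_field(ev$restores)
      if (length(setdiff(c(dis, res), c(alive, ev$cluster)))) {
        stop("inconsistent history: linkage change for unknown cluster")
      }
      linked <- union(setdiff(linked, dis), res)
    }
    m[linked, i] <- "present"
  }
  presence_matrix(m)
}

#' Paralog-cluster tree implied by a simulation's truth
#'
#' Builds the cluster (paralog) tree a sequence phylogeny would recover
#' under the logged history: duplication events nest the new cluster as
#' sister to its source cluster, and each cluster lineage is expanded into
#' the species subtree of the species retaining it (leaves labelled
#' `cluster@species`). Used to test duplication-count recovery by
#' [reconcile_duplications()].
#'
#' @param sim a `sim_output`.
#' @return List with `tree` ([ape::phylo]) and `species_map` (leaf label ->
#'   species), or `NULL` when fewer than two leaves would remain.
#' @export
true_cluster_tree <- function(sim) {
  truth <- sim$truth
  tm <- sim$truth_matrix
  if (is.null(tm)) return(NULL)
  origins <- truth[truth$type %in% c("gain", "duplication"), , drop = FALSE]
  # nested cluster-level topology: duplication splices (source, new)
  topo <- NULL
  for (i in seq_len(nrow(origins))) {
    ev <- origins[i, ]
    if (ev$type == "gain") {
      topo <- ev$cluster
    } else {
      splice <- function(node) {
        if (is.character(node)) {
          if (node == ev$gene) list(node, ev$cluster) else node
        } else {
          lapply(node, splice)
        }
      }
      topo <- splice(topo)
    }
  }
  subtree_nwk <- function(cl) {
    sp <- colnames(tm)[tm[cl, ] == "present"]
    if (length(sp) == 0L) return(NULL)
    if (length(sp) == 1L) return(paste0(cl, "@", sp))
    st <- ape::keep.tip(sim$tree, sp)
    st$tip.label <- paste0(cl, "@", st$tip.label)
    st$edge.length <- NULL
    sub(";$", "", ape::write.tree(st))
  }
  render <- function(node) {
    if (is.character(node)) return(subtree_nwk(node))
    parts <- Filter(Negate(is.null), lapply(node, render))
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- render(topo)
  if (is.null(nwk) || !grepl(",", nwk)) return(NULL)
  tree <- read_newick_text(paste0(nwk, ";"))
  list(tree = tree,
       species_map = setNames(sub("^.*@", "", tree$tip.label),
                              tree$tip.label))
}
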