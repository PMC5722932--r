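#' Construct a genome annotation from a gene table
#'
#' A genome annotation is a data frame of gene records — one row per gene,
#' with 1-based inclusive coordinates — sorted by (scaffold, start). It is
#' the coordinate-level container every downstream operation consumes; no
#' sequence is attached, the pipeline is entirely coordinate- and
#' label-based.
#'
#' @param genes data frame with columns `gene_id`, `species`, `scaffold`,
#'   `start`, `end`, `strand` ("+" or "-"), `group` (ortholog-group label)
#'   and `family` ("PDI", "RhoGDI" or "other").
#' @return A `genome_annotation`: the validated data frame, sorted by
#'   (scaffold, start, gene_id), with row names dropped.
#' @examples
#' ann <- genome_annotation(data.frame(
#'   gene_id = c("g2", "g1"), species = "toy", scaffold = "s1",
#'   start = c(500L, 100L), end = c(900L, 200L), strand = "+",
#'   group = c("B", "A"), family = "other"))
#' ann$gene_id  # sorted by start: g1, g2
#' @export
genome_annotation <- function(genes) {
  required <- c("gene_id", "species", "scaffold", "start", "end",
                "strand", "group", "family")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0L) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "))
  }
  genes <- as.data.frame(genes)[required]
  genes$gene_id  <- as.character(genes$gene_id)
  genes$species  <- as.character(genes$species)
  genes$scaffold <- as.character(genes$scaffold)
  genes$strand   <- as.character(genes$strand)
  genes$group    <- as.character(genes$group)
  genes$family   <- as.character(genes$family)
  genes$start    <- as.integer(genes$start)
  genes$end      <- as.integer(genes$end)
  if (nrow(genes) > 0L) {
    bad <- genes$start > genes$end
    if (any(bad)) {
      stop("start > end for gene_id: ",
           paste(genes$gene_id[bad], collapse = ", "))
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      bad <- genes$gene_id[!genes$strand %in% c("+", "-")]
      stop("strand must be '+' or '-' (gene_id: ",
           paste(bad, collapse = ", "), ")")
    }
    key <- paste(genes$species, genes$gene_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (species, gene_id): ",
           paste(unique(genes$gene_id[duplicated(key)]), collapse = ", "))
    }
    genes <- genes[order(genes$scaffold, genes$start, genes$gene_id), ]
  }
  rownames(genes) <- NULL
  class(genes) <- c("genome_annotation", "data.frame")
  genes
}

#' Read a gene table from TSV or GFF3
#'
#' The TSV dialect has a header line with the eight annotation columns
#' (`gene_id`, `species`, `scaffold`, `start`, `end`, `strand`, `group`,
#' `family`). GFF3 input is read through [rtracklayer::import()]; only
#' features of type `gene` are kept and the `ID` attribute becomes
#' `gene_id`. GFF3 coordinates are 1-based inclusive per the standard and
#' are taken as-is. Optional GFF3 attributes `group` and `family` are
#' honoured; absent ones default to the gene ID / "other".
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param species species label to assign when the file does not carry one
#'   (required for GFF3; for TSV it overrides nothing).
#' @param strip_chr if `TRUE`, a leading `"chr"` is stripped from scaffold
#'   names at the boundary. Off by default: scaffolds compare as exact
#'   strings.
#' @return A [genome_annotation()].
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"),
                            species = NULL, strip_chr = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    if (file.size(path) == 0L ||
        length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
      warning("empty gene table: ", path)
      return(empty_annotation())
    }
    tab <- tryCatch(
      read.delim(path, header = TRUE, sep = "\t", quote = "",
                 colClasses = "character", comment.char = "#"),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e)))
    if (nrow(tab) == 0L) {
      warning("empty gene table: ", path)
      return(empty_annotation())
    }
    nstart <- suppressWarnings(as.integer(tab$start))
    nend <- suppressWarnings(as.integer(tab$end))
    bad <- which(is.na(nstart) | is.na(nend))
    if (length(bad) > 0L) {
      stop("malformed line ", bad[1L] + 1L, " in ", path,
           ": non-numeric coordinate")
    }
    tab$start <- nstart
    tab$end <- nend
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e)))
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) {
      warning("no gene features in ", path)
      return(empty_annotation())
    }
    if (is.null(gr$ID) || anyNA(gr$ID)) {
      stop("GFF3 gene feature without ID attribute in ", path)
    }
    if (is.null(species)) stop("species label required for GFF3 input")
    meta <- as.data.frame(gr)
    tab <- data.frame(
      gene_id = as.character(meta$ID),
      species = species,
      scaffold = as.character(meta$seqnames),
      start = meta$start,
      end = meta$end,
      strand = as.character(meta$strand),
      group = if ("group" %in% names(meta)) as.character(meta$group)
              else as.character(meta$ID),
      family = if ("family" %in% names(meta)) as.character(meta$family)
               else "other",
      stringsAsFactors = FALSE)
  }
  if (strip_chr) tab$scaffold <- sub("^chr", "", tab$scaffold)
  genome_annotation(tab)
}

#' Write a genome annotation as TSV
#'
#' Inverse of [read_gene_table()] for the TSV dialect: writing then reading
#' reproduces every field exactly.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(annotation, path) {
  write.table(as.data.frame(annotation), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

empty_annotation <- function() {
  genome_annotation(data.frame(
    gene_id = character(), species = character(), scaffold = character(),
    start = integer(), end = integer(), strand = character(),
    group = character(), family = character(), stringsAsFactors = FALSE))
}

#' Read a rooted species tree in Newick format
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' evolutionary operations rely on: a single tree, unique leaf labels,
#' a root. Polytomies are preserved (Dollo reconstruction accepts them;
#' reconciliation rejects them at its own boundary).
#'
#' @param path file path containing one Newick tree.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1L]]
  }
  validate_tree(tr)
  tr
}

#' @rdname read_newick
#' @param text a Newick string (alternative entry point for trees built in
#'   code).
#' @export
read_newick_text <- function(text) {
  tr <- suppressWarnings(ape::read.tree(text = text))
  if (is.null(tr)) stop("Newick parse error")
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylogenetic tree")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  }
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  invisible(tr)
}

#' Address a tree node by its set of descendant leaves
#'
#' Internal nodes are addressed by the exact set of leaves they subtend;
#' a single leaf label addresses that leaf. Errors if no node subtends
#' exactly the given set.
#'
#' @param tree an [ape::phylo] tree.
#' @param tips character vector of leaf labels.
#' @return Integer node id (ape numbering).
#' @export
node_by_tips <- function(tree, tips) {
  tips <- unique(as.character(tips))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("leaf label(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  node <- ape::getMRCA(tree, tips)
  below <- tree$tip.label[descendant_tips(tree, node)]
  if (!setequal(below, tips)) {
    stop("no node subtends exactly {", paste(sort(tips), collapse = ", "),
         "}; nearest clade adds: ",
         paste(setdiff(below, tips), collapse = ", "))
  }
  node
}

# tip indices below a node (a tip is below itself)
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- node_children(tree, node)
  unlist(lapply(kids, descendant_tips, tree = tree), use.names = FALSE)
}

node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

#' Annotate a tree node with an age
#'
#' Ages (in million years) are annotations carried alongside the tree; no
#' inference is performed. [date_node()] retrieves them.
#'
#' @param tree an [ape::phylo] tree.
#' @param tips leaf label(s) addressing the node (see [node_by_tips()]).
#' @param age_mya numeric age in million years.
#' @return The tree with the annotation attached.
#' @export
set_node_age <- function(tree, tips, age_mya) {
  node <- node_by_tips(tree, tips)
  ages <- attr(tree, "node_ages")
  if (is.null(ages)) ages <- numeric(0)
  ages[as.character(node)] <- as.numeric(age_mya)
  attr(tree, "node_ages") <- ages
  tree
}
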