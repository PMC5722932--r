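#' Detection criteria for microsyntenic pairs
#'
#' Microsynteny is fine-scale syntenic linkage with no or very few genes
#' interposed. The defaults operationalise that: at most 500 kb between the
#' facing gene boundaries (admits the coelacanth pairs at 84.5 and 198.8 kb
#' while rejecting the >1 Mb Drosophila separation), at most 3 interposed
#' genes, and the same transcription direction for both genes.
#'
#' @param max_intergenic_bp maximum intergenic distance in bp (> 0).
#' @param max_interposed maximum number of interposed genes (>= 0).
#' @param require_same_orientation must both genes share a strand?
#' @return A `pair_criteria` list.
#' @export
pair_criteria <- function(max_intergenic_bp = 500000L,
                          max_interposed = 3L,
                          require_same_orientation = TRUE) {
  if (max_intergenic_bp <= 0) stop("max_intergenic_bp must be > 0")
  if (max_interposed < 0) stop("max_interposed must be >= 0")
  structure(list(max_intergenic_bp = as.integer(max_intergenic_bp),
                 max_interposed = as.integer(max_interposed),
                 require_same_orientation = isTRUE(require_same_orientation)),
            class = "pair_criteria")
}

get_gene <- function(annotation, gene_id) {
  i <- match(gene_id, annotation$gene_id)
  if (is.na(i)) stop("gene not in annotation: ", gene_id)
  annotation[i, , drop = FALSE]
}

#' Intergenic distance between two genes on one scaffold
#'
#' The distance is the simple difference between the facing boundaries:
#' `max(0, max(starts) - min(ends))`. Overlapping or boundary-sharing genes
#' are at distance 0. This equals the minimum base-to-base distance between
#' the two gene intervals and is symmetric in argument order. No -1 gap
#' correction is applied; at the two-significant-figure reporting precision
#' both conventions agree on every published value.
#'
#' @param g1,g2 one-row gene records (rows of a [genome_annotation()]).
#' @return Non-negative integer distance in bp.
#' @examples
#' ann <- builtin_fixture("human_table1")
#' intergenic_distance(ann[ann$gene_id == "ARHGDIG", ],
#'                     ann[ann$gene_id == "PDIA2", ])  # 142
#' @export
intergenic_distance <- function(g1, g2) {
  if (g1$scaffold != g2$scaffold) {
    stop("genes on different scaffolds: ", g1$scaffold, " vs ", g2$scaffold)
  }
  max(0L, max(g1$start, g2$start) - min(g1$end, g2$end))
}

#' Count genes interposed between two genes
#'
#' A gene counts as interposed when its interval midpoint lies strictly
#' between the facing boundaries of the two query genes. The two query
#' genes themselves never count.
#'
#' @param g1,g2 one-row gene records, both present in `annotation` and on
#'   the same scaffold; `g1` and `g2` must be distinct genes.
#' @param annotation a [genome_annotation()].
#' @return Non-negative integer count.
#' @export
interposed_count <- function(g1, g2, annotation) {
  r1 <- get_gene(annotation, g1$gene_id)
  r2 <- get_gene(annotation, g2$gene_id)
  if (r1$gene_id == r2$gene_id) stop("g1 and g2 are the same gene")
  if (r1$scaffold != r2$scaffold) {
    stop("genes on different scaffolds: ", r1$scaffold, " vs ", r2$scaffold)
  }
  lo <- min(r1$end, r2$end)
  hi <- max(r1$start, r2$start)
  if (hi <= lo) return(0L)  # overlapping/book-ended: nothing fits between
  others <- annotation[annotation$scaffold == r1$scaffold &
                       !(annotation$gene_id %in% c(r1$gene_id, r2$gene_id)), ,
                       drop = FALSE]
  if (nrow(others) == 0L) return(0L)
  mid <- (others$start + others$end) / 2
  sum(mid > lo & mid < hi)
}

#' Detect microsyntenic PDI/RhoGDI-style pairs in an annotation
#'
#' Enumerates all (PDI-family, RhoGDI-family) gene pairs sharing a scaffold,
#' keeps those meeting the [pair_criteria()], and greedily matches each gene
#' into at most one reported pair: candidates are taken in order of
#' ascending intergenic distance, ties broken by the lexicographic pair of
#' gene IDs. The result is sorted by (scaffold, leftmost start) and is
#' independent of input row order.
#'
#' @param annotation a [genome_annotation()] carrying `family` labels.
#' @param criteria a [pair_criteria()].
#' @return Data frame of class `syntenic_pairs` with one row per detected
#'   pair: `species`, `scaffold`, `gene_pdi`, `gene_gdi`, `group_pdi`,
#'   `group_gdi`, `intergenic_distance_bp`, `interposed_genes`,
#'   `same_orientation`.
#' @examples
#' detect_pairs(builtin_fixture("human_table1"))  # the three human pairs
#' @export
detect_pairs <- function(annotation, criteria = pair_criteria()) {
  stopifnot(inherits(criteria, "pair_criteria"))
  empty <- data.frame(species = character(), scaffold = character(),
                      gene_pdi = character(), gene_gdi = character(),
                      group_pdi = character(), group_gdi = character(),
                      intergenic_distance_bp = integer(),
                      interposed_genes = integer(),
                      same_orientation = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("syntenic_pairs", "data.frame")
  pdi <- annotation[annotation$family == "PDI", , drop = FALSE]
  gdi <- annotation[annotation$family == "RhoGDI", , drop = FALSE]
  if (nrow(pdi) == 0L || nrow(gdi) == 0L) return(empty)
  cand <- list()
  for (i in seq_len(nrow(pdi))) {
    for (j in seq_len(nrow(gdi))) {
      a <- pdi[i, , drop = FALSE]
      b <- gdi[j, , drop = FALSE]
      if (a$scaffold != b$scaffold) next
      d <- intergenic_distance(a, b)
      if (d > criteria$max_intergenic_bp) next
      same <- a$strand == b$strand
      if (criteria$require_same_orientation && !same) next
      k <- interposed_count(a, b, annotation)
      if (k > criteria$max_interposed) next
      cand[[length(cand) + 1L]] <- data.frame(
        species = a$species, scaffold = a$scaffold,
        gene_pdi = a$gene_id, gene_gdi = b$gene_id,
        group_pdi = a$group, group_gdi = b$group,
        intergenic_distance_bp = d, interposed_genes = k,
        same_orientation = same, min_start = min(a$start, b$start),
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  # greedy one-pair-per-gene matching by smallest distance, deterministic
  cand <- cand[order(cand$intergenic_distance_bp, cand$gene_pdi,
                     cand$gene_gdi), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$gene_pdi[i] %in% used || cand$gene_gdi[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, cand$gene_pdi[i], cand$gene_gdi[i])
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$scaffold, out$min_start, out$gene_pdi), , drop = FALSE]
  out$min_start <- NULL
  rownames(out) <- NULL
  class(out) <- c("syntenic_pairs", "data.frame")
  out
}

# round half-up to 2 significant figures (float-safe for bp-derived values)
signif2_half_up <- function(x) {
  if (x == 0) return(0)
  e <- floor(log10(abs(x)))
  scale <- 10^(e - 1)
  floor(abs(x) / scale + 0.5 + 1e-9) * scale * sign(x)
}

format_sig2 <- function(value) {
  v <- signif2_half_up(value)
  decimals <- max(0L, 1L - floor(log10(abs(v))))
  s <- formatC(v, format = "f", digits = decimals)
  # trim trailing zeros beyond the first decimal place ("0.40" -> "0.4",
  # but "1.0" stays "1.0")
  while (grepl("\\.\\d+0$", s)) s <- sub("0$", "", s)
  s
}

#' Format a bp distance in kb at two significant figures
#'
#' Reporting convention of the published tables: half-up rounding to two
#' significant figures, e.g. 142 bp is "0.14 kb" and 2,935 bp is "2.9 kb".
#'
#' @param distance_bp non-negative distance in bp.
#' @return Character scalar like `"0.14 kb"`; `0` formats as `"0 kb"`.
#' @export
format_kb <- function(distance_bp) {
  stopifnot(distance_bp >= 0)
  if (distance_bp == 0) return("0 kb")
  paste0(format_sig2(distance_bp / 1000), " kb")
}
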