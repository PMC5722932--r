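# Enhancer blocks and CAMP calling. Blocks are genomic intervals carrying
# aggregated enhancer evidence; a syntenic pair whose two genes both lie
# within a TSS-distance window of the same block shares that block, and a
# pair sharing at least one block qualifies as a conserved ancestral
# microsyntenic pair (CAMP).

#' Enhancer block size formatted in kb
#'
#' `(end - start) / 1000`, half-up rounded to two significant figures —
#' the reporting convention of the published block table.
#'
#' @param block one-row data frame (or list) with `start` and `end`.
#' @return Character scalar, e.g. `"8.9"`.
#' @examples
#' block_size_kb(list(start = 81864502, end = 81873384))  # "8.9"
#' @export
block_size_kb <- function(block) {
  if (block$start >= block$end) {
    stop("invalid block: start (", block$start, ") >= end (", block$end, ")")
  }
  format_sig2((block$end - block$start) / 1000)
}

#' Transcription start site of a gene record
#'
#' Under the coordinate convention used throughout: the `start` coordinate
#' for a plus-strand gene, the `end` coordinate for a minus-strand gene.
#'
#' @param gene one-row gene record.
#' @return Integer base-pair position.
#' @export
tss_position <- function(gene) {
  if (gene$strand == "+") gene$start else gene$end
}

#' Signed TSS-to-block distance in kb
#'
#' Distance from the gene's TSS to the nearest block boundary, 0 if the
#' block spans the TSS. The sign is relative to the gene's own
#' transcription direction: negative when the block lies upstream of the
#' TSS.
#'
#' @param block one-row block record with `scaffold`, `start`, `end`.
#' @param gene one-row gene record on the same scaffold.
#' @return Signed numeric distance in kb.
#' @export
signed_tss_distance_kb <- function(block, gene) {
  if (block$scaffold != gene$scaffold) {
    stop("block and gene on different scaffolds: ", block$scaffold,
         " vs ", gene$scaffold)
  }
  tss <- tss_position(gene)
  if (tss >= block$start && tss <= block$end) return(0)
  dist_bp <- if (tss < block$start) block$start - tss else tss - block$end
  downstream <- if (gene$strand == "+") tss < block$start else tss > block$end
  (if (downstream) dist_bp else -dist_bp) / 1000
}

#' CAMP call for a syntenic pair against a block set
#'
#' A block is shared by the pair when the absolute signed TSS distance is
#' within `window_kb` for BOTH genes; the pair is a CAMP if at least one
#' block is shared. The call is monotone in `window_kb`.
#'
#' @param pair one-row `syntenic_pairs` record (see [detect_pairs()]).
#' @param annotation the [genome_annotation()] the pair was detected in
#'   (provides the two gene records and their TSSs).
#' @param blocks data frame of enhancer blocks (`block_id`, `scaffold`,
#'   `start`, `end`).
#' @param window_kb window half-width in kb. The default of 100 covers
#'   every published pair-to-block distance (max 74.1 kb) with margin.
#' @return List of class `camp_call`: `pair` label, `shared_blocks`
#'   (character vector of block IDs) and `is_camp`.
#' @export
camp_call <- function(pair, annotation, blocks, window_kb = 100) {
  g_pdi <- get_gene(annotation, pair$gene_pdi)
  g_gdi <- get_gene(annotation, pair$gene_gdi)
  shared <- character(0)
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    on_scaffold <- blocks[blocks$scaffold == pair$scaffold, , drop = FALSE]
    for (i in seq_len(nrow(on_scaffold))) {
      b <- on_scaffold[i, , drop = FALSE]
      d1 <- signed_tss_distance_kb(b, g_pdi)
      d2 <- signed_tss_distance_kb(b, g_gdi)
      if (abs(d1) <= window_kb && abs(d2) <= window_kb) {
        shared <- c(shared, b$block_id)
      }
    }
  }
  structure(list(
    pair = paste(pair$gene_pdi, pair$gene_gdi, sep = "-"),
    shared_blocks = shared,
    is_camp = length(shared) > 0L),
    class = "camp_call")
}
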