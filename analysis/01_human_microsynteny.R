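#!/usr/bin/env Rscript
# Detect the human PDI/RhoGDI microsyntenic pairs from the published
# coordinates and report their descriptive quantities.
#
# Finding: three microsyntenic clusters, one per RhoGDI paralog, each with
# zero interposed genes and a shared transcription direction. The
# coordinate-derived PDIA1 pair distance is 7,027 bp ("7.0 kb"), which
# diverges from the "7.1 kb" the source table prints for that pair; the
# other two distances ("0.14 kb", "2.9 kb") match the printed values.

library(camps)

dir.create("results", showWarnings = FALSE)

# the same table ships as a plain TSV; reading it through the parser and
# using the in-memory fixture give identical annotations
tsv <- system.file("extdata", "human_table1.tsv", package = "camps")
ann <- read_gene_table(tsv, "tsv")
stopifnot(identical(as.data.frame(ann),
                    as.data.frame(builtin_fixture("human_table1"))))

pairs <- detect_pairs(ann, pair_criteria())
pairs$distance_kb <- vapply(pairs$intergenic_distance_bp, format_kb, "")

cat("Detected", nrow(pairs), "human PDI/RhoGDI pairs:\n")
print(pairs)

write.table(pairs, "results/human_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwrote results/human_pairs.tsv\n")

p4hb <- pairs[pairs$gene_pdi == "P4HB", ]
cat(sprintf(paste0(
  "\nNote: the PDIA1/RhoGDIa pair computes to %d bp (%s) from the stored\n",
  "coordinates, while the source table prints 7.1 kb for this pair; the\n",
  "discrepancy is kept explicit rather than reconciled.\n"),
  p4hb$intergenic_distance_bp, p4hb$distance_kb))
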