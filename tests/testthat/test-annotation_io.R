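test_that("toy partition: 40 exonic + 10 intronic + 50 intergenic bp", {
  p <- partition_stats(toy_genome())
  expect_equal(p$gene_bp, 40)
  expect_equal(p$intron_bp, 10)
  expect_equal(p$intergenic_bp, 50)
  expect_equal(p$gene_bp + p$intron_bp + p$intergenic_bp, p$total)
  expect_equal(unname(p$counts["insertion_sites"]), 1)
})

test_that("a gene-free genome is 100% intergenic", {
  g <- annotated_genome("empty", "Emp", strrep("A", 50), list())
  p <- partition_stats(g)
  expect_equal(p$intergenic_bp, 50)
  expect_equal(unname(p$ratios["intergenic"]), 100)
})

test_that("gene model validation: overlaps are errors, frame violations warn", {
  expect_error(gene_model("x", "protein", "+", rbind(c(0, 30), c(20, 50))),
               "overlap")
  expect_warning(gene_model("y", "protein", "+", rbind(c(0, 10))),
                 "divisible by 3")
})

test_that("minus-strand intron ordinals follow transcript, not genomic, order", {
  g <- toy_minus_genome()
  ins <- extract_introns(g)
  expect_length(ins, 2)
  # ordinal 1 is the genomically *last* gap on a minus-strand gene
  ord1 <- ins[[which(vapply(ins, `[[`, integer(1), "ordinal") == 1)]]
  expect_equal(ord1$start, 90)
  expect_equal(ord1$end, 100)
  # its upstream coding length is the 3'-most exon (genomic [100,130) = 30 nt)
  expect_equal(ord1$coding_offset, 30)
  expect_equal(ord1$phase, 0L)
  # sequences are transcript-oriented (reverse complement of forward slice)
  expect_equal(ord1$sequence,
               euglintron:::revcomp(substr(g$sequence, 91, 100)))
})

test_that("phase is cumulative coding length mod 3", {
  set.seed(21)
  seq <- random_dna(100)
  gene <- gene_model("pz", "protein", "+",
                     exons = rbind(c(0, 4), c(20, 40), c(60, 96)),
                     intron_features = NULL)
  g <- suppressWarnings(annotated_genome("pz1", "Pz", seq, list(gene)))
  ins <- extract_introns(g)
  expect_equal(ins[[1]]$phase, 4 %% 3)   # after 4 coding nt
  expect_equal(ins[[2]]$phase, 24 %% 3)
})

test_that("twintron nesting: parent listed once, children accessible", {
  g <- toy_twintron_genome()
  ins <- extract_introns(g)
  expect_length(ins, 1)                      # one insertion site
  expect_length(ins[[1]]$children, 1)        # internal intron
  expect_length(ins[[1]]$children[[1]]$children, 1)  # third level
  p <- partition_stats(g)
  expect_equal(unname(p$counts["insertion_sites"]), 1)
  expect_equal(p$intron_bp, 60)              # the external span [30,90)
})

test_that("an intron feature outside exon gaps is a structural error", {
  gene <- gene_model("bad", "protein", "+",
                     exons = rbind(c(0, 30), c(60, 90)),
                     intron_features = rbind(c(100, 110)))
  g <- annotated_genome("bad1", "Bad", strrep("A", 120), list(gene))
  expect_error(extract_introns(g), "not flanked by exons")
})

test_that("GFF3 write -> parse round-trips features and partitions", {
  g <- toy_twintron_genome()
  gff <- withr::local_tempfile(fileext = ".gff3")
  fas <- withr::local_tempfile(fileext = ".fasta")
  write_genome_gff3(g, gff, fas)
  g2 <- parse_genome_record(gff, "gff3", fasta = fas, species_tag = "Toy3")
  expect_equal(g2$length, g$length)
  expect_equal(g2$sequence, g$sequence)
  p1 <- partition_stats(g); p2 <- partition_stats(g2)
  expect_equal(p2$gene_bp, p1$gene_bp)
  expect_equal(p2$intron_bp, p1$intron_bp)
  i1 <- extract_introns(g); i2 <- extract_introns(g2)
  expect_equal(length(i1), length(i2))
  expect_equal(i2[[1]]$sequence, i1[[1]]$sequence)
  expect_length(i2[[1]]$children, 1)
})

test_that("GenBank flat files parse: joins, complements, intron features", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(genbank_fixture_text(), f)
  g <- parse_genome_record(f, "genbank", species_tag = "Tst")
  expect_equal(g$length, 300)
  expect_true(g$circular)
  nms <- vapply(g$genes, `[[`, character(1), "name")
  expect_setequal(nms, c("genA", "genB", "trnX"))
  genA <- g$genes[[which(nms == "genA")]]
  expect_equal(nrow(genA$exons), 2)
  expect_equal(genA$exons[1, ], c(start = 10, end = 40))
  genB <- g$genes[[which(nms == "genB")]]
  expect_equal(genB$strand, "-")
  expect_equal(g$genes[[which(nms == "trnX")]]$kind, "tRNA")
  ins <- extract_introns(g)
  expect_length(ins, 1)
  expect_equal(ins[[1]]$start, 40)
  expect_equal(ins[[1]]$end, 70)
})

test_that("EMBL flat files parse", {
  f <- withr::local_tempfile(fileext = ".embl")
  writeLines(embl_fixture_text(), f)
  g <- parse_genome_record(f, "embl")
  expect_equal(g$length, 240)
  nms <- vapply(g$genes, `[[`, character(1), "name")
  expect_setequal(nms, c("genC", "rrnX"))
  expect_equal(g$genes[[which(nms == "rrnX")]]$kind, "rRNA")
})

test_that("origin-spanning features are normalized by rotation", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(genbank_wrap_text(), f)
  g <- parse_genome_record(f, "genbank")
  expect_equal(g$origin_offset, 100)
  expect_equal(g$length, 120)
  wrapA <- g$genes[[1]]
  expect_equal(nrow(wrapA$exons), 1)        # contiguous after rotation
  expect_equal(unname(wrapA$exons[1, ]), c(0, 60))
})

test_that("malformed records raise parse errors", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("DEFINITION  no locus", "ORIGIN", "//"), f)
  expect_error(parse_genome_record(f, "genbank"), "LOCUS")
  expect_error(parse_genome_record("/nonexistent/file.gb", "genbank"),
               "no such file")
})

test_that("reversing genome orientation preserves per-gene intron ordinals", {
  set.seed(22)
  cfg <- simulation_config("(A,(B,C));", gain_rate = 3, seed = 31)
  sim <- simulate_clade(cfg)
  g <- sim$genomes[[1]]
  fwd <- extract_introns(g)
  rev <- extract_introns(reverse_genome(g))
  key <- function(x) paste(x$host_gene, x$ordinal)
  fwd_map <- stats::setNames(vapply(fwd, `[[`, character(1), "sequence"),
                             vapply(fwd, key, character(1)))
  rev_map <- stats::setNames(vapply(rev, `[[`, character(1), "sequence"),
                             vapply(rev, key, character(1)))
  expect_mapequal(as.list(rev_map), as.list(fwd_map))
})

test_that("partition conservation holds on simulated genomes", {
  cfg <- simulation_config("(A,(B,(C,D)));", gain_rate = 2, nest_prob = 0.2,
                           seed = 33)
  sim <- simulate_clade(cfg)
  for (g in sim$genomes) {
    p <- partition_stats(g)
    expect_equal(p$gene_bp + p$intergenic_bp + p$intron_bp, g$length)
  }
})

test_that("duplicated genes are counted once but their bp every occurrence", {
  set.seed(23)
  seq <- random_dna(300)
  g1 <- suppressWarnings(gene_model("rrn", "rRNA", "+", rbind(c(0, 50)),
                                    duplicate_group = "rrn_op"))
  g2 <- suppressWarnings(gene_model("rrn", "rRNA", "+", rbind(c(100, 150)),
                                    duplicate_group = "rrn_op"))
  g <- annotated_genome("dup1", "Dup", seq, list(g1, g2))
  p <- partition_stats(g)
  expect_equal(unname(p$counts["genes_total"]), 1)
  expect_equal(p$gene_bp, 100)
})
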