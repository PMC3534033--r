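# Programmatic fixtures: toy genomes and flat-file records built in code.

# 100 bp genome: one +strand gene with two 20 bp exons separated by a 10 bp
# intron (gene 40 exonic bp, intron 10 bp, intergenic 50 bp).
seq_blocks <- function(seq, width = 60) {
  starts <- seq(1, nchar(seq), width)
  substring(seq, starts, pmin(starts + width - 1, nchar(seq)))
}

toy_genome <- function() {
  set.seed(7)
  seq <- random_dna(100)
  # 40 exonic bp is deliberately not a multiple of 3 (frame warning expected)
  gene <- suppressWarnings(
    gene_model("toyA", "protein", "+",
               exons = rbind(c(10, 30), c(40, 60))))
  # exon bp = 20+20+... wait: [10,30)+[40,60) = 40 bp, gap [30,40) = 10 bp
  annotated_genome("toy1", "Toy", seq, list(gene), circular = FALSE)
}

# Minus-strand gene with two introns; transcript reads right-to-left.
toy_minus_genome <- function() {
  set.seed(8)
  seq <- random_dna(200)
  gene <- gene_model("toyB", "protein", "-",
                     exons = rbind(c(20, 50), c(60, 90), c(100, 130)))
  annotated_genome("toy2", "Toy2", seq, list(gene), circular = FALSE)
}

# A genome whose single gene carries a twintron: external intron [30,90)
# containing an internal intron feature [45,75), itself containing [55,65).
toy_twintron_genome <- function() {
  set.seed(9)
  seq <- random_dna(160)
  gene <- gene_model("toyC", "protein", "+",
                     exons = rbind(c(0, 30), c(90, 120)),
                     intron_features = rbind(c(45, 75), c(55, 65)))
  annotated_genome("toy3", "Toy3", seq, list(gene), circular = FALSE)
}

# Build a genome with prescribed partition sizes: one protein gene whose two
# exons total `gene_bp`, separated by one intron of `intron_bp`, padded with
# intergenic sequence to `total`.
partition_fixture_genome <- function(tag, gene_bp, intergenic_bp, intron_bp) {
  total <- gene_bp + intergenic_bp + intron_bp
  set.seed(nchar(tag) + gene_bp %% 1000L)
  lead <- intergenic_bp %/% 2L
  e1 <- gene_bp %/% 2L
  e2 <- gene_bp - e1
  x1 <- lead
  exons <- rbind(c(x1, x1 + e1), c(x1 + e1 + intron_bp, x1 + gene_bp + intron_bp))
  seq <- random_dna(total)
  gene <- suppressWarnings(
    gene_model(paste0(tag, "_gene"), "protein", "+", exons))
  annotated_genome(paste0(tag, "_fixture"), tag, seq, list(gene))
}

# GenBank flat-file text for a small record: two genes (one minus-strand,
# one with a join and an annotated intron feature), plus a tRNA.
genbank_fixture_text <- function() {
  set.seed(11)
  seq <- tolower(random_dna(300))
  blocks <- seq_blocks(seq)
  seq_lines <- sprintf("%9d %s", seq(1, 300, 60), blocks)
  c("LOCUS       TESTREC1                 300 bp    DNA     circular PLN 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(11..40,71..100)",
    '                     /gene="genA"',
    "     intron          41..70",
    '                     /gene="genA"',
    "     CDS             complement(121..180)",
    '                     /gene="genB"',
    "     tRNA            201..250",
    '                     /gene="trnX"',
    "ORIGIN",
    seq_lines,
    "//")
}

embl_fixture_text <- function() {
  set.seed(12)
  seq <- tolower(random_dna(240))
  blocks <- seq_blocks(seq)
  seq_lines <- sprintf("     %s %d", blocks, pmin(seq(60, 240, 60), 240))
  c("ID   TESTREC2; SV 1; circular; genomic DNA; STD; PLN; 240 BP.",
    "FH   Key             Location/Qualifiers",
    "FT   CDS             join(6..35,66..95)",
    'FT                   /gene="genC"',
    "FT   rRNA            121..200",
    'FT                   /gene="rrnX"',
    "SQ   Sequence 240 BP;",
    seq_lines,
    "//")
}

# GenBank record with a gene wrapping the origin (join spans the end).
genbank_wrap_text <- function() {
  set.seed(13)
  seq <- tolower(random_dna(120))
  blocks <- seq_blocks(seq)
  seq_lines <- sprintf("%9d %s", seq(1, 120, 60), blocks)
  c("LOCUS       WRAPREC                  120 bp    DNA     circular PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(101..120,1..40)",
    '                     /gene="wrapA"',
    "ORIGIN",
    seq_lines,
    "//")
}
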