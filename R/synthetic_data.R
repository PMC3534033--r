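# Synthetic data with known truth. Three generators:
#  * generate_intron_sequence(): intron sequences that satisfy the euglenid
#    group III landmarks by construction (5' NUNNG, 3' pseudo-domain VI),
#    U-rich interiors for group III;
#  * simulate_clade(): a clade of annotated genomes evolved under per-branch
#    intron gain (Poisson), per-branch per-site loss (Bernoulli) and
#    twintron nesting, with the full truth recorded (gain branch, losses,
#    sharing matrix) so the mapping pipeline can be validated end to end;
#  * build_paper_fixture() / build_twintron_cohort(): the published-table
#    transcriptions as analysis-ready objects, and a 12-site candidate
#    cohort with the published composition (4 complete, 2 partial,
#    6 external-only).
# All randomness comes from R's RNG; callers seed it (or pass `seed`).

sample_bases <- function(n, weights = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (n <= 0) return(character(0))
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate an intron sequence satisfying the group II/III consensuses
#'
#' The sequence starts with a 5-mer matching N-U-N-N-G (group III; group II
#' uses the canonical GUGCG start, which also satisfies it), ends with a
#' planted pseudo-domain VI motif (Watson-Crick 6-bp stem, loop of 3-8 nt,
#' bulged A, 4-nt tail), and has a U-rich interior for group III.
#'
#' @param kind "group_III" (length >= 30) or "group_II" (length >= 200).
#' @param length Total length in nt.
#' @param u_target Interior U fraction for group III.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return A DNA-alphabet sequence string.
#' @export
generate_intron_sequence <- function(kind = c("group_III", "group_II"),
                                     length, u_target = 0.45, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  min_len <- if (kind == "group_III") 30L else 200L
  if (length < min_len)
    stop(kind, " intron length must be >= ", min_len, " nt")
  five <- if (kind == "group_III")
    paste0(sample_bases(1), "T", paste(sample_bases(2), collapse = ""), "G")
  else "GTGCG"
  # planted domain VI: WC stem so it is found at 0 mismatches
  stem <- sample_bases(6)
  loop_len <- sample(3:8, 1)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  arm <- comp[stem]                       # a'..f'
  motif <- paste(c(stem, sample_bases(loop_len),
                   rev(arm[4:6]),          # f' e' d'
                   "A",
                   rev(arm[1:3]),          # c' b' a'
                   sample_bases(4)), collapse = "")
  interior_len <- length - 5L - nchar(motif)
  if (interior_len < 0)
    stop("length too short for the 5' consensus plus the domain VI motif")
  w <- if (kind == "group_III") {
    r <- (1 - u_target) / 3
    c(A = r + 0.10, C = r - 0.05, G = r - 0.05, T = u_target)
  } else c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)
  paste0(five, paste(sample_bases(interior_len, w), collapse = ""), motif)
}

# Codon sampler avoiding stop codons, at roughly euglenid A+T content.
random_coding_sequence <- function(n_codons, at = 0.70) {
  p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample_bases(3, p), collapse = "")
      if (!cd %in% c("TAA", "TAG", "TGA")) break
    }
    out[i] <- cd
  }
  paste(out, collapse = "")
}

# ---- clade simulator -------------------------------------------------------

#' Configuration for the clade simulator
#'
#' @param tree Rooted tree (ape::phylo, newick string, or file path).
#' @param gain_rate Expected new insertion sites per branch (scalar, or a
#'   vector named by branch id = sorted clade tip set; see
#'   \code{\link{dollo_map}}). The root stem is branch id of all tips.
#' @param burst Named multiplier on \code{gain_rate} for designated "burst"
#'   branches.
#' @param loss_prob Per-branch per-site loss probability.
#' @param nest_prob Per-branch probability that an existing site acquires an
#'   internal intron (twintron nesting).
#' @param genes Named integer vector: gene lengths in codons.
#' @param g3_fraction Fraction of gained introns that are group III.
#' @param seed Seed fixing all randomness.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(tree, gain_rate = 2, burst = NULL,
                              loss_prob = 0, nest_prob = 0,
                              genes = c(geneA = 180L, geneB = 150L,
                                        geneC = 120L, geneD = 100L),
                              g3_fraction = 0.7, seed = 1L) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  if (!ape::is.rooted(tree)) stop("simulator needs a rooted tree")
  stopifnot(loss_prob >= 0, loss_prob <= 1, nest_prob >= 0, nest_prob <= 1,
            all(gain_rate >= 0), length(genes) > 0)
  structure(list(tree = tree, gain_rate = gain_rate, burst = burst,
                 loss_prob = loss_prob, nest_prob = nest_prob,
                 genes = genes, g3_fraction = g3_fraction, seed = seed),
            class = "simulation_config")
}

#' Simulate a clade of annotated genomes with a known intron history
#'
#' Traverses the rooted tree from the root; on each branch, new sites are
#' gained (Poisson with the branch's intensity) at uniformly chosen (gene,
#' codon, phase) positions (never reusing a position — cognate means
#' homologous), existing sites are lost with \code{loss_prob}, and existing
#' sites acquire internal introns with \code{nest_prob}. Each site's intron
#' sequence is generated once and shared by all carriers (orthology); leaf
#' genomes are assembled with exon sequences common to the clade.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{genomes} (named list of
#'   \code{\link{annotated_genome}}), \code{truth} (data.frame per site:
#'   site_key, gene, codon, phase, kind, gain_branch, loss_branches,
#'   present = ";"-joined leaves, nested), \code{sharing} (leaf x leaf
#'   co-presence count matrix), \code{branch_gains} (named vector over
#'   branches with at least one surviving-site gain), \code{tree}.
#' @export
simulate_clade <- function(config) {
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids_of(node), tips_below))
  }
  branch_id <- function(node) clade_id(tips_below(node))
  rate_of <- function(bid) {
    gr <- config$gain_rate
    r <- if (is.null(names(gr))) gr[1]
         else if (bid %in% names(gr)) gr[[bid]] else 0
    if (!is.null(config$burst) && bid %in% names(config$burst))
      r <- r * config$burst[[bid]]
    r
  }

  sites <- list()      # registry: site_key -> record
  used <- character(0) # occupied (gene, codon, phase) keys
  new_sites_on <- function(bid) {
    n <- stats::rpois(1, rate_of(bid))
    keys <- character(0)
    for (k in seq_len(n)) {
      repeat {
        gene <- sample(names(config$genes), 1)
        codon <- sample(seq_len(config$genes[[gene]] - 2L), 1) # interior
        phase <- sample(0:2, 1)
        key <- paste(gene, codon, phase, sep = ".")
        if (!key %in% used) break
      }
      used <<- c(used, key)
      kind <- if (stats::runif(1) < config$g3_fraction) "group_III" else "group_II"
      len <- if (kind == "group_III") sample(70:140, 1) else sample(250:420, 1)
      sites[[key]] <<- list(key = key, gene = gene, codon = codon,
                            phase = phase, kind = kind,
                            sequence = generate_intron_sequence(kind, len),
                            gain_branch = bid, loss_branches = character(0),
                            internals = list())
      keys <- c(keys, key)
    }
    keys
  }

  leaf_sites <- list()
  walk <- function(node, carried) {
    bid <- branch_id(node)
    # losses on this branch
    lost <- carried[stats::runif(length(carried)) < config$loss_prob]
    for (key in lost)
      sites[[key]]$loss_branches <<- c(sites[[key]]$loss_branches, bid)
    carried <- setdiff(carried, lost)
    # nesting events on this branch
    for (key in carried) {
      if (stats::runif(1) < config$nest_prob) {
        host <- sites[[key]]$sequence
        ilen <- sample(60:110, 1)
        pos <- sample(seq(10L, nchar(host) - 25L), 1)
        sites[[key]]$internals <<- c(sites[[key]]$internals,
          list(list(seq = generate_intron_sequence("group_III", ilen),
                    pos = pos, branch = bid)))
      }
    }
    # gains on this branch
    carried <- c(carried, new_sites_on(bid))
    if (node <= ntip) {
      leaf_sites[[tree$tip.label[node]]] <<- carried
    } else {
      for (k in kids_of(node)) walk(k, carried)
    }
  }
  # root stem is a branch too (ancestral gains)
  walk(root, character(0))

  # shared exon sequences
  exon_seq <- stats::setNames(
    lapply(config$genes, random_coding_sequence), names(config$genes))

  genomes <- list()
  for (leaf in tree$tip.label) {
    present <- leaf_sites[[leaf]]
    genes <- list()
    cursor <- 0L
    parts <- character(0)
    gi <- 0L
    for (gene in names(config$genes)) {
      gi <- gi + 1L
      strand <- if (gi %% 2 == 0) "-" else "+"
      spacer <- paste(sample_bases(60, c(A = .35, C = .15, G = .15, T = .35)),
                      collapse = "")
      here <- present[vapply(present, function(k) sites[[k]]$gene == gene,
                             logical(1))]
      # order 5'->3' by coding offset
      offs <- vapply(here, function(k)
        3L * sites[[k]]$codon + sites[[k]]$phase, integer(1))
      here <- here[order(offs)]
      offs <- sort(offs)
      # transcript-with-introns, built 3'->5' to keep offsets valid
      tseq <- exon_seq[[gene]]
      intron_iv <- list()
      for (j in rev(seq_along(here))) {
        s <- sites[[here[j]]]
        iseq <- s$sequence
        # internal positions are all relative to the bare external sequence:
        # insert from 3' to 5' so earlier offsets stay valid
        int_ord <- order(vapply(s$internals, `[[`, numeric(1), "pos"),
                         decreasing = TRUE)
        for (it in s$internals[int_ord])
          iseq <- paste0(substr(iseq, 1, it$pos), it$seq,
                         substr(iseq, it$pos + 1, nchar(iseq)))
        tseq <- paste0(substr(tseq, 1, offs[j]), iseq,
                       substr(tseq, offs[j] + 1, nchar(tseq)))
      }
      # transcript-coordinate exon/intron intervals
      tlen <- nchar(tseq)
      ivs <- matrix(integer(0), ncol = 2)
      shift <- 0L
      feat <- matrix(integer(0), ncol = 2)
      for (j in seq_along(here)) {
        s <- sites[[here[j]]]
        ilen_full <- nchar(s$sequence) +
          sum(vapply(s$internals, function(it) nchar(it$seq), integer(1)))
        iv <- c(offs[j] + shift, offs[j] + shift + ilen_full)
        ivs <- rbind(ivs, iv)
        # internal features (transcript coords): an internal at position q is
        # shifted by the lengths of internals sitting 5' of it
        if (length(s$internals)) {
          ipos <- vapply(s$internals, `[[`, numeric(1), "pos")
          ilens <- vapply(s$internals, function(it) nchar(it$seq), integer(1))
          for (u in order(ipos)) {
            shift_u <- sum(ilens[ipos < ipos[u]])
            feat <- rbind(feat, c(iv[1] + ipos[u] + shift_u,
                                  iv[1] + ipos[u] + shift_u + ilens[u]))
          }
        }
        shift <- shift + ilen_full
      }
      # exons = complement of introns within [0, tlen)
      bounds <- c(0L, t(ivs), tlen)
      ex <- matrix(bounds, ncol = 2, byrow = TRUE)
      # genomic placement
      g0 <- cursor + nchar(spacer)
      if (strand == "+") {
        gex <- ex + g0
        gfeat <- if (nrow(feat)) feat + g0 else NULL
        gseq <- tseq
      } else {
        gex <- cbind(g0 + tlen - ex[, 2], g0 + tlen - ex[, 1])
        gex <- gex[order(gex[, 1]), , drop = FALSE]
        gfeat <- if (nrow(feat))
          cbind(g0 + tlen - feat[, 2], g0 + tlen - feat[, 1]) else NULL
        gseq <- revcomp(tseq)
      }
      genes[[length(genes) + 1]] <- gene_model(
        name = gene, kind = "protein", strand = strand, exons = gex,
        intron_features = gfeat)
      parts <- c(parts, spacer, gseq)
      cursor <- g0 + tlen
    }
    parts <- c(parts, paste(sample_bases(60), collapse = ""))
    genomes[[leaf]] <- annotated_genome(
      id = paste0("sim_", leaf), species_tag = leaf,
      sequence = paste(parts, collapse = ""), genes = genes)
  }

  # truth tables
  truth_rows <- lapply(sites, function(s) {
    carriers <- tree$tip.label[vapply(tree$tip.label, function(lf)
      s$key %in% leaf_sites[[lf]], logical(1))]
    data.frame(site_key = s$key, gene = s$gene, codon = s$codon,
               phase = s$phase, kind = s$kind, gain_branch = s$gain_branch,
               loss_branches = paste(s$loss_branches, collapse = ";"),
               present = paste(carriers, collapse = ";"),
               nested = length(s$internals) > 0, stringsAsFactors = FALSE)
  })
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(site_key = character(0), gene = character(0),
               codon = integer(0), phase = integer(0), kind = character(0),
               gain_branch = character(0), loss_branches = character(0),
               present = character(0), nested = logical(0))
  rownames(truth) <- NULL
  leaves <- tree$tip.label
  sharing <- matrix(0L, length(leaves), length(leaves),
                    dimnames = list(leaves, leaves))
  for (i in seq_len(nrow(truth))) {
    sp <- strsplit(truth$present[i], ";", fixed = TRUE)[[1]]
    sp <- sp[nzchar(sp)]
    if (length(sp)) sharing[sp, sp] <- sharing[sp, sp] + 1L
  }
  observed <- truth[nchar(truth$present) > 0, , drop = FALSE]
  bg <- table(observed$gain_branch)
  list(genomes = genomes, truth = truth, sharing = sharing,
       branch_gains = stats::setNames(as.integer(bg), names(bg)),
       tree = tree)
}

#' Write a simulated clade to disk (GFF3+FASTA per genome, tree, truth TSV)
#'
#' @param sim Output of \code{\link{simulate_clade}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_clade <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (leaf in names(sim$genomes)) {
    write_genome_gff3(sim$genomes[[leaf]],
                      file.path(dir, paste0(leaf, ".gff3")),
                      file.path(dir, paste0(leaf, ".fasta")))
  }
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_tsv_file(sim$truth, file.path(dir, "truth_sites.tsv"))
  invisible(dir)
}

#' Run the site-mapping pipeline on a set of annotated genomes
#'
#' For every gene present in two or more genomes: translate the exons,
#' align the orthologs (center-star), project each genome's introns into
#' alignment coordinates, and cluster cognate sites. Single-copy genes
#' contribute singleton sites.
#'
#' @param genomes Named list of \code{\link{annotated_genome}} (names =
#'   species tags).
#' @param scheme Protein \code{\link{scoring_scheme}}.
#' @return Site groups (see \code{\link{cluster_cognate_sites}}).
#' @export
recover_site_groups <- function(genomes, scheme = scoring_scheme()) {
  introns <- lapply(genomes, extract_introns)
  gene_names <- unique(unlist(lapply(genomes, function(g)
    vapply(g$genes, `[[`, character(1), "name"))))
  all_sites <- list()
  for (gene in gene_names) {
    seqs <- character(0)
    for (sp in names(genomes)) {
      gm <- Filter(function(x) x$name == gene && x$kind == "protein",
                   genomes[[sp]]$genes)
      if (length(gm) == 0) next
      gm <- gm[[1]]
      cds <- paste(vapply(seq_len(nrow(gm$exons)), function(k) {
        s <- substr(genomes[[sp]]$sequence, gm$exons[k, 1] + 1L, gm$exons[k, 2])
        s
      }, character(1)), collapse = "")
      if (gm$strand == "-") cds <- revcomp(cds)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), if.fuzzy.codon = "X"))
      seqs[sp] <- aa
    }
    if (length(seqs) == 0) next
    al <- if (length(seqs) >= 2) star_msa(seqs, scheme) else
      msa(seqs)
    for (sp in names(seqs)) {
      for (rec in introns[[sp]]) {
        if (rec$host_gene != gene || is.na(rec$phase)) next
        all_sites[[length(all_sites) + 1]] <- project_site(rec, al, sp)
      }
    }
  }
  if (length(all_sites) == 0) return(list())
  cluster_cognate_sites(do.call(rbind, all_sites))
}

#' Demo configuration emulating the euglenid plastid clade
#'
#' Per-branch gain intensities transcribe the qualitative pattern of the
#' published clade at reduced scale: a small ancestral contribution on the
#' stem of the photosynthetic euglenids (the psbC-type ancestral site),
#' larger waves on the branches leading to the Euglena/Monomorphina
#' ancestor and within the Euglena lineage, and substantial ongoing
#' lineage-specific gain on the terminal branches of the intron-rich taxa
#' (most published sites are species-specific: e.g. 21 of the 23 sites of
#' Eta. viridis). Branch ids are sorted clade tip sets.
#'
#' @param loss_prob,nest_prob,seed Passed to
#'   \code{\link{simulation_config}}.
#' @return A \code{simulation_config}.
#' @export
euglenid_demo_config <- function(loss_prob = 0, nest_prob = 0.05, seed = 1L) {
  tree <- ape::read.tree(text = "(Ppar,(Egym,(Evir,(Maen,(Elon,Egra)))));")
  rates <- c(
    "Egra,Egym,Elon,Evir,Maen,Ppar" = 0.2,  # root stem
    "Egra,Egym,Elon,Evir,Maen" = 0.5,       # photosynthetic euglenids + Elon
    "Egra,Elon,Evir,Maen" = 0.5,            # ancestral (psbC-era) gains
    "Egra,Elon,Maen" = 4,                   # first wave
    "Egra,Elon" = 5,                        # Euglena lineage wave
    Ppar = 0.3, Egym = 1, Evir = 8, Maen = 6, Elon = 0.5, Egra = 12)
  simulation_config(tree, gain_rate = rates, loss_prob = loss_prob,
                    nest_prob = nest_prob, seed = seed)
}

# ---- published-table fixtures ---------------------------------------------

fixture_path <- function(file) {
  system.file("extdata", file, package = "euglintron", mustWork = TRUE)
}

#' Load the transcription of the published shared/unique site tables
#'
#' Builds aligned-site rows from the repo's machine-readable transcription
#' of the shared-site and unique-site tables. Alignment columns are
#' synthetic (consistent within each cognate group, distinct between
#' groups), which is all the catalog and sharing analyses require.
#'
#' @return List with \code{sites} (aligned-site data.frame),
#'   \code{shared_rows}, \code{unique_rows} (the raw transcriptions).
#' @export
build_paper_fixture <- function() {
  shared <- read_tsv_file(fixture_path("shared_insertion_sites.tsv"))
  uniq <- read_tsv_file(fixture_path("unique_insertion_sites.tsv"))
  rows <- list()
  col_counter <- stats::setNames(integer(0), character(0))
  next_col <- function(gene) {
    cur <- if (gene %in% names(col_counter)) col_counter[[gene]] else 0L
    col_counter[[gene]] <<- cur + 10L
    col_counter[[gene]]
  }
  for (i in seq_len(nrow(shared))) {
    gene <- shared$gene[i]
    col <- next_col(gene)
    for (m in strsplit(shared$sites[i], ",", fixed = TRUE)[[1]]) {
      p <- strsplit(trimws(m), ".", fixed = TRUE)[[1]]
      rows[[length(rows) + 1]] <- aligned_site(
        gene = gene, species_tag = p[1], ordinal = as.integer(p[2]),
        column = col, phase = 0L,
        twintron = isTRUE(shared$egra_twintron[i]))
    }
  }
  for (i in seq_len(nrow(uniq))) {
    p <- strsplit(uniq$site_id[i], ".", fixed = TRUE)[[1]]
    rows[[length(rows) + 1]] <- aligned_site(
      gene = p[1], species_tag = p[2], ordinal = as.integer(p[3]),
      column = next_col(p[1]), phase = 0L,
      ambiguous = isTRUE(uniq$ambiguous[i]))
  }
  list(sites = do.call(rbind, rows), shared_rows = shared, unique_rows = uniq)
}

#' Build the synthetic 12-site candidate twintron cohort
#'
#' Twelve reference twintrons with targets constructed to the published
#' composition: 4 sites carry orthologs of the external and all internal
#' introns (complete), 2 carry the external plus exactly one internal
#' (partial intermediates), and 6 carry the external only. Targets are
#' point-mutated copies of the corresponding reference components
#' (\code{divergence} substitutions per site).
#'
#' @param seed Seed for sequence generation and mutation.
#' @param divergence Per-site substitution rate applied to targets.
#' @return A list of candidates (\code{ref}, \code{target},
#'   \code{expected}) suitable for \code{\link{classify_cohort}}.
#' @export
build_twintron_cohort <- function(seed = 1L, divergence = 0.08) {
  set.seed(seed)
  spec <- list(
    # site_id                n_internals  retained internals
    list(id = "psbC.Maen.2",  n = 2, keep = c(1, 2), exp = "complete_twintron"),
    list(id = "rpoC1.Maen.2", n = 1, keep = 1,       exp = "complete_twintron"),
    list(id = "rpoC1.Maen.9", n = 1, keep = 1,       exp = "complete_twintron"),
    list(id = "rps3.Maen.1",  n = 2, keep = c(1, 2), exp = "complete_twintron"),
    list(id = "petB.Maen.1",  n = 2, keep = 2,       exp = "partial_twintron"),
    list(id = "psbC.Maen.1",  n = 3, keep = 3,       exp = "partial_twintron"),
    list(id = "atpE.Maen.1",  n = 1, keep = integer(0), exp = "external_only"),
    list(id = "psbK.Maen.1",  n = 1, keep = integer(0), exp = "external_only"),
    list(id = "psbT.Maen.1",  n = 2, keep = integer(0), exp = "external_only"),
    list(id = "rpl16.Maen.1", n = 1, keep = integer(0), exp = "external_only"),
    list(id = "rpoC1.Maen.3", n = 1, keep = integer(0), exp = "external_only"),
    list(id = "rps18.Maen.2", n = 1, keep = integer(0), exp = "external_only"))
  lapply(spec, function(sp) {
    ext_len <- sample(160:260, 1)
    external <- generate_intron_sequence("group_II", max(200, ext_len))
    internals <- lapply(seq_len(sp$n), function(i) {
      list(seq = generate_intron_sequence("group_III", sample(80:140, 1)),
           pos = sample(seq(20L, nchar(external) - 30L), 1))
    })
    ref <- twintron_reference(sp$id, external, internals)
    # target: mutated external with the retained internals (mutated) inserted
    tgt_ref <- twintron_reference(
      paste0(sp$id, ".target"), mutate_seq(external, divergence),
      lapply(sp$keep, function(i)
        list(seq = mutate_seq(internals[[i]]$seq, divergence),
             pos = internals[[i]]$pos)))
    list(ref = ref, target = full_twintron_seq(tgt_ref), expected = sp$exp)
  })
}
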