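# Annotated genome records: parsing (GFF3+FASTA, GenBank/EMBL flat files),
# writing, intron extraction, and the genome partition accounting
# (coding / intergenic / intronic bp and the associated feature counts).
#
# Coordinates are 0-based half-open on the forward strand internally, with a
# per-gene strand flag; user-facing reports are 1-based inclusive. Introns
# are the gaps between consecutive exons of a gene; explicitly annotated
# `intron` features record nesting (twintrons) and must lie inside such a
# gap (or inside another intron feature).

#' Construct a gene model
#'
#' @param name Gene name (e.g. "psbC").
#' @param kind One of "protein", "tRNA", "rRNA", "ORF".
#' @param strand "+" or "-".
#' @param exons Integer matrix with columns \code{start}, \code{end}
#'   (0-based half-open, genomic forward coordinates, ascending,
#'   non-overlapping).
#' @param duplicate_group Optional key shared by the copies of a multi-copy
#'   gene (copies are counted once in gene counts).
#' @param intron_features Optional integer matrix of annotated intron
#'   intervals (same convention) used to describe nesting.
#' @return A \code{gene_model} object.
#' @export
gene_model <- function(name, kind = c("protein", "tRNA", "rRNA", "ORF"),
                       strand = c("+", "-"), exons,
                       duplicate_group = NA_character_,
                       intron_features = NULL) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", name)
  if (!is.null(intron_features)) {
    intron_features <- matrix(as.integer(intron_features), ncol = 2,
                              dimnames = list(NULL, c("start", "end")))
  }
  g <- structure(list(name = name, kind = kind, strand = strand,
                      exons = exons, duplicate_group = duplicate_group,
                      intron_features = intron_features),
                 class = "gene_model")
  if (kind == "protein" && sum(exons[, 2] - exons[, 1]) %% 3 != 0)
    warning("total exon length of protein gene ", name,
            " is not divisible by 3 (possible unannotated exon)")
  g
}

#' Construct an annotated genome
#'
#' @param id Record identifier.
#' @param species_tag Short species tag (e.g. "Maen").
#' @param sequence Nucleotide sequence (character).
#' @param genes List of \code{\link{gene_model}} objects.
#' @param circular Whether the molecule maps as a circle.
#' @param origin_offset Rotation applied at parse time to un-wrap features
#'   spanning the origin (0 if none).
#' @return An \code{annotated_genome} object.
#' @export
annotated_genome <- function(id, species_tag, sequence, genes = list(),
                             circular = TRUE, origin_offset = 0L) {
  sequence <- norm_nt(sequence)
  len <- nchar(sequence)
  for (g in genes) {
    if (any(g$exons < 0) || any(g$exons > len))
      stop("gene ", g$name, " outside [0, genome length)")
  }
  structure(list(id = id, species_tag = species_tag, circular = circular,
                 sequence = sequence, genes = genes, length = len,
                 origin_offset = as.integer(origin_offset)),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome %s [%s]: %s bp, %d genes, %s\n",
              x$id, x$species_tag, format(x$length, big.mark = ","),
              length(x$genes), if (x$circular) "circular" else "linear"))
  invisible(x)
}

# ---- intron extraction -----------------------------------------------------

# Containment forest over intron feature intervals within [lo, hi).
# Returns a list of records (start, end, children), ordered 5'->3' genomic.
nest_features <- function(feats, lo, hi) {
  if (is.null(feats) || nrow(feats) == 0) return(list())
  inside <- feats[feats[, 1] >= lo & feats[, 2] <= hi, , drop = FALSE]
  # skip a feature identical to the enclosing interval (annotation of the
  # gap itself)
  inside <- inside[!(inside[, 1] == lo & inside[, 2] == hi), , drop = FALSE]
  if (nrow(inside) == 0) return(list())
  inside <- inside[order(inside[, 1], -inside[, 2]), , drop = FALSE]
  # top-level = not contained in any other retained feature
  top <- rep(TRUE, nrow(inside))
  for (i in seq_len(nrow(inside))) for (j in seq_len(nrow(inside))) {
    if (i != j && inside[i, 1] >= inside[j, 1] && inside[i, 2] <= inside[j, 2] &&
        !(inside[i, 1] == inside[j, 1] && inside[i, 2] == inside[j, 2]))
      top[i] <- FALSE
  }
  lapply(which(top), function(i) {
    rest <- inside[-i, , drop = FALSE]
    list(start = inside[i, 1], end = inside[i, 2],
         children = nest_features(rest, inside[i, 1], inside[i, 2]))
  })
}

attach_sequences <- function(rec, genome_seq, strand) {
  seq_fwd <- substr(genome_seq, rec$start + 1L, rec$end)
  rec$sequence <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
  rec$children <- lapply(rec$children, attach_sequences, genome_seq, strand)
  rec
}

#' Extract intron records from an annotated genome
#'
#' Top-level introns are the gaps between consecutive exons of each gene;
#' ordinals are assigned 5' to 3' in transcript orientation. The codon phase
#' of an insertion is the number of coding nucleotides 5' of the insertion
#' point, mod 3 (protein genes only). Annotated nested intron features are
#' attached as children (twintron internals); a twintron counts as a single
#' insertion site.
#'
#' @param g An \code{\link{annotated_genome}}.
#' @return List of intron records: \code{host_gene}, \code{ordinal},
#'   \code{start}, \code{end}, \code{phase} (NA for non-protein hosts),
#'   \code{coding_offset}, \code{sequence} (transcript orientation),
#'   \code{children}.
#' @export
extract_introns <- function(g) {
  out <- list()
  for (gene in g$genes) {
    ex <- gene$exons
    n_int <- nrow(ex) - 1L
    gaps <- if (n_int > 0)
      cbind(start = ex[-nrow(ex), 2], end = ex[-1, 1]) else
      matrix(integer(0), ncol = 2)
    if (n_int > 0 && any(gaps[, 2] <= gaps[, 1]))
      stop("adjacent or overlapping exons leave no intron in gene ", gene$name)
    # check every annotated intron feature is accounted for
    if (!is.null(gene$intron_features) && nrow(gene$intron_features) > 0) {
      for (k in seq_len(nrow(gene$intron_features))) {
        f <- gene$intron_features[k, ]
        ok <- n_int > 0 && any(f[1] >= gaps[, 1] & f[2] <= gaps[, 2])
        if (!ok)
          stop("intron feature [", f[1], ",", f[2], ") in gene ", gene$name,
               " is not flanked by exons of its host")
      }
    }
    if (n_int == 0) next
    # transcript order of the gaps
    ord <- if (gene$strand == "+") seq_len(n_int) else rev(seq_len(n_int))
    exon_len <- ex[, 2] - ex[, 1]
    recs <- vector("list", n_int)
    for (pos in seq_len(n_int)) {
      gi <- ord[pos]                 # genomic gap index for ordinal `pos`
      coding_before <- if (gene$strand == "+")
        sum(exon_len[seq_len(gi)]) else sum(exon_len[seq(gi + 1L, nrow(ex))])
      rec <- list(host_gene = gene$name, ordinal = pos,
                  start = unname(gaps[gi, 1]), end = unname(gaps[gi, 2]),
                  phase = if (gene$kind == "protein")
                    coding_before %% 3L else NA_integer_,
                  coding_offset = coding_before,
                  children = nest_features(gene$intron_features,
                                           gaps[gi, 1], gaps[gi, 2]))
      recs[[pos]] <- attach_sequences(rec, g$sequence, gene$strand)
    }
    out <- c(out, recs)
  }
  out
}

# ---- partition accounting --------------------------------------------------

#' Genome partition accounting
#'
#' Classifies every genomic position exactly once with precedence
#' intron > exon > intergenic, so gene_bp + intron_bp + intergenic_bp equals
#' the genome length. Counting rules: duplicated genes are counted once
#' (their bp every occurrence — bp is physical); free-standing ORFs are not
#' included in gene counts; intronic ORFs (maturases) are excluded from gene
#' counts and gene bp (their positions are intronic) and reported as
#' "intron ORFs"; a twintron counts as a single insertion site.
#'
#' @param g An \code{\link{annotated_genome}}.
#' @return A \code{genome_partition} list: \code{total}, \code{gene_bp},
#'   \code{intergenic_bp}, \code{intron_bp}, \code{at_percent},
#'   \code{ratios} (coding/intergenic/intronic, percent), \code{counts}
#'   (genes_total, protein, tRNA, rRNA, insertion_sites, intron_orfs).
#' @export
partition_stats <- function(g) {
  len <- g$length
  empty <- IRanges::IRanges()
  rng <- function(m) {
    if (is.null(m) || nrow(m) == 0) empty else
      IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2])
  }
  # top-level intron intervals = inter-exon gaps of every gene
  gap_list <- lapply(g$genes, function(gene) {
    ex <- gene$exons
    if (nrow(ex) < 2) return(NULL)
    cbind(ex[-nrow(ex), 2], ex[-1, 1])
  })
  gaps <- do.call(rbind, gap_list[!vapply(gap_list, is.null, logical(1))])
  intron_rng <- IRanges::reduce(rng(gaps))
  exon_all <- do.call(rbind, lapply(g$genes, function(gene) gene$exons))
  exon_rng <- IRanges::reduce(rng(exon_all))
  gene_rng <- IRanges::setdiff(exon_rng, intron_rng)
  intron_bp <- sum(IRanges::width(intron_rng))
  gene_bp <- sum(IRanges::width(gene_rng))
  intergenic_bp <- len - gene_bp - intron_bp

  # counts
  in_intron <- function(gene) {
    r <- rng(gene$exons)
    length(r) > 0 &&
      all(IRanges::overlapsAny(r, intron_rng, type = "within"))
  }
  is_orf <- vapply(g$genes, function(x) x$kind == "ORF", logical(1))
  intronic_orf <- is_orf & vapply(g$genes, in_intron, logical(1))
  counted <- g$genes[!is_orf]
  # duplicates once
  key <- vapply(counted, function(x)
    if (!is.na(x$duplicate_group)) paste0("dup:", x$duplicate_group)
    else paste0("gene:", x$name, ":", x$exons[1, 1]), character(1))
  counted <- counted[!duplicated(key)]
  kinds <- vapply(counted, `[[`, character(1), "kind")
  n_sites <- sum(vapply(counted, function(x) nrow(x$exons) - 1L, integer(1)))
  structure(list(
    total = len,
    gene_bp = gene_bp, intergenic_bp = intergenic_bp, intron_bp = intron_bp,
    at_percent = round(at_percent(g$sequence), 1),
    ratios = c(coding = round(100 * gene_bp / len, 1),
               intergenic = round(100 * intergenic_bp / len, 1),
               intronic = round(100 * intron_bp / len, 1)),
    counts = c(genes_total = length(counted),
               protein = sum(kinds == "protein"),
               tRNA = sum(kinds == "tRNA"),
               rRNA = sum(kinds == "rRNA"),
               insertion_sites = n_sites,
               intron_orfs = sum(intronic_orf))),
    class = "genome_partition")
}

#' @export
print.genome_partition <- function(x, ...) {
  cat(sprintf("genome partition: %s bp total (A+T %.1f%%)\n",
              format(x$total, big.mark = ","), x$at_percent))
  cat(sprintf("  genes %s | intergenic %s | introns %s bp\n",
              format(x$gene_bp, big.mark = ","),
              format(x$intergenic_bp, big.mark = ","),
              format(x$intron_bp, big.mark = ",")))
  cat(sprintf("  ratios %.1f / %.1f / %.1f %%\n",
              x$ratios["coding"], x$ratios["intergenic"], x$ratios["intronic"]))
  cat("  counts:", paste(names(x$counts), x$counts, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate partitions of several genomes as a feature report
#'
#' One column per genome, rows mirroring a "main features" table
#' (sizes, ratios, counts).
#'
#' @param stats Named list of \code{genome_partition} objects.
#' @param path Optional TSV output path.
#' @return A data.frame.
#' @export
partition_report <- function(stats, path = NULL) {
  col <- function(p) c(p$at_percent, p$total, p$gene_bp, p$intergenic_bp,
                       p$intron_bp, p$ratios, p$counts)
  df <- data.frame(feature = c("at_percent", "total_bp", "genes_bp",
                               "intergenic_bp", "introns_bp",
                               "coding_pct", "intergenic_pct", "intronic_pct",
                               "genes_total", "protein_coding", "tRNAs",
                               "rRNAs", "insertion_sites", "intron_orfs"))
  for (nm in names(stats)) df[[nm]] <- col(stats[[nm]])
  if (!is.null(path)) write_tsv_file(df, path)
  df
}

# ---- GFF3 + FASTA ----------------------------------------------------------

#' Parse an annotated genome record
#'
#' @param path Path to the record: for \code{format = "gff3"} the GFF3 file
#'   (with \code{fasta} giving the sequence); for "genbank"/"embl" the flat
#'   file.
#' @param format One of "gff3", "genbank", "embl".
#' @param fasta FASTA path (required for GFF3 input).
#' @param species_tag Short tag; defaults to the record id.
#' @return An \code{\link{annotated_genome}}.
#' @export
parse_genome_record <- function(path, format = c("gff3", "genbank", "embl"),
                                fasta = NULL, species_tag = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") {
    if (is.null(fasta)) stop("GFF3 input needs a FASTA sequence file")
    parse_gff3_genome(path, fasta, species_tag)
  } else {
    parse_flatfile_genome(path, format, species_tag)
  }
}

parse_gff3_genome <- function(gff_path, fasta_path, species_tag = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1) stop("expected a single-sequence FASTA: ", fasta_path)
  id <- sub("\\s.*", "", names(ss)[1])
  mc <- S4Vectors::mcols(gr)
  typ <- as.character(mc$type)
  ids <- as.character(mc$ID)
  parent_of <- vapply(seq_along(gr), function(i) {
    p <- mc$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  strands <- as.character(BiocGenerics::strand(gr))

  gene_idx <- which(typ == "gene")
  if (length(gene_idx) == 0 && any(typ == "intron"))
    NULL # introns with no genes handled below as error
  genes <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    exi <- which(typ == "exon" & parent_of == gid)
    if (length(exi) == 0)
      stop("gene ", gid, " has no exon features (", gff_path, ")")
    # intron features belonging to this gene via Parent chains
    ini <- which(typ == "intron")
    host <- vapply(ini, function(i) {
      p <- parent_of[i]
      seen <- character(0)
      while (!is.na(p) && !(p %in% seen)) {
        if (p == gid) return(TRUE)
        seen <- c(seen, p)
        j <- match(p, ids)
        p <- if (is.na(j)) NA_character_ else parent_of[j]
      }
      FALSE
    }, logical(1))
    ini <- ini[host]
    feats <- if (length(ini))
      cbind(start0[ini], end0[ini]) else NULL
    if (!is.null(feats)) {
      span <- range(c(start0[exi], end0[exi]))
      if (any(feats[, 1] < span[1] | feats[, 2] > span[2]))
        stop("intron feature outside its host gene ", gid)
    }
    kind <- if (!is.null(mc$kind)) {
      k <- as.character(mc$kind[gi]); if (is.na(k)) "protein" else k
    } else "protein"
    dg <- if (!is.null(mc$duplicate_group))
      as.character(mc$duplicate_group[gi]) else NA_character_
    genes[[length(genes) + 1]] <- gene_model(
      name = gid, kind = kind, strand = strands[gi],
      exons = cbind(start0[exi], end0[exi]),
      duplicate_group = dg, intron_features = feats)
  }
  # orphan introns (no resolvable host gene)
  orphan <- which(typ == "intron" & is.na(parent_of))
  if (length(orphan))
    stop("intron feature with no host gene at line-range ",
         paste(start0[orphan] + 1L, collapse = ","))
  annotated_genome(id = id, species_tag = species_tag %||% id,
                   sequence = as.character(ss[[1]]), genes = genes)
}

#' Write an annotated genome as GFF3 + FASTA
#'
#' @param g An \code{\link{annotated_genome}}.
#' @param gff_path,fasta_path Output paths.
#' @export
write_genome_gff3 <- function(g, gff_path, fasta_path) {
  rows <- list()
  add <- function(type, start0, end0, strand, id = NA, parent = NA,
                  kind = NA, dup = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, start = start0 + 1L, end = end0, strand = strand,
      ID = id, Parent = parent, kind = kind, duplicate_group = dup,
      stringsAsFactors = FALSE)
  }
  emit_introns <- function(recs, parent_id, prefix, strand) {
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      iid <- paste0(prefix, ".in", i)
      add("intron", r$start, r$end, strand, id = iid, parent = parent_id)
      emit_introns(r$children, iid, iid, strand)
    }
  }
  for (gene in g$genes) {
    gid <- gene$name
    add("gene", min(gene$exons[, 1]), max(gene$exons[, 2]), gene$strand,
        id = gid, kind = gene$kind, dup = gene$duplicate_group)
    for (k in seq_len(nrow(gene$exons)))
      add("exon", gene$exons[k, 1], gene$exons[k, 2], gene$strand,
          id = paste0(gid, ".e", k), parent = gid)
    # nested intron features (children only exist below top-level gaps)
    if (!is.null(gene$intron_features) && nrow(gene$intron_features) > 0) {
      # emit the containment forest so nesting is preserved
      ex <- gene$exons
      if (nrow(ex) > 1) {
        gaps <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
        for (k in seq_len(nrow(gaps))) {
          forest <- nest_features(gene$intron_features, gaps[k, 1], gaps[k, 2])
          top_id <- paste0(gid, ".gap", k)
          add("intron", gaps[k, 1], gaps[k, 2], gene$strand,
              id = top_id, parent = gid)
          emit_introns(forest, top_id, top_id, gene$strand)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = g$id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA, df$Parent)
  S4Vectors::mcols(gr)$kind <- df$kind
  S4Vectors::mcols(gr)$duplicate_group <- df$duplicate_group
  rtracklayer::export(gr, gff_path, format = "gff3")
  ss <- Biostrings::DNAStringSet(stats::setNames(g$sequence, g$id))
  Biostrings::writeXStringSet(ss, fasta_path)
  invisible(gff_path)
}

# ---- GenBank / EMBL flat files --------------------------------------------

# Parse a feature location string like "complement(join(10..80,120..200))".
# Returns list(segments = matrix of 1-based inclusive start/end, strand).
parse_location <- function(loc) {
  s <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^(join|order)\\(", s))
    s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  seg <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]][1:2])
    } else {
      v <- as.integer(p); c(v, v)
    }
  }, integer(2)))
  if (any(is.na(seg))) stop("malformed feature location: ", loc)
  list(segments = unname(seg), strand = strand)
}

read_flatfile_features <- function(lines, format) {
  if (format == "embl") {
    ft <- grepl("^FT", lines)
    lines_ft <- sub("^FT", "  ", lines[ft])
  } else {
    i0 <- grep("^FEATURES", lines)
    i1 <- grep("^ORIGIN", lines)
    if (length(i0) == 0 || length(i1) == 0)
      stop("malformed GenBank record: missing FEATURES or ORIGIN")
    lines_ft <- lines[(i0 + 1):(i1 - 1)]
  }
  feats <- list()
  cur <- NULL
  for (ln in lines_ft) {
    if (grepl("^\\s{5}\\S", ln) && !grepl("^\\s{6,}", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
      key <- sub("^\\s+", "", substr(ln, 1, 20))
      key <- sub("\\s.*", "", key)
      cur <- list(key = key, loc = sub("^\\s*\\S+\\s+", "", ln),
                  quals = character(0))
    } else if (!is.null(cur)) {
      txt <- sub("^\\s+", "", ln)
      if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
      else if (nzchar(txt)) {
        # continuation of the location (or of the last qualifier)
        if (length(cur$quals) == 0) cur$loc <- paste0(cur$loc, txt)
        else cur$quals[length(cur$quals)] <-
               paste0(cur$quals[length(cur$quals)], txt)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
  feats
}

qual_value <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- quals[grepl(pat, quals)]
  if (length(hit) == 0) return(NA_character_)
  gsub('^"|"$', "", sub(pat, "", hit[1]))
}

parse_flatfile_genome <- function(path, format, species_tag = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (format == "genbank") {
    loc_line <- grep("^LOCUS", lines, value = TRUE)
    if (length(loc_line) == 0) stop("malformed GenBank record: no LOCUS line")
    id <- strsplit(sub("^LOCUS\\s+", "", loc_line[1]), "\\s+")[[1]][1]
    circular <- grepl("circular", loc_line[1])
    i1 <- grep("^ORIGIN", lines)
    seq_lines <- lines[(i1 + 1):length(lines)]
  } else {
    id_line <- grep("^ID", lines, value = TRUE)
    if (length(id_line) == 0) stop("malformed EMBL record: no ID line")
    id <- strsplit(sub("^ID\\s+", "", id_line[1]), "[;\\s]+")[[1]][1]
    circular <- grepl("circular", id_line[1])
    i1 <- grep("^SQ", lines)
    if (length(i1) == 0) stop("malformed EMBL record: no SQ block")
    seq_lines <- lines[(i1 + 1):length(lines)]
  }
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  len <- nchar(sequence)

  feats <- read_flatfile_features(lines, format)
  feats <- Filter(function(f)
    f$key %in% c("CDS", "tRNA", "rRNA", "intron"), feats)
  parsed <- lapply(feats, function(f) {
    loc <- parse_location(f$loc)
    list(key = f$key, segments = loc$segments, strand = loc$strand,
         gene = qual_value(f$quals, "gene") %||% NA_character_,
         locus_tag = qual_value(f$quals, "locus_tag"))
  })

  # circular wrap: a join whose later segment starts before an earlier one
  # ends wraps the origin; rotate so the genome starts right after the wrap.
  offset <- 0L
  wraps <- Filter(function(p) nrow(p$segments) > 1 &&
                    any(diff(p$segments[, 1]) < 0), parsed)
  if (length(wraps) > 0) {
    if (!circular) stop("origin-spanning feature in a linear record")
    offset <- wraps[[1]]$segments[1, 1] - 1L
    sequence <- paste0(substr(sequence, offset + 1L, len),
                       substr(sequence, 1L, offset))
    parsed <- lapply(parsed, function(p) {
      p$segments <- ((p$segments - 1L - offset) %% len) + 1L
      p$segments <- p$segments[order(p$segments[, 1]), , drop = FALSE]
      p
    })
  }

  genes <- list()
  intron_feats <- list()
  for (p in parsed) {
    nm <- if (!is.na(p$gene)) p$gene else p$locus_tag
    if (is.na(nm)) nm <- paste0("feat", length(genes) + 1)
    seg0 <- cbind(p$segments[, 1] - 1L, p$segments[, 2])
    # merge segments made contiguous by origin rotation
    if (nrow(seg0) > 1) {
      keep <- list(seg0[1, ])
      for (k in 2:nrow(seg0)) {
        last <- keep[[length(keep)]]
        if (seg0[k, 1] == last[2])
          keep[[length(keep)]] <- c(last[1], seg0[k, 2])
        else keep[[length(keep) + 1]] <- seg0[k, ]
      }
      seg0 <- do.call(rbind, keep)
    }
    if (p$key == "intron") {
      intron_feats[[length(intron_feats) + 1]] <-
        list(gene = p$gene, interval = seg0)
      next
    }
    kind <- switch(p$key, CDS = if (grepl("^orf", nm)) "ORF" else "protein",
                   tRNA = "tRNA", rRNA = "rRNA")
    genes[[length(genes) + 1]] <- list(name = nm, kind = kind,
                                       strand = p$strand, exons = seg0)
  }
  # attach intron features to hosts (by gene name, else by containment)
  models <- list()
  for (gn in genes) {
    span <- c(min(gn$exons[, 1]), max(gn$exons[, 2]))
    mine <- Filter(function(f) {
      if (!is.na(f$gene)) f$gene == gn$name else
        all(f$interval[, 1] >= span[1] & f$interval[, 2] <= span[2])
    }, intron_feats)
    fm <- if (length(mine))
      do.call(rbind, lapply(mine, `[[`, "interval")) else NULL
    if (!is.null(fm) &&
        any(fm[, 1] < span[1] | fm[, 2] > span[2]))
      stop("intron feature outside its host gene ", gn$name)
    models[[length(models) + 1]] <- gene_model(
      name = gn$name, kind = gn$kind, strand = gn$strand,
      exons = gn$exons, intron_features = fm)
  }
  annotated_genome(id = id, species_tag = species_tag %||% id,
                   sequence = sequence, genes = models,
                   circular = circular, origin_offset = offset)
}

#' Reverse the orientation of a genome (reverse complement)
#'
#' All features are remapped; per-gene intron ordinals (transcript
#' orientation) are unchanged by construction.
#'
#' @param g An \code{\link{annotated_genome}}.
#' @return The reversed \code{annotated_genome}.
#' @export
reverse_genome <- function(g) {
  len <- g$length
  flip <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(m)
    out <- cbind(len - m[, 2], len - m[, 1])
    out[order(out[, 1]), , drop = FALSE]
  }
  genes <- lapply(g$genes, function(gene) {
    gene_model(name = gene$name, kind = gene$kind,
               strand = if (gene$strand == "+") "-" else "+",
               exons = flip(gene$exons),
               duplicate_group = gene$duplicate_group,
               intron_features = flip(gene$intron_features))
  })
  annotated_genome(id = g$id, species_tag = g$species_tag,
                   sequence = revcomp(g$sequence), genes = genes,
                   circular = g$circular, origin_offset = g$origin_offset)
}
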