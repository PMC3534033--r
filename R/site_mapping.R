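# Insertion-site homology mapping. An intron insertion point is projected
# into the coordinate frame of an ortholog protein alignment as
# (alignment column of the interrupted residue, codon phase). Sites from
# different species are cognate iff they share gene, column and phase:
# insertions within the same amino acid but at different positions within
# the codon are distinct. Sites flagged ambiguous never cluster.

#' Build an aligned-site record
#'
#' @param gene Gene name.
#' @param species_tag Species tag (e.g. "Maen").
#' @param ordinal 1-based intron index on the gene, 5' to 3'.
#' @param column 0-based alignment column of the interrupted residue.
#' @param phase Codon phase of the insertion (0, 1, 2).
#' @param twintron Logical: site reported to display a twintron (in the
#'   reference species).
#' @param ambiguous Logical: site position ambiguous (kept distinct).
#' @return One-row data.frame with a parseable
#'   \code{site_id = gene.species.ordinal}.
#' @export
aligned_site <- function(gene, species_tag, ordinal, column, phase,
                         twintron = FALSE, ambiguous = FALSE) {
  data.frame(site_id = paste(gene, species_tag, ordinal, sep = "."),
             gene = gene, species_tag = species_tag,
             ordinal = as.integer(ordinal), column = as.integer(column),
             phase = as.integer(phase), twintron = twintron,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Project an intron record onto a protein alignment
#'
#' The insertion point interrupts the codon of one residue; the site is
#' (column of that residue, phase). A phase-0 insertion (exactly between
#' codons) is assigned to the following residue's column.
#'
#' @param intron An intron record from \code{\link{extract_introns}} (needs
#'   \code{host_gene}, \code{ordinal}, \code{coding_offset}, \code{phase}).
#' @param alignment An \code{\link{msa}} whose row names are species tags.
#' @param species_tag Row of the host species.
#' @return An \code{\link{aligned_site}} row.
#' @export
project_site <- function(intron, alignment, species_tag) {
  if (!species_tag %in% names(alignment$rows))
    stop("species ", species_tag, " not a row of the alignment")
  if (is.na(intron$phase))
    stop("site projection requires a protein-coding host (phase defined)")
  off <- intron$coding_offset
  residue0 <- off %/% 3L   # phase>0: codon containing the point; phase 0: next
  col <- msa_col_of(alignment, species_tag, residue0)
  aligned_site(gene = intron$host_gene, species_tag = species_tag,
               ordinal = intron$ordinal, column = col,
               phase = intron$phase,
               twintron = length(intron$children) > 0)
}

#' Cluster cognate insertion sites across species
#'
#' Sites group iff they share (gene, column, phase); ambiguous sites are
#' always singletons. Two sites of one species at the same position are a
#' data error (duplicate annotation).
#'
#' @param sites A data.frame of \code{\link{aligned_site}} rows (all sites
#'   of one or more genes, each gene projected onto its own alignment).
#' @return List of site groups, ordered by gene then column then phase;
#'   each is a list with \code{gene}, \code{column}, \code{phase},
#'   \code{members} (data.frame), \code{n}, \code{twintron},
#'   \code{ambiguous}.
#' @export
cluster_cognate_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0) return(list())
  key <- paste(sites$gene, sites$column, sites$phase, sep = "\r")
  dup <- duplicated(paste(key, sites$species_tag, sep = "\r")) & !sites$ambiguous
  if (any(dup))
    stop("duplicate annotation: two sites of one species at the same ",
         "(gene, column, phase): ", sites$site_id[dup][1])
  idx <- split(seq_len(nrow(sites)),
               ifelse(sites$ambiguous, paste0("amb\r", seq_len(nrow(sites))), key))
  groups <- lapply(idx, function(i) {
    m <- sites[i, , drop = FALSE]
    list(gene = m$gene[1], column = m$column[1], phase = m$phase[1],
         members = m, n = nrow(m),
         twintron = any(m$twintron), ambiguous = any(m$ambiguous))
  })
  ord <- order(vapply(groups, `[[`, character(1), "gene"),
               vapply(groups, `[[`, integer(1), "column"),
               vapply(groups, `[[`, integer(1), "phase"))
  unname(groups[ord])
}

group_has <- function(g, species) species %in% g$members$species_tag

#' Catalog the insertion sites of a focal species
#'
#' Per-site rows with cognate partners, plus summary counts (total, shared,
#' unique). A twintron counts as a single insertion site.
#'
#' @param groups Output of \code{\link{cluster_cognate_sites}}.
#' @param focal_species Species tag (e.g. "Maen").
#' @param path Optional TSV output path for the per-site table.
#' @return List with \code{table} (site_id, gene, column, phase, partners,
#'   n_partners, twintron, ambiguous, shared) and \code{summary}
#'   (total, shared, unique).
#' @export
site_catalog <- function(groups, focal_species, path = NULL) {
  keep <- Filter(function(g) group_has(g, focal_species), groups)
  if (length(keep) == 0 &&
      !any(vapply(groups, function(g) group_has(g, focal_species), logical(1))))
    if (length(groups) > 0) stop("unknown focal species: ", focal_species)
  rows <- lapply(keep, function(g) {
    me <- g$members[g$members$species_tag == focal_species, , drop = FALSE]
    partners <- g$members$site_id[g$members$species_tag != focal_species]
    data.frame(site_id = me$site_id[1], gene = g$gene, column = g$column,
               phase = g$phase,
               partners = paste(partners, collapse = ","),
               n_partners = length(partners),
               twintron = g$twintron, ambiguous = g$ambiguous,
               shared = length(partners) > 0, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(0), gene = character(0),
               column = integer(0), phase = integer(0),
               partners = character(0), n_partners = integer(0),
               twintron = logical(0), ambiguous = logical(0),
               shared = logical(0))
  if (!is.null(path)) write_tsv_file(tab, path)
  list(table = tab,
       summary = c(total = nrow(tab), shared = sum(tab$shared),
                   unique = sum(!tab$shared)))
}

#' Count focal-species groups that include a given partner
#'
#' @param groups Output of \code{\link{cluster_cognate_sites}}.
#' @param focal_species,partner Species tags.
#' @return Number of groups containing both species.
#' @export
count_shared_with <- function(groups, focal_species, partner) {
  sum(vapply(groups, function(g)
    group_has(g, focal_species) && group_has(g, partner), logical(1)))
}
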