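# Protein (and nucleotide) alignment: the common coordinate frame used to
# compare intron insertion sites across species. Pairwise optimal alignment
# is affine-gap Needleman-Wunsch (Biostrings engine); small multiple
# alignments are built by center-star progressive merging with the classic
# "once a gap, always a gap" rule. Externally produced alignments (e.g.
# MAFFT L-INS-i) can be imported and take precedence when available.

#' Affine-gap scoring scheme for protein alignment
#'
#' A gap run of length L costs \code{gap_open + gap_extend * L} (the
#' Biostrings convention). Defaults follow the common half-bit BLOSUM62
#' practice.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. "BLOSUM62"), or a numeric matrix.
#' @param gap_open,gap_extend Non-negative penalties with
#'   \code{gap_open >= gap_extend}.
#' @return A \code{scoring_scheme} object.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), gap_open >= gap_extend, gap_extend >= 0)
  structure(list(submat = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, alphabet = "AA"),
            class = "scoring_scheme")
}

#' Nucleotide scoring scheme (used for intron/twintron component alignment)
#'
#' The moderate gap-extension penalty keeps spurious gap-chasing alignments
#' unrewarding while still letting a component alignment jump the large
#' insertions that nested (internal) introns create in a target.
#'
#' @param match,mismatch Match reward and mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties, \code{gap_open >= gap_extend}.
#' @return A \code{scoring_scheme} object.
#' @export
dna_scoring_scheme <- function(match = 2, mismatch = -3,
                               gap_open = 10, gap_extend = 1) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = TRUE)
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(submat = m, gap_open = gap_open,
                 gap_extend = gap_extend, alphabet = "DNA"),
            class = "scoring_scheme")
}

# ---- MSA container ---------------------------------------------------------

#' Construct a multiple alignment object
#'
#' @param rows Named character vector of equal-length aligned rows
#'   ("-" for gaps).
#' @return An object of class \code{msa}.
#' @export
msa <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("msa rows must have unique names")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("ragged alignment: rows differ in length")
  structure(list(rows = rows, ncol = w), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns\n", length(x$rows), x$ncol))
  for (id in names(x$rows)) {
    r <- x$rows[[id]]
    if (nchar(r) > 60) r <- paste0(substr(r, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", id, r))
  }
  invisible(x)
}

#' Remove gaps from one alignment row
#' @param x An \code{msa}.
#' @param id Row name.
#' @return Ungapped sequence string.
#' @export
msa_ungap <- function(x, id) gsub("-", "", x$rows[[id]], fixed = TRUE)

#' Map a residue index to its alignment column
#'
#' @param x An \code{msa}.
#' @param id Row name.
#' @param residue0 0-based index into the ungapped sequence of that row.
#' @return 0-based alignment column.
#' @export
msa_col_of <- function(x, id, residue0) {
  v <- chars(x$rows[[id]])
  pos <- which(v != "-")
  if (residue0 < 0 || residue0 >= length(pos))
    stop(sprintf("residue index %d out of range for row '%s'", residue0, id))
  pos[residue0 + 1L] - 1L
}

#' Map an alignment column to the residue index in one row
#'
#' @inheritParams msa_col_of
#' @param col0 0-based alignment column.
#' @return 0-based residue index, or NA if that row is gapped there.
#' @export
msa_residue_of <- function(x, id, col0) {
  v <- chars(x$rows[[id]])
  if (col0 < 0 || col0 >= x$ncol) stop("column out of range")
  if (v[col0 + 1L] == "-") return(NA_integer_)
  sum(v[seq_len(col0 + 1L)] != "-") - 1L
}

# ---- pairwise and star alignment ------------------------------------------

as_xstring <- function(seq, alphabet) {
  if (alphabet == "AA") Biostrings::AAString(seq) else
    Biostrings::DNAString(norm_nt(seq))
}

check_alphabet <- function(seq, alphabet) {
  ok <- if (alphabet == "AA") {
    grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", toupper(seq))
  } else {
    grepl("^[ACGT]+$", norm_nt(seq))
  }
  if (!ok) stop("illegal residue symbol in input sequence")
}

#' Optimal global pairwise alignment
#'
#' Affine-gap Needleman-Wunsch over the scheme's substitution matrix; the
#' traceback is deterministic.
#'
#' @param a,b Sequences (character). Names \code{a}/\code{b} are taken from
#'   the vector names when present.
#' @param scheme A \code{\link{scoring_scheme}}.
#' @param type Alignment type passed to the engine: "global" or
#'   "global-local" (reference global, target flanks free).
#' @return A list with elements \code{msa} (2-row \code{msa}) and
#'   \code{score}.
#' @export
global_align <- function(a, b, scheme = scoring_scheme(), type = "global") {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  check_alphabet(a, scheme$alphabet)
  check_alphabet(b, scheme$alphabet)
  ida <- names(a) %||% "a"; idb <- names(b) %||% "b"
  pa <- Biostrings::pairwiseAlignment(
    as_xstring(unname(a), scheme$alphabet),
    as_xstring(unname(b), scheme$alphabet),
    substitutionMatrix = scheme$submat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = type)
  rows <- c(as.character(Biostrings::alignedPattern(pa)),
            as.character(Biostrings::alignedSubject(pa)))
  names(rows) <- c(ida, idb)
  list(msa = msa(rows), score = Biostrings::score(pa))
}

# Gap profile of an aligned row relative to its ungapped sequence: an integer
# vector of length (nresidue + 1) counting gaps before residue i (and after
# the last). Two profiles over the same sequence merge by taking pmax.
gap_profile <- function(aligned_row) {
  v <- chars(aligned_row)
  n_res <- sum(v != "-")
  prof <- integer(n_res + 1L)
  slot <- 1L
  for (ch in v) {
    if (ch == "-") prof[slot] <- prof[slot] + 1L else slot <- slot + 1L
  }
  prof
}

# Rebuild an aligned row from the ungapped sequence and a gap profile.
apply_profile <- function(seq, prof) {
  v <- chars(seq)
  out <- character(0)
  for (i in seq_along(prof)) {
    out <- c(out, rep("-", prof[i]), if (i <= length(v)) v[i])
  }
  paste(out, collapse = "")
}

# Insert extra master gaps into a non-center aligned row. `old` and `new`
# are center gap profiles before/after merging; `row` is aligned under `old`.
pad_row_to_profile <- function(row, old, new) {
  v <- chars(row)
  out <- character(0)
  k <- 1L
  for (i in seq_along(old)) {
    # copy this slot's gap columns + residue column
    take <- old[i] + (if (i < length(old)) 1L else 0L)
    extra <- new[i] - old[i]
    out <- c(out, rep("-", extra), v[seq_len(take) + k - 1L])
    k <- k + take
  }
  paste(out, collapse = "")
}

#' Center-star progressive multiple alignment
#'
#' The center sequence maximizes its summed pairwise alignment score against
#' all others; every other sequence is aligned to the center and gaps are
#' propagated with the "once a gap, always a gap" rule.
#'
#' @param seqs Named character vector of >= 2 sequences.
#' @param scheme A \code{\link{scoring_scheme}}.
#' @return An \code{msa} with rows in the input order.
#' @export
star_msa <- function(seqs, scheme = scoring_scheme()) {
  if (length(seqs) < 2) stop("star_msa needs at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n == 2) {
    al <- global_align(seqs[1], seqs[2], scheme)
    return(al$msa)
  }
  # pairwise score sums to pick the center
  sums <- numeric(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- global_align(seqs[i], seqs[j], scheme)$score
    sums[i] <- sums[i] + s; sums[j] <- sums[j] + s
  }
  ci <- which.max(sums)
  center <- seqs[[ci]]
  others <- setdiff(seq_len(n), ci)
  prof <- integer(nchar(center) + 1L)            # merged center gap profile
  pair_rows <- list(); pair_profs <- list()
  for (j in others) {
    al <- global_align(seqs[ci], seqs[j], scheme)
    p <- gap_profile(al$msa$rows[[1]])
    pair_rows[[as.character(j)]] <- al$msa$rows[[2]]
    pair_profs[[as.character(j)]] <- p
    prof <- pmax(prof, p)
  }
  rows <- stats::setNames(vector("character", n), names(seqs))
  rows[ci] <- apply_profile(center, prof)
  for (j in others) {
    key <- as.character(j)
    rows[j] <- pad_row_to_profile(pair_rows[[key]], pair_profs[[key]], prof)
  }
  msa(rows)
}

# ---- import / export -------------------------------------------------------

#' Import an aligned FASTA file as an \code{msa}
#' @param path Aligned FASTA (equal-length rows, "-" gaps).
#' @return An \code{msa}.
#' @export
import_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(ss), names(ss))
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged rows in aligned FASTA: ", path)
  msa(rows)
}

#' Export an \code{msa} to aligned FASTA
#' @param x An \code{msa}.
#' @param path Output file.
#' @export
export_alignment <- function(x, path) {
  ss <- Biostrings::BStringSet(x$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
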