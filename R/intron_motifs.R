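# Group II / group III intron consensus scanning.
#
# Euglenid plastid group III introns are small, U-rich, highly degenerate
# group II introns that retain only two recognizable landmarks: a relaxed
# 5' NUNNG terminus and, near the 3' end, a "pseudo-domain VI" stem-loop
# carrying the bulged adenosine (the branch point of the splicing reaction).
# The 3' consensus is written abcdef (3-8) f'e'd' A* c'b'a' (4): a 6-bp stem
# (a..f paired to a'..f'), a 3-8 nt terminal loop, the bulged A between d'
# and c', and 4 nt from a' to the intron's 3' end. The scanner enumerates
# every placement of that layout against the 3' end of an intron.

#' Scanner parameters for the pseudo-domain VI consensus
#'
#' @param loop_min,loop_max Allowed terminal loop lengths (nt).
#' @param tail_min,tail_max Allowed distance (nt) from a' to the intron 3'
#'   end; the published consensus states exactly 4.
#' @param allow_gu Accept G·U wobble pairs in the stem.
#' @param max_mismatch Maximum number of unpaired stem positions.
#' @param search_window The motif must lie within this many nt of the 3' end.
#' @return A \code{motif_params} object.
#' @export
motif_params <- function(loop_min = 3, loop_max = 8,
                         tail_min = 4, tail_max = 4,
                         allow_gu = TRUE, max_mismatch = 0,
                         search_window = 40) {
  stopifnot(loop_min <= loop_max, loop_min >= 0,
            tail_min <= tail_max, tail_min >= 0,
            max_mismatch >= 0, search_window > 0)
  structure(list(loop_min = loop_min, loop_max = loop_max,
                 tail_min = tail_min, tail_max = tail_max,
                 allow_gu = allow_gu, max_mismatch = max_mismatch,
                 search_window = search_window),
            class = "motif_params")
}

# Is x·y an accepted base pair (DNA letters; U normalized to T upstream)?
base_pairs <- function(x, y, allow_gu = TRUE) {
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
        (x == "G" & y == "C") | (x == "C" & y == "G")
  if (allow_gu) wc <- wc | (x == "G" & y == "T") | (x == "T" & y == "G")
  wc
}

#' Test the 5' NUNNG consensus of an intron
#'
#' True iff position 2 is U and position 5 is G (N positions free).
#'
#' @param seq Intron sequence (DNA or RNA, length >= 5).
#' @return List with \code{match} (logical) and \code{fivemer}.
#' @export
scan_5prime <- function(seq) {
  s <- norm_nt(seq)
  if (nchar(s) < 5) stop("sequence shorter than 5 nt")
  fm <- substr(s, 1, 5)
  list(match = substr(s, 2, 2) == "T" && substr(s, 5, 5) == "G",
       fivemer = chartr("T", "U", fm))
}

#' Scan for the 3' pseudo-domain VI stem-bulge-tail motif
#'
#' Enumerates all placements ending at the intron 3' terminus (tail length
#' within the configured range) and lying within \code{search_window} nt of
#' the 3' end, requiring the 6 stem pairings (Watson-Crick, optionally G·U)
#' with at most \code{max_mismatch} failures, a loop in range, and an
#' adenosine bulged between d' and c'.
#'
#' @param seq Intron sequence.
#' @param params A \code{\link{motif_params}}.
#' @return A data.frame of hits (possibly 0 rows) with 1-based coordinates:
#'   \code{stem5_start}, \code{loop_len}, \code{bulge_index},
#'   \code{tail_len}, \code{mismatches}, \code{span}; sorted by fewest
#'   mismatches, then shortest loop, then 3'-most placement.
#' @export
find_domain_vi <- function(seq, params = motif_params()) {
  s <- norm_nt(seq)
  n <- nchar(s)
  v <- chars(s)
  hits <- list()
  for (tail in params$tail_min:params$tail_max) {
    for (loop in params$loop_min:params$loop_max) {
      span <- 13L + loop + tail
      start <- n - span + 1L
      if (start < 1L || span > params$search_window) next
      # layout offsets (1-based within the motif)
      stem5 <- v[start:(start + 5L)]                       # a b c d e f
      arm3a <- v[(start + 6L + loop):(start + 8L + loop)]  # f' e' d'
      bulge <- v[start + 9L + loop]                        # A*
      arm3b <- v[(start + 10L + loop):(start + 12L + loop)] # c' b' a'
      if (bulge != "A") next
      partners <- c(rev(arm3b), rev(arm3a))                # a' b' c' d' e' f'
      mm <- sum(!base_pairs(stem5, partners, params$allow_gu))
      if (mm > params$max_mismatch) next
      hits[[length(hits) + 1L]] <- data.frame(
        stem5_start = start, loop_len = loop,
        bulge_index = start + 9L + loop, tail_len = tail,
        mismatches = mm, span = span)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(stem5_start = integer(0), loop_len = integer(0),
                      bulge_index = integer(0), tail_len = integer(0),
                      mismatches = integer(0), span = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$mismatches, out$loop_len, -out$stem5_start), , drop = FALSE]
}

#' Classify an intron as group II, group III, or unclassified
#'
#' Group III requires the 5' NUNNG consensus, at least one pseudo-domain VI
#' hit, and a length at or below \code{max_g3_len}; an intron longer than
#' \code{max_g3_len} with a domain VI hit is called group II; anything else
#' is unclassified. The U fraction is reported as a diagnostic only.
#'
#' @param x Intron sequence, or an intron record (list with \code{sequence}).
#' @param params A \code{\link{motif_params}}.
#' @param max_g3_len Length ceiling (nt) for the group III call; not a
#'   published value, exposed as a knob (default 150).
#' @return List with \code{class}, \code{length}, \code{u_fraction},
#'   \code{fivemer_match}, \code{n_domain_vi_hits}.
#' @export
classify_intron <- function(x, params = motif_params(), max_g3_len = 150) {
  seq <- if (is.list(x)) x$sequence else x
  seq <- norm_nt(seq)
  if (nchar(seq) == 0) stop("empty intron sequence")
  p5 <- if (nchar(seq) >= 5) scan_5prime(seq)$match else FALSE
  nh <- nrow(find_domain_vi(seq, params))
  cls <- if (p5 && nh >= 1 && nchar(seq) <= max_g3_len) "group_III"
         else if (nchar(seq) > max_g3_len && nh >= 1) "group_II"
         else "unclassified"
  list(class = cls, length = nchar(seq), u_fraction = u_fraction(seq),
       fivemer_match = p5, n_domain_vi_hits = nh)
}

#' Scan a FASTA of introns and write a TSV report
#'
#' @param fasta_path Input FASTA of intron sequences.
#' @param out_path Output TSV path (optional).
#' @param params A \code{\link{motif_params}}.
#' @param max_g3_len See \code{\link{classify_intron}}.
#' @return The report data.frame (id, length, u_fraction, fivemer,
#'   n_domain_vi_hits, class), invisibly written to \code{out_path} if given.
#' @export
scan_report <- function(fasta_path, out_path = NULL,
                        params = motif_params(), max_g3_len = 150) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  rows <- lapply(seq_along(ss), function(i) {
    s <- as.character(ss[[i]])
    cl <- classify_intron(s, params, max_g3_len)
    data.frame(id = names(ss)[i], length = cl$length,
               u_fraction = round(cl$u_fraction, 3),
               fivemer = if (nchar(s) >= 5) scan_5prime(s)$fivemer else NA,
               n_domain_vi_hits = cl$n_domain_vi_hits, class = cl$class)
  })
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), length = integer(0),
               u_fraction = numeric(0), fivemer = character(0),
               n_domain_vi_hits = integer(0), class = character(0))
  if (!is.null(out_path)) write_tsv_file(rep, out_path)
  rep
}
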