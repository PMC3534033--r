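# Twintron decomposition. A twintron is an intron inserted within another
# intron: the internal intron(s) must be excised first, leaving the external
# intron to splice. To ask whether a candidate site in a target genome
# shares a reference (E. gracilis-style) twintron, the reference is broken
# into its external and internal components and each component is aligned
# semi-globally against the target intron sequence (reference fully aligned,
# target flanks free), alongside a full-span alignment. Component support
# (coverage, identity, and a permutation-null guard on identity) yields one
# of four classifications: complete twintron, partial twintron (a subset of
# internals present — the intermediate stage), external-only, or unrelated.

#' Describe a reference twintron
#'
#' @param site_id Site identifier of the reference twintron.
#' @param external External intron sequence (internals excised).
#' @param internals List of internal components, each a list with
#'   \code{seq} and \code{pos} (0-based offset into the external sequence
#'   at which the internal sits). Positions refer to the external with all
#'   prior internals excised.
#' @param groups Optional character vector of group labels ("GII"/"GIII")
#'   for (external, internals...).
#' @return A \code{twintron_reference} object.
#' @export
twintron_reference <- function(site_id, external, internals = list(),
                               groups = NULL) {
  external <- norm_nt(external)
  if (nchar(external) == 0) stop("empty external component")
  for (it in internals) {
    if (is.null(it$seq) || nchar(it$seq) == 0)
      stop("empty internal component in ", site_id)
    if (it$pos < 0 || it$pos > nchar(external))
      stop("internal position outside the external span in ", site_id)
  }
  structure(list(site_id = site_id, external = external,
                 internals = internals, groups = groups),
            class = "twintron_reference")
}

#' Reconstruct the full (nested) sequence of a reference twintron
#' @param ref A \code{\link{twintron_reference}}.
#' @return The external sequence with all internals inserted.
#' @export
full_twintron_seq <- function(ref) {
  s <- ref$external
  ord <- order(vapply(ref$internals, `[[`, numeric(1), "pos"),
               decreasing = TRUE)
  for (i in ord) {
    it <- ref$internals[[i]]
    s <- paste0(substr(s, 1, it$pos), norm_nt(it$seq),
                substr(s, it$pos + 1, nchar(s)))
  }
  s
}

# Coverage/identity of one reference component aligned semi-globally
# (pattern-global) against the target.
component_evidence <- function(component, target, scheme) {
  al <- global_align(c(ref = component), c(target = target), scheme,
                     type = "global-local")
  p <- chars(al$msa$rows[[1]])
  s <- chars(al$msa$rows[[2]])
  respos <- p != "-"
  aligned <- respos & s != "-"
  matches <- sum(aligned & p == s)
  c(coverage = sum(aligned) / sum(respos),
    identity = if (sum(aligned) > 0) matches / sum(aligned) else 0,
    score = al$score)
}

#' Align reference twintron components against a target intron
#'
#' Computes, for the full reference span, the external component and each
#' internal component: coverage (fraction of the component aligned opposite
#' target residues), identity (identical fraction over aligned columns), and
#' a permutation null for identity obtained by shuffling the target
#' (\code{n_shuffles} seeded shuffles), from which a z-score is derived.
#'
#' @param target Target intron sequence.
#' @param ref A \code{\link{twintron_reference}}.
#' @param scheme Nucleotide \code{\link{dna_scoring_scheme}}.
#' @param n_shuffles Shuffles for the permutation null (0 disables).
#' @return A \code{twintron_evidence} object: data.frame \code{components}
#'   with component, length, coverage, identity, null_mean, null_sd, z.
#' @export
component_align <- function(target, ref, scheme = dna_scoring_scheme(),
                            n_shuffles = 30) {
  target <- norm_nt(target)
  if (nchar(target) == 0) stop("empty target sequence")
  comps <- c(list(full = full_twintron_seq(ref), external = ref$external),
             stats::setNames(lapply(ref$internals, function(x) norm_nt(x$seq)),
                             paste0("internal", seq_along(ref$internals))))
  shuffled <- if (n_shuffles > 0)
    vapply(seq_len(n_shuffles), function(i)
      paste(sample(chars(target)), collapse = ""), character(1)) else character(0)
  rows <- lapply(names(comps), function(nm) {
    ev <- component_evidence(comps[[nm]], target, scheme)
    if (length(shuffled)) {
      null_id <- vapply(shuffled, function(s)
        component_evidence(comps[[nm]], s, scheme)["identity"], numeric(1))
      mu <- mean(null_id); sdv <- stats::sd(null_id)
      z <- if (sdv > 0) (ev["identity"] - mu) / sdv else Inf
    } else {
      mu <- NA_real_; sdv <- NA_real_; z <- NA_real_
    }
    data.frame(component = nm, length = nchar(comps[[nm]]),
               coverage = unname(ev["coverage"]),
               identity = unname(ev["identity"]),
               null_mean = mu, null_sd = sdv, z = unname(z),
               stringsAsFactors = FALSE)
  })
  structure(list(site_id = ref$site_id, target_length = nchar(target),
                 components = do.call(rbind, rows)),
            class = "twintron_evidence")
}

#' Default thresholds for twintron component support
#'
#' A component is supported when coverage >= \code{coverage}, identity >=
#' \code{identity}, and (when the permutation null was computed) the
#' identity z-score >= \code{z}. \code{surplus} is the unexplained target
#' length (nt) above which a motif scan of the target is reported when
#' internals are unsupported.
#'
#' @param coverage,identity Support thresholds in [0, 1].
#' @param z Minimum identity z-score against the permutation null.
#' @param surplus Unexplained-length trigger (nt) for the motif scan.
#' @return A list of thresholds.
#' @export
twintron_thresholds <- function(coverage = 0.5, identity = 0.5, z = 3,
                                surplus = 60) {
  if (coverage < 0 || coverage > 1 || identity < 0 || identity > 1)
    stop("support thresholds must lie in [0, 1]")
  list(coverage = coverage, identity = identity, z = z, surplus = surplus)
}

#' Classify a candidate twintron site from component evidence
#'
#' @param evidence A \code{twintron_evidence} from
#'   \code{\link{component_align}}.
#' @param thresholds See \code{\link{twintron_thresholds}}.
#' @param target Optional target sequence; when internals are unsupported
#'   and the unexplained length surplus exceeds \code{thresholds$surplus},
#'   a 5'/domain VI scan of the target is attached as a diagnostic.
#' @return A \code{twintron_status} list: \code{status} in
#'   \{complete_twintron, partial_twintron, external_only, unrelated\},
#'   \code{supported_internals} (integer indices), \code{evidence}, and
#'   optionally \code{surplus}, \code{surplus_scan}.
#' @export
classify_site <- function(evidence, thresholds = twintron_thresholds(),
                          target = NULL) {
  cmp <- evidence$components
  supported <- cmp$coverage >= thresholds$coverage &
    cmp$identity >= thresholds$identity &
    (is.na(cmp$z) | cmp$z >= thresholds$z)
  names(supported) <- cmp$component
  internal_idx <- grep("^internal", cmp$component)
  int_ok <- supported[internal_idx]
  ext_ok <- supported[["external"]]
  status <- if (ext_ok && length(internal_idx) > 0 && all(int_ok))
    "complete_twintron"
  else if (ext_ok && any(int_ok)) "partial_twintron"
  else if (ext_ok) "external_only"
  else "unrelated"
  out <- list(site_id = evidence$site_id, status = status,
              supported_internals = which(unname(int_ok)),
              evidence = evidence)
  # unexplained length surplus: target beyond external + supported internals
  explained <- cmp$length[cmp$component == "external"] +
    sum(cmp$length[internal_idx][int_ok])
  surplus <- evidence$target_length - explained
  if (any(!int_ok) && surplus > thresholds$surplus) {
    out$surplus <- surplus
    if (!is.null(target))
      out$surplus_scan <- classify_intron(target)
  }
  out
}

#' Splice-order decomposition of a nested intron
#'
#' Returns the excision plan for a (possibly multiply) nested intron,
#' innermost first — the order in which components must be removed for the
#' mature external intron to emerge.
#'
#' @param intron An intron record with \code{children} (from
#'   \code{\link{extract_introns}}).
#' @return A data.frame of steps: \code{step}, \code{id}, \code{level},
#'   \code{start}, \code{end} (genomic 0-based half-open).
#' @export
decompose_nested <- function(intron) {
  collect <- function(rec, id, level) {
    kids <- rec$children
    if (length(kids) > 1) {
      iv <- t(vapply(kids, function(k) c(k$start, k$end), numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("overlapping (non-nested) internal introns in ", id)
    }
    rows <- data.frame(id = id, level = level,
                       start = rec$start, end = rec$end)
    for (i in seq_along(kids))
      rows <- rbind(collect(kids[[i]], paste0(id, ".", i), level + 1L), rows)
    rows
  }
  plan <- collect(intron, paste(intron$host_gene, intron$ordinal, sep = "."), 0L)
  # innermost (deepest) first; among equals, 5'-most first
  plan <- plan[order(-plan$level, plan$start), , drop = FALSE]
  plan$step <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  plan[, c("step", "id", "level", "start", "end")]
}

#' Excise intervals from a sequence
#'
#' @param seq Sequence string.
#' @param intervals Matrix of 0-based half-open intervals (relative to
#'   \code{seq}) to remove; must be non-overlapping.
#' @return The sequence with the intervals removed.
#' @export
excise <- function(seq, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(seq)
  iv <- intervals[order(-intervals[, 1]), , drop = FALSE]
  for (k in seq_len(nrow(iv)))
    seq <- paste0(substr(seq, 1, iv[k, 1]), substr(seq, iv[k, 2] + 1, nchar(seq)))
  seq
}

#' Classify a cohort of candidate twintron sites
#'
#' @param cohort A list of candidates, each a list with \code{ref}
#'   (a \code{\link{twintron_reference}}) and \code{target} (sequence).
#' @param scheme Nucleotide scoring scheme.
#' @param thresholds See \code{\link{twintron_thresholds}}.
#' @param n_shuffles Permutation-null shuffles per component.
#' @param path Optional TSV output of per-site evidence and status.
#' @return A data.frame: site_id, status, n_internals, supported_internals,
#'   external_coverage, external_identity, external_z, shares_twintron
#'   (status complete or partial).
#' @export
classify_cohort <- function(cohort, scheme = dna_scoring_scheme(),
                            thresholds = twintron_thresholds(),
                            n_shuffles = 30, path = NULL) {
  rows <- lapply(cohort, function(cand) {
    ev <- component_align(cand$target, cand$ref, scheme, n_shuffles)
    st <- classify_site(ev, thresholds, target = cand$target)
    ext <- ev$components[ev$components$component == "external", ]
    data.frame(site_id = cand$ref$site_id, status = st$status,
               n_internals = length(cand$ref$internals),
               supported_internals =
                 paste(st$supported_internals, collapse = ","),
               external_coverage = round(ext$coverage, 3),
               external_identity = round(ext$identity, 3),
               external_z = round(ext$z, 2),
               shares_twintron = st$status %in%
                 c("complete_twintron", "partial_twintron"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write_tsv_file(out, path)
  out
}
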