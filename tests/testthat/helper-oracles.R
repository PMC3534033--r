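# Independent oracles used to validate the optimized implementations.

# --- exhaustive global alignment score (affine gaps) ------------------------
# Enumerates every global alignment of a and b as an op sequence (M/I/D) and
# scores it with: sum of substitution scores minus, per maximal gap run,
# (gap_open + gap_extend * run_length). Feasible for lengths <= 5.
brute_force_align_score <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sm <- scheme$submat
  best <- -Inf
  rec <- function(i, j, score, last_op, run) {
    # close out a pending gap run
    settle <- function(s, op, r) {
      if (op %in% c("I", "D")) s - scheme$gap_open - scheme$gap_extend * r
      else s
    }
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, settle(score, last_op, run))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s2 <- settle(score, last_op, run) + sm[av[i], bv[j]]
      rec(i + 1, j + 1, s2, "M", 0)
    }
    if (i <= length(av)) { # gap in b (deletion)
      if (last_op == "D") rec(i + 1, j, score, "D", run + 1)
      else rec(i + 1, j, settle(score, last_op, run), "D", 1)
    }
    if (j <= length(bv)) { # gap in a (insertion)
      if (last_op == "I") rec(i, j + 1, score, "I", run + 1)
      else rec(i, j + 1, settle(score, last_op, run), "I", 1)
    }
    invisible()
  }
  rec(1, 1, 0, "M", 0)
  best
}

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# --- exhaustive pseudo-domain VI placement enumerator -----------------------
# Walks every (loop, tail) placement ending at the 3' terminus and checks the
# stem by explicit string comparison against the complement (independent of
# the package's vectorized pairing check).
oracle_domain_vi <- function(seq, params = motif_params()) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pair_ok <- function(x, y) {
    (comp[[x]] == y) ||
      (params$allow_gu && ((x == "G" && y == "T") || (x == "T" && y == "G")))
  }
  hits <- data.frame()
  for (tail in params$tail_min:params$tail_max) {
    for (loop in params$loop_min:params$loop_max) {
      span <- 6 + loop + 3 + 1 + 3 + tail
      st <- n - span + 1
      if (st < 1 || span > params$search_window) next
      if (v[st + 9 + loop] != "A") next
      mm <- 0
      # a..f at st..st+5; partners a'..f' at st+12+loop .. (reading back)
      partner_pos <- c(st + 12 + loop, st + 11 + loop, st + 10 + loop,
                       st + 8 + loop, st + 7 + loop, st + 6 + loop)
      for (k in 1:6) if (!pair_ok(v[st + k - 1], v[partner_pos[k]])) mm <- mm + 1
      if (mm <= params$max_mismatch)
        hits <- rbind(hits, data.frame(stem5_start = st, loop_len = loop,
                                       tail_len = tail, mismatches = mm))
    }
  }
  hits
}

# --- brute-force Dollo: min losses over all single-gain placements ----------
# For every gain node whose clade contains all present tips, enumerate
# subsets of candidate loss branches (clades with no present tip) and find
# the smallest subset covering every applicable absent tip in the clade.
oracle_dollo <- function(tree, st) {
  ntip <- length(tree$tip.label)
  kids <- function(n) tree$edge[tree$edge[, 1] == n, 2]
  below <- function(n) if (n <= ntip) tree$tip.label[n] else
    unlist(lapply(kids(n), below))
  nodes <- sort(unique(c(tree$edge[, 2], ntip + 1L)))
  present <- names(st)[st == "present"]
  absent <- names(st)[st == "absent"]
  best <- Inf
  best_gain <- NULL
  for (g in nodes) {
    tps <- below(g)
    if (!all(present %in% tps)) next
    need <- intersect(absent, tps)
    if (length(need) == 0) {
      if (best > 0) { best <- 0; best_gain <- paste(sort(tps), collapse = ",") }
      next
    }
    cand <- Filter(function(n2) {
      b <- below(n2)
      all(b %in% tps) && length(intersect(b, present)) == 0 && n2 != g
    }, nodes)
    for (k in seq_len(length(cand))) {
      if (k >= best) break
      found <- FALSE
      for (cs in utils::combn(length(cand), k, simplify = FALSE)) {
        covered <- unlist(lapply(cand[cs], below))
        if (all(need %in% covered)) { found <- TRUE; break }
      }
      if (found) {
        if (k < best) { best <- k; best_gain <- paste(sort(tps), collapse = ",") }
        break
      }
    }
  }
  list(min_losses = best, gain_branch = best_gain)
}

random_state_row <- function(tree) {
  repeat {
    st <- stats::setNames(
      sample(c("present", "absent", "inapplicable"), length(tree$tip.label),
             replace = TRUE, prob = c(0.45, 0.40, 0.15)),
      tree$tip.label)
    if (any(st == "present")) return(st)
  }
}
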