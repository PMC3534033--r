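# Phylogenetic mapping of insertion sites: the pairwise shared-site matrix
# and Dollo-parsimony reconstruction of gains and losses on a rooted species
# tree. Insertion-site homology implies a unique origin, so each site is
# allowed exactly one gain (on the branch above the MRCA of the taxa
# carrying it) and any number of subsequent losses; taxa that have lost the
# host gene are "inapplicable" and constrain nothing.

#' Pairwise shared-site matrix
#'
#' Entry (i, j) is the number of site groups containing both species i and
#' j; the diagonal holds per-species totals. A parallel matrix counts the
#' groups flagged as twintron sites.
#'
#' @param groups Output of \code{\link{cluster_cognate_sites}}.
#' @param species Character vector of species tags (matrix order). Species
#'   absent from every group get a zero row with a warning.
#' @return A \code{sharing_matrix} list: \code{counts},
#'   \code{twintron_counts}, \code{species}.
#' @export
sharing_matrix <- function(groups, species) {
  n <- length(species)
  counts <- matrix(0L, n, n, dimnames = list(species, species))
  tw <- counts
  for (g in groups) {
    sp <- intersect(species, g$members$species_tag)
    if (length(sp) == 0) next
    counts[sp, sp] <- counts[sp, sp] + 1L
    if (isTRUE(g$twintron)) tw[sp, sp] <- tw[sp, sp] + 1L
  }
  missing <- species[diag(counts) == 0]
  if (length(missing))
    warning("species with no sites in any group: ",
            paste(missing, collapse = ", "))
  structure(list(counts = counts, twintron_counts = tw, species = species),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("shared insertion sites (twintron sites in brackets):\n")
  m <- matrix(sprintf("%d [%d]", x$counts, x$twintron_counts),
              nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  invisible(x)
}

# ---- tree utilities --------------------------------------------------------

# Branch identifier: sorted tip labels of the clade below the branch.
clade_id <- function(tips) paste(sort(tips), collapse = ",")

# For a rooted ape::phylo tree, list every branch (edge above each non-root
# node, plus the root stem) with its subtended tip set.
tree_branches <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- c(seq_len(ntip), setdiff(unique(tree$edge[, 1]), integer(0)))
  nodes <- sort(unique(c(tree$edge[, 2], root)))
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  lapply(nodes, function(nd)
    list(node = nd, tips = below(nd), id = clade_id(below(nd)),
         is_root = nd == root))
}

# node (ape index) of the MRCA of a tip set
mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("species not in tree: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}

#' Dollo-parsimony gain/loss map of presence/absence characters
#'
#' Each site's gain is placed on the branch above the MRCA of the taxa in
#' which it is present; losses are the minimal set of branches within that
#' clade whose (applicable) descendants are all absent. Branches are
#' identified by the sorted tip set of the clade they subtend; the branch
#' above the root is the "stem" (all tips).
#'
#' @param states Character matrix, rows = sites, columns = species, entries
#'   in \{"present", "absent", "inapplicable"\}.
#' @param tree A rooted \code{ape::phylo} tree, or a path/string in newick.
#' @return A \code{gain_loss_map} list: \code{sites} data.frame (site,
#'   gain_branch, n_losses, loss_branches), \code{branch_gains} (named
#'   vector of gains per branch id), \code{tree}.
#' @export
dollo_map <- function(states, tree) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  sp <- colnames(states)
  if (is.null(sp)) stop("states needs species column names")
  if (!all(sp %in% tree$tip.label))
    stop("species not in tree: ",
         paste(setdiff(sp, tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  kids_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids_of(node), tips_below))
  }
  rows <- list()
  gains <- list()
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    present <- sp[st == "present"]
    if (length(present) == 0) {
      rows[[i]] <- data.frame(site = rownames(states)[i] %||% i,
                              gain_branch = NA, n_losses = NA,
                              loss_branches = NA)
      next
    }
    gnode <- mrca_node(tree, present)
    gid <- clade_id(tips_below(gnode))
    # minimal losses: maximal all-absent (applicable) subtrees under gnode
    losses <- character(0)
    state_of <- function(tip) st[[tip]]
    walk <- function(node) {
      tps <- tips_below(node)
      stt <- vapply(tps, state_of, character(1))
      appl <- stt != "inapplicable"
      if (!any(appl)) return(invisible())        # inapplicable-only: free
      if (all(stt[appl] == "absent")) {
        losses <<- c(losses, clade_id(tps))
        return(invisible())
      }
      if (node > ntip) for (k in kids_of(node)) walk(k)
      invisible()
    }
    if (gnode > ntip) for (k in kids_of(gnode)) walk(k)
    rows[[i]] <- data.frame(site = rownames(states)[i] %||% i,
                            gain_branch = gid, n_losses = length(losses),
                            loss_branches = paste(losses, collapse = ";"),
                            stringsAsFactors = FALSE)
    gains[[gid]] <- (gains[[gid]] %||% 0L) + 1L
  }
  sites <- do.call(rbind, rows)
  structure(list(sites = sites,
                 branch_gains = unlist(gains) %||% integer(0),
                 tree = tree),
            class = "gain_loss_map")
}

#' Presence/absence/inapplicable state matrix from site groups
#'
#' @param groups Output of \code{\link{cluster_cognate_sites}}.
#' @param species Species tags (columns).
#' @param inapplicable Optional named list mapping gene name to the species
#'   lacking that gene (state "inapplicable" rather than "absent").
#' @return Character matrix sites x species.
#' @export
states_from_groups <- function(groups, species, inapplicable = list()) {
  m <- matrix("absent", nrow = length(groups), ncol = length(species),
              dimnames = list(
                vapply(groups, function(g)
                  paste(g$gene, g$column, g$phase, sep = "."), character(1)),
                species))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    m[i, intersect(species, g$members$species_tag)] <- "present"
    na_sp <- inapplicable[[g$gene]]
    if (!is.null(na_sp)) {
      na_sp <- setdiff(intersect(na_sp, species), g$members$species_tag)
      m[i, na_sp] <- "inapplicable"
    }
  }
  m
}

#' Fitch parsimony score of presence/absence characters (sensitivity check)
#'
#' Unordered binary Fitch counts state changes without the single-gain
#' constraint; exposed for comparison with the Dollo reconstruction.
#' Inapplicable entries are treated as missing.
#'
#' @inheritParams dollo_map
#' @return Integer vector of per-site Fitch change counts.
#' @export
fitch_score <- function(states, tree) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  kids_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  apply(states, 1, function(st) {
    changes <- 0L
    fitch <- function(node) {
      if (node <= ntip) {
        s <- st[[tree$tip.label[node]]]
        return(switch(s, present = "P", absent = "A", inapplicable = "PA"))
      }
      sets <- vapply(kids_of(node), function(k) fitch(k), character(1))
      splitsets <- strsplit(sets, "")
      common <- Reduce(intersect, splitsets)
      if (length(common) > 0) return(paste(common, collapse = ""))
      changes <<- changes + length(splitsets) - 1L
      paste(sort(unique(unlist(splitsets))), collapse = "")
    }
    fitch(ntip + 1L)
    changes
  })
}
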