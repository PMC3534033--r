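euglenid_tree <- function() {
  ape::read.tree(text = "(Ppar,(Egym,(Evir,(Maen,(Elon,Egra)))));")
}

test_that("the sharing matrix reproduces the published pairwise counts", {
  fx <- build_paper_fixture()
  gr <- cluster_cognate_sites(fx$sites)
  sm <- sharing_matrix(gr, c("Maen", "Egra", "Evir", "Egym"))
  expect_equal(sm$counts["Maen", "Egra"], 40L)
  expect_equal(sm$counts["Maen", "Maen"], 53L)
  expect_equal(sm$twintron_counts["Maen", "Egra"], 12L)
  # exactly one site common to all four photosynthetic taxa
  four <- sum(vapply(gr, function(g)
    all(c("Maen", "Egra", "Evir", "Egym") %in% g$members$species_tag),
    logical(1)))
  expect_equal(four, 1L)
})

test_that("sharing matrices are symmetric with totals on the diagonal", {
  set.seed(301)
  sites <- do.call(rbind, lapply(1:40, function(i)
    aligned_site(sample(c("gA", "gB", "gC"), 1), paste0("S", sample(1:5, 1)),
                 i, sample(1:8, 1) * 5L, sample(0:2, 1))))
  sites <- sites[!duplicated(paste(sites$gene, sites$column, sites$phase,
                                   sites$species_tag)), ]
  gr <- cluster_cognate_sites(sites)
  sp <- paste0("S", 1:5)
  sm <- sharing_matrix(gr, sp)
  expect_true(isSymmetric(sm$counts))
  for (s in sp) {
    tot <- sum(vapply(gr, function(g) s %in% g$members$species_tag, logical(1)))
    expect_equal(unname(sm$counts[s, s]), tot)
    expect_true(all(sm$counts[s, ] <= sm$counts[s, s]))
  }
})

test_that("a single species yields a 1x1 matrix of its total", {
  sites <- rbind(aligned_site("g", "Solo", 1, 5, 0),
                 aligned_site("g", "Solo", 2, 15, 1))
  gr <- cluster_cognate_sites(sites)
  sm <- sharing_matrix(gr, "Solo")
  expect_equal(unname(sm$counts[1, 1]), 2L)
})

test_that("adding a siteless taxon warns and changes no existing entries", {
  sites <- rbind(aligned_site("g", "A", 1, 5, 0),
                 aligned_site("g", "B", 1, 5, 0))
  gr <- cluster_cognate_sites(sites)
  sm1 <- sharing_matrix(gr, c("A", "B"))
  expect_warning(sm2 <- sharing_matrix(gr, c("A", "B", "Z")), "no sites")
  expect_equal(sm2$counts[c("A", "B"), c("A", "B")], sm1$counts)
  expect_true(all(sm2$counts["Z", ] == 0))
})

test_that("an ancestral four-taxon site maps to the photosynthetic ancestor", {
  tr <- euglenid_tree()
  st <- matrix(c("present", "present", "present", "present",
                 "inapplicable", "absent"),
               nrow = 1,
               dimnames = list("psbC_site",
                               c("Maen", "Egra", "Evir", "Egym",
                                 "Elon", "Ppar")))
  dm <- dollo_map(st, tr)
  expect_equal(dm$sites$gain_branch, "Egra,Egym,Elon,Evir,Maen")
  expect_equal(dm$sites$n_losses, 0L)     # Elon inapplicable costs nothing
})

test_that("inapplicable masking: gain above the MRCA of present taxa only", {
  tr <- euglenid_tree()
  st <- matrix(c("present", "present", "inapplicable", "absent", "absent",
                 "absent"),
               nrow = 1,
               dimnames = list("s", c("Egra", "Maen", "Elon", "Evir",
                                      "Egym", "Ppar")))
  dm <- dollo_map(st, tr)
  expect_equal(dm$sites$gain_branch, "Egra,Elon,Maen")
  expect_equal(dm$sites$n_losses, 0L)
})

test_that("losses are placed within the gained clade", {
  tr <- euglenid_tree()
  st <- matrix(c("present", "absent", "present", "absent", "absent",
                 "absent"),
               nrow = 1,
               dimnames = list("s", c("Egra", "Elon", "Maen", "Evir",
                                      "Egym", "Ppar")))
  dm <- dollo_map(st, tr)
  expect_equal(dm$sites$gain_branch, "Egra,Elon,Maen")
  expect_equal(dm$sites$n_losses, 1L)
  expect_equal(dm$sites$loss_branches, "Elon")
})

test_that("Dollo loss counts equal brute-force minima on random cases", {
  set.seed(302)
  for (i in 1:120) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    st <- random_state_row(tr)
    m <- matrix(st, nrow = 1, dimnames = list("s", names(st)))
    dm <- dollo_map(m, tr)
    or <- oracle_dollo(tr, st)
    expect_equal(dm$sites$n_losses, or$min_losses,
                 info = paste(ape::write.tree(tr), paste(st, collapse = ",")))
  }
})

test_that("invalid inputs are rejected", {
  tr <- euglenid_tree()
  st <- matrix("present", 1, 1, dimnames = list("s", "NotATip"))
  expect_error(dollo_map(st, tr), "not in tree")
  unrooted <- ape::unroot(ape::rtree(4))
  st2 <- matrix("present", 1, 4,
                dimnames = list("s", unrooted$tip.label))
  expect_error(dollo_map(st2, unrooted), "rooted")
})

test_that("states_from_groups marks presence and gene-loss masking", {
  sites <- rbind(aligned_site("psbC", "Maen", 1, 5, 0),
                 aligned_site("psbC", "Egra", 1, 5, 0))
  gr <- cluster_cognate_sites(sites)
  st <- states_from_groups(gr, c("Maen", "Egra", "Elon", "Evir"),
                           inapplicable = list(psbC = "Elon"))
  expect_equal(unname(st[1, ]),
               c("present", "present", "inapplicable", "absent"))
})

test_that("Fitch sensitivity scores are bounded by gains-plus-losses", {
  set.seed(303)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    st <- random_state_row(tr)
    m <- matrix(st, nrow = 1, dimnames = list("s", names(st)))
    dm <- dollo_map(m, tr)
    fs <- fitch_score(m, tr)
    # Dollo admits one gain + n_losses changes; Fitch is the unconstrained
    # minimum and can never exceed it
    expect_lte(fs, 1 + dm$sites$n_losses)
  }
})
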