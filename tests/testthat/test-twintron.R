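# A compact reference twintron for component tests: external with two
# internals at known positions.
make_ref <- function(seed = 201) {
  set.seed(seed)
  external <- generate_intron_sequence("group_II", 220)
  internals <- list(
    list(seq = generate_intron_sequence("group_III", 90), pos = 60),
    list(seq = generate_intron_sequence("group_III", 110), pos = 150))
  twintron_reference("testsite.1", external, internals)
}

test_that("full twintron reconstruction inserts internals at their offsets", {
  ref <- twintron_reference("x", "AAAACCCC",
                            list(list(seq = "GG", pos = 4)))
  expect_equal(full_twintron_seq(ref), "AAAAGGCCCC")
  ref2 <- twintron_reference("y", "AAAACCCC",
                             list(list(seq = "GG", pos = 4),
                                  list(seq = "TT", pos = 6)))
  expect_equal(full_twintron_seq(ref2), "AAAAGGCCTTCC")
})

test_that("reference validation rejects empty or out-of-span components", {
  expect_error(twintron_reference("z", ""), "empty external")
  expect_error(twintron_reference("z", "ACGT",
                                  list(list(seq = "", pos = 1))),
               "empty internal")
  expect_error(twintron_reference("z", "ACGT",
                                  list(list(seq = "GG", pos = 9))),
               "outside the external span")
})

test_that("a target identical to the full reference supports every component", {
  ref <- make_ref()
  set.seed(202)
  ev <- component_align(full_twintron_seq(ref), ref, n_shuffles = 20)
  expect_true(all(ev$components$coverage == 1))
  expect_true(all(ev$components$identity == 1))
  st <- classify_site(ev)
  expect_equal(st$status, "complete_twintron")
  expect_equal(st$supported_internals, c(1L, 2L))
})

test_that("a target equal to the bare external is external-only", {
  ref <- make_ref()
  set.seed(203)
  ev <- component_align(ref$external, ref, n_shuffles = 20)
  cmp <- ev$components
  expect_equal(cmp$identity[cmp$component == "external"], 1)
  ints <- cmp[grep("internal", cmp$component), ]
  expect_true(all(ints$z < 3))      # internals indistinguishable from noise
  st <- classify_site(ev, target = ref$external)
  expect_equal(st$status, "external_only")
})

test_that("retaining one of two internals gives a partial intermediate", {
  ref <- make_ref()
  set.seed(204)
  kept <- twintron_reference("t", euglintron:::mutate_seq(ref$external, 0.05),
                             list(list(seq = euglintron:::mutate_seq(
                               ref$internals[[2]]$seq, 0.05),
                               pos = ref$internals[[2]]$pos)))
  ev <- component_align(full_twintron_seq(kept), ref, n_shuffles = 20)
  st <- classify_site(ev)
  expect_equal(st$status, "partial_twintron")
  expect_equal(st$supported_internals, 2L)
})

test_that("deleting internals monotonically demotes the classification", {
  ref <- make_ref()
  set.seed(205)
  rank <- c(unrelated = 0, external_only = 1, partial_twintron = 2,
            complete_twintron = 3)
  full <- full_twintron_seq(ref)
  one <- full_twintron_seq(twintron_reference("t", ref$external,
                                              ref$internals[1]))
  none <- ref$external
  statuses <- vapply(list(full, one, none), function(tgt) {
    classify_site(component_align(tgt, ref, n_shuffles = 20))$status
  }, character(1))
  expect_equal(statuses[1], "complete_twintron")
  expect_true(rank[statuses[1]] >= rank[statuses[2]])
  expect_true(rank[statuses[2]] >= rank[statuses[3]])
})

test_that("a shuffled target is statistically indistinguishable from the null", {
  ref <- make_ref()
  set.seed(206)
  shuf <- paste(sample(strsplit(full_twintron_seq(ref), "")[[1]]),
                collapse = "")
  ev <- component_align(shuf, ref, n_shuffles = 30)
  expect_true(all(ev$components$z < 3))
  expect_equal(classify_site(ev)$status, "unrelated")
})

test_that("unexplained length surplus triggers a motif scan diagnostic", {
  ref <- make_ref()
  set.seed(207)
  # external plus a *different* intron inserted: internals unsupported but
  # the target is much longer than the external alone
  alien <- generate_intron_sequence("group_III", 140)
  tgt <- paste0(substr(ref$external, 1, 100), alien,
                substr(ref$external, 101, nchar(ref$external)))
  ev <- component_align(tgt, ref, n_shuffles = 20)
  st <- classify_site(ev, target = tgt)
  expect_equal(st$status, "external_only")
  expect_gt(st$surplus, 60)
  expect_false(is.null(st$surplus_scan))
})

test_that("splice-order decomposition is innermost-first", {
  g <- toy_twintron_genome()
  rec <- extract_introns(g)[[1]]
  plan <- decompose_nested(rec)
  expect_equal(nrow(plan), 3)
  expect_equal(plan$level, c(2L, 1L, 0L))
  expect_equal(plan$start[1], 55)   # deepest internal excised first
  # single-child case: 2 steps
  rec1 <- rec; rec1$children[[1]]$children <- list()
  expect_equal(nrow(decompose_nested(rec1)), 2)
})

test_that("overlapping (non-nested) internals are a structural error", {
  rec <- list(host_gene = "g", ordinal = 1, start = 0, end = 100,
              children = list(
                list(start = 10, end = 50, children = list()),
                list(start = 40, end = 80, children = list())))
  expect_error(decompose_nested(rec), "overlapping")
})

test_that("excising internals reconstitutes a fragmented intron-encoded ORF", {
  set.seed(208)
  # an external intron carrying an ORF split into two pieces by an internal
  orf_nt <- paste(c("ATG", replicate(20, {
    repeat { cd <- random_dna(3); if (!cd %in% c("TAA", "TAG", "TGA")) break }
    cd
  })), collapse = "")
  left <- substr(orf_nt, 1, 30)
  right <- substr(orf_nt, 31, nchar(orf_nt))
  internal <- generate_intron_sequence("group_III", 80)
  external <- paste0("GTTTG", left, internal, right, "ACGTAT")
  int_start <- 5 + 30
  spliced <- excise(external, rbind(c(int_start, int_start + 80)))
  expect_equal(spliced, paste0("GTTTG", orf_nt, "ACGTAT"))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf_nt)))
  expect_false(grepl("\\*", aa))    # contiguous ORF after excision
})

test_that("threshold validation rejects out-of-range support levels", {
  expect_error(twintron_thresholds(coverage = 1.2), "\\[0, 1\\]")
  expect_error(twintron_thresholds(identity = -0.1), "\\[0, 1\\]")
})
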