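# Discovery cascade: two species, subtraction bookkeeping, exclusive
# classification. A single planted pair of sets is shared across tests.
#
# Planting design mirrors the promoter architecture the detector was built
# for: a jittered canonical TATA-box in one promoter subset, a TC-element
# embedded in pyrimidine context (three TCT repeats) in a disjoint subset,
# and a downstream TC-microsatellite tract (the Y-patch) in a third.

cascade_set <- function(seed) sim_promoters(
  1000,
  plantings = list(
    planting("TATAAA", -32, 1, subset = 1:200, interval = c(-38, -27)),
    planting("TCTTCTTCT", -34, 1, subset = 201:350, interval = c(-39, -29))),
  tract = tc_tract(1, subset = 351:600, units = c("TC", "TTTC"),
                   n_units = c(10, 16), start = c(5, 60)),
  seed = seed)$set

set_a <- cascade_set(102)
set_b <- cascade_set(103)
cascade <- run_cascade(set_a, set_b)

test_that("the cascade recovers the planted TATA and TC classes", {
  expect_true(length(cascade$tatawa) == 1L)
  expect_true("TCTTCT" %in% cascade$tc_elements)
  # the TC-element is found only after TA-class subtraction: the records
  # come from the TA-less scan and sit in the target region
  rec <- cascade$records$a[["TCTTCT"]]
  expect_true(plm_in_region(rec))
  # dinucleotides with broad downstream microsatellite signal are not
  # accepted as positionally constrained PLMs
  expect_false(any(c("TC", "CT", "TT") %in% cascade$dinucleotides))
})

test_that("every accepted motif has in-region records in both species", {
  for (m in c(cascade$tatawa, unlist(cascade$tata_delta),
              cascade$dinucleotides, cascade$tc_elements)) {
    expect_true(plm_in_region(cascade$records$a[[m]]), label = paste(m, "a"))
    expect_true(plm_in_region(cascade$records$b[[m]]), label = paste(m, "b"))
  }
})

test_that("the subtraction ledger balances at every stage", {
  led <- cascade$ledger
  expect_true(all(led$before == led$after + led$removed))
  # successive stages chain: after of one stage == before of the next
  for (sp in unique(seq_len(nrow(led)) %% 2)) {
    rows <- led[seq_len(nrow(led)) %% 2 == sp, ]
    if (nrow(rows) > 1)
      expect_equal(rows$before[-1], rows$after[-nrow(rows)])
  }
  expect_equal(length(cascade$ta_less_ids$a),
               led$after[nrow(led) - 1])
})

test_that("ring acceptances are disjoint from earlier rings", {
  d1 <- cascade$tata_delta[["1"]]
  d2 <- cascade$tata_delta[["2"]]
  d3 <- cascade$tata_delta[["3"]]
  expect_length(intersect(d1, d2), 0)
  expect_length(intersect(c(d1, d2), d3), 0)
  expect_false(any(unlist(cascade$tata_delta) %in%
                     expand_pattern("TATAWA")))
})

test_that("a null input yields an empty cascade and full TA-less sets", {
  a0 <- sim_promoters(250, seed = 500)$set
  b0 <- sim_promoters(250, seed = 501)$set
  cas0 <- run_cascade(a0, b0)
  expect_length(cas0$tatawa, 0)
  expect_length(unlist(cas0$tata_delta), 0)
  expect_length(cas0$dinucleotides, 0)
  expect_length(cas0$tc_elements, 0)
  expect_equal(sort(cas0$ta_less_ids$a), sort(a0$ids))
})

test_that("swapping the species leaves the accepted motif sets unchanged", {
  swapped <- run_cascade(set_b, set_a)
  expect_setequal(swapped$tatawa, cascade$tatawa)
  for (d in 1:3)
    expect_setequal(swapped$tata_delta[[as.character(d)]],
                    cascade$tata_delta[[as.character(d)]])
  expect_setequal(swapped$dinucleotides, cascade$dinucleotides)
  expect_setequal(swapped$tc_elements, cascade$tc_elements)
})

test_that("exclusive classification partitions the promoter set", {
  cls <- classify_promoters(set_a, cascade)
  counts <- attr(cls, "counts")
  expect_equal(sum(counts), length(set_a))
  # planted TATA subset members without other classes are tata_only
  expect_true(any(cls$label == "tata_only"))
  expect_true(any(cls$label == "tc_only"))
  # multi-class promoters are in no "only" set
  multi <- cls$id[cls$label == "multi_class"]
  expect_false(any(multi %in% cls$id[cls$label %in%
    c("tata_only", "tatad_only", "tc_only")]))
  # labels agree with the flags
  expect_true(all(cls$tata[cls$label == "tata_only"]))
  expect_false(any(cls$tatad[cls$label == "tata_only"] |
                     cls$tc[cls$label == "tata_only"]))
  expect_false(any(cls$tata[cls$label == "plm_less"] |
                     cls$tatad[cls$label == "plm_less"] |
                     cls$tc[cls$label == "plm_less"]))
})

test_that("hand-built promoters classify as expected", {
  up <- 1000
  mk <- function(...) {
    s <- paste(sample(c("A", "C", "G", "T"), 1100, TRUE), collapse = "")
    for (pl in list(...)) {
      i <- pl$at + up + 1
      substr(s, i, i + nchar(pl$m) - 1) <- pl$m
    }
    s
  }
  set.seed(42)
  seqs <- c(mk(list(m = "TATAAA", at = -32)),                 # tata only
            mk(list(m = "TATAAA", at = -32),
               list(m = "TCTTCT", at = -39)),                 # both classes
            mk())                                             # nothing
  # scrub chance target-region hits of the classified motifs in the
  # background by regenerating until clean would be overkill; instead use
  # a cascade whose accepted sets we control directly
  fake <- cascade
  fake$tata_delta <- list(`1` = character(0), `2` = character(0),
                          `3` = character(0))
  fake$tc_elements <- "TCTTCT"
  tiny <- promoter_set(c("x1", "x2", "x3"), seqs, up)
  cls <- classify_promoters(tiny, fake)
  expect_equal(cls$label[2], "multi_class")
  expect_true(cls$tata[1])
})
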