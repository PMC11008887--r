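test_that("recode maps gaps to 0 and everything else to 1", {
  a <- msa(c("a", "b"), c("AC-", "A-G"))
  expect_identical(recode(a), rbind(c(1L, 1L, 0L), c(1L, 0L, 1L)))
  expect_true(all(recode(msa(c("a", "b"), c("ACG", "TTn"))) == 1L))
  expect_identical(recode(msa(c("a", "b"), c("A-C", "A-C")))[, 2L], c(0L, 0L))
})

test_that("all-gap columns are stripped without touching residues", {
  a <- msa(c("a", "b"), c("A-T", "A-T"))
  expect_identical(strip_all_gap_columns(a)$rows, c("AT", "AT"))
  b <- msa(c("a", "b"), c("A-T", "AG-"))
  expect_identical(strip_all_gap_columns(b)$rows, b$rows)
  expect_error(strip_all_gap_columns(msa(c("a", "b"), c("-", "-"))),
               "only of gap columns")
})

test_that("cutting sites match the hand-enumerated prefix-pace examples", {
  # identical masks cut after every column
  m <- rbind(c(1L, 0L, 1L), c(1L, 1L, 1L))
  cuts <- find_cutting_sites(m, m)
  expect_equal(unname(cuts[, "c1"]), 1:3)
  expect_equal(unname(cuts[, "c2"]), 1:3)

  # prefix paces share only the endpoint
  m1 <- rbind(c(1L, 1L, 0L), c(1L, 0L, 1L))
  m2 <- rbind(c(0L, 1L, 1L), c(1L, 1L, 0L))
  cuts <- find_cutting_sites(m1, m2)
  expect_equal(nrow(cuts), 1L)
  expect_equal(as.vector(cuts[1L, ]), c(3L, 3L))

  # paces coincide at (1,2)/(2,3) prefixes -> cuts (2,2) and (3,3)
  m3 <- rbind(c(1L, 0L, 1L), c(1L, 1L, 1L))
  m4 <- rbind(c(0L, 1L, 1L), c(1L, 1L, 1L))
  cuts <- find_cutting_sites(m3, m4)
  expect_equal(as.vector(cuts[, "c1"]), c(2L, 3L))
  expect_equal(as.vector(cuts[, "c2"]), c(2L, 3L))

  expect_error(find_cutting_sites(m1, rbind(c(1L, 1L, 1L), c(1L, 0L, 1L))),
               "unequal per-sequence residue totals")
})

test_that("two-pointer scan equals the brute-force prefix intersection on random masks", {
  set.seed(123)
  for (rep in 1:60) {
    m1 <- random_mask(sample(2:10, 1L), sample(5:60, 1L))
    m2 <- matched_mask(m1)
    cuts <- find_cutting_sites(m1, m2)
    oracle <- brute_cuts(m1, m2)
    expect_equal(unname(cuts[, "c1"]), unname(oracle[, "c1"]))
    expect_equal(unname(cuts[, "c2"]), unname(oracle[, "c2"]))
    # completeness: final cut is always the pair of full widths
    expect_equal(as.vector(cuts[nrow(cuts), ]), c(ncol(m1), ncol(m2)))
    # linear scan: each column of each mask is consumed exactly once
    expect_equal(attr(cuts, "advances"), ncol(m1) + ncol(m2))
    # cut order is invariant to which mask is scanned first
    swapped <- find_cutting_sites(m2, m1)
    expect_equal(unname(swapped[, "c1"]), unname(cuts[, "c2"]))
  }
})

test_that("blocks delimit identical fragments and reconstruct both inputs", {
  set.seed(9)
  r <- generate_reference(n_sequences = 6, length_range = c(40, 60), seed = 9)
  ens <- generate_ensemble(r, k = 2, seed = 10)
  a1 <- strip_all_gap_columns(ens[[1L]])
  a2 <- strip_all_gap_columns(ens[[2L]])
  cuts <- find_cutting_sites(recode(a1), recode(a2))
  blocks <- partition_blocks(a1, a2, cuts)
  expect_equal(nrow(blocks), nrow(cuts))

  for (b in seq_len(nrow(blocks))) {
    f1 <- degap(substr(a1$rows, blocks$start1[b] + 1L, blocks$end1[b]))
    f2 <- degap(substr(a2$rows, blocks$start2[b] + 1L, blocks$end2[b]))
    expect_identical(toupper(f1), toupper(f2))
    expect_equal(blocks$sp1[b], sp_score(a1, blocks$start1[b], blocks$end1[b]))
  }
  rebuilt1 <- vapply(a1$rows, function(row)
    paste(substr(rep(row, nrow(blocks)), blocks$start1 + 1L, blocks$end1),
          collapse = ""), character(1), USE.NAMES = FALSE)
  expect_identical(rebuilt1, a1$rows)
  rebuilt2 <- vapply(a2$rows, function(row)
    paste(substr(rep(row, nrow(blocks)), blocks$start2 + 1L, blocks$end2),
          collapse = ""), character(1), USE.NAMES = FALSE)
  expect_identical(rebuilt2, a2$rows)
})

test_that("identical alignments partition into width-1 blocks", {
  a <- strip_all_gap_columns(msa(c("x", "y"), c("AC-G", "A-TG")))
  cuts <- find_cutting_sites(recode(a), recode(a))
  blocks <- partition_blocks(a, a, cuts)
  expect_equal(nrow(blocks), a$width)
  expect_true(all(blocks$end1 - blocks$start1 == 1L))
  expect_equal(blocks$sp1, blocks$sp2)
})
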