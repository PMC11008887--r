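test_that("merging an alignment with itself returns it unchanged", {
  set.seed(5)
  for (rep in 1:5) {
    a <- strip_all_gap_columns(random_alignment(sample(3:6, 1L),
                                                sample(10:40, 1L)))
    res <- merge_pair(a, a)
    expect_identical(res$alignment$rows, a$rows)
    expect_true(all(res$report$tie))
    expect_true(all(res$report$winner == 1L))
  }
})

test_that("the better single block wins and ties keep the first operand", {
  a1 <- msa(c("s1", "s2"), c("AC-", "A-G"))  # SP -3
  a2 <- msa(c("s1", "s2"), c("-AC", "AG-"))  # SP -5
  res <- merge_pair(a1, a2)
  expect_identical(res$alignment$rows, a1$rows)
  expect_equal(nrow(res$report), 1L)
  expect_equal(res$report$winner, 1L)

  # two tying blocks: first operand's blocks are kept verbatim
  b1 <- msa(c("s1", "s2"), c("A-T", "AAT"))
  b2 <- msa(c("s1", "s2"), c("-AT", "AAT"))
  res2 <- merge_pair(b1, b2)
  expect_identical(res2$alignment$rows, b1$rows)
  expect_true(all(res2$report$tie))
  expect_equal(sp_score(res2$alignment), 0)
  expect_equal(sp_score(b1), sp_score(b2))
})

test_that("pairwise merge dominates both inputs and preserves consistency", {
  set.seed(21)
  for (rep in 1:20) {
    r <- generate_reference(n_sequences = sample(4:10, 1L),
                            length_range = c(30, 80),
                            seed = sample.int(1e6, 1L))
    ens <- generate_ensemble(r, k = 2, seed = sample.int(1e6, 1L))
    a1 <- ens[[1L]]; a2 <- ens[[2L]]
    res <- merge_pair(a1, a2)
    sp_out <- sp_score(res$alignment)
    expect_gte(sp_out, max(sp_score(a1), sp_score(a2)))
    expect_equal(sp_out, brute_sp(res$alignment))
    expect_true(isTRUE(check_consistency(res$alignment, r)))
    # per-block max recomposition
    expect_equal(sp_out, sum(pmax(res$report$sp1, res$report$sp2)))
    # objective is symmetric in the operands even if tie-broken rows differ
    expect_equal(sp_score(merge_pair(a2, a1)$alignment), sp_out)
  }
})

test_that("ensembles merge in descending SP order with m-1 steps", {
  set.seed(31)
  r <- generate_reference(n_sequences = 6, length_range = c(40, 60), seed = 31)
  ens <- generate_ensemble(r, k = 4, seed = 32)
  rep_v <- validate_ensemble(ens, r)
  out <- merge_ensemble(rep_v)
  expect_length(out$steps, length(ens) - 1L)
  expect_identical(out$order,
                   names(sort(out$input_sp, decreasing = TRUE)))
  expect_gte(out$sp, max(out$input_sp))
  expect_true(isTRUE(check_consistency(out$alignment, r)))
})

test_that("a single validated alignment is returned unmerged with a warning", {
  r <- seq_set(c("s1", "s2"), c("AC", "AG"))
  a <- msa(r$ids, c("AC-", "A-G"))
  rep_v <- validate_ensemble(list(a), r)
  expect_warning(out <- merge_ensemble(rep_v), "only one validated")
  expect_identical(out$alignment$rows, a$rows)
  expect_length(out$steps, 0L)
})

test_that("equal-SP inputs keep stable input order in the merge", {
  r <- seq_set(c("s1", "s2"), c("AC", "AG"))
  a <- msa(r$ids, c("A-C", "AG-"))
  b <- msa(r$ids, c("AC-", "A-G"))
  expect_equal(sp_score(a), sp_score(b))
  out <- merge_ensemble(validate_ensemble(list(a, b), r))
  expect_identical(out$order, c("aln1", "aln2"))
})
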