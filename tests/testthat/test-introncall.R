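# Candidate-intron enumeration against the brute-force oracle and the
# printed architectures.

test_that("the realized 320-nt CIS yields the 158-nt minimal candidate at offset 4", {
  r <- realize_cached("lipofer_D45")
  cands <- find_candidate_introns(r$seq)
  expect_gt(length(cands), 0)
  expect_identical(cands[[1]]$length, 158L)
  expect_identical(cands[[1]]$start, 4L)
  expect_identical(cands[[1]]$donor$sequence, "GUAAGU")
  expect_identical(cands[[1]]$branch$sequence, "ACUGAC")
})

test_that("sequences without a GU dinucleotide yield no candidates", {
  expect_identical(find_candidate_introns(strrep("A", 200)), list())
  expect_identical(find_candidate_introns("ACACACAC"), list())
})

test_that("a single canonical template yields exactly one candidate of the summed length", {
  tpl <- cis_template(
    "one43",
    list(tok_lit("GUAAGU"), tok_spacer(20), tok_lit("ACUAAC"),
         tok_spacer(8), tok_lit("UAG")),
    truth = list(cis_length = 43L, path_signatures = list(43L)))
  r <- realize_template(tpl, seed = 11)
  cands <- find_candidate_introns(r$seq)
  expect_length(cands, 1)
  expect_identical(cands[[1]]$length, 43L)
  # and the 46-nt canonical intron of the shortest printed gene
  r46 <- realize_template(canonical_intron_template(46, branch_gap = 8),
                          seed = 3)
  c46 <- brute_force_candidates(r46$seq)
  expect_length(c46, 1)
  expect_identical(c46[[1]]$length, 46L)
})

test_that("fast scan and brute-force oracle agree on templates and random sequences", {
  for (nm in names(TEMPLATES)) {
    r <- realize_cached(nm)
    expect_identical(candidate_signature(find_candidate_introns(r$seq)),
                     candidate_signature(brute_force_candidates(r$seq)),
                     info = nm)
  }
  set.seed(202)
  for (i in 1:12) {
    s <- random_rna(sample(80:350, 1))
    f <- find_candidate_introns(s)
    b <- brute_force_candidates(s)
    expect_identical(candidate_signature(f), candidate_signature(b),
                     info = paste("random case", i))
    # reported candidates begin GU and end AG
    for (cd in f) {
      expect_identical(substr(s, cd$start + 1, cd$start + 2), "GU")
      expect_identical(substr(s, cd$end - 1, cd$end), "AG")
    }
  }
})

test_that("tightening the length window never adds candidates", {
  set.seed(303)
  s <- random_rna(300)
  base <- candidate_signature(find_candidate_introns(s))
  tighter <- candidate_signature(find_candidate_introns(
    s, params = splicing_params(min_intron_len = 60, max_intron_len = 200)))
  expect_true(all(tighter %in% base))
  expect_lte(length(tighter), length(base))
})

test_that("region handling validates bounds and restricts the search", {
  r <- realize_cached("lipofer_D45")
  expect_error(find_candidate_introns(r$seq, c(-1, 10)), "region")
  expect_error(find_candidate_introns(r$seq, c(0, 999)), "region")
  expect_error(brute_force_candidates(strrep("A", 1200)), "1000")
  inner <- find_candidate_introns(r$seq, c(4, 162))
  expect_true(all(vapply(inner, function(cd) cd$start >= 4 && cd$end <= 162,
                         logical(1))))
  expect_identical(brute_force_candidates("ACGU", c(2, 2)), list())
})

test_that("branch attachment prefers the strongest hexamer, ties to the 3'-most", {
  # two strong branches in the window of one acceptor: 3'-most attached
  tpl <- cis_template(
    "twobranch",
    list(tok_lit("GUAAGU"), tok_spacer(14), tok_lit("ACUAAC"),
         tok_spacer(2), tok_lit("ACUAAC"), tok_spacer(8), tok_lit("UAG")),
    truth = list(cis_length = 45L, path_signatures = list(45L)))
  r <- realize_template(tpl, seed = 2, verify = FALSE)
  cands <- find_candidate_introns(r$seq)
  expect_length(cands, 1)
  expect_identical(cands[[1]]$branch$start, 28L)      # the 3'-most copy
  expect_length(cands[[1]]$alt_branches, 1)
  expect_identical(cands[[1]]$alt_branches[[1]]$start, 20L)
})
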