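# Ordered excision by intron definition, path enumeration, and the printed
# splicing schemes of the four nested architectures.

test_that("excise removes the interval and ligates the flanks", {
  s <- rna_seq("AAGUACGUCC")
  expect_identical(residues(excise(s, c(2, 8))), "AACC")
  expect_identical(residues(excise(s, c(0, 10))), "")
  expect_error(excise(s, c(3, 3)), "zero-length")
  expect_error(excise(s, c(5, 12)), "bounds")
})

test_that("internal excision reconstitutes the external donor (two-step scheme)", {
  r <- realize_cached("lipofer_D45")
  after <- excise(r$seq, c(4, 162))
  expect_identical(substr(residues(after), 1, 6), "GUGAGU")
  expect_identical(score_donor(substr(residues(after), 1, 6))$tier, "strong")
})

test_that("the four architectures resolve to their printed path signatures", {
  expect_identical(path_signature(resolve_cis(realize_cached("lipofer_D45"))),
                   "158+162")
  expect_identical(path_signature(resolve_cis(realize_cached("suomiensis_D78"))),
                   "61+79")
  expect_identical(path_signature(resolve_cis(realize_cached("japonicus_D78"))),
                   "162+124")
  expect_identical(path_signature(resolve_cis(realize_cached("starkeyi_D67"))),
                   c("120+132", "246"))
})

test_that("the internal intron uses the 3'-most of two donors one nt apart", {
  out <- resolve_cis(realize_cached("suomiensis_D78"))
  ev1 <- out$paths[[1]]$events[[1]]
  expect_identical(ev1$donor$primary_start, 7L)
  expect_identical(ev1$donor$sequence, "GUAGGU")
  # and the mature 5' splice site of the whole CIS is the 5'-most donor
  ev2 <- out$paths[[1]]$events[[2]]
  expect_identical(unname(ev2$primary_intervals[1, "start"]), 0L)
})

test_that("alternative splicing yields two mature products differing by 6 nt", {
  out <- resolve_cis(realize_cached("starkeyi_D67"))
  expect_length(out$paths, 2)
  expect_length(out$mature_products, 2)
  expect_identical(abs(diff(nchar(out$mature_products))), 6L)
  one_step <- Filter(function(p) p$mode == "single_step", out$paths)[[1]]
  expect_identical(one_step$leftover, 6L)
  # the retained residues are the 5'-most donor hexamer
  expect_identical(one_step$mature$residues,
                   substr(residues(realize_cached("starkeyi_D67")$seq), 1, 6))
})

test_that("length is conserved and intermediates chain by single excisions", {
  for (nm in names(TEMPLATES)) {
    for (seed in c(1, 5)) {
      r <- realize_cached(nm, seed)
      out <- resolve_cis(r)
      pre <- nchar(residues(r$seq))
      for (p in out$paths) {
        lens <- vapply(p$events, `[[`, integer(1), "excised_length")
        expect_identical(pre, nchar(p$mature$residues) + sum(lens) -
                           0L, info = nm)
        expect_identical(p$leftover, pre - sum(lens))
        # each intermediate is the previous molecule minus one intron
        prev <- residues(r$seq)
        for (i in seq_along(p$events)) {
          ev <- p$events[[i]]
          manual <- paste0(substr(prev, 1, ev$mol_start),
                           substr(prev, ev$mol_end + 1, nchar(prev)))
          expect_identical(p$intermediates[[i]], manual, info = nm)
          prev <- p$intermediates[[i]]
        }
        expect_identical(p$mature$residues,
                         p$intermediates[[length(p$intermediates)]])
      }
    }
  }
})

test_that("primary-transcript coordinates of successive events are disjoint", {
  out <- resolve_cis(realize_cached("starkeyi_D67"))
  for (p in out$paths) {
    covered <- integer(0)
    for (ev in p$events) {
      iv <- ev$primary_intervals
      pos <- unlist(lapply(seq_len(nrow(iv)),
                           function(i) seq.int(iv[i, 1], iv[i, 2] - 1L)))
      expect_length(intersect(covered, pos), 0)
      covered <- c(covered, pos)
    }
  }
})

test_that("resolution is deterministic and single-path when all elements are strong", {
  r <- realize_cached("lipofer_D45")
  a <- resolve_cis(r); b <- resolve_cis(r)
  expect_identical(splicing_report(a)$paths, splicing_report(b)$paths)
  # lipofer, suomiensis, japonicus have a unique resolution
  for (nm in c("lipofer_D45", "suomiensis_D78", "japonicus_D78")) {
    expect_length(resolve_cis(realize_cached(nm))$paths, 1)
  }
})

test_that("a region with no valid candidate yields an empty outcome", {
  out <- resolve_splicing(strrep("A", 120), c(0, 120))
  expect_length(out$paths, 0)
  expect_length(out$mature_products, 0)
  expect_error(resolve_splicing("ACGU", c(0, 9)), "bounds")
})

test_that("splicing context outside the region is preserved verbatim", {
  r <- realize_cached("japonicus_D78")
  pre <- paste0("AUGGCAUCU", residues(r$seq), "GCUUGGUAA")
  out <- resolve_splicing(pre, c(9, 9 + 286))
  expect_length(out$paths, 1)
  expect_identical(out$mature_products, "AUGGCAUCUGCUUGGUAA")
})

test_that("the splicing report carries event tables and retained nucleotides", {
  out <- resolve_cis(realize_cached("starkeyi_D67"))
  rep <- splicing_report(out)
  expect_identical(rep$n_paths, 2L)
  two <- Filter(function(p) p$mode == "two_step", rep$paths)[[1]]
  expect_identical(two$events$excised_length, c(120L, 132L))
  expect_identical(two$events$branch_tier, c("weak", "strong"))
  expect_identical(two$events$donor_tier, c("strong", "weak"))
  empty <- splicing_report(resolve_splicing(strrep("C", 60), c(0, 60)))
  expect_identical(empty$n_paths, 0L)
})
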