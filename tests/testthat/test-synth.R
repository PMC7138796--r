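# Template realization: token arithmetic, seed determinism, decoy-policy
# soundness and truth fidelity.

test_that("built-in template arithmetic matches the declared architecture", {
  expect_setequal(names(TEMPLATES),
                  c("lipofer_D45", "suomiensis_D78", "japonicus_D78",
                    "starkeyi_D67"))
  for (nm in names(TEMPLATES)) {
    t <- TEMPLATES[[nm]]
    expect_identical(t$total, t$truth$cis_length, info = nm)
    expect_identical(t$truth$internal_length + t$truth$external_length,
                     t$truth$cis_length, info = nm)
  }
  expect_error(
    cis_template("bad", list(tok_lit("GUAAGU"), tok_spacer(10)),
                 truth = list(cis_length = 99L, path_signatures = list())),
    "truth declares")
})

test_that("realization is seed-deterministic and length-preserving", {
  for (nm in names(TEMPLATES)) {
    a <- realize_template(TEMPLATES[[nm]], seed = 77)
    b <- realize_template(TEMPLATES[[nm]], seed = 77)
    c <- realize_template(TEMPLATES[[nm]], seed = 78)
    expect_identical(residues(a$seq), residues(b$seq), info = nm)
    expect_false(identical(residues(a$seq), residues(c$seq)))
    expect_identical(nchar(residues(a$seq)), TEMPLATES[[nm]]$truth$cis_length)
  }
})

test_that("a literal-only template realizes to its concatenation, seed-independent", {
  tpl <- cis_template(
    "lits",
    list(tok_lit("GUAAGU"), tok_lit("CCCC"), tok_lit("UAG")),
    truth = list(cis_length = 13L, path_signatures = list()))
  a <- realize_template(tpl, seed = 1, verify = FALSE)
  b <- realize_template(tpl, seed = 999, verify = FALSE)
  expect_identical(residues(a$seq), "GUAAGUCCCCUAG")
  expect_identical(residues(a$seq), residues(b$seq))
})

test_that("literal tokens survive realization untouched", {
  r <- realize_cached("starkeyi_D67")
  s <- residues(r$seq)
  expect_identical(substr(s, 1, 12), paste0("GUACGU", "GUAAGU"))
  expect_identical(substr(s, 88, 93), "AUUCAU")
  expect_identical(substr(s, 108, 113), "UUUAAU")
  expect_identical(substr(s, 124, 126), "CAG")
  expect_identical(substr(s, 237, 242), "GCUGAC")
  expect_identical(substr(s, 250, 252), "UAG")
})

test_that("realized spacers harbour no candidate intron beyond the intended parse", {
  # policy soundness: every element of every candidate lies in literal tokens
  for (nm in names(TEMPLATES)) {
    t <- TEMPLATES[[nm]]
    lens <- vapply(t$tokens, function(tok) {
      if (tok$type == "literal") nchar(tok$seq) else tok$len
    }, integer(1))
    literal <- unlist(lapply(seq_along(t$tokens), function(i) {
      rep(t$tokens[[i]]$type == "literal", lens[i])
    }))
    r <- realize_cached(nm, seed = 13)
    for (cd in find_candidate_introns(r$seq)) {
      expect_true(all(literal[(cd$start + 1):(cd$start + 6)]), info = nm)
      expect_true(all(literal[(cd$branch$start + 1):(cd$branch$start + 6)]),
                  info = nm)
      expect_true(all(literal[(cd$end - 2):cd$end]), info = nm)
    }
  }
})

test_that("truth fidelity holds across many seeds", {
  for (nm in names(TEMPLATES)) {
    t <- TEMPLATES[[nm]]
    for (seed in seq_len(25)) {
      r <- realize_template(t, seed = seed)
      out <- resolve_cis(r)
      sig <- path_signature(out)
      want <- sort(vapply(t$truth$path_signatures, paste, character(1),
                          collapse = "+"))
      expect_identical(sig, want, info = sprintf("%s seed %d", nm, seed))
      rel <- derive_relation(out)
      expect_identical(rel$k, t$truth$k, info = nm)
      expect_identical(classify_nesting(rel)$label, t$truth$class_label,
                       info = nm)
    }
  }
})

test_that("gene fixtures keep the reading frame and reproduce the truth path", {
  fx <- make_gene_fixture(TEMPLATES$japonicus_D78, exon5_len = 100,
                          exon3_len = 162, seed = 9)
  expect_identical(nchar(residues(fx$genome)), 100L + 286L + 162L)
  mrna <- residues(mature_mrna(fx$model, fx$genome))
  expect_identical(substr(mrna, 1, 3), "AUG")
  n_codons <- nchar(mrna) %/% 3L
  codons <- substring(mrna, 3 * (0:(n_codons - 1)) + 1, 3 * (1:n_codons))
  stops <- which(codons %in% c("UAA", "UAG", "UGA"))
  expect_identical(stops, n_codons)           # exactly one stop, terminal
  out <- resolve_splicing(fx$genome, fx$cis_region)
  expect_identical(path_signature(out), "162+124")
  expect_error(make_gene_fixture(TEMPLATES$lipofer_D45, 2, 2), "reading frame")
})

test_that("orthologue-set generation validates its occupancy spec", {
  expect_error(make_orthologue_set(matrix(1, 2, 2)), "logical")
  big <- matrix(TRUE, 10, 5,
                dimnames = list(paste0("s", 1:10), NULL))
  expect_error(make_orthologue_set(big), "9 species")
  noname <- matrix(TRUE, 2, 2)
  expect_error(make_orthologue_set(noname), "rownames")
})
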