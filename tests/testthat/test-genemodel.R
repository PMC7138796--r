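# Gene-model arithmetic: phases, mature mRNA assembly, and conservation
# mapping on the synthetic orthologue emulation.

toy_genome <- function(n, seed = 1) {
  set.seed(seed)
  rna_seq(random_rna(n), "toy")
}

test_that("intron phases follow cumulative coding length mod 3", {
  # first coding exon contributes 7 coding nt -> first intron phase 1
  m <- gene_model("g", rbind(c(0, 7), c(50, 70), c(100, 129)),
                  coding_start = 0, coding_end = 121)
  ph <- introns_of(m)
  expect_identical(ph$phase, c(1L, 0L))      # 7 mod 3; (7+20) mod 3
  expect_identical(ph$index, 1:2)
  # single-exon model has no introns
  single <- gene_model("s", rbind(c(0, 30)), 0, 30)
  expect_identical(nrow(introns_of(single)), 0L)
  # phases cycle: phase(i+1) = (phase(i) + exon length between) mod 3
  m2 <- gene_model("g2", rbind(c(0, 10), c(20, 33), c(40, 57), c(70, 78)),
                   coding_start = 0, coding_end = 78)
  ph2 <- introns_of(m2)$phase
  lens <- c(13L, 17L)
  for (i in 1:2) {
    expect_identical(ph2[i + 1], (ph2[i] + lens[i]) %% 3L)
  }
})

test_that("the fixture gene has a phase-1 first intron and a 165-nt second exon", {
  fx <- make_gene_fixture(TEMPLATES$lipofer_D45, exon5_len = 100,
                          exon3_len = 165, seed = 1)
  expect_identical(nchar(residues(fx$genome)), 100L + 320L + 165L)
  expect_identical(introns_of(fx$model)$phase, 1L)
  mrna <- mature_mrna(fx$model, fx$genome)
  expect_identical(nchar(residues(mrna)), 265L)
  expect_identical(unname(fx$model$exons[2, 2] - fx$model$exons[2, 1]), 165L)
  # the mature mRNA equals the splicing-engine product of the two-step path
  out <- resolve_splicing(fx$genome, fx$cis_region)
  expect_identical(out$mature_products, residues(mrna))
})

test_that("mature mRNA is additive and reverse-complemented on the minus strand", {
  g <- toy_genome(100)
  m <- gene_model("g", rbind(c(5, 15), c(40, 60)), coding_start = 5,
                  coding_end = 60, strand = "+")
  expect_identical(nchar(residues(mature_mrna(m, g))), 30L)
  minus <- gene_model("m", rbind(c(10, 40)), 10, 40, strand = "-")
  fwd <- substr(residues(g), 11, 40)
  expect_identical(residues(mature_mrna(minus, g)),
                   chartr("ACGU", "UGCA",
                          paste(rev(strsplit(fwd, "")[[1]]), collapse = "")))
  expect_error(mature_mrna(gene_model("x", rbind(c(0, 200)), 0, 198), g),
               "bounds")
})

test_that("gene models reject malformed exon chains and frames", {
  expect_error(gene_model("g", rbind(c(10, 5)), 0, 3), "exceed")
  expect_error(gene_model("g", rbind(c(0, 10), c(5, 20)), 0, 18),
               "non-overlapping")
  expect_error(gene_model("g", rbind(c(0, 10)), 0, 8), "divisible")
  expect_error(gene_model("g", rbind(c(0, 10)), 2, 14), "within exons")
})

test_that("conservation mapping reproduces the occupancy pattern of the emulation", {
  ortho <- make_orthologue_set(fig_occupancy_spec(), seed = 5)
  mat <- conserved_position_matrix(ortho$models, ortho$genomes,
                                   ortho$alignment)
  expect_identical(dim(mat), c(9L, 5L))
  expect_identical(sum(mat["oligophaga", ]), 1L)     # one lone intron
  expect_identical(unname(mat["suomiensis", 3:4]), c(FALSE, FALSE))
  expect_identical(sum(mat["doorenjongii", ]), 2L)
  expect_identical(unname(mat["doorenjongii", 1:2]), c(TRUE, TRUE))
  expect_true(all(mat["starkeyi", ]))
  # species order does not affect the column set or occupancy
  perm <- rev(seq_along(ortho$models))
  mat2 <- conserved_position_matrix(ortho$models[perm], ortho$genomes,
                                    ortho$alignment)
  expect_identical(mat2[rownames(mat), colnames(mat)], mat)
})

test_that("identical models collapse to a single fully-occupied column set", {
  spec <- matrix(TRUE, 3, 3,
                 dimnames = list(c("sp1", "sp2", "sp3"), NULL))
  ortho <- make_orthologue_set(spec, seed = 2)
  mat <- conserved_position_matrix(ortho$models, ortho$genomes,
                                   ortho$alignment)
  expect_identical(ncol(mat), 3L)
  expect_true(all(mat))
})

test_that("a CDS/alignment mismatch is rejected naming the species", {
  ortho <- make_orthologue_set(fig_occupancy_spec()[1:2, ], seed = 3)
  aln <- ortho$alignment
  aln[["mesembrius"]] <- paste0(substr(aln[["mesembrius"]], 2, 100), "A")
  expect_error(
    conserved_position_matrix(ortho$models, ortho$genomes, aln),
    "mesembrius")
})
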