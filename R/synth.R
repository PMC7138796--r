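# Seeded synthetic-sequence generation: templates of literal splice-element
# motifs separated by spacers, realized with decoy splice motifs excluded so
# that each realization has exactly the intended parse, plus gene fixtures
# and toy orthologue sets for conservation mapping.

#' Template tokens
#'
#' `tok_lit()` declares a literal run of residues (sacrosanct: never touched
#' by decoy resampling); `tok_spacer()` declares a run of `len` pseudo-random
#' residues to be filled at realization time.
#'
#' @param seq Literal residues (character).
#' @param len Spacer length in nt.
#' @return A token list for [cis_template()].
#' @export
tok_lit <- function(seq) {
  list(type = "literal", seq = residues(as_rna(seq, id = "literal")))
}

#' @rdname tok_lit
#' @export
tok_spacer <- function(len) {
  len <- as.integer(len)
  stopifnot(len >= 0L)
  list(type = "spacer", len = len)
}

token_len <- function(tok) {
  if (tok$type == "literal") nchar(tok$seq) else tok$len
}

#' Define a complex-intervening-sequence template
#'
#' A template is an ordered list of literal and spacer tokens together with
#' a truth annotation: the expected internal-intron placement, external
#' intron length, stwintron class label, and the expected path signature(s)
#' (ordered excision lengths per splicing path). Token arithmetic is checked
#' against the truth at construction.
#'
#' @param name Template name.
#' @param tokens List of [tok_lit()] / [tok_spacer()] tokens.
#' @param truth List with elements `cis_length`, `path_signatures` (list of
#'   integer vectors) and, for nested templates, `internal_start`,
#'   `internal_length`, `external_length`, `k`, `class_label`, `sensu`.
#' @return An object of class `cis_template`.
#' @export
cis_template <- function(name, tokens, truth) {
  total <- sum(vapply(tokens, token_len, integer(1)))
  if (!identical(as.integer(truth$cis_length), as.integer(total))) {
    stop("token lengths sum to ", total, " but truth declares ",
         truth$cis_length, call. = FALSE)
  }
  if (!is.null(truth$internal_length)) {
    if (truth$internal_start + truth$internal_length > total ||
        truth$internal_length + truth$external_length != total) {
      stop("truth intron lengths inconsistent with template total",
           call. = FALSE)
    }
  }
  for (sig in truth$path_signatures) {
    if (sum(sig) > total) {
      stop("path signature exceeds template total", call. = FALSE)
    }
  }
  structure(list(name = name, tokens = tokens, truth = truth,
                 total = as.integer(total)),
            class = "cis_template")
}

#' @export
print.cis_template <- function(x, ...) {
  toks <- vapply(x$tokens, function(t) {
    if (t$type == "literal") t$seq else sprintf("<%d>", t$len)
  }, character(1))
  cat(sprintf("<cis_template> %s (%d nt): %s\n", x$name, x$total,
              paste(toks, collapse = " ")))
  invisible(x)
}

#' Built-in nested-intron templates
#'
#' The four complex intervening sequence (CIS) architectures printed for the
#' reticulon-like gene of four *Lipomyces* species, given as literal splice
#' elements separated by spacers of the stated lengths:
#' \describe{
#'   \item{lipofer_D45}{320-nt CIS; 158-nt internal intron disrupting the
#'     donor of a 162-nt external intron after its 4th nt (sensu stricto).}
#'   \item{suomiensis_D78}{140-nt CIS; 61-nt internal intron one nt
#'     downstream of the external donor (k = 7, sensu lato); the internal
#'     donor GUAGGU is the 3'-most of two donor hexamers one nt apart.}
#'   \item{japonicus_D78}{286-nt CIS; 162-nt internal intron, 124-nt
#'     external intron, k = 7 (sensu lato).}
#'   \item{starkeyi_D67}{252-nt CIS with abutting donors (k = 6, sensu
#'     lato); the internal intron's only in-window branch element (UUUAAU)
#'     is weak, so the CIS splices alternatively: two-step 120 + 132 nt, or
#'     one standard 246-nt excision that leaves the 5'-most donor hexamer
#'     (GUACGU) in the mature product. Both printed internal branch
#'     candidates (AUUCAU and UUUAAU) are stored as literals.}
#' }
#'
#' @return Named list of four [cis_template()] objects.
#' @export
builtin_templates <- function() {
  list(
    lipofer_D45 = cis_template(
      "lipofer_D45",
      list(tok_lit("GUGA"),
           tok_lit("GUAAGU"), tok_spacer(131), tok_lit("ACUGAC"),
           tok_spacer(12), tok_lit("UAG"),
           tok_lit("GU"), tok_spacer(137), tok_lit("ACUAAC"),
           tok_spacer(10), tok_lit("UAG")),
      truth = list(cis_length = 320L, internal_start = 4L,
                   internal_length = 158L, external_length = 162L,
                   k = 4L, class_label = "[D4,5]", sensu = "stricto",
                   path_signatures = list(c(158L, 162L)))),
    suomiensis_D78 = cis_template(
      "suomiensis_D78",
      list(tok_lit("GUGAGUG"),
           tok_lit("GUAGGU"), tok_spacer(38), tok_lit("UCUAAC"),
           tok_spacer(8), tok_lit("UAG"),
           tok_lit("A"), tok_spacer(45), tok_lit("ACUGAC"),
           tok_spacer(17), tok_lit("UAG")),
      truth = list(cis_length = 140L, internal_start = 7L,
                   internal_length = 61L, external_length = 79L,
                   k = 7L, class_label = "[D7,8]", sensu = "lato",
                   path_signatures = list(c(61L, 79L)))),
    japonicus_D78 = cis_template(
      "japonicus_D78",
      list(tok_lit("GUAAGUG"),
           tok_lit("GUAAGU"), tok_spacer(135), tok_lit("ACUAAC"),
           tok_spacer(12), tok_lit("UAG"),
           tok_lit("A"), tok_spacer(97), tok_lit("AUUAAU"),
           tok_spacer(10), tok_lit("UAG")),
      truth = list(cis_length = 286L, internal_start = 7L,
                   internal_length = 162L, external_length = 124L,
                   k = 7L, class_label = "[D7,8]", sensu = "lato",
                   path_signatures = list(c(162L, 124L)))),
    starkeyi_D67 = cis_template(
      "starkeyi_D67",
      list(tok_lit("GUACGU"),
           tok_lit("GUAAGU"), tok_spacer(75), tok_lit("AUUCAU"),
           tok_spacer(14), tok_lit("UUUAAU"), tok_spacer(10), tok_lit("CAG"),
           tok_lit("A"), tok_spacer(109), tok_lit("GCUGAC"),
           tok_spacer(7), tok_lit("UAG")),
      truth = list(cis_length = 252L, internal_start = 6L,
                   internal_length = 120L, external_length = 132L,
                   k = 6L, class_label = "[D6,7]", sensu = "lato",
                   path_signatures = list(c(120L, 132L), 246L),
                   mature_difference = 6L))
  )
}

#' Template for a single canonical U2 intron
#'
#' Convenience constructor of a one-intron template (strong donor, strong
#' branch, UAG acceptor) of the requested total length; the 5' spacer
#' absorbs the slack. Used as the ancestral state of the evolution
#' simulator and as a base case for the splicing engine.
#'
#' @param length Total intron length in nt (minimum 24).
#' @param branch_gap Spacer between branch element end and acceptor start.
#' @return A [cis_template()].
#' @export
canonical_intron_template <- function(length = 140L, branch_gap = 10L) {
  length <- as.integer(length); branch_gap <- as.integer(branch_gap)
  sp5 <- length - 15L - branch_gap
  if (sp5 < 0L) stop("length too small for a canonical intron", call. = FALSE)
  cis_template(
    sprintf("canonical_%dnt", length),
    list(tok_lit("GUAAGU"), tok_spacer(sp5), tok_lit("ACUAAC"),
         tok_spacer(branch_gap), tok_lit("UAG")),
    truth = list(cis_length = length, path_signatures = list(length)))
}

#' Decoy-exclusion policy for spacer realization
#'
#' Constraints that guarantee a realized template contains no unintended
#' splice motifs: no spurious donor-like hexamer (GU-prefixed, with at most
#' `forbid_donor_like` mismatches against the donor consensus) overlapping a
#' spacer; no spurious acceptor trimer within the branch-to-acceptor window
#' downstream of any valid branch element; no spurious branch element
#' within the window upstream of an intended acceptor. Literal tokens are
#' sacrosanct and never repaired.
#'
#' @param forbid_donor_like Maximum donor mismatches for a forbidden
#'   spurious hexamer.
#' @param forbid_spurious_acceptor_context Enable the branch/acceptor
#'   coupling rules.
#' @param max_rejection_attempts Resampling budget.
#' @return An object of class `decoy_policy`.
#' @export
decoy_policy <- function(forbid_donor_like = 1L,
                         forbid_spurious_acceptor_context = TRUE,
                         max_rejection_attempts = 10000L) {
  structure(list(forbid_donor_like = as.integer(forbid_donor_like),
                 forbid_spurious_acceptor_context =
                   isTRUE(forbid_spurious_acceptor_context),
                 max_rejection_attempts = as.integer(max_rejection_attempts)),
            class = "decoy_policy")
}

# All decoy-policy violations of a realized character vector. `literal` is a
# logical mask; each violation is the integer positions (1-based) of the
# offending window. Only windows overlapping spacer positions are ever
# flagged: all-literal element matches are intended by construction.
policy_violations <- function(chars, literal, params, policy) {
  m <- params$motif_model
  n <- length(chars)
  viols <- list()
  add <- function(win) viols[[length(viols) + 1L]] <<- win

  if (n >= 6L) {
    mm36 <- window_mismatches(chars, substr(m$donor_pattern, 3L, 6L))
    i <- seq_len(n - 5L)
    donor_like <- chars[i] == "G" & chars[i + 1L] == "U" &
      mm36[i + 2L] <= policy$forbid_donor_like
    for (d in i[donor_like]) {
      win <- d:(d + 5L)
      if (any(!literal[win])) add(win)
    }
  }
  if (policy$forbid_spurious_acceptor_context && n >= 9L) {
    bp <- window_mismatches(chars, m$branch_pattern)
    bs <- window_mismatches(chars, m$branch_strict_pattern)
    bvalid <- which(bp <= m$branch_max_primary_mismatch &
                    (bp + bs) < m$branch_invalid_cutoff)
    am <- window_mismatches(chars, m$acceptor_pattern)
    avalid <- which(am == 0L)
    a_literal <- vapply(avalid, function(a) all(literal[a:(a + 2L)]),
                        logical(1))
    for (ai in seq_along(avalid)) {
      a <- avalid[ai]
      jlo <- a - 6L - params$branch_to_acceptor_max
      jhi <- a - 6L - params$branch_to_acceptor_min
      paired <- bvalid[bvalid >= max(1L, jlo) & bvalid <= jhi]
      if (!length(paired)) next
      if (!a_literal[ai]) {
        # spurious acceptor coupled to some branch: resample the acceptor
        add(a:(a + 2L))
      } else {
        # intended acceptor: spurious branches in its window are forbidden
        for (j in paired) {
          win <- j:(j + 5L)
          if (any(!literal[win])) add(win)
        }
      }
    }
  }
  viols
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Realize a template into a concrete sequence
#'
#' Fills the template's spacers with seeded pseudo-random residues and
#' iteratively resamples any spacer positions that participate in a decoy
#' policy violation until the realized sequence is clean. A final
#' verification pass runs the splicing engine and checks the path
#' signature(s) against the template truth; verification failure triggers a
#' full respin. Identical (template, seed, policy) always yield identical
#' sequences.
#'
#' @param template A [cis_template()].
#' @param seed Integer seed.
#' @param policy A [decoy_policy()].
#' @param params A [splicing_params()] (the caller's view used for
#'   verification).
#' @param verify Run the splicing-engine verification pass (default TRUE).
#' @return An object of class `realized_cis`: list with `seq` (an
#'   `rna_seq`), `template`, `truth`, `seed`.
#' @export
realize_template <- function(template, seed = 1L, policy = decoy_policy(),
                             params = splicing_params(), verify = TRUE) {
  stopifnot(inherits(template, "cis_template"))
  lens <- vapply(template$tokens, token_len, integer(1))
  n <- sum(lens)
  literal <- logical(n)
  chars <- character(n)
  off <- 0L
  spacer_ids <- integer(n)                 # which spacer token owns a position
  for (ti in seq_along(template$tokens)) {
    tok <- template$tokens[[ti]]
    idx <- if (lens[ti] > 0L) (off + 1L):(off + lens[ti]) else integer(0)
    if (tok$type == "literal") {
      literal[idx] <- TRUE
      chars[idx] <- strsplit(tok$seq, "", fixed = TRUE)[[1]]
    } else {
      spacer_ids[idx] <- ti
    }
    off <- off + lens[ti]
  }
  spacer_pos <- which(!literal)
  alphabet <- c("A", "C", "G", "U")

  result <- with_seed(as.integer(seed), {
    done <- FALSE
    for (respin in 1:20) {
      chars[spacer_pos] <- sample(alphabet, length(spacer_pos),
                                  replace = TRUE)
      attempts <- 0L
      repeat {
        viols <- policy_violations(chars, literal, params, policy)
        if (!length(viols)) break
        attempts <- attempts + 1L
        if (attempts > policy$max_rejection_attempts) {
          bad <- unique(spacer_ids[setdiff(unlist(viols), which(literal))])
          stop("decoy resampling budget exhausted at spacer token(s) ",
               paste(bad, collapse = ", "), " of template ", template$name,
               call. = FALSE)
        }
        resample <- setdiff(unlist(viols), which(literal))
        if (!length(resample)) {
          stop("decoy policy violated within literal tokens of template ",
               template$name, call. = FALSE)
        }
        chars[resample] <- sample(alphabet, length(resample), replace = TRUE)
      }
      seq <- paste(chars, collapse = "")
      if (!verify) { done <- TRUE; break }
      out <- resolve_splicing(seq, c(0L, n), params = params)
      sig <- lapply(out$paths, function(p) {
        as.integer(vapply(p$events, `[[`, integer(1), "excised_length"))
      })
      want <- lapply(template$truth$path_signatures, as.integer)
      canon <- function(x) sort(vapply(x, paste, character(1), collapse = "+"))
      if (identical(canon(sig), canon(want))) { done <- TRUE; break }
    }
    if (!done) {
      stop("could not realize template ", template$name,
           " to match its truth annotation", call. = FALSE)
    }
    paste(chars, collapse = "")
  })

  structure(list(
    seq = structure(list(id = sprintf("%s_seed%d", template$name,
                                      as.integer(seed)),
                         residues = result), class = "rna_seq"),
    template = template, truth = template$truth, seed = as.integer(seed)),
    class = "realized_cis")
}

#' @export
print.realized_cis <- function(x, ...) {
  cat(sprintf("<realized_cis> %s: %d nt (seed %d)\n", x$template$name,
              nchar(x$seq$residues), x$seed))
  invisible(x)
}

# Codons free of stop triplets, used when writing synthetic coding exons.
non_stop_codons <- function() {
  codons <- apply(expand.grid(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                              c("A", "C", "G", "U")), 1L, paste, collapse = "")
  setdiff(codons, c("UAA", "UAG", "UGA"))
}

#' Embed a realized template in a synthetic two-exon gene
#'
#' Builds a pre-mRNA of `exon5_len` coding-exon nt, the realized CIS, and
#' `exon3_len` second-exon nt, with an intact reading frame across the
#' predicted mature junction: the ORF starts at position 0 with AUG, carries
#' no premature stop, and terminates at the last complete codon of the
#' mature mRNA. The truth annotation is returned as a feature table (see
#' [write_gff3()]) with nested intron features.
#'
#' @param template A [cis_template()].
#' @param exon5_len,exon3_len Exon lengths in nt (each at least 3, summing
#'   to at least 6).
#' @param seed Integer seed (drives both spacer fill and exon content).
#' @param policy,params Passed to [realize_template()].
#' @return List with `genome` (an `rna_seq`), `model` (a [gene_model()]),
#'   `features` (truth data frame), `realized`, `cis_region` (`c(start,
#'   end)` of the CIS in the genome).
#' @export
make_gene_fixture <- function(template, exon5_len = 100L, exon3_len = 165L,
                              seed = 1L, policy = decoy_policy(),
                              params = splicing_params()) {
  exon5_len <- as.integer(exon5_len); exon3_len <- as.integer(exon3_len)
  if (exon5_len < 3L || exon3_len < 3L || exon5_len + exon3_len < 6L) {
    stop("exon lengths too small to carry an open reading frame",
         call. = FALSE)
  }
  realized <- realize_template(template, seed = seed, policy = policy,
                               params = params)
  mature_len <- exon5_len + exon3_len
  n_codons <- mature_len %/% 3L
  mature <- with_seed(as.integer(seed) + 10007L, {
    body <- sample(non_stop_codons(), n_codons - 2L, replace = TRUE)
    utr <- sample(c("A", "C", "G", "U"), mature_len %% 3L, replace = TRUE)
    paste0("AUG", paste(body, collapse = ""), "UAA",
           paste(utr, collapse = ""))
  })
  exon5 <- substr(mature, 1L, exon5_len)
  exon3 <- substr(mature, exon5_len + 1L, mature_len)
  cis <- realized$seq$residues
  cis_len <- nchar(cis)
  genome <- paste0(exon5, cis, exon3)
  total <- nchar(genome)
  coding_end_mature <- 3L * n_codons
  coding_end <- if (coding_end_mature <= exon5_len) coding_end_mature
                else exon5_len + cis_len + (coding_end_mature - exon5_len)
  model <- gene_model(
    gene_id = template$name,
    exons = rbind(c(0L, exon5_len), c(exon5_len + cis_len, total)),
    coding_start = 0L, coding_end = coding_end,
    strand = "+", species = template$name)

  seqid <- sprintf("%s_fixture", template$name)
  tr <- template$truth
  feats <- data.frame(
    seqid = seqid,
    type = c("gene", "mRNA", "exon", "exon", "intron"),
    start = c(0L, 0L, 0L, exon5_len + cis_len, exon5_len),
    end = c(total, total, exon5_len, total, exon5_len + cis_len),
    strand = "+",
    ID = c("gene1", "mRNA1", "exon1", "exon2", "cis1"),
    Parent = c(NA, "gene1", "mRNA1", "mRNA1", "mRNA1"),
    stwintron_class = NA_character_,
    nesting = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(tr$internal_length)) {
    i_start <- exon5_len + tr$internal_start
    i_end <- i_start + tr$internal_length
    nested <- data.frame(
      seqid = seqid,
      type = "intron",
      start = c(i_start, exon5_len, i_end),
      end = c(i_end, i_start, exon5_len + cis_len),
      strand = "+",
      ID = c("cis1_internal", "cis1_external", "cis1_external"),
      Parent = "cis1",
      stwintron_class = tr$class_label,
      nesting = c("internal", "external", "external"),
      stringsAsFactors = FALSE)
    feats$stwintron_class[feats$ID == "cis1"] <- tr$class_label
    feats <- rbind(feats, nested)
  }
  list(genome = structure(list(id = seqid, residues = genome),
                          class = "rna_seq"),
       model = model, features = feats, realized = realized,
       cis_region = c(exon5_len, exon5_len + cis_len))
}

#' Occupancy pattern of the nine-species orthologue emulation
#'
#' The per-species presence/absence of introns at the five conserved
#' positions of the reticulon-like gene family emulation: five species carry
#' all five introns, one lacks the most 3' position, one lacks positions 3
#' and 4, one carries only the first two, and one harbours a single intron
#' at the most 5' position.
#'
#' @return A 9 x 5 logical matrix with species rownames.
#' @export
fig_occupancy_spec <- function() {
  species <- c("starkeyi", "mesembrius", "arxii", "kononenkoae", "lipofer",
               "japonicus", "suomiensis", "doorenjongii", "oligophaga")
  mat <- matrix(FALSE, 9L, 5L,
                dimnames = list(species, paste0("pos", 1:5)))
  mat[c("starkeyi", "mesembrius", "arxii", "kononenkoae", "lipofer"), ] <- TRUE
  mat["japonicus", 1:4] <- TRUE
  mat["suomiensis", c(1L, 2L, 5L)] <- TRUE
  mat["doorenjongii", 1:2] <- TRUE
  mat["oligophaga", 1L] <- TRUE
  mat
}

#' Generate a toy orthologue set with prescribed intron occupancy
#'
#' Builds consistent single-gene models for up to 9 species over up to 5
#' conserved intron positions: all species share one coding sequence (and
#' hence one protein, so the "alignment" is trivially consistent), and each
#' species carries a canonical intron at exactly the prescribed positions.
#' [conserved_position_matrix()] on the result reproduces the occupancy
#' spec.
#'
#' @param spec Logical matrix (species x positions), e.g.
#'   [fig_occupancy_spec()].
#' @param seed Integer seed.
#' @param peptide_len Length of the shared peptide (default 60 aa).
#' @return List with `models`, `genomes` (named lists by species),
#'   `alignment` (named character), and `spec`.
#' @export
make_orthologue_set <- function(spec, seed = 1L, peptide_len = 60L) {
  spec <- as.matrix(spec)
  if (!is.logical(spec)) stop("occupancy spec must be logical", call. = FALSE)
  if (nrow(spec) > 9L || ncol(spec) > 5L) {
    stop("occupancy spec limited to 9 species x 5 positions", call. = FALSE)
  }
  if (is.null(rownames(spec)) || anyDuplicated(rownames(spec))) {
    stop("occupancy spec needs unique species rownames", call. = FALSE)
  }
  peptide_len <- as.integer(peptide_len)
  n_pos <- ncol(spec)
  # insertion points: codon index (0-based) and phase per conserved position;
  # the first position is phase 1, echoing the gene family emulated
  codon_idx <- as.integer(round(seq(8L, peptide_len - 12L,
                                    length.out = max(n_pos, 1L))))
  phases <- rep_len(c(1L, 0L, 2L, 1L, 0L), n_pos)
  coding_offsets <- 3L * codon_idx + phases

  built <- with_seed(as.integer(seed), {
    body <- sample(non_stop_codons(), peptide_len - 1L, replace = TRUE)
    cds <- paste0("AUG", paste(body, collapse = ""), "UAA")
    intron <- realize_template(canonical_intron_template(46L, branch_gap = 8L),
                               seed = sample.int(2147483647L, 1L))
    list(cds = cds, intron = intron$seq$residues)
  })
  cds <- built$cds
  cds_len <- nchar(cds)
  ilen <- nchar(built$intron)

  models <- list(); genomes <- list(); alignment <- character(0)
  protein <- sub("\\*$", "", translate_rna(cds))
  for (sp in rownames(spec)) {
    occupied <- coding_offsets[spec[sp, ]]
    occupied <- sort(occupied)
    pieces <- character(0)
    prev <- 0L
    exons <- NULL
    goff <- 0L
    for (co in occupied) {
      pieces <- c(pieces, substr(cds, prev + 1L, co), built$intron)
      exons <- rbind(exons, c(goff, goff + (co - prev)))
      goff <- goff + (co - prev) + ilen
      prev <- co
    }
    pieces <- c(pieces, substr(cds, prev + 1L, cds_len))
    exons <- rbind(exons, c(goff, goff + (cds_len - prev)))
    genome <- paste(pieces, collapse = "")
    models[[sp]] <- gene_model(
      gene_id = paste0("rtn_", sp), exons = exons,
      coding_start = 0L, coding_end = nchar(genome),
      strand = "+", species = sp)
    genomes[[sp]] <- structure(list(id = sp, residues = genome),
                               class = "rna_seq")
    alignment[[sp]] <- protein
  }
  list(models = models, genomes = genomes, alignment = alignment, spec = spec)
}
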