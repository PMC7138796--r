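# Gene-model arithmetic: exon chains, intron phases, mature mRNA assembly
# and intron-position conservation against a protein alignment.

#' Construct a gene model
#'
#' Exons are 0-based half-open genomic intervals, sorted and
#' non-overlapping. The coding interval must start and end inside exons and
#' span a coding length divisible by 3 (a complete ORF including the stop
#' codon).
#'
#' @param gene_id Gene identifier.
#' @param exons Two-column matrix or data frame of exon `start`,`end`
#'   (0-based half-open, genomic).
#' @param coding_start,coding_end Genomic offsets (0-based half-open) of the
#'   ORF within the exon chain.
#' @param strand `"+"` or `"-"`.
#' @param species Species tag (defaults to `gene_id`).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, exons, coding_start, coding_end,
                       strand = c("+", "-"), species = gene_id) {
  strand <- match.arg(strand)
  ex <- as.matrix(exons)
  if (ncol(ex) != 2L) stop("exons must have two columns (start, end)",
                           call. = FALSE)
  storage.mode(ex) <- "integer"
  colnames(ex) <- c("start", "end")
  if (any(ex[, 2L] <= ex[, 1L])) stop("exon end must exceed exon start",
                                      call. = FALSE)
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, 1L], strictly = TRUE) ||
        any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
      stop("exons must be sorted and non-overlapping", call. = FALSE)
    }
  }
  cs <- as.integer(coding_start); ce <- as.integer(coding_end)
  if (is.na(cs) || is.na(ce) || cs >= ce) {
    stop("invalid coding interval", call. = FALSE)
  }
  in_exon <- function(pos) any(pos >= ex[, 1L] & pos < ex[, 2L])
  if (!in_exon(cs) || !in_exon(ce - 1L)) {
    stop("coding interval must start and end within exons", call. = FALSE)
  }
  clen <- sum(pmax(0L, pmin(ex[, 2L], ce) - pmax(ex[, 1L], cs)))
  if (clen %% 3L != 0L) {
    stop("total CDS length must be divisible by 3 (got ", clen, ")",
         call. = FALSE)
  }
  structure(list(gene_id = gene_id, exons = ex,
                 coding_start = cs, coding_end = ce,
                 strand = strand, species = species, cds_length = clen),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s strand): %d exon(s), CDS %d nt\n",
              x$gene_id, x$species, x$strand, nrow(x$exons), x$cds_length))
  invisible(x)
}

# Genomic positions of the transcript in transcription order.
transcript_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    seq.int(model$exons[i, 1L], model$exons[i, 2L] - 1L)
  }))
  if (model$strand == "-") rev(pos) else pos
}

#' Intron annotations of a gene model
#'
#' One annotation per inter-exon gap, numbered in transcription order, with
#' the phase computed as (coding nucleotides upstream of the intron) mod 3.
#' Introns located outside the coding region get phase `NA`.
#'
#' @param model A [gene_model()].
#' @return Data frame with columns `index`, `start`, `end` (genomic, 0-based
#'   half-open) and `phase`; zero rows for single-exon models.
#' @export
introns_of <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  k <- nrow(ex)
  if (k < 2L) {
    return(data.frame(index = integer(0), start = integer(0),
                      end = integer(0), phase = integer(0)))
  }
  gaps <- cbind(start = ex[-k, 2L], end = ex[-1L, 1L])
  ord <- if (model$strand == "-") rev(seq_len(k - 1L)) else seq_len(k - 1L)
  coding_overlap <- function(a, b) {
    max(0L, min(b, model$coding_end) - max(a, model$coding_start))
  }
  res <- lapply(seq_along(ord), function(i) {
    g <- ord[i]
    if (model$strand == "+") {
      upstream <- sum(vapply(seq_len(g), function(j) {
        coding_overlap(ex[j, 1L], ex[j, 2L])
      }, integer(1)))
    } else {
      upstream <- sum(vapply((g + 1L):k, function(j) {
        coding_overlap(ex[j, 1L], ex[j, 2L])
      }, integer(1)))
    }
    phase <- if (upstream == 0L || upstream >= model$cds_length) {
      NA_integer_
    } else {
      upstream %% 3L
    }
    data.frame(index = i, start = gaps[g, 1L], end = gaps[g, 2L],
               phase = phase)
  })
  do.call(rbind, res)
}

#' Assemble the mature mRNA of a gene model
#'
#' Concatenates the exon residues in transcription order
#' (reverse-complemented for the minus strand).
#'
#' @param model A [gene_model()].
#' @param genome An `rna_seq` or character scalar covering the exon
#'   intervals.
#' @return An `rna_seq` whose length is the sum of exon lengths.
#' @export
mature_mrna <- function(model, genome) {
  g <- as_rna(genome)
  n <- nchar(g$residues)
  if (any(model$exons[, 2L] > n)) {
    stop("exon interval out of genome bounds", call. = FALSE)
  }
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    substr(g$residues, model$exons[i, 1L] + 1L, model$exons[i, 2L])
  }, character(1))
  out <- if (model$strand == "-") {
    paste(vapply(rev(pieces), revcomp_rna, character(1)), collapse = "")
  } else {
    paste(pieces, collapse = "")
  }
  structure(list(id = paste0(model$gene_id, "_mRNA"), residues = out),
            class = "rna_seq")
}

# Coding sequence (transcription order) of a model on its genome.
cds_of <- function(model, genome) {
  g <- as_rna(genome)
  chars <- strsplit(g$residues, "", fixed = TRUE)[[1]]
  pos <- transcript_positions(model)
  keep <- pos >= model$coding_start & pos < model$coding_end
  sel <- chars[pos[keep] + 1L]
  if (model$strand == "-") sel <- chartr("ACGU", "UGCA", sel)
  paste(sel, collapse = "")
}

translate_rna <- function(cds) {
  dna <- Biostrings::DNAString(chartr("U", "T", cds))
  as.character(Biostrings::translate(dna, no.init.codon = TRUE))
}

#' Intron-position conservation matrix across orthologues
#'
#' Maps every coding intron of every model to the protein-alignment column
#' of the codon containing its insertion point, together with its phase.
#' Introns of different species sharing (column, phase) collapse to one
#' conserved position; the matrix reports per-species occupancy. Each
#' model's translated CDS (terminal stop removed) must equal its alignment
#' row with gaps removed.
#'
#' @param models List of [gene_model()] objects.
#' @param genomes Named list (by species) or parallel list of genome
#'   sequences (`rna_seq` or character).
#' @param protein_alignment Named character vector of aligned protein rows
#'   (equal lengths; names matching the models' `species`).
#' @return Logical matrix, species x conserved positions; position names are
#'   `"col<column>_ph<phase>"`, ordered by column then phase.
#' @export
conserved_position_matrix <- function(models, genomes, protein_alignment) {
  stopifnot(length(models) >= 1L)
  if (length(unique(nchar(protein_alignment))) != 1L) {
    stop("alignment rows must have equal length", call. = FALSE)
  }
  keys_by_species <- list()
  for (model in models) {
    sp <- model$species
    genome <- if (!is.null(names(genomes))) genomes[[sp]]
              else genomes[[match(sp, vapply(models, `[[`, "", "species"))]]
    if (is.null(genome)) stop("no genome supplied for species ", sp,
                              call. = FALSE)
    if (!sp %in% names(protein_alignment)) {
      stop("no alignment row for species ", sp, call. = FALSE)
    }
    row <- protein_alignment[[sp]]
    aa <- translate_rna(cds_of(model, genome))
    aa <- sub("\\*$", "", aa)
    degap <- gsub("-", "", row, fixed = TRUE)
    if (!identical(aa, degap)) {
      stop("translated CDS does not match alignment row for species ", sp,
           call. = FALSE)
    }
    aln_chars <- strsplit(row, "", fixed = TRUE)[[1]]
    col_of_res <- which(aln_chars != "-")
    intr <- introns_of(model)
    keys <- character(0)
    if (nrow(intr)) {
      # recompute upstream coding length per intron to place the codon
      ex <- model$exons; k <- nrow(ex)
      ord <- if (model$strand == "-") rev(seq_len(k - 1L)) else seq_len(k - 1L)
      for (i in seq_len(nrow(intr))) {
        if (is.na(intr$phase[i])) next
        g <- ord[i]
        co <- function(a, b) max(0L, min(b, model$coding_end) -
                                   max(a, model$coding_start))
        upstream <- if (model$strand == "+") {
          sum(vapply(seq_len(g), function(j) co(ex[j, 1L], ex[j, 2L]),
                     integer(1)))
        } else {
          sum(vapply((g + 1L):k, function(j) co(ex[j, 1L], ex[j, 2L]),
                     integer(1)))
        }
        res_idx <- upstream %/% 3L + 1L          # residue holding the codon
        if (res_idx > length(col_of_res)) next   # insertion at the stop codon
        keys <- c(keys, sprintf("col%04d_ph%d", col_of_res[res_idx],
                                upstream %% 3L))
      }
    }
    keys_by_species[[sp]] <- keys
  }
  all_keys <- sort(unique(unlist(keys_by_species)))
  species <- names(keys_by_species)
  mat <- matrix(FALSE, nrow = length(species), ncol = length(all_keys),
                dimnames = list(species, all_keys))
  for (sp in species) mat[sp, keys_by_species[[sp]]] <- TRUE
  mat
}
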