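# Standard-format I/O. FASTA goes through Biostrings; GFF3 through
# rtracklayer/GenomicRanges. Sequences are RNA internally and written back
# as DNA (U -> T) to match FASTA/GFF convention; coordinates are 0-based
# half-open internally and 1-based inclusive on disk.

#' Read sequences from a FASTA file
#'
#' Nucleotide records are normalized to the internal RNA alphabet (DNA
#' accepted, T transcribed to U); protein records are returned as plain
#' named character strings.
#'
#' @param path FASTA file path.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return For nucleotide input, a list of `rna_seq`; for protein input, a
#'   named character vector. Empty file yields an empty result.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("cannot open FASTA file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    return(if (alphabet == "nucleotide") list() else character(0))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  strings <- as.character(set)
  if (alphabet == "protein") {
    names(strings) <- ids
    return(strings)
  }
  out <- lapply(seq_along(strings), function(i) rna_seq(strings[[i]], ids[i]))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' Nucleotide sequences are written in the DNA alphabet (U mapped back to
#' T).
#'
#' @param seqs A list of `rna_seq` (or character scalars), or a named
#'   character vector of proteins.
#' @param path Output path.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "protein") {
    set <- Biostrings::BStringSet(seqs)
  } else {
    if (inherits(seqs, "rna_seq")) seqs <- list(seqs)
    ids <- vapply(seq_along(seqs), function(i) {
      if (inherits(seqs[[i]], "rna_seq")) seqs[[i]]$id
      else if (!is.null(names(seqs))) names(seqs)[i]
      else paste0("seq", i)
    }, character(1))
    dna <- vapply(seqs, function(s) chartr("U", "T", residues(s)),
                  character(1))
    set <- Biostrings::DNAStringSet(dna)
    names(set) <- ids
  }
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

gff_extra_cols <- function(features) {
  setdiff(colnames(features),
          c("seqid", "source", "type", "start", "end", "score", "strand",
            "phase", "ID", "Parent"))
}

#' Write features to a GFF3 file
#'
#' `features` is a data frame with columns `seqid`, `type`, `start`, `end`
#' (0-based half-open), `strand`, `ID`, optionally `Parent` and arbitrary
#' extra attribute columns (e.g. `stwintron_class`, `nesting`). Coordinates
#' are converted to the 1-based inclusive GFF3 convention on disk. Nested
#' intron features (a non-NA `nesting` attribute) without a `Parent` raise
#' a validation warning.
#'
#' @param features Feature data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(is.data.frame(features))
  need <- c("seqid", "type", "start", "end", "ID")
  missing_cols <- setdiff(need, colnames(features))
  if (length(missing_cols)) {
    stop("features lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(features$end <= features$start)) {
    stop("coordinate inversion: end must exceed start (half-open intervals)",
         call. = FALSE)
  }
  if ("nesting" %in% colnames(features)) {
    orphan <- !is.na(features$nesting) &
      (!"Parent" %in% colnames(features) | is.na(features$Parent))
    if (any(orphan)) {
      warning("nested intron feature(s) without a Parent link: ",
              paste(features$ID[orphan], collapse = ", "), call. = FALSE)
    }
  }
  strand <- if ("strand" %in% colnames(features)) features$strand else "+"
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$ID
  if ("Parent" %in% colnames(features)) {
    S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
      lapply(features$Parent, function(p) {
        if (is.na(p)) character(0) else p
      }))
  }
  for (cc in gff_extra_cols(features)) {
    S4Vectors::mcols(gr)[[cc]] <- features[[cc]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features from a GFF3 file
#'
#' Inverse of [write_gff3()]: returns a data frame with 0-based half-open
#' `start`/`end` plus `ID`, `Parent` and any extra attribute columns.
#'
#' @param path GFF3 file path.
#' @return Feature data frame.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% colnames(mc)) {
    vapply(as.list(mc$Parent), function(p) {
      if (length(p)) paste(p, collapse = ",") else NA_character_
    }, character(1))
  } else NA_character_
  out <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(mc$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = if ("ID" %in% colnames(mc)) as.character(mc$ID) else NA_character_,
    Parent = parent,
    stringsAsFactors = FALSE)
  for (cc in setdiff(colnames(mc), c("type", "ID", "Parent", "source",
                                     "score", "phase"))) {
    val <- mc[[cc]]
    if (methods::is(val, "List")) {
      val <- vapply(as.list(val), function(p) {
        if (length(p)) paste(p, collapse = ",") else NA_character_
      }, character(1))
    }
    out[[cc]] <- as.character(val)
  }
  out$strand[out$strand == "*"] <- "+"
  out
}
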