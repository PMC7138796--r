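# U2 splice-element models: alphabet handling, IUPAC matching and two-tier
# (strong/weak) scoring of donor, lariat branch point and acceptor elements.

#' IUPAC ambiguity classes over the RNA alphabet
#'
#' Named list mapping each IUPAC code to the set of concrete RNA residues it
#' admits. Used by [match_iupac()] and the element scanners.
#'
#' @format A named list of character vectors.
#' @export
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Normalize raw nucleotide text into an RNA sequence
#'
#' The internal canonical alphabet is RNA: input is upper-cased and T is
#' transcribed to U. Only concrete residues are accepted; IUPAC ambiguity
#' codes (e.g. N) are rejected because every downstream operation works on
#' concrete sequences. Normalization is idempotent.
#'
#' @param residues Character scalar of nucleotide text (DNA or RNA, any case).
#' @param id Free-text identifier kept with the sequence.
#' @return An object of class `rna_seq`: a list with `id` and `residues`.
#' @examples
#' rna_seq("gtacgt")            # -> GUACGU
#' @export
rna_seq <- function(residues, id = "seq") {
  if (inherits(residues, "rna_seq")) {
    return(structure(list(id = id, residues = residues$residues),
                     class = "rna_seq"))
  }
  stopifnot(is.character(residues), length(residues) == 1L)
  x <- chartr("tT", "uU", residues)
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad)) {
    stop(sprintf("non-nucleotide character '%s' at position %d in sequence '%s'",
                 chars[bad[1L]], bad[1L], id), call. = FALSE)
  }
  structure(list(id = id, residues = x), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  n <- nchar(x$residues)
  head <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<rna_seq> %s (%d nt)\n  %s\n", x$id, n, head))
  invisible(x)
}

# Coerce character or rna_seq input; used by every sequence-consuming entry.
as_rna <- function(x, id = "seq") {
  if (inherits(x, "rna_seq")) x else rna_seq(x, id = id)
}

#' Residues of a sequence as a single character string
#' @param x An `rna_seq` or character scalar.
#' @return Character scalar of RNA residues.
#' @export
residues <- function(x) as_rna(x)$residues

# Reverse complement on the RNA alphabet.
revcomp_rna <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

#' Match a window of residues against an IUPAC pattern
#'
#' TRUE iff every residue belongs to the IUPAC class at the corresponding
#' pattern position. Pattern and window must have equal length.
#'
#' @param pattern IUPAC string (T accepted, treated as U).
#' @param window Concrete residues of the same length.
#' @return Logical scalar.
#' @examples
#' match_iupac("GURWGY", "GUAAGU")  # TRUE
#' match_iupac("HAG", "GAG")        # FALSE: H excludes G
#' @export
match_iupac <- function(pattern, window) {
  p <- strsplit(toupper(chartr("t", "u", pattern)), "", fixed = TRUE)[[1]]
  w <- strsplit(toupper(chartr("t", "u", window)), "", fixed = TRUE)[[1]]
  if (length(p) != length(w)) {
    stop("pattern and window must have equal length", call. = FALSE)
  }
  unknown <- setdiff(p, names(IUPAC_RNA))
  if (length(unknown)) {
    stop("unknown IUPAC code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(p)) {
    if (!w[i] %in% IUPAC_RNA[[p[i]]]) return(FALSE)
  }
  TRUE
}

# Count of positions where `window` is outside the IUPAC class of `pattern`.
iupac_mismatches <- function(pattern, window) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  stopifnot(length(p) == length(w))
  sum(vapply(seq_along(p), function(i) !w[i] %in% IUPAC_RNA[[p[i]]], logical(1)))
}

# Vectorized mismatch counts of every window of `pattern`'s length over a
# character vector of residues; element i corresponds to the window starting
# at (1-based) position i.
window_mismatches <- function(chars, pattern) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(p)
  n <- length(chars)
  if (n < L) return(integer(0))
  starts <- seq_len(n - L + 1L)
  mm <- integer(length(starts))
  for (j in seq_len(L)) {
    mm <- mm + as.integer(!chars[starts + j - 1L] %in% IUPAC_RNA[[p[j]]])
  }
  mm
}

#' Consensus model of the three U2 splice elements
#'
#' Encodes the fungal U2 consensus motifs: the 6-nt donor `GURWGY` (with a
#' mandatory literal GU prefix), the 6-nt lariat branch point element
#' `DYURAY`, and the 3-nt acceptor `HAG`. Canonicality is graded with a
#' two-tier scheme: a donor is *strong* with 0 mismatches over positions 3-6
#' and *weak* with up to `donor_max_mismatch`; a branch element's *strength*
#' is its mismatch count against `DYURAY` plus its mismatch count against the
#' stricter secondary reference `HCURAC`, and the element is *strong* when
#' strength is at most `branch_strong_cutoff`, invalid at or beyond
#' `branch_invalid_cutoff`, weak in between. The secondary reference is what
#' separates frequent-but-aberrant branch elements (e.g. UUUAAU, which matches
#' `DYURAY` exactly yet splices poorly) from fully canonical ones.
#'
#' @param donor_pattern,branch_pattern,branch_strict_pattern,acceptor_pattern
#'   IUPAC strings; lengths 6, 6, 6 and 3.
#' @param donor_mandatory_prefix Literal prefix required of every donor.
#' @param donor_max_mismatch Maximum mismatches over donor positions 3-6.
#' @param branch_max_primary_mismatch Maximum mismatches against
#'   `branch_pattern` for a branch element to be valid at all.
#' @param branch_strong_cutoff,branch_invalid_cutoff Strength thresholds;
#'   `0 <= branch_strong_cutoff < branch_invalid_cutoff`.
#' @return An object of class `splice_motif_model`.
#' @export
splice_motif_model <- function(donor_pattern = "GURWGY",
                               branch_pattern = "DYURAY",
                               branch_strict_pattern = "HCURAC",
                               acceptor_pattern = "HAG",
                               donor_mandatory_prefix = "GU",
                               donor_max_mismatch = 1L,
                               branch_max_primary_mismatch = 1L,
                               branch_strong_cutoff = 1L,
                               branch_invalid_cutoff = 5L) {
  pats <- c(donor_pattern, branch_pattern, branch_strict_pattern,
            acceptor_pattern)
  ok <- vapply(pats, function(p) {
    all(strsplit(p, "", fixed = TRUE)[[1]] %in% names(IUPAC_RNA))
  }, logical(1))
  if (!all(ok)) stop("patterns must be valid IUPAC strings", call. = FALSE)
  if (nchar(donor_pattern) != 6L || nchar(branch_pattern) != 6L ||
      nchar(branch_strict_pattern) != 6L || nchar(acceptor_pattern) != 3L) {
    stop("donor/branch patterns must be 6 nt and the acceptor 3 nt",
         call. = FALSE)
  }
  if (!(branch_strong_cutoff >= 0L &&
        branch_strong_cutoff < branch_invalid_cutoff)) {
    stop("need 0 <= branch_strong_cutoff < branch_invalid_cutoff",
         call. = FALSE)
  }
  structure(list(
    donor_pattern = donor_pattern,
    branch_pattern = branch_pattern,
    branch_strict_pattern = branch_strict_pattern,
    acceptor_pattern = acceptor_pattern,
    donor_mandatory_prefix = donor_mandatory_prefix,
    donor_max_mismatch = as.integer(donor_max_mismatch),
    branch_max_primary_mismatch = as.integer(branch_max_primary_mismatch),
    branch_strong_cutoff = as.integer(branch_strong_cutoff),
    branch_invalid_cutoff = as.integer(branch_invalid_cutoff)
  ), class = "splice_motif_model")
}

element_match <- function(kind, start, sequence, primary_mismatches,
                          strength = NA_integer_, tier) {
  structure(list(kind = kind, start = start, sequence = sequence,
                 primary_mismatches = as.integer(primary_mismatches),
                 strength = if (is.na(strength)) NA_integer_ else as.integer(strength),
                 tier = tier),
            class = "element_match")
}

#' Score a hexamer as a 5' donor element
#'
#' A donor must begin with the literal GU dinucleotide; positions 3-6 are
#' compared against the donor consensus and at most
#' `model$donor_max_mismatch` mismatches are tolerated. Zero mismatches give
#' tier "strong", otherwise "weak". Returns `NULL` for invalid hexamers.
#'
#' @param hexamer Exactly 6 residues (character or `rna_seq`).
#' @param model A [splice_motif_model()].
#' @return An `element_match` (kind "donor") or `NULL`.
#' @examples
#' score_donor("GUAAGU")$tier   # "strong" (ideal consensus)
#' score_donor("GUACGU")$tier   # "weak"   (one mismatch at position 4)
#' is.null(score_donor("AUAAGU"))  # TRUE: mandatory GU prefix absent
#' @export
score_donor <- function(hexamer, model = splice_motif_model()) {
  h <- residues(as_rna(hexamer, id = "hexamer"))
  if (nchar(h) != 6L) stop("donor hexamer must be exactly 6 residues",
                           call. = FALSE)
  if (substr(h, 1L, 2L) != model$donor_mandatory_prefix) return(NULL)
  mm <- iupac_mismatches(substr(model$donor_pattern, 3L, 6L), substr(h, 3L, 6L))
  if (mm > model$donor_max_mismatch) return(NULL)
  element_match("donor", NA_integer_, h, mm,
                tier = if (mm == 0L) "strong" else "weak")
}

#' Score a hexamer as a lariat branch point element
#'
#' Mismatches against the primary consensus in excess of
#' `model$branch_max_primary_mismatch` invalidate the hexamer. The combined
#' strength (primary plus strict-reference mismatches) sets the tier; see
#' [splice_motif_model()]. Returns `NULL` for invalid hexamers.
#'
#' @inheritParams score_donor
#' @return An `element_match` (kind "branch") or `NULL`.
#' @examples
#' score_branch("ACUAAC")$tier      # "strong", strength 0
#' score_branch("UUUAAU")$strength  # 2 -> "weak"
#' @export
score_branch <- function(hexamer, model = splice_motif_model()) {
  h <- residues(as_rna(hexamer, id = "hexamer"))
  if (nchar(h) != 6L) stop("branch hexamer must be exactly 6 residues",
                           call. = FALSE)
  primary <- iupac_mismatches(model$branch_pattern, h)
  if (primary > model$branch_max_primary_mismatch) return(NULL)
  strength <- primary + iupac_mismatches(model$branch_strict_pattern, h)
  if (strength >= model$branch_invalid_cutoff) return(NULL)
  element_match("branch", NA_integer_, h, primary, strength,
                tier = if (strength <= model$branch_strong_cutoff) "strong"
                       else "weak")
}

#' Score a trimer as a 3' acceptor element
#'
#' Binary: valid iff the trimer matches the acceptor consensus (HAG); valid
#' acceptors are always tier "strong" (acceptors are not graded).
#'
#' @param trimer Exactly 3 residues.
#' @inheritParams score_donor
#' @return An `element_match` (kind "acceptor") or `NULL`.
#' @examples
#' score_acceptor("UAG")$tier      # "strong"
#' is.null(score_acceptor("GAG"))  # TRUE
#' @export
score_acceptor <- function(trimer, model = splice_motif_model()) {
  t3 <- residues(as_rna(trimer, id = "trimer"))
  if (nchar(t3) != 3L) stop("acceptor trimer must be exactly 3 residues",
                            call. = FALSE)
  if (!match_iupac(model$acceptor_pattern, t3)) return(NULL)
  element_match("acceptor", NA_integer_, t3, 0L, tier = "strong")
}
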