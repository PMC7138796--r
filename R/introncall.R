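# Candidate-intron enumeration: all (donor, branch, acceptor) triples that
# satisfy element validity, intron length bounds and the branch-to-acceptor
# spacing window.

#' Parameters for candidate-intron enumeration and splicing
#'
#' Length bounds bracket the intron sizes seen in small-intron fungi (the
#' defaults cover introns of 46-320 nt with margin), and the
#' branch-to-acceptor window brackets the observed spacers (7-17 nt) between
#' the end of the branch hexamer and the start of the acceptor trimer.
#'
#' @param min_intron_len,max_intron_len Inclusive intron length bounds in nt;
#'   `9 <= min_intron_len <= max_intron_len`.
#' @param branch_to_acceptor_min,branch_to_acceptor_max Inclusive bounds, in
#'   nt, on the gap between branch hexamer end and acceptor trimer start.
#' @param motif_model A [splice_motif_model()].
#' @return An object of class `splicing_params`.
#' @export
splicing_params <- function(min_intron_len = 40L, max_intron_len = 400L,
                            branch_to_acceptor_min = 5L,
                            branch_to_acceptor_max = 25L,
                            motif_model = splice_motif_model()) {
  min_intron_len <- as.integer(min_intron_len)
  max_intron_len <- as.integer(max_intron_len)
  bmin <- as.integer(branch_to_acceptor_min)
  bmax <- as.integer(branch_to_acceptor_max)
  if (!(min_intron_len >= 9L && min_intron_len <= max_intron_len)) {
    stop("need 9 <= min_intron_len <= max_intron_len", call. = FALSE)
  }
  if (!(bmin >= 0L && bmin <= bmax)) {
    stop("need 0 <= branch_to_acceptor_min <= branch_to_acceptor_max",
         call. = FALSE)
  }
  stopifnot(inherits(motif_model, "splice_motif_model"))
  structure(list(min_intron_len = min_intron_len,
                 max_intron_len = max_intron_len,
                 branch_to_acceptor_min = bmin,
                 branch_to_acceptor_max = bmax,
                 motif_model = motif_model),
            class = "splicing_params")
}

new_candidate <- function(start, end, donor, branch, acceptor,
                          alt_branches = list()) {
  structure(list(
    start = as.integer(start), end = as.integer(end),
    length = as.integer(end - start),
    donor = donor, branch = branch, acceptor = acceptor,
    alt_branches = alt_branches,
    weak_dependent = identical(donor$tier, "weak") ||
      identical(branch$tier, "weak"),
    total_mismatches = donor$primary_mismatches + branch$primary_mismatches
  ), class = "candidate_intron")
}

#' @export
print.candidate_intron <- function(x, ...) {
  cat(sprintf(
    "<candidate_intron> [%d,%d) %d nt  donor %s (%s)  branch %s (%s)  acceptor %s%s\n",
    x$start, x$end, x$length,
    x$donor$sequence, x$donor$tier, x$branch$sequence, x$branch$tier,
    x$acceptor$sequence, if (x$weak_dependent) "  [weak-dependent]" else ""))
  invisible(x)
}

sort_candidates <- function(cands) {
  if (length(cands) < 2L) return(cands)
  len <- vapply(cands, `[[`, integer(1), "length")
  mm <- vapply(cands, `[[`, integer(1), "total_mismatches")
  st <- vapply(cands, `[[`, integer(1), "start")
  cands[order(len, mm, st)]
}

# Pick the attached branch for one donor/acceptor pair: lowest strength,
# ties broken toward the 3'-most hexamer (proximity to the acceptor).
pick_branch <- function(branches) {
  strength <- vapply(branches, `[[`, integer(1), "strength")
  st <- vapply(branches, `[[`, integer(1), "start")
  ord <- order(strength, -st)
  list(best = branches[[ord[1L]]], alternates = branches[ord[-1L]])
}

#' Enumerate all candidate U2 introns in a region
#'
#' Exhaustively lists every (donor, branch, acceptor) triple within `region`
#' that passes the tier model of `params$motif_model`, the intron length
#' bounds, and the branch-to-acceptor spacing window. When several valid
#' branch hexamers serve one donor/acceptor pair, the candidate carries the
#' strongest (ties resolved toward the 3'-most); the others are retained in
#' `alt_branches`. Candidates are sorted by (length, combined element
#' mismatches, start). All coordinates are 0-based half-open offsets into
#' `seq`.
#'
#' @param seq An `rna_seq` or character scalar.
#' @param region Optional `c(start, end)` 0-based half-open bounds; defaults
#'   to the whole sequence.
#' @param params A [splicing_params()].
#' @return List of `candidate_intron` objects (possibly empty).
#' @seealso [brute_force_candidates()] for the independent cubic-enumeration
#'   oracle used in tests.
#' @export
find_candidate_introns <- function(seq, region = NULL,
                                   params = splicing_params()) {
  s <- as_rna(seq)
  n <- nchar(s$residues)
  if (is.null(region)) region <- c(0L, n)
  rs <- as.integer(region[1L]); re <- as.integer(region[2L])
  if (is.na(rs) || is.na(re) || rs < 0L || re > n || rs > re) {
    stop("region outside sequence bounds", call. = FALSE)
  }
  if (re - rs < params$min_intron_len) return(list())
  chars <- strsplit(substr(s$residues, rs + 1L, re), "", fixed = TRUE)[[1]]
  m <- params$motif_model
  nn <- length(chars)

  # element scans over the region (1-based starts into `chars`)
  mm36 <- window_mismatches(chars, substr(m$donor_pattern, 3L, 6L))
  donor_starts <- integer(0); donor_mm <- integer(0)
  if (nn >= 6L) {
    i <- seq_len(nn - 5L)
    pref <- chars[i] == substr(m$donor_mandatory_prefix, 1, 1) &
      chars[i + 1L] == substr(m$donor_mandatory_prefix, 2, 2)
    ok <- pref & mm36[i + 2L] <= m$donor_max_mismatch
    donor_starts <- i[ok]; donor_mm <- mm36[i[ok] + 2L]
  }
  bp <- window_mismatches(chars, m$branch_pattern)
  bs <- window_mismatches(chars, m$branch_strict_pattern)
  bstrength <- bp + bs
  bvalid <- which(bp <= m$branch_max_primary_mismatch &
                  bstrength < m$branch_invalid_cutoff)
  am <- window_mismatches(chars, m$acceptor_pattern)
  acc_starts <- which(am == 0L)

  if (!length(donor_starts) || !length(bvalid) || !length(acc_starts)) {
    return(list())
  }

  branch_of <- function(j) {           # j: 1-based start into chars
    element_match("branch", rs + j - 1L,
                  paste(chars[j:(j + 5L)], collapse = ""),
                  bp[j], bstrength[j],
                  tier = if (bstrength[j] <= m$branch_strong_cutoff) "strong"
                         else "weak")
  }

  cands <- list()
  for (a in acc_starts) {
    a_end0 <- rs + a + 2L                       # 0-based exclusive intron end
    # branch start j must satisfy gap = (a-1) - (j+5) in [bmin, bmax]
    jlo <- a - 6L - params$branch_to_acceptor_max
    jhi <- a - 6L - params$branch_to_acceptor_min
    bset <- bvalid[bvalid >= max(1L, jlo) & bvalid <= jhi]
    if (!length(bset)) next
    for (di in seq_along(donor_starts)) {
      d <- donor_starts[di]
      d0 <- rs + d - 1L                         # 0-based intron start
      len <- a_end0 - d0
      if (len < params$min_intron_len || len > params$max_intron_len) next
      bavail <- bset[bset >= d + 6L]
      if (!length(bavail)) next
      picked <- pick_branch(lapply(bavail, branch_of))
      donor <- element_match("donor", d0,
                             paste(chars[d:(d + 5L)], collapse = ""),
                             donor_mm[di],
                             tier = if (donor_mm[di] == 0L) "strong" else "weak")
      acceptor <- element_match("acceptor", a_end0 - 3L,
                                paste(chars[a:(a + 2L)], collapse = ""),
                                0L, tier = "strong")
      cands[[length(cands) + 1L]] <-
        new_candidate(d0, a_end0, donor, picked$best, acceptor,
                      picked$alternates)
    }
  }
  sort_candidates(cands)
}

#' Brute-force candidate enumeration (test oracle)
#'
#' Produces the same candidate set as [find_candidate_introns()] by cubic
#' enumeration of all position triples, scoring each window independently
#' with [score_donor()], [score_branch()] and [score_acceptor()]. Kept
#' deliberately naive and independent of the scanning path; restricted to
#' regions of at most 1000 nt.
#'
#' @inheritParams find_candidate_introns
#' @return List of `candidate_intron` objects, sorted as in
#'   [find_candidate_introns()].
#' @export
brute_force_candidates <- function(seq, region = NULL,
                                   params = splicing_params()) {
  s <- as_rna(seq)
  n <- nchar(s$residues)
  if (is.null(region)) region <- c(0L, n)
  rs <- as.integer(region[1L]); re <- as.integer(region[2L])
  if (rs < 0L || re > n || rs > re) {
    stop("region outside sequence bounds", call. = FALSE)
  }
  if (re - rs > 1000L) stop("brute-force oracle limited to regions <= 1000 nt",
                            call. = FALSE)
  res <- s$residues
  m <- params$motif_model
  cands <- list()
  for (d0 in rs:(max(rs, re - 1L))) {
    if (d0 + 6L > re) break
    donor <- score_donor(substr(res, d0 + 1L, d0 + 6L), m)
    if (is.null(donor)) next
    donor$start <- d0
    for (e0 in (d0 + 1L):re) {                  # candidate end (exclusive)
      len <- e0 - d0
      if (len < params$min_intron_len || len > params$max_intron_len) next
      if (e0 - 3L < d0 + 6L) next
      acceptor <- score_acceptor(substr(res, e0 - 2L, e0), m)
      if (is.null(acceptor)) next
      acceptor$start <- e0 - 3L
      branches <- list()
      b_starts <- if (e0 - 9L >= d0 + 6L) (d0 + 6L):(e0 - 9L) else integer(0)
      for (b0 in b_starts) {
        if (b0 + 6L > e0 - 3L) break
        gap <- (e0 - 3L) - (b0 + 6L)
        if (gap < params$branch_to_acceptor_min ||
            gap > params$branch_to_acceptor_max) next
        br <- score_branch(substr(res, b0 + 1L, b0 + 6L), m)
        if (is.null(br)) next
        br$start <- b0
        branches[[length(branches) + 1L]] <- br
      }
      if (!length(branches)) next
      picked <- pick_branch(branches)
      cands[[length(cands) + 1L]] <-
        new_candidate(d0, e0, donor, picked$best, acceptor, picked$alternates)
    }
  }
  sort_candidates(cands)
}
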