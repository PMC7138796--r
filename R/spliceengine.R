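# Intron-definition splicing engine: ordered excision of an intervening
# region with enumeration of alternative splicing paths.
#
# Selection rule: at each step the smallest valid candidate intron in the
# residual intervening region is excised (intron definition); ties on length
# break by fewest combined element mismatches, then 5'-most start. When the
# smallest candidate depends on a weak element (weak donor or weak branch)
# the outcome bifurcates: one path excises it, the other ignores that
# candidate's 3' splice-site group (its branch/acceptor pairing) for the
# remainder of the path and takes the next-smallest candidate.
#
# A terminated path is complete when at least one excision happened, a fresh
# (unsuppressed) scan of the residual region finds no valid candidate, and
# the residual length is divisible by 3 so the reading frame across the
# junction is preserved. Residual nucleotides of a complete path become
# exonic in the mature product (the basis of the alternative-splicing case,
# where one mature product retains the 5'-most donor hexamer).

# Convert a sorted vector of primary coordinates into half-open intervals.
runs_to_intervals <- function(pos) {
  if (!length(pos)) return(matrix(integer(0), ncol = 2))
  breaks <- which(diff(pos) != 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))] + 1L
  cbind(start = starts, end = ends)
}

#' Excise an intron from a sequence
#'
#' Removes the half-open interval covered by `intron` and ligates the
#' flanks. `intron` may be a `candidate_intron` or a `c(start, end)` pair of
#' 0-based half-open coordinates. A zero-length excision is rejected.
#'
#' @param seq An `rna_seq` or character scalar.
#' @param intron A `candidate_intron` or integer `c(start, end)`.
#' @return An `rna_seq` shorter than `seq` by the intron length.
#' @export
excise <- function(seq, intron) {
  s <- as_rna(seq)
  n <- nchar(s$residues)
  if (inherits(intron, "candidate_intron")) {
    st <- intron$start; en <- intron$end
  } else {
    st <- as.integer(intron[1L]); en <- as.integer(intron[2L])
  }
  if (is.na(st) || is.na(en) || st < 0L || en > n) {
    stop("intron coordinates out of sequence bounds", call. = FALSE)
  }
  if (en <= st) stop("zero-length excision rejected", call. = FALSE)
  out <- paste0(substr(s$residues, 1L, st), substr(s$residues, en + 1L, n))
  structure(list(id = s$id, residues = out), class = "rna_seq")
}

#' Resolve ordered excision of an intervening region
#'
#' Iteratively applies the intron-definition selection rule to the designated
#' intervening region of `premrna`, bifurcating on weak-dependent smallest
#' candidates, and returns every complete splicing path (see the package
#' vignette for the completeness rule). Event coordinates are reported both
#' in the molecule current at the time of the event and mapped back to the
#' primary transcript.
#'
#' @param premrna An `rna_seq` or character scalar (the primary transcript).
#' @param cis_region `c(start, end)` 0-based half-open bounds of the
#'   intervening region within `premrna`.
#' @param params A [splicing_params()].
#' @param max_paths Cap on the number of complete paths; exceeding it is an
#'   error (guards termination on adversarial inputs).
#' @return An object of class `splicing_outcome` with elements `paths` (list
#'   of `splicing_path`), `mature_products` (deduplicated mature residue
#'   strings), `premrna`, `cis_region`.
#' @export
resolve_splicing <- function(premrna, cis_region, params = splicing_params(),
                             max_paths = 16L) {
  s <- as_rna(premrna)
  res <- s$residues
  n <- nchar(res)
  rs <- as.integer(cis_region[1L]); re <- as.integer(cis_region[2L])
  if (is.na(rs) || is.na(re) || rs < 0L || re > n || rs > re) {
    stop("cis_region outside premrna bounds", call. = FALSE)
  }
  prefix <- substr(res, 1L, rs)
  suffix <- substr(res, re + 1L, n)
  paths <- list()

  key_of <- function(cand, pmap) {
    paste(pmap[cand$branch$start + 1L], pmap[cand$acceptor$start + 1L])
  }

  walk <- function(region, pmap, suppressed, events, inters) {
    cands <- find_candidate_introns(region, params = params)
    keys <- vapply(cands, key_of, character(1), pmap = pmap)
    avail <- which(!(keys %in% suppressed))
    if (!length(avail)) {
      leftover <- nchar(region)
      if (length(events) >= 1L && length(cands) == 0L &&
          leftover %% 3L == 0L) {
        mature <- structure(list(id = paste0(s$id, "_mature"),
                                 residues = paste0(prefix, region, suffix)),
                            class = "rna_seq")
        mode <- switch(as.character(min(length(events), 3L)),
                       "1" = "single_step", "2" = "two_step", "multi_step")
        if (length(paths) >= max_paths) {
          stop("splicing path cap exceeded (", max_paths, ")", call. = FALSE)
        }
        paths[[length(paths) + 1L]] <<- structure(
          list(events = events, intermediates = inters, mature = mature,
               mode = mode, leftover = leftover),
          class = "splicing_path")
      }
      return(invisible(NULL))
    }
    top <- cands[[avail[1L]]]
    if (isTRUE(top$weak_dependent)) {
      # alternative path: the weak-dependent 3' splice-site group is not
      # recognised; every candidate sharing it stays suppressed downstream
      walk(region, pmap, c(suppressed, key_of(top, pmap)), events, inters)
    }
    idx <- (top$start + 1L):top$end
    prim <- pmap[idx]
    new_region <- paste0(substr(region, 1L, top$start),
                         substr(region, top$end + 1L, nchar(region)))
    ev <- list(
      step = length(events) + 1L,
      cur_start = top$start, cur_end = top$end,
      mol_start = rs + top$start, mol_end = rs + top$end,
      excised_length = top$length,
      primary_intervals = runs_to_intervals(prim),
      donor = c(top$donor, list(primary_start = pmap[top$donor$start + 1L])),
      branch = c(top$branch, list(primary_start = pmap[top$branch$start + 1L])),
      acceptor = c(top$acceptor,
                   list(primary_start = pmap[top$acceptor$start + 1L])),
      alt_branches = top$alt_branches,
      weak_dependent = top$weak_dependent)
    inter <- paste0(prefix, new_region, suffix)
    walk(new_region, pmap[-idx], suppressed,
         c(events, list(ev)), c(inters, list(inter)))
    invisible(NULL)
  }

  region0 <- substr(res, rs + 1L, re)
  pmap0 <- if (rs < re) rs:(re - 1L) else integer(0)
  walk(region0, pmap0, character(0), list(), list())

  sig <- vapply(paths, function(p) {
    paste(vapply(p$events,
                 function(e) paste(e$primary_intervals, collapse = ","),
                 character(1)), collapse = ";")
  }, character(1))
  paths <- paths[!duplicated(sig)]
  if (length(paths)) {
    nev <- vapply(paths, function(p) length(p$events), integer(1))
    first <- vapply(paths, function(p) p$events[[1L]]$primary_intervals[1L, 1L],
                    integer(1))
    paths <- paths[order(-nev, first)]
  }
  mature_products <- unique(vapply(paths, function(p) p$mature$residues,
                                   character(1)))
  structure(list(paths = paths, mature_products = mature_products,
                 premrna = s, cis_region = c(rs, re), params = params),
            class = "splicing_outcome")
}

#' @export
print.splicing_outcome <- function(x, ...) {
  cat(sprintf("<splicing_outcome> %d path(s), %d mature product(s)\n",
              length(x$paths), length(x$mature_products)))
  for (i in seq_along(x$paths)) {
    p <- x$paths[[i]]
    lens <- vapply(p$events, `[[`, integer(1), "excised_length")
    cat(sprintf("  path %d (%s): excised %s nt%s\n", i, p$mode,
                paste(lens, collapse = " + "),
                if (p$leftover > 0)
                  sprintf(", %d nt retained in mature product", p$leftover)
                else ""))
  }
  invisible(x)
}

#' Structured report of a splicing outcome
#'
#' Flattens a [resolve_splicing()] outcome into plain data frames and
#' character vectors suitable for serialization (e.g. with
#' `jsonlite::toJSON`). Event coordinates are given in both conventions:
#' 0-based half-open (`*_0based`) and 1-based inclusive (`*_1based`), on the
#' primary transcript.
#'
#' @param outcome A `splicing_outcome`.
#' @return A list of class `splicing_report` with `n_paths`, `paths` (each
#'   with an event table, intermediates and mature product) and
#'   `mature_products`.
#' @export
splicing_report <- function(outcome) {
  stopifnot(inherits(outcome, "splicing_outcome"))
  fmt_path <- function(p) {
    ev <- lapply(p$events, function(e) {
      iv <- e$primary_intervals
      data.frame(
        step = e$step,
        excised_length = e$excised_length,
        primary_start_0based = iv[1L, 1L],
        primary_intervals = paste(sprintf("[%d,%d)", iv[, 1L], iv[, 2L]),
                                  collapse = "+"),
        primary_start_1based = iv[1L, 1L] + 1L,
        donor_seq = e$donor$sequence, donor_tier = e$donor$tier,
        branch_seq = e$branch$sequence, branch_tier = e$branch$tier,
        acceptor_seq = e$acceptor$sequence,
        stringsAsFactors = FALSE)
    })
    list(mode = p$mode,
         events = do.call(rbind, ev),
         intermediates = vapply(p$intermediates, identity, character(1)),
         mature = p$mature$residues,
         retained_nt = p$leftover)
  }
  structure(list(n_paths = length(outcome$paths),
                 paths = lapply(outcome$paths, fmt_path),
                 mature_products = outcome$mature_products),
            class = "splicing_report")
}
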