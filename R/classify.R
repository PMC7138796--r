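# Stwintron taxonomy: classification of a nested intron pair into
# [Dk,k+1] / [Lm,m+1] / [Am,m+1] classes, sensu stricto or sensu lato.

new_nesting_relation <- function(internal, external, k) {
  if (k < 1L) {
    stop("internal intron precedes the external donor (k = 0)", call. = FALSE)
  }
  structure(list(internal = internal, external = external, k = as.integer(k)),
            class = "nesting_relation")
}

#' @export
print.nesting_relation <- function(x, ...) {
  cat(sprintf(
    "<nesting_relation> internal %d nt inside external %d nt after external nt %d (k=%d)\n",
    x$internal$length, x$external$length, x$k, x$k))
  invisible(x)
}

#' Classify a nested intron pair
#'
#' Applies the stwintron nomenclature: the label names the element of the
#' external intron that the internal intron interrupts (D donor, L lariat
#' branch point element, A acceptor) and the two external-intron nucleotide
#' positions flanking the insertion point. Insertion within the 6-nt donor
#' (k in 1..5) is sensu stricto; k = 6 (abutting donors) and k = 7 (donors
#' one nt apart) are sensu lato since consecutive excision is still
#' required; insertions inside the branch hexamer or acceptor trimer are
#' sensu stricto [L]/[A] classes numbered within the element; anything else
#' is sensu lato between elements. Insertion points beyond k = 7 that fall
#' outside every element keep the [Dk,k+1]-style label but carry
#' `warning = TRUE` because such configurations are an extrapolation.
#'
#' @param relation A `nesting_relation` from [derive_relation()] or
#'   [build_cis()].
#' @param model A [splice_motif_model()] (reserved for element geometry;
#'   the element positions recorded in `relation` take precedence).
#' @return An object of class `stwintron_class` with `label`, `sensu`
#'   ("stricto"/"lato"), `disrupted_element`, `k` and `warning`.
#' @examples
#' bc <- build_cis(strrep("A", 20), strrep("C", 10), k = 4)
#' classify_nesting(bc$relation)$label   # "[D4,5]"
#' @export
classify_nesting <- function(relation, model = splice_motif_model()) {
  stopifnot(inherits(relation, "nesting_relation"))
  k <- relation$k
  if (k < 1L) {
    stop("internal intron precedes the external donor (k = 0)", call. = FALSE)
  }
  b0 <- relation$external$branch_start
  a0 <- relation$external$length - 3L
  out <- function(label, sensu, elem, warning = FALSE) {
    structure(list(label = label, sensu = sensu, disrupted_element = elem,
                   k = k, warning = warning), class = "stwintron_class")
  }
  if (k <= 5L) {
    return(out(sprintf("[D%d,%d]", k, k + 1L), "stricto", "donor"))
  }
  if (k == 6L) return(out("[D6,7]", "lato", "inter_element"))
  if (k == 7L) return(out("[D7,8]", "lato", "inter_element"))
  if (!is.null(b0) && !is.na(b0) && k > b0 && k < b0 + 6L) {
    m <- k - b0
    return(out(sprintf("[L%d,%d]", m, m + 1L), "stricto", "branch"))
  }
  if (!is.na(a0) && k > a0 && k < a0 + 3L) {
    m <- k - a0
    return(out(sprintf("[A%d,%d]", m, m + 1L), "stricto", "acceptor"))
  }
  out(sprintf("[D%d,%d]", k, k + 1L), "lato", "inter_element", warning = TRUE)
}

#' @export
print.stwintron_class <- function(x, ...) {
  cat(sprintf("<stwintron_class> %s sensu %s (%s disrupted)%s\n",
              x$label, x$sensu, x$disrupted_element,
              if (isTRUE(x$warning)) "  [unattested k]" else ""))
  invisible(x)
}

#' Build a complex intervening sequence from its constituent introns
#'
#' Inserts `internal_seq` after the k-th residue of `external_seq` and
#' returns the resulting CIS together with the truth nesting relation (the
#' inverse of classification; used by tests and the evolution simulator).
#' If the external sequence forms a full-span candidate intron under
#' `params`, its element layout is recorded in the relation so that [L]/[A]
#' insertions can be recognised; otherwise only `k` is available.
#'
#' @param external_seq,internal_seq Residues (character or `rna_seq`).
#' @param k Insertion offset: number of external residues 5' of the internal
#'   intron; `1 <= k <= nchar(external_seq)`.
#' @param params A [splicing_params()] used to locate the external elements.
#' @return List with `cis` (an `rna_seq`) and `relation` (a
#'   `nesting_relation`).
#' @export
build_cis <- function(external_seq, internal_seq, k,
                      params = splicing_params()) {
  ext <- as_rna(external_seq, id = "external")
  int <- as_rna(internal_seq, id = "internal")
  elen <- nchar(ext$residues)
  ilen <- nchar(int$residues)
  k <- as.integer(k)
  if (ilen < 1L) stop("internal intron must be non-empty", call. = FALSE)
  if (is.na(k) || k < 1L || k > elen) {
    stop("insertion offset k out of range 1..", elen, call. = FALSE)
  }
  cis <- paste0(substr(ext$residues, 1L, k), int$residues,
                substr(ext$residues, k + 1L, elen))
  b0 <- NA_integer_
  full <- tryCatch({
    cands <- find_candidate_introns(ext, params = params)
    Filter(function(cd) cd$start == 0L && cd$end == elen, cands)
  }, error = function(e) list())
  if (length(full)) b0 <- full[[1L]]$branch$start
  relation <- new_nesting_relation(
    internal = list(start = k, end = k + ilen, length = ilen),
    external = list(length = elen, branch_start = b0,
                    primary_intervals = rbind(c(0L, k), c(k + ilen, elen + ilen))),
    k = k)
  list(cis = structure(list(id = paste0("cis_k", k), residues = cis),
                       class = "rna_seq"),
       relation = relation)
}

#' Derive the nesting relation from a splicing outcome
#'
#' Takes the two-step path of an outcome (the internal intron is the first
#' event, the external intron the second, mapped back to pre-excision
#' coordinates) and computes the insertion offset k: the number of external
#' nucleotides 5' of the internal intron start. Returns `NULL` when the
#' outcome has no two-step path or when the two events are not nested.
#'
#' @param outcome A `splicing_outcome` from [resolve_splicing()].
#' @param cis_region Optional override of the region bounds (defaults to the
#'   outcome's own).
#' @return A `nesting_relation` or `NULL`.
#' @export
derive_relation <- function(outcome, cis_region = NULL) {
  stopifnot(inherits(outcome, "splicing_outcome"))
  two <- Filter(function(p) length(p$events) == 2L && p$leftover == 0L,
                outcome$paths)
  if (!length(two)) return(NULL)
  p <- two[[1L]]
  e1 <- p$events[[1L]]; e2 <- p$events[[2L]]
  iv1 <- e1$primary_intervals; iv2 <- e2$primary_intervals
  if (nrow(iv1) != 1L || nrow(iv2) != 2L) return(NULL)   # not a nested pair
  if (!(iv2[1L, 2L] == iv1[1L, 1L] && iv1[1L, 2L] == iv2[2L, 1L])) {
    return(NULL)
  }
  k <- iv1[1L, 1L] - iv2[1L, 1L]
  # external element positions in ligated external-intron coordinates
  b_lig <- e2$branch$start - e2$cur_start
  relation <- new_nesting_relation(
    internal = list(start = iv1[1L, 1L], end = iv1[1L, 2L],
                    length = e1$excised_length,
                    donor = e1$donor, branch = e1$branch,
                    acceptor = e1$acceptor),
    external = list(length = e2$excised_length, branch_start = b_lig,
                    primary_intervals = iv2,
                    donor = e2$donor, branch = e2$branch,
                    acceptor = e2$acceptor),
    k = k)
  relation
}
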