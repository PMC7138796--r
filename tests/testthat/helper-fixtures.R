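# Shared fixtures: realized built-in templates (cached per session) and
# small generators used by property-style tests.

TEMPLATES <- builtin_templates()

realized_cache <- new.env(parent = emptyenv())

realize_cached <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (is.null(realized_cache[[key]])) {
    realized_cache[[key]] <- realize_template(TEMPLATES[[name]], seed = seed)
  }
  realized_cache[[key]]
}

resolve_cis <- function(realized, ...) {
  resolve_splicing(realized$seq, c(0L, nchar(realized$seq$residues)), ...)
}

path_signature <- function(outcome) {
  sort(vapply(outcome$paths, function(p) {
    paste(vapply(p$events, `[[`, integer(1), "excised_length"),
          collapse = "+")
  }, character(1)))
}

candidate_signature <- function(cands) {
  vapply(cands, function(cd) {
    paste(cd$start, cd$end, cd$branch$start,
          paste(vapply(cd$alt_branches, `[[`, integer(1), "start"),
                collapse = "|"),
          sep = ":")
  }, character(1))
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
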