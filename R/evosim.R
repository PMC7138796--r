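# Monte-Carlo simulator of stwintron emergence ("stwintronisation"): tandem
# duplication anchored at the donor element (the signature of asymmetric
# double-strand-break repair) plus per-site point mutation, with
# splice-ability as the viability proxy.

#' Parameters of the stwintronisation simulator
#'
#' @param p_dup Per-generation probability of one tandem duplication event.
#' @param dup_len_range Inclusive duplication length range in nt (default
#'   4-7, the footprint of repair of an asymmetric double-strand break with
#'   a short 3' overhang).
#' @param dup_window 0-based offsets eligible as duplication anchor
#'   (default: positions overlapping the donor hexamer, `0:5`).
#' @param mu Per-nucleotide per-generation substitution probability.
#' @param n_generations,n_reps Run length and replicate count.
#' @param seed Integer master seed (split into one stream per replicate).
#' @param selection `"reject_lethal"` discards events that abolish every
#'   splicing resolution (a purifying-selection proxy); `"neutral"` keeps
#'   them.
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(p_dup = 0.05, dup_len_range = c(4L, 7L),
                             dup_window = 0:5, mu = 0.002,
                             n_generations = 50L, n_reps = 100L,
                             seed = 1L,
                             selection = c("reject_lethal", "neutral")) {
  selection <- match.arg(selection)
  dup_len_range <- as.integer(dup_len_range)
  if (!(p_dup >= 0 && p_dup <= 1)) stop("need 0 <= p_dup <= 1", call. = FALSE)
  if (!(mu >= 0 && mu <= 1)) stop("need 0 <= mu <= 1", call. = FALSE)
  if (length(dup_len_range) != 2L || dup_len_range[1L] > dup_len_range[2L] ||
      dup_len_range[1L] < 1L || dup_len_range[2L] > 20L) {
    stop("dup_len_range must be an increasing pair within [1, 20]",
         call. = FALSE)
  }
  structure(list(p_dup = p_dup, dup_len_range = dup_len_range,
                 dup_window = as.integer(dup_window), mu = mu,
                 n_generations = as.integer(n_generations),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 selection = selection),
            class = "evolution_params")
}

#' Tandem duplication anchored at the donor
#'
#' Duplicates the `dup_len` residues starting at 0-based `anchor` in place
#' (the copy is inserted immediately after the original), growing the
#' sequence by exactly `dup_len`. Residues outside the insertion are
#' untouched.
#'
#' @param intron_seq An `rna_seq` or character scalar.
#' @param anchor 0-based anchor; must belong to `params$dup_window`.
#' @param dup_len Duplication length; must fall in `params$dup_len_range`.
#' @param params An [evolution_params()].
#' @return An `rna_seq` longer than the input by `dup_len`.
#' @examples
#' residues(duplicate_donor("GUAAGUCCC", 0, 6))  # "GUAAGUGUAAGUCCC"
#' @export
duplicate_donor <- function(intron_seq, anchor, dup_len,
                            params = evolution_params()) {
  s <- as_rna(intron_seq)
  n <- nchar(s$residues)
  anchor <- as.integer(anchor); dup_len <- as.integer(dup_len)
  if (!anchor %in% params$dup_window) {
    stop("anchor ", anchor, " outside the duplication window", call. = FALSE)
  }
  if (dup_len < params$dup_len_range[1L] ||
      dup_len > params$dup_len_range[2L]) {
    stop("dup_len ", dup_len, " outside the allowed range ",
         params$dup_len_range[1L], "-", params$dup_len_range[2L],
         call. = FALSE)
  }
  if (anchor + dup_len > n) {
    stop("duplication extends past the end of the sequence", call. = FALSE)
  }
  out <- paste0(substr(s$residues, 1L, anchor + dup_len),
                substr(s$residues, anchor + 1L, n))
  structure(list(id = s$id, residues = out), class = "rna_seq")
}

#' Assess the splicing state of an intervening sequence
#'
#' Runs the splicing engine on the region (optionally embedded in flanking
#' exonic context) and labels the outcome: `canonical` when a unique
#' single-step path restores the exon junction exactly; `stwintron_stricto`
#' or `stwintron_lato` when the unique resolution is consecutive excision of
#' nested introns, labelled by [classify_nesting()]; `alternative` when at
#' least two distinct mature products arise; `nonfunctional` when no
#' complete resolution exists (including outcomes whose only products retain
#' residual nucleotides).
#'
#' @param intervening_seq The intervening region (`rna_seq` or character).
#' @param flank_context Optional `list(upstream=, downstream=)` exonic
#'   context.
#' @param params A [splicing_params()].
#' @return List with `state` (character) and `class` (a `stwintron_class` or
#'   `NULL`).
#' @export
assess_state <- function(intervening_seq, flank_context = NULL,
                         params = splicing_params()) {
  up <- if (is.null(flank_context)) "" else residues(flank_context$upstream)
  down <- if (is.null(flank_context)) "" else residues(flank_context$downstream)
  region <- residues(intervening_seq)
  premrna <- paste0(up, region, down)
  cis <- c(nchar(up), nchar(up) + nchar(region))
  outcome <- resolve_splicing(premrna, cis, params = params)
  if (!length(outcome$paths)) {
    return(list(state = "nonfunctional", class = NULL))
  }
  if (length(outcome$mature_products) >= 2L) {
    return(list(state = "alternative", class = NULL))
  }
  clean <- Filter(function(p) p$leftover == 0L, outcome$paths)
  if (!length(clean)) {
    return(list(state = "nonfunctional", class = NULL))
  }
  p <- clean[[1L]]
  if (p$mode == "single_step") {
    return(list(state = "canonical", class = NULL))
  }
  if (p$mode == "two_step") {
    rel <- derive_relation(outcome)
    if (!is.null(rel)) {
      cls <- classify_nesting(rel, params$motif_model)
      state <- if (cls$sensu == "stricto") "stwintron_stricto"
               else "stwintron_lato"
      return(list(state = state, class = cls))
    }
  }
  # consecutive excision without a nested two-step relation (rare, >2 steps
  # or sequential introns): still an obligatorily multi-step configuration
  list(state = "stwintron_lato", class = NULL)
}

#' Simulate stwintronisation trajectories
#'
#' Starts from a canonical intron and applies, per generation, at most one
#' tandem donor duplication (probability `p_dup`) followed by independent
#' per-site substitutions (probability `mu` per site, to a uniformly chosen
#' different base). Under `reject_lethal` selection any generation whose
#' events leave the region unspliceable is discarded and the previous state
#' retained. The state is re-assessed after every accepted event set; the
#' first generation at which a stwintron or alternative-splicing
#' configuration appears is recorded.
#'
#' @param start The ancestral intervening sequence: a `realized_cis` (e.g.
#'   of [canonical_intron_template()]), `rna_seq` or character. Must assess
#'   as canonical.
#' @param params An [evolution_params()].
#' @param splicing A [splicing_params()].
#' @param flank_context Optional flanks for [assess_state()].
#' @return An object of class `evosim_result`: list with `stats`
#'   (`fraction_by_state`, `mean_emergence_time`, `class_distribution`) and
#'   `trajectories` (one record per replicate).
#' @export
simulate_trajectories <- function(start, params = evolution_params(),
                                  splicing = splicing_params(),
                                  flank_context = NULL) {
  seq0 <- if (inherits(start, "realized_cis")) start$seq$residues
          else residues(start)
  init <- assess_state(seq0, flank_context, splicing)
  if (!identical(init$state, "canonical")) {
    stop("start sequence must assess as canonical (got ", init$state, ")",
         call. = FALSE)
  }
  states <- c("canonical", "stwintron_stricto", "stwintron_lato",
              "alternative", "nonfunctional")
  alphabet <- c("A", "C", "G", "U")
  rep_seeds <- with_seed(params$seed,
                         sample.int(2147483647L, params$n_reps))

  trajectories <- vector("list", params$n_reps)
  for (r in seq_len(params$n_reps)) {
    trajectories[[r]] <- with_seed(rep_seeds[r], {
      chars <- strsplit(seq0, "", fixed = TRUE)[[1]]
      state <- "canonical"; cls <- NULL
      emergence <- NA_integer_; cls_at <- NULL
      event_log <- list()
      for (g in seq_len(params$n_generations)) {
        prop <- chars
        events <- list()
        if (stats::runif(1L) < params$p_dup) {
          anchor <- if (length(params$dup_window) == 1L) params$dup_window
                    else sample(params$dup_window, 1L)
          dlen <- if (params$dup_len_range[1L] == params$dup_len_range[2L]) {
            params$dup_len_range[1L]
          } else {
            sample(params$dup_len_range[1L]:params$dup_len_range[2L], 1L)
          }
          if (anchor + dlen <= length(prop)) {
            prop <- append(prop, prop[(anchor + 1L):(anchor + dlen)],
                           after = anchor + dlen)
            events[[length(events) + 1L]] <-
              list(type = "duplication", generation = g,
                   anchor = anchor, length = dlen)
          }
        }
        hit <- which(stats::runif(length(prop)) < params$mu)
        if (length(hit)) {
          for (h in hit) {
            prop[h] <- sample(setdiff(alphabet, prop[h]), 1L)
          }
          events[[length(events) + 1L]] <-
            list(type = "substitution", generation = g, sites = hit - 1L)
        }
        if (!length(events)) next
        st <- assess_state(paste(prop, collapse = ""), flank_context,
                           splicing)
        if (identical(st$state, "nonfunctional") &&
            params$selection == "reject_lethal") {
          next                                  # purifying selection
        }
        chars <- prop
        state <- st$state
        cls <- st$class
        event_log <- c(event_log, events)
        if (is.na(emergence) &&
            state %in% c("stwintron_stricto", "stwintron_lato",
                         "alternative")) {
          emergence <- g
          cls_at <- cls
        }
      }
      list(final_state = state, emergence_generation = emergence,
           class_at_emergence = cls_at, event_log = event_log,
           final_length = length(chars))
    })
  }

  finals <- vapply(trajectories, `[[`, character(1), "final_state")
  fraction_by_state <- vapply(states, function(s) mean(finals == s),
                              numeric(1))
  emerged <- vapply(trajectories, `[[`, integer(1), "emergence_generation")
  labels <- vapply(trajectories, function(t) {
    if (is.null(t$class_at_emergence)) NA_character_
    else t$class_at_emergence$label
  }, character(1))
  structure(list(
    stats = list(
      fraction_by_state = fraction_by_state,
      mean_emergence_time = if (all(is.na(emerged))) NA_real_
                            else mean(emerged, na.rm = TRUE),
      class_distribution = table(labels[!is.na(labels)])),
    trajectories = trajectories,
    params = params),
    class = "evosim_result")
}

#' @export
print.evosim_result <- function(x, ...) {
  cat(sprintf("<evosim_result> %d replicates x %d generations\n",
              x$params$n_reps, x$params$n_generations))
  f <- x$stats$fraction_by_state
  for (s in names(f)) cat(sprintf("  %-18s %.3f\n", s, f[[s]]))
  if (!is.na(x$stats$mean_emergence_time)) {
    cat(sprintf("  mean emergence at generation %.1f\n",
                x$stats$mean_emergence_time))
  }
  invisible(x)
}
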