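# Minimal diagnosis: exhaustive search for the smallest character-state
# combinations that separate one OTU from every other OTU in the study.

#' Minimal diagnostic character-state sets for an OTU
#'
#' Exhaustively searches combinations of the OTU's coded
#' (character, state) pairs up to `max_size` and returns every minimal
#' set that excludes all other OTUs. A test excludes an OTU when the
#' tested state matches none of that OTU's coded states for the
#' character (an uncoded character excludes trivially). Results are
#' deterministic: candidate tests follow stored character order, sets are
#' reported smallest first.
#'
#' @param s a study.
#' @param otu OTU id or taxon name.
#' @param max_size maximum set size (combinatorial guard, at most 4).
#' @return list of data.frames (character_label, state_label), one per
#'   minimal set; empty with an `overlap` attribute (the other OTUs no
#'   single candidate excludes) when no distinguishing set exists within
#'   `max_size`.
#' @export
minimal_diagnosis <- function(s, otu, max_size = 3L) {
  assert_that(max_size >= 1L && max_size <= 4L,
              "max_size must be between 1 and 4")
  i <- match(otu, s$otus$id)
  if (is.na(i)) i <- match(otu, s$otus$taxon_name)
  assert_that(!is.na(i), sprintf("OTU '%s' absent from study", otu))
  otu_id <- s$otus$id[[i]]
  others <- setdiff(s$otus$id, otu_id)
  cand <- s$codings[s$codings$otu_id == otu_id, , drop = FALSE]
  cand <- cand[order(match(cand$character_id, s$characters$id),
                     s$states$label[match(cand$state_id, s$states$id)]), ,
               drop = FALSE]
  if (!nrow(cand) || !length(others)) return(list())
  # exclusion matrix: candidate x other OTU
  excl <- vapply(others, function(oo) {
    vapply(seq_len(nrow(cand)), function(r) {
      coded <- s$codings$state_id[s$codings$otu_id == oo &
                                    s$codings$character_id ==
                                      cand$character_id[[r]]]
      !cand$state_id[[r]] %in% coded
    }, logical(1))
  }, logical(nrow(cand)))
  excl <- matrix(excl, nrow = nrow(cand))
  found <- list()
  found_idx <- list()
  for (size in seq_len(min(max_size, nrow(cand)))) {
    combos <- utils::combn(nrow(cand), size, simplify = FALSE)
    for (cmb in combos) {
      if (any(vapply(found_idx, function(fi) all(fi %in% cmb),
                     logical(1)))) {
        next  # proper superset of a known minimal set
      }
      covered <- apply(excl[cmb, , drop = FALSE], 2, any)
      if (all(covered)) {
        found_idx[[length(found_idx) + 1L]] <- cmb
        found[[length(found) + 1L]] <- data.frame(
          character_label = s$characters$label[
            match(cand$character_id[cmb], s$characters$id)],
          state_label = s$states$label[match(cand$state_id[cmb],
                                             s$states$id)],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(found)) {
    never <- others[!apply(excl, 2, any)]
    attr(found, "overlap") <- s$otus$taxon_name[match(never, s$otus$id)]
  }
  found
}
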