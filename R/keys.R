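# Dichotomous identification keys over the matrix. A key is an explicit
# couplet graph: every couplet has exactly two leads, each lead bundles
# one or more "character: state" tests (conjunctive: all must match) and
# points either to another couplet or to a taxon leaf.

#' Build a key from couplet descriptions
#'
#' @param couplets list of couplets; each
#'   `list(id, leads = list(list(tests, couplet|taxon), ...))` with
#'   `tests` a list of `c(character_label, state_label)` pairs.
#' @param root id of the starting couplet.
#' @param name display name.
#' @return an object of class `sempheno_key`.
#' @export
key <- function(couplets, root, name = "") {
  ids <- vapply(couplets, `[[`, character(1), "id")
  assert_that(!anyDuplicated(ids), "duplicate couplet ids")
  assert_that(root %in% ids, "root couplet missing")
  for (cp in couplets) {
    assert_that(length(cp$leads) == 2L,
                sprintf("couplet '%s' must have exactly two leads", cp$id))
    for (ld in cp$leads) {
      assert_that(length(ld$tests) >= 1L,
                  sprintf("couplet '%s': leads need at least one test",
                          cp$id))
      nxt <- !is.null(ld$couplet)
      leaf <- !is.null(ld$taxon)
      assert_that(xor(nxt, leaf),
                  sprintf("couplet '%s': each lead needs a next couplet or a taxon",
                          cp$id))
      if (nxt) {
        assert_that(ld$couplet %in% ids,
                    sprintf("couplet '%s' points to unknown couplet '%s'",
                            cp$id, ld$couplet))
      }
    }
  }
  k <- structure(list(name = name, root = root,
                      couplets = stats::setNames(couplets, ids)),
                 class = "sempheno_key")
  assert_that(!key_has_cycle(k), "couplet graph must be acyclic")
  k
}

key_has_cycle <- function(k) {
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- if (exists(id, state)) get(id, state) else "new"
    if (st == "active") return(TRUE)
    if (st == "done") return(FALSE)
    assign(id, "active", envir = state)
    for (ld in k$couplets[[id]]$leads) {
      if (!is.null(ld$couplet) && visit(ld$couplet)) return(TRUE)
    }
    assign(id, "done", envir = state)
    FALSE
  }
  any(vapply(names(k$couplets), visit, logical(1)))
}

#' Read a key from its JSON fixture format
#'
#' @param path JSON file with fields `name`, `root` and `couplets` (each
#'   couplet: `id`, `leads`; each lead: `tests` as two-element arrays,
#'   plus `couplet` or `taxon`).
#' @return a [key()].
#' @export
read_key <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  couplets <- lapply(j$couplets, function(cp) {
    list(id = cp$id, leads = lapply(cp$leads, function(ld) {
      out <- list(tests = lapply(ld$tests, function(t) {
        c(t[[1]], t[[2]])
      }))
      if (!is.null(ld$couplet)) out$couplet <- ld$couplet
      if (!is.null(ld$taxon)) out$taxon <- ld$taxon
      out
    }))
  })
  key(couplets, root = j$root, name = j$name %||% "")
}

#' Evaluate a key for one OTU
#'
#' At each couplet a lead is satisfied when every one of its tests matches
#' some coded state of the OTU (any-match under polymorphism). Exactly
#' one satisfiable lead is followed; zero or two satisfiable leads stop
#' the traversal with an ambiguity report listing the failing tests. A
#' test on a character the OTU is not coded for raises a cannot-evaluate
#' error naming the character.
#'
#' @param k a [key()].
#' @param s the companion study.
#' @param otu OTU id or taxon name.
#' @return list with `status` (`"identified"` or `"ambiguous"`), `taxon`
#'   (when identified), `path` (couplet ids traversed) and, when
#'   ambiguous, `report` describing each lead's failures.
#' @export
evaluate_key <- function(k, s, otu) {
  i <- match(otu, s$otus$id)
  if (is.na(i)) i <- match(otu, s$otus$taxon_name)
  assert_that(!is.na(i), sprintf("OTU '%s' absent from study", otu))
  otu_id <- s$otus$id[[i]]
  test_result <- function(t) {
    ch <- s$characters$id[match(t[[1]], s$characters$label)]
    assert_that(!is.na(ch),
                sprintf("cannot evaluate: key tests unknown character '%s'",
                        t[[1]]))
    coded <- study_state_labels(s, otu_id, ch)
    if (!length(coded)) {
      stop(sprintf("cannot evaluate: OTU '%s' has no coding for character '%s'",
                   s$otus$taxon_name[[i]], t[[1]]), call. = FALSE)
    }
    t[[2]] %in% coded
  }
  path <- character(0)
  node <- k$root
  repeat {
    path <- c(path, node)
    cp <- k$couplets[[node]]
    lead_eval <- lapply(cp$leads, function(ld) {
      res <- vapply(ld$tests, test_result, logical(1))
      list(satisfied = all(res),
           failing = ld$tests[!res])
    })
    sat <- vapply(lead_eval, `[[`, logical(1), "satisfied")
    if (sum(sat) != 1L) {
      return(list(status = "ambiguous", taxon = NA_character_,
                  path = path,
                  report = list(couplet = node, satisfied = sat,
                                failing = lapply(lead_eval, `[[`,
                                                 "failing"))))
    }
    ld <- cp$leads[[which(sat)]]
    if (!is.null(ld$taxon)) {
      return(list(status = "identified", taxon = ld$taxon, path = path))
    }
    node <- ld$couplet
  }
}

#' Verify a key against its companion study
#'
#' Evaluates every OTU through the key and reports whether each reaches
#' its own leaf uniquely. Cannot-evaluate errors are reported, not
#' raised.
#'
#' @param k a [key()].
#' @param s the companion study; every key leaf must name one of its
#'   OTUs.
#' @return data.frame (taxon_name, status, reached, ok) with attribute
#'   `consistent` (TRUE iff every OTU identifies as itself).
#' @export
verify_key <- function(k, s) {
  leaves <- unlist(lapply(k$couplets, function(cp) {
    unlist(lapply(cp$leads, `[[`, "taxon"))
  }))
  missing <- setdiff(leaves, s$otus$taxon_name)
  assert_that(length(missing) == 0L,
              sprintf("key leaves absent from study: %s",
                      paste(missing, collapse = ", ")))
  rows <- lapply(seq_len(nrow(s$otus)), function(i) {
    taxon <- s$otus$taxon_name[[i]]
    res <- tryCatch(evaluate_key(k, s, taxon), error = function(e) {
      list(status = "cannot_evaluate", taxon = NA_character_,
           message = conditionMessage(e))
    })
    data.frame(taxon_name = taxon, status = res$status,
               reached = res$taxon %||% NA_character_,
               ok = identical(res$taxon, taxon), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "consistent") <- all(out$ok)
  out
}
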