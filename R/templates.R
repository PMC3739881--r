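# EQ phenotype templates.
#
# Four template structures cover the character forms of the matrix:
# qualitative (a nested has_part locator chain whose innermost entity
# bears a quality), presence/absence, count (exact cardinality on
# has_part) and relative measurement (a quality with a towards-style
# filler, plus a documenting rule). Template matching is most-specific
# first: count, then relative measurement, then presence/absence, then
# qualitative; anything else is nonstandard.

#' Compose a qualitative EQ expression
#'
#' `chain` lists the locator classes outermost secondary locator first and
#' the primary locator (the quality-bearing entity) last. The result is
#' `has_part some (L1 and has_part some (... and bearer_of some Q))`; a
#' length-1 chain gives `has_part some (E and bearer_of some Q)`.
#'
#' @param chain character vector of anatomical class IRIs (length >= 1).
#' @param quality IRI of the quality class.
#' @param config a [sempheno_config()].
#' @return a class expression.
#' @export
compose_qualitative <- function(chain, quality,
                                config = sempheno_config()) {
  assert_that(length(chain) >= 1L, "locator chain must be non-empty")
  pr <- config$properties
  build <- function(k) {
    inner <- if (k == length(chain)) {
      ce_some(pr$bearer_of, ce_named(quality))
    } else {
      build(k + 1L)
    }
    ce_some(pr$has_part, ce_and(ce_named(chain[[k]]), inner))
  }
  build(1L)
}

#' Compose a presence/absence EQ expression
#'
#' Presence: a nested has_part chain ending `has_part some E`. Absence
#' carries no negation: the quality `absent` is borne by the innermost
#' containing structure (by the organism itself when the chain has length
#' 1), and the missing part is recorded machine-readably in the
#' `absent_part` attribute of the returned expression, which
#' [annotate_state()] copies onto the phenotype.
#'
#' @param chain character vector of class IRIs, the described (possibly
#'   missing) part last.
#' @param present logical flag.
#' @param config a [sempheno_config()].
#' @return a class expression (with an `absent_part` attribute for
#'   absences).
#' @export
compose_presence_absence <- function(chain, present,
                                     config = sempheno_config()) {
  assert_that(length(chain) >= 1L, "locator chain must be non-empty")
  pr <- config$properties
  if (isTRUE(present)) {
    build <- function(k) {
      if (k == length(chain)) return(ce_some(pr$has_part,
                                             ce_named(chain[[k]])))
      ce_some(pr$has_part, ce_and(ce_named(chain[[k]]), build(k + 1L)))
    }
    return(build(1L))
  }
  part <- chain[[length(chain)]]
  containers <- chain[-length(chain)]
  expr <- if (!length(containers)) {
    ce_some(pr$bearer_of, ce_named(pr$absent))
  } else {
    build <- function(k) {
      inner <- if (k == length(containers)) {
        ce_some(pr$bearer_of, ce_named(pr$absent))
      } else {
        build(k + 1L)
      }
      ce_some(pr$has_part, ce_and(ce_named(containers[[k]]), inner))
    }
    build(1L)
  }
  attr(expr, "absent_part") <- part
  expr
}

#' Compose a count EQ expression
#'
#' @param chain character vector of class IRIs of the structure bearing
#'   the counted parts (outermost first).
#' @param counted IRI of the counted part class.
#' @param n non-negative integer count.
#' @param config a [sempheno_config()].
#' @return a class expression ending in
#'   `has_part exactly n counted`.
#' @export
compose_count <- function(chain, counted, n, config = sempheno_config()) {
  assert_that(length(chain) >= 1L, "locator chain must be non-empty")
  assert_that(is.numeric(n) && length(n) == 1L && n >= 0 &&
                n == as.integer(n), "count must be a non-negative integer")
  pr <- config$properties
  build <- function(k) {
    inner <- if (k == length(chain)) {
      ce_exactly(pr$has_part, as.integer(n), ce_named(counted))
    } else {
      build(k + 1L)
    }
    ce_some(pr$has_part, ce_and(ce_named(chain[[k]]), inner))
  }
  build(1L)
}

#' Compose a relative-measurement EQ expression and its rule
#'
#' The class expression
#' `has_part some (e1 and bearer_of some (quality and towards some e2))`
#' cannot bind the compared structure to the same organism (an OWL
#' tree-model limitation: an antenna need only be longer than at least
#' one eye in the world); the returned rule documents the intended
#' semantics — if an organism has parts x:e1 and y:e2 with the
#' direction's magnitude relation between them, the organism belongs to
#' the phenotype class. The rule head uses a placeholder class that
#' [annotate_state()] replaces with the minted phenotype class.
#'
#' @param e1,e2 IRIs of the compared entity classes.
#' @param quality IRI of the compared quality (e.g. length).
#' @param direction `"increased"`, `"decreased"` or `"equal"`.
#' @param config a [sempheno_config()].
#' @return list with elements `expression` and `rule`; a degenerate
#'   self-comparison (`direction = "equal"`, `e1 == e2`) is accepted and
#'   flagged via the `degenerate` element.
#' @export
compose_relative <- function(e1, quality, e2,
                             direction = c("increased", "decreased",
                                           "equal"),
                             config = sempheno_config()) {
  direction <- match.arg(direction)
  assert_that(e1 != e2 || direction == "equal",
              "distinct entities required unless direction is 'equal'")
  pr <- config$properties
  rel <- switch(direction, increased = pr$increased,
                decreased = pr$decreased, equal = pr$equal)
  expr <- ce_some(pr$has_part, ce_and(
    ce_named(e1),
    ce_some(pr$bearer_of, ce_and(ce_named(quality),
                                 ce_some(pr$towards, ce_named(e2))))
  ))
  head_placeholder <- phenotype_placeholder(config)
  rl <- rule(
    body = list(
      list(type = "property", property = pr$has_part, var1 = "o",
           var2 = "x"),
      list(type = "property", property = pr$has_part, var1 = "o",
           var2 = "y"),
      list(type = "class", var = "x", class = e1),
      list(type = "class", var = "y", class = e2),
      list(type = "property", property = rel, var1 = "x", var2 = "y")
    ),
    head = list(type = "class", var = "o", class = head_placeholder)
  )
  list(expression = expr, rule = rl,
       degenerate = direction == "equal" && e1 == e2)
}

phenotype_placeholder <- function(config) {
  iri_expand("sp:PhenotypeClassPlaceholder", config$prefixes)
}

# -- template classification -------------------------------------------------

# chain body: final(X), or And(Named L, rest) where rest is final or a
# deeper has_part link.
match_chain <- function(e, final, has_part) {
  if (e$kind != "some" || e$property != has_part) return(FALSE)
  body <- function(x) {
    if (final(x)) return(TRUE)
    if (x$kind == "and" && length(x$args) == 2L &&
        x$args[[1]]$kind == "named") {
      tailp <- x$args[[2]]
      if (final(tailp)) return(TRUE)
      if (tailp$kind == "some" && tailp$property == has_part) {
        return(body(tailp$filler))
      }
    }
    FALSE
  }
  body(e$filler)
}

#' Classify an EQ expression into its template category
#'
#' Structural match against the four template grammars, most specific
#' first (count, relative measurement, presence/absence, qualitative);
#' expressions matching none are `"nonstandard"`. Deterministic; matching
#' precedence cannot be ambiguous because count requires an exact
#' cardinality, relative measurement requires the towards-style nesting,
#' and absence is keyed to the configured `absent` quality.
#'
#' @param expr a class expression.
#' @param config a [sempheno_config()].
#' @return one of `"count"`, `"relative_measurement"`,
#'   `"presence_absence"`, `"qualitative"`, `"nonstandard"`.
#' @export
classify_template <- function(expr, config = sempheno_config()) {
  pr <- config$properties
  hp <- pr$has_part
  final_count <- function(x) {
    x$kind == "exactly" && x$property == hp && x$filler$kind == "named"
  }
  final_relative <- function(x) {
    x$kind == "some" && x$property == pr$bearer_of &&
      x$filler$kind == "and" && length(x$filler$args) == 2L &&
      x$filler$args[[1]]$kind == "named" &&
      x$filler$args[[2]]$kind == "some" &&
      x$filler$args[[2]]$property == pr$towards &&
      x$filler$args[[2]]$filler$kind == "named"
  }
  final_absent <- function(x) {
    x$kind == "some" && x$property == pr$bearer_of &&
      x$filler$kind == "named" && x$filler$iri == pr$absent
  }
  final_presence <- function(x) x$kind == "named"
  final_quality <- function(x) {
    x$kind == "some" && x$property == pr$bearer_of &&
      x$filler$kind == "named" && x$filler$iri != pr$absent
  }
  if (match_chain(expr, final_count, hp)) return("count")
  if (match_chain(expr, final_relative, hp)) return("relative_measurement")
  if (final_absent(expr)) return("presence_absence")  # chain of length 1
  if (match_chain(expr, final_absent, hp)) return("presence_absence")
  if (match_chain(expr, final_presence, hp)) return("presence_absence")
  if (match_chain(expr, final_quality, hp)) return("qualitative")
  "nonstandard"
}

#' Annotate a character state with a phenotype definition
#'
#' Mints the phenotype class P deterministically from the state IRI
#' (suffix `#phenotype`), asserts `P SubClassOf definition` (subclass,
#' never equivalence: the EQ expression gives necessary, not sufficient,
#' conditions) and `state Type (denotes only P)`, stores the annotation
#' on the study and records the generated axioms on the annotation.
#'
#' @param s a study.
#' @param state a state IRI, or a `"Character label: state label"` string.
#' @param definition the defining class expression (or Manchester text,
#'   parsed against `labels`).
#' @param config a [sempheno_config()].
#' @param ontology optional ontology; when given, the definition is
#'   validated against its declared classes and properties, and its labels
#'   are used to parse Manchester text.
#' @param rule optional [rule()] for relative-measurement states; the
#'   placeholder head class is rewritten to the minted P.
#' @param replace set TRUE to re-annotate an already-annotated state
#'   (otherwise an error).
#' @return the updated study; the new annotation (with its `axioms`) is
#'   stored under the state id.
#' @export
annotate_state <- function(s, state, definition,
                           config = sempheno_config(), ontology = NULL,
                           rule = NULL, replace = FALSE) {
  state_id <- resolve_state(s, state)
  if (state_id %in% names(s$annotations) && !isTRUE(replace)) {
    stop(sprintf("state '%s' is already annotated (set replace = TRUE)",
                 state), call. = FALSE)
  }
  if (is.character(definition)) {
    labels <- if (!is.null(ontology)) ontology_labels(ontology) else NULL
    definition <- parse_manchester(definition, config$prefixes, labels)
  }
  if (!is.null(ontology)) {
    known <- c(ontology$classes$iri, builtin_terms(ontology$prefixes))
    miss <- setdiff(ce_classes(definition), known)
    assert_that(length(miss) == 0L,
                sprintf("definition references undeclared classes: %s",
                        paste(miss, collapse = ", ")))
  }
  p_iri <- paste0(state_id, "#phenotype")
  template <- classify_template(definition, config)
  if (!is.null(rule)) {
    rule$head$class <- p_iri
    assert_that(template == "relative_measurement",
                "rules accompany relative-measurement phenotypes only")
  }
  axioms <- list(
    axiom_subclass(ce_named(p_iri), definition),
    axiom_class_assertion(state_id,
                          ce_only(config$properties$denotes,
                                  ce_named(p_iri)))
  )
  s$annotations[[state_id]] <- list(
    state = state_id, phenotype = p_iri, definition = definition,
    template = template, rule = rule,
    absent_part = attr(definition, "absent_part", exact = TRUE),
    axioms = axioms
  )
  s
}

resolve_state <- function(s, state) {
  if (state %in% s$states$id) return(state)
  m <- regmatches(state, regexec("^(.*): (.*)$", state))[[1]]
  if (length(m) == 3L) {
    ch <- s$characters$id[match(m[[2]], s$characters$label)]
    if (!is.na(ch)) {
      i <- which(s$states$character_id == ch & s$states$label == m[[3]])
      if (length(i) == 1L) return(s$states$id[[i]])
    }
  }
  stop(sprintf("unknown state '%s'", state), call. = FALSE)
}

#' Annotate states from a tabular batch
#'
#' @param s a study.
#' @param table data.frame with columns `state` (IRI or
#'   `"Character label: state label"`) and `expression` (Manchester text),
#'   or a path to a TSV file with those columns.
#' @param config,ontology,replace see [annotate_state()].
#' @return the updated study.
#' @export
annotate_states_table <- function(s, table, config = sempheno_config(),
                                  ontology = NULL, replace = FALSE) {
  if (is.character(table)) {
    table <- utils::read.delim(table, colClasses = "character",
                               check.names = FALSE)
  }
  for (i in seq_len(nrow(table))) {
    s <- annotate_state(s, table$state[[i]], table$expression[[i]],
                        config = config, ontology = ontology,
                        replace = replace)
  }
  s
}
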