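# Ontology container: class and property declarations, axioms, rules.

#' Declare an ontology class
#'
#' @param iri absolute IRI.
#' @param label display label (defaults to the IRI fragment with
#'   underscores replaced by spaces).
#' @return a one-row data.frame (iri, label).
#' @export
ont_class <- function(iri, label = NULL) {
  assert_that(is_string(iri), "class IRI required")
  data.frame(iri = iri, label = label %||% local_name(iri),
             stringsAsFactors = FALSE)
}

#' Declare an object property
#'
#' @param iri absolute IRI.
#' @param label display label.
#' @param transitive whether the property is transitive.
#' @return a one-row data.frame (iri, label, transitive).
#' @export
ont_property <- function(iri, label = NULL, transitive = FALSE) {
  assert_that(is_string(iri), "property IRI required")
  data.frame(iri = iri, label = label %||% local_name(iri),
             transitive = isTRUE(transitive), stringsAsFactors = FALSE)
}

local_name <- function(iri) {
  gsub("_", " ", sub("^.*[#/]", "", iri))
}

# --- axioms -----------------------------------------------------------------

axiom_subclass <- function(sub, sup) {
  assert_that(is_ce(sub) && is_ce(sup), "subclass axiom requires expressions")
  structure(list(type = "subclass", sub = sub, sup = sup),
            class = "sempheno_axiom")
}

axiom_class_assertion <- function(individual, expr) {
  assert_that(is_string(individual), "individual IRI required")
  assert_that(is_ce(expr), "class assertion requires an expression")
  structure(list(type = "class_assertion", individual = individual,
                 expr = expr), class = "sempheno_axiom")
}

axiom_property_assertion <- function(subject, property, object) {
  assert_that(is_string(subject) && is_string(property) && is_string(object),
              "property assertion requires subject/property/object IRIs")
  structure(list(type = "property_assertion", subject = subject,
                 property = property, object = object),
            class = "sempheno_axiom")
}

# --- rules ------------------------------------------------------------------

#' Build a rule (relative-measurement documentation)
#'
#' Rules are stored and serialized but never fired during ordinary
#' reasoning; they document the intended semantics of relative-measurement
#' phenotypes, which OWL class expressions cannot fully capture. A class
#' atom is `list(type = "class", var, class)`; a property atom is
#' `list(type = "property", property, var1, var2)`.
#'
#' @param body list of atoms.
#' @param head a single class atom whose variable appears in the body.
#' @return an object of class `sempheno_rule`.
#' @export
rule <- function(body, head) {
  assert_that(is.list(body) && length(body) >= 1L, "rule body required")
  assert_that(is.list(head) && identical(head$type, "class"),
              "rule head must be a class atom")
  body_vars <- unlist(lapply(body, function(a) {
    if (a$type == "class") a$var else c(a$var1, a$var2)
  }))
  assert_that(head$var %in% body_vars,
              "head variable must appear in the rule body")
  structure(list(body = body, head = head,
                 variables = sort_c(unique(c(body_vars, head$var)))),
            class = "sempheno_rule")
}

# --- ontology ---------------------------------------------------------------

#' Assemble an ontology
#'
#' Enforces referential closure: every class or property IRI referenced by
#' an axiom or rule must be declared (individuals named in assertions are
#' exempt, as are a handful of built-in OWL/RDF terms).
#'
#' @param classes data.frame with columns iri, label (rows from
#'   [ont_class()]).
#' @param properties data.frame with columns iri, label, transitive.
#' @param axioms list of axiom objects.
#' @param rules list of [rule()] objects.
#' @param prefixes prefix map.
#' @param chains named list of property chains; each element is a character
#'   vector of step property IRIs and its name the entailed property IRI.
#' @return an object of class `sempheno_ontology`.
#' @export
ontology <- function(classes = NULL, properties = NULL, axioms = list(),
                     rules = list(), prefixes = sempheno_prefixes(),
                     chains = list()) {
  empty_cls <- data.frame(iri = character(0), label = character(0),
                          stringsAsFactors = FALSE)
  empty_prp <- data.frame(iri = character(0), label = character(0),
                          transitive = logical(0), stringsAsFactors = FALSE)
  classes <- classes %||% empty_cls
  properties <- properties %||% empty_prp
  validate_prefix_map(prefixes)
  assert_that(!anyDuplicated(classes$iri), "duplicate class IRIs")
  assert_that(!anyDuplicated(properties$iri), "duplicate property IRIs")
  for (ch in chains) {
    assert_that(length(ch) >= 2L, "chain axioms must have length >= 2")
  }
  o <- structure(
    list(classes = classes, properties = properties, axioms = axioms,
         rules = rules, prefixes = prefixes, chains = chains),
    class = "sempheno_ontology"
  )
  validate_ontology(o)
  o
}

builtin_terms <- function(prefixes = sempheno_prefixes()) {
  c(iri_expand("owl:Thing", prefixes), iri_expand("owl:Nothing", prefixes))
}

validate_ontology <- function(o) {
  known_cls <- c(o$classes$iri, builtin_terms(o$prefixes))
  known_prp <- o$properties$iri
  check_expr <- function(e, where) {
    miss_c <- setdiff(ce_classes(e), known_cls)
    miss_p <- setdiff(ce_properties(e), known_prp)
    if (length(miss_c) || length(miss_p)) {
      stop(sprintf("undeclared IRIs in %s: %s", where,
                   paste(c(miss_c, miss_p), collapse = ", ")), call. = FALSE)
    }
  }
  for (ax in o$axioms) {
    switch(ax$type,
      subclass = {
        check_expr(ax$sub, "subclass axiom")
        check_expr(ax$sup, "subclass axiom")
      },
      class_assertion = check_expr(ax$expr, "class assertion"),
      property_assertion = {
        if (!ax$property %in% known_prp) {
          stop(sprintf("undeclared property '%s' in property assertion",
                       ax$property), call. = FALSE)
        }
      }
    )
  }
  for (r in o$rules) {
    for (a in c(r$body, list(r$head))) {
      if (a$type == "class" && !a$class %in% known_cls) {
        stop(sprintf("undeclared class '%s' in rule", a$class), call. = FALSE)
      }
      if (a$type == "property" && !a$property %in% known_prp) {
        stop(sprintf("undeclared property '%s' in rule", a$property),
             call. = FALSE)
      }
    }
  }
  for (i in seq_along(o$chains)) {
    entailed <- names(o$chains)[i]
    for (p in c(entailed, o$chains[[i]])) {
      if (!p %in% known_prp) {
        stop(sprintf("undeclared property '%s' in chain axiom", p),
             call. = FALSE)
      }
    }
  }
  invisible(o)
}

#' Label lookup table of an ontology
#'
#' @param o an ontology.
#' @return named character vector label -> IRI, suitable for
#'   [parse_manchester()] / [render_manchester()].
#' @export
ontology_labels <- function(o) {
  structure(c(o$classes$iri, o$properties$iri),
            names = c(o$classes$label, o$properties$label))
}

#' Source-ontology tag for an IRI
#'
#' @param iri class IRI.
#' @param namespace_map named character vector namespace -> tag.
#' @return the tag, or `"unknown"` when no namespace matches.
#' @export
source_tag <- function(iri, namespace_map) {
  hit <- startsWith(iri, names(namespace_map))
  if (any(hit)) unname(namespace_map[hit][1]) else "unknown"
}

#' @export
print.sempheno_ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d classes, %d properties, %d axioms, %d rules\n",
              nrow(x$classes), nrow(x$properties), length(x$axioms),
              length(x$rules)))
  invisible(x)
}
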