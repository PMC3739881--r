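# Prefix, namespace and property configuration.
#
# Concrete ontology IRIs drift across releases, so every property the model
# depends on (has_part, part_of, bearer_of, denotes, the towards-style and
# magnitude-relation properties, and the three steps of the denotes chain)
# is a configuration entry that can be remapped to real HAO/PATO/RO/CDAO/IAO
# IRIs without touching code.

#' Default prefix map
#'
#' The packaged fixtures emulate HAO/PATO/BSPO-style ontologies under
#' `example.com` mini namespaces; they are synthetic stand-ins, not the real
#' ontologies.
#'
#' @return named character vector, prefix -> namespace IRI.
#' @export
sempheno_prefixes <- function() {
  c(
    ex    = "http://example.com/study/",
    hao   = "http://example.com/mini-hao#",
    pato  = "http://example.com/mini-pato#",
    bspo  = "http://example.com/mini-bspo#",
    ro    = "http://example.com/mini-ro#",
    cdao  = "http://example.com/mini-cdao#",
    dsw   = "http://example.com/mini-dsw#",
    iao   = "http://example.com/mini-iao#",
    sp    = "http://example.com/sempheno/vocab#",
    rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
    owl   = "http://www.w3.org/2002/07/owl#",
    xsd   = "http://www.w3.org/2001/XMLSchema#"
  )
}

#' Package configuration: prefixes, namespace buckets, model properties
#'
#' @param prefixes prefix map (see [sempheno_prefixes()]).
#' @param namespace_map named character vector mapping namespace IRI to a
#'   source-ontology tag (used to bucket class-usage counts).
#' @param properties named list of absolute property/class IRIs used by the
#'   model; missing entries fall back to defaults derived from `prefixes`.
#' @param transitive character vector of transitive property IRIs.
#' @param chains named list; each element is a character vector of property
#'   IRIs (length >= 2) whose composition entails the property named by the
#'   element (the denotes chain is configured here by default; has_part over
#'   part_of folding is off unless added explicitly).
#' @return a list of class `sempheno_config`.
#' @export
sempheno_config <- function(prefixes = sempheno_prefixes(),
                            namespace_map = NULL,
                            properties = list(),
                            transitive = NULL,
                            chains = NULL) {
  validate_prefix_map(prefixes)
  p <- function(x) iri_expand(x, prefixes)
  defaults <- list(
    has_part   = p("ro:has_part"),
    part_of    = p("ro:part_of"),
    bearer_of  = p("ro:bearer_of"),
    towards    = p("ro:towards"),
    increased  = p("ro:increased_in_magnitude_relative_to"),
    decreased  = p("ro:decreased_in_magnitude_relative_to"),
    equal      = p("ro:similar_in_magnitude_relative_to"),
    denotes    = p("iao:denotes"),
    has_state  = p("cdao:has_state"),
    state_of   = p("cdao:state_of"),
    belongs_to_tu = p("cdao:belongs_to_TU"),
    top        = p("owl:Thing"),
    absent     = p("pato:absent"),
    quality_root = p("pato:quality")
  )
  props <- utils::modifyList(defaults, properties)
  if (is.null(namespace_map)) {
    namespace_map <- c(
      structure("HAO", names = prefixes[["hao"]]),
      structure("PATO", names = prefixes[["pato"]]),
      structure("BSPO", names = prefixes[["bspo"]]),
      structure("CDAO", names = prefixes[["cdao"]]),
      structure("RO", names = prefixes[["ro"]]),
      structure("IAO", names = prefixes[["iao"]])
    )
  }
  if (is.null(transitive)) {
    transitive <- c(props$part_of, props$has_part)
  }
  if (is.null(chains)) {
    # state -(state_of)-> coding -(belongs_to_TU)-> TU -(denotes)-> specimen
    # entails state -(denotes)-> specimen.
    chains <- list()
    chains[[props$denotes]] <-
      c(props$state_of, props$belongs_to_tu, props$denotes)
  }
  for (ch in chains) {
    assert_that(length(ch) >= 2L, "chain axioms must have length >= 2")
  }
  structure(
    list(prefixes = prefixes, namespace_map = namespace_map,
         properties = props, transitive = transitive, chains = chains),
    class = "sempheno_config"
  )
}

#' Read a configuration from a JSON file
#'
#' The file may contain any of the fields `prefixes` (object of
#' prefix -> either a namespace string or `{namespace, source}`),
#' `properties`, `transitive`, `chains`.
#'
#' @param path path to a JSON config file.
#' @return a `sempheno_config` object.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  prefixes <- sempheno_prefixes()
  namespace_map <- NULL
  if (!is.null(cfg$prefixes)) {
    ns <- vapply(cfg$prefixes, function(x) {
      if (is.list(x)) x$namespace else x
    }, character(1))
    prefixes <- structure(ns, names = names(cfg$prefixes))
    src <- lapply(cfg$prefixes, function(x) if (is.list(x)) x$source else NULL)
    keep <- !vapply(src, is.null, logical(1))
    if (any(keep)) {
      namespace_map <- structure(unlist(src[keep]), names = ns[keep])
    }
  }
  sempheno_config(
    prefixes = prefixes,
    namespace_map = namespace_map,
    properties = lapply(cfg$properties %||% list(), unlist),
    transitive = unlist(cfg$transitive %||% NULL),
    chains = lapply(cfg$chains %||% NULL, unlist)
  )
}
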