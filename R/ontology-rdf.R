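# Ontology <-> RDF graph mapping.
#
# Class expressions use the standard OWL 2 RDF mapping (owl:Restriction,
# owl:intersectionOf / owl:unionOf with expanded rdf:first/rdf:rest lists,
# owl:qualifiedCardinality + owl:onClass). Rules use a minimal documented
# vocabulary under the sp: namespace (reified body/head atoms) rather than
# SWRL/XML: in this data model rules are declarative documentation of
# relative-measurement semantics and are never fired by default.

rdf_terms <- function(prefixes) {
  p <- function(x) iri_expand(x, prefixes)
  list(
    type = p("rdf:type"), first = p("rdf:first"), rest = p("rdf:rest"),
    nil = p("rdf:nil"), label = p("rdfs:label"),
    subclassof = p("rdfs:subClassOf"),
    owl_class = p("owl:Class"), objprop = p("owl:ObjectProperty"),
    transprop = p("owl:TransitiveProperty"),
    restriction = p("owl:Restriction"), on_property = p("owl:onProperty"),
    some = p("owl:someValuesFrom"), only = p("owl:allValuesFrom"),
    qcard = p("owl:qualifiedCardinality"), on_class = p("owl:onClass"),
    intersection = p("owl:intersectionOf"), union = p("owl:unionOf"),
    chain = p("owl:propertyChainAxiom"),
    nni = p("xsd:nonNegativeInteger"),
    rule = p("sp:Rule"), rule_body = p("sp:body"), rule_head = p("sp:head"),
    class_atom = p("sp:ClassAtom"), prop_atom = p("sp:PropertyAtom"),
    predicate = p("sp:predicate"), var = p("sp:var"),
    var1 = p("sp:var1"), var2 = p("sp:var2")
  )
}

new_blank_counter <- function(prefix = "b") {
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  function() {
    env$i <- env$i + 1L
    sprintf("_:%s%d", prefix, env$i)
  }
}

triple_sink <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  list(
    add = function(s, p, o, otype = "iri", dt = NA_character_) {
      env$rows[[length(env$rows) + 1L]] <- list(s = s, p = p, o = o,
                                                otype = otype, dt = dt)
    },
    graph = function() {
      if (!length(env$rows)) return(rdf_graph())
      rdf_graph(
        s = vapply(env$rows, `[[`, character(1), "s"),
        p = vapply(env$rows, `[[`, character(1), "p"),
        o = vapply(env$rows, `[[`, character(1), "o"),
        otype = vapply(env$rows, `[[`, character(1), "otype"),
        dt = vapply(env$rows, function(r) as.character(r$dt), character(1))
      )
    }
  )
}

emit_list <- function(items, sink, terms, gensym) {
  if (!length(items)) return(terms$nil)
  head_node <- gensym()
  node <- head_node
  for (i in seq_along(items)) {
    it <- items[[i]]
    sink$add(node, terms$first, it$value, it$otype)
    nxt <- if (i < length(items)) gensym() else terms$nil
    sink$add(node, terms$rest, nxt, if (i < length(items)) "blank" else "iri")
    node <- nxt
  }
  head_node
}

expr_to_node <- function(e, sink, terms, gensym) {
  node_of <- function(x) {
    n <- expr_to_node(x, sink, terms, gensym)
    list(value = n, otype = if (is_blank(n)) "blank" else "iri")
  }
  switch(e$kind,
    named = e$iri,
    and = ,
    or = {
      b <- gensym()
      sink$add(b, terms$type, terms$owl_class)
      lst <- emit_list(lapply(e$args, node_of), sink, terms, gensym)
      pred <- if (e$kind == "and") terms$intersection else terms$union
      sink$add(b, pred, lst, if (is_blank(lst)) "blank" else "iri")
      b
    },
    some = ,
    only = {
      b <- gensym()
      sink$add(b, terms$type, terms$restriction)
      sink$add(b, terms$on_property, e$property)
      f <- node_of(e$filler)
      pred <- if (e$kind == "some") terms$some else terms$only
      sink$add(b, pred, f$value, f$otype)
      b
    },
    exactly = {
      b <- gensym()
      sink$add(b, terms$type, terms$restriction)
      sink$add(b, terms$on_property, e$property)
      sink$add(b, terms$qcard, as.character(e$n), "literal", terms$nni)
      f <- node_of(e$filler)
      sink$add(b, terms$on_class, f$value, f$otype)
      b
    }
  )
}

# Reconstruct a class expression from its RDF node.
node_to_expr <- function(node, g, terms) {
  objs <- function(s, p) g[g$s == s & g$p == p, , drop = FALSE]
  read_list <- function(node) {
    out <- list()
    while (node != terms$nil) {
      f <- objs(node, terms$first)
      assert_that(nrow(f) == 1L, "malformed RDF list")
      out[[length(out) + 1L]] <- f$o[[1]]
      r <- objs(node, terms$rest)
      assert_that(nrow(r) == 1L, "malformed RDF list")
      node <- r$o[[1]]
    }
    out
  }
  if (!is_blank(node)) return(ce_named(node))
  inter <- objs(node, terms$intersection)
  if (nrow(inter)) {
    return(ce_and(lapply(read_list(inter$o[[1]]), node_to_expr, g = g,
                         terms = terms)))
  }
  uni <- objs(node, terms$union)
  if (nrow(uni)) {
    return(ce_or(lapply(read_list(uni$o[[1]]), node_to_expr, g = g,
                        terms = terms)))
  }
  prop <- objs(node, terms$on_property)
  assert_that(nrow(prop) == 1L, "unserializable expression node")
  sv <- objs(node, terms$some)
  if (nrow(sv)) {
    return(ce_some(prop$o[[1]], node_to_expr(sv$o[[1]], g, terms)))
  }
  av <- objs(node, terms$only)
  if (nrow(av)) {
    return(ce_only(prop$o[[1]], node_to_expr(av$o[[1]], g, terms)))
  }
  qc <- objs(node, terms$qcard)
  if (nrow(qc)) {
    oc <- objs(node, terms$on_class)
    assert_that(nrow(oc) == 1L, "qualified cardinality without onClass")
    return(ce_exactly(prop$o[[1]], as.integer(qc$o[[1]]),
                      node_to_expr(oc$o[[1]], g, terms)))
  }
  stop("unsupported restriction node in RDF input", call. = FALSE)
}

ontology_to_graph <- function(o) {
  terms <- rdf_terms(o$prefixes)
  sink <- triple_sink()
  gensym <- new_blank_counter()
  for (i in seq_len(nrow(o$classes))) {
    iri <- o$classes$iri[[i]]
    sink$add(iri, terms$type, terms$owl_class)
    sink$add(iri, terms$label, o$classes$label[[i]], "literal")
  }
  for (i in seq_len(nrow(o$properties))) {
    iri <- o$properties$iri[[i]]
    sink$add(iri, terms$type, terms$objprop)
    sink$add(iri, terms$label, o$properties$label[[i]], "literal")
    if (o$properties$transitive[[i]]) {
      sink$add(iri, terms$type, terms$transprop)
    }
  }
  for (i in seq_along(o$chains)) {
    steps <- lapply(o$chains[[i]], function(x) list(value = x, otype = "iri"))
    lst <- emit_list(steps, sink, terms, gensym)
    sink$add(names(o$chains)[[i]], terms$chain, lst, "blank")
  }
  for (ax in o$axioms) {
    switch(ax$type,
      subclass = {
        sub_n <- expr_to_node(ax$sub, sink, terms, gensym)
        sup_n <- expr_to_node(ax$sup, sink, terms, gensym)
        sink$add(sub_n, terms$subclassof, sup_n,
                 if (is_blank(sup_n)) "blank" else "iri")
      },
      class_assertion = {
        n <- expr_to_node(ax$expr, sink, terms, gensym)
        sink$add(ax$individual, terms$type, n,
                 if (is_blank(n)) "blank" else "iri")
      },
      property_assertion = {
        sink$add(ax$subject, ax$property, ax$object)
      }
    )
  }
  for (r in o$rules) {
    rb <- gensym()
    sink$add(rb, terms$type, terms$rule)
    emit_atom <- function(a, pred) {
      ab <- gensym()
      if (a$type == "class") {
        sink$add(ab, terms$type, terms$class_atom)
        sink$add(ab, terms$predicate, a$class)
        sink$add(ab, terms$var, a$var, "literal")
      } else {
        sink$add(ab, terms$type, terms$prop_atom)
        sink$add(ab, terms$predicate, a$property)
        sink$add(ab, terms$var1, a$var1, "literal")
        sink$add(ab, terms$var2, a$var2, "literal")
      }
      sink$add(rb, pred, ab, "blank")
    }
    for (a in r$body) emit_atom(a, terms$rule_body)
    emit_atom(r$head, terms$rule_head)
  }
  sink$graph()
}

graph_to_ontology <- function(g, prefixes) {
  terms <- rdf_terms(prefixes)
  decl_of <- function(type_iri) {
    sort_c(unique(g$s[g$p == terms$type & g$o == type_iri & !is_blank(g$s)]))
  }
  label_of <- function(iri) {
    hit <- g$o[g$s == iri & g$p == terms$label & g$otype == "literal"]
    if (length(hit)) hit[[1]] else local_name(iri)
  }
  cls <- decl_of(terms$owl_class)
  prp <- decl_of(terms$objprop)
  trans <- decl_of(terms$transprop)
  classes <- if (length(cls)) {
    do.call(rbind, lapply(cls, function(x) ont_class(x, label_of(x))))
  } else NULL
  properties <- if (length(prp)) {
    do.call(rbind, lapply(prp, function(x) {
      ont_property(x, label_of(x), transitive = x %in% trans)
    }))
  } else NULL
  read_list <- function(node) {
    out <- character(0)
    while (node != terms$nil) {
      out <- c(out, g$o[g$s == node & g$p == terms$first][[1]])
      node <- g$o[g$s == node & g$p == terms$rest][[1]]
    }
    out
  }
  chains <- list()
  ch_rows <- g[g$p == terms$chain, , drop = FALSE]
  for (i in seq_len(nrow(ch_rows))) {
    chains[[length(chains) + 1L]] <- read_list(ch_rows$o[[i]])
    names(chains)[length(chains)] <- ch_rows$s[[i]]
  }
  axioms <- list()
  sc_rows <- g[g$p == terms$subclassof, , drop = FALSE]
  for (i in seq_len(nrow(sc_rows))) {
    axioms[[length(axioms) + 1L]] <- axiom_subclass(
      node_to_expr(sc_rows$s[[i]], g, terms),
      node_to_expr(sc_rows$o[[i]], g, terms)
    )
  }
  decl_types <- c(terms$owl_class, terms$objprop, terms$transprop,
                  terms$restriction, terms$rule, terms$class_atom,
                  terms$prop_atom)
  ty_rows <- g[g$p == terms$type & !is_blank(g$s) &
                 !g$o %in% decl_types & !g$s %in% c(cls, prp), , drop = FALSE]
  for (i in seq_len(nrow(ty_rows))) {
    axioms[[length(axioms) + 1L]] <- axiom_class_assertion(
      ty_rows$s[[i]], node_to_expr(ty_rows$o[[i]], g, terms)
    )
  }
  pa_rows <- g[g$p %in% prp & !is_blank(g$s) & g$otype == "iri", ,
               drop = FALSE]
  for (i in seq_len(nrow(pa_rows))) {
    axioms[[length(axioms) + 1L]] <- axiom_property_assertion(
      pa_rows$s[[i]], pa_rows$p[[i]], pa_rows$o[[i]]
    )
  }
  rules <- list()
  read_atom <- function(node) {
    ty <- g$o[g$s == node & g$p == terms$type][[1]]
    pred <- g$o[g$s == node & g$p == terms$predicate][[1]]
    if (ty == terms$class_atom) {
      list(type = "class", var = g$o[g$s == node & g$p == terms$var][[1]],
           class = pred)
    } else {
      list(type = "property", property = pred,
           var1 = g$o[g$s == node & g$p == terms$var1][[1]],
           var2 = g$o[g$s == node & g$p == terms$var2][[1]])
    }
  }
  for (rnode in decl_of2(g, terms$type, terms$rule)) {
    body_nodes <- sort_c(g$o[g$s == rnode & g$p == terms$rule_body])
    head_node <- g$o[g$s == rnode & g$p == terms$rule_head][[1]]
    rules[[length(rules) + 1L]] <- rule(lapply(body_nodes, read_atom),
                                        read_atom(head_node))
  }
  ontology(classes = classes, properties = properties, axioms = axioms,
           rules = rules, prefixes = prefixes, chains = chains)
}

decl_of2 <- function(g, type_pred, type_iri) {
  sort_c(unique(g$s[g$p == type_pred & g$o == type_iri]))
}

#' Serialize an ontology to Turtle or RDF/XML
#'
#' Round trip: [load_rdf()] on the output yields an ontology whose RDF
#' graph is isomorphic to the input's (blank-node renaming allowed).
#'
#' @param o a [ontology()] object.
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @param path optional output file; when NULL the serialization is
#'   returned as a string.
#' @return the serialized text (invisibly when `path` is given).
#' @export
write_rdf <- function(o, dialect = c("turtle", "rdfxml"), path = NULL) {
  dialect <- match.arg(dialect)
  g <- ontology_to_graph(o)
  txt <- if (dialect == "turtle") write_turtle(g, o$prefixes)
         else write_rdfxml(g, o$prefixes)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Load an ontology from Turtle or RDF/XML text or file
#'
#' @param x text, or a path to a file.
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @return a `sempheno_ontology`.
#' @export
load_rdf <- function(x, dialect = c("turtle", "rdfxml")) {
  dialect <- match.arg(dialect)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- paste(readLines(x, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  }
  parsed <- if (dialect == "turtle") read_turtle(x) else read_rdfxml(x)
  prefixes <- parsed$prefixes
  base <- sempheno_prefixes()
  for (p in names(base)) {
    if (!p %in% names(prefixes)) prefixes[[p]] <- base[[p]]
  }
  prefixes <- prefixes[!duplicated(unlist(prefixes))]
  graph_to_ontology(parsed$graph, prefixes)
}
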