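# TBox index: precomputed named-class hierarchy closure, told complex
# superclasses, transitive properties and chain axioms, recomputable
# deterministically from an ontology.

#' Build a TBox index from an ontology
#'
#' Collects (i) the reflexive-transitive closure of the told named-class
#' hierarchy, (ii) told complex superclasses of named classes (e.g.
#' `'ventro-lateral region' SubClassOf part_of some mesosoma`),
#' (iii) transitive properties (stored internally as `r o r -> r` chains)
#' and (iv) declared property-chain axioms.
#'
#' @param o an [ontology()].
#' @param top IRI of the top class (defaults to `owl:Thing` in the
#'   ontology's prefix map).
#' @return an object of class `sempheno_tbox`.
#' @export
build_tbox <- function(o, top = NULL) {
  top <- top %||% iri_expand("owl:Thing", o$prefixes)
  parents <- new.env(parent = emptyenv())
  told_complex <- new.env(parent = emptyenv())
  add_parent <- function(a, b) {
    assign(a, unique(c(if (exists(a, parents)) get(a, parents), b)),
           envir = parents)
  }
  add_complex <- function(a, e) {
    cur <- if (exists(a, told_complex)) get(a, told_complex) else list()
    assign(a, c(cur, list(e)), envir = told_complex)
  }
  for (ax in o$axioms) {
    if (ax$type != "subclass") next
    if (ax$sub$kind != "named") next
    if (ax$sup$kind == "named") {
      add_parent(ax$sub$iri, ax$sup$iri)
    } else {
      add_complex(ax$sub$iri, ax$sup)
    }
  }
  # reflexive-transitive ancestor closure by memoized DFS
  anc_memo <- new.env(parent = emptyenv())
  ancestors <- function(x) {
    if (exists(x, anc_memo)) return(get(x, anc_memo))
    assign(x, x, envir = anc_memo)  # cycle guard: at least itself
    out <- x
    if (exists(x, parents)) {
      for (p in get(x, parents)) out <- union(out, ancestors(p))
    }
    out <- sort_c(unique(out))
    assign(x, out, envir = anc_memo)
    out
  }
  for (cl in o$classes$iri) ancestors(cl)
  chains <- o$chains
  trans <- o$properties$iri[o$properties$transitive]
  for (r in trans) {
    chains[[length(chains) + 1L]] <- c(r, r)
    names(chains)[length(chains)] <- r
  }
  structure(
    list(top = top, ancestors = ancestors, told_complex = told_complex,
         transitive = trans, chains = chains, ontology = o),
    class = "sempheno_tbox"
  )
}

tbox_ancestors <- function(tbox, iri) tbox$ancestors(iri)

tbox_complex_sups <- function(tbox, iri) {
  if (exists(iri, tbox$told_complex)) get(iri, tbox$told_complex) else list()
}

#' @export
print.sempheno_tbox <- function(x, ...) {
  cat(sprintf("<tbox> top=%s, %d transitive properties, %d chains\n",
              x$top, length(x$transitive), length(x$chains)))
  invisible(x)
}
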