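# Brute-force subsumption oracle over canonical models.
#
# For the EL core (named classes, and, or, some, with named hierarchies,
# told complex superclasses, transitive properties and chain axioms) the
# canonical (minimal) model of the sub expression, saturated under the
# TBox, satisfies the sup expression at its root exactly when sub is
# subsumed by sup. Or on the sub side is handled by expanding to
# disjunctive normal form: one canonical model per disjunct, all of which
# must satisfy sup. The construction is exponential and guarded by size
# caps; it is a test oracle, not the production reasoner, and shares no
# code with is_subsumed().

oracle_caps <- function() {
  list(max_depth = 6L, max_classes = 64L, max_nodes = 600L)
}

#' Brute-force subsumption oracle
#'
#' Decides subsumption by constructing the canonical model of `sub` (one
#' individual per existential, saturated under hierarchy, told complex
#' superclasses, transitivity and chains) and model-checking `sup` at the
#' root. Only the EL core is supported: `only` and `exactly` raise an
#' error, as do expressions or ontologies beyond the resource caps.
#'
#' @param sub,sup class expressions in the EL core.
#' @param o an [ontology()]; its axioms, transitive properties and chains
#'   form the background TBox.
#' @param top IRI treated as the top class.
#' @return `TRUE` or `FALSE`.
#' @export
oracle_subsumed <- function(sub, sup, o, top = NULL) {
  caps <- oracle_caps()
  top <- top %||% iri_expand("owl:Thing", o$prefixes)
  check_fragment <- function(e) {
    if (e$kind %in% c("only", "exactly")) {
      stop("oracle_subsumed supports the EL core only (no 'only'/'exactly')",
           call. = FALSE)
    }
    switch(e$kind, and = , or = for (a in e$args) check_fragment(a),
           some = check_fragment(e$filler))
  }
  check_fragment(sub); check_fragment(sup)
  assert_that(ce_depth(sub) <= caps$max_depth &&
                ce_depth(sup) <= caps$max_depth,
              "oracle resource guard: expression too deep")
  assert_that(nrow(o$classes) <= caps$max_classes,
              "oracle resource guard: ontology too large")
  tbx <- build_tbox(o, top = top)
  disjuncts <- ce_dnf(sub)
  all(vapply(disjuncts, function(d) {
    m <- canonical_model(d, tbx, caps)
    model_check(sup, m$root, m, top)
  }, logical(1)))
}

# Canonical model: nodes with label sets and directed property edges.
canonical_model <- function(d, tbx, caps) {
  m <- new.env(parent = emptyenv())
  m$labels <- list()   # node id -> character vector of class IRIs
  m$edges <- list()    # list of c(src, prop, dst)
  m$n <- 0L
  m$applied <- character(0)  # "node|axiom-key" pairs already unfolded
  new_node <- function() {
    m$n <- m$n + 1L
    assert_that(m$n <= caps$max_nodes,
                "oracle resource guard: canonical model too large")
    id <- as.character(m$n)
    m$labels[[id]] <- character(0)
    id
  }
  add_edge <- function(src, prop, dst) {
    key <- paste(src, prop, dst)
    if (!key %in% names(m$edges)) {
      m$edges[[key]] <- c(src, prop, dst)
      TRUE
    } else {
      FALSE
    }
  }
  # interpret a disjunct-free expression at a node, creating successors
  interpret <- function(e, node) {
    switch(e$kind,
      named = {
        m$labels[[node]] <- union(m$labels[[node]], e$iri)
      },
      and = for (a in e$args) interpret(a, node),
      some = {
        succ <- new_node()
        add_edge(node, e$property, succ)
        interpret(e$filler, succ)
      },
      or = stop("internal: disjunct expected", call. = FALSE)
    )
  }
  root <- new_node()
  interpret(d, root)
  # saturation to fixpoint
  repeat {
    changed <- FALSE
    # hierarchy closure on labels
    for (id in names(m$labels)) {
      lab <- m$labels[[id]]
      closed <- unique(unlist(lapply(lab, tbox_ancestors, tbox = tbx)))
      if (length(setdiff(closed, lab))) {
        m$labels[[id]] <- union(lab, closed)
        changed <- TRUE
      }
    }
    # unfold told complex superclasses once per (node, axiom)
    for (id in names(m$labels)) {
      for (cl in m$labels[[id]]) {
        for (e in tbox_complex_sups(tbx, cl)) {
          key <- paste0(id, "|", cl, "|", ce_key(e))
          if (key %in% m$applied) next
          m$applied <- c(m$applied, key)
          for (dd in ce_dnf(e)) {      # told sups here are disjunct-free
            interpret(dd, id)
          }
          changed <- TRUE
        }
      }
    }
    # chains (transitivity included): r1 o ... o rk edges imply a head edge
    edge_mat <- m$edges
    for (i in seq_along(tbx$chains)) {
      head_p <- names(tbx$chains)[[i]]
      steps <- tbx$chains[[i]]
      frontier <- lapply(edge_mat, function(e) {
        if (e[[2]] == steps[[1]]) c(e[[1]], e[[3]]) else NULL
      })
      frontier <- Filter(Negate(is.null), frontier)
      for (s in steps[-1]) {
        nxt <- list()
        for (f in frontier) {
          for (e in m$edges) {
            if (e[[2]] == s && e[[1]] == f[[2]]) {
              nxt[[length(nxt) + 1L]] <- c(f[[1]], e[[3]])
            }
          }
        }
        frontier <- nxt
      }
      for (f in frontier) {
        if (add_edge(f[[1]], head_p, f[[2]])) changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(root = root, labels = m$labels, edges = unname(m$edges))
}

model_check <- function(e, node, m, top) {
  switch(e$kind,
    named = e$iri == top || e$iri %in% m$labels[[node]],
    and = all(vapply(e$args, model_check, logical(1), node = node, m = m,
                     top = top)),
    or = any(vapply(e$args, model_check, logical(1), node = node, m = m,
                    top = top)),
    some = {
      for (ed in m$edges) {
        if (ed[[1]] == node && ed[[2]] == e$property &&
            model_check(e$filler, ed[[3]], m, top)) {
          return(TRUE)
        }
      }
      FALSE
    },
    stop("oracle fragment violation", call. = FALSE)
  )
}
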