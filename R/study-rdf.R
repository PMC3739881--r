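# Study <-> RDF: matrix elements in CDAO roles (Standard Character,
# character state, TU, coding cell), specimens in Darwin-SW roles, denotes
# edges from each OTU to its specimens, and the denotes-only annotation
# axioms on character states.

study_terms <- function(config) {
  p <- function(x) iri_expand(x, config$prefixes)
  c(rdf_terms(config$prefixes), list(
    std_character = p("cdao:StandardCharacter"),
    character_state = p("cdao:CharacterStateDomainElement"),
    tu = p("cdao:TU"),
    coding = p("cdao:Coding"),
    belongs_to_character = p("cdao:belongs_to_character"),
    specimen = p("dsw:Specimen"),
    repository = p("dsw:repository"),
    country = p("dsw:country"),
    subdivision = p("dsw:subdivision"),
    role = p("dsw:role"),
    sex = p("dsw:sex"),
    verbatim = p("dsw:verbatim"),
    material = p("sp:material"),
    body_region = p("sp:bodyRegion"),
    template = p("sp:templateCategory"),
    absent_part = p("sp:absentPart"),
    has_rule = p("sp:hasRule")
  ))
}

#' Export a study as an RDF graph
#'
#' Characters, states, TUs and coding cells take CDAO roles (coding cells
#' are blank nodes); specimens take Darwin-SW roles; each OTU `denotes`
#' each of its specimens; each annotated state carries the
#' `denotes only P` class assertion, with `P SubClassOf definition` and
#' the definition serialized through the OWL 2 RDF mapping. Materializing
#' the configured denotes chain over this graph yields
#' `denotes(state, specimen)` edges.
#'
#' @param s a study.
#' @param config a [sempheno_config()].
#' @return an [rdf_graph()].
#' @export
study_to_rdf <- function(s, config = sempheno_config()) {
  tm <- study_terms(config)
  pr <- config$properties
  sink <- triple_sink()
  gensym <- new_blank_counter("x")
  for (i in seq_len(nrow(s$characters))) {
    id <- s$characters$id[[i]]
    sink$add(id, tm$type, tm$std_character)
    sink$add(id, tm$label, s$characters$label[[i]], "literal")
    sink$add(id, tm$body_region, s$characters$body_region[[i]], "literal")
    sink$add(id, tm$template, s$characters$template_category[[i]],
             "literal")
  }
  for (i in seq_len(nrow(s$states))) {
    id <- s$states$id[[i]]
    sink$add(id, tm$type, tm$character_state)
    sink$add(id, tm$label, s$states$label[[i]], "literal")
    sink$add(id, tm$belongs_to_character, s$states$character_id[[i]])
  }
  for (i in seq_len(nrow(s$otus))) {
    id <- s$otus$id[[i]]
    sink$add(id, tm$type, tm$tu)
    sink$add(id, tm$label, s$otus$taxon_name[[i]], "literal")
    mat <- s$otus$material[[i]]
    if (!is.na(mat) && nzchar(mat)) {
      sink$add(id, tm$material, mat, "literal")
    }
  }
  cell_key <- paste(s$codings$otu_id, s$codings$character_id)
  cell_ids <- if (nrow(s$codings)) {
    paste0("_:coding_", match(cell_key, unique(cell_key)))
  } else {
    character(0)
  }
  for (cid in unique(cell_ids)) {
    sink$add(cid, tm$type, tm$coding)
  }
  for (i in seq_len(nrow(s$codings))) {
    cid <- cell_ids[[i]]
    sink$add(cid, pr$has_state, s$codings$state_id[[i]])
    sink$add(s$codings$state_id[[i]], pr$state_of, cid, "blank")
    sink$add(cid, pr$belongs_to_tu, s$codings$otu_id[[i]])
  }
  for (i in seq_len(nrow(s$specimens))) {
    id <- s$specimens$catalog_urn[[i]]
    sink$add(id, tm$type, tm$specimen)
    sink$add(s$specimens$otu_id[[i]], pr$denotes, id)
    sink$add(id, tm$repository, s$specimens$repository_coden[[i]], "literal")
    sink$add(id, tm$country, s$specimens$country[[i]], "literal")
    sink$add(id, tm$subdivision, s$specimens$subdivision[[i]], "literal")
    sink$add(id, tm$role, s$specimens$role[[i]], "literal")
    sink$add(id, tm$sex, s$specimens$sex[[i]], "literal")
    sink$add(id, tm$verbatim, s$specimens$verbatim[[i]], "literal")
  }
  for (st in names(s$annotations)) {
    a <- s$annotations[[st]]
    p_iri <- a$phenotype
    sink$add(p_iri, tm$type, tm$owl_class)
    defn_node <- expr_to_node(a$definition, sink, tm, gensym)
    sink$add(p_iri, tm$subclassof, defn_node,
             if (is_blank(defn_node)) "blank" else "iri")
    only_node <- expr_to_node(ce_only(pr$denotes, ce_named(p_iri)), sink,
                              tm, gensym)
    sink$add(st, tm$type, only_node, "blank")
    sink$add(p_iri, tm$template, a$template, "literal")
    if (!is.null(a$absent_part)) {
      sink$add(p_iri, tm$absent_part, a$absent_part)
    }
    if (!is.null(a$rule)) {
      rb <- gensym()
      sink$add(p_iri, tm$has_rule, rb, "blank")
      sink$add(rb, tm$type, tm$rule)
      emit_atom <- function(at, pred) {
        ab <- gensym()
        if (at$type == "class") {
          sink$add(ab, tm$type, tm$class_atom)
          sink$add(ab, tm$predicate, at$class)
          sink$add(ab, tm$var, at$var, "literal")
        } else {
          sink$add(ab, tm$type, tm$prop_atom)
          sink$add(ab, tm$predicate, at$property)
          sink$add(ab, tm$var1, at$var1, "literal")
          sink$add(ab, tm$var2, at$var2, "literal")
        }
        sink$add(rb, pred, ab, "blank")
      }
      for (at in a$rule$body) emit_atom(at, tm$rule_body)
      emit_atom(a$rule$head, tm$rule_head)
    }
  }
  sink$graph()
}

#' Rebuild a study from its RDF graph
#'
#' Inverse of [study_to_rdf()]: preserves characters, states, OTUs,
#' codings, specimens and state annotations.
#'
#' @param g an [rdf_graph()] produced by [study_to_rdf()].
#' @param config a [sempheno_config()].
#' @return a [study()].
#' @export
rdf_to_study <- function(g, config = sempheno_config()) {
  tm <- study_terms(config)
  pr <- config$properties
  lit <- function(s, p) {
    hit <- g$o[g$s == s & g$p == p & g$otype == "literal"]
    if (length(hit)) hit[[1]] else ""
  }
  obj1 <- function(s, p) {
    hit <- g$o[g$s == s & g$p == p]
    if (length(hit)) hit[[1]] else NA_character_
  }
  chars <- decl_of2(g, tm$type, tm$std_character)
  characters <- if (length(chars)) data.frame(
    id = chars,
    label = vapply(chars, lit, character(1), p = tm$label),
    body_region = vapply(chars, lit, character(1), p = tm$body_region),
    template_category = vapply(chars, lit, character(1), p = tm$template),
    stringsAsFactors = FALSE
  ) else NULL
  sts <- decl_of2(g, tm$type, tm$character_state)
  states <- if (length(sts)) data.frame(
    id = sts,
    character_id = vapply(sts, obj1, character(1),
                          p = tm$belongs_to_character),
    label = vapply(sts, lit, character(1), p = tm$label),
    stringsAsFactors = FALSE
  ) else NULL
  tus <- decl_of2(g, tm$type, tm$tu)
  otus <- if (length(tus)) data.frame(
    id = tus,
    taxon_name = vapply(tus, lit, character(1), p = tm$label),
    material = vapply(tus, lit, character(1), p = tm$material),
    stringsAsFactors = FALSE
  ) else NULL
  cells <- decl_of2(g, tm$type, tm$coding)
  codings <- list()
  for (cid in cells) {
    otu <- obj1(cid, pr$belongs_to_tu)
    st <- g$o[g$s == cid & g$p == pr$has_state]
    for (x in st) {
      codings[[length(codings) + 1L]] <- data.frame(
        otu_id = otu, character_id = states$character_id[
          match(x, states$id)], state_id = x, stringsAsFactors = FALSE
      )
    }
  }
  codings <- if (length(codings)) do.call(rbind, codings) else NULL
  specs <- decl_of2(g, tm$type, tm$specimen)
  specimens <- if (length(specs)) {
    den <- g[g$p == pr$denotes, , drop = FALSE]
    data.frame(
      catalog_urn = specs,
      otu_id = vapply(specs, function(x) {
        hit <- den$s[den$o == x & den$s %in% tus]
        hit[[1]]
      }, character(1)),
      repository_coden = vapply(specs, lit, character(1),
                                p = tm$repository),
      country = vapply(specs, lit, character(1), p = tm$country),
      subdivision = vapply(specs, lit, character(1), p = tm$subdivision),
      role = vapply(specs, lit, character(1), p = tm$role),
      sex = vapply(specs, lit, character(1), p = tm$sex),
      verbatim = vapply(specs, lit, character(1), p = tm$verbatim),
      stringsAsFactors = FALSE
    )
  } else NULL
  annotations <- list()
  ty <- g[g$p == tm$type & g$otype == "blank", , drop = FALSE]
  for (i in seq_len(nrow(ty))) {
    if (!ty$s[[i]] %in% (states$id %||% character(0))) next
    expr <- tryCatch(node_to_expr(ty$o[[i]], g, tm), error = function(e) NULL)
    if (is.null(expr) || expr$kind != "only") next
    p_iri <- expr$filler$iri
    defn_nodes <- g$o[g$s == p_iri & g$p == tm$subclassof]
    defn <- node_to_expr(defn_nodes[[1]], g, tm)
    ap <- g$o[g$s == p_iri & g$p == tm$absent_part]
    read_atom <- function(node) {
      aty <- g$o[g$s == node & g$p == tm$type][[1]]
      pred <- g$o[g$s == node & g$p == tm$predicate][[1]]
      if (aty == tm$class_atom) {
        list(type = "class", var = g$o[g$s == node & g$p == tm$var][[1]],
             class = pred)
      } else {
        list(type = "property", property = pred,
             var1 = g$o[g$s == node & g$p == tm$var1][[1]],
             var2 = g$o[g$s == node & g$p == tm$var2][[1]])
      }
    }
    rnode <- g$o[g$s == p_iri & g$p == tm$has_rule]
    rl <- if (length(rnode)) {
      rule(lapply(sort_c(g$o[g$s == rnode[[1]] & g$p == tm$rule_body]),
                  read_atom),
           read_atom(g$o[g$s == rnode[[1]] & g$p == tm$rule_head][[1]]))
    } else NULL
    annotations[[ty$s[[i]]]] <- list(
      state = ty$s[[i]], phenotype = p_iri, definition = defn,
      template = lit(p_iri, tm$template),
      rule = rl,
      absent_part = if (length(ap)) ap[[1]] else NULL
    )
  }
  study(characters = characters, states = states, otus = otus,
        codings = codings, specimens = specimens,
        annotations = annotations, prefixes = config$prefixes)
}
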