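# ABox: asserted and inferred property edges with provenance, and
# individual class assertions; property-chain materialization; phenotype
# propagation through the denotes-only pattern.

#' Construct an ABox graph
#'
#' @param s,p,o character vectors of subject IRI, property IRI, object IRI
#'   for the asserted edges.
#' @param assertions list of class assertions, each
#'   `list(individual = iri, expr = <class expression>)`.
#' @return an object of class `sempheno_abox`: a list with an `edges`
#'   data.frame (s, p, o, inferred, derivation) and the `assertions` list.
#' @export
abox_graph <- function(s = character(0), p = character(0), o = character(0),
                       assertions = list()) {
  edges <- data.frame(s = s, p = p, o = o,
                      inferred = logical(length(s)),
                      derivation = rep(NA_character_, length(s)),
                      stringsAsFactors = FALSE)
  edges <- sort_df(unique(edges), c("s", "p", "o"))
  structure(list(edges = edges, assertions = assertions),
            class = "sempheno_abox")
}

#' Materialize property chains and transitivity to a fixed point
#'
#' Repeatedly applies every chain axiom in the TBox (declared-transitive
#' properties contribute the chain `r o r -> r`) until no new edge can be
#' derived. Every inferred edge records a derivation string naming the
#' chain and the intermediate nodes. The result is deterministic (edges
#' sorted lexicographically) and idempotent: materializing the output adds
#' nothing.
#'
#' @param abox an [abox_graph()].
#' @param tbox a [build_tbox()] index supplying chains and transitive
#'   properties.
#' @return the materialized `sempheno_abox`.
#' @export
materialize <- function(abox, tbox) {
  edges <- abox$edges
  if (nrow(edges) == 0L) return(abox)
  have <- paste(edges$s, edges$p, edges$o)
  repeat {
    added <- FALSE
    for (i in seq_along(tbox$chains)) {
      head_p <- names(tbox$chains)[[i]]
      steps <- tbox$chains[[i]]
      step_edges <- edges[edges$p == steps[[1]], c("s", "o"), drop = FALSE]
      if (nrow(step_edges) == 0L) next
      paths <- data.frame(s = step_edges$s, via = step_edges$o,
                          trail = paste0(step_edges$s, " -", steps[[1]],
                                         "-> ", step_edges$o),
                          stringsAsFactors = FALSE)
      ok <- TRUE
      for (st in steps[-1]) {
        nxt <- edges[edges$p == st, c("s", "o"), drop = FALSE]
        if (nrow(nxt) == 0L) { ok <- FALSE; break }
        m <- merge(paths, nxt, by.x = "via", by.y = "s")
        if (nrow(m) == 0L) { ok <- FALSE; break }
        paths <- data.frame(s = m$s, via = m$o,
                            trail = paste0(m$trail, " -", st, "-> ", m$o),
                            stringsAsFactors = FALSE)
      }
      if (!ok) next
      keys <- paste(paths$s, head_p, paths$via)
      new_rows <- which(!keys %in% have)
      if (length(new_rows)) {
        add <- data.frame(
          s = paths$s[new_rows], p = head_p, o = paths$via[new_rows],
          inferred = TRUE,
          derivation = sprintf("chain[%s] %s",
                               paste(steps, collapse = " o "),
                               paths$trail[new_rows]),
          stringsAsFactors = FALSE
        )
        add <- add[!duplicated(paste(add$s, add$p, add$o)), , drop = FALSE]
        edges <- rbind(edges, add)
        have <- c(have, paste(add$s, add$p, add$o))
        added <- TRUE
      }
    }
    if (!added) break
  }
  out <- abox
  out$edges <- sort_df(edges, c("s", "p", "o"))
  out
}

#' Propagate phenotype classes from character states to specimens
#'
#' For every annotated state S (annotation pairs S with its phenotype
#' class P; the study asserts `S Type (denotes only P)`) and every
#' materialized `denotes(S, x)` edge, the specimen x is classified into P.
#' With a TBox, every named superclass of P entailed by the hierarchy is
#' reported separately as an entailed expression.
#'
#' @param study_graph a materialized [abox_graph()].
#' @param annotations data.frame with columns `state`, `phenotype` (IRIs),
#'   or a list of `c(state, phenotype)` pairs.
#' @param tbox optional [build_tbox()] index used to derive entailed
#'   superclasses.
#' @param denotes IRI of the denotes property.
#' @return data.frame (specimen, phenotype), sorted and duplicate-free,
#'   with an `entailed` attribute holding a data.frame
#'   (specimen, expression) of inherited named superclasses.
#' @export
propagate_phenotypes <- function(study_graph, annotations, tbox = NULL,
                                 denotes = sempheno_config()$properties$denotes) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- data.frame(
      state = vapply(annotations, `[[`, character(1), 1L),
      phenotype = vapply(annotations, `[[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  }
  edges <- study_graph$edges
  known <- unique(c(edges$s, edges$o,
                    vapply(study_graph$assertions, `[[`, character(1),
                           "individual")))
  missing <- setdiff(annotations$state, known)
  if (length(missing)) {
    stop(sprintf("annotation references unknown state IRI(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  den <- edges[edges$p == denotes, , drop = FALSE]
  hits <- merge(annotations, den, by.x = "state", by.y = "s")
  out <- data.frame(specimen = hits$o, phenotype = hits$phenotype,
                    stringsAsFactors = FALSE)
  out <- sort_df(unique(out), c("specimen", "phenotype"))
  entailed <- data.frame(specimen = character(0), expression = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(tbox) && nrow(out)) {
    rows <- lapply(seq_len(nrow(out)), function(i) {
      sup <- setdiff(tbox_ancestors(tbox, out$phenotype[[i]]),
                     out$phenotype[[i]])
      if (!length(sup)) return(NULL)
      data.frame(specimen = out$specimen[[i]], expression = sup,
                 stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) {
      entailed <- sort_df(unique(do.call(rbind, rows)),
                          c("specimen", "expression"))
    }
  }
  attr(out, "entailed") <- entailed
  out
}

#' Export inferred edges as Turtle with provenance comments
#'
#' @param abox a materialized [abox_graph()].
#' @param prefixes prefix map.
#' @return a string of Turtle text; each inferred triple is preceded by a
#'   comment naming its derivation.
#' @export
write_inferences_turtle <- function(abox, prefixes) {
  e <- abox$edges
  header <- sprintf("@prefix %s: <%s> .", sort_c(names(prefixes)),
                    unlist(prefixes[sort_c(names(prefixes))]))
  lines <- character(0)
  for (i in seq_len(nrow(e))) {
    if (e$inferred[[i]]) {
      lines <- c(lines, paste0("# inferred: ", e$derivation[[i]]))
    }
    lines <- c(lines, sprintf("%s %s %s .",
                              iri_compact(e$s[[i]], prefixes),
                              iri_compact(e$p[[i]], prefixes),
                              iri_compact(e$o[[i]], prefixes)))
  }
  paste(c(header, "", lines, ""), collapse = "\n")
}

#' Tabular report of propagated phenotypes
#'
#' @param propagation output of [propagate_phenotypes()].
#' @param path optional file; when given, a TSV with columns specimen,
#'   phenotype is written there.
#' @return the report data.frame, invisibly when written to file.
#' @export
write_propagation_tsv <- function(propagation, path = NULL) {
  df <- as.data.frame(propagation)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
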