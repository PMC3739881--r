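# Reasoner-driven analytics over annotated studies: ontology class-usage
# counts, cross-study comparison, anatomical/quality partitions, template
# tallies. Counts are of distinct class IRIs, never mentions; all reports
# are deterministically ordered.

#' Ontology class usage within a study's phenotype expressions
#'
#' Walks every phenotype definition AST, collects the distinct named-class
#' IRIs and buckets them by namespace. IRIs matching no namespace are
#' bucketed `"unknown"`.
#'
#' @param s an annotated study.
#' @param namespace_map named character vector namespace IRI -> bucket tag
#'   (defaults to the package configuration's map).
#' @return an object of class `sempheno_usage`: list with `counts` (named
#'   integer vector, sorted by bucket) and `sets` (the underlying IRI sets
#'   per bucket).
#' @export
usage_counts <- function(s, namespace_map = sempheno_config()$namespace_map) {
  iris <- character(0)
  for (a in s$annotations) {
    iris <- c(iris, ce_classes(a$definition))
  }
  iris <- sort_c(unique(iris))
  buckets <- vapply(iris, source_tag, character(1),
                    namespace_map = namespace_map)
  sets <- split(iris, buckets)
  sets <- sets[sort_c(names(sets))]
  structure(
    list(counts = vapply(sets, length, integer(1)), sets = sets,
         namespace_map = namespace_map),
    class = "sempheno_usage"
  )
}

#' @export
print.sempheno_usage <- function(x, ...) {
  cat("<class usage>\n")
  for (b in names(x$counts)) {
    cat(sprintf("  %s: %d\n", b, x$counts[[b]]))
  }
  invisible(x)
}

#' Compare class usage between two studies
#'
#' Per-bucket union and intersection of the underlying IRI sets
#' (inclusion-exclusion holds: |A union B| = |A| + |B| - |A intersect B|).
#'
#' @param a,b [usage_counts()] reports built with the same namespace map.
#' @return data.frame with columns bucket, a, b, union, intersection.
#' @export
usage_compare <- function(a, b) {
  assert_that(identical(a$namespace_map, b$namespace_map),
              "usage reports built with different namespace maps")
  buckets <- sort_c(union(names(a$sets), names(b$sets)))
  rows <- lapply(buckets, function(k) {
    sa <- a$sets[[k]] %||% character(0)
    sb <- b$sets[[k]] %||% character(0)
    data.frame(bucket = k, a = length(sa), b = length(sb),
               union = length(union(sa, sb)),
               intersection = length(intersect(sa, sb)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

annotated_characters <- function(s) {
  st <- s$states[s$states$id %in% names(s$annotations), , drop = FALSE]
  sort_c(unique(st$character_id))
}

partition_query_entity <- function(e, config) {
  pr <- config$properties
  ce_or(ce_some(pr$has_part, ce_named(e)),
        ce_some(pr$has_part, ce_some(pr$part_of, ce_named(e))))
}

partition_query_quality <- function(q, config) {
  pr <- config$properties
  ce_some(pr$has_part, ce_some(pr$bearer_of, ce_named(q)))
}

partition_count <- function(s, query, tbox) {
  chars <- annotated_characters(s)
  n <- length(chars)
  if (n == 0L) return(list(count = 0L, percentage = 0, n = 0L))
  hit <- vapply(chars, function(ch) {
    st_ids <- s$states$id[s$states$character_id == ch]
    any(vapply(st_ids, function(si) {
      a <- s$annotations[[si]]
      !is.null(a) && is_subsumed(a$definition, query, tbox)
    }, logical(1)))
  }, logical(1))
  list(count = sum(hit), percentage = 100 * sum(hit) / n, n = n)
}

#' Anatomical partition of a study's characters
#'
#' A character counts for entity E when any of its states' phenotype
#' definitions is subsumed by
#' `(has_part some E) or (has_part some (part_of some E))`. The
#' percentage is over the study's annotated characters.
#'
#' @param s an annotated study.
#' @param e IRI of the anatomical query class.
#' @param tbox TBox built from the study's ontologies.
#' @param config a [sempheno_config()].
#' @return list with `count`, `percentage` (exact), `n` (annotated
#'   characters).
#' @export
partition_by_entity <- function(s, e, tbox, config = sempheno_config()) {
  assert_that(e %in% tbox$ontology$classes$iri,
              sprintf("query class '%s' unknown in the TBox", e))
  partition_count(s, partition_query_entity(e, config), tbox)
}

#' Quality partition of a study's characters
#'
#' As [partition_by_entity()], with the single-form query
#' `has_part some (bearer_of some Q)`.
#'
#' @param s an annotated study.
#' @param q IRI of the quality query class.
#' @param tbox TBox built from the study's ontologies.
#' @param config a [sempheno_config()].
#' @return list with `count`, `percentage`, `n`.
#' @export
partition_by_quality <- function(s, q, tbox, config = sempheno_config()) {
  assert_that(q %in% tbox$ontology$classes$iri,
              sprintf("query class '%s' unknown in the TBox", q))
  partition_count(s, partition_query_quality(q, config), tbox)
}

#' Partition report over several query classes
#'
#' @param s an annotated study.
#' @param entities,qualities character vectors of query class IRIs.
#' @param tbox TBox built from the study's ontologies.
#' @param config a [sempheno_config()].
#' @return data.frame (class, kind, count, percentage) with percentages
#'   formatted to one decimal; exact values are kept in the
#'   `percentage_exact` column.
#' @export
partition_report <- function(s, entities = character(0),
                             qualities = character(0), tbox,
                             config = sempheno_config()) {
  rows <- c(
    lapply(entities, function(e) {
      r <- partition_by_entity(s, e, tbox, config)
      data.frame(class = e, kind = "entity", count = r$count,
                 percentage = sprintf("%.1f", r$percentage),
                 percentage_exact = r$percentage, stringsAsFactors = FALSE)
    }),
    lapply(qualities, function(q) {
      r <- partition_by_quality(s, q, tbox, config)
      data.frame(class = q, kind = "quality", count = r$count,
                 percentage = sprintf("%.1f", r$percentage),
                 percentage_exact = r$percentage, stringsAsFactors = FALSE)
    })
  )
  if (!length(rows)) {
    return(data.frame(class = character(0), kind = character(0),
                      count = integer(0), percentage = character(0),
                      percentage_exact = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Tally characters by template category
#'
#' An annotated character's category is the shared category of its
#' annotated states' definitions (disagreement makes it nonstandard);
#' unannotated characters fall back to the stored `template_category`
#' column. An override table (data.frame or CSV path with columns
#' `character_label`, `template_category`) reconciles categories against
#' an external annotation set and wins over both.
#'
#' @param s a study.
#' @param overrides optional override table or CSV path.
#' @param config a [sempheno_config()].
#' @return named integer vector over all template categories; the
#'   non-`unannotated` entries sum to the number of annotated characters.
#' @export
template_tally <- function(s, overrides = NULL,
                           config = sempheno_config()) {
  if (is.character(overrides)) {
    overrides <- utils::read.csv(overrides, colClasses = "character")
  }
  cat_of <- function(i) {
    ch <- s$characters$id[[i]]
    st_ids <- s$states$id[s$states$character_id == ch]
    ann <- s$annotations[names(s$annotations) %in% st_ids]
    if (length(ann)) {
      cats <- unique(vapply(ann, function(a) {
        classify_template(a$definition, config)
      }, character(1)))
      if (length(cats) == 1L) cats else "nonstandard"
    } else {
      s$characters$template_category[[i]]
    }
  }
  cats <- vapply(seq_len(nrow(s$characters)), cat_of, character(1))
  if (!is.null(overrides) && nrow(overrides)) {
    m <- match(s$characters$label, overrides$character_label)
    cats[!is.na(m)] <- overrides$template_category[m[!is.na(m)]]
    assert_that(all(cats %in% template_categories),
                "override table contains unknown template categories")
  }
  out <- vapply(template_categories, function(k) sum(cats == k),
                integer(1))
  names(out) <- template_categories
  out
}
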