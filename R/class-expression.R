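# Class expressions for the restricted OWL fragment:
# named classes, intersection, union, existential and universal property
# restrictions, and exact cardinality. No negation, no data properties.

new_ce <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "sempheno_ce")
}

is_ce <- function(x) inherits(x, "sempheno_ce")

#' Class-expression constructors
#'
#' Validated constructors for the abstract syntax tree of the supported OWL
#' fragment. `ce_and()`/`ce_or()` require at least two operands; operand
#' order is preserved as authored (never sorted), so rendered expressions
#' survive round trips byte-stably. `ce_exactly()` requires a non-negative
#' integer cardinality.
#'
#' @param iri absolute IRI of a named class.
#' @param ... two or more class expressions (for `ce_and`/`ce_or`).
#' @param property absolute IRI of an object property.
#' @param filler a class expression.
#' @param n non-negative integer cardinality.
#' @return an object of class `sempheno_ce`.
#' @examples
#' wing <- ce_named("http://example.com/mini-hao#wing")
#' curved <- ce_named("http://example.com/mini-pato#curved")
#' ce_and(wing, ce_some("http://example.com/mini-ro#bearer_of", curved))
#' @export
ce_named <- function(iri) {
  assert_that(is_string(iri), "named class requires a non-empty IRI")
  new_ce("named", list(iri = iri))
}

#' @rdname ce_named
#' @export
ce_and <- function(...) {
  args <- ce_operands(...)
  assert_that(length(args) >= 2L, "'and' requires at least two operands")
  new_ce("and", list(args = args))
}

#' @rdname ce_named
#' @export
ce_or <- function(...) {
  args <- ce_operands(...)
  assert_that(length(args) >= 2L, "'or' requires at least two operands")
  new_ce("or", list(args = args))
}

ce_operands <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !is_ce(args[[1]])) args <- args[[1]]
  for (a in args) assert_that(is_ce(a), "operands must be class expressions")
  args
}

#' @rdname ce_named
#' @export
ce_some <- function(property, filler) {
  assert_that(is_string(property), "restriction requires a property IRI")
  assert_that(is_ce(filler), "filler must be a class expression")
  new_ce("some", list(property = property, filler = filler))
}

#' @rdname ce_named
#' @export
ce_only <- function(property, filler) {
  assert_that(is_string(property), "restriction requires a property IRI")
  assert_that(is_ce(filler), "filler must be a class expression")
  new_ce("only", list(property = property, filler = filler))
}

#' @rdname ce_named
#' @export
ce_exactly <- function(property, n, filler) {
  assert_that(is_string(property), "restriction requires a property IRI")
  assert_that(is.numeric(n) && length(n) == 1L && !is.na(n) &&
                n >= 0 && n == as.integer(n),
              "cardinality must be a non-negative integer")
  assert_that(is_ce(filler), "filler must be a class expression")
  new_ce("exactly", list(property = property, n = as.integer(n),
                         filler = filler))
}

#' Structural equality of class expressions
#'
#' @param a,b class expressions.
#' @return `TRUE` iff the two ASTs are structurally identical (same
#'   constructors, same IRIs, same authored operand order).
#' @export
ce_equal <- function(a, b) {
  identical(unclass_rec(a), unclass_rec(b))
}

unclass_rec <- function(x) {
  if (is_ce(x)) {
    x <- unclass(x)
    lapply(x, unclass_rec)
  } else if (is.list(x)) {
    lapply(x, unclass_rec)
  } else {
    x
  }
}

#' Collect the named-class IRIs mentioned in an expression
#'
#' @param expr a class expression.
#' @return sorted unique character vector of class IRIs (properties are not
#'   included).
#' @export
ce_classes <- function(expr) {
  acc <- character(0)
  walk <- function(e) {
    switch(e$kind,
      named = acc[[length(acc) + 1L]] <<- e$iri,
      and = ,
      or = for (a in e$args) walk(a),
      some = ,
      only = walk(e$filler),
      exactly = walk(e$filler)
    )
  }
  walk(expr)
  sort_c(unique(acc))
}

#' Collect the object-property IRIs mentioned in an expression
#'
#' @param expr a class expression.
#' @return sorted unique character vector of property IRIs.
#' @export
ce_properties <- function(expr) {
  acc <- character(0)
  walk <- function(e) {
    switch(e$kind,
      and = ,
      or = for (a in e$args) walk(a),
      some = ,
      only = ,
      exactly = {
        acc[[length(acc) + 1L]] <<- e$property
        walk(e$filler)
      }
    )
  }
  walk(expr)
  sort_c(unique(acc))
}

ce_depth <- function(expr) {
  switch(expr$kind,
    named = 1L,
    and = ,
    or = 1L + max(vapply(expr$args, ce_depth, integer(1))),
    some = ,
    only = ,
    exactly = 1L + ce_depth(expr$filler)
  )
}

#' @export
print.sempheno_ce <- function(x, ...) {
  cat("<class expression> ", render_manchester(x, sempheno_prefixes()),
      "\n", sep = "")
  invisible(x)
}

#' @export
format.sempheno_ce <- function(x, ...) {
  render_manchester(x, sempheno_prefixes())
}
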