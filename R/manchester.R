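# Manchester-syntax subset: parser and canonical renderer.
#
# Grammar (precedence low -> high):
#   expr        := and_expr ("or" and_expr)*
#   and_expr    := unary ("and" unary)*
#   unary       := term ("some"|"only") unary
#                | term "exactly" INT primary
#                | primary
#   primary     := "(" expr ")" | term
#   term        := NAME | 'quoted label' | <full-iri>
#
# Unsupported OWL constructs ("not", "value", "min", "max", inverse syntax)
# are a hard error: silently dropping them would corrupt annotations.

manchester_keywords <- c("and", "or", "some", "only", "exactly", "not",
                         "value", "min", "max", "inverse", "that")

tokenize_manchester <- function(text) {
  n <- nchar(text)
  tokens <- list()
  i <- 1L
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LPAR", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAR", ")", i); i <- i + 1L; next }
    if (ch == "'") {
      rest <- substr(text, i + 1L, n)
      close <- regexpr("'", rest, fixed = TRUE)
      if (close < 0L) {
        stop(sprintf("Manchester syntax error at position %d: unterminated quoted label", i),
             call. = FALSE)
      }
      push("QUOTED", substr(rest, 1L, close - 1L), i)
      i <- i + close + 1L
      next
    }
    if (ch == "<") {
      rest <- substr(text, i, n)
      close <- regexpr(">", rest, fixed = TRUE)
      if (close < 0L) {
        stop(sprintf("Manchester syntax error at position %d: unterminated IRI", i),
             call. = FALSE)
      }
      push("IRIREF", substr(rest, 2L, close - 1L), i)
      i <- i + close
      next
    }
    m <- regexpr("^[^\\s()']+", substr(text, i, n), perl = TRUE)
    if (m > 0L) {
      word <- regmatches(substr(text, i, n), m)
      type <- if (word %in% manchester_keywords) "KEYWORD" else "NAME"
      push(type, word, i)
      i <- i + attr(m, "match.length")
      next
    }
    stop(sprintf("Manchester syntax error at position %d: unexpected character '%s'", i, ch),
         call. = FALSE)
  }
  tokens
}

#' Parse a Manchester-subset class expression
#'
#' Supports named classes, `and`, `or`, `some`, `only`, `exactly n`,
#' parentheses, single-quoted multiword labels, prefixed IRIs and full IRIs
#' in angle brackets. Unsupported constructs (e.g. `not`) raise an explicit
#' error with the offending position; they are never silently dropped.
#'
#' @param text the expression text, e.g. `"wing and bearer_of some curved"`.
#' @param prefixes prefix map (named character vector) used to expand
#'   compact IRIs.
#' @param labels optional named character vector mapping display label ->
#'   absolute IRI; bare and quoted tokens are resolved through it before
#'   prefix expansion is attempted.
#' @return a class expression (see [ce_named()]).
#' @examples
#' labs <- c(wing = "http://example.com/mini-hao#wing",
#'           bearer_of = "http://example.com/mini-ro#bearer_of",
#'           curved = "http://example.com/mini-pato#curved")
#' parse_manchester("wing and bearer_of some curved",
#'                  sempheno_prefixes(), labs)
#' @export
parse_manchester <- function(text, prefixes, labels = NULL) {
  assert_that(is_string(text), "expression text must be non-empty")
  validate_prefix_map(prefixes)
  tokens <- tokenize_manchester(text)
  assert_that(length(tokens) > 0L, "expression text must be non-empty")
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  fail <- function(tok, msg) {
    at <- if (is.null(tok)) "end of input" else sprintf("position %d", tok$pos)
    stop(sprintf("Manchester syntax error at %s: %s", at, msg), call. = FALSE)
  }

  resolve <- function(tok) {
    v <- tok$value
    if (tok$type == "IRIREF") return(v)
    if (!is.null(labels) && v %in% names(labels)) return(labels[[v]])
    if (grepl(":", v, fixed = TRUE)) {
      out <- tryCatch(iri_expand(v, prefixes), error = function(e) e)
      if (inherits(out, "error")) {
        fail(tok, conditionMessage(out))
      }
      return(out)
    }
    fail(tok, sprintf("cannot resolve '%s': not a known label or compact IRI", v))
  }

  parse_expr <- function() {
    parts <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "KEYWORD" &&
           peek()$value == "or") {
      advance()
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1]] else ce_or(parts)
  }

  parse_and <- function() {
    parts <- list(parse_unary())
    while (!is.null(peek()) && peek()$type == "KEYWORD" &&
           peek()$value == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parse_unary()
    }
    if (length(parts) == 1L) parts[[1]] else ce_and(parts)
  }

  parse_unary <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "expected a class expression")
    if (tok$type %in% c("NAME", "QUOTED", "IRIREF")) {
      nxt <- if (pos + 1L <= length(tokens)) tokens[[pos + 1L]] else NULL
      if (!is.null(nxt) && nxt$type == "KEYWORD" &&
          nxt$value %in% c("some", "only", "exactly")) {
        prop_tok <- advance()
        kw <- advance()
        prop <- resolve(prop_tok)
        if (kw$value == "exactly") {
          ntok <- peek()
          if (is.null(ntok) || ntok$type != "NAME" ||
              !grepl("^[0-9]+$", ntok$value)) {
            fail(ntok, "'exactly' requires a non-negative integer")
          }
          advance()
          filler <- parse_primary()
          return(ce_exactly(prop, as.integer(ntok$value), filler))
        }
        filler <- parse_unary()
        if (kw$value == "some") return(ce_some(prop, filler))
        return(ce_only(prop, filler))
      }
      return(parse_primary())
    }
    parse_primary()
  }

  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "expected a class expression")
    if (tok$type == "LPAR") {
      advance()
      inner <- parse_expr()
      close <- peek()
      if (is.null(close) || close$type != "RPAR") {
        fail(close, "expected ')'")
      }
      advance()
      return(inner)
    }
    if (tok$type == "KEYWORD") {
      if (tok$value %in% c("not", "value", "min", "max", "inverse", "that")) {
        fail(tok, sprintf("unsupported construct '%s'", tok$value))
      }
      fail(tok, sprintf("unexpected keyword '%s'", tok$value))
    }
    if (tok$type %in% c("NAME", "QUOTED", "IRIREF")) {
      advance()
      return(ce_named(resolve(tok)))
    }
    fail(tok, sprintf("unexpected token '%s'", tok$value))
  }

  out <- parse_expr()
  trailing <- peek()
  if (!is.null(trailing)) {
    fail(trailing, sprintf("unexpected trailing input '%s'", trailing$value))
  }
  out
}

needs_quotes <- function(label) {
  !grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", label) ||
    label %in% manchester_keywords
}

render_term <- function(iri, prefixes, labels_by_iri) {
  if (!is.null(labels_by_iri) && iri %in% names(labels_by_iri)) {
    lab <- labels_by_iri[[iri]]
    if (needs_quotes(lab)) return(paste0("'", lab, "'"))
    return(lab)
  }
  iri_compact(iri, prefixes)
}

#' Render a class expression to canonical Manchester-subset text
#'
#' The rendering is deterministic: operand order is preserved as authored
#' and every non-named operand or filler is parenthesized, so
#' `parse_manchester(render_manchester(e))` reproduces `e` structurally and
#' rendering a parsed string is idempotent. Terms with a known label render
#' as the label (quoted when multiword); otherwise as a compact IRI, or as
#' `<iri>` when no prefix matches.
#'
#' @param expr a class expression.
#' @param prefixes prefix map used to compact IRIs.
#' @param labels optional named character vector label -> IRI (same
#'   orientation as for [parse_manchester()]).
#' @return a single string.
#' @export
render_manchester <- function(expr, prefixes, labels = NULL) {
  assert_that(is_ce(expr), "expr must be a class expression")
  labels_by_iri <- NULL
  if (!is.null(labels)) {
    labels_by_iri <- structure(names(labels), names = unname(labels))
  }
  wrap <- function(e) {
    s <- render(e)
    if (e$kind == "named") s else paste0("(", s, ")")
  }
  render <- function(e) {
    switch(e$kind,
      named = render_term(e$iri, prefixes, labels_by_iri),
      and = paste(vapply(e$args, wrap, character(1)), collapse = " and "),
      or = paste(vapply(e$args, wrap, character(1)), collapse = " or "),
      some = paste(render_term(e$property, prefixes, labels_by_iri),
                   "some", wrap(e$filler)),
      only = paste(render_term(e$property, prefixes, labels_by_iri),
                   "only", wrap(e$filler)),
      exactly = paste(render_term(e$property, prefixes, labels_by_iri),
                      "exactly", e$n, wrap(e$filler))
    )
  }
  render(expr)
}
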