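#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

# Deterministic lexicographic sort, independent of the user's locale.
sort_c <- function(x) {
  if (length(x) == 0L) return(x)
  x[order(x, method = "radix")]
}

order_c <- function(...) order(..., method = "radix")

# Collapse a data.frame to a canonical row order over the given columns.
sort_df <- function(df, cols) {
  if (nrow(df) == 0L) return(df)
  o <- do.call(order_c, unname(as.list(df[cols])))
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a compact IRI against a prefix map
#'
#' A prefix map is a named character vector mapping prefix to namespace IRI
#' (the empty name is the default prefix). Namespaces must be distinct.
#'
#' @param x a compact IRI such as `"hao:wing"`, or a full IRI in angle
#'   brackets.
#' @param prefixes named character vector, prefix -> namespace IRI.
#' @return the absolute IRI string.
#' @export
iri_expand <- function(x, prefixes) {
  assert_that(is_string(x), "IRI must be a non-empty string")
  if (startsWith(x, "<") && endsWith(x, ">")) {
    return(substr(x, 2L, nchar(x) - 1L))
  }
  colon <- regexpr(":", x, fixed = TRUE)
  if (colon > 0L) {
    pfx <- substr(x, 1L, colon - 1L)
    local <- substr(x, colon + 1L, nchar(x))
    if (pfx %in% names(prefixes)) {
      return(paste0(prefixes[[pfx]], local))
    }
    stop(sprintf("unresolvable prefix '%s' in '%s'", pfx, x), call. = FALSE)
  }
  stop(sprintf("'%s' is not a compact or absolute IRI", x), call. = FALSE)
}

#' Compact an absolute IRI against a prefix map
#'
#' @param iri absolute IRI string.
#' @param prefixes named character vector, prefix -> namespace IRI.
#' @return `"pfx:local"` when a namespace matches (the longest namespace
#'   wins), otherwise `"<iri>"`.
#' @export
iri_compact <- function(iri, prefixes) {
  assert_that(is_string(iri), "IRI must be a non-empty string")
  if (length(prefixes)) {
    ns <- unlist(prefixes)
    hit <- startsWith(iri, ns)
    if (any(hit)) {
      cand <- ns[hit]
      best <- which.max(nchar(cand))
      pfx <- names(cand)[best]
      return(paste0(pfx, ":", substr(iri, nchar(cand[[best]]) + 1L, nchar(iri))))
    }
  }
  paste0("<", iri, ">")
}

validate_prefix_map <- function(prefixes) {
  assert_that(is.character(prefixes), "prefix map must be a character vector")
  if (length(prefixes)) {
    assert_that(!is.null(names(prefixes)) && !anyNA(names(prefixes)),
                "prefix map must be named")
    assert_that(!anyDuplicated(names(prefixes)), "duplicate prefixes")
    assert_that(!anyDuplicated(unlist(prefixes)),
                "prefix map is not injective: duplicate namespaces")
  }
  invisible(prefixes)
}
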