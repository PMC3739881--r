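# Structural subsumption for the supported fragment.
#
# The decision rules implement EL-style reasoning: named-class hierarchy,
# And introduction/elimination, Some monotonicity in the filler,
# distribution of Or (expanded to disjunctive normal form on the sub side,
# checked disjunct-wise on the sup side), and property chains (transitivity
# is the chain r o r -> r). Only and Exactly are compared structurally:
# Only appears in this data model solely in the denotes-only linkage, and
# Exactly(r, n >= 1, C) is additionally weakened to entail Some(r, C).

ce_key <- function(e) {
  switch(e$kind,
    named = e$iri,
    and = paste0("(", paste(vapply(e$args, ce_key, character(1)),
                            collapse = "&"), ")"),
    or = paste0("(", paste(vapply(e$args, ce_key, character(1)),
                           collapse = "|"), ")"),
    some = paste0("E[", e$property, "].", ce_key(e$filler)),
    only = paste0("A[", e$property, "].", ce_key(e$filler)),
    exactly = paste0("N[", e$property, ",", e$n, "].", ce_key(e$filler))
  )
}

# Distribute Or over And/Some down to disjunctive normal form. Or nested
# inside Only/Exactly fillers is left in place (no sound distribution).
ce_dnf <- function(e, cap = 512L) {
  out <- switch(e$kind,
    named = list(e),
    only = ,
    exactly = list(e),
    or = {
      parts <- lapply(e$args, ce_dnf, cap = cap)
      do.call(c, parts)
    },
    and = {
      parts <- lapply(e$args, ce_dnf, cap = cap)
      combos <- list(list())
      for (p in parts) {
        combos <- do.call(c, lapply(combos, function(cmb) {
          lapply(p, function(d) c(cmb, list(d)))
        }))
        assert_that(length(combos) <= cap, "expression too disjunctive")
      }
      lapply(combos, function(cmb) {
        if (length(cmb) == 1L) cmb[[1]] else ce_and(cmb)
      })
    },
    some = {
      lapply(ce_dnf(e$filler, cap = cap), function(d) ce_some(e$property, d))
    }
  )
  assert_that(length(out) <= cap, "expression too disjunctive")
  out
}

# Saturated conjunct set of a disjunct-free expression: named conjuncts
# closed under the hierarchy, restriction conjuncts extended by unfolding
# told complex superclasses of named conjuncts.
conjunct_set <- function(d, tbox) {
  named <- character(0)
  restr <- list()
  seen_named <- character(0)
  add_expr <- function(e) {
    switch(e$kind,
      named = add_named(e$iri),
      and = for (a in e$args) add_expr(a),
      or = {
        restr[[length(restr) + 1L]] <<- e  # opaque; no sound unfolding
      },
      some = ,
      only = ,
      exactly = restr[[length(restr) + 1L]] <<- e
    )
  }
  add_named <- function(iri) {
    if (iri %in% seen_named) return(invisible())
    seen_named <<- c(seen_named, iri)
    anc <- tbox_ancestors(tbox, iri)
    named <<- union(named, anc)
    for (a in anc) {
      for (e in tbox_complex_sups(tbox, a)) add_expr(e)
      if (!a %in% seen_named) seen_named <<- c(seen_named, a)
    }
  }
  add_expr(d)
  list(named = named, restr = restr)
}

#' Structural subsumption check
#'
#' Decides whether `sub` is subsumed by `sup` under the TBox: named-class
#' hierarchy, And rules, Some monotonicity, Or (any disjunct on the sup
#' side; all disjuncts must hold on the sub side), property chains and
#' transitivity inside Some, and told complex superclasses of named
#' classes (so `'ventro-lateral region'` with a declared
#' `part_of some mesosoma` superclass is found by
#' `has_part some (part_of some mesosoma)` queries). Only and Exactly are
#' compared structurally (see package docs).
#'
#' @param sub,sup class expressions.
#' @param tbox a [build_tbox()] index.
#' @return `TRUE` or `FALSE`.
#' @export
is_subsumed <- function(sub, sup, tbox) {
  assert_that(inherits(tbox, "sempheno_tbox"), "tbox index required")
  memo_true <- new.env(parent = emptyenv())
  in_progress <- new.env(parent = emptyenv())

  sub_q <- function(sub, sup) {
    key <- paste0(ce_key(sub), " << ", ce_key(sup))
    if (exists(key, memo_true)) return(TRUE)
    if (exists(key, in_progress)) return(FALSE)  # no well-founded proof here
    assign(key, TRUE, envir = in_progress)
    on.exit(rm(list = key, envir = in_progress), add = TRUE)
    res <- sub_q_uncached(sub, sup)
    if (res) assign(key, TRUE, envir = memo_true)
    res
  }

  sub_q_uncached <- function(sub, sup) {
    if (identical(ce_key(sub), ce_key(sup))) return(TRUE)
    disjuncts <- ce_dnf(sub)
    if (length(disjuncts) > 1L) {
      return(all(vapply(disjuncts, function(d) sub_q(d, sup), logical(1))))
    }
    d <- disjuncts[[1]]
    conj <- conjunct_set(d, tbox)
    check_sup(d, conj, sup)
  }

  check_sup <- function(d, conj, sup) {
    switch(sup$kind,
      named = sup$iri == tbox$top || sup$iri %in% conj$named,
      and = all(vapply(sup$args, function(s) check_sup(d, conj, s),
                       logical(1))),
      or = any(vapply(sup$args, function(s) check_sup(d, conj, s),
                      logical(1))),
      some = check_some(d, conj, sup),
      only = check_only(conj, sup),
      exactly = check_exactly(conj, sup)
    )
  }

  check_some <- function(d, conj, sup) {
    r <- sup$property
    existentials <- Filter(function(cj) {
      cj$kind == "some" || (cj$kind == "exactly" && cj$n >= 1L)
    }, conj$restr)
    for (cj in existentials) {
      if (cj$property == r && sub_q(cj$filler, sup$filler)) return(TRUE)
    }
    # Chain axioms with head r (transitivity included as r o r -> r):
    # match a told conjunct on the chain's first step, then require the
    # filler to reach sup's filler along the remaining steps. The
    # recursion always descends into the filler, so it terminates.
    for (i in seq_along(tbox$chains)) {
      if (names(tbox$chains)[[i]] != r) next
      steps <- tbox$chains[[i]]
      target <- sup$filler
      for (j in rev(seq_along(steps))[seq_len(length(steps) - 1L)]) {
        target <- ce_some(steps[[j]], target)
      }
      for (cj in existentials) {
        if (cj$property == steps[[1]] && sub_q(cj$filler, target)) {
          return(TRUE)
        }
      }
    }
    FALSE
  }

  check_only <- function(conj, sup) {
    for (cj in conj$restr) {
      if (cj$kind == "only" && cj$property == sup$property &&
          sub_q(cj$filler, sup$filler)) {
        return(TRUE)
      }
    }
    FALSE
  }

  check_exactly <- function(conj, sup) {
    for (cj in conj$restr) {
      if (cj$kind == "exactly" && cj$property == sup$property &&
          cj$n == sup$n && sub_q(cj$filler, sup$filler) &&
          sub_q(sup$filler, cj$filler)) {
        return(TRUE)
      }
    }
    FALSE
  }

  sub_q(sub, sup)
}
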