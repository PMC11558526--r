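# Combinatorial expansion of the leukocyte differential into dimensionless
# indicators (DIs): canonical monomials over unit-free base variables.

di_variable_codes <- function() {
  c(lymph_pct = "L", neut_pct = "N", mono_pct = "M",
    eos_pct = "E", baso_pct = "B",
    lymph_frac = "l", neut_frac = "n", mono_frac = "m")
}

#' Named leukocyte ratios
#'
#' The field's standard derived ratios: `NL` (neutrophil/lymphocyte
#' percentage ratio), `MN` (monocyte/neutrophil), `NL_over_MN`
#' (`[N/L]/[M/N]`, the monocyte-adjusted N/L ratio elevated jointly with
#' N/L in intermediary suppression) and its reciprocal `MN_over_NL`.
#'
#' @param obs data.frame with strictly positive `lymph_pct`, `neut_pct`,
#'   `mono_pct` columns (e.g. the observation table of a `sepsis_cohort`).
#' @return data.frame with columns `NL`, `MN`, `NL_over_MN`, `MN_over_NL`.
#' @export
named_ratios <- function(obs) {
  if (inherits(obs, "sepsis_cohort")) obs <- obs$observations
  need <- c("lymph_pct", "neut_pct", "mono_pct")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0)
    stopf("named_ratios: missing column(s) %s", paste(miss, collapse = ", "))
  bad <- which(Reduce(`|`, lapply(need, function(cn)
    is.na(obs[[cn]]) | obs[[cn]] <= 0)))
  if (length(bad) > 0)
    stopf("named_ratios: missing or non-positive percentage at observation %d",
          bad[1])
  nl <- obs$neut_pct / obs$lymph_pct
  mn <- obs$mono_pct / obs$neut_pct
  data.frame(NL = nl, MN = mn, NL_over_MN = nl / mn, MN_over_NL = mn / nl)
}

#' Define a dimensionless-indicator grammar
#'
#' A grammar describes the expansion space: which unit-free base variables
#' may appear (leukocyte percentages and/or WBC count fractions), which
#' operators combine them, and the maximum expression-tree depth. Ratios are
#' formed from base variables at depth 1; deeper levels combine
#' already-formed ratios by ratio or product ("products of ratios"), so
#' every expression canonicalizes to a monomial whose exponents sum to zero
#' — the algebraic statement that only relative (compositional) information
#' is used. Dimensioned variables (raw counts) are rejected at construction,
#' as is the `sum` operator, which has no monomial canonical form.
#'
#' @param variables base variables; default: the five leukocyte percentages
#'   plus the lymphocyte/neutrophil/monocyte count fractions (count / WBC).
#' @param operators subset of `c("ratio", "product")`; `"ratio"` is required.
#' @param max_depth maximum expression-tree depth, 0..3 (hard cap 3; the
#'   monomial degree grows as `2^(max_depth - 1)`).
#' @return Object of class `di_grammar`.
#' @export
di_grammar <- function(variables = c("lymph_pct", "neut_pct", "mono_pct",
                                     "eos_pct", "baso_pct",
                                     "lymph_frac", "neut_frac", "mono_frac"),
                       operators = c("ratio", "product"),
                       max_depth = 3) {
  allowed <- names(di_variable_codes())
  bad <- setdiff(variables, allowed)
  if (length(bad) > 0)
    stopf("dimensioned or unknown base variable(s) rejected: %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  if (anyDuplicated(variables)) stopf("duplicated base variables")
  if ("sum" %in% operators)
    stopf("the 'sum' operator is not supported: sums have no monomial canonical form")
  if (!"ratio" %in% operators) stopf("the grammar requires the 'ratio' operator")
  if (length(setdiff(operators, c("ratio", "product"))) > 0)
    stopf("unknown operator(s): %s",
          paste(setdiff(operators, c("ratio", "product")), collapse = ", "))
  if (!is.numeric(max_depth) || max_depth != floor(max_depth) || max_depth < 0)
    stopf("max_depth must be a nonnegative integer")
  if (max_depth > 3)
    stopf("max_depth capped at 3 to bound the combinatorial expansion")
  structure(list(variables = variables, operators = operators,
                 max_depth = as.integer(max_depth)),
            class = "di_grammar")
}

#' @export
print.di_grammar <- function(x, ...) {
  cat("DI grammar:", length(x$variables), "base variables, depth <=",
      x$max_depth, "\n  variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

# all nonnegative integer k-vectors summing to p, lexicographic order
compositions_of <- function(p, k) {
  if (k == 1) return(matrix(p, 1, 1))
  do.call(rbind, lapply(0:p, function(i)
    cbind(i, compositions_of(p - i, k - 1), deparse.level = 0)))
}

#' Enumerate all distinct dimensionless indicators of a grammar
#'
#' Exhaustively enumerates the canonically distinct monomials the grammar
#' can express. Canonical form is the vector of per-variable integer
#' exponents; expressions that simplify to the same monomial (e.g.
#' `(N/L) * (L/N)`) collapse and are dropped, as is the empty monomial.
#' A depth-`d` expression is a product/ratio tree over up to `2^(d-1)`
#' base-variable ratios, so the enumeration covers every sum-zero exponent
#' vector whose positive degree is at most `2^(d-1)`. Enumeration order is
#' deterministic: by degree, then lexicographically.
#'
#' @param grammar a [di_grammar()].
#' @return Object of class `di_definitions`: list with `id` (canonical
#'   exponent signature), `formula` (readable form), `exponents` (integer
#'   matrix, definitions x variables), and the grammar.
#' @export
enumerate_dis <- function(grammar = di_grammar()) {
  stopifnot(inherits(grammar, "di_grammar"))
  vars <- grammar$variables
  k <- length(vars)
  if (grammar$max_depth == 0 || k < 2) {
    E <- matrix(integer(0), 0, k, dimnames = list(NULL, vars))
    return(structure(list(id = character(0), formula = character(0),
                          exponents = E, grammar = grammar),
                     class = "di_definitions"))
  }
  p_max <- 2^(grammar$max_depth - 1)
  blocks <- vector("list", p_max)
  for (p in seq_len(p_max)) {
    U <- compositions_of(p, k)
    sup <- (U > 0) * 1L
    disjoint <- sup %*% t(sup) == 0
    idx <- which(disjoint, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    blocks[[p]] <- U[idx[, 1], , drop = FALSE] - U[idx[, 2], , drop = FALSE]
  }
  E <- do.call(rbind, blocks)
  colnames(E) <- vars
  structure(list(id = di_ids(E), formula = di_formulas(E),
                 exponents = E, grammar = grammar),
            class = "di_definitions")
}

di_ids <- function(E) {
  codes <- di_variable_codes()[colnames(E)]
  id <- rep("", nrow(E))
  for (j in seq_len(ncol(E))) {
    nz <- E[, j] != 0
    piece <- paste0(codes[j], E[nz, j])
    id[nz] <- ifelse(id[nz] == "", piece, paste(id[nz], piece, sep = "."))
  }
  id
}

di_formulas <- function(E) {
  vars <- colnames(E)
  side <- function(M) {
    out <- rep("", nrow(M))
    nfac <- integer(nrow(M))
    for (j in seq_len(ncol(M))) {
      nz <- M[, j] > 0
      piece <- ifelse(M[nz, j] == 1, vars[j],
                      paste0(vars[j], "^", M[nz, j]))
      out[nz] <- ifelse(out[nz] == "", piece, paste(out[nz], piece, sep = "*"))
      nfac[nz] <- nfac[nz] + 1
    }
    list(s = out, n = nfac)
  }
  num <- side(E * (E > 0))
  den <- side(-E * (E < 0))
  ns <- ifelse(num$n == 0, "1", ifelse(num$n > 1, paste0("(", num$s, ")"), num$s))
  ds <- ifelse(den$n > 1, paste0("(", den$s, ")"), den$s)
  ifelse(den$n == 0, ns, paste0(ns, "/", ds))
}

#' @export
print.di_definitions <- function(x, ...) {
  cat("DI definitions:", length(x$id), "canonically distinct indicators\n")
  if (length(x$id) > 0) {
    show <- utils::head(data.frame(id = x$id, formula = x$formula,
                                   stringsAsFactors = FALSE), 6)
    print(show, row.names = FALSE)
    if (length(x$id) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.di_definitions <- function(x) length(x$id)

#' @export
`[.di_definitions` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(id = x$id[i], formula = x$formula[i],
                 exponents = x$exponents[i, , drop = FALSE],
                 grammar = x$grammar),
            class = "di_definitions")
}

# base-variable matrix (observations x variables) for a definition set
di_base_matrix <- function(obs, vars) {
  if (inherits(obs, "sepsis_cohort")) obs <- obs$observations
  X <- matrix(NA_real_, nrow(obs), length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    X[, v] <- if (grepl("_frac$", v)) {
      cc <- sub("_frac$", "_count", v)
      if (!cc %in% names(obs) || !"wbc_count" %in% names(obs))
        stopf("evaluate_dis: base variable %s needs columns %s and wbc_count",
              v, cc)
      obs[[cc]] / obs$wbc_count
    } else {
      if (!v %in% names(obs)) stopf("evaluate_dis: missing column %s", v)
      obs[[v]]
    }
  }
  X
}

#' Evaluate dimensionless indicators over a cohort
#'
#' Pure evaluation of each canonical monomial at each observation.
#'
#' @param obs a `sepsis_cohort` or observation data.frame.
#' @param definitions a `di_definitions` object.
#' @param ids optional subset of definition ids to evaluate.
#' @return Numeric matrix (observations x indicators) with the definition
#'   ids as column names; rows are named `patient_id:day` when available.
#'   Every value is finite and positive; a non-finite result (possible only
#'   on corrupted inputs) is an error naming the indicator and observation.
#' @export
evaluate_dis <- function(obs, definitions, ids = NULL) {
  stopifnot(inherits(definitions, "di_definitions"))
  if (!is.null(ids)) definitions <- definitions[ids]
  if (inherits(obs, "sepsis_cohort")) obs <- obs$observations
  E <- definitions$exponents
  used <- colnames(E)[colSums(E != 0) > 0]
  n <- nrow(obs)
  if (length(definitions$id) == 0) {
    M <- matrix(numeric(0), n, 0)
  } else {
    X <- di_base_matrix(obs, colnames(E))
    bad <- which(rowSums(is.na(X[, used, drop = FALSE]) |
                           X[, used, drop = FALSE] <= 0) > 0)
    if (length(bad) > 0)
      stopf("evaluate_dis: missing or non-positive base variable at observation %d",
            bad[1])
    lx <- log(X)
    lx[, setdiff(colnames(E), used)] <- 0   # unused vars may be NA
    M <- exp(lx %*% t(E))
    if (any(!is.finite(M))) {
      w <- which(!is.finite(M), arr.ind = TRUE)[1, ]
      stopf("non-finite DI value: indicator %s at observation %d (corrupt data?)",
            definitions$id[w[2]], w[1])
    }
    colnames(M) <- definitions$id
  }
  if (all(c("patient_id", "day") %in% names(obs)))
    rownames(M) <- paste(obs$patient_id, obs$day, sep = ":")
  M
}
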