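#' Min-max normalization
#'
#' Affine rescaling `(x - min) / (max - min)` onto `[0, 1]`.
#'
#' @param values Numeric vector with `max > min`.
#' @return Normalized vector (names preserved).
#' @export
min_max_normalize <- function(values) {
  values <- stats::setNames(as.numeric(values), names(values))
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) stop("degenerate range: all values equal ", lo)
  (values - lo) / (hi - lo)
}

#' Evaluate Boolean gates on normalized response features
#'
#' Per character, with strict inequalities throughout:
#' \describe{
#'   \item{AND}{`A > T_A` and `P > T_P` — large amplitude and long period.}
#'   \item{OR}{`A > T_A` or `P > T_P`.}
#'   \item{NOT}{small amplitude or brief period: `A < T_A` or `P < T_P`
#'     (`not_rule = "or"`, default); `not_rule = "and"` requires both.}
#'   \item{NAND / NOR}{element-wise negations of AND / OR.}
#' }
#' At the default thresholds `T_A = T_P = 1` no normalized value can
#' strictly exceed its threshold, giving the characteristic count pattern
#' (0, 0, 26, 26, 26).
#'
#' @param A_norm,P_norm Normalized amplitude and period vectors over the
#'   same 26 labels (named, or taken to be `A`-`Z` in order).
#' @param T_A,T_P Thresholds on the normalized scale.
#' @param not_rule Combination rule for the two published single-feature
#'   NOT gates: `"or"` (disjunction, default) or `"and"`.
#' @return A `gate_table`: list with `thresholds`, `gates` (named list of
#'   logical 26-vectors), and `table` (data frame `gate`, `count`,
#'   `characters`).
#' @export
evaluate_gates <- function(A_norm, P_norm, T_A = 1, T_P = 1,
                           not_rule = c("or", "and")) {
  not_rule <- match.arg(not_rule)
  if (length(A_norm) != length(P_norm)) stop("feature vectors differ in length")
  labels <- names(A_norm)
  if (is.null(labels)) labels <- LETTERS[seq_along(A_norm)]
  if (!is.null(names(P_norm)) && !identical(labels, names(P_norm))) {
    stop("label mismatch between amplitude and period vectors")
  }
  if (!all(is.finite(c(T_A, T_P)))) stop("thresholds must be finite")
  gates <- list(
    AND = A_norm > T_A & P_norm > T_P,
    OR = A_norm > T_A | P_norm > T_P,
    NOT = if (not_rule == "or") A_norm < T_A | P_norm < T_P else
      A_norm < T_A & P_norm < T_P
  )
  gates$NAND <- !gates$AND
  gates$NOR <- !gates$OR
  gates <- lapply(gates, stats::setNames, labels)
  tab <- data.frame(
    gate = names(gates),
    count = vapply(gates, sum, integer(1)),
    characters = vapply(gates, function(g) paste(labels[g], collapse = ", "),
                        ""),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(thresholds = c(T_A = T_A, T_P = T_P), not_rule = not_rule,
                 gates = gates, table = tab),
            class = "gate_table")
}

#' @export
print.gate_table <- function(x, ...) {
  cat(sprintf("<gate_table> T_A = %g, T_P = %g (NOT rule: %s)\n",
              x$thresholds["T_A"], x$thresholds["T_P"], x$not_rule))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Boolean-gate table from a profile table
#'
#' Min-max normalizes the 26 mean amplitudes and mean periods and evaluates
#' the five gates.
#'
#' @param profiles A `profile_table` (default: the packaged published
#'   table).
#' @inheritParams evaluate_gates
#' @return A `gate_table`.
#' @export
gates_from_profiles <- function(profiles = load_profile_table(check = "none"),
                                T_A = 1, T_P = 1, not_rule = c("or", "and")) {
  stopifnot(inherits(profiles, "profile_table"))
  A_norm <- min_max_normalize(stats::setNames(profiles$amp_mean,
                                              profiles$label))
  P_norm <- min_max_normalize(stats::setNames(profiles$per_mean,
                                              profiles$label))
  evaluate_gates(A_norm, P_norm, T_A = T_A, T_P = T_P, not_rule = not_rule)
}
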