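#' Estimate first and second moments of a field over the parameter cube
#'
#' Accumulates `M_m = sum_i w_i f(xi_i)^m`, `m = 1, 2`, with the rule's
#' weights; the variance is `M_2 - M_1^2`, clipped at zero.  An
#' inadmissible deformation at any node is an error naming the node —
#' silently skipping nodes would bias the moments.
#'
#' @param rule A [quadrature_rule()].
#' @param evaluator Deterministic function `xi -> numeric field vector`.
#' @param progress Print progress every so many nodes (0 = quiet).
#' @return An object of class `moment_field` with `m1`, `m2`, `var`,
#'   `std`, `n_nodes` and the rule provenance.
#' @export
estimate_moments <- function(rule, evaluator, progress = 0) {
  n <- nrow(rule$nodes)
  m1 <- NULL; m2 <- NULL
  for (i in seq_len(n)) {
    y <- tryCatch(evaluator(rule$nodes[i, ]),
                  error = function(e) stopf(
                    "evaluation failed at quadrature node %d of %d: %s",
                    i, n, conditionMessage(e)))
    if (is.null(m1)) { m1 <- 0 * y; m2 <- 0 * y }
    m1 <- m1 + rule$weights[i] * y
    m2 <- m2 + rule$weights[i] * y^2
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  node %d / %d", i, n))
  }
  v <- pmax(m2 - m1^2, 0)
  structure(list(m1 = m1, m2 = m2, var = v, std = sqrt(v),
                 n_nodes = n, provenance = rule$provenance),
            class = "moment_field")
}

# relative sup-norm discrepancy of a moment against a reference
moment_error <- function(m, ref) max(abs(m - ref)) / max(abs(ref))

#' Least-squares convergence rate on a log-log error plot
#'
#' @param n Budgets (numbers of nodes).
#' @param err Errors (same length; pairs with `err <= 0` are dropped).
#' @return Negated least-squares slope of `log10(err)` vs `log10(n)`.
#' @export
fit_rate <- function(n, err) {
  keep <- err > 0
  if (sum(keep) < 2) stopf("need at least two positive errors to fit a rate")
  -unname(stats::coef(stats::lm(log10(err[keep]) ~ log10(n[keep])))[2])
}

#' Convergence study of a sequence of quadrature rules
#'
#' For each rule, estimates the first and second moment of the field and
#' measures the relative sup-norm error against a reference
#' [estimate_moments()] result (computed with a substantially larger
#' budget); fits the pooled log-log convergence rate over both moments.
#'
#' @param rules List of at least three [quadrature_rule()]s.
#' @param evaluator As in [estimate_moments()].
#' @param reference A [estimate_moments()] result used as the truth.
#' @param progress Passed to [estimate_moments()].
#' @return List with `table` (data frame: n, error_m1, error_m2), `rate`
#'   (pooled fit), `rate_m1`, `rate_m2` and the per-rule `moments`.
#' @export
convergence_study <- function(rules, evaluator, reference, progress = 0) {
  if (length(rules) < 3)
    stopf("need at least three rule sizes for a convergence study")
  moments <- lapply(rules, estimate_moments, evaluator = evaluator,
                    progress = progress)
  n <- vapply(moments, function(m) m$n_nodes, 1)
  e1 <- vapply(moments, function(m) moment_error(m$m1, reference$m1), 1)
  e2 <- vapply(moments, function(m) moment_error(m$m2, reference$m2), 1)
  list(table = data.frame(n = n, error_m1 = e1, error_m2 = e2),
       rate = fit_rate(c(n, n), c(e1, e2)),
       rate_m1 = fit_rate(n, e1),
       rate_m2 = fit_rate(n, e2),
       moments = moments)
}
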