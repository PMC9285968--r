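# cached 1-D Gauss-Legendre rules on [-1, 1] with the uniform density 1/2
# (weights sum to one)
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre_1d <- function(m) {
  key <- as.character(m)
  hit <- .gl_cache[[key]]
  if (!is.null(hit)) return(hit)
  rule <- if (m == 1L) list(x = 0, w = 1) else {
    gl <- pracma::gaussLegendre(m, -1, 1)
    list(x = gl$x, w = gl$w / 2)
  }
  .gl_cache[[key]] <- rule
  rule
}

#' Quadrature rule on the parameter cube
#'
#' Nodes in `[-1, 1]^K` with weights that include the uniform product
#' density, so the weights of a moment rule sum to one.
#'
#' @param nodes `N x K` node matrix.
#' @param weights Length-`N` weight vector.
#' @param provenance Free-form tag (sparse level / QMC count).
#' @return An object of class `quadrature_rule`.
#' @export
quadrature_rule <- function(nodes, weights, provenance = NULL) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) != length(weights))
    stopf("one weight per node required")
  if (any(abs(nodes) > 1 + 1e-12))
    stopf("nodes must lie in the closed cube [-1, 1]^K")
  structure(list(nodes = nodes, weights = as.numeric(weights),
                 provenance = provenance),
            class = "quadrature_rule")
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat(sprintf("quadrature_rule: N=%d nodes in K=%d dims (%s)\n",
              nrow(x$nodes), ncol(x$nodes),
              paste(deparse(x$provenance), collapse = "")))
  invisible(x)
}

#' Anisotropy weights from the Karhunen-Loeve mode decay
#'
#' Dimension weights `alpha_j = max(1, log2(r_max / r_j))` with `r_j` the
#' sup norm of weighted mode `j`: dimensions whose modes have decayed the
#' most are refined last by the sparse rule.
#'
#' @param kl A [build_kl()] expansion.
#' @return Positive weights, smallest equal to 1.
#' @export
anisotropy_weights <- function(kl) {
  r <- apply(abs(kl$modes), 2, max)
  pmax(1, log2(max(r) / r))
}

# enumerate the anisotropic total-degree index set
# {k >= 0 : sum_j alpha_j k_j <= level}; indices are returned sparsely as
# lists with dims and orders of the non-zero entries
enumerate_index_set <- function(alpha, level) {
  active <- which(alpha <= level)
  out <- list(list(dims = integer(0), ords = integer(0)))
  recurse <- function(pos, budget, dims, ords) {
    for (ii in seq(pos, length(active))) {
      j <- active[ii]
      kmax <- floor(budget / alpha[j] + 1e-12)
      if (kmax < 1) next
      for (k in seq_len(kmax)) {
        nd <- c(dims, j); no <- c(ords, k)
        out[[length(out) + 1L]] <<- list(dims = nd, ords = no)
        if (ii < length(active))
          recurse(ii + 1L, budget - alpha[j] * k, nd, no)
      }
    }
  }
  if (length(active)) recurse(1L, level, integer(0), integer(0))
  out
}

#' Anisotropic sparse Gauss-Legendre quadrature
#'
#' Combination-technique (Smolyak) rule over the anisotropic total-degree
#' index set `{k : sum_j alpha_j k_j <= level}` with 1-D Gauss-Legendre
#' rules of size `m(l) = l + 1` and the uniform density `1/2` per
#' dimension.  Duplicate nodes arising from overlapping tensor grids are
#' merged.  The rule integrates constants exactly (weights sum to one) at
#' every level; level 0 is the single midpoint node.
#'
#' @param k_dims Parametric dimension K.
#' @param level Sparse-grid level L (>= 0).
#' @param alpha Per-dimension anisotropy weights (>= 1 after normalising
#'   the smallest to 1); default isotropic.
#' @param node_budget Reject rules exceeding this many nodes.
#' @return A [quadrature_rule()] with provenance
#'   `list(method = "sparse", level, n_raw)`.
#' @export
sparse_rule <- function(k_dims, level, alpha = rep(1, k_dims),
                        node_budget = Inf) {
  comb <- sparse_combination(k_dims, level, alpha)
  nodes_list <- list(); w_list <- list()
  total_raw <- 0L
  for (term in comb) {
    cf <- term$coef
    dims <- term$dims; ords <- term$ords
    rules <- lapply(ords, function(k) gauss_legendre_1d(k + 1L))
    grid <- if (length(dims))
      as.matrix(expand.grid(lapply(rules, `[[`, "x"))) else
      matrix(0, 1, 0)
    wgrid <- if (length(dims))
      apply(as.matrix(expand.grid(lapply(rules, `[[`, "w"))), 1, prod) else 1
    nd <- matrix(0, nrow(grid), k_dims)
    if (length(dims)) nd[, dims] <- grid
    total_raw <- total_raw + nrow(nd)
    if (total_raw > node_budget)
      stopf("sparse rule at level %g exceeds the node budget (%d > %g)",
            level, total_raw, node_budget)
    nodes_list[[length(nodes_list) + 1L]] <- nd
    w_list[[length(w_list) + 1L]] <- cf * wgrid
  }
  nodes <- do.call(rbind, nodes_list)
  weights <- unlist(w_list)
  # merge duplicate nodes
  key <- apply(signif(nodes, 13), 1, paste, collapse = ",")
  agg <- rowsum(weights, key)
  first <- !duplicated(key)
  nodes <- nodes[first, , drop = FALSE]
  weights <- as.numeric(agg[match(key[first], rownames(agg)), 1])
  quadrature_rule(nodes, weights,
                  provenance = list(method = "sparse", level = level,
                                    n_raw = total_raw))
}

# combination-technique terms: tensor grids T_k with non-zero coefficient
# c_k = sum over e in {0,1}^K with k + e in the index set of (-1)^|e|
sparse_combination <- function(k_dims, level, alpha = rep(1, k_dims)) {
  if (level < 0) stopf("level must be non-negative")
  if (length(alpha) != k_dims) stopf("one anisotropy weight per dimension")
  alpha <- alpha / min(alpha)
  idx <- enumerate_index_set(alpha, level)
  coefs <- new.env(parent = emptyenv())
  keyof <- function(dims, ords)
    if (!length(dims)) "o" else paste(dims, ords, sep = ":", collapse = ",")
  for (ix in idx) {
    supp <- seq_along(ix$dims)
    nsub <- bitwShiftL(1L, length(supp))
    for (mask in 0:(nsub - 1L)) {
      e <- bitwAnd(bitwShiftR(mask, supp - 1L), 1L) == 1L
      no <- ix$ords - e
      keep <- no > 0L
      key <- keyof(ix$dims[keep], no[keep])
      coefs[[key]] <- (if (is.null(coefs[[key]])) 0 else coefs[[key]]) +
        (-1)^sum(e)
    }
  }
  out <- list()
  for (key in ls(coefs, all.names = TRUE)) {
    if (abs(coefs[[key]]) < 1e-12) next
    if (key == "o") { dims <- integer(0); ords <- integer(0) } else {
      parts <- strsplit(strsplit(key, ",")[[1]], ":")
      dims <- vapply(parts, function(p) as.integer(p[1]), 1L)
      ords <- vapply(parts, function(p) as.integer(p[2]), 1L)
    }
    out[[length(out) + 1L]] <- list(dims = dims, ords = ords,
                                    coef = coefs[[key]])
  }
  out
}

# number of nodes of the sparse rule before merging (cheap size probe)
sparse_rule_size <- function(k_dims, level, alpha = rep(1, k_dims)) {
  comb <- sparse_combination(k_dims, level, alpha)
  sum(vapply(comb, function(term) prod(term$ords + 1), 1))
}

# radical inverse of integers ii (vector) in base b
radical_inverse <- function(ii, b) {
  out <- numeric(length(ii))
  f <- 1 / b
  while (any(ii > 0)) {
    out <- out + f * (ii %% b)
    ii <- ii %/% b
    f <- f / b
  }
  out
}

#' Halton quasi-Monte Carlo rule
#'
#' First `n` points of the (unscrambled) Halton sequence in bases the
#' first `k_dims` primes, radical inverse starting at index 1, mapped to
#' `[-1, 1]^K` by `x -> 2x - 1`, with equal weights `1/n`.
#'
#' @param k_dims Parametric dimension K.
#' @param n Number of points.
#' @return A [quadrature_rule()] with provenance
#'   `list(method = "halton", n = n)`.
#' @export
halton_rule <- function(k_dims, n) {
  if (n < 1) stopf("n must be at least 1")
  bound <- max(100, 20 * k_dims)
  primes <- pracma::primes(bound)
  while (length(primes) < k_dims) {
    bound <- bound * 2
    primes <- pracma::primes(bound)
  }
  primes <- primes[seq_len(k_dims)]
  nodes <- vapply(primes, function(b) 2 * radical_inverse(seq_len(n), b) - 1,
                  numeric(n))
  quadrature_rule(matrix(nodes, nrow = n), rep(1 / n, n),
                  provenance = list(method = "halton", n = n))
}
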