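test_that("sparse rules integrate polynomials with Gauss exactness", {
  # level 0: the single midpoint node with unit weight
  r0 <- sparse_rule(7L, 0)
  expect_identical(nrow(r0$nodes), 1L)
  expect_true(all(r0$nodes == 0))
  expect_identical(r0$weights, 1)
  # K = 1 reduces to plain Gauss-Legendre: moment of xi^2 is 1/3
  for (l in 1:4) {
    r <- sparse_rule(1L, l)
    expect_identical(nrow(r$nodes), l + 1L)
    expect_equal(sum(r$weights * r$nodes[, 1]^2), 1 / 3, tolerance = 1e-13)
  }
  # constants are integrated exactly at every level and anisotropy
  for (l in c(0, 1, 2.5, 4)) {
    r <- sparse_rule(5L, l, alpha = c(1, 1, 1.7, 2.4, 6))
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
  }
})

test_that("the combination technique matches brute-force enumeration", {
  # independent implementation: expand Delta_k1 x Delta_k2 over the
  # isotropic total-degree set |k| <= 2 directly
  gl <- function(m) if (m == 1) list(x = 0, w = 1) else {
    g <- pracma::gaussLegendre(m, -1, 1); list(x = g$x, w = g$w / 2)
  }
  nodes <- NULL; w <- NULL
  for (k1 in 0:2) for (k2 in 0:(2 - k1)) {
    for (e1 in 0:min(1, k1)) for (e2 in 0:min(1, k2)) {
      r1 <- gl(k1 - e1 + 1); r2 <- gl(k2 - e2 + 1)
      g <- expand.grid(x1 = r1$x, x2 = r2$x)
      gw <- expand.grid(w1 = r1$w, w2 = r2$w)
      nodes <- rbind(nodes, as.matrix(g))
      w <- c(w, (-1)^(e1 + e2) * gw$w1 * gw$w2)
    }
  }
  key <- apply(signif(nodes, 12), 1, paste, collapse = ",")
  ref_w <- rowsum(w, key)
  ref_w <- ref_w[abs(ref_w[, 1]) > 1e-14, , drop = FALSE]
  r <- sparse_rule(2L, 2)
  got_key <- apply(signif(r$nodes, 12), 1, paste, collapse = ",")
  keep <- abs(r$weights) > 1e-14
  expect_setequal(got_key[keep], rownames(ref_w))
  m <- match(got_key[keep], rownames(ref_w))
  expect_lt(max(abs(r$weights[keep] - ref_w[m, 1])), 1e-13)
})

test_that("node counts grow monotonically with the level", {
  alpha <- c(1, 1.3, 2.1, 4)
  sizes <- vapply(0:5, function(l) sparse_rule_size(4L, l, alpha), 1)
  expect_true(all(diff(sizes) >= 0))
  expect_error(sparse_rule(4L, 5, alpha, node_budget = 10), "budget")
})

test_that("Halton points are the classic radical-inverse sequence", {
  r <- halton_rule(2L, 3L)
  expect_equal(r$nodes[1, ], c(0, -1 / 3), tolerance = 1e-15)
  expect_equal(r$nodes[2, ], c(-1 / 2, 1 / 3), tolerance = 1e-15)
  expect_equal(r$nodes[3, ], c(1 / 2, -7 / 9), tolerance = 1e-15)
  expect_identical(r$weights, rep(1 / 3, 3))
  # equidistribution sanity at larger n, many dims (first primes as bases)
  big <- halton_rule(25L, 2000L)
  expect_true(all(abs(big$nodes) <= 1))
  expect_lt(max(abs(colMeans(big$nodes))), 0.05)
  expect_equal(sum(big$weights), 1, tolerance = 1e-12)
})

test_that("anisotropy weights are normalised and decay-adaptive", {
  kl <- default_snapshot()$kl
  a <- anisotropy_weights(kl)
  expect_identical(length(a), kl$rank)
  expect_equal(min(a), 1)
  expect_true(all(a >= 1))
  # heavier modes get smaller weights (refined earlier), on average
  r <- apply(abs(kl$modes), 2, max)
  expect_lt(mean(a[r >= stats::median(r)]), mean(a[r < stats::median(r)]))
})
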