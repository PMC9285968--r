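# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# circle of radius a: exactly an order-1 trigonometric curve
circle_curve <- function(a, role = "chest") {
  closed_curve(c(0, a), c(0, 0), c(0, 0), c(0, a), role = role)
}

# concentric-circle annulus oracle: pericardium radius a inside chest
# radius b; separation of variables gives, for u = cos(2 pi m s),
# chest amplitude 2 a^m b^m / (a^(2m) + b^(2m)) and pericardial normal
# derivative (exterior-to-domain normal) with closed-form amplitude
annulus_blocks <- function(a = 1, b = 2, n = 128L) {
  memo(sprintf("annulus_%g_%g_%d", a, b, n), function()
    assemble_blocks(circle_curve(a, "pericardium"), circle_curve(b, "chest"),
                    n, n))
}

annulus_chest_amp <- function(a, b, m) 2 * a^m * b^m / (a^(2 * m) + b^(2 * m))

default_torso <- function() memo("torso", function() synthesize_torso())

default_snapshot <- function(n_sigma = 64L)
  memo(sprintf("snap_%d", n_sigma), function()
    uq_snapshot(default_torso(), n_sigma = n_sigma))

# small uniform points on a closed curve for fitting tests
sample_points <- function(f, n) t(vapply((seq_len(n) - 1) / n, f, numeric(2)))
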