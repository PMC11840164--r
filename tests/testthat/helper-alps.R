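# Shared fixtures, all generated in code.

# Small fittable scheme: n_dir directions at b = 1000 plus one b0.
test_scheme <- function(n_dir = 32, bval = 1000) {
  default_scheme(n_dir = n_dir, bval = bval)
}

# Random symmetric positive-definite tensor at brain-tissue scale (mm^2/s).
random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  D <- crossprod(A)
  D <- D / max(eigen(D, only.values = TRUE)$values) * 1.5e-3
  D + diag(3) * 1e-4
}

# Small noise-free phantom spec for fast pipeline checks.
quick_phantom <- function(g = 0.2e-3, noise = "none", seed = 1L,
                          n_dir = 32, ...) {
  phantom_spec(dims = c(10, 10, 6), g = g, noise = noise, seed = seed,
               scheme = test_scheme(n_dir), ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}

# All permutations of 1:n as rows of a matrix.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
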