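# Independent oracles used to validate the implementation paths.

# Natural cubic spline via the truncated power basis: with knots
# xi_1 < ... < xi_K (boundary knots included), the K-dimensional space is
# spanned by {1, x, d_k(x) - d_{K-1}(x), k = 1..K-2} where
# d_k(x) = ((x - xi_k)_+^3 - (x - xi_K)_+^3) / (xi_K - xi_k).
tpb_natural_basis <- function(x, knots) {
  knots <- sort(knots)
  K <- length(knots)
  pos3 <- function(u) pmax(u, 0)^3
  d <- function(k) (pos3(x - knots[k]) - pos3(x - knots[K])) /
    (knots[K] - knots[k])
  cols <- lapply(seq_len(K - 2L), function(k) d(k) - d(K - 1L))
  cbind(x, do.call(cbind, cols))
}

# Hand-coded Welch t-test.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Hand-coded pooled-variance t-test.
pooled_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Hand-coded paired t-test.
paired_oracle <- function(x, y) {
  d <- x - y; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# BH step-up q-values from the definition: sort ascending, q_(i) =
# min_{j >= i} p_(j) * m / j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Small reference timecourse for trajectory tests.
make_reference <- function(seed = 1, n_per_age = 8,
                           ages = seq(21, 112, by = 7), ...) {
  timecourse_from_records(
    generate_reference_timecourse(ages, n_per_age, seed = seed, ...))
}

# A genuinely peaked mean trajectory (not spline-representable) for tests
# that need an interior maximum.
peaked_trajectory <- function(age)
  1 + 0.5 * exp(-0.5 * ((age - 42) / 12)^2)
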