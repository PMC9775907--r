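# Independent nullcline oracle for a 2-node toggle switch parameter set:
# counts stable fixed points by 1-D root bracketing on the A-nullcline
# composed with the B-nullcline, with linear stability from the Jacobian
# determinant (trace is always negative). Kept free of the integrator code
# it is used to check.
ts_nullcline_count <- function(ps) {
  gA <- ps$G[["A"]] / ps$k[["A"]]
  gB <- ps$G[["B"]] / ps$k[["B"]]
  eBA <- ps$edges[ps$edges$source == "B" & ps$edges$target == "A", ]
  eAB <- ps$edges[ps$edges$source == "A" & ps$edges$target == "B", ]
  H <- function(x, e) {
    (e$threshold^e$n + e$lambda * x^e$n) / (e$threshold^e$n + x^e$n)
  }
  Hp <- function(x, e) {
    t0 <- e$threshold^e$n
    (e$lambda - 1) * t0 * e$n * x^(e$n - 1) / (t0 + x^e$n)^2
  }
  B_of <- function(A) gB * H(A, eAB)
  f <- function(A) gA * H(B_of(A), eBA) - A
  grid <- sort(unique(c(0, 10^seq(-4, log10(gA) + 0.5, length.out = 4000),
                        gA * 1.1)))
  fv <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (fv[i] == 0) {
      roots <- c(roots, grid[i])
    } else if (fv[i] * fv[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                       tol = 1e-12)$root)
    }
  }
  n_stable <- 0L
  for (A in roots) {
    B <- B_of(A)
    det_j <- ps$k[["A"]] * ps$k[["B"]] -
      ps$G[["A"]] * Hp(B, eBA) * ps$G[["B"]] * Hp(A, eAB)
    if (det_j > 0) n_stable <- n_stable + 1L
  }
  n_stable
}

# hand-build a symmetric TS parameter set (equal rates, thresholds at the
# half point G/(2k)) with a given inhibitory fold change
symmetric_ts_params <- function(lambda_inh, G = 40, k = 0.5, n = 4) {
  edges <- build_motif("TS")$edges
  edges$n <- n
  edges$lambda <- lambda_inh
  edges$threshold <- G / (2 * k)
  structure(list(G = c(A = G, B = G), k = c(A = k, B = k), edges = edges),
            class = "parameter_set")
}
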