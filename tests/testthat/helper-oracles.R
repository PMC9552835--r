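# Independent oracles shared by the junction and acceptance tests.

# Random plausible junction port setups around a working state.
random_ports <- function(n_parents, n_children, seed) {
  set.seed(seed)
  n <- n_parents + n_children
  lapply(seq_len(n), function(k) {
    parent <- k <= n_parents
    A0 <- runif(1, 0.03, 0.15)
    law <- wall_law("coronary")
    f <- stiffness_f(sqrt(A0 / pi), law)
    r <- runif(1, 800, 2500)          # dx/dt
    Aop <- A0 * runif(1, 1.0, 1.05)   # operating area
    Qop <- runif(1, -1, 3)
    # intercept chosen so the affine relation passes near (Aop, Qop)
    icpt <- Qop - (if (parent) -r else r) * Aop
    junction_port(if (parent) "parent" else "child",
                  list(slope = if (parent) -r else r, intercept = icpt),
                  A0 = A0, f = f, A_init = Aop, P0 = 76.41 * 1333.22)
  })
}

# Dense iterated grid search over the area box minimising the squared
# residuals of the junction system; derivative-free and independent of the
# Newton implementation.
brute_force_junction <- function(ports, rho = 1.06) {
  n <- length(ports)
  sgn <- vapply(ports, function(p) if (p$role == "parent") 1 else -1, 0)
  slope <- vapply(ports, `[[`, 0, "slope")
  icpt <- vapply(ports, `[[`, 0, "intercept")
  A0 <- vapply(ports, `[[`, 0, "A0")
  f <- vapply(ports, `[[`, 0, "f")
  P0 <- vapply(ports, `[[`, 0, "P0")
  obj <- function(Amat) {  # rows = candidate area vectors
    Qm <- sweep(sweep(Amat, 2, slope, "*"), 2, icpt, "+")
    Pm <- sweep(1 - sqrt(sweep(1 / Amat, 2, A0, "*")), 2, f, "*")
    Pm <- sweep(Pm, 2, P0, "+")
    phi <- Pm + rho / 2 * (Qm / Amat)^2
    rmass <- (Qm %*% sgn) / (mean(abs(slope)) * mean(A0))
    rp <- (phi[, 1] - phi[, -1, drop = FALSE]) / mean(f)
    rmass^2 + rowSums(rp^2)
  }
  centre <- vapply(ports, `[[`, 0, "A_init")
  width <- 0.4 * centre
  for (iter in 1:16) {
    grids <- lapply(seq_len(n), function(k) {
      seq(centre[k] - width[k], centre[k] + width[k], length.out = 7)
    })
    Amat <- as.matrix(do.call(expand.grid, grids))
    Amat <- Amat[apply(Amat > 0, 1, all), , drop = FALSE]
    best <- which.min(obj(Amat))
    centre <- Amat[best, ]
    width <- width * 0.34
  }
  centre
}

# Sub-sample peak time by parabolic refinement around the sampled maximum.
peak_time <- function(tt, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(tt[i])
  d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
  tt[i] + d * (tt[2] - tt[1])
}
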