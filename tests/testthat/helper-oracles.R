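# Independent oracles kept deliberately separate from the package
# implementations: closed-form OLS, brute-force maximin grid search, and a
# tiny random pathway generator for property tests.

R_KJ_ORACLE <- 8.314e-3

# Closed-form OLS (X'X)^{-1} X'y with intercept.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)  # (intercept, slope)
}

# Exhaustive grid-search maximin driving force. S: metabolites x reactions.
# Returns list(B, tol): the grid optimum and the resolution bound on how far
# it can sit below the true optimum.
grid_mdf_oracle <- function(S, dg0, lb_M, ub_M, pts = 21, T_K = 298.15) {
  RT <- R_KJ_ORACLE * T_K
  lb <- log(lb_M); ub <- log(ub_M)
  grids <- mapply(function(l, u) seq(l, u, length.out = pts),
                  lb, ub, SIMPLIFY = FALSE)
  X <- as.matrix(expand.grid(grids))
  G <- X %*% S                                   # sum_i s_ij x_i per row
  force <- NULL
  for (j in seq_along(dg0)) {
    fj <- -(dg0[j] + RT * G[, j])
    force <- if (is.null(force)) fj else pmin(force, fj)
  }
  steps <- vapply(grids, function(g) if (length(g) > 1) g[2] - g[1] else 0,
                  numeric(1))
  tol <- max(RT * colSums(abs(S) * steps / 2))
  list(B = max(force), tol = tol)
}

# Random small pathway instance: <= 4 metabolites, 1-3 reactions, +/-1
# coefficients, each reaction consuming and producing something.
random_mdf_instance <- function() {
  n_met <- sample(2:4, 1)
  n_rxn <- sample(1:3, 1)
  repeat {
    S <- matrix(0, n_met, n_rxn)
    for (j in seq_len(n_rxn)) {
      k <- if (n_met == 2) 2L else sample(2:n_met, 1)
      rows <- sample(n_met, k)
      signs <- c(-1, 1, sample(c(-1, 1), k - 2, replace = TRUE))
      S[rows, j] <- signs
    }
    if (all(colSums(S < 0) >= 1) && all(colSums(S > 0) >= 1)) break
  }
  rownames(S) <- paste0("m", seq_len(n_met))
  dg0 <- runif(n_rxn, -10, 10)
  lb <- 10^runif(n_met, -6, -4)
  ub <- lb * 10^runif(n_met, 1, 3)
  list(S = S, dg0 = dg0, lb = setNames(lb, rownames(S)),
       ub = setNames(ub, rownames(S)))
}

# Wrap a raw (S, dg0) instance as a pathway_spec.
instance_to_pathway <- function(inst) {
  rxns <- lapply(seq_len(ncol(inst$S)), function(j) {
    st <- inst$S[, j]
    reaction_spec(paste0("r", j), st[st != 0], inst$dg0[j])
  })
  pathway_spec(rxns)
}
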