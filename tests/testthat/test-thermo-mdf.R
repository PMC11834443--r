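test_that("driving force matches closed forms", {
  r <- reaction_spec("r", c(a = -1, b = 1), dg0_prime = 0)
  expect_equal(driving_force(r, c(a = 1, b = 1)), 0)
  # frozen: RT * ln(1e-4) at 298.15 K
  expect_equal(driving_force(r, c(a = 1e-2, b = 1e-6)),
               -22.830767631555663, tolerance = 1e-12)
  # balanced reaction (sum s_i = 0): scaling all concentrations is neutral
  r2 <- reaction_spec("r2", c(a = -1, b = -1, c = 1, d = 1), dg0_prime = 3)
  cc <- c(a = 1e-3, b = 2e-3, c = 5e-4, d = 1e-5)
  expect_equal(driving_force(r2, cc), driving_force(r2, 2 * cc),
               tolerance = 1e-12)
  expect_error(driving_force(r, c(a = 1e-3)), "missing concentrations")
  expect_error(driving_force(r, c(a = 1e-3, b = -1)), "> 0")
})

test_that("water is excluded from concentration terms", {
  r <- reaction_spec("eno", c(pep = -1, h2o = -1, `2pg` = 1), dg0_prime = 4)
  expect_equal(driving_force(r, c(pep = 1e-3, `2pg` = 1e-3)), 4)
  pw <- pathway_spec(list(r))
  expect_false("h2o" %in% pw$metabolites)
})

test_that("solve_mdf reproduces closed-form single-reaction optima", {
  r <- reaction_spec("r", c(a = -1, b = 1), dg0_prime = 0)
  pw <- pathway_spec(list(r))
  # both species pinned at 1 mM: equilibrium
  pinned <- concentration_bounds(c(a = 1e-3, b = 1e-3), c(a = 1e-3, b = 1e-3))
  sol <- solve_mdf(pw, pinned)
  expect_equal(sol$mdf_B, 0, tolerance = 1e-9)
  expect_equal(unname(sol$dg_prime), 0, tolerance = 1e-9)
  # default range: a at 10 mM, b at 1 uM
  sol2 <- solve_mdf(pw, default_bounds(pw$metabolites))
  expect_equal(sol2$mdf_B, 22.830767631555663, tolerance = 1e-8)
  expect_equal(max(sol2$dg_prime), -sol2$mdf_B, tolerance = 1e-8)
  expect_true(all(sol2$log_conc >= log(1e-6) - 1e-9 &
                    sol2$log_conc <= log(1e-2) + 1e-9))
})

test_that("LP optimum matches the brute-force grid oracle on random pathways", {
  withr::with_seed(11, {
    for (i in 1:12) {
      inst <- random_mdf_instance()
      pw <- instance_to_pathway(inst)
      sol <- solve_mdf(pw, concentration_bounds(inst$lb, inst$ub))
      oracle <- grid_mdf_oracle(inst$S, inst$dg0, inst$lb, inst$ub, pts = 21)
      # grid points are feasible, so the LP can never fall below the grid;
      # it can exceed it only within the grid resolution bound
      expect_gte(sol$mdf_B, oracle$B - 1e-6)
      expect_lte(sol$mdf_B, oracle$B + oracle$tol + 1e-6)
    }
  })
})

test_that("widening concentration bounds never decreases the MDF", {
  withr::with_seed(23, {
    for (i in 1:10) {
      inst <- random_mdf_instance()
      pw <- instance_to_pathway(inst)
      b0 <- concentration_bounds(inst$lb, inst$ub)
      B0 <- solve_mdf(pw, b0)$mdf_B
      wide <- sample(length(inst$lb), 1)
      lb2 <- inst$lb; ub2 <- inst$ub
      lb2[wide] <- lb2[wide] / 10; ub2[wide] <- ub2[wide] * 10
      B1 <- solve_mdf(pw, concentration_bounds(lb2, ub2))$mdf_B
      expect_gte(B1, B0 - 1e-8)
    }
  })
})

test_that("bounds from measured concentrations follow the percent rule", {
  b <- make_bounds_from_measured(c(atp = 4e-3), percent_range = 100)
  expect_equal(unname(b$ub["atp"]), 8e-3)
  expect_equal(unname(b$lb["atp"]), 1e-9)  # clipped to the positive floor
  b2 <- make_bounds_from_measured(c(x = 1e-3), percent_range = 0)
  expect_equal(unname(b2$lb["x"]), 1e-3)
  expect_equal(unname(b2$ub["x"]), 1e-3)
  b3 <- make_bounds_from_measured(c(x = 1e-3), percent_range = 40)
  expect_equal(unname(b3$lb["x"]), 0.6e-3)
  expect_equal(unname(b3$ub["x"]), 1.4e-3)
  b4 <- make_bounds_from_measured(c(x = 1e-3), 40, metabolites = c("x", "y"))
  expect_equal(unname(b4$lb["y"]), 1e-6)
  expect_equal(unname(b4$ub["y"]), 1e-2)
  expect_error(make_bounds_from_measured(c(x = -1), 40), "> 0")
  expect_error(make_bounds_from_measured(c(x = 1e-3), 250), "\\[0, 200\\)")
})

test_that("cumulative profiles telescope and ignore intermediate choices", {
  # linear chain a -> b -> c -> d
  rxns <- list(reaction_spec("r1", c(a = -1, b = 1), -3),
               reaction_spec("r2", c(b = -1, c = 1), -1),
               reaction_spec("r3", c(c = -1, d = 1), 2))
  pw <- pathway_spec(rxns)
  conc1 <- c(a = 1e-3, b = 1e-4, c = 1e-5, d = 1e-3)
  conc2 <- c(a = 1e-3, b = 1e-6, c = 1e-2, d = 1e-3)  # permuted interior
  total1 <- sum(vapply(rxns, driving_force, numeric(1), conc1))
  total2 <- sum(vapply(rxns, driving_force, numeric(1), conc2))
  expect_equal(total1, total2, tolerance = 1e-10)

  sol <- solve_mdf(pw, default_bounds(pw$metabolites))
  prof <- cumulative_profile(sol, pw)
  expect_equal(prof$cumulative, cumsum(prof$dg_prime))
  # the 1 mM reference profile is just the dG'0 running sum for a chain
  expect_equal(prof$reference_cumulative, cumsum(c(-3, -1, 2)))
  # two fixed reactions: cumulative is the running sum
  pinned <- concentration_bounds(
    setNames(rep(1e-3, 4), pw$metabolites),
    setNames(rep(1e-3, 4), pw$metabolites))
  prof2 <- cumulative_profile(solve_mdf(pw, pinned), pw)
  expect_equal(prof2$cumulative, cumsum(c(-3, -1, 2)))
})

test_that("bottleneck detection reports all ties and respects the tolerance", {
  rxns <- list(reaction_spec("r1", c(a = -1, b = 1), 0),
               reaction_spec("r2", c(b = -1, c = 1), 0))
  pw <- pathway_spec(rxns)
  # symmetric chain: both reactions bind at the optimum
  sol <- solve_mdf(pw, default_bounds(pw$metabolites))
  expect_setequal(sol$bottlenecks, c("r1", "r2"))
  # independent reactions with skewed dG'0: only the weaker one binds
  rxns2 <- list(reaction_spec("r1", c(a = -1, b = 1), 0),
                reaction_spec("r2", c(c = -1, d = 1), -30))
  sol2 <- solve_mdf(pathway_spec(rxns2), default_bounds(c("a", "b", "c", "d")))
  expect_identical(sol2$bottlenecks, "r1")
  # recomputing dG' at the optimum reproduces the bottleneck set
  recomp <- vapply(rxns2, driving_force, numeric(1), sol2$concentrations_M)
  expect_setequal(sol2$bottlenecks,
                  c("r1", "r2")[recomp >= -sol2$mdf_B - 0.1])
})

test_that("flux-force ratios satisfy the exact identities", {
  ff0 <- flux_force(0)
  expect_equal(ff0$net_ratio, 0)
  expect_equal(ff0$forward_ratio, 0.5)
  expect_equal(ff0$reverse_ratio, 0.5)
  dg <- seq(-30, 30, length.out = 101)
  ff <- flux_force(dg)
  expect_equal(ff$forward_ratio + ff$reverse_ratio, rep(1, 101),
               tolerance = 1e-14)
  expect_equal(ff$net_ratio, ff$forward_ratio - ff$reverse_ratio,
               tolerance = 1e-12)
  RT <- 8.314e-3 * 298.15
  expect_equal(ff$net_ratio, tanh(-dg / (2 * RT)), tolerance = 1e-14)
  expect_true(all(sign(ff$net_ratio) == -sign(dg)))
  # frozen evaluations of the printed relation
  expect_equal(flux_force(-2.97)$net_ratio, 0.5363914465985693,
               tolerance = 1e-12)
  expect_equal(flux_force(-0.27)$net_ratio, 0.054407635513936514,
               tolerance = 1e-12)
})

test_that("reaction formulas parse with coefficients and duplicate species", {
  st <- parse_reaction_formula("pyruvate + atp + hco3 = oaa + adp + pi")
  expect_equal(st[["pyruvate"]], -1)
  expect_equal(st[["oaa"]], 1)
  st2 <- parse_reaction_formula("2 pg + 2 atp = 2 bpg + 2 adp")
  expect_equal(st2[["pg"]], -2)
  expect_equal(st2[["bpg"]], 2)
  expect_error(parse_reaction_formula("a + b"), "exactly one '='")
})

test_that("infeasible and degenerate bound sets are rejected loudly", {
  expect_error(concentration_bounds(c(a = 1e-3), c(a = 1e-4)), ">=")
  expect_error(concentration_bounds(c(a = 0), c(a = 1e-3)),
               "strictly positive")
})
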