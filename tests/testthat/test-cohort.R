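test_that("event draws follow the per-individual risks", {
  expect_identical(simulate_events(rep(0, 100)), rep(0L, 100))
  expect_identical(simulate_events(rep(1, 100)), rep(1L, 100))
  expect_error(simulate_events(c(0.5, 1.2)), "probabilities")

  set.seed(5)
  ev <- simulate_events(rep(0.1, 1e6))
  # 4 binomial SE: sqrt(0.1 * 0.9 / 1e6) * 4 = 0.0012
  expect_lt(abs(mean(ev) - 0.1), 0.0012)
})

test_that("fatality rates satisfy the overall-rate constraint exactly", {
  # no differential: both genotypes share the overall rate
  r0 <- solve_fatality_rates(F = 0.5, d = 0, q = 0.59)
  expect_equal(r0$f_c, 0.5)
  expect_equal(r0$f_n, 0.5)

  # independent oracle: solve the two linear constraints directly
  lin_solve <- function(F, d, q, convention) {
    if (convention == "relative") {
      # q*f_c + (1-q)*f_n = F ; (1-d)*f_c - f_n = 0
      as.numeric(solve(rbind(c(q, 1 - q), c(1 - d, -1)), c(F, 0)))
    } else {
      # q*f_c + (1-q)*f_n = F ; f_c - f_n = d*F
      as.numeric(solve(rbind(c(q, 1 - q), c(1, -1)), c(F, d * F)))
    }
  }

  r <- solve_fatality_rates(0.5, 0.25, 0.59, convention = "relative")
  expect_equal(c(r$f_c, r$f_n), lin_solve(0.5, 0.25, 0.59, "relative"),
               tolerance = 1e-12)
  expect_equal(r$f_c, 0.55710306, tolerance = 1e-7)
  expect_equal(r$f_n, 0.41782729, tolerance = 1e-7)

  r2 <- solve_fatality_rates(0.415, 0.10, 0.59, convention = "relative")
  expect_equal(c(r2$f_c, r2$f_n), lin_solve(0.415, 0.10, 0.59, "relative"),
               tolerance = 1e-12)
  expect_equal(r2$f_c, 0.43274244, tolerance = 1e-7)
  expect_equal(r2$f_n, 0.38946819, tolerance = 1e-7)

  # default convention reproduces the canonical 55% / 43% illustration
  r3 <- solve_fatality_rates(0.5, 0.25, 0.59)
  expect_equal(c(r3$f_c, r3$f_n),
               lin_solve(0.5, 0.25, 0.59, "mean_relative"), tolerance = 1e-12)
  expect_equal(round(100 * r3$f_c), 55)
  expect_equal(round(100 * r3$f_n), 43)
  expect_equal(0.59 * r3$f_c + 0.41 * r3$f_n, 0.5, tolerance = 1e-12)
})

test_that("weighted fatality is conserved over a parameter sweep", {
  set.seed(42)
  for (i in 1:200) {
    F <- runif(1, 0, 0.7)
    d <- runif(1, 0, 0.5)
    q <- runif(1, 0.05, 0.95)
    conv <- sample(c("relative", "mean_relative"), 1)
    r <- try(solve_fatality_rates(F, d, q, conv), silent = TRUE)
    if (inherits(r, "try-error")) next  # infeasible corner, correctly refused
    expect_lt(abs(q * r$f_c + (1 - q) * r$f_n - F), 1e-9)
    expect_true(r$f_n <= r$f_c)
    expect_true(r$f_n >= 0 && r$f_c < 1)
  }
  expect_error(solve_fatality_rates(0.9, 0.8, 0.59, "relative"), "infeasible")
})

test_that("survival filtering excludes exactly the fatal cases", {
  n <- 1e5
  set.seed(9)
  cohort <- data.frame(
    carrier = rep(c(1L, 0L), c(59000, 41000)),
    event = simulate_events(rep(0.5, n))
  )
  no_fatal <- structure(list(f_c = 0, f_n = 0, F = 0, d = 0, q = 0.59,
                             convention = "relative"),
                        class = "fatality_rates")
  out <- apply_survival_filter(cohort, no_fatal)
  expect_true(all(out$included == 1L))
  expect_true(all(out$fatal == 0L))

  all_fatal <- structure(list(f_c = 1, f_n = 1, F = 1, d = 0, q = 0.59,
                              convention = "relative"),
                         class = "fatality_rates")
  out2 <- apply_survival_filter(cohort, all_fatal)
  expect_identical(out2$fatal, out2$event)
  expect_true(all(out2$included[out2$event == 1L] == 0L))
  expect_true(all(out2$included[out2$event == 0L] == 1L))

  # genotype-specific rates: empirical fatality among carrier cases
  rates <- solve_fatality_rates(0.5, 0.25, 0.59, convention = "relative")
  set.seed(10)
  out3 <- apply_survival_filter(cohort, rates)
  # conservation: fatal is a subset of events; included complements fatal
  expect_true(all(out3$fatal <= out3$event))
  expect_identical(out3$included, 1L - out3$fatal)
  cc <- out3$event == 1L & out3$carrier == 1L
  nc <- out3$event == 1L & out3$carrier == 0L
  se_c <- sqrt(rates$f_c * (1 - rates$f_c) / sum(cc))
  se_n <- sqrt(rates$f_n * (1 - rates$f_n) / sum(nc))
  expect_lt(abs(mean(out3$fatal[cc]) - rates$f_c), 4 * se_c)
  expect_lt(abs(mean(out3$fatal[nc]) - rates$f_n), 4 * se_n)
})

test_that("cohort simulation is reproducible with independent stage streams", {
  demog <- pkg_demog()
  inc <- pkg_baseline()
  cfg <- scenario_config(n = 2e4, replicates = 1, base_seed = 77,
                         RR = 1.5, F = 0.4, d = 0.2, s = 0.3)
  a <- simulate_cohort(cfg, demog, inc, replicate = 1)
  b <- simulate_cohort(cfg, demog, inc, replicate = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(attr(a, "clipped"), 0)

  # different replicate index -> different draws
  c2 <- simulate_cohort(cfg, demog, inc, replicate = 2)
  expect_false(identical(a$event, c2$event))

  # toggling the statin fraction must not perturb any other stage
  # (e = 0 makes statin risk-neutral, so events must be identical too)
  cfg_s0 <- scenario_config(n = 2e4, replicates = 1, base_seed = 77,
                            RR = 1.5, F = 0.4, d = 0.2, s = 0, e = 0)
  cfg_s5 <- scenario_config(n = 2e4, replicates = 1, base_seed = 77,
                            RR = 1.5, F = 0.4, d = 0.2, s = 0.5, e = 0)
  x <- simulate_cohort(cfg_s0, demog, inc, replicate = 1)
  y <- simulate_cohort(cfg_s5, demog, inc, replicate = 1)
  expect_identical(x$age, y$age)
  expect_identical(x$carrier, y$carrier)
  expect_identical(x$event, y$event)
  expect_identical(x$fatal, y$fatal)
  expect_false(identical(x$statin, y$statin))
})

test_that("cohort invariants hold on a simulated replicate", {
  demog <- pkg_demog()
  inc <- pkg_baseline()
  cfg <- scenario_config(n = 5e4, replicates = 1, base_seed = 3,
                         RR = 1.25, F = 0.415, d = 0.25)
  x <- simulate_cohort(cfg, demog, inc, replicate = 1)
  expect_true(all(x$fatal <= x$event))
  expect_identical(x$included + x$fatal, rep(1L, nrow(x)))
  expect_true(all(x$risk >= 0 & x$risk <= 1))
  expect_true(all(x$age >= 40 & x$age <= 89))
})
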