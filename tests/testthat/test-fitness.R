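test_that("normalization divides by the per-cytokine clinical maximum", {
  tg <- simple_targets("TNFa", c(3, 48, 72), mins = c(1, 2, 1),
                       maxs = c(5, 10, 4))
  r <- fake_result(c(3, 48, 72), cbind(TNFa = c(5, 5, 5)))
  norm <- normalize_trajectory(r, tg)
  expect_equal(unname(norm[, 1]), c(0.5, 0.5, 0.5))  # clinical max is 10
  # all-zero series stays all-zero
  r0 <- fake_result(c(3, 48, 72), cbind(TNFa = c(0, 0, 0)))
  expect_equal(unname(normalize_trajectory(r0, tg)[, 1]), c(0, 0, 0))
  # missing cytokine errors; zero clinical max warns
  expect_error(normalize_trajectory(
    fake_result(1, cbind(IL10 = 1)), tg), "not in trajectory")
  tg0 <- simple_targets("TNFa", c(3, 48, 72), mins = 0, maxs = 0)
  expect_warning(normalize_trajectory(r, tg0), "zero clinical maximum")
})

test_that("normalization is invariant to joint rescaling", {
  tg1 <- simple_targets("TNFa", c(3, 48, 72), mins = c(1, 2, 1),
                        maxs = c(5, 10, 4))
  tg2 <- tg1; tg2$ranges <- tg1$ranges * 37
  r1 <- fake_result(c(3, 48, 72), cbind(TNFa = c(2, 7, 3)))
  r2 <- fake_result(c(3, 48, 72), cbind(TNFa = c(2, 7, 3) * 37))
  expect_equal(normalize_trajectory(r1, tg1), normalize_trajectory(r2, tg2))
})

test_that("envelopes are replicate min/max and grow monotonically", {
  tg <- simple_targets("TNFa", c(3, 48, 72), mins = 0, maxs = 10)
  r1 <- fake_result(c(3, 48, 72), cbind(TNFa = c(2, 8, 4)))
  r2 <- fake_result(c(3, 48, 72), cbind(TNFa = c(6, 2, 4)))
  e1 <- build_envelope(list(r1), tg)
  expect_equal(e1$env[, , "min"], e1$env[, , "max"])
  e2 <- build_envelope(list(r1, r2), tg)
  expect_equal(unname(e2$env[1, , "min"]), c(2, 2, 4) / 10)
  expect_equal(unname(e2$env[1, , "max"]), c(6, 8, 4) / 10)
  # adding a replicate inside the current envelope changes nothing
  r3 <- fake_result(c(3, 48, 72), cbind(TNFa = c(4, 5, 4)))
  e3 <- build_envelope(list(r1, r2, r3), tg)
  expect_equal(e3$env, e2$env)
  expect_error(build_envelope(list(), tg), "no replicates")
})

test_that("early-ending replicates carry their last value forward", {
  tg <- simple_targets("TNFa", c(3, 48, 72), mins = 0, maxs = 10)
  dead <- fake_result(c(0, 3, 6), cbind(TNFa = c(0, 2, 9)),
                      outcome = "died", death_time_hours = 6)
  s <- sample_at_targets(dead, tg)
  expect_equal(unname(s[1, ]), c(2, 9, 9) / 10)
  env <- build_envelope(list(dead), tg)
  expect_equal(env$mortality, 1)
})

test_that("fitness reproduces the hand-computed worked example", {
  # one cytokine, two evaluated time points; target maxima (1, 2), model
  # maxima (0.5, 2.5), w = 1, k = 10, R_e = 0.5, R_m = 0.6:
  # F = 0.5 + 0.5 + 10 * 0.1 = 2
  tg <- simple_targets("X", c(3, 24), mins = 0, maxs = c(1, 2),
                       mortality_rate = 0.5, k = 10, held_out_hours = numeric(0))
  env <- structure(list(
    env = array(c(0, 0, 0.5, 2.5), dim = c(1, 2, 2)),
    mortality = 0.6, n_replicates = 50), class = "range_envelope")
  expect_equal(compute_fitness(env, tg), 2)
})

test_that("a perfect range and mortality match scores zero", {
  tg <- simple_targets("X", c(3, 24, 96), mins = c(0.2, 0.3, 0.1),
                       maxs = c(1, 2, 0.5), mortality_rate = 0.5,
                       held_out_hours = numeric(0))
  env <- structure(list(env = tg$ranges, mortality = 0.5, n_replicates = 50),
                   class = "range_envelope")
  expect_equal(compute_fitness(env, tg), 0)
  expect_true(is_bioplausible(env, tg))  # boundary-inclusive containment
  # the normalized form of the targets matches a normalized perfect envelope
  ntg <- normalize_targets(tg)
  nenv <- structure(list(env = ntg$ranges, mortality = 0.5,
                         n_replicates = 50), class = "range_envelope")
  expect_equal(compute_fitness(nenv, ntg), 0)
})

test_that("held-out time points do not affect fitness", {
  tg <- simple_targets("X", c(3, 48, 72, 192), mins = 0,
                       maxs = c(1, 1, 1, 1), mortality_rate = 0.5,
                       held_out_hours = c(48, 192))
  base <- structure(list(env = array(c(rep(0, 4), rep(0.5, 4)),
                                     dim = c(1, 4, 2)),
                         mortality = 0.5, n_replicates = 10),
                    class = "range_envelope")
  perturbed <- base
  perturbed$env[1, c(2, 4), 2] <- 9  # held-out columns only
  expect_equal(compute_fitness(base, tg), compute_fitness(perturbed, tg))
  # perturbing an evaluated time point does change F
  shifted <- base
  shifted$env[1, 3, 2] <- 9
  expect_gt(compute_fitness(shifted, tg), compute_fitness(base, tg))
})

test_that("fitness is monotone in any single max difference and in weights", {
  tg <- simple_targets(c("A", "B"), c(3, 24), mins = 0, maxs = 1,
                       mortality_rate = 0.5, weights = c(A = 1, B = 1),
                       held_out_hours = numeric(0))
  mk_env <- function(a1) structure(
    list(env = array(c(rep(0, 4), a1, 0.5, 0.5, 0.5), dim = c(2, 2, 2)),
         mortality = 0.5, n_replicates = 10), class = "range_envelope")
  # growing the single |max difference| at (A, t1) grows F: target max is 1,
  # so a1 = 1 + d with increasing d
  f <- vapply(1 + seq(0, 2, by = 0.25), function(v)
    compute_fitness(mk_env(v), tg), numeric(1))
  expect_true(all(diff(f) > 0))
  # doubling one cytokine's weight exactly doubles its contribution
  tgA2 <- simple_targets(c("A", "B"), c(3, 24), mins = 0, maxs = 1,
                         mortality_rate = 0.5, weights = c(A = 2, B = 1),
                         held_out_hours = numeric(0))
  env <- mk_env(1.5)
  contribA <- abs(1 - 1.5) + abs(1 - 0.5)
  expect_equal(compute_fitness(env, tgA2) - compute_fitness(env, tg),
               contribA)
  # k = 0 removes mortality from the fitness entirely
  tg_k0 <- simple_targets(c("A", "B"), c(3, 24), mins = 0, maxs = 1,
                          mortality_rate = 0.5, weights = c(A = 1, B = 1),
                          k = 0, held_out_hours = numeric(0))
  env_wrong_mort <- mk_env(0.5)
  env_wrong_mort$mortality <- 0.9
  ref <- mk_env(0.5)
  expect_equal(compute_fitness(env_wrong_mort, tg_k0),
               compute_fitness(ref, tg_k0))
})

test_that("minmax mode adds the symmetric range-minimum terms", {
  tg <- simple_targets("X", c(3, 24), mins = 0.4, maxs = 1,
                       mortality_rate = 0.5, held_out_hours = numeric(0))
  env <- structure(list(env = array(c(0.2, 0.2, 1, 1), dim = c(1, 2, 2)),
                        mortality = 0.5, n_replicates = 10),
                   class = "range_envelope")
  expect_equal(compute_fitness(env, tg), 0)
  expect_equal(compute_fitness(env, tg, range_mode = "minmax"),
               2 * abs(0.4 - 0.2))
})

test_that("non-viability triggers on death before the first sampling time", {
  die2 <- fake_result(c(0, 2), cbind(TNFa = c(0, 1)), outcome = "died",
                      death_time_hours = 2)
  die5 <- fake_result(c(0, 5), cbind(TNFa = c(0, 1)), outcome = "died",
                      death_time_hours = 5)
  heal <- fake_result(c(0, 5), cbind(TNFa = c(0, 0)), outcome = "healed")
  expect_true(is_nonviable(list(die2, heal)))
  expect_false(is_nonviable(list(die5, heal)))
  expect_false(is_nonviable(list(heal, heal)))
  expect_false(is_nonviable(list(die2, heal), mode = "all"))
  expect_true(is_nonviable(list(die2, die2), mode = "all"))
})

test_that("bioplausibility is inclusive containment at evaluated points", {
  tg <- simple_targets("X", c(3, 48, 72), mins = 0.2, maxs = 0.8,
                       held_out_hours = 48)
  inside <- structure(list(env = array(c(rep(0.3, 3), rep(0.6, 3)),
                                       dim = c(1, 3, 2)),
                           mortality = 0.5, n_replicates = 10),
                      class = "range_envelope")
  expect_true(is_bioplausible(inside, tg))
  above <- inside; above$env[1, 3, 2] <- 1.2
  expect_false(is_bioplausible(above, tg))
  held_out_excursion <- inside; held_out_excursion$env[1, 2, 2] <- 1.2
  expect_true(is_bioplausible(held_out_excursion, tg))
  below <- inside; below$env[1, 1, 1] <- 0.1
  expect_false(is_bioplausible(below, tg))
})

test_that("targets serializations round-trip", {
  tg <- simple_targets(c("TNFa", "IL10"), c(3, 48, 72),
                       mins = c(0.1, 0.2, 0.3), maxs = c(1, 2, 3),
                       weights = c(TNFa = 1, IL10 = 2))
  js <- withr::local_tempfile(fileext = ".json")
  write_targets_json(tg, js)
  back <- read_targets_json(js)
  expect_equal(back$ranges, tg$ranges)
  expect_equal(back$weights, tg$weights)
  expect_equal(back$held_out_hours, tg$held_out_hours)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_targets_csv(tg, csv)
  back2 <- read_targets_csv(csv)
  expect_equal(back2$ranges, tg$ranges)
  expect_equal(back2$mortality_rate, tg$mortality_rate)
})
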