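test_that("an uninjured sterile patient heals at step 0", {
  cfg <- bare_config()
  r <- run_simulation(injury_params(injury_size = 0), zero_genome(cfg), cfg,
                      seed = 1)
  expect_identical(r$outcome, "healed")
  expect_equal(max(r$times_hours), 0)
})

test_that("initialization carves the requested contiguous injured patch", {
  cfg <- sim_config()  # 40x40
  sim <- init_simulation(injury_params(injury_size = 0.25),
                         rep(0, genome_length(cfg)), cfg, seed = 3)
  st <- sim_state(sim)
  expect_equal(sum(st$damage == 1), ceiling(0.25 * 1600))  # 400 sites
  expect_equal(sum(st$damage), 400)
  expect_equal(st$damage_fraction, 0.25)
  # the patch is one connected blob: all damaged sites within a tight disk
  idx <- which(st$damage == 1, arr.ind = TRUE)
  centre <- c(mean(idx[, 1]), mean(idx[, 2]))
  d2 <- (idx[, 1] - centre[1])^2 + (idx[, 2] - centre[2])^2
  expect_lt(max(d2), (sqrt(400 / pi) + 1.5)^2)
})

test_that("an infectious injury with no injured sites is rejected", {
  cfg <- bare_config()
  expect_error(
    init_simulation(injury_params(injury_size = 0,
                                  microbial_invasiveness = 0.5,
                                  microbial_toxigenesis = 0.1),
                    zero_genome(cfg), cfg, seed = 1),
    "non-empty injured patch")
})

test_that("identical (params, genome, seed) reproduce bit-identical results", {
  cfg <- desk_sim_config()
  g <- make_reference_calibrated_genome(cfg, desk = TRUE)
  p <- reference_burn_injury(desk = TRUE)
  r1 <- run_simulation(p, g, cfg, seed = 99)
  r2 <- run_simulation(p, g, cfg, seed = 99)
  expect_identical(r1$totals, r2$totals)
  expect_identical(r1$outcome, r2$outcome)
  expect_identical(r1$damage_fraction, r2$damage_fraction)
})

test_that("different seeds can diverge to different outcomes", {
  cfg <- desk_sim_config()
  g <- make_reference_calibrated_genome(cfg, desk = TRUE)
  p <- reference_burn_injury(desk = TRUE)
  out <- vapply(derive_seeds(4L, 12L), function(s)
    run_simulation(p, g, cfg, seed = s)$outcome, character(1))
  expect_gt(length(unique(out)), 1)
})

test_that("an all-zero genome produces no mediators", {
  cfg <- bare_config()
  sim <- init_simulation(injury_params(injury_size = 0.4, host_resilience = 0),
                         zero_genome(cfg), cfg, seed = 1)
  step_simulation(sim, 20)
  st <- sim_state(sim)
  expect_true(all(vapply(st$fields, sum, numeric(1)) == 0))
})

test_that("a constant damage source grows mediator totals linearly", {
  # 13 damaged sites, rule TNFa <- 1 * damage, no diffusion/decay/repair:
  # total TNFa after k steps is 13 * k
  cfg <- bare_config()
  g <- flatten(build_matrix(
    data.frame(rule = "endothelial->TNFa", entity = "damage", value = 1),
    rule_labels(cfg), entity_columns(cfg)))
  sim <- init_simulation(injury_params(injury_size = 0.5, host_resilience = 0),
                         g, cfg, seed = 1)
  step_simulation(sim, 10)
  tr <- mrmcal:::result_from_sim(sim)
  n_injured <- ceiling(0.5 * 25)
  expect_equal(tr$totals[, "TNFa"], n_injured * (0:10))
})

test_that("single-site dynamics reproduce the worked two-rule iteration", {
  # M1' = max(0, M1 + M2); M2' = max(0, -M1 + M3); M3 has no source and
  # fully decays.  decay = 1 realizes full per-step turnover so the rule
  # output *is* the next state.
  cfg <- sim_config(grid_width = 1L, grid_height = 1L, step_minutes = 60,
                    mediators = c("M1", "M2", "M3"),
                    diffusion = 0, decay = 1, toxicity = 0,
                    init_fields = c(M1 = 1, M2 = 1, M3 = 0.5),
                    agent_counts = c(macrophage = 1),
                    attractant = c(macrophage = NA),
                    rules = data.frame(cell_type = "macrophage",
                                       output = c("M1", "M2")))
  m <- worked_example_matrix()
  g <- flatten(build_matrix(
    data.frame(rule = c("macrophage->M1", "macrophage->M1",
                        "macrophage->M2", "macrophage->M2"),
               entity = c("M1", "M2", "M1", "M3"),
               value = c(1, 1, -1, 1)),
    rule_labels(cfg), entity_columns(cfg)))
  sim <- init_simulation(injury_params(injury_size = 0), g, cfg, seed = 7)
  n_steps <- 6
  step_simulation(sim, n_steps)
  tr <- mrmcal:::result_from_sim(sim)
  # independent hand iteration
  state <- c(M1 = 1, M2 = 1, M3 = 0.5)
  expected <- matrix(NA_real_, n_steps + 1, 3,
                     dimnames = list(NULL, names(state)))
  expected[1, ] <- state
  for (k in seq_len(n_steps)) {
    state <- c(M1 = max(0, state["M1"] + state["M2"]),
               M2 = max(0, -state["M1"] + state["M3"]),
               M3 = 0)
    expected[k + 1, ] <- state
  }
  expect_equal(unname(tr$totals), unname(expected))
})

test_that("death occurs exactly when damage fraction first exceeds 0.80", {
  cfg <- bare_config()
  # 85% initial damage is immediately lethal
  r <- run_simulation(injury_params(injury_size = 0.85, host_resilience = 0),
                      zero_genome(cfg), cfg, seed = 1)
  expect_identical(r$outcome, "died")
  expect_equal(r$death_time_hours, 0)
  # 80% exactly is NOT lethal (strict inequality)
  r80 <- init_simulation(injury_params(injury_size = 0.8,
                                       host_resilience = 0),
                         zero_genome(cfg), cfg, seed = 1)
  expect_equal(sim_state(r80)$damage_fraction, 0.8)
  rr <- run_simulation(injury_params(injury_size = 0.8, host_resilience = 0),
                       zero_genome(cfg), cfg, seed = 1,
                       horizon_hours = 5)
  expect_identical(rr$outcome, "censored")
})

test_that("toxigenesis death time matches an independent lattice iteration", {
  # 2x2 grid, two infected dead sites, infection spreads and damages tissue
  # deterministically (no agents, no repair, no RNG-dependent channels)
  cfg <- sim_config(grid_width = 2L, grid_height = 2L, step_minutes = 60,
                    mediators = c("TNFa", "IL10"), diffusion = 0, decay = 0,
                    toxicity = 0, phagocytosis = 0,
                    agent_counts = c(macrophage = 0, neutrophil = 0, th0 = 0,
                                     th1 = 0, th2 = 0),
                    rules = data.frame(cell_type = "endothelial",
                                       output = "TNFa"))
  p <- injury_params(injury_size = 0.5, microbial_invasiveness = 0.5,
                     microbial_toxigenesis = 0.15, host_resilience = 0)
  r <- run_simulation(p, zero_genome(cfg), cfg, seed = 1)
  expect_identical(r$outcome, "died")

  # independent oracle: replicate substep (4) on the 2x2 torus
  sim0 <- init_simulation(p, zero_genome(cfg), cfg, seed = 1)
  st <- sim_state(sim0)
  dmg <- st$damage; inf <- st$infection
  nb_mean <- function(m, x, y) {
    W <- ncol(m); H <- nrow(m)
    (m[y, (x %% W) + 1] + m[y, ((x - 2) %% W) + 1] +
       m[(y %% H) + 1, x] + m[((y - 2) %% H) + 1, x]) / 4
  }
  death_step <- NA
  for (k in 1:100) {
    snap <- inf
    for (y in 1:2) for (x in 1:2)
      inf[y, x] <- min(cfg$infection_cap,
                       inf[y, x] + p$microbial_invasiveness * nb_mean(snap, x, y))
    dmg <- pmin(1, dmg + p$microbial_toxigenesis * inf)
    if (mean(dmg) > 0.8) { death_step <- k; break }
  }
  expect_equal(r$death_time_hours, death_step)
})

test_that("harm is monotone when repair and the immune response are off", {
  cfg <- bare_config()
  p <- injury_params(injury_size = 0.3, microbial_invasiveness = 0.4,
                     microbial_toxigenesis = 0.03, host_resilience = 0)
  r <- run_simulation(p, zero_genome(cfg), cfg, seed = 2, horizon_hours = 48)
  expect_true(all(diff(r$damage_fraction) >= 0))
  expect_true(all(r$damage_fraction <= 1))
})

test_that("mediator totals are never negative despite inhibitory rules", {
  cfg <- desk_sim_config()
  set.seed(21)
  g <- runif(genome_length(cfg), -2, 2)
  r <- run_simulation(reference_burn_injury(desk = TRUE), g, cfg, seed = 5,
                      horizon_hours = 72)
  expect_true(all(r$totals >= 0))
})

test_that("replicate runs estimate mortality and demand distinct seeds", {
  cfg <- bare_config()
  res <- run_replicates(injury_params(injury_size = 0), zero_genome(cfg),
                        cfg, seeds = 1:5)
  expect_equal(attr(res, "mortality"), 0)
  expect_error(run_replicates(injury_params(injury_size = 0),
                              zero_genome(cfg), cfg, seeds = c(1, 1)),
               "distinct")
  expect_length(derive_seeds(1L, 50L), 50L)
  expect_false(anyDuplicated(derive_seeds(1L, 50L)) > 0)
})
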