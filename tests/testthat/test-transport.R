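mk_assign <- function(mat, mols = seq_len(nrow(mat)), species = NULL,
                      dt = 10) {
  lapply(seq_len(ncol(mat)), function(j)
    layer_assignment(mols, mat[, j], time = (j - 1) * dt, species = species))
}

test_that("detect_transitions: direct count and debounce examples", {
  a <- mk_assign(matrix(c("layer1", "layer1", "layer2", "layer2"), nrow = 1))
  tr <- detect_transitions(a, persistence = 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$from, "layer1")
  expect_equal(tr$to, "layer2")
  expect_equal(tr$frame, 3L)
  expect_equal(tr$time, 20)

  flick <- mk_assign(matrix(c("layer1", "layer2", "layer1"), nrow = 1))
  expect_equal(nrow(detect_transitions(flick, persistence = 2)), 0L)
  expect_equal(nrow(detect_transitions(flick, persistence = 1)), 2L)
  expect_error(detect_transitions(a[1]), "two")
})

test_that("detect_transitions agrees with the explicit persistent-run oracle", {
  set.seed(123)
  regions <- c("layer1", "layer2", "bulk_octanol")
  for (rep in 1:25) {
    labs <- sample(regions, 30, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    p <- sample(1:3, 1)
    a <- mk_assign(matrix(labs, nrow = 1))
    got <- detect_transitions(a, persistence = p)
    ora <- transitions_oracle(labs, p)
    expect_equal(nrow(got), nrow(ora), label = paste("rep", rep))
    if (nrow(ora)) {
      expect_equal(got$from, ora$from)
      expect_equal(got$to, ora$to)
      expect_equal(got$frame, ora$frame)
    }
  }
})

test_that("classifier recovers planted mechanisms, carriers and merges co-transport", {
  sc <- event_script(
    mechanism = c("hinge", "hinge", "flip", "diffusion"),
    direction = c("L1->L2", "L2->L1", "L1->L2", "L2->bulk"),
    t_start = c(20, 30, 20, 30), duration = rep(30, 4),
    n_oct = c(4, 5, 1, 0), m_water = c(2, 3, 1, 1))
  g <- gen_event_trajectory(sc, n_frames = 12, seed = 2)
  ev <- classify_transfers(detect_transitions(g$assignments),
                           g$trajectory, g$assignments)
  tab <- event_table(ev)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$mechanism, c("hinge", "flip", "diffusion"))
  h <- tab[tab$mechanism == "hinge", ]
  expect_setequal(h$n_octanol, c(4L, 5L))
  expect_setequal(h$n_waters, c(2L, 3L))  # co-transported waters merged
  expect_equal(tab$n_octanol[tab$mechanism == "flip"], 1L)
  expect_equal(tab$n_octanol[tab$mechanism == "diffusion"], 0L)
  expect_equal(tab$direction[tab$mechanism == "diffusion"], "L2->bulk")
})

test_that("flip census counts directions, water-HB load, and is zero when static", {
  sc <- event_script(
    mechanism = rep("flip", 5),
    direction = c("L1->L2", "L1->L2", "L2->L1", "L2->L1", "L1->L2"),
    t_start = c(20, 30, 20, 40, 40), duration = rep(20, 5),
    n_oct = rep(1, 5), m_water = c(1, 0, 0, 0, 0))
  g <- gen_event_trajectory(sc, n_frames = 10, seed = 4)
  hbg <- lapply(g$trajectory$frames, detect_hbonds)
  fc <- flip_census(g$assignments, hbg)
  expect_equal(fc$n_fwd, 3L)
  expect_equal(fc$n_rev, 2L)
  expect_equal(sum(fc$events$water_hb_count == 1), 1L)
  expect_equal(fc$rate_fwd, 3 / 90 * 10)

  static <- mk_assign(matrix("layer1", 1, 4), species = "octanol")
  expect_equal(flip_census(static, vector("list", 4))$n_fwd, 0L)
})

test_that("transfer_statistics reproduces share and stoichiometry arithmetic", {
  # single event: fractions degenerate, stoichiometry 3 oct / 2 water
  one <- data.frame(direction = "L1->L2", mechanism = "hinge", n_waters = 2L,
                    n_octanol = 3L, n_water_carrier = 2L, t_start = 0,
                    t_end = 10)
  s1 <- transfer_statistics(one)
  expect_equal(s1$`L1->L2`$fraction_waters, c(0, 0, 1))
  expect_equal(s1$`L1->L2`$stoichiometry, 1.5)

  # conservation: waters by mechanism sum to the total
  sc <- event_script(mechanism = c("hinge", "flip", "diffusion"),
                     direction = rep("L1->L2", 3),
                     t_start = c(20, 20, 20), duration = rep(20, 3),
                     n_oct = c(3, 1, 0), m_water = c(2, 1, 1))
  g <- gen_event_trajectory(sc, n_frames = 8, seed = 3)
  ev <- classify_transfers(detect_transitions(g$assignments),
                           g$trajectory, g$assignments)
  st <- transfer_statistics(ev)$pooled
  expect_equal(sum(st$fraction_waters * st$waters_transferred),
               st$waters_transferred)
  expect_equal(st$waters_transferred, 4L)
})

test_that("arrhenius_ea: closed forms, monotonicity and flagging", {
  expect_equal(arrhenius_ea(2, 2, 300)$Ea, 0)
  e1 <- arrhenius_ea(1, exp(1), 300)
  expect_equal(e1$Ea, 1.98720425864083e-3 * 300, tolerance = 1e-12)
  k1 <- arrhenius_ea(1, 10, 300)$Ea
  k2 <- arrhenius_ea(2, 10, 300)$Ea
  expect_equal(k1 - k2, 1.98720425864083e-3 * 300 * log(2), tolerance = 1e-12)
  expect_true(arrhenius_ea(10, 1, 300)$flagged)
  expect_error(arrhenius_ea(-1, 1, 300), "positive")
  expect_error(arrhenius_ea(1, 1, 0), "positive")
})

# synthetic event stream with planted Poisson rates and symmetric layers
stream <- function(rate_f, rate_r, n_frames = 600, dt = 10, seed = 1) {
  set.seed(seed)
  mat <- matrix(rep(c("layer1", "layer1", "layer2", "layer2"), n_frames),
                nrow = 4)
  asg <- mk_assign(mat, species = c("water", "octanol", "water", "octanol"),
                   dt = dt)
  mk_ev <- function(rate, dir) {
    n <- rpois(1, rate * n_frames * dt / 10)
    if (n == 0) return(NULL)
    data.frame(direction = dir, mechanism = "hinge", n_waters = 1L,
               n_octanol = 2L, n_water_carrier = 1L,
               t_start = sort(runif(n, 0, (n_frames - 1) * dt)),
               t_end = NA_real_)
  }
  ev <- rbind(mk_ev(rate_f, "L1->L2"), mk_ev(rate_r, "L2->L1"))
  list(events = ev, assignments = asg)
}

test_that("hinge_reaction_rates: symmetry, planted gap, prefactor identity", {
  R <- 1.98720425864083e-3; T <- 300
  # planted barrier gap dE with a shared prefactor
  dE <- 0.5
  s <- stream(rate_f = 0.4 * exp(-dE / (R * T)), rate_r = 0.4, seed = 7)
  hr <- hinge_reaction_rates(s$events, s$assignments, T = T,
                             A_fwd = 5, A_rev = 5)
  gap <- hr$forward$Ea - hr$reverse$Ea
  sem <- sqrt(hr$sem_fwd^2 + hr$sem_rev^2)
  expect_lt(abs(gap - dE), 3 * sem + 1e-9)

  # symmetric rates: gap ~ 0
  s0 <- stream(0.4, 0.4, seed = 8)
  hr0 <- hinge_reaction_rates(s0$events, s0$assignments, T = T,
                              A_fwd = 5, A_rev = 5)
  expect_lt(abs(hr0$forward$Ea - hr0$reverse$Ea),
            3 * sqrt(hr0$sem_fwd^2 + hr0$sem_rev^2) + 1e-9)

  # prefactor conventions differ by exactly R T log(A_a / A_b)
  hrA <- hinge_reaction_rates(s0$events, s0$assignments, T = T,
                              A_fwd = 5, A_rev = 5, prefactor = "hb_formation")
  hrB <- hinge_reaction_rates(s0$events, s0$assignments, T = T,
                              A_fwd = 8, A_rev = 8, prefactor = "adsorption_hb")
  expect_equal(hrB$forward$Ea - hrA$forward$Ea, R * T * log(8 / 5),
               tolerance = 1e-12)
})

test_that("hinge_reaction_rates reports concentrations and conventions", {
  s <- stream(0.3, 0.3, seed = 10)
  hr <- hinge_reaction_rates(s$events, s$assignments, T = 300,
                             A_fwd = 2, A_rev = 2)
  expect_equal(unname(hr$concentrations["water_L1"]), 1)
  expect_equal(unname(hr$concentrations["octanol_L2"]), 1)
  expect_match(hr$metadata$concentration_normalisation, "count")
  expect_equal(hr$nu, 2)  # 2 octanols per 1 water planted
})
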