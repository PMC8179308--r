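# A 12-molecule hand-built slab: 4 bulk waters, 4 surface waters, one
# Layer-1 octanol HB'd to a surface water, one Layer-2 octanol (head toward
# the organic phase) with an HB-attached water, one deep bulk octanol, one
# penetrated water.
tiny_slab <- function() {
  at <- rbind(
    w3(1, c(3, 3, 3)), w3(2, c(9, 3, 3)), w3(3, c(3, 9, 3)), w3(4, c(9, 9, 3)),
    w3(5, c(3, 3, 6), h1 = c(3, 3, 6.96)),   # surface waters, one H up
    w3(6, c(9, 3, 6), h1 = c(9, 3, 6.96)),
    w3(7, c(3, 9, 6), h1 = c(3, 9, 6.96)),
    w3(8, c(9, 9, 6), h1 = c(9, 9, 6.96)),
    oct3(9, c(3, 3, 8.8), axis = c(0.707, 0, 0.707)),     # layer1 (HB to 5)
    oct3(10, c(9, 3, 20), axis = c(0.6, 0, -0.8)),        # layer2 candidate
    w3(11, c(9, 5.8, 20), h1 = c(9, 4.84, 20)),           # water HB'd to 10
    oct3(12, c(3, 9, 38), axis = c(0, 0.8, -0.6)))        # deep bulk octanol
  pen <- w3(13, c(9, 9, 30))
  md_frame(rbind(at, pen), box3(12, 12, 48))
}

test_that("assign_layers labels a constructed 13-molecule slab correctly", {
  fr <- tiny_slab()
  hb <- detect_hbonds(fr)
  asg <- assign_layers(fr, surface_waters = 5:8, hbgraph = hb,
                       penetrated = 13L, water_side = "below",
                       interface_z = 6, layer2_zmax = 25)
  reg <- stats::setNames(asg$region, asg$mol)
  expect_equal(unname(reg[as.character(1:4)]), rep("bulk_water", 4))
  expect_equal(unname(reg[as.character(5:8)]), rep("water_surface", 4))
  expect_equal(unname(reg["9"]), "layer1")
  expect_equal(unname(reg["10"]), "layer2")
  expect_equal(unname(reg["11"]), "layer2")  # inherited via HB
  expect_equal(unname(reg["12"]), "bulk_octanol")  # beyond the depth bound
  expect_equal(unname(reg["13"]), "bulk_octanol")  # penetrated water
  expect_error(assign_layers(fr, NULL, hb), "surface waters")
})

test_that("region labels partition every molecule exactly once", {
  s <- gen_slab(seed = 21, n_penetrated = 2)
  hb <- detect_hbonds(s$frame)
  spl <- split_penetrated_waters(s$frame, hb)
  sw <- itim_layer(s$frame, spl$aqueous, itim_params())
  asg <- assign_layers(s$frame, sw, hb, penetrated = spl$penetrated)
  expect_equal(sort(asg$mol), sort(unique(s$frame$atoms$mol)))
  expect_false(any(is.na(asg$region)))
  expect_true(all(asg$region %in% c("bulk_water", "water_surface", "layer1",
                                    "layer2", "bulk_octanol")))
})

test_that("planted Layer-1, islands and penetrated waters are recovered end to end", {
  s <- gen_slab(seed = 3, n_penetrated = 2)
  hb <- detect_hbonds(s$frame)
  spl <- split_penetrated_waters(s$frame, hb)
  sw <- itim_layer(s$frame, spl$aqueous, itim_params())
  expect_setequal(sw$molecules, s$truth$surface_waters)
  asg <- assign_layers(s$frame, sw, hb, penetrated = spl$penetrated)
  l1 <- asg$mol[asg$region == "layer1"]
  expect_setequal(l1, s$truth$layer1)
  l2 <- asg$mol[asg$region == "layer2"]
  expect_true(all(s$truth$layer2 %in% l2))  # all island members labelled layer2
  isl <- find_bilayer_islands(asg, s$frame)
  expect_equal(length(isl), 3L)
  expect_setequal(vapply(isl, `[[`, 0L, "octanol_count"), c(4L, 4L, 5L))
})

test_that("octanol orientation cosines follow the end-to-end definition", {
  fr <- md_frame(rbind(oct3(1, c(5, 5, 5), axis = c(0, 0, 1)),
                       oct3(2, c(15, 5, 5), axis = c(0.7071068, 0, 0.7071068)),
                       oct3(3, c(25, 5, 5), axis = c(1, 0, 0))),
                 box3(40, 40, 40))
  ori <- octanol_orientations(fr)
  expect_equal(ori$cos_theta, c(1, 0.7071068, 0), tolerance = 1e-6)
})

test_that("orientation profile: planted 45-degree tilt and isotropic null", {
  s <- gen_slab(seed = 13, island_sizes = integer(0),
                bulk_octanol_spacing = NULL)
  prof <- orientation_profile(s$frame, bin_width = 4)
  l1z <- mean(s$frame$atoms$z[s$frame$atoms$role == "hydroxyl_O"])
  band <- prof[abs(prof$z - l1z) <= 4, ]
  expect_equal(sum(band$n), s$truth$n_octanol)
  expect_equal(stats::weighted.mean(band$mean_cos, band$n), 0.7071,
               tolerance = 0.05 / 0.7071)

  # isotropic ensemble: bin mean ~ 0 within 3 SEM
  set.seed(99)
  n <- 400
  rows <- lapply(seq_len(n), function(i) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    oct3(i, c(runif(1, 12, 88), runif(1, 12, 88), 50), axis = u,
         atom0 = (i - 1) * 3 + 1)
  })
  fr <- md_frame(do.call(rbind, rows), box3(100, 100, 100))
  ori <- octanol_orientations(fr)
  sem <- sd(ori$cos_theta) / sqrt(n)
  expect_lt(abs(mean(ori$cos_theta)), 3 * sem)
})

test_that("density profile conserves counts and resolves a two-slab step", {
  # uniform gas: flat within counting noise and exact integral
  fr <- rand_water_frame(500, L = 20, seed = 8, Lz = 20)
  fr <- wrap_frame(fr)
  prof <- density_profile(fr, roles = "water_O", bin_width = 2)
  expect_equal(sum(prof$density) * 2 * 20 * 20, 500)
  expect_lt(max(abs(prof$density - mean(prof$density))) / mean(prof$density), 0.6)

  # two-slab fixture: occupied vs empty halves split at a known z
  at <- do.call(rbind, lapply(1:100, function(i)
    w3(i, c(runif(1, 0, 10), runif(1, 0, 10), runif(1, 0, 10)))))
  fr2 <- wrap_frame(md_frame(at, box3(10, 10, 20)))
  p2 <- density_profile(fr2, roles = "water_O", bin_width = 1)
  expect_equal(sum(p2$density[p2$z > 10.5]), 0)
  expect_gt(mean(p2$density[p2$z < 9.5]), 0)
})

test_that("2D RDF: ideal gas is flat, pair peak matches the analytic norm", {
  set.seed(5)
  n <- 300
  at <- do.call(rbind, lapply(seq_len(n), function(i)
    w3(i, c(runif(1, 0, 30), runif(1, 0, 30), 5))))
  fr <- md_frame(at, box3(30, 30, 10))
  g <- rdf2d(fr, 1:n, dr = 0.5)
  mid <- g$g[g$r > 2 & g$r < 12]
  expect_lt(abs(mean(mid) - 1), 0.05)
  expect_true(all(g$g >= 0))

  # one fixed pair at distance d: the single occupied bin matches 2/(N rho 2 pi r dr)
  at2 <- rbind(w3(1, c(10, 10, 5)), w3(2, c(14.2, 10, 5)))
  fr2 <- md_frame(at2, box3(30, 30, 10))
  g2 <- rdf2d(fr2, 1:2, dr = 0.1)
  k <- which(g2$g > 0)
  expect_length(k, 1L)
  expect_equal(g2$r[k], 4.2, tolerance = 0.05 / 4.2)  # bin containing d
  rho <- 2 / 900
  expect_equal(g2$g[k], 2 / (2 * rho * 2 * pi * g2$r[k] * 0.1))
})

test_that("rdf2d matches the brute-force O(N^2) histogram oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    at <- do.call(rbind, lapply(seq_len(n), function(i)
      w3(i, c(runif(1, 0, 20), runif(1, 0, 20), runif(1, 4, 6)))))
    fr <- md_frame(at, box3(20, 20, 10))
    g <- rdf2d(fr, 1:n, dr = 0.25)
    expect_equal(g$g, rdf2d_oracle(fr, 1:n, dr = 0.25, r_max = 10),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})

test_that("ECN: uniform limit, delta bump plateau, and depletion sign", {
  mkrdf <- function(r, g, rho) structure(data.frame(r = r, g = g),
                                         class = c("rdf2d", "data.frame"),
                                         rho = rho, dr = r[2] - r[1])
  r <- seq(0.05, 10, by = 0.1)
  e0 <- ecn(mkrdf(r, rep(1, length(r)), rho = 0.3))
  expect_true(all(abs(e0$n_excess) < 1e-12))
  expect_equal(e0$n_excess[1], 0)

  # bump of unit area in (g-1) 2 pi r dr around r0 -> plateau at rho * weight
  r0 <- 4; w <- 0.3
  bump <- exp(-(r - r0)^2 / (2 * w^2))
  bump <- bump / sum(bump * 2 * pi * r * 0.1)  # unit integral weight
  e1 <- ecn(mkrdf(r, 1 + bump, rho = 0.3))
  expect_equal(tail(e1$n_excess, 1), 0.3, tolerance = 1e-3)

  # depletion: g < 1 inside a shell -> negative ECN over that range
  gdep <- ifelse(r < 3, 0, 1)
  e2 <- ecn(mkrdf(r, gdep, rho = 0.3))
  expect_true(all(e2$n_excess[e2$r >= 3] < 0))
})

test_that("ecn(rdf2d(.)) equals direct brute-force excess counting", {
  # uniform points (g ~ 1), fine bins and frame averaging keep the
  # trapezoid-vs-counting half-bin terms below the quadrature tolerance
  set.seed(77)
  n <- 1600; L <- 50; M <- 5
  frames <- lapply(seq_len(M), function(m) {
    at <- do.call(rbind, lapply(seq_len(n), function(i)
      w3(i, c(runif(1, 0, L), runif(1, 0, L), 5))))
    fr <- md_frame(at, box3(L, L, 10)); fr$time <- m; fr
  })
  g <- rdf2d(frames, 1:n, dr = 0.02, r_max = 8)
  e <- ecn(g)
  rho <- n / L^2
  for (r in c(3, 6, 8)) {
    cnt <- 0
    for (fr in frames) {
      ox <- fr$atoms[fr$atoms$role == "water_O", ]
      for (i in seq_len(n)) {
        dx <- abs(ox$x - ox$x[i]); dx <- pmin(dx, L - dx)
        dy <- abs(ox$y - ox$y[i]); dy <- pmin(dy, L - dy)
        cnt <- cnt + sum(dx^2 + dy^2 < r^2) - 1
      }
    }
    direct <- cnt / (n * M) - rho * pi * r^2
    at_r <- stats::approx(e$r, e$n_excess, xout = min(r, max(e$r)))$y
    expect_lt(abs(at_r - direct), 1e-2,
              label = paste("ecn vs direct count at r =", r))
  }
})

test_that("packing density arithmetic, intensivity and the planar limit", {
  expect_equal(packing_density(280, 10000)$mean, 2.80)  # 100 nm^2 in A^2
  expect_equal(packing_density(560, 20000)$mean, 2.80)
  expect_error(packing_density(10, 0), "area")
  s <- gen_slab(seed = 40, island_sizes = integer(0),
                bulk_octanol_spacing = NULL)
  waters <- s$frame$atoms$mol[s$frame$atoms$species == "water"]
  wc <- willard_chandler(s$frame, waters)
  pd <- packing_density(length(s$truth$layer1), wc$area)
  flat <- length(s$truth$layer1) / (40 * 40) * 100
  expect_equal(pd$mean, flat, tolerance = 0.02)
})

test_that("bilayer islands: planted recovery, emptiness, and water-size scaling", {
  s <- gen_slab(seed = 55, island_sizes = c(4), island_loading_slope = 0.5,
                bulk_octanol_spacing = NULL)
  isl <- find_bilayer_islands(s$truth$assignment, s$frame)
  expect_length(isl, 1L)
  expect_equal(isl[[1]]$octanol_count, 4L)
  expect_equal(isl[[1]]$water_count, 2L)

  # layer2 octanols all far apart -> no islands (>= 2 octanols required)
  at <- rbind(oct3(1, c(5, 5, 20)), oct3(2, c(25, 25, 20)))
  fr <- md_frame(at, box3(40, 40, 40))
  asg <- layer_assignment(1:2, rep("layer2", 2), species = rep("octanol", 2))
  expect_length(find_bilayer_islands(asg, fr), 0L)

  # linear water loading: rank correlation across island sizes > 0.9
  s2 <- gen_slab(box = box3(80, 80, 120), boundary_z = 60,
                 island_sizes = c(2, 3, 4, 5, 6, 7, 8),
                 island_loading_slope = 0.4, bulk_octanol_spacing = NULL,
                 seed = 60)
  isl2 <- find_bilayer_islands(s2$truth$assignment, s2$frame)
  expect_length(isl2, 7L)
  oc <- vapply(isl2, `[[`, 0L, "octanol_count")
  wc2 <- vapply(isl2, `[[`, 0L, "water_count")
  expect_gt(stats::cor(oc, wc2, method = "spearman"), 0.9)
})
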