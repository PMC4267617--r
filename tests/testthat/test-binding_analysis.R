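# binding_analysis: occupancy, residence kinetics, distances, pockets

test_that("occupancy traces follow the cutoff semantics", {
  site <- ion_traj(matrix(c(10, 10, 10), 1), n_frames = 5,
                   box = c(20, 20, 20), species = "K+")
  ion <- ion_traj(matrix(c(12, 10, 10), 1), n_frames = 5,
                  box = c(20, 20, 20), species = "Na+")
  sys <- merge_trajectories(site, ion)
  tr <- occupancy_trace(sys, 1L, "Na+", cutoff = 3, window = FALSE)
  expect_equal(tr$p, rep(1L, 5))
  expect_equal(occupancy_fraction(tr), 100)
  tr0 <- occupancy_trace(sys, 1L, "Na+", cutoff = 0, window = FALSE)
  expect_equal(tr0$p, rep(0L, 5))
  expect_error(occupancy_trace(sys, integer(0), "Na+"), "empty")
  expect_error(occupancy_trace(sys, 1L, "Na+", window = c(1e6, 2e6)),
               "no frames")
})

test_that("occupancy equals the brute-force oracle on a 5-frame fixture", {
  set.seed(33)
  box <- c(15, 15, 15)
  sites <- ion_traj(matrix(runif(6, 0, 15), 2), n_frames = 5, box = box,
                    species = "K+")
  ions <- ion_traj(array(runif(2 * 3 * 5, 0, 15), c(2, 3, 5)), box = box,
                   species = "Na+")
  sys <- merge_trajectories(sites, ions)
  for (cutoff in c(2, 5, 8)) {
    tr <- occupancy_trace(sys, 1:2, "Na+", cutoff = cutoff, window = FALSE)
    oracle <- occupancy_oracle(sys, 1:2, 3:4, cutoff, 1:5)
    expect_equal(tr$p, as.integer(oracle))
  }
})

test_that("occupancy_fraction matches the two-state stationary value", {
  expect_equal(occupancy_fraction(rep(1L, 10)), 100)
  expect_equal(occupancy_fraction(rep(c(1L, 0L), 5)), 50)
  # telegraph: stationary occupancy k_on / (k_on + k_off)
  occ <- vapply(1:12, function(s) {
    out <- simulate_telegraph(telegraph_spec(k_on = 0.4, k_off = 0.6, dt = 10,
                                             T = 150, seed = 400 + s))
    occupancy_fraction(occupancy_trace(out$traj, 1L, "Na+", window = FALSE))
  }, 0)
  se <- sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - 100 * 0.4 / (0.4 + 0.6)), 3 * se)
})

test_that("occupancy_fraction is order-invariant but residence is not", {
  set.seed(5)
  p <- as.integer(runif(400) < 0.4)
  # give the trace temporal structure: sort half of it into runs
  p[1:200] <- sort(p[1:200])
  perm <- sample(400)
  expect_equal(occupancy_fraction(p), occupancy_fraction(p[perm]))
  mk <- function(pp) structure(list(p = pp, dt = 10), class = "OccupancyTrace")
  c1 <- residence_time(mk(p), lag_min = 10, lag_max = 300)$C
  c2 <- residence_time(mk(p[perm]), lag_min = 10, lag_max = 300)$C
  expect_gt(max(abs(c1 - c2)), 1e-3)
})

test_that("C(t) equals the enumeration oracle and censoring works", {
  per <- structure(list(p = rep(c(1L, 0L), 100), dt = 10),
                   class = "OccupancyTrace")
  rr <- residence_time(per, lag_min = 10, lag_max = 100)
  oracle <- autocorr_oracle(per$p, 1:10)
  expect_equal(rr$C, oracle, tolerance = 1e-12)
  # alternating trace: C is 1 at even frame lags, 0 at odd
  expect_equal(rr$C, rep(c(0, 1), 5))
  # all-ones trace never decays: censored
  ones <- structure(list(p = rep(1L, 500), dt = 10), class = "OccupancyTrace")
  expect_true(residence_time(ones)$censored)
  zeros <- structure(list(p = rep(0L, 500), dt = 10), class = "OccupancyTrace")
  expect_error(residence_time(zeros), "never occupied")
})

test_that("residence time recovers telegraph bound durations within 10%", {
  # mean bound duration tau* across a spread of kinetic regimes; trace
  # length 200 tau*, symmetric rates (occupancy 50%, ~100 bound episodes)
  for (tau in c(0.25, 2.0)) {
    est <- vapply(1:20, function(s) {
      sp <- telegraph_spec(k_on = 1 / tau, k_off = 1 / tau, dt = 10,
                           T = 200 * tau, seed = 500 + s)
      out <- simulate_telegraph(sp)
      tr <- occupancy_trace(out$traj, 1L, "Na+", sp$cutoff, window = FALSE)
      rt <- residence_time(tr)
      if (rt$censored) NA_real_ else rt$tau_R
    }, 0)
    expect_lt(abs(median(est, na.rm = TRUE) / tau - 1), 0.10)
  }
})

test_that("binding distances are recovered from constructed geometries", {
  box <- c(20, 20, 20)
  site <- ion_traj(matrix(c(10, 10, 10), 1), n_frames = 300, box = box,
                   species = "K+")
  # pinned ion at exactly 2.39 A
  ion <- ion_traj(matrix(c(12.39, 10, 10), 1), n_frames = 300, box = box)
  sys <- merge_trajectories(site, ion)
  bs <- binding_distance_stats(sys, 1L, "Na+", cutoff = 3, window = FALSE)
  expect_equal(bs$mean, 2.39, tolerance = 1e-12)
  expect_equal(bs$sd, 0)
  expect_equal(bs$n_bound_frames, 300)
  # distances drawn Gaussian(2.38, 0.13) truncated at the cutoff
  set.seed(77)
  n <- 2000
  r <- rnorm(n, 2.38, 0.13)
  r <- ifelse(r >= 3 | r <= 0, 2.38, r)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- array(t(sweep(u * r, 2, c(10, 10, 10), "+")), c(1, 3, n))
  sys2 <- merge_trajectories(ion_traj(matrix(c(10, 10, 10), 1), n_frames = n,
                                      box = box, species = "K+"),
                             ion_traj(pos, box = box))
  bs2 <- binding_distance_stats(sys2, 1L, "Na+", cutoff = 3, window = FALSE)
  expect_lt(abs(bs2$mean - 2.38), 4 * 0.13 / sqrt(n))
  expect_lte(bs2$mean, bs2$cutoff)
  # no bound frames: undefined flag, not an exception
  far <- merge_trajectories(site, ion_traj(matrix(c(1, 1, 1), 1),
                                           n_frames = 300, box = box))
  bs3 <- binding_distance_stats(far, 1L, "Na+", cutoff = 3, window = FALSE)
  expect_true(bs3$undefined)
})

test_that("pockets are detected with intersection-over-dwell semantics", {
  th <- acos(-1 / 3)
  dirs <- rbind(c(0, 0, 1),
                c(sin(th), 0, cos(th)),
                c(sin(th) * cos(2 * pi / 3), sin(th) * sin(2 * pi / 3), cos(th)),
                c(sin(th) * cos(4 * pi / 3), sin(th) * sin(4 * pi / 3), cos(th)))
  pos <- 2.4 * dirs + 10
  atoms <- data.frame(name = c("O2", "O2", "O2'", "O2'"), element = "O",
                      residue = 1:4, base = "C", chain = "A", charge = 0,
                      resname = "DC")
  top <- topology(rbind(atoms, ION_DF(1, "Na+")),
                  pairing = data.frame(res1 = 1, res2 = 2))
  co <- array(NA_real_, c(5, 3, 100))
  for (f in 1:100) { co[1:4, , f] <- pos; co[5, , f] <- c(10, 10, 10) }
  tr <- trajectory(top, co, c(20, 20, 20), dt = 10,
                   species = list("Na+" = 5L))
  pk <- detect_pockets(tr, "Na+", cutoff = 3, min_sites = 4)
  expect_length(pk, 1)
  expect_length(pk[[1]]$members, 4)
  expect_equal(pk[[1]]$dwell, 100 * 10)
  expect_match(pk[[1]]$member_names, "O2'\\(C\\) x2")
  expect_match(pk[[1]]$member_names, "O2\\(C\\) x2")
  # threshold semantics
  expect_length(detect_pockets(tr, "Na+", cutoff = 3, min_sites = 5), 0)
  # nothing within cutoff: empty list
  far <- tr
  far$coords[5, , ] <- 1
  expect_length(detect_pockets(far, "Na+", cutoff = 3, min_sites = 2), 0)
  # pocket membership consistent with occupancy: every member's trace is 1
  # throughout the dwell
  for (m in pk[[1]]$members) {
    trm <- occupancy_trace(tr, m, "Na+", cutoff = 3, window = FALSE)
    span <- pk[[1]]$frames[1]:pk[[1]]$frames[2]
    expect_true(all(trm$p[span] == 1L))
  }
})

test_that("occupancy by sequence localizes binding and mirrors strands", {
  dup <- build_duplex(duplex_spec("B-DNA"))
  a <- dup$topology$atoms
  o6 <- which(a$residue == 8 & a$name == "O6")
  # place an ion 2 A from G8-O6, further than 3 A from every other atom on
  # a different residue (fixture checked below)
  dir <- dup$coords[o6, ] - colMeans(dup$coords)
  dir <- dir / sqrt(sum(dir^2))
  ion_pos <- dup$coords[o6, ] + 2.0 * dir
  dmin <- min_image_distance(matrix(ion_pos, nrow(dup$coords), 3, byrow = TRUE),
                             dup$coords, rep(82, 3))
  near <- unique(a$residue[dmin < 3])
  touched <- sort(unique(a$residue[dmin < 3 & classify_region(a$name, a$base) ==
                                     "major"]))
  ion <- ion_traj(matrix(ion_pos, 1), n_frames = 4)
  sys <- duplex_system(ion)
  tab <- occupancy_by_sequence(sys, "Na+", cutoff = 3, window = FALSE)
  nz <- tab[!is.na(tab$occupancy) & tab$occupancy > 0, ]
  expect_true(all(nz$region == "major"))
  expect_setequal(nz$residue, touched)
  expect_true(8 %in% nz$residue)
  # no normalization across regions: each region's occupancy can reach 100
  expect_true(all(nz$occupancy == 100))
})

test_that("strand-mirror symmetry and cutoff monotonicity hold for gas ions", {
  gas <- simulate_ion_gas(22, 800, "Na+", box = 82, dt = 10, seed = 23)
  sys <- duplex_system(gas)
  t6 <- occupancy_by_sequence(sys, "Na+", cutoff = 6, window = FALSE)
  t3 <- occupancy_by_sequence(sys, "Na+", cutoff = 3, window = FALSE)
  # monotonicity: occupancy at 6 A >= occupancy at 3 A everywhere
  ok <- !is.na(t6$occupancy)
  expect_true(all(t6$occupancy[ok] >= t3$occupancy[ok]))
  # mirror symmetry: the strands are dyad images, so occupancies at the
  # same 5'->3' position agree within sampling error (iid frames;
  # per-cell binomial SE is at most ~1.8 points here)
  a6 <- t6[t6$strand == "A", ]
  b6 <- t6[t6$strand == "B", ]
  key <- paste(a6$position, a6$region)
  d <- a6$occupancy - b6$occupancy[match(key, paste(b6$position, b6$region))]
  expect_lt(max(abs(d), na.rm = TRUE), 8)
})
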