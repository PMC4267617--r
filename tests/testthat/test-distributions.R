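# distributions: CDF, RDF, peaks, coordination, charge accumulation,
# convergence

test_that("ideal-gas CDF is flat at the analytic density and conserves mass", {
  gas <- simulate_ion_gas(200, 300, "Na+", box = 82, dt = 10, seed = 7)
  hf <- helix_frame(rep(41, 3), c(0, 0, 1), c(-20, 20))
  d <- compute_cdf(gas, "Na+", hf, r_max = 30, dr = 2)
  rho_M <- 200 / (6.02214076e23 * 82^3 * 1e-27)
  expect_true(all(abs(d$values - rho_M) <= 3 * d$stderr))
  # mass conservation: binned concentration integrates to the mean count
  integrated <- sum(d$values * 6.02214076e23 * d$meta$shell_vol * 1e-27)
  expect_equal(integrated, d$meta$mean_count, tolerance = 1e-9)
  # absent species: all bins zero, not an error
  d0 <- compute_cdf(gas, "K+", hf, r_max = 30, dr = 2)
  expect_true(all(d0$values == 0))
  # r_max beyond half box records a warning in the result
  dw <- compute_cdf(gas, "Na+", hf, r_max = 45, dr = 5)
  expect_match(dw$meta$warnings, "half the smallest box edge")
  expect_error(compute_cdf(gas, "Na+", hf, window = c(1e6, 2e6)), "no frames")
})

test_that("CDF estimators are invariant to rigid translation with re-wrap", {
  gas <- simulate_ion_gas(100, 50, "Na+", box = 40, dt = 10, seed = 19)
  hf <- helix_frame(rep(20, 3), c(0, 0, 1), c(-10, 10))
  d1 <- compute_cdf(gas, "Na+", hf, r_max = 15, dr = 1)
  shift <- c(13, -7, 29)
  gas2 <- gas
  gas2$coords <- (gas$coords + array(rep(shift, each = 100),
                                     dim(gas$coords))) %% 40
  hf2 <- helix_frame(rep(20, 3) + shift, c(0, 0, 1), c(-10, 10))
  d2 <- compute_cdf(gas2, "Na+", hf2, r_max = 15, dr = 1)
  expect_equal(d2$values, d1$values, tolerance = 1e-12)
})

test_that("ideal-gas RDF is unity within pooled sampling error", {
  gas <- simulate_ion_gas(200, 300, "Na+", box = 82, dt = 10, seed = 7)
  d <- compute_rdf(gas, "Na+", sites = 1:4, r_max = 20, dr = 0.5)
  sel <- (head(d$bin_edges, -1) + tail(d$bin_edges, -1)) / 2 > 2
  expect_lt(mean(abs(d$values[sel] - 1)),
            3 * mean(d$stderr[sel], na.rm = TRUE))
  expect_error(compute_rdf(gas, "Na+", sites = integer(0)), "empty")
})

test_that("RDF pair counts equal hand-enumerated distances on a tiny fixture", {
  # 2 frames, 3 ions, 2 sites; fixed coordinates
  box <- c(20, 20, 20)
  sites <- rbind(c(5, 5, 5), c(15, 15, 15))
  site_df <- data.frame(name = c("O6", "N7"), element = "N", residue = 1,
                        base = "G", chain = "A", charge = 0, resname = "DG")
  ions <- aperm(array(c(c(6.2, 5, 5), c(8.1, 5, 5), c(19.3, 15, 15),
                        c(5, 7.7, 5), c(5, 5, 13.3), c(15, 15, 14.3)),
                      c(3, 3, 2)), c(2, 1, 3))
  co <- array(NA_real_, c(5, 3, 2))
  co[1:2, , 1] <- sites; co[1:2, , 2] <- sites
  co[3:5, , 1] <- ions[, , 1]; co[3:5, , 2] <- ions[, , 2]
  top <- topology(rbind(site_df, ION_DF(3, "Na+")))
  tr <- trajectory(top, co, box, dt = 10,
                   species = list("Na+" = 3:5))
  d <- compute_rdf(tr, "Na+", sites = 1:2, r_max = 10, dr = 0.5)
  # oracle: enumerate the 12 site-ion distances and bin by hand
  dd <- c()
  for (f in 1:2) for (s in 1:2) for (i in 3:5) {
    dd <- c(dd, brute_min_image(co[s, , f], co[i, , f], box))
  }
  oracle <- as.vector(table(cut(dd[dd < 10], breaks = d$bin_edges)))
  expect_equal(d$raw_counts, oracle)
})

test_that("first_peak reports the first qualifying maximum", {
  mk <- function(values, dr = 0.1) {
    edges <- seq(0, by = dr, length.out = length(values) + 1)
    ionscape:::distribution_result(edges, values, rep(0L, length(values)),
                                   1L, "Na+", "rdf",
                                   meta = list(rho_bulk = 1,
                                               shell_vol = diff(edges^3) * 4 / 3 * pi,
                                               n_sites = 1))
  }
  ctrs <- function(d) (head(d$bin_edges, -1) + tail(d$bin_edges, -1)) / 2
  # single Gaussian profile centered at 2.4 A (first-shell binding scale)
  x <- seq(0.05, 6, by = 0.1)
  g <- 8 * exp(-(x - 2.4)^2 / (2 * 0.1^2))
  pk <- first_peak(mk(g))
  expect_false(pk$none)
  expect_equal(pk$r_peak, 2.35, tolerance = 0.11)  # within one bin of 2.4
  # monotone decreasing: none
  expect_true(first_peak(mk(rev(sort(g))))$none)
  # two peaks: returns the first, not the taller
  g2 <- 3 * exp(-(x - 4.1)^2 / 0.02) + 6 * exp(-(x - 6.5)^2 / 0.02)
  hmm <- first_peak(mk(g2))
  expect_equal(hmm$r_peak, x[which.min(abs(x - 4.1))], tolerance = 0.11)
})

test_that("coordination numbers match direct neighbor counting", {
  site <- ion_traj(matrix(c(15, 15, 15), 1), n_frames = 100,
                   box = c(30, 30, 30), species = "K+")
  gas <- simulate_ion_gas(300, 100, "Na+", box = 30, dt = 10, seed = 5)
  sys <- merge_trajectories(site, gas)
  d <- compute_rdf(sys, "Na+", sites = 1L, r_max = 10, dr = 0.25)
  rho <- 300 / 30^3
  n5 <- coordination_number(d, 5)
  # counting oracle: mean number of Na+ within 5 A of the site
  cnt <- mean(vapply(1:100, function(f) {
    p <- sys$coords[2:301, , f]
    sum(min_image_distance(p, matrix(c(15, 15, 15), 300, 3, byrow = TRUE),
                           sys$box) < 5)
  }, 0))
  expect_equal(n5, cnt, tolerance = 1e-9)
  # ideal gas: N(r) = rho * 4/3 pi r^3 within sampling error
  expect_equal(n5, rho * 4 / 3 * pi * 5^3, tolerance = 0.1 * n5)
  expect_error(coordination_number(d, 50), "outside")
})

test_that("hydration-shell RDF recovers the constructed first shell", {
  ht <- hydration_trajectory(800, n_shell = 6, d0 = 2.43, sigma = 0.05,
                             rho_bulk = 0.0334, box = 20, seed = 11)
  d <- compute_rdf(ht, "WAT-O", sites = 1L, r_max = 8, dr = 0.05)
  pk <- first_peak(d)
  expect_false(pk$none)
  expect_lt(abs(pk$r_peak - 2.43), 0.05 + 1e-9)   # within one bin of d0
  mn <- first_minimum(d)
  expect_false(mn$none)
  expect_gt(mn$r_min, pk$r_peak)
  expect_equal(coordination_number(d, mn$r_min), 6, tolerance = 0.1)
})

test_that("charge accumulation is conservative, monotone and oracle-exact", {
  dup <- build_duplex(duplex_spec("B-DNA"))
  hfs <- NULL
  # neutral box: 22 cations, duplex -22e; full-box axial bounds and r_max
  # beyond the half-diagonal capture every ion -> asymptote exactly 1
  gas <- simulate_ion_gas(22, 100, "Na+", box = 82, dt = 10, seed = 3)
  sys <- duplex_system(gas)
  hf <- helix_frames(sys, frames = 1, pyrimidine_ref = "N1")[[1]]
  q <- charge_accumulation(sys, hf, r_max = 60, dr = 1, axial = "box")
  expect_equal(q$values[length(q$values)], 1, tolerance = 1e-12)
  expect_true(all(diff(q$values) >= -1e-12))        # cations only: monotone
  expect_lte(max(abs(q$values)), 22 / 22 + 1e-12)   # never exceeds total/|net|
  # mixed-salt system: cumulative curve equals brute-force counting per bin
  salt <- merge_trajectories(
    simulate_ion_gas(50, 20, "Na+", box = 82, dt = 10, seed = 8),
    simulate_ion_gas(28, 20, "Cl-", box = 82, dt = 10, seed = 9))
  sys2 <- duplex_system(salt)
  q2 <- charge_accumulation(sys2, hf, r_max = 40, dr = 2, axial = "box")
  oracle <- rep(0, length(q2$values))
  zb <- c(-sum(abs(hf$direction) * sys2$box) / 2,
          sum(abs(hf$direction) * sys2$box) / 2)
  for (f in 1:20) {
    for (sp in c("Na+", "Cl-")) {
      z <- if (sp == "Na+") 1 else -1
      for (i in sys2$species[[sp]]) {
        v <- sys2$coords[i, , f] - hf$origin
        v <- v - sys2$box * round(v / sys2$box)
        zc <- sum(v * hf$direction)
        r <- sqrt(sum(v^2) - zc^2)
        if (zc >= zb[1] && zc <= zb[2]) {
          oracle <- oracle + z * (q2$bin_edges[-1] >= r) / 20
        }
      }
    }
  }
  expect_equal(q2$values, oracle / 22, tolerance = 1e-9)
  # species with undefined charge errors
  bad <- sys2
  bad$species[["Xx"]] <- 1L
  expect_error(charge_accumulation(bad, hf), "undefined charge")
  # zero net duplex charge errors
  gasonly <- salt
  expect_error(charge_accumulation(gasonly, hf), "net charge")
})

test_that("convergence series shrinks for stationary input and flags drift", {
  set.seed(21)
  hf <- helix_frame(rep(20, 3), c(0, 0, 1), c(-15, 15))
  gas <- simulate_ion_gas(150, 360, "Na+", box = 40, dt = 10, seed = 13)
  t0 <- 0
  ends <- c(600, 1200, 1800, 2400, 3000, 3590)
  windows <- lapply(ends, function(e) c(t0, e))
  cs <- convergence_series(gas, windows, species = "Na+", hf = hf,
                           r_max = 15, dr = 1.5)
  expect_length(cs$sup_diffs, 5)
  expect_lt(cs$trend_rho, 0)
  expect_false(cs$non_shrinking)
  # first profile equals the direct call
  direct <- compute_cdf(gas, "Na+", hf, r_max = 15, dr = 1.5,
                        window = windows[[1]])
  expect_equal(cs$profiles[[1]]$values, direct$values)
  # drifting process: ions collapse toward the axis mid-trace
  drift <- gas
  late <- 181:360
  for (f in late) {
    u <- t(gas$coords[, , f])
    dirxy <- sweep(u[, 1:2, drop = FALSE], 2, c(20, 20))
    u[, 1:2] <- sweep(dirxy * 0.2, 2, c(20, 20), "+")
    drift$coords[, , f] <- t(u)
  }
  w2 <- lapply(c(600, 1200, 1800, 3590), function(e) c(t0, e))
  cs2 <- convergence_series(drift, w2, species = "Na+", hf = hf,
                            r_max = 15, dr = 1.5)
  expect_true(cs2$non_shrinking)
  # malformed windows
  expect_error(convergence_series(gas, list(c(0, 100), c(50, 200)),
                                  species = "Na+", hf = hf), "share")
  expect_error(convergence_series(gas, list(c(0, 200))), "at least 2")
})
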