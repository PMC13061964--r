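test_that("lognormal fits anchor the stated moments", {
  # sd = 0 collapses to a point mass at the mean
  fit0 <- fit_lognormal(0.928, 0, "moment_matched")
  expect_identical(fit0$params$sdlog, 0)
  expect_equal(sample_dist(fit0, 3), rep(0.928, 3))

  mm <- fit_lognormal(0.928, 0.72, "moment_matched")
  # closed-form arithmetic moments of the fitted lognormal
  m <- exp(mm$params$meanlog + mm$params$sdlog^2 / 2)
  s <- m * sqrt(exp(mm$params$sdlog^2) - 1)
  expect_equal(m, 0.928)
  expect_equal(s, 0.72)
  set.seed(101)
  x <- sample_dist(mm, 2e5)
  expect_equal(mean(x), 0.928, tolerance = 0.01)
  expect_equal(sd(x), 0.72, tolerance = 0.01)

  ma <- fit_lognormal(0.928, 0.72, "median_anchored")
  expect_equal(exp(ma$params$meanlog), 0.928) # median pinned to the mean
  set.seed(102)
  y <- sample_dist(ma, 2e5)
  expect_equal(median(y), 0.928, tolerance = 0.01)

  expect_error(fit_lognormal(0, 0.1), "strictly positive")
})

test_that("distribution draws respect their declared support", {
  expect_equal(sample_dist(dist_point(6.6e-3), 5), rep(6.6e-3, 5))
  set.seed(103)
  u <- sample_dist(dist_uniform(350, 365), 5000)
  expect_true(all(u >= 350 & u <= 365))
  tn <- sample_dist(dist_normal(70, 10, 50, 90), 5000)
  expect_true(all(tn >= 50 & tn <= 90))
  ln <- sample_dist(fit_lognormal(3.501, 2.15), 5000)
  expect_true(all(ln > 0))
  expect_error(sample_dist(dist_normal(0, 1, 50, 40)), "ordered")
  expect_error(sample_dist(dist_normal(0, 1e-9, 50, 90), 10),
               "zero probability mass")
})

test_that("summaries use interpolated percentiles and exceedance fractions", {
  s <- summarize_samples(1:100, threshold = 1)
  expect_equal(s$p50, 50.5)
  expect_equal(s$p95, 95.05)
  expect_equal(s$p_exceed, 0.99)
  cc <- summarize_samples(rep(3.2, 10), threshold = 1)
  expect_equal(cc$mean, 3.2)
  expect_equal(cc$p50, 3.2)
  expect_equal(cc$p95, 3.2)
  expect_equal(cc$p_exceed, 1)
  expect_error(summarize_samples(numeric()), "empty")
})

test_that("point-mass simulation equals the deterministic assessment", {
  tab <- mushroom_concentrations()
  det <- assess_risk(tab)
  for (group in c("adult", "child")) {
    scen <- default_scenario(group)
    cfg <- simulation_config(tab, group, n_iter = 3,
                             concentration_dist = "point",
                             ir = dist_point(scen$ir), ef = dist_point(scen$ef),
                             ed = dist_point(scen$ed), bw = dist_point(scen$bw))
    sim <- simulate_risk(cfg)
    for (sp in unique(tab$species)) {
      d <- det[det$species == sp & det$group == group, ][1, ]
      expect_equal(sim$samples[[sp]]$hi, rep(d$hi, 3), tolerance = 1e-13)
      expect_equal(sim$samples[[sp]]$tcr, rep(d$tcr, 3), tolerance = 1e-13)
    }
  }
})

test_that("a single seeded draw matches hand-propagated arithmetic", {
  tab <- data.frame(species = "A", element = c("Cd", "As"),
                    mean_conc = c(2, 1), sd_conc = c(1, 0.5))
  cfg <- simulation_config(tab, "adult", n_iter = 1, seed = 99)
  sim <- simulate_risk(cfg)
  # replay the same substreams by hand
  redraw <- function(label, spec) {
    set.seed(mycorisk:::substream_seed(99, label))
    sample_dist(spec, 1)
  }
  ir <- redraw("ir", cfg$ir); ef <- redraw("ef", cfg$ef)
  ed <- redraw("ed", cfg$ed); bw <- redraw("bw", cfg$bw)
  cd <- redraw("mc:A:Cd", cfg$mc_specs$A$Cd)
  as_ <- redraw("mc:A:As", cfg$mc_specs$A$As)
  hi_hand <- cd * ir / bw / 1e-3 + as_ * ir / bw / 3e-4
  tcr_hand <- cd * ir * ed * ef / (bw * 25550) * 6.3 +
    as_ * ir * ed * ef / (bw * 25550) * 1.5
  expect_equal(sim$samples$A$hi, hi_hand)
  expect_equal(sim$samples$A$tcr, tcr_hand)
})

test_that("simulations are seed-deterministic and stable across seeds", {
  tab <- mushroom_concentrations()
  cfg <- simulation_config(tab, "adult", n_iter = 4000, seed = 5)
  s1 <- simulate_risk(cfg)
  s2 <- simulate_risk(cfg)
  expect_identical(s1$summary, s2$summary)
  cfg3 <- simulation_config(tab, "adult", n_iter = 4000, seed = 6)
  s3 <- simulate_risk(cfg3)
  expect_false(identical(s1$summary$mean, s3$summary$mean))
  # different seeds agree within Monte Carlo error (generous 4 sigma)
  hi1 <- s1$samples[["Laccaria laccata"]]$hi
  hi3 <- s3$samples[["Laccaria laccata"]]$hi
  se <- sqrt(var(hi1) / 4000 + var(hi3) / 4000)
  expect_lt(abs(mean(hi1) - mean(hi3)), 4 * se)
})

test_that("per-parameter substreams isolate species from one another", {
  tab <- mushroom_concentrations()
  sub <- validate_concentration_table(
    tab[tab$species != "Pholiota carbonaria", ])
  full <- simulate_risk(simulation_config(tab, "adult", n_iter = 500,
                                          seed = 17))
  part <- simulate_risk(simulation_config(sub, "adult", n_iter = 500,
                                          seed = 17))
  expect_identical(part$samples[["Laccaria laccata"]]$hi,
                   full$samples[["Laccaria laccata"]]$hi)
})

test_that("scaling every concentration scales HI and TCR draws exactly", {
  tab <- mushroom_concentrations()
  k <- 3
  scaled <- tab
  scaled$mean_conc <- scaled$mean_conc * k
  scaled$sd_conc <- scaled$sd_conc * k
  base <- simulate_risk(simulation_config(tab, "adult", n_iter = 300,
                                          seed = 23))
  up <- simulate_risk(simulation_config(scaled, "adult", n_iter = 300,
                                        seed = 23))
  for (sp in names(base$samples)) {
    expect_equal(up$samples[[sp]]$hi, k * base$samples[[sp]]$hi)
    expect_equal(up$samples[[sp]]$tcr, k * base$samples[[sp]]$tcr)
  }
})

test_that("median never exceeds the 95th percentile", {
  tab <- mushroom_concentrations()
  for (group in c("adult", "child", "lifespan")) {
    sim <- simulate_risk(simulation_config(tab, group, n_iter = 1000,
                                           seed = 29))
    expect_true(all(sim$summary$p50 <= sim$summary$p95))
    expect_true(all(sim$summary$p_exceed >= 0 & sim$summary$p_exceed <= 1))
  }
})

test_that("histogram export writes deterministic binned counts", {
  tab <- validate_concentration_table(
    data.frame(species = "A", element = "Cd", mean_conc = 2, sd_conc = 1))
  sim <- simulate_risk(simulation_config(tab, "adult", n_iter = 2000,
                                         seed = 31))
  dir <- withr::local_tempdir()
  files <- export_histograms(sim, dir, bins = 25, image = TRUE)
  csvs <- grep("\\.csv$", files, value = TRUE)
  expect_length(csvs, 2) # one per metric for the single species
  expect_length(grep("\\.png$", files), 2)
  counts <- read.csv(csvs[1])
  expect_identical(sum(counts$count), 2000L)
  expect_identical(nrow(counts), 25L)

  # constant draws occupy a single bin
  cfgc <- simulation_config(tab, "adult", n_iter = 100,
                            concentration_dist = "point",
                            ir = dist_point(6.6e-3), ef = dist_point(350),
                            ed = dist_point(26), bw = dist_point(70))
  simc <- simulate_risk(cfgc)
  dirc <- withr::local_tempdir()
  fc <- export_histograms(simc, dirc, bins = 10, image = FALSE)
  cc <- read.csv(grep("_hi\\.csv$", fc, value = TRUE))
  expect_identical(sum(cc$count > 0), 1L)

  # uniform draws give approximately flat bins (chi-square vs flat)
  set.seed(37)
  u <- sample_dist(dist_uniform(0, 1), 10000)
  obs <- tabulate(findInterval(u, seq(0, 1, length.out = 21),
                               rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = 20)
  p <- stats::chisq.test(obs, p = rep(1 / 20, 20))$p.value
  expect_gt(p, 1e-4)
})
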