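# Torsion-knowledge module: periodic KDE fitting, rule assignment, library IO.

test_that("single-mode observations yield one dominant peak at the mode", {
  obs <- torsion_observations("[C:1][C:2][C:3][C:4]",
                              protaconf:::.wrap_angle(180 + seq(-2, 2, length.out = 200)))
  rule <- fit_torsion_rule(obs, bandwidth = 10)
  expect_lte(circ_diff(rule$peaks$angle[1], 180), 3)
  expect_equal(rule$peaks$probability[1], 1.0, tolerance = 1e-9)
  expect_equal(sum(rule$peaks$probability), 1.0, tolerance = 1e-9)
})

test_that("a symmetric two-mode mixture splits probability evenly", {
  set.seed(42)
  angles <- c(60 + rnorm(100, sd = 3), -60 + rnorm(100, sd = 3))
  rule <- fit_torsion_rule(torsion_observations("*", angles), bandwidth = 10)
  expect_equal(nrow(rule$peaks), 2L)
  expect_lte(min(circ_diff(rule$peaks$angle, 60)), 3)
  expect_lte(min(circ_diff(rule$peaks$angle, -60)), 3)
  # histogram-mass oracle on 1-degree bins: mass on the positive half vs
  # negative half of the circle (split at 0/180)
  pos_mass <- mean(angles > 0 & angles < 180)
  expect_lt(abs(rule$peaks$probability[rule$peaks$angle > 0] - pos_mass), 0.05)
  expect_lt(abs(rule$peaks$probability[1] - 0.5), 0.05)
})

test_that("peak count respects max_peaks and defaults cap at 10", {
  set.seed(7)
  angles <- protaconf:::.wrap_angle(runif(500, -180, 180))
  rule <- fit_torsion_rule(torsion_observations("*", angles),
                           bandwidth = 5, max_peaks = 10)
  expect_lte(nrow(rule$peaks), 10L)
  rule3 <- fit_torsion_rule(torsion_observations("*", angles),
                            bandwidth = 5, max_peaks = 3)
  expect_lte(nrow(rule3$peaks), 3L)
  expect_equal(sum(rule3$peaks$probability), 1.0, tolerance = 1e-9)
})

test_that("fitting is invariant under a 360-degree shift of observations", {
  set.seed(11)
  angles <- c(75 + rnorm(80, sd = 5), -150 + rnorm(40, sd = 5))
  angles <- protaconf:::.wrap_angle(angles)
  r1 <- fit_torsion_rule(torsion_observations("*", angles))
  r2 <- fit_torsion_rule(torsion_observations("*",
                                              protaconf:::.wrap_angle(angles + 360)))
  expect_equal(r1$peaks, r2$peaks, tolerance = 1e-12)
})

test_that("fitted mass ratio converges to the mixture ratio", {
  modes <- data.frame(angle = c(180, 40), weight = c(0.7, 0.3), sd = 8)
  obs <- sample_torsion_observations(modes, n = 10000, seed = 99)
  rule <- fit_torsion_rule(obs, bandwidth = 10)
  p180 <- rule$peaks$probability[which.min(circ_diff(rule$peaks$angle, 180))]
  p40 <- rule$peaks$probability[which.min(circ_diff(rule$peaks$angle, 40))]
  expect_lt(abs(p180 / p40 - 0.7 / 0.3), 0.1 * (0.7 / 0.3))
})

test_that("empty or out-of-range observations are rejected", {
  expect_error(torsion_observations("*", numeric()), "at least one")
  expect_error(torsion_observations("*", c(10, 190)), "-180")
  expect_error(fit_torsion_rule(torsion_observations("*", 10), bandwidth = -1))
})

test_that("rule assignment is total: pattern match first, fallback else", {
  # C-C-C-O-C-C ether chain: the two C-O bonds take the ether rule, the
  # interior C-C bond falls back (terminal bonds are not rotatable)
  mol <- chain_mol(6, c("C", "C", "C", "O", "C", "C"))
  ether <- torsion_rule("[C:1][C:2][O:3][C:4]",
                        data.frame(angle = c(180, 75, -75),
                                   probability = c(0.5, 0.25, 0.25)))
  lib <- torsion_library(list(ether), default_fallback_rule())
  asg <- assign_rules(mol, lib)
  expect_equal(nrow(asg), 3L)  # bonds 2-3, 3-4, 4-5
  pat <- vapply(asg$rule, function(r) r$pattern, character(1))
  co_bond <- (asg$a == 3 & asg$b == 4) | (asg$a == 4 & asg$b == 5)
  expect_true(all(pat[co_bond] == "[C:1][C:2][O:3][C:4]"))
  expect_true(all(pat[!co_bond] == "*"))
})

test_that("a molecule with no rotatable bonds gets an empty assignment", {
  asg <- assign_rules(benzene_mol(), torsion_library())
  expect_equal(nrow(asg), 0L)
})

test_that("library files round-trip bit-exactly and reject bad records", {
  r1 <- torsion_rule("[C:1][C:2][O:3][C:4]",
                     data.frame(angle = c(179.123456789, -61.5, 62.25),
                                probability = c(0.5, 0.25, 0.25)), 12.5)
  r2 <- torsion_rule("[C:1][C:2][C:3][C:4]",
                     data.frame(angle = 180, probability = 1))
  lib <- torsion_library(list(r1, r2), default_fallback_rule())
  path <- withr::local_tempfile(fileext = ".txt")
  write_torsion_library(lib, path)
  lib2 <- read_torsion_library(path)
  expect_identical(lapply(lib$rules, unclass), lapply(lib2$rules, unclass))
  expect_identical(unclass(lib$fallback), unclass(lib2$fallback))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PATTERN [C:1][C:2][C:3][C:4]", "PEAK 180 0.5", "PEAK 60 0.3",
               "", "PATTERN *", "PEAK 180 1.0"), bad)
  expect_error(read_torsion_library(bad), "sum to 1")

  fallback_only <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PATTERN *", "BANDWIDTH 10", "PEAK 180 1"), fallback_only)
  libf <- read_torsion_library(fallback_only)
  expect_length(libf$rules, 0L)
  expect_equal(libf$fallback$peaks$angle, 180)

  no_fallback <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PATTERN [C:1][C:2][C:3][C:4]", "PEAK 180 1"), no_fallback)
  expect_error(read_torsion_library(no_fallback), "fallback")
})

test_that("the bundled default library loads and matches its observations", {
  lib <- default_torsion_library()
  expect_gte(length(lib$rules), 4L)
  expect_equal(lib$fallback$pattern, "*")
  for (r in lib$rules)
    expect_equal(sum(r$peaks$probability), 1, tolerance = 1e-9)
  # refit from the bundled observation files reproduces the shipped rules
  obs_dir <- system.file("extdata", "torsion_obs", package = "protaconf")
  fls <- list.files(obs_dir, full.names = TRUE)
  expect_gte(length(fls), 4L)
  obs <- read_torsion_observations(fls[1])
  refit <- fit_torsion_rule(obs, bandwidth = 10)
  shipped <- Filter(function(r) r$pattern == obs$pattern, lib$rules)[[1]]
  expect_equal(refit$peaks$angle, shipped$peaks$angle, tolerance = 0.51)
  expect_equal(refit$peaks$probability, shipped$peaks$probability,
               tolerance = 0.01)
})
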