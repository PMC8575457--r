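test_that("the spike simulator respects its rate structure and seed", {
  empty <- simulate_spike_train(spike_sim_config(0, 0, seed = 1))
  expect_length(empty$spike_times, 0L)

  # homogeneous 20 Hz over 10 s: total count near 200
  cfg <- spike_sim_config(20, 20, recording_span = 10, seed = 2)
  tr <- simulate_spike_train(cfg)
  expect_lt(abs(length(tr$spike_times) - 200), 4 * sqrt(200))
  expect_true(!is.unsorted(tr$spike_times))
  expect_true(all(tr$spike_times >= 0 & tr$spike_times <= 10))

  # same seed, byte-identical; different seed, different draw
  tr2 <- simulate_spike_train(cfg)
  expect_identical(tr$spike_times, tr2$spike_times)
  cfg3 <- spike_sim_config(20, 20, recording_span = 10, seed = 3)
  expect_false(identical(tr$spike_times,
                         simulate_spike_train(cfg3)$spike_times))

  expect_error(spike_sim_config(-1, 10), ">= 0")
  expect_error(spike_sim_config(10, 10, stimulus_onset = 0.5), "baseline")
})

test_that("count_response is unbiased for the programmed rate difference", {
  # evoked 60 Hz vs baseline 20 Hz in 0.5 s windows: expectation 2*(30-10)
  vals <- vapply(1:300, function(s) {
    count_response(simulate_spike_train(spike_sim_config(20, 60, seed = s)))
  }, numeric(1))
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 40), 3 * sem + 1e-9)
})

test_that("panel simulation reproduces its programmed structure", {
  muts <- mutation_set(c("A", "B", "C"))
  base <- c(C2 = 80, C3 = 40, C4 = 20)

  # zero effects, zero noise: every row equals the baseline tuning
  cfg0 <- panel_sim_config(base, list(), noise_sd = 0, n_sensilla = 3, seed = 1)
  sim0 <- simulate_panel(cfg0, muts)
  expect_equal(length(unique(genotypes(sim0$matrix))), 8L)
  expect_true(all(apply(unclass(sim0$matrix), 1,
                        function(r) all(r == base))))

  # effects and interactions compose into the genotype means
  cfg <- panel_sim_config(base,
                          effects = list(A = c(C4 = 10), B = c(C4 = 20)),
                          interactions = list("A:B" = c(C4 = -30)),
                          noise_sd = 0, n_sensilla = 3, seed = 1)
  sim <- simulate_panel(cfg, mutation_set(c("A", "B")))
  truth <- sim$truth$mean_response
  expect_equal(truth[["wt"]][["C4"]], 20)
  expect_equal(truth[["A"]][["C4"]], 30)
  expect_equal(truth[["B"]][["C4"]], 40)
  expect_equal(truth[["A,B"]][["C4"]], 20)  # 20 + 10 + 20 - 30
  ab_rows <- genotypes(sim$matrix) == "A,B"
  expect_true(all(unclass(sim$matrix)[ab_rows, "C4"] == 20))
})

test_that("same seed gives byte-identical panels; missing rate converges", {
  muts <- mutation_set(c("A", "B"))
  base <- c(C2 = 80, C4 = 20)
  cfg <- panel_sim_config(base, list(A = c(C4 = 10), B = c(C4 = 10)),
                          noise_sd = 5, n_sensilla = 50,
                          missing_rate = 0.1, seed = 12)
  s1 <- simulate_panel(cfg, muts)
  s2 <- simulate_panel(cfg, muts)
  expect_identical(unclass(s1$matrix)[, ], unclass(s2$matrix)[, ])
  frac <- mean(is.na(s1$matrix))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / length(s1$matrix)))
})

test_that("simulated response moments converge to the programmed values", {
  muts <- mutation_set("A")
  base <- c(C2 = 60, C4 = 30)
  cfg <- panel_sim_config(base, list(A = c(C4 = 25)), noise_sd = 8,
                          n_sensilla = 1000, seed = 4)
  sim <- simulate_panel(cfg, muts)
  a_rows <- genotypes(sim$matrix) == "A"
  x <- unclass(sim$matrix)[a_rows, "C4"]
  sem <- 8 / sqrt(1000)
  expect_lt(abs(mean(x) - 55), 3 * sem)
  expect_lt(abs(sd(x) - 8), 3 * 8 / sqrt(2 * 999))
})

test_that("estimated per-mutation effects recover the programmed effects within 2 SEM", {
  muts <- mutation_set(c("A", "B"))
  base <- c(C2 = 80, C4 = 20)
  cfg <- panel_sim_config(base, list(A = c(C4 = 18), B = c(C4 = 9)),
                          noise_sd = 5, n_sensilla = 40, seed = 21)
  sim <- simulate_panel(cfg, muts)
  v <- unclass(sim$matrix)[, "C4"]
  g <- genotypes(sim$matrix)
  for (nm in c("A", "B")) {
    est <- mean(v[g == nm]) - mean(v[g == "wt"])
    sem <- sqrt(var(v[g == nm]) / 40 + var(v[g == "wt"]) / 40)
    expect_lt(abs(est - c(A = 18, B = 9)[[nm]]), 2 * sem + 1e-9)
  }
})

test_that("spike CSVs round-trip through the quantification interchange format", {
  cfg <- spike_sim_config(20, 60, seed = 33)
  trains <- lapply(1:3, function(i) {
    simulate_spike_train(spike_sim_config(20, 60, seed = i))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_csv(trains, path)
  back <- read_spike_csv(path, stimulus_onset = 3)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$spike_times, trains[[i]]$spike_times)
    expect_equal(count_response(back[[i]]), count_response(trains[[i]]))
  }
})

test_that("the fixture tree carries the ten-species topology and cluster states", {
  ft <- fixture_tree()
  expect_length(ft$tree$tip.label, 10L)
  expect_equal(sort(names(ft$tip_states)), sort(ft$tree$tip.label))
  expect_equal(sum(ft$tip_states == "C2"), 6L)
  expect_equal(sum(ft$tip_states == "C4"), 4L)
  expect_equal(fitch(ft$tree, ft$tip_states)$min_changes, 2L)
  relabeled <- setNames(rep("C2", 10), names(ft$tip_states))
  expect_equal(fitch(ft$tree, relabeled)$min_changes, 0L)
})
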