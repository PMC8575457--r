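test_that("the hypercube between two alleles has 2^n genotypes, guarded against explosion", {
  gs3 <- enumerate_genotypes(c("T289S", "Q536K", "F538L"))
  expect_length(gs3$labels, 8L)
  expect_true("wt" %in% gs3$labels)
  expect_true("T289S,Q536K,F538L" %in% gs3$labels)
  expect_false(anyDuplicated(gs3$labels) > 0)
  expect_equal(gs3$labels, sort(gs3$labels))  # lexicographic order

  expect_length(enumerate_genotypes("F538L")$labels, 2L)
  # a 114-substitution divergence is refused, quoting the scale
  expect_error(enumerate_genotypes(paste0("m", 1:114)), "2\\^114 = 2e\\+34")
})

test_that("stepwise paths number n!, each adding one mutation, jointly covering the hypercube", {
  p3 <- enumerate_paths(c("A", "B", "C"))
  expect_length(p3, 6L)
  expect_true(all(lengths(p3) == 4L))
  expect_true(all(vapply(p3, function(x) x[1] == "wt" && x[4] == "A,B,C",
                         logical(1))))
  expect_length(enumerate_paths("A"), 1L)

  p4 <- enumerate_paths(c("A", "B", "C", "D"))
  expect_length(p4, 24L)
  visited <- sort(unique(unlist(p4)))
  expect_equal(visited, sort(enumerate_genotypes(c("A", "B", "C", "D"))$labels))
  expect_error(enumerate_paths(letters[1:9]), "<= 8")
})

test_that("step classification requires both significance and an increase", {
  withr::local_seed(55)
  a <- rnorm(10, 50, 3)
  same <- step_test(a, a + rnorm(10, 0, 1e-8))
  expect_equal(same$classification, "dashed")
  expect_gt(same$p_raw, 0.5)

  up <- step_test(a, rnorm(10, 60, 1))
  expect_equal(up$classification, "solid")
  expect_equal(up$direction, "increase")

  down <- step_test(a, rnorm(10, 40, 1))
  expect_equal(down$classification, "dashed")  # significant but decreasing
  expect_lt(down$p_corrected, 0.05)
  expect_equal(down$direction, "decrease")
})

test_that("the epistasis bootstrap is seeded, reproducible, and exchangeable in its inputs", {
  withr::local_seed(88)
  ph <- additive_phenotypes()
  e1 <- epistasis_test(ph$initial, ph$intA, ph$intB, ph$combined, seed = 42)
  e2 <- epistasis_test(ph$initial, ph$intA, ph$intB, ph$combined, seed = 42)
  expect_identical(e1$expected_distribution, e2$expected_distribution)
  expect_identical(e1$p_raw, e2$p_raw)
  e3 <- epistasis_test(ph$initial, ph$intA, ph$intB, ph$combined, seed = 43)
  expect_false(identical(e1$expected_distribution, e3$expected_distribution))

  # swapping the two intermediates leaves the expected-sum law unchanged:
  # compare the full distributions across many seeds
  sums_ab <- unlist(lapply(1:20, function(s) {
    epistasis_test(ph$initial, ph$intA, ph$intB, ph$combined,
                   n_boot = 200, seed = s)$expected_distribution
  }))
  sums_ba <- unlist(lapply(21:40, function(s) {
    epistasis_test(ph$initial, ph$intB, ph$intA, ph$combined,
                   n_boot = 200, seed = s)$expected_distribution
  }))
  expect_gt(suppressWarnings(ks.test(sums_ab, sums_ba)$p.value), 0.01)
  expect_equal(mean(sums_ab), mean(sums_ba), tolerance = 0.02)
})

test_that("a strong negative interaction is detected with the right sign; the all-null case is quiet", {
  withr::local_seed(99)
  # both effects +20 but the combined genotype sits at the initial mean
  n <- 10
  ini <- rnorm(n, 50, 3)
  iA <- rnorm(n, 70, 3); iB <- rnorm(n, 70, 3)
  comb <- rnorm(n, 50, 3)
  et <- epistasis_test(ini, iA, iB, comb, seed = 1)
  expect_true(et$epistatic)
  expect_equal(et$sign, "negative")

  # all four samples literally identical: no deviation from additivity
  base <- rnorm(n, 50, 3)
  et0 <- epistasis_test(base, base, base, base, seed = 2)
  expect_false(et0$epistatic)

  expect_error(epistasis_test(ini[1:2], iA, iB, comb), "at least 3")
  expect_warning(epistasis_test(ini, iA, iB, comb, n_boot = 50, seed = 3),
                 "small")
})

test_that("the expected distribution is the re-anchored sum of resampled effects", {
  ini <- c(10, 20, 30)          # mean 20
  iA <- c(25, 25, 25)           # effect +5 exactly
  iB <- c(30, 30, 30)           # effect +10 exactly
  comb <- c(34, 35, 36)
  et <- epistasis_test(ini, iA, iB, comb, n_boot = 500, seed = 9)
  # degenerate effects: every bootstrap sum must be 20 + 5 + 10
  expect_true(all(et$expected_distribution == 35))
  expect_length(et$expected_distribution, 500L)
})

test_that("run_landscape assembles phenotypes, steps, and epistasis over the full hypercube", {
  muts <- mutation_set(c("A", "B", "C"))
  base <- c(C1 = 10, C2 = 90, C3 = 50, C4 = 20, C5 = 10, C6 = 5)
  eff <- list(A = c(C2 = -5, C4 = 5), B = c(C2 = -20, C4 = 20),
              C = c(C2 = -35, C4 = 35, C5 = 10))
  cfg <- panel_sim_config(base, eff, noise_sd = 5, n_sensilla = 10, seed = 77)
  sim <- simulate_panel(cfg, muts)
  rep <- run_landscape(sim$matrix, muts, seed = 5)

  expect_s3_class(rep, "landscape_report")
  expect_equal(nrow(rep$genotypes), 8L)
  expect_equal(nrow(rep$steps), 12L)           # 3 * 2^2 hypercube edges
  expect_equal(nrow(rep$epistasis), 6L)        # 3 single-single + 3 single-double
  expect_equal(sort(unique(rep$epistasis$type)),
               c("single-double", "single-single"))
  expect_equal(rep$family_size, 18L)
  expect_true(all(rep$epistasis$p_corrected >= rep$epistasis$p_raw))
  # the wild type is the most C2-tuned, the triple mutant the most C4-tuned
  summ <- rep$genotypes
  expect_equal(summ$label[which.min(summ$mean_pc1)], "wt")
  expect_equal(summ$label[which.max(summ$mean_pc1)], "A,B,C")

  # reproducibility: identical seed, identical report
  rep2 <- run_landscape(sim$matrix, muts, seed = 5)
  expect_identical(rep$epistasis, rep2$epistasis)
  expect_identical(rep$steps, rep2$steps)
})

test_that("a programmed negative interaction is flagged for the right pair through the full pipeline", {
  muts <- mutation_set(c("A", "B"))
  base <- c(C1 = 10, C2 = 90, C3 = 50, C4 = 20, C5 = 10, C6 = 5)
  eff <- list(A = c(C2 = -25, C4 = 25), B = c(C2 = -25, C4 = 25))
  inter <- list("A:B" = c(C4 = -40, C2 = 40))
  cfg <- panel_sim_config(base, eff, interactions = inter, noise_sd = 5,
                          n_sensilla = 10, seed = 31)
  sim <- simulate_panel(cfg, muts)
  rep <- run_landscape(sim$matrix, muts, seed = 8)
  epi <- rep$epistasis
  expect_equal(nrow(epi), 1L)
  expect_true(epi$epistatic)
  expect_equal(epi$sign, "negative")
  expect_equal(sort(c(epi$intA, epi$intB)), c("A", "B"))
})

test_that("run_landscape errors on absent or undersized genotypes", {
  muts <- mutation_set(c("A", "B"))
  base <- c(C2 = 90, C3 = 50, C4 = 20)
  cfg <- panel_sim_config(base, list(A = c(C4 = 10), B = c(C4 = 10)),
                          noise_sd = 5, n_sensilla = 4, seed = 3)
  sim <- simulate_panel(cfg, muts)
  keep <- genotypes(sim$matrix) != "A,B"
  trimmed <- response_matrix(unclass(sim$matrix)[keep, ],
                             genotype = genotypes(sim$matrix)[keep])
  expect_error(run_landscape(trimmed, muts), "A,B")

  # all genotypes present, but one with too many incomplete sensilla
  m2 <- unclass(sim$matrix)
  rows_b <- which(genotypes(sim$matrix) == "B")[1:2]
  m2[rows_b, 1] <- NA
  damaged <- response_matrix(m2, genotype = genotypes(sim$matrix))
  expect_error(run_landscape(damaged, muts), "fewer than 3.*B")
})

test_that("landscape reports serialize to tidy CSVs and JSON", {
  muts <- mutation_set(c("A", "B"))
  base <- c(C2 = 90, C3 = 50, C4 = 20)
  cfg <- panel_sim_config(base, list(A = c(C4 = 15), B = c(C4 = 15)),
                          noise_sd = 5, n_sensilla = 6, seed = 13)
  sim <- simulate_panel(cfg, muts)
  rep <- run_landscape(sim$matrix, muts, seed = 2)
  prefix <- file.path(withr::local_tempdir(), "land")
  paths <- write_landscape(rep, prefix)
  expect_true(all(file.exists(paths)))
  steps <- read.csv(paths[2])
  expect_equal(nrow(steps), nrow(rep$steps))
  summ <- jsonlite::read_json(paths[4])
  expect_equal(summ$family_size, rep$family_size)
})
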