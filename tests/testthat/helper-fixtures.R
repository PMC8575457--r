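# shared fixture builders for the test suite (everything generated in code)

random_response_matrix <- function(n = 6, odors = c("C1", "C2", "C3", "C4"),
                                   missing_rate = 0, genotypes = NULL) {
  vals <- matrix(rnorm(n * length(odors), mean = 40, sd = 20),
                 nrow = n, dimnames = list(NULL, odors))
  if (missing_rate > 0) {
    vals[matrix(runif(length(vals)) < missing_rate, nrow = n)] <- NA
  }
  if (is.null(genotypes)) genotypes <- paste0("g", seq_len(n))
  response_matrix(vals, genotype = genotypes)
}

# random rooted tree with random tip states; optionally collapse short
# internal edges into polytomies
random_pheno_tree <- function(ntip, nstates = 2, polytomies = FALSE) {
  tree <- ape::rtree(ntip)
  if (polytomies && ntip >= 4) {
    tree$edge.length[] <- runif(nrow(tree$edge))
    tree <- ape::di2multi(tree, tol = 0.5)
  }
  states <- paste0("S", seq_len(nstates))
  tips <- setNames(sample(states, length(tree$tip.label), replace = TRUE),
                   tree$tip.label)
  list(tree = tree, tip_states = tips)
}

# independent oracle: minimum change count by exhaustive enumeration of all
# internal-node labelings
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- sort(unique(unname(tip_states[tree$tip.label])))
  grid <- as.matrix(expand.grid(rep(list(states), nnode),
                                stringsAsFactors = FALSE))
  tip_vec <- unname(tip_states[tree$tip.label])
  e <- tree$edge
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tip_vec, grid[r, ])
    changes <- sum(lab[e[, 1]] != lab[e[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# independent oracle: PCA by explicit covariance eigendecomposition
eigen_pca <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc), symmetric = TRUE)
  list(variance_fraction = ev$values / sum(ev$values),
       loadings = ev$vectors)
}

# additive two-mutation phenotype samples for epistasis-test checks
additive_phenotypes <- function(n = 10, sd = 5, mu0 = 50, a = 20, b = 15,
                                interaction = 0) {
  list(initial = rnorm(n, mu0, sd),
       intA = rnorm(n, mu0 + a, sd),
       intB = rnorm(n, mu0 + b, sd),
       combined = rnorm(n, mu0 + a + b + interaction, sd))
}
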