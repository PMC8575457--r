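#' Define a mutation set
#'
#' The ordered set of amino acid substitutions separating two receptor
#' alleles, e.g. `c("T289S", "Q536K", "F538L")` between the
#' *D. melanogaster* and *D. sechellia* Ir75a alleles. Every subset is one
#' genotype on the 2^n hypercube between the two alleles.
#'
#' @param names Character vector of unique substitution names, n >= 1.
#' @return An object of class `mutation_set` (a character vector).
#' @export
mutation_set <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("need at least one mutation")
  if (anyDuplicated(names)) stop("mutation names must be unique")
  structure(names, class = "mutation_set")
}

#' Canonical genotype label
#'
#' Mutations present in the genotype, in mutation-set order, joined by
#' commas; the empty genotype (initial allele) is labeled `"wt"`.
#'
#' @param bits Logical vector over the mutation set.
#' @param muts A [mutation_set()].
#' @return Character label, e.g. `"T289S,F538L"`.
#' @export
genotype_label <- function(bits, muts) {
  if (!any(bits)) "wt" else paste(unclass(muts)[bits], collapse = ",")
}

#' Enumerate the genotype hypercube
#'
#' All 2^n combinations of n substitutions, from the initial allele (empty
#' set, `"wt"`) to the final allele (full set). Enumeration is refused for
#' n > 20, where the lattice (2^n genotypes) is far beyond what can be
#' phenotyped.
#'
#' @param muts A [mutation_set()].
#' @return An object of class `genotype_set`: list with `muts`, `bits`
#'   (2^n x n logical matrix, columns named by mutation) and `labels`,
#'   rows sorted lexicographically by label.
#' @export
enumerate_genotypes <- function(muts) {
  muts <- mutation_set(muts)
  n <- length(muts)
  if (n > 20L) {
    stop(sprintf("refusing to enumerate 2^%d = %s genotypes; restrict the mutation set",
                 n, format(2^n, digits = 1)))
  }
  bits <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(bits) <- list(NULL, unclass(muts))
  labels <- apply(bits, 1L, genotype_label, muts = muts)
  ord <- order(labels)
  structure(list(muts = muts, bits = bits[ord, , drop = FALSE],
                 labels = labels[ord]),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("Genotype hypercube: %d mutations, %d genotypes\n",
              length(x$muts), length(x$labels)))
  cat(" ", paste(x$labels, collapse = "; "), "\n")
  invisible(x)
}

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Enumerate stepwise mutational paths
#'
#' All n! monotone paths across the hypercube from the initial to the final
#' allele, each step adding exactly one of the n substitutions.
#'
#' @param muts A [mutation_set()] with n <= 8.
#' @return List of n! character vectors, each a chain of n+1 genotype
#'   labels from `"wt"` to the full set.
#' @export
enumerate_paths <- function(muts) {
  muts <- mutation_set(muts)
  n <- length(muts)
  if (n > 8L) stop("refusing to enumerate ", n, "! paths; n must be <= 8")
  idx <- seq_len(n)
  lapply(permutations(idx), function(ord) {
    bits <- rep(FALSE, n)
    chain <- character(n + 1L)
    chain[1L] <- genotype_label(bits, muts)
    for (k in idx) {
      bits[ord[k]] <- TRUE
      chain[k + 1L] <- genotype_label(bits, muts)
    }
    chain
  })
}

#' Test one mutational step for a significant phenotype increase
#'
#' Compares the scalar phenotypes (PC1 projections) of two genotypes one
#' mutation apart with the normality-gated two-sample test and classifies
#' the step: `"solid"` (evolutionarily favored under the
#' increasing-phenotype reading) only when the Bonferroni-corrected p-value
#' is below `alpha` *and* the mean phenotype increases from `a` to `b`;
#' otherwise `"dashed"`.
#'
#' @param a,b Numeric phenotype samples (from- and to-genotype), >= 3
#'   values each.
#' @param alpha Significance level (default 0.05).
#' @param m Bonferroni family size.
#' @return An object of class `step_test`: list with `p_raw`,
#'   `p_corrected`, `test_used`, `direction` (`"increase"`/`"decrease"`),
#'   `classification` (`"solid"`/`"dashed"`) and the two group means.
#' @export
step_test <- function(a, b, alpha = 0.05, m = 1) {
  gt <- gated_two_sample_test(a, b, m = m)
  direction <- if (mean(b) > mean(a)) "increase" else "decrease"
  solid <- gt$p_corrected < alpha && direction == "increase"
  structure(list(p_raw = gt$p_raw, p_corrected = gt$p_corrected,
                 test_used = gt$test_used, direction = direction,
                 classification = if (solid) "solid" else "dashed",
                 mean_a = mean(a), mean_b = mean(b)),
            class = "step_test")
}

#' Bootstrap test of additivity (epistasis) between two mutations
#'
#' Tests whether the phenotype of a combined genotype deviates from the sum
#' of its constituent mutations' individual effects. The per-sensillum
#' "effects" of each constituent are its phenotype values minus the mean
#' phenotype of the initial genotype; `n_boot` random pairs of effects
#' (uniform, with replacement) are summed and re-anchored at the initial
#' mean to form the expected phenotype distribution under additivity. The
#' expected and observed (combined-genotype) distributions are compared
#' with a two-sided Wilcoxon rank-sum test; the mutations are called
#' epistatic when the Bonferroni-corrected p-value is below `alpha`, with
#' the sign of the interaction read off the difference of means (negative
#' when the combined phenotype falls short of the additive expectation).
#'
#' For triple-mutant (single + double) contexts, pass the single as one
#' intermediate and the double as the other; their effects are both taken
#' relative to the initial mean.
#'
#' @param initial Phenotype sample of the initial genotype.
#' @param intA,intB Phenotype samples of the two intermediate genotypes
#'   whose effects are summed.
#' @param combined Phenotype sample of the genotype carrying both.
#' @param n_boot Number of bootstrap sums (default 1000; < 100 draws a
#'   warning).
#' @param seed Optional integer seed for the bootstrap index sampling
#'   (reproducible expected distribution).
#' @param m Bonferroni family size.
#' @param alpha Significance level for the epistasis call (default 0.05).
#' @return An object of class `epistasis_test`: list with
#'   `expected_distribution` (length `n_boot`), `observed`, `p_raw`,
#'   `p_corrected`, `epistatic`, `sign` (`"negative"`/`"positive"`),
#'   `mean_expected`, `mean_observed`.
#' @export
epistasis_test <- function(initial, intA, intB, combined, n_boot = 1000,
                           seed = NULL, m = 1, alpha = 0.05) {
  samples <- list(initial = initial, intA = intA, intB = intB,
                  combined = combined)
  for (nm in names(samples)) {
    if (length(samples[[nm]]) < 3L) {
      stop("sample '", nm, "' needs at least 3 values")
    }
    if (anyNA(samples[[nm]])) stop("sample '", nm, "' contains NA")
  }
  if (n_boot < 100L) {
    warning("n_boot = ", n_boot, " is small; the expected distribution ",
            "will be noisy", call. = FALSE)
  }
  base <- mean(initial)
  effA <- intA - base
  effB <- intB - base
  draw <- function() {
    i <- sample.int(length(effA), n_boot, replace = TRUE)
    j <- sample.int(length(effB), n_boot, replace = TRUE)
    base + effA[i] + effB[j]
  }
  expected <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ht <- suppressWarnings(stats::wilcox.test(expected, combined,
                                            exact = FALSE, correct = TRUE))
  p_corr <- min(1, m * ht$p.value)
  structure(list(expected_distribution = expected, observed = combined,
                 p_raw = ht$p.value, p_corrected = p_corr,
                 epistatic = p_corr < alpha,
                 sign = if (mean(combined) < mean(expected)) "negative" else "positive",
                 mean_expected = mean(expected),
                 mean_observed = mean(combined)),
            class = "epistasis_test")
}

#' @export
print.epistasis_test <- function(x, ...) {
  cat(sprintf("Epistasis bootstrap test: expected %.3g vs observed %.3g, p = %.4g (corrected %.4g)\n",
              x$mean_expected, x$mean_observed, x$p_raw, x$p_corrected))
  cat(if (x$epistatic) sprintf("  %s epistasis detected\n", x$sign)
      else "  no significant deviation from additivity\n")
  invisible(x)
}

# the (single,single) and (single,double) intermediate pairs whose
# combination is tested for epistasis, all relative to the initial allele
epistasis_contexts <- function(gs) {
  bits <- gs$bits
  sizes <- rowSums(bits)
  singles <- which(sizes == 1L)
  doubles <- which(sizes == 2L)
  out <- list()
  for (a in singles) {
    for (b in c(singles, doubles)) {
      if (b <= a && sizes[b] == 1L) next        # unordered single pairs
      if (any(bits[a, ] & bits[b, ])) next      # must be disjoint
      comb <- bits[a, ] | bits[b, ]
      out[[length(out) + 1L]] <- list(
        intA = gs$labels[a], intB = gs$labels[b],
        combined = genotype_label(comb, gs$muts),
        type = if (sizes[b] == 1L) "single-single" else "single-double")
    }
  }
  out
}

#' Full evolutionary-landscape analysis of a genotype panel
#'
#' Runs the whole landscape pipeline on a response panel covering all 2^n
#' genotypes between two alleles: z-scores each sensillum, fits (or reuses)
#' the tuning-space PCA, takes per-sensillum PC1 projections as the scalar
#' phenotype, tests every hypercube edge for a significant phenotype
#' increase ([step_test()]), and runs the bootstrap additivity test
#' ([epistasis_test()]) for every single-with-single and single-with-double
#' combination of mutations. All p-values are Bonferroni-corrected; by
#' default the family is every statistical comparison performed in the run
#' (edges + epistasis contexts), the most conservative reading.
#'
#' @param matrix A [response_matrix()] whose genotype labels cover every
#'   label of `enumerate_genotypes(muts)` with >= 3 complete sensilla each.
#' @param muts A [mutation_set()].
#' @param pca Optional [run_pca()] fit to project onto; fitted on the
#'   z-scored panel itself when `NULL`.
#' @param alpha Significance level (default 0.05).
#' @param n_boot Bootstrap draws per epistasis test (default 1000).
#' @param seed Optional integer seed; per-test child seeds are derived from
#'   it so the run is reproducible.
#' @param family_size Bonferroni family size; `NULL` (default) uses the
#'   total number of tests in the run.
#' @return An object of class `landscape_report`: list with `genotypes`
#'   (label, n, mean PC1, SEM), `steps` (one row per hypercube edge),
#'   `epistasis` (one row per tested combination), `pca`, `family_size`,
#'   and `phenotypes` (named list of per-genotype PC1 samples).
#' @export
run_landscape <- function(matrix, muts, pca = NULL, alpha = 0.05,
                          n_boot = 1000, seed = NULL, family_size = NULL) {
  muts <- mutation_set(muts)
  gs <- enumerate_genotypes(muts)
  gt <- genotypes(matrix)
  absent <- setdiff(gs$labels, unique(gt))
  if (length(absent)) {
    stop("panel lacks genotype(s): ", paste(absent, collapse = ", "))
  }
  z <- zscore_rows(matrix)
  if (is.null(pca)) pca <- run_pca(z)
  phen_all <- project_pc1_rows(z, pca)
  row_gt <- stats::setNames(genotypes(z), rownames(z))
  phen <- split(unname(phen_all), row_gt[names(phen_all)])
  small <- gs$labels[vapply(gs$labels, function(l) {
    is.null(phen[[l]]) || length(phen[[l]]) < 3L
  }, logical(1))]
  if (length(small)) {
    stop("fewer than 3 complete sensilla for genotype(s): ",
         paste(small, collapse = ", "))
  }
  # hypercube edges: add one mutation at a time
  edges <- list()
  for (r in seq_along(gs$labels)) {
    b <- gs$bits[r, ]
    for (k in which(!b)) {
      to <- b; to[k] <- TRUE
      edges[[length(edges) + 1L]] <- list(
        from = gs$labels[r], to = genotype_label(to, gs$muts),
        mutation = unclass(muts)[k])
    }
  }
  contexts <- epistasis_contexts(gs)
  n_tests <- length(edges) + length(contexts)
  m_fam <- if (is.null(family_size)) n_tests else family_size
  step_rows <- lapply(edges, function(e) {
    st <- step_test(phen[[e$from]], phen[[e$to]], alpha = alpha, m = m_fam)
    data.frame(from = e$from, to = e$to, mutation = e$mutation,
               mean_from = st$mean_a, mean_to = st$mean_b,
               test_used = st$test_used, p_raw = st$p_raw,
               p_corrected = st$p_corrected, direction = st$direction,
               classification = st$classification, stringsAsFactors = FALSE)
  })
  epi_rows <- lapply(seq_along(contexts), function(i) {
    cx <- contexts[[i]]
    child <- if (is.null(seed)) NULL else (seed + i) %% 2147483647L
    et <- epistasis_test(phen[["wt"]], phen[[cx$intA]], phen[[cx$intB]],
                         phen[[cx$combined]], n_boot = n_boot, seed = child,
                         m = m_fam, alpha = alpha)
    data.frame(intA = cx$intA, intB = cx$intB, combined = cx$combined,
               type = cx$type, mean_expected = et$mean_expected,
               mean_observed = et$mean_observed, p_raw = et$p_raw,
               p_corrected = et$p_corrected, epistatic = et$epistatic,
               sign = et$sign, stringsAsFactors = FALSE)
  })
  summ <- data.frame(
    label = gs$labels,
    n = vapply(gs$labels, function(l) length(phen[[l]]), integer(1)),
    mean_pc1 = vapply(gs$labels, function(l) mean(phen[[l]]), numeric(1)),
    sem_pc1 = vapply(gs$labels, function(l) {
      stats::sd(phen[[l]]) / sqrt(length(phen[[l]]))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  epi_df <- if (length(epi_rows)) do.call(rbind, epi_rows) else
    data.frame(intA = character(0), intB = character(0),
               combined = character(0), type = character(0),
               mean_expected = numeric(0), mean_observed = numeric(0),
               p_raw = numeric(0), p_corrected = numeric(0),
               epistatic = logical(0), sign = character(0))
  structure(list(genotypes = summ,
                 steps = do.call(rbind, step_rows),
                 epistasis = epi_df,
                 pca = pca, family_size = m_fam, alpha = alpha,
                 phenotypes = phen),
            class = "landscape_report")
}

#' @export
print.landscape_report <- function(x, ...) {
  cat(sprintf("Evolutionary landscape: %d genotypes, %d steps, %d epistasis tests (Bonferroni family %d)\n",
              nrow(x$genotypes), nrow(x$steps), nrow(x$epistasis),
              x$family_size))
  cat("Per-genotype PC1 phenotype:\n")
  print(transform(x$genotypes, mean_pc1 = round(mean_pc1, 3),
                  sem_pc1 = round(sem_pc1, 3)), row.names = FALSE)
  nsolid <- sum(x$steps$classification == "solid")
  cat(sprintf("%d of %d steps significantly increase PC1 (solid)\n",
              nsolid, nrow(x$steps)))
  epi <- x$epistasis[x$epistasis$epistatic, , drop = FALSE]
  if (nrow(epi)) {
    cat("Epistatic combinations:\n")
    for (i in seq_len(nrow(epi))) {
      cat(sprintf("  %s x %s -> %s (%s, corrected p = %.3g)\n",
                  epi$intA[i], epi$intB[i], epi$combined[i], epi$sign[i],
                  epi$p_corrected[i]))
    }
  } else {
    cat("No epistatic combinations detected\n")
  }
  invisible(x)
}

#' Write a landscape report to disk
#'
#' Tidy CSVs of the step and epistasis tables plus a JSON summary.
#'
#' @param report A [run_landscape()] result.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_landscape <- function(report, prefix) {
  if (!inherits(report, "landscape_report")) {
    stop("'report' must be a landscape_report")
  }
  paths <- paste0(prefix, c("_genotypes.csv", "_steps.csv",
                            "_epistasis.csv", "_summary.json"))
  utils::write.csv(report$genotypes, paths[1], row.names = FALSE)
  utils::write.csv(report$steps, paths[2], row.names = FALSE)
  utils::write.csv(report$epistasis, paths[3], row.names = FALSE)
  jsonlite::write_json(
    list(family_size = report$family_size, alpha = report$alpha,
         n_solid_steps = sum(report$steps$classification == "solid"),
         epistatic = report$epistasis[report$epistasis$epistatic,
                                      c("intA", "intB", "combined", "sign")]),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
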