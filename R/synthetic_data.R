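#' Spike-train simulation settings
#'
#' Settings for the inhomogeneous-Poisson spike generator: a constant
#' baseline firing rate over the recorded span, elevated to the evoked rate
#' during the odor pulse, which starts `delivery_delay` seconds after the
#' nominal stimulus onset (the air-path delay) and lasts `pulse_duration`
#' seconds (a 500 ms pulse by default).
#'
#' @param baseline_rate Baseline firing rate (Hz), >= 0.
#' @param evoked_rate Firing rate during the pulse (Hz), >= 0.
#' @param stimulus_onset Nominal stimulus onset (s); default 3 so the
#'   baseline window 2 s before delivery lies within the recording.
#' @param delivery_delay Air-path delay (s); default 0.2.
#' @param pulse_duration Pulse length (s); default 0.5.
#' @param recording_span Recorded span (s); must cover both the baseline
#'   and stimulus analysis windows; default 5.
#' @param seed Optional integer seed.
#' @return An object of class `spike_sim_config`.
#' @export
spike_sim_config <- function(baseline_rate, evoked_rate, stimulus_onset = 3,
                             delivery_delay = 0.2, pulse_duration = 0.5,
                             recording_span = 5, seed = NULL) {
  if (baseline_rate < 0 || evoked_rate < 0) stop("rates must be >= 0")
  if (pulse_duration <= 0) stop("'pulse_duration' must be > 0")
  delivery <- stimulus_onset + delivery_delay
  if (delivery - 2 < 0 || delivery + pulse_duration > recording_span) {
    stop("recording span must cover the baseline window (2 s before ",
         "delivery) and the stimulus window")
  }
  structure(list(baseline_rate = baseline_rate, evoked_rate = evoked_rate,
                 stimulus_onset = stimulus_onset,
                 delivery_delay = delivery_delay,
                 pulse_duration = pulse_duration,
                 recording_span = recording_span, seed = seed),
            class = "spike_sim_config")
}

#' Simulate a spike train
#'
#' Draws one trial from an inhomogeneous Poisson process whose rate equals
#' the baseline rate everywhere in `[0, recording_span]` except during the
#' odor pulse, where it equals the evoked rate. Reproducible under
#' `cfg$seed`.
#'
#' @param cfg A [spike_sim_config()].
#' @return A [spike_train()] carrying the stimulus timing of `cfg`.
#' @export
simulate_spike_train <- function(cfg) {
  if (!inherits(cfg, "spike_sim_config")) {
    stop("'cfg' must be a spike_sim_config")
  }
  t1 <- cfg$stimulus_onset + cfg$delivery_delay
  t2 <- t1 + cfg$pulse_duration
  draw <- function() {
    segs <- rbind(c(0, t1, cfg$baseline_rate),
                  c(t1, t2, cfg$evoked_rate),
                  c(t2, cfg$recording_span, cfg$baseline_rate))
    times <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      len <- segs[i, 2] - segs[i, 1]
      if (len <= 0) return(numeric(0))
      n <- stats::rpois(1L, segs[i, 3] * len)
      segs[i, 1] + sort(stats::runif(n, 0, len))
    }))
    sort(times)
  }
  times <- if (is.null(cfg$seed)) draw() else withr::with_seed(cfg$seed, draw())
  spike_train(times, stimulus_onset = cfg$stimulus_onset,
              delivery_delay = cfg$delivery_delay, window = 0.5,
              baseline_offset = 2, span = cfg$recording_span)
}

#' Genotype response-panel simulation settings
#'
#' Settings for the panel generator used to test the landscape analysis
#' with known ground truth. Each sensillum of genotype g responds to odor o
#' with
#' `baseline(o) + sum of effects of mutations in g + sum of interaction
#' terms of mutation pairs in g + Gaussian noise`.
#' Noise is Gaussian rather than Poisson because panel entries model
#' solvent-corrected differences of counts, which are approximately normal;
#' count-level realism lives in [simulate_spike_train()].
#'
#' @param baseline Named numeric vector: response of the initial genotype
#'   to each odor (spikes/s).
#' @param effects Named list: mutation name -> named numeric per-odor
#'   additive shift (spikes/s). Odors absent from an effect vector shift
#'   by 0.
#' @param interactions Optional named list: `"A:B"` -> named numeric
#'   per-odor pairwise interaction term, applied when both A and B are
#'   present.
#' @param noise_sd Gaussian noise SD (spikes/s), >= 0; default 5.
#' @param n_sensilla Sensilla recorded per genotype, >= 3; default 10.
#' @param missing_rate Fraction of cells masked missing, in `[0, 1)`;
#'   default 0.
#' @param seed Optional integer seed; per-genotype child seeds are derived
#'   from it so each genotype's block is reproducible in isolation.
#' @return An object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(baseline, effects, interactions = NULL,
                             noise_sd = 5, n_sensilla = 10,
                             missing_rate = 0, seed = NULL) {
  if (is.null(names(baseline))) stop("'baseline' must be named by odor")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_sensilla < 3L) stop("'n_sensilla' must be >= 3")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must be in [0, 1)")
  }
  for (e in effects) {
    if (is.null(names(e))) stop("each effect vector must be named by odor")
  }
  if (!is.null(interactions)) {
    bad <- !grepl(":", names(interactions), fixed = TRUE)
    if (any(bad)) stop("interaction names must be of the form 'A:B'")
  }
  structure(list(baseline = baseline, effects = effects,
                 interactions = interactions, noise_sd = noise_sd,
                 n_sensilla = as.integer(n_sensilla),
                 missing_rate = missing_rate, seed = seed),
            class = "panel_sim_config")
}

# deterministic fan-out of one global seed into per-component child seeds
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}

odor_shift <- function(shifts, odors) {
  out <- stats::setNames(rep(0, length(odors)), odors)
  if (!is.null(shifts)) {
    known <- intersect(names(shifts), odors)
    out[known] <- shifts[known]
  }
  out
}

#' Simulate a genotype response panel
#'
#' Generates a [response_matrix()] over all 2^n genotypes of a mutation
#' set, with programmed additive mutation effects, pairwise interaction
#' terms, Gaussian sensillum noise, and an optional missing-cell mask.
#'
#' @param cfg A [panel_sim_config()].
#' @param muts A [mutation_set()]; effect and interaction names must refer
#'   to its mutations.
#' @return List with `matrix` (the simulated `response_matrix`) and
#'   `truth` (per-genotype noise-free mean responses plus the config).
#' @export
simulate_panel <- function(cfg, muts) {
  if (!inherits(cfg, "panel_sim_config")) stop("'cfg' must be a panel_sim_config")
  muts <- mutation_set(muts)
  unknown <- setdiff(names(cfg$effects), unclass(muts))
  if (length(unknown)) {
    stop("effect(s) for unknown mutation(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$interactions)) {
    pairs <- strsplit(names(cfg$interactions), ":", fixed = TRUE)
    for (p in pairs) {
      if (length(p) != 2L || !all(p %in% unclass(muts))) {
        stop("interaction '", paste(p, collapse = ":"),
             "' does not name two mutations of the set")
      }
    }
  }
  odors <- names(cfg$baseline)
  gs <- enumerate_genotypes(muts)
  mu <- list()
  blocks <- vector("list", length(gs$labels))
  for (r in seq_along(gs$labels)) {
    present <- unclass(muts)[gs$bits[r, ]]
    m_g <- cfg$baseline
    for (mname in present) {
      m_g <- m_g + odor_shift(cfg$effects[[mname]], odors)
    }
    if (!is.null(cfg$interactions) && length(present) >= 2L) {
      for (iname in names(cfg$interactions)) {
        p <- strsplit(iname, ":", fixed = TRUE)[[1L]]
        if (all(p %in% present)) {
          m_g <- m_g + odor_shift(cfg$interactions[[iname]], odors)
        }
      }
    }
    mu[[gs$labels[r]]] <- m_g
    gen <- function() {
      vals <- matrix(stats::rnorm(cfg$n_sensilla * length(odors),
                                  mean = rep(m_g, each = cfg$n_sensilla),
                                  sd = cfg$noise_sd),
                     nrow = cfg$n_sensilla, dimnames = list(NULL, odors))
      if (cfg$missing_rate > 0) {
        mask <- matrix(stats::runif(length(vals)) < cfg$missing_rate,
                       nrow = nrow(vals))
        vals[mask] <- NA_real_
      }
      vals
    }
    cs <- child_seed(cfg$seed, r)
    blocks[[r]] <- if (is.null(cs)) gen() else withr::with_seed(cs, gen())
  }
  vals <- do.call(rbind, blocks)
  mat <- response_matrix(vals,
                         genotype = rep(gs$labels, each = cfg$n_sensilla))
  list(matrix = mat, truth = list(mean_response = mu, config = cfg))
}

#' The drosophilid phenotype fixture tree
#'
#' The standard 10-species drosophilid topology used throughout:
#' melanogaster subgroup (*D. melanogaster*, *D. simulans*,
#' *D. sechellia*, *D. yakuba*, *D. erecta*) plus *D. ananassae*, the
#' obscura-group *D. pseudoobscura*, *D. willistoni*, and the Drosophila
#' subgenus (*D. mojavensis*, *D. virilis*), with each tip labeled by its
#' ac2 (Ir75a neuron) tuning phenotype: maximal response to acetic acid
#' (`C2`) or butyric acid (`C4`). *D. sechellia* is the lone C4 sensor
#' inside the melanogaster/obscura clade; the distant species are all C4.
#'
#' @return List of class `pheno_tree` with `tree` (an [ape::phylo]) and
#'   `tip_states` (named character vector).
#' @export
fixture_tree <- function() {
  nwk <- "((((((Dmel,(Dsim,Dsec)),(Dyak,Dere)),Dana),Dpse),Dwil),(Dmoj,Dvir));"
  tree <- ape::read.tree(text = nwk)
  states <- c(Dmel = "C2", Dsim = "C2", Dsec = "C4", Dyak = "C2",
              Dere = "C2", Dana = "C2", Dpse = "C2", Dwil = "C4",
              Dmoj = "C4", Dvir = "C4")
  structure(list(tree = tree, tip_states = states), class = "pheno_tree")
}

#' @export
print.pheno_tree <- function(x, ...) {
  cat("Phenotype-labeled tree:", length(x$tree$tip.label), "tips\n")
  cat(" ", paste(names(x$tip_states), x$tip_states, sep = "=",
                 collapse = ", "), "\n")
  invisible(x)
}

#' Write simulated spike times as CSV
#'
#' Two-column CSV (trial, spike time in seconds), the interchange format
#' the quantification stage reads.
#'
#' @param trains List of [spike_train()] objects (one per trial).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(seq_along(trains), function(i) {
    data.frame(trial = i, time = trains[[i]]$spike_times)
  }))
  if (is.null(df)) df <- data.frame(trial = integer(0), time = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike times from CSV
#'
#' @param path Two-column CSV (trial, time).
#' @param stimulus_onset,delivery_delay,window,baseline_offset,span Timing
#'   passed to [spike_train()] for every trial.
#' @return Named list of [spike_train()] objects, one per trial.
#' @export
read_spike_csv <- function(path, stimulus_onset, delivery_delay = 0.2,
                           window = 0.5, baseline_offset = 2, span = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("spike CSV must have columns (trial, time)")
  lapply(split(df[[2L]], df[[1L]]), function(tms) {
    spike_train(sort(tms), stimulus_onset = stimulus_onset,
                delivery_delay = delivery_delay, window = window,
                baseline_offset = baseline_offset, span = span)
  })
}
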