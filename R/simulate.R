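#' Configuration for the generative ChIP-seq simulator
#'
#' The simulator emulates a multi-assay histone-modification experiment on a
#' single synthetic chromosome. A Markov chain lays out background and peak
#' states with fixed run lengths (background 1000 bp; narrow 450 bp; broad
#' 1200 bp; randomly-placed 750 bp). Latent per-bin tracks are drawn for
#' accessibility `a` and non-specific signal `n` (unit-median log-AR(1)
#' processes), mappability `m` (i.i.d. Beta rescaled into (0.5, 1]), and a
#' mark-specific enrichment `s_h` that is positive only inside that mark's
#' peaks (flat-top amplitude profile with 1-bin linear shoulders). Expected
#' bin counts are `D * a * m * n` for a control replicate and
#' `D * a * m * (k * s_h + n)` for a treatment replicate, where `D` is a
#' per-sample depth factor and `k` the antibody specificity; observed counts
#' are Poisson (optionally negative-binomial or noiseless) draws around the
#' expectation.
#'
#' @param genome_length simulated chromosome length in bp.
#' @param bin_width bin width in bp.
#' @param state_lengths named lengths (bp) of the `background`, `narrow`,
#'   `broad` and `random` states.
#' @param transition named probabilities of moving from background into each
#'   state (must sum to 1); every peak state returns to background.
#' @param marks data.frame with columns `name`, `type` (one of
#'   `narrow`/`broad`/`random`), `replicates`, `amplitude` (mean enrichment
#'   over background).
#' @param control_replicates number of input-control replicates.
#' @param depth mean per-bin control coverage (scales all depth factors).
#' @param sd_log_depth log-sd of per-sample depth factors.
#' @param k_range range of per-sample antibody specificities `k`.
#' @param sigma_a,rho_a log-sd and lag-1 autocorrelation of accessibility.
#' @param sigma_n,rho_n log-sd and lag-1 autocorrelation of the non-specific
#'   signal.
#' @param m_noise mappability noise amplitude in `[0, 1]`; 0 gives `m = 1`
#'   everywhere, 1 gives the full (0.5, 1] range.
#' @param m_beta two Beta shape parameters for mappability.
#' @param amp_sd_log log-sd of per-peak amplitudes.
#' @param noise `"poisson"`, `"nb"` or `"none"`.
#' @param nb_size negative-binomial size (overdispersion) when `noise="nb"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6, bin_width = 200,
                       state_lengths = c(background = 1000, narrow = 450,
                                         broad = 1200, random = 750),
                       transition = c(background = 1/2, narrow = 1/6,
                                      broad = 1/6, random = 1/6),
                       marks = data.frame(
                         name = c("narrow_mark", "broad_mark", "random_mark"),
                         type = c("narrow", "broad", "random"),
                         replicates = 3L,
                         amplitude = c(6, 3, 4)),
                       control_replicates = 2L,
                       depth = 20, sd_log_depth = 0.15,
                       k_range = c(0.6, 0.95),
                       sigma_a = 0.25, rho_a = 0.8,
                       sigma_n = 0.25, rho_n = 0.8,
                       m_noise = 1, m_beta = c(2, 2),
                       amp_sd_log = 0.25,
                       noise = c("poisson", "nb", "none"), nb_size = 10) {
  noise <- match.arg(noise)
  stopifnot(all(state_lengths > 0), genome_length > 0, bin_width > 0,
            abs(sum(transition) - 1) < 1e-8, all(transition >= 0),
            all(marks$type %in% c("narrow", "broad", "random")),
            control_replicates >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Lay out the synthetic genome as a Markov chain of states
#'
#' Starting from background, each step either stays in background or enters a
#' peak state (with the configured probabilities); every peak state returns
#' to background, so background always separates consecutive peaks. Each
#' emitted run occupies exactly its configured state length; the final run is
#' truncated at the genome end and adjacent background runs are merged.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return `GRanges` on chromosome `chrSim` with a `state` metadata column.
#' @export
layout_genome <- function(config, seed = NULL) {
  sl <- config$state_lengths
  peak_states <- names(config$transition)[names(config$transition) != "background"]
  active <- peak_states[config$transition[peak_states] > 0]
  if (length(active) && config$genome_length < sl["background"] + max(sl[active]))
    stop("genome too short for one background+peak cycle")
  with_seed(seed, {
    states <- character(0)
    total <- 0
    state <- "background"
    while (total < config$genome_length) {
      states <- c(states, state)
      total <- total + sl[[state]]
      state <- if (state != "background") "background"
               else sample(names(config$transition), 1L,
                           prob = config$transition)
    }
    lens <- unname(sl[states])
    lens[length(lens)] <- config$genome_length - sum(head(lens, -1))
    # a peak only exists at its full configured length; a truncated final
    # peak becomes background so every emitted peak run is length-exact
    last <- length(states)
    if (states[last] != "background" && lens[last] != sl[[states[last]]])
      states[last] <- "background"
    # merge consecutive background runs into single intervals
    r <- rle(states)
    grp <- rep(seq_along(r$lengths), r$lengths)
    lens2 <- as.numeric(tapply(lens, grp, sum))
    ends <- cumsum(lens2)
    GRanges("chrSim", IRanges(start = c(1, head(ends, -1) + 1), end = ends),
            state = r$values,
            seqlengths = c(chrSim = as.integer(config$genome_length)))
  })
}

# per-bin flat-top profile with 1-bin linear shoulders for one peak's bins
.peak_profile <- function(w) {
  p <- rep(1, w)
  if (w >= 3) p[c(1, w)] <- 0.5
  p
}

# stationary AR(1) series: z1 ~ N(0,1), z_t = rho z_{t-1} + sqrt(1-rho^2) e_t
.ar1 <- function(n, rho) {
  e <- rnorm(n)
  if (rho == 0) return(e)
  z <- numeric(n)
  z[1] <- e[1]
  s <- sqrt(1 - rho^2)
  for (t in 2:n) z[t] <- rho * z[t - 1] + s * e[t]
  z
}

#' Draw the latent ground-truth tracks and sample factors
#'
#' @param layout state track from [layout_genome()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return A `sim_truth` list with bins, per-bin `a`, `m`, `n`, the `s`
#'   matrix (one column per mark), per-sample depth factors `D` and
#'   specificities `k`, the state layout, and the sample metadata sheet.
#' @export
draw_latents <- function(layout, config, seed = NULL) {
  glen <- config$genome_length
  bins <- genome_bins(c(chrSim = as.integer(glen)), config$bin_width)
  G <- length(bins)
  with_seed(seed, {
    a <- exp(config$sigma_a * .ar1(G, config$rho_a))
    n <- exp(config$sigma_n * .ar1(G, config$rho_n))
    m <- 1 - 0.5 * config$m_noise * rbeta(G, config$m_beta[1], config$m_beta[2])

    s <- matrix(0, G, nrow(config$marks),
                dimnames = list(NULL, config$marks$name))
    for (j in seq_len(nrow(config$marks))) {
      runs <- layout[layout$state == config$marks$type[j]]
      if (length(runs)) {
        ov <- GenomicRanges::findOverlaps(runs, bins)
        for (p in seq_along(runs)) {
          b <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == p]
          amp <- exp(log(config$marks$amplitude[j]) +
                       config$amp_sd_log * rnorm(1))
          s[b, j] <- pmax(s[b, j], amp * .peak_profile(length(b)))
        }
      }
    }

    sheet <- .sim_sample_sheet(config)
    D <- config$depth * exp(config$sd_log_depth * rnorm(nrow(sheet)))
    k <- ifelse(sheet$is_control, NA_real_,
                runif(nrow(sheet), config$k_range[1], config$k_range[2]))
    structure(list(bins = bins, a = a, m = m, n = n, s = s,
                   D = D, k = k, layout = layout, sheet = sheet),
              class = "sim_truth")
  })
}

.sim_sample_sheet <- function(config) {
  rows <- data.frame(
    filepath = sprintf("control_rep%d.bedGraph", seq_len(config$control_replicates)),
    condition = "control", is_control = TRUE,
    replicate = seq_len(config$control_replicates))
  for (j in seq_len(nrow(config$marks))) {
    r <- config$marks$replicates[j]
    rows <- rbind(rows, data.frame(
      filepath = sprintf("%s_rep%d.bedGraph", config$marks$name[j], seq_len(r)),
      condition = config$marks$name[j], is_control = FALSE,
      replicate = seq_len(r)))
  }
  structure(rows, conditions = c("control", config$marks$name),
            class = c("sample_sheet", "data.frame"))
}

#' Emit observed per-bin counts for every sample
#'
#' The expected value of each bin is exactly the generative model (control:
#' `D a m n`; treatment: `D a m (k s + n)`); the observation is a Poisson,
#' negative-binomial or noiseless draw around it.
#'
#' @param truth a [draw_latents()] result.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return A [binned_tracks()] object with the expected-value matrix attached
#'   as attribute `expected`.
#' @export
emit_counts <- function(truth, config, seed = NULL) {
  sheet <- truth$sheet
  G <- length(truth$bins)
  base <- truth$a * truth$m
  E <- matrix(0, G, nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    E[, i] <- if (sheet$is_control[i]) truth$D[i] * base * truth$n
              else truth$D[i] * base *
                   (truth$k[i] * truth$s[, sheet$condition[i]] + truth$n)
  }
  obs <- with_seed(seed, switch(config$noise,
    poisson = matrix(rpois(length(E), E), G),
    nb = matrix(rnbinom(length(E), mu = E, size = config$nb_size), G),
    none = E))
  out <- binned_tracks(truth$bins, obs, sheet)
  attr(out, "expected") <- E
  out
}

#' Simulate a complete multi-assay ChIP-seq experiment
#'
#' Runs [layout_genome()], [draw_latents()] and [emit_counts()] under a
#' single seed; the same seed reproduces the output exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A `chip_sim` list: `tracks` ([binned_tracks()]), `truth`
#'   ([draw_latents()] result), `config`, `seed`.
#' @examples
#' sim <- simulate_experiment(sim_config(genome_length = 5e4), seed = 1)
#' sim$tracks
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1L) {
  layout <- layout_genome(config, derive_seed(seed, 1L))
  truth <- draw_latents(layout, config, derive_seed(seed, 2L))
  tracks <- emit_counts(truth, config, derive_seed(seed, 3L))
  structure(list(tracks = tracks, truth = truth, config = config, seed = seed),
            class = "chip_sim")
}

#' @export
print.chip_sim <- function(x, ...) {
  cat(sprintf("chip_sim: %g bp genome, %d bins, %d samples (seed %s)\n",
              x$config$genome_length, length(x$truth$bins),
              ncol(x$tracks$values), format(x$seed)))
  invisible(x)
}

#' Ground-truth peak regions of one simulated mark
#'
#' @param truth a `sim_truth` object.
#' @param mark mark name (column of `truth$s`).
#' @return `GRanges` of merged bins where the true enrichment is positive.
#' @export
truth_peaks <- function(truth, mark) {
  GenomicRanges::reduce(truth$bins[truth$s[, mark] > 0])
}

#' Write a simulated experiment to disk
#'
#' Writes one bedGraph per sample, one bedGraph per latent truth track
#' (`a`, `m`, `n`, and each `s_h`), a truth-peak BED per mark, and a JSON
#' manifest with depth factors, specificities, seed and the configuration.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$tracks
  files <- character(0)
  for (i in seq_len(ncol(tr$values))) {
    f <- file.path(dir, tr$samples$filepath[i])
    write_bedgraph(tr$bins, tr$values[, i], f)
    files <- c(files, f)
  }
  for (nm in c("a", "m", "n")) {
    f <- file.path(dir, sprintf("truth_%s.bedGraph", nm))
    write_bedgraph(tr$bins, sim$truth[[nm]], f)
    files <- c(files, f)
  }
  for (mark in colnames(sim$truth$s)) {
    f <- file.path(dir, sprintf("truth_s_%s.bedGraph", mark))
    write_bedgraph(tr$bins, sim$truth$s[, mark], f)
    fb <- file.path(dir, sprintf("truth_peaks_%s.bed", mark))
    pk <- truth_peaks(sim$truth, mark)
    .write_bed3(pk, fb)
    files <- c(files, f, fb)
  }
  man <- file.path(dir, "simulation.json")
  cfg <- unclass(sim$config)
  cfg$marks <- as.list(cfg$marks)
  jsonlite::write_json(
    list(seed = sim$seed, D = sim$truth$D, k = sim$truth$k,
         samples = sim$truth$sheet, config = cfg),
    man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, man))
}

.write_bed3 <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
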