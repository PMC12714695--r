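#' Write binned tracks to disk
#'
#' The container is a plain TSV (`<prefix>.tsv`: `chrom`, `start`, `end`,
#' then one column per sample, 0-based half-open coordinates) with a JSON
#' sidecar (`<prefix>.json`) holding the sample metadata, condition order,
#' chromosome lengths and fragment lengths.
#'
#' @param tracks a [binned_tracks()] object.
#' @param prefix output path prefix.
#' @return Character vector of the two files written, invisibly.
#' @export
write_binned_tracks <- function(tracks, prefix) {
  df <- data.frame(chrom = as.character(seqnames(tracks$bins)),
                   start = start(tracks$bins) - 1L,
                   end = end(tracks$bins))
  vals <- as.data.frame(tracks$values)
  names(vals) <- colnames(tracks$values)
  tsv <- paste0(prefix, ".tsv")
  write.table(cbind(df, signif(vals, 10)), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(samples = tracks$samples, conditions = tracks$conditions,
         fragment_lengths = as.list(tracks$fragment_lengths),
         seqlengths = as.list(seqlengths(tracks$bins))),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, side))
}

#' Read binned tracks written by [write_binned_tracks()]
#'
#' @param prefix the path prefix used when writing.
#' @return A [binned_tracks()] object.
#' @export
read_binned_tracks <- function(prefix) {
  tab <- read.csv(paste0(prefix, ".tsv"), sep = "\t", check.names = FALSE)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  sl <- unlist(side$seqlengths)
  bins <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end),
                  seqlengths = sl[unique(tab$chrom)])
  samples <- as.data.frame(side$samples)
  attr(samples, "conditions") <- side$conditions
  class(samples) <- c("sample_sheet", "data.frame")
  fl <- unlist(side$fragment_lengths)
  binned_tracks(bins, as.matrix(tab[, -(1:3), drop = FALSE]), samples,
                if (length(fl)) fl else NULL)
}

#' Read / write a pipeline run configuration
#'
#' The configuration is a single YAML file that round-trips losslessly; its
#' defaults equal the method's stated values (200-bp bins, 25-million-read
#' library target, L2 weights 0.01/0.001, 98th-percentile rescaling, 0.1
#' divisor floor, training-bin presets).
#'
#' @param path YAML file path.
#' @return For `read_run_config`, the configuration list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config configuration list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.stage_record <- function(name, t0, files) {
  files <- files[file.exists(files)]
  list(stage = name, wall_seconds = round(as.numeric(Sys.time()) - t0, 3),
       files = as.list(stats::setNames(unname(md5sum(files)), basename(files))))
}

#' Run the full pipeline: simulate/preprocess, deconvolve, de-bias, call peaks
#'
#' Executes the stages in order and records each stage's outputs with MD5
#' hashes, wall time and a configuration echo in `manifest.json` under
#' `outdir`. A re-run with the same seed reproduces the hashes. On a stage
#' failure the manifest records the partial progress before the error is
#' re-raised.
#'
#' The configuration list (or YAML file) may contain: `simulate` (a list of
#' [sim_config()] arguments; presence switches to simulation input),
#' `sample_sheet` (CSV path), `no_control`, `bin_width` (default 200),
#' `blacklist` (BED path), `deconvolve` (arguments to [chipdeconv()]), and
#' `peaks` (arguments to [call_regions()]).
#'
#' @param config configuration list or YAML path.
#' @param outdir output directory.
#' @param seed integer seed for the whole run.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir, seed = 1L) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config = config, stages = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  on.exit(flush_manifest())

  if (!is.null(config$simulate)) {
    t0 <- as.numeric(Sys.time())
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    sim <- simulate_experiment(do.call(sim_config, sim_args), seed)
    files <- write_simulation(sim, file.path(outdir, "simulation"))
    tracks <- sim$tracks
    manifest$stages <- c(manifest$stages,
                         list(.stage_record("simulate", t0, files)))
  } else {
    t0 <- as.numeric(Sys.time())
    if (is.null(config$sample_sheet))
      stop("config must provide either a 'simulate' section or a ",
           "'sample_sheet' path")
    sheet <- parse_sample_sheet(config$sample_sheet,
                                no_control = isTRUE(config$no_control))
    blacklist <- if (!is.null(config$blacklist))
      rtracklayer::import.bed(config$blacklist)
    tracks <- preprocess_samples(sheet,
                                 seqlengths = unlist(config$seqlengths),
                                 bin_width = config$bin_width %||% 200,
                                 blacklist = blacklist)
    files <- write_binned_tracks(tracks, file.path(outdir, "binned"))
    manifest$stages <- c(manifest$stages,
                         list(.stage_record("preprocess", t0, files)))
  }

  t0 <- as.numeric(Sys.time())
  fit <- do.call(chipdeconv,
                 c(list(tracks = tracks, seed = derive_seed(seed, 21L)),
                   config$deconvolve))
  files <- character(0)
  for (j in seq_len(ncol(fit$W))) {
    f <- file.path(outdir, sprintf("signal_%s.bedGraph", colnames(fit$W)[j]))
    write_bedgraph(fit$bins, fit$W[, j], f)
    files <- c(files, f)
  }
  kcsv <- file.path(outdir, "mixing_matrix.csv")
  write.csv(as.data.frame(fit$K), kcsv, row.names = TRUE)
  runlog <- file.path(outdir, "deconvolution.json")
  jsonlite::write_json(
    list(seed = seed, config = fit$config, loss = fit$loss,
         hsr = lapply(fit$hsr, function(h)
           h[c("intercept", "slope", "n_fit", "floor")]),
         rescale_q = attr(fit, "rescale_q")),
    runlog, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  files <- c(files, kcsv, runlog)
  manifest$stages <- c(manifest$stages,
                       list(.stage_record("deconvolve", t0, files)))

  t0 <- as.numeric(Sys.time())
  files <- character(0)
  for (mark in colnames(fit$s_hat)) {
    f <- file.path(outdir, sprintf("foldchange_%s.bedGraph", mark))
    write_bedgraph(fit$bins, fit$s_hat[, mark], f)
    files <- c(files, f)
  }
  manifest$stages <- c(manifest$stages,
                       list(.stage_record("denoise", t0, files)))

  t0 <- as.numeric(Sys.time())
  files <- character(0)
  for (mark in colnames(fit$s_hat)) {
    regions <- do.call(call_regions,
                       c(list(s_hat = fit$s_hat[, mark], bins = fit$bins,
                              name = mark), config$peaks))
    f <- file.path(outdir, sprintf("peaks_%s.bed", mark))
    write_regions(regions, f)
    files <- c(files, f, paste0(f, ".tsv"))
  }
  manifest$stages <- c(manifest$stages,
                       list(.stage_record("call_peaks", t0, files)))

  diagcsv <- file.path(outdir, "mixing_diagnostics.csv")
  write.csv(diagnose_mixing(fit), diagcsv, row.names = FALSE)
  manifest$stages <- c(manifest$stages,
                       list(.stage_record("diagnose", as.numeric(Sys.time()),
                                          diagcsv)))
  flush_manifest()
  on.exit()
  manifest$fit <- NULL
  invisible(structure(manifest, fit = fit))
}
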