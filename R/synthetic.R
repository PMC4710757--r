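# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Noise specification for synthetic traces
#'
#' @param snr_db target signal-to-noise ratio in decibels (finite)
#' @param seed integer random seed; identical specifications yield
#'   bit-identical noisy traces
#' @return an object of class `"noise_spec"`
#' @export
noise_spec <- function(snr_db, seed) {
  stopifnot(is.numeric(snr_db), length(snr_db) == 1L, is.finite(snr_db),
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(snr_db = snr_db, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a ground-truth synthetic trace
#'
#' Simulates the model at its base (Courtemanche) parameter values. The
#' generating parameters are recorded in the trace metadata for later
#' accuracy assessment, but the estimation pipeline never reads them: the
#' optimizers see only the trace itself.
#'
#' @param model a [current_model()]
#' @param protocol a [clamp_protocol()]
#' @return a synthetic [current_trace()]
#' @export
generate_ground_truth <- function(model, protocol = standard_protocol()) {
  tr <- simulate_current(model, model$base, protocol)
  tr$meta$ground_truth_params <- model$base
  tr
}

#' Corrupt a trace with additive Gaussian white noise at a prescribed SNR
#'
#' The noise variance is `sigma^2 = P_signal / 10^(snr_db/10)`, where
#' `P_signal` is the mean squared current pooled over all samples of all
#' sweeps (one SNR figure per dataset). Noise samples are i.i.d. zero-mean
#' Gaussian, white in time and across sweeps.
#'
#' @param trace a [current_trace()]
#' @param spec a [noise_spec()]
#' @return a noisy copy of `trace` with the noise metadata recorded
#' @export
add_noise <- function(trace, spec) {
  stopifnot(inherits(trace, "current_trace"), inherits(spec, "noise_spec"))
  p_signal <- mean(trace$current^2)
  if (p_signal == 0) {
    stop("SNR is undefined for an all-zero trace")
  }
  sigma2 <- p_signal / 10^(spec$snr_db / 10)
  noisy <- trace
  noisy$current <- trace$current +
    with_seed(spec$seed,
              matrix(stats::rnorm(length(trace$current), sd = sqrt(sigma2)),
                     nrow = nrow(trace$current)))
  noisy$meta$noise <- list(snr_db = spec$snr_db, seed = spec$seed,
                           sigma2 = sigma2, p_signal = p_signal)
  noisy
}

#' Sum of squared differences between two traces on one grid
#'
#' Used both as the noise-energy lower bound for the cost on noisy data (the
#' energy of the injected noise) and as the error metric against the clean
#' ground truth.
#'
#' @param noisy,clean two [current_trace()] objects on the same sample grid
#' @return sum of squared sample-wise differences in (pA/pF)^2
#' @export
ground_truth_sse <- function(noisy, clean) {
  check_same_grid(noisy, clean)
  sum((noisy$current - clean$current)^2)
}

#' Write a set of clean + noisy synthetic fixtures
#'
#' Emits one clean CSV trace plus one noisy copy per SNR level (default 10,
#' 20, 35, 60 dB -- one copy per level) and a JSON manifest recording model,
#' seed, SNR and realized noise variance for each file.
#'
#' @param model a [current_model()]
#' @param dir output directory (created if needed)
#' @param snr_db SNR levels in dB
#' @param seed master seed; noisy copy k uses `seed + k`
#' @param protocol clamp protocol to simulate
#' @return invisibly, the manifest as a list
#' @export
make_noise_fixtures <- function(model, dir, snr_db = c(10, 20, 35, 60),
                                seed = 1L, protocol = standard_protocol()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clean <- generate_ground_truth(model, protocol)
  clean_path <- file.path(dir, sprintf("%s_clean.csv", model$current_id))
  write_trace_csv(clean, clean_path)
  entries <- list(list(file = basename(clean_path), snr_db = NA,
                       seed = NA, sigma2 = 0))
  for (k in seq_along(snr_db)) {
    spec <- noise_spec(snr_db[k], seed + k)
    noisy <- add_noise(clean, spec)
    path <- file.path(dir, sprintf("%s_snr%02d.csv", model$current_id,
                                   round(snr_db[k])))
    write_trace_csv(noisy, path)
    entries[[k + 1L]] <- list(file = basename(path), snr_db = snr_db[k],
                              seed = spec$seed,
                              sigma2 = noisy$meta$noise$sigma2)
  }
  manifest <- list(model = model$current_id, master_seed = seed,
                   files = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
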