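#' Configuration of a full simulation experiment
#'
#' Bundles every stage (substrate, sequences, random walk, perfusion,
#' encoding scheme) with a global seed and a replicate count.  All
#' stage seeds are derived deterministically from the global seed, so the
#' same configuration reproduces identical results.
#'
#' @param substrate Named list of substrate parameters: `n_cells`,
#'   `mean_diameter`, `jitter`, `ecv` (target ECV fraction or `NULL` for
#'   the raw packing), `Lz`, `icd_depth`, `ha_rate`, `half_shift`, `voxel`.
#' @param sequences Named list of [sequence_spec()]s (default all three).
#' @param walk A [walk_config()].
#' @param perfusion A [perfusion_config()], or `NULL` to simulate
#'   diffusion only.
#' @param scheme An [encoding_scheme()].
#' @param replicates Number of replicate simulations (protocol default 6).
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(substrate = list(),
                       sequences = list(STEAM = sequence_spec("STEAM"),
                                        PGSE = sequence_spec("PGSE"),
                                        MCSE = sequence_spec("MCSE")),
                       walk = walk_config(),
                       perfusion = NULL,
                       scheme = encoding_scheme(),
                       replicates = 6, seed = 1L) {
  sub_def <- list(n_cells = 100, mean_diameter = 18, jitter = 0.3,
                  ecv = 0.2469, Lz = 127, icd_depth = 2, ha_rate = 10,
                  half_shift = TRUE, voxel = c(2800, 2800, 8000))
  sub_def[names(substrate)] <- substrate
  structure(list(substrate = sub_def, sequences = sequences, walk = walk,
                 perfusion = perfusion, scheme = scheme,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "run_config")
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483629)
}

build_substrate_from_config <- function(sc, seed) {
  cs <- generate_cross_sections(sc$n_cells, sc$mean_diameter, sc$jitter,
                                seed = seed)
  if (!is.null(sc$ecv)) cs <- morph_ecv(cs, sc$ecv)
  build_substrate(tissue_block(cs, Lz = sc$Lz, icd_depth = sc$icd_depth),
                  voxel = sc$voxel, ha_rate = sc$ha_rate,
                  half_shift = sc$half_shift)
}

#' Run a complete simulation experiment
#'
#' Builds the substrate, runs the diffusion random walk for every sequence
#' and replicate, optionally runs the perfusion model and mixes the signals
#' with the configured perfusion fraction, fits a tensor per sequence and
#' replicate, and aggregates replicate means with normal-theory 95%
#' confidence intervals.
#'
#' @param config A [run_config()].
#' @return A list of class `myowalk_experiment` with elements `signals`
#'   (all per-replicate measurements), `tensors` (per-replicate scalar
#'   metrics), `summary` (replicate mean and 95% CI per metric), and
#'   `provenance` (seeds and configuration fingerprint).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  s <- build_substrate_from_config(config$substrate,
                                   derive_seed(config$seed, 0))
  sig_all <- list()
  ten_all <- list()
  for (r in seq_len(config$replicates)) {
    wcfg <- config$walk
    wcfg$seed <- derive_seed(config$seed, r)
    sig <- run_diffusion(s, config$sequences, wcfg, config$scheme)
    if (!is.null(config$perfusion)) {
      pcf <- config$perfusion
      pcf$seed <- derive_seed(config$seed, 1000 + r)
      pcf$voxel <- config$substrate$voxel
      pcf$ha_rate <- config$substrate$ha_rate
      bs <- sort(unique(config$scheme$measurements$b))
      bs <- bs[bs > 0]
      perf <- lapply(names(config$sequences), function(nm) {
        p <- run_perfusion(pcf, config$sequences[[nm]], b = bs,
                           directions = config$scheme$directions)
        p$sequence <- nm
        p
      })
      perf <- dplyr::bind_rows(perf)
      sig <- dplyr::bind_rows(lapply(split(sig, sig$sequence), function(d) {
        pd <- perf[perf$sequence == d$sequence[1], ]
        keyed <- pd[, c("sequence", "b", "gx", "gy", "gz", "S_over_S0")]
        if (any(d$b == 0)) {
          keyed <- dplyr::bind_rows(
            keyed,
            dplyr::mutate(d[d$b == 0, c("sequence", "b", "gx", "gy", "gz")],
                          S_over_S0 = 1))
        }
        combine_signals(d[, c("sequence", "b", "gx", "gy", "gz", "S_over_S0")],
                        keyed, pcf$f)
      }))
    }
    sig$replicate <- r
    sig_all[[r]] <- sig
    fits <- lapply(split(sig, sig$sequence), function(d) {
      g <- glance(fit_tensor(d, bref = config$scheme$bref))
      g$sequence <- d$sequence[1]
      g
    })
    ten <- dplyr::bind_rows(fits)
    ten$replicate <- r
    ten_all[[r]] <- ten
  }
  tensors <- dplyr::bind_rows(ten_all)
  metrics <- c("MD", "FA", "lambda1", "lambda2", "lambda3",
               "lambda2_over_lambda3")
  long <- tidyr::pivot_longer(tensors, dplyr::all_of(metrics),
                              names_to = "metric")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$sequence, .data$metric),
    mean = mean(.data$value),
    ci_lo = ci_bound(.data$value, -1),
    ci_hi = ci_bound(.data$value, 1),
    .groups = "drop")
  structure(list(signals = dplyr::bind_rows(sig_all),
                 tensors = tensors, summary = summ,
                 provenance = list(
                   seed = config$seed,
                   replicates = config$replicates,
                   config_hash = rlang::hash(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("myowalk")),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "myowalk_experiment")
}

ci_bound <- function(x, side) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  mean(x) + side * stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
}

#' @export
print.myowalk_experiment <- function(x, ...) {
  cat(sprintf("<myowalk_experiment> %d replicate(s), seed %d\n",
              x$provenance$replicates, x$provenance$seed))
  print(tidyr::pivot_wider(x$summary[, c("sequence", "metric", "mean")],
                           names_from = "metric", values_from = "mean"))
  invisible(x)
}

#' Plot replicate tensor metrics of an experiment
#'
#' @param object A `myowalk_experiment`.
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot with replicate means and 95% CIs per sequence.
#' @export
autoplot.myowalk_experiment <- function(object,
                                        metrics = c("MD", "FA", "lambda1"),
                                        ...) {
  df <- object$summary[object$summary$metric %in% metrics, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sequence, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = NULL, x = NULL)
}
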