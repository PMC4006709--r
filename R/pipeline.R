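#' Run a configured experiment end to end
#'
#' Config-driven orchestration: reads a flat JSON config (or an equivalent
#' named list), expands it into (model, condition, seed) runs, simulates
#' each network, computes the measurement suite, and writes rasters,
#' coordinate tables and a machine-readable summary to `out_dir`. Re-running
#' the same config with the same seeds reproduces the summary bit for bit.
#'
#' Config keys (all optional unless noted):
#' \describe{
#'   \item{preset}{`"table2"` (the four canonical networks: IF, GIF, and the
#'     two r-matched variants), `"fig4"` (canonical IF + GIF with per-neuron
#'     recording for distance-resolved correlations), `"fig5-sweep"`
#'     (coupling sweep over `ghat_values`), `"shunting"` (inhibitory
#'     reversal +4 mV, raised thresholds), or absent for a single custom
#'     condition.}
#'   \item{model}{`"if"`, `"gif"`, or `"both"` (custom runs).}
#'   \item{seeds}{integer vector of master seeds (default 1).}
#'   \item{N, L, ghat, tau_syn, e_inh_rec, dt, t_discard, t_measure}{network
#'     overrides.}
#'   \item{k, ge0, sigma_e, sigma_ratio, Ei}{background overrides. The
#'     `"shunting"` preset sets both `Ei` and `e_inh_rec` to +4 mV.}
#'   \item{v_th, v_reset, tau_ref}{neuron overrides.}
#'   \item{vth_rmatched_if, vth_rmatched_gif}{thresholds for the r-matched
#'     models; when absent they are calibrated by [match_rate_threshold()]
#'     (`calib_time` ms per iterate).}
#'   \item{ghat_values}{coupling values for `"fig5-sweep"`.}
#'   \item{mpc}{compute Mean Phase Coherence (default `TRUE`).}
#'   \item{write_rasters}{write per-run TSV rasters (default `TRUE`).}
#' }
#'
#' @param config path to a JSON config file, or a named list.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the summary data.frame (one row per model, condition
#'   and seed), also written to `out_dir/summary.json` together with the
#'   config and its content hash.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config_hash <- unname(
      tools::md5sum(textConnection_write(jsonlite::toJSON(config))))
  }
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  conds <- expand_conditions(cfg)
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    for (seed in cfg$seeds) {
      cd <- conds[ci, ]
      neuron <- make_neuron(cd$model, cd$v_th, cfg)
      bg <- make_bg(cfg, cd$k, cd$ei_bg)
      net <- network_config(N = cfg$N, L = cfg$L, ghat = cd$ghat,
                            tau_syn = cfg$tau_syn, E_syn = cd$e_inh_rec,
                            dt = cfg$dt, t_discard = cfg$t_discard,
                            t_measure = cfg$t_measure, seed = seed)
      rec <- if (isTRUE(cfg$record_neurons)) seq_len(cfg$N) - 1L
             else integer(0)
      sim <- simulate_network(neuron, bg, net, record_neurons = rec)
      ms <- network_measures(sim, mpc = isTRUE(cfg$mpc))
      tag <- sprintf("%s_%s_seed%d", cd$model, cd$condition, seed)
      if (isTRUE(cfg$write_rasters))
        write_raster_tsv(sim$raster,
                         file.path(out_dir, paste0("raster_", tag, ".tsv")),
                         file.path(out_dir, paste0("coords_", tag, ".tsv")))
      rows[[length(rows) + 1L]] <- data.frame(
        model = cd$model, condition = cd$condition, seed = seed,
        v_th = cd$v_th, ghat = cd$ghat, k = cd$k,
        e_inh_rec = cd$e_inh_rec,
        rate_mean_hz = ms$rate_mean, isi_cv_mean = ms$isi_cv_mean,
        f_net_hz = ms$f_net_hz, oscillating = ms$oscillating,
        r_mpc_global = ms$r_mpc_global, config_hash = config_hash)
    }
  }
  summary <- do.call(rbind, rows)
  jsonlite::write_json(list(config = cfg, config_hash = config_hash,
                            results = summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}

textConnection_write <- function(x) {
  f <- tempfile(fileext = ".json")
  writeLines(x, f)
  f
}

config_defaults <- function() {
  list(preset = NULL, model = "both", seeds = 1L,
       N = 400, L = 1, ghat = 0.25, tau_syn = 1, e_inh_rec = -10,
       dt = 0.01, t_discard = 2000, t_measure = 3000,
       k = 5, ge0 = 0.5, sigma_e = 0.6, sigma_ratio = 2.5, Ei = -10,
       v_th = 6.3, v_th_shunting = 15, v_reset = 3, tau_ref = 3,
       vth_rmatched_if = NULL, vth_rmatched_gif = NULL,
       calib_time = 1e5, calib_rate_time = 5e4,
       ghat_values = c(0, 0.05, 0.25, 1),
       mpc = TRUE, write_rasters = TRUE, record_neurons = FALSE)
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  checks <- list(
    N = function(x) length(x) == 1 && x >= 4 &&
      abs(sqrt(x) - round(sqrt(x))) < 1e-9,
    t_measure = function(x) length(x) == 1 && x > 0,
    seeds = function(x) length(x) >= 1 && all(x == round(x)),
    model = function(x) x %in% c("if", "gif", "both"),
    k = function(x) length(x) == 1 && x >= 0)
  for (nm in names(checks))
    if (!is.null(cfg[[nm]]) && !checks[[nm]](cfg[[nm]]))
      stop(sprintf("config field '%s' is invalid", nm))
  if (!is.null(cfg$preset) &&
      !cfg$preset %in% c("table2", "fig4", "fig5-sweep", "shunting"))
    stop("config field 'preset' must be one of table2, fig4, fig5-sweep, ",
         "shunting")
  cfg$seeds <- as.integer(cfg$seeds)
  cfg
}

make_neuron <- function(model, v_th, cfg) {
  if (model == "gif")
    gif_neuron(v_th = v_th, v_reset = cfg$v_reset, tau_ref = cfg$tau_ref)
  else
    if_neuron(v_th = v_th, v_reset = cfg$v_reset, tau_ref = cfg$tau_ref)
}

make_bg <- function(cfg, k = NULL, Ei = NULL) {
  background_params(ge0 = cfg$ge0, sigma_e = cfg$sigma_e,
                    k = if (is.null(k) || is.na(k)) cfg$k else k,
                    sigma_ratio = cfg$sigma_ratio,
                    Ei = if (is.null(Ei) || is.na(Ei)) cfg$Ei else Ei)
}

rmatched_threshold <- function(model, cfg) {
  stored <- cfg[[paste0("vth_rmatched_", model)]]
  if (!is.null(stored)) return(stored)
  # target: the background-driven rate of the *other* canonical model
  other <- if (model == "if") "gif" else "if"
  bg <- make_bg(cfg)
  spk <- simulate_neuron(make_neuron(other, cfg$v_th, cfg), bg,
                         t_measure = cfg$calib_rate_time, seed = 1,
                         trace_bin = 0)$spikes
  target <- isi_stats(spk)[["rate"]]
  match_rate_threshold(make_neuron(model, cfg$v_th, cfg), bg, target,
                       sim_time = cfg$calib_time, seed = 1)$v_th
}

expand_conditions <- function(cfg) {
  base <- function(model, condition, v_th, ghat = cfg$ghat, k = cfg$k,
                   e_inh = cfg$e_inh_rec, ei_bg = cfg$Ei)
    data.frame(model = model, condition = condition, v_th = v_th,
               ghat = ghat, k = k, e_inh_rec = e_inh, ei_bg = ei_bg)
  if (is.null(cfg$preset)) {
    models <- if (cfg$model == "both") c("if", "gif") else cfg$model
    return(do.call(rbind, lapply(models, function(m)
      base(m, "custom", cfg$v_th))))
  }
  switch(cfg$preset,
    table2 = rbind(base("if", "canonical", cfg$v_th),
                   base("gif", "canonical", cfg$v_th),
                   base("if", "rmatched", rmatched_threshold("if", cfg)),
                   base("gif", "rmatched", rmatched_threshold("gif", cfg))),
    fig4 = rbind(base("if", "canonical", cfg$v_th),
                 base("gif", "canonical", cfg$v_th)),
    `fig5-sweep` = do.call(rbind, lapply(cfg$ghat_values, function(gh)
      rbind(base("if", sprintf("ghat%g", gh), cfg$v_th, ghat = gh),
            base("gif", sprintf("ghat%g", gh), cfg$v_th, ghat = gh)))),
    # the shunting variant moves both the recurrent and the background
    # inhibitory reversal to +4 mV
    shunting = rbind(
      base("if", "shunting", cfg$v_th_shunting, e_inh = 4, ei_bg = 4),
      base("gif", "shunting", cfg$v_th_shunting, e_inh = 4, ei_bg = 4)))
}

#' Command-line interface
#'
#' Dispatcher behind the `inst/cli/ingnet` script. Verbs:
#' `linear-analysis`, `simulate-neuron`, `calibrate`, `simulate-network`,
#' `reproduce`. Arguments are `--key value` pairs; see the script for usage.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the verb's result. Results are printed as JSON.
#' @export
ing_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) stop(cli_usage())
  verb <- args[1]
  opt <- parse_cli_args(args[-1])
  get_model <- function(default_vth) {
    model <- tolower(opt$model %||% "gif")
    vth <- as.numeric(opt$vth %||% default_vth)
    if (model == "gif") gif_neuron(v_th = vth) else if_neuron(v_th = vth)
  }
  bg <- background_params(k = as.numeric(opt$k %||% 5))
  emit <- function(x) {
    cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE), "\n")
    invisible(x)
  }
  switch(verb,
    "linear-analysis" = {
      la <- linearize(get_model(6.3), bg = bg)
      emit(list(v_rest = la$v_rest, lambda_re = Re(la$eigenvalues),
                lambda_im = Im(la$eigenvalues),
                tau_eff_ms = la$tau_eff_ms, f_eff_hz = la$f_eff_hz))
    },
    "simulate-neuron" = {
      out <- simulate_neuron(get_model(6.3), bg,
                             t_measure = as.numeric(opt$duration %||% 5e4),
                             seed = as.numeric(opt$seed %||% 1),
                             trace_bin = 0)
      st <- isi_stats(out$spikes)
      emit(list(n_spikes = length(out$spikes), rate_hz = st[["rate"]],
                isi_cv = st[["cv"]]))
    },
    "calibrate" = {
      res <- match_rate_threshold(
        get_model(6.3), bg,
        target_rate = as.numeric(opt$`target-rate`),
        sim_time = as.numeric(opt$duration %||% 1e5),
        seed = as.numeric(opt$seed %||% 1))
      emit(list(v_th = res$v_th, rate_hz = res$rate,
                rate_check_hz = res$rate_check))
    },
    "simulate-network" = {
      net <- network_config(
        N = as.numeric(opt$n %||% 400),
        ghat = as.numeric(opt$ghat %||% 0.25),
        E_syn = as.numeric(opt$`e-inh-rec` %||% -10),
        t_measure = as.numeric(opt$duration %||% 3000),
        seed = as.numeric(opt$seed %||% 1))
      sim <- simulate_network(get_model(6.3), bg, net)
      ms <- network_measures(sim)
      if (!is.null(opt$out)) {
        dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
        write_raster_tsv(sim$raster, file.path(opt$out, "raster.tsv"),
                         file.path(opt$out, "coords.tsv"))
        write_trace_tsv(sim$trace, file.path(opt$out, "trace.tsv"),
                        sim$trace_bin)
      }
      emit(ms[c("rate_mean", "isi_cv_mean", "f_net_hz", "r_mpc_global")])
    },
    "reproduce" = {
      cfgfile <- opt$config
      cfg <- if (!is.null(cfgfile)) cfgfile
             else list(preset = opt$preset %||% "table2")
      emit(run_experiment(cfg, opt$out %||% "ingnet-out"))
    },
    stop(cli_usage()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_args <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --key value pairs, got: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opt[[key]] <- TRUE; i <- i + 1
    } else {
      opt[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  opt
}

cli_usage <- function() {
  paste("usage: ingnet <verb> [--key value ...]; verbs: linear-analysis,",
        "simulate-neuron, calibrate, simulate-network, reproduce")
}
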