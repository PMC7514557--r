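# Pipeline driver and tabular output: ties the analysis stages together
# behind a single serializable configuration, so a saved config reproduces a
# run exactly. Outputs are CSV tables and JSON summaries stamped with the
# seed and a fingerprint of the configuration.

# FNV-1a hash of the serialized config: a stable run fingerprint
# (provenance stamp, not cryptographic). All arithmetic stays below 2^41,
# exact in doubles; bitwXor only ever sees sub-2^16 integers.
.config_fingerprint <- function(config) {
  bytes <- as.integer(serialize(config, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), b)
    h <- h - (h %% 65536) + lo
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.write_stamped_csv <- function(df, path, fingerprint, seed) {
  df$config_hash <- fingerprint
  df$seed <- seed
  write.csv(df, path, row.names = FALSE)
  path
}

.validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  known <- c("command", "model", "models", "u", "s", "r", "alpha", "y", "mu0",
             "tau", "tau_p", "tau_grid", "sigma_hat_ss", "sigma_hat_ss_grid",
             "sigma_avg", "mu0_grid", "k_on", "k_off", "R0", "R1", "tau_deg",
             "g_max", "n_starts", "n_polish", "seed", "out_dir", "n_trace",
             "bounds", "s_min", "mu0_range", "duration", "n_traj")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$command) ||
      !config$command %in% c("simulate", "optimize", "sweep", "cost",
                             "suboptimal", "bursty", "learning", "table1"))
    stop("config must set 'command' to one of: simulate, optimize, sweep, ",
         "cost, suboptimal, bursty, learning, table1", call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must set 'out_dir'", call. = FALSE)
  config
}

.config_params <- function(cfg) {
  model <- cfg$model %||% "no_feedback"
  if (model %in% c("S", "S_tilde")) model <- "no_feedback"
  if (model %in% c("F", "F_tilde")) model <- "feedback"
  if (model == "no_feedback")
    circuit_params("no_feedback", u = cfg$u, s = cfg$s, r = cfg$r %||% 1)
  else
    circuit_params("feedback", alpha = cfg$alpha, y = cfg$y, s = cfg$s,
                   r = cfg$r %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordering comparison of the four model variants
#'
#' Optimizes all four models on a grid of readout times and dissipation
#' budgets and tabulates the information and cost orderings between them:
#' steady-state versus free initial condition, and feedback versus none.
#'
#' @param tau_grid readout delays (rescaled).
#' @param sigma_grid steady-state dissipation budgets.
#' @param tau_p reset time; defaults to each `tau`.
#' @param ... passed to [opt_problem()].
#' @return `data.frame`: one row per grid point with the four `I*` values,
#'   total costs, and logical ordering columns.
#' @export
table_one <- function(tau_grid = c(0.5, 1, 2),
                      sigma_grid = c(0.15, 0.35, 0.75),
                      tau_p = NULL, ...) {
  rows <- list()
  for (tau in tau_grid) for (sg in sigma_grid) {
    tp <- tau_p %||% tau
    cc <- cost_comparison(tau = tau, tau_p = tp, sigma_hat_ss = sg, ...)
    val <- function(m, col) cc[cc$model == m, col][1]
    rows[[length(rows) + 1L]] <- data.frame(
      tau = tau, tau_p = tp, sigma_hat_ss = sg,
      I_S = val("S", "I_star"), I_F = val("F", "I_star"),
      I_S_tilde = val("S_tilde", "I_star"), I_F_tilde = val("F_tilde", "I_star"),
      C_S = val("S", "total_cost"), C_F = val("F", "total_cost"),
      C_S_tilde = val("S_tilde", "total_cost"),
      C_F_tilde = val("F_tilde", "total_cost"),
      I_S_lt_I_F = val("S", "I_star") <= val("F", "I_star") + 1e-6,
      I_S_lt_I_S_tilde = val("S", "I_star") <= val("S_tilde", "I_star") + 1e-6,
      I_F_lt_I_F_tilde = val("F", "I_star") <= val("F_tilde", "I_star") + 1e-6,
      I_S_tilde_le_I_F_tilde =
        val("S_tilde", "I_star") <= val("F_tilde", "I_star") + 1e-6,
      C_S_tilde_ge_C_F_tilde =
        val("S_tilde", "total_cost") >= val("F_tilde", "total_cost") - 1e-6)
  }
  do.call(rbind, rows)
}

#' Run an analysis pipeline from a configuration
#'
#' Dispatches on `config$command` and writes CSV tables plus a JSON summary
#' and a run log into `config$out_dir`. Every table row carries the config
#' fingerprint and the seed, and running the same config twice produces
#' byte-identical outputs.
#'
#' Commands: `simulate` (dissipation trace of one circuit), `optimize` (one
#' [optimize_circuit()] run), `sweep` ([sweep_tau()]), `cost`
#' ([cost_comparison()]), `suboptimal` ([evaluate_suboptimal()]), `bursty`
#' (stationary distribution and dissipation decomposition), `learning`
#' ([learning_report()]), `table1` ([table_one()]).
#'
#' @param config a named list or path to a YAML file. Required keys depend
#'   on the command; unknown keys raise a schema error listing them.
#' @return Invisibly, a list with the written file paths and the in-memory
#'   results.
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- .config_fingerprint(cfg[setdiff(names(cfg), "out_dir")])
  paths <- character()
  emit_csv <- function(df, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".csv"))
    paths <<- c(paths, .write_stamped_csv(df, p, fp, cfg$seed))
  }
  emit_json <- function(x, name) {
    p <- file.path(cfg$out_dir, paste0(name, ".json"))
    jsonlite::write_json(c(x, list(config_hash = fp, seed = cfg$seed)),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
  }

  result <- switch(
    cfg$command,
    simulate = {
      G <- build_generator(.config_params(cfg))
      rep <- dissipation_report(G, mu0 = cfg$mu0 %||% mu_steady_state(G),
                                tau_p = cfg$tau_p %||% 1,
                                n_trace = cfg$n_trace %||% 64)
      emit_csv(rep$trace, "sigma_hat_trace")
      emit_csv(data.frame(state = .state_labels,
                          probability = as.numeric(steady_state(G))),
               "steady_state")
      emit_json(rep[c("sigma_hat_ss", "sigma_avg", "relaxation_cost", "tau_p")],
                "dissipation")
      rep
    },
    optimize = {
      pb <- opt_problem(cfg$model, tau = cfg$tau, tau_p = cfg$tau_p %||% cfg$tau,
                        sigma_hat_ss = cfg$sigma_hat_ss,
                        sigma_avg = cfg$sigma_avg,
                        n_starts = cfg$n_starts %||% 12L,
                        seed = cfg$seed)
      res <- optimize_circuit(pb)
      if (res$status == "converged") {
        emit_json(list(model = res$model, I_star = res$I_star, mu0 = res$mu0,
                       sigma_hat_ss = res$sigma_hat_ss, sigma_avg = res$sigma_avg,
                       constraint_residual = res$constraint_residual,
                       params = unclass(res$params)[-1],
                       n_restarts_agreeing = res$n_restarts_agreeing),
                  "opt_result")
      } else emit_json(list(status = res$status, message = res$message),
                       "opt_result")
      res
    },
    sweep = {
      pb <- opt_problem(cfg$model, tau = cfg$tau_grid[1],
                        sigma_hat_ss = cfg$sigma_hat_ss,
                        n_starts = cfg$n_starts %||% 12L, seed = cfg$seed)
      df <- sweep_tau(pb, cfg$tau_grid)
      emit_csv(df, "sweep")
      df
    },
    cost = {
      df <- cost_comparison(tau = cfg$tau, tau_p = cfg$tau_p %||% cfg$tau,
                            sigma_hat_ss = cfg$sigma_hat_ss,
                            models = cfg$models %||% c("S", "S_tilde", "F", "F_tilde"),
                            n_starts = cfg$n_starts %||% 12L, seed = cfg$seed)
      emit_csv(df, "cost_comparison")
      df
    },
    suboptimal = {
      pb <- opt_problem(cfg$model, tau = cfg$tau, tau_p = cfg$tau_p %||% cfg$tau,
                        sigma_hat_ss = cfg$sigma_hat_ss,
                        n_starts = cfg$n_starts %||% 12L, seed = cfg$seed)
      fit <- optimize_circuit(pb)
      df <- evaluate_suboptimal(fit, mu0_grid = cfg$mu0_grid %||%
                                  seq(0, 1, length.out = 21))
      emit_csv(df, "suboptimal")
      df
    },
    bursty = {
      bp <- bursty_params(cfg$k_on, cfg$k_off, cfg$R0, cfg$R1,
                          tau_deg = cfg$tau_deg %||% 1, g_max = cfg$g_max)
      ss <- bursty_steady_state(bp)
      dd <- dissipation_decomposition(bp, ss)
      emit_csv(data.frame(g = ss$g, P0 = ss$P0, P1 = ss$P1), "bursty_stationary")
      emit_json(list(sigma0 = dd$sigma0, sigma1 = dd$sigma1, sigma2 = dd$sigma2,
                     total = dd$total, sigma_FS = dd$sigma_fs,
                     occupancy = ss$occupancy), "bursty_dissipation")
      list(stationary = ss, dissipation = dd)
    },
    learning = {
      G <- build_generator(.config_params(cfg))
      rep <- learning_report(G)
      emit_json(rep, "learning")
      rep
    },
    table1 = {
      df <- table_one(tau_grid = cfg$tau_grid %||% c(0.5, 1, 2),
                      sigma_grid = cfg$sigma_hat_ss_grid %||% c(0.15, 0.35, 0.75),
                      n_starts = cfg$n_starts %||% 12L, seed = cfg$seed)
      emit_csv(df, "table1")
      df
    })

  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(c(paste("command:", cfg$command),
               paste("config_hash:", fp),
               paste("seed:", cfg$seed),
               paste("package_version:",
                     as.character(utils::packageVersion("circdiss"))),
               paste("outputs:", paste(basename(paths), collapse = ", "))),
             log_path)
  invisible(list(paths = c(paths, log_path), result = result,
                 config_hash = fp))
}
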