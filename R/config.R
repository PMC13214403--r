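default_config <- function() {
  par_defaults <- formals(ll_parameters)
  par_defaults <- lapply(par_defaults[setdiff(names(par_defaults),
                                              "multiplier_base")], eval)
  par_defaults$multiplier_base <- "pathway"
  list(
    parameters = par_defaults,
    life_table = list(source = "synthetic", a = 5e-4, b = 3.5e-5,
                      c = 1.095, max_age = 120L),
    psa = list(n_iter = 1000L, seed = 1L, ess = 50, cost_cv = 0.30),
    wtp_grid = list(from = 0, to = 50000, by = 500),
    budget = list(horizon_years = 15L, patients_per_year = 15,
                  discounting = "program_start", label = "full uptake"),
    output = list(dir = "results")
  )
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key `%s` in block `%s`",
                 unknown[1L], block), call. = FALSE)
  }
  defaults[names(user)] <- user
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration file,
#' fills every omitted key with its default, rejects unknown keys, and
#' validates the parameter block through [ll_parameters()]. An empty file
#' (or `path = NULL`) yields the full default configuration. The blocks
#' are `parameters` (every model parameter), `life_table` (either
#' `path: <file>` or the synthetic generator parameters `a`, `b`, `c`,
#' `max_age`), `psa` (`n_iter`, `seed`, `ess`, `cost_cv`), `wtp_grid`
#' (`from`, `to`, `by`), `budget` (`horizon_years`, `patients_per_year`,
#' `discounting`, `label`) and `output` (`dir`).
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return A validated `run_config` list with all defaults resolved.
#' @seealso [run_all()], [write_config()]
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration must be a mapping", call. = FALSE)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key `%s`", unknown[1L]),
         call. = FALSE)
  }
  cfg <- defaults
  # life_table accepts either a file path or generator parameters
  if (!is.null(user$life_table$path)) {
    cfg$life_table <- list(source = "file", path = user$life_table$path)
    user$life_table <- NULL
  }
  for (block in names(defaults)) {
    if (block == "life_table" && identical(cfg$life_table$source, "file")) next
    cfg[[block]] <- merge_block(defaults[[block]], user[[block]], block)
  }
  # validates ranges; errors name the key and constraint
  do.call(ll_parameters, cfg$parameters)
  if (!cfg$budget$discounting %in% c("program_start", "none")) {
    stop("`budget.discounting` must be 'program_start' or 'none'",
         call. = FALSE)
  }
  if (cfg$psa$n_iter < 1) stop("`psa.n_iter` must be >= 1", call. = FALSE)
  check_wtp_grid(with(cfg$wtp_grid, seq(from, to, by = by)))
  structure(cfg, class = c("run_config", "list"))
}

#' Echo a configuration to a YAML file
#'
#' Writes the fully resolved configuration so a run can be reproduced;
#' `load_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_life_table <- function(cfg) {
  lt <- cfg$life_table
  if (identical(lt$source, "file")) {
    read_life_table(lt$path)
  } else {
    gompertz_makeham_table(a = lt$a, b = lt$b, c = lt$c,
                           max_age = lt$max_age)
  }
}

#' Run the full pipeline from a configuration
#'
#' Executes base case, probabilistic sensitivity analysis,
#' decision-uncertainty curves and budget impact, writing every artifact to
#' `out_dir`: the life table used (`life_table.csv`), per-strategy cohort
#' traces (`trace_<strategy>.csv`), base-case results (`base_case.json`),
#' PSA samples (`psa_samples.csv`: iter, strategy, cost, qaly) and sampled
#' parameters (`psa_parameters.csv`), the CEAC/CEAF/EVPI table
#' (`voi_curves.csv`), the budget table (`budget.csv`), the effective
#' configuration (`config_echo.yaml`) and a run manifest
#' (`manifest.json`: seed, iteration and rejection counts, package
#' version). Outputs are deterministic given the configured seed.
#'
#' @param config `run_config` from [load_config()] (default configuration
#'   if omitted).
#' @param out_dir Output directory; defaults to the configured one.
#' @param quiet Suppress progress messages (they go to `stderr`; output
#'   files never contain log noise).
#' @return Invisibly, a list with elements `model` ([ll_model()] fit),
#'   `psa`, `voi`, `budget`, `files`.
#' @export
#' @examples
#' \donttest{
#' cfg <- load_config()
#' cfg$psa$n_iter <- 20L
#' res <- run_all(cfg, out_dir = tempfile(), quiet = TRUE)
#' res$model$icer
#' }
run_all <- function(config = load_config(), out_dir = config$output$dir,
                    quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)

  params <- do.call(ll_parameters, config$parameters)
  life <- config_life_table(config)
  write_life_table(life, fp("life_table.csv"))

  say("base case: %d cycles from age %d", params$n_cycles, params$start_age)
  fit <- ll_model(params, life)
  for (s in names(fit$traces)) {
    utils::write.csv(as.data.frame(fit$traces[[s]]),
                     fp(sprintf("trace_%s.csv", s)), row.names = FALSE)
  }
  cmp <- fit$comparison
  jsonlite::write_json(
    list(qalys = as.list(fit$qalys), costs = as.list(fit$costs),
         delta_qaly = cmp$delta_qaly, delta_cost = cmp$delta_cost,
         icer = cmp$icer, nmb = as.list(cmp$nmb), wtp = cmp$wtp),
    fp("base_case.json"), auto_unbox = TRUE, digits = NA, null = "null")

  say("PSA: %d iterations (seed %s)", config$psa$n_iter,
      format(config$psa$seed))
  specs <- psa_distributions(params, ess = config$psa$ess,
                             cost_cv = config$psa$cost_cv, quiet = quiet)
  psa <- run_psa(params, life, n_iter = config$psa$n_iter,
                 seed = config$psa$seed, specs = specs)
  long <- data.frame(
    iter = rep(seq_len(psa$n_iter), times = 2L),
    strategy = rep(colnames(psa$costs), each = psa$n_iter),
    cost = as.numeric(psa$costs),
    qaly = as.numeric(psa$qalys))
  utils::write.csv(long, fp("psa_samples.csv"), row.names = FALSE)
  utils::write.csv(cbind(iter = seq_len(psa$n_iter),
                         as.data.frame(psa$samples)),
                   fp("psa_parameters.csv"), row.names = FALSE)

  say("decision-uncertainty curves")
  grid <- with(config$wtp_grid, seq(from, to, by = by))
  voi <- voi_curves(psa, grid)
  utils::write.csv(as.data.frame(voi), fp("voi_curves.csv"),
                   row.names = FALSE)

  say("budget impact: %g patients/year over %d years",
      config$budget$patients_per_year, config$budget$horizon_years)
  stream <- cost_stream(params, life)
  budget <- run_budget(stream,
                       patients_per_year = config$budget$patients_per_year,
                       horizon = config$budget$horizon_years,
                       r_cost = params$r_cost,
                       discounting = config$budget$discounting,
                       label = config$budget$label)
  utils::write.csv(as.data.frame(budget), fp("budget.csv"),
                   row.names = FALSE)

  write_config(config, fp("config_echo.yaml"))
  jsonlite::write_json(
    list(package = "achecon",
         version = as.character(utils::packageVersion("achecon")),
         seed = config$psa$seed, n_iter = psa$n_iter,
         psa_rejections = psa$rejections,
         effective_config = unclass(config)),
    fp("manifest.json"), auto_unbox = TRUE, digits = NA, null = "null")

  files <- list.files(out_dir)
  say("wrote %d files to %s", length(files), out_dir)
  invisible(list(model = fit, psa = psa, voi = voi, budget = budget,
                 files = files))
}
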