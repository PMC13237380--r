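# End-to-end orchestration: configuration, report bundles, logging.
#
# Configs are plain lists (or YAML files read with yaml::read_yaml),
# validated against a fixed key schema; unknown keys are errors so a
# typo cannot silently change an analysis.

config_schemas <- list(
  group = c("input", "simulate", "groups_compare", "n_boot", "n_perm",
            "seed"),
  bayes = c("input", "simulate", "chains", "iterations", "warmup", "seed",
            "pooled", "recovery"),
  photometry = c("signals", "events_file", "simulate", "event", "pre",
                 "post", "baseline", "seed")
)

simulate_schema <- c("groups", "protocol", "sessions", "seed",
                     "duration", "events", "transients", "rate_hz",
                     "noise_sd")

load_config <- function(config, kind) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path")
  unknown <- setdiff(names(config), config_schemas[[kind]])
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$simulate)) {
    bad <- setdiff(names(config$simulate), simulate_schema)
    if (length(bad)) {
      abort(sprintf("unknown simulate key(s): %s",
                    paste(bad, collapse = ", ")))
    }
    if (is.null(config$simulate$seed)) {
      abort("every stochastic stage needs an explicit seed: simulate$seed")
    }
  }
  config
}

new_bundle <- function(kind, config) {
  structure(list(
    kind = kind, results = list(), config = config,
    log = character(), excluded = tibble::tibble(),
    version = as.character(packageVersion("safeval")),
    converged = NA, partial = FALSE
  ), class = "report_bundle")
}

log_line <- function(bundle, fmt, ...) {
  bundle$log <- c(bundle$log,
                  sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                          sprintf(fmt, ...)))
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle:%s> %d result block(s)%s\n", x$kind,
              length(x$results),
              if (isTRUE(x$partial)) " [PARTIAL]" else ""))
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes `results.json`, `config.yaml` and `log.txt`. Files are written
#' to temporaries and renamed into place (atomic on one filesystem);
#' existing outputs are never overwritten unless `overwrite = TRUE`.
#'
#' @param bundle A `report_bundle`.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow replacing existing result files.
#' @return The bundle, invisibly.
#' @export
write_bundle <- function(bundle, out_dir, overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  targets <- file.path(out_dir, c("results.json", "config.yaml", "log.txt"))
  if (!overwrite && any(file.exists(targets))) {
    abort("output files exist; pass overwrite = TRUE to replace them")
  }
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  payload <- list(kind = bundle$kind, version = bundle$version,
                  converged = bundle$converged, partial = bundle$partial,
                  results = bundle$results,
                  excluded = bundle$excluded)
  atomically(targets[1], function(p) {
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  })
  atomically(targets[2], function(p) yaml::write_yaml(bundle$config, p))
  atomically(targets[3], function(p) writeLines(bundle$log, p))
  invisible(bundle)
}

resolve_table <- function(config) {
  if (!is.null(config$input)) return(read_behavior(config$input))
  if (is.null(config$simulate)) abort("config needs `input` or `simulate`")
  sim <- config$simulate
  sched <- make_schedule(sim$protocol %||% "standard_2aa",
                         sessions = sim$sessions,
                         seed = derive_seed(sim$seed, 1L))
  groups <- lapply(sim$groups, function(g) {
    list(n = g$n,
         params = agent_params(g$alpha, g$beta, g$v1, g$tau %||% 0.8),
         jitter = g$jitter %||% 0)
  })
  simulate_cohort(cohort_spec(groups, sched, seed = sim$seed))
}

#' Run the group-level analysis pipeline
#'
#' Simulates (or loads) a behavior table, builds per-group empirical
#' curves, fits the Rescorla-Wagner model to each, estimates subject-
#' bootstrap standard errors, and runs the label-permutation test for
#' each pair of groups. Any stage failure marks the bundle partial
#' rather than discarding earlier results.
#'
#' @param config List or YAML path; keys: `input` or `simulate`
#'   (simulation spec with `groups`, `protocol`, `sessions`, `seed`),
#'   `n_boot`, `n_perm`, `seed`.
#' @param out_dir Optional directory for [write_bundle()].
#' @param overwrite Passed to [write_bundle()].
#' @return A `report_bundle` whose `results` carry `curves`, `fits`,
#'   `bootstrap`, `permutation`.
#' @export
run_group_analysis <- function(config, out_dir = NULL, overwrite = FALSE) {
  config <- load_config(config, "group")
  bundle <- new_bundle("group", config)
  res <- tryCatch({
    table <- resolve_table(config)
    bundle <- log_line(bundle, "behavior table: %d rows, %d subjects",
                       nrow(table), length(unique(table$subject_id)))
    groups <- unique(table$group)
    seed <- config$seed %||% 1L
    curves <- lapply(setNames(groups, groups), function(g)
      empirical_group_curve(table, g))
    fits <- lapply(setNames(groups, groups), function(g)
      fit_group(curves[[g]]))
    boots <- lapply(setNames(groups, groups), function(g)
      bootstrap_se(table, g, n_boot = config$n_boot %||% 1000L,
                   seed = derive_seed(seed, match(g, groups))))
    bundle <- log_line(bundle, "fitted %d group(s): %s", length(groups),
                       paste(groups, collapse = ", "))
    perms <- list()
    if (length(groups) >= 2L) {
      prs <- utils::combn(groups, 2, simplify = FALSE)
      for (pr in prs) {
        key <- paste(pr, collapse = "_vs_")
        perms[[key]] <- permutation_test(
          table[table$group == pr[1], ], table[table$group == pr[2], ],
          n_perm = config$n_perm %||% 5000L,
          seed = derive_seed(seed, 1000L + length(perms)))
        bundle <- log_line(bundle, "permutation %s: %s", key,
                           paste(sprintf("%s p=%.4f",
                                         names(perms[[key]]$p_values),
                                         perms[[key]]$p_values),
                                 collapse = ", "))
      }
    }
    list(
      curves = lapply(curves, as.data.frame),
      fits = lapply(fits, function(f) c(as.list(f$params), sse = f$sse,
                                        alpha_identifiable =
                                          f$alpha_identifiable)),
      bootstrap = lapply(boots, function(b)
        list(se = as.list(b$se), n_boot = b$n_boot, seed = b$seed)),
      permutation = lapply(perms, function(p)
        list(observed = as.list(p$observed), p_values = as.list(p$p_values),
             n_perm = p$n_perm, seed = p$seed)))
  }, error = function(e) {
    bundle <<- log_line(bundle, "FAILED: %s", conditionMessage(e))
    bundle$partial <<- TRUE
    NULL
  })
  if (!is.null(res)) bundle$results <- res
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, overwrite)
  bundle
}

#' Run the hierarchical Bayesian pipeline
#'
#' Fits the hierarchical model to a (simulated or loaded) behavior table,
#' summarises the posterior with split-R-hat gatekeeping (any parameter
#' with R-hat >= 1.01 marks the bundle non-converged), compares groups
#' when more than one is present, and optionally audits parameter
#' recovery against simulation ground truth.
#'
#' @param config List or YAML path; keys: `input`/`simulate`, `chains`,
#'   `iterations`, `warmup`, `seed`, `pooled`, `recovery`.
#' @param out_dir,overwrite As in [run_group_analysis()].
#' @return A `report_bundle` with `summary`, `diagnostics`, optional
#'   `group_comparison` and `recovery`.
#' @export
run_bayes_analysis <- function(config, out_dir = NULL, overwrite = FALSE) {
  config <- load_config(config, "bayes")
  bundle <- new_bundle("bayes", config)
  res <- tryCatch({
    table <- resolve_table(config)
    spec <- hier_model_spec(pooled = config$pooled %||% TRUE)
    post <- sample_posterior(
      table, spec, chains = config$chains %||% 4L,
      iterations = config$iterations %||% 2000L,
      warmup = config$warmup %||% 1000L, seed = config$seed %||% 1L)
    s <- tidy(post)
    g <- glance(post)
    bundle <- log_line(bundle, "sampled %d params, max R-hat %.4f",
                       nrow(s), g$max_rhat)
    bundle$converged <- g$converged
    if (!g$converged) {
      bundle <- log_line(bundle, "NON-CONVERGED: R-hat >= 1.01")
    }
    out <- list(summary = as.data.frame(s), diagnostics = as.list(g))
    if (length(post$groups) >= 2L) {
      out$group_comparison <- as.data.frame(compare_groups(post))
    }
    truth <- attr(table, "truth")
    if (isTRUE(config$recovery) && !is.null(truth)) {
      rec <- parameter_recovery(
        truth, make_schedule(config$simulate$protocol %||% "standard_2aa",
                             sessions = config$simulate$sessions,
                             seed = derive_seed(config$seed %||% 1L, 77L)),
        spec = spec, chains = config$chains %||% 4L,
        iterations = config$iterations %||% 2000L,
        warmup = config$warmup %||% 1000L,
        seed = derive_seed(config$seed %||% 1L, 78L))
      out$recovery <- as.data.frame(rec$summary)
      bundle <- log_line(bundle, "recovery: %s",
                         paste(sprintf("%s cov=%.2f", rec$summary$parameter,
                                       rec$summary$coverage),
                               collapse = ", "))
    }
    out
  }, error = function(e) {
    bundle <<- log_line(bundle, "FAILED: %s", conditionMessage(e))
    bundle$partial <<- TRUE
    NULL
  })
  if (!is.null(res)) bundle$results <- res
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, overwrite)
  bundle
}

#' Run the photometry pipeline
#'
#' Loads (or synthesises) a two-channel session, computes dF/F against
#' the fitted isosbestic control, aligns to the requested event,
#' z-scores against the pre-event baseline, and tabulates trapezoid AUCs.
#' Excluded trials (incomplete windows, zero baseline SD) are enumerated
#' in the bundle, never silently dropped.
#'
#' @param config List or YAML path; keys: `signals`/`events_file` or
#'   `simulate` (with `duration`, `events` name->times, `transients`,
#'   `seed`), `event`, `pre`, `post`, `baseline`.
#' @param out_dir,overwrite As in [run_group_analysis()].
#' @return A `report_bundle` with `fit_coefficients`, `auc`, `windows`,
#'   `n_trials`, `excluded`.
#' @export
run_photometry_analysis <- function(config, out_dir = NULL,
                                    overwrite = FALSE) {
  config <- load_config(config, "photometry")
  bundle <- new_bundle("photometry", config)
  res <- tryCatch({
    if (!is.null(config$signals)) {
      session <- read_photometry(config$signals, config$events_file)
    } else {
      sim <- config$simulate
      spec_args <- sim$transients %||% list()
      spec <- do.call(transient_spec, spec_args)
      session <- generate_photometry(sim$events, spec, sim$duration,
                                     seed = sim$seed)
    }
    bundle <- log_line(bundle, "session: %d samples at %g Hz",
                       nrow(session$signals), session$rate_hz)
    event <- config$event %||% session$events$event[1]
    pre <- config$pre %||% 5
    post <- config$post %||% 5
    dff <- compute_dff(session)
    tens <- align_to_events(dff, session$events, event = event,
                            pre = pre, post = post)
    tens <- zscore_baseline(tens, config$baseline %||% c(-pre, 0))
    auc <- auc_pre_post(tens, pre_window = c(-pre, 0),
                        post_window = c(0, post))
    bundle$excluded <- tens$excluded
    bundle <- log_line(bundle, "%d trials aligned to '%s', %d excluded",
                       nrow(tens$mat), event, nrow(tens$excluded))
    list(fit_coefficients = as.list(attr(dff, "coefficients")),
         windows = list(pre = pre, post = post,
                        baseline = config$baseline %||% c(-pre, 0)),
         n_trials = nrow(tens$mat),
         auc = as.data.frame(auc))
  }, error = function(e) {
    bundle <<- log_line(bundle, "FAILED: %s", conditionMessage(e))
    bundle$partial <<- TRUE
    NULL
  })
  if (!is.null(res)) bundle$results <- res
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, overwrite)
  bundle
}
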