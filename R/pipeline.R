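#' Simulate a dataset to disk (CLI stage)
#'
#' @param out_dir output directory.
#' @param config a [simulation_config()] or path to a JSON config file.
#' @param seed optional override of the config seed.
#' @return the dataset directory, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = simulation_config(), seed = NULL) {
  config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_sim_config(config)
  generate_dataset(config, out_dir = out_dir)
  invisible(out_dir)
}

load_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    vals <- jsonlite::read_json(config, simplifyVector = TRUE)
    known <- names(formals(simulation_config))
    bad <- setdiff(names(vals), known)
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    return(do.call(simulation_config, vals))
  }
  if (is.list(config)) return(do.call(simulation_config, config))
  stop("config must be a sim_config, a list, or a JSON file path", call. = FALSE)
}

#' Run the full analysis on a dataset directory (CLI stage)
#'
#' Chain: eligibility filter -> (tree grafting for any plant missing from
#' the tree) -> per-plant metrics -> mixed models per guild scope. Writes
#' `plant_metrics.csv`, `models.csv`, `lrt.csv`, `r2.csv`,
#' `graft_report.csv`, `eligibility.csv`, `manifest.json` and a plain-text
#' `summary.txt` of effect signs per scope.
#'
#' @param dataset_dir dataset directory as written by [write_dataset()].
#' @param out_dir results directory.
#' @param tree_path optional Newick path overriding the dataset's tree
#'   (taxonomy still taken from the dataset).
#' @param scopes guild scopes to fit.
#' @param alpha LRT threshold.
#' @param from_metrics optional path to a precomputed `plant_metrics.csv`;
#'   when given, the filter/graft/metrics stages are skipped and models
#'   are fitted directly on it.
#' @return list as from [run_full_analysis()], invisibly.
#' @export
cmd_run <- function(dataset_dir, out_dir, tree_path = NULL,
                    scopes = c("all", "endophage", "exophage"),
                    alpha = 0.05, from_metrics = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(from_metrics)) {
    met <- read.csv(from_metrics, stringsAsFactors = FALSE)
    res <- fit_metrics_table(met, scopes = scopes, alpha = alpha)
  } else {
    ds <- read_dataset(dataset_dir)
    tt <- ds$tree
    if (!is.null(tree_path)) {
      tt <- tax_tree(ape::read.tree(tree_path), tt$taxonomy)
    }
    filtered <- lapply(ds$assemblages, drop_unusable_plants)
    elig <- do.call(rbind, lapply(filtered, check_eligibility))
    write.csv(elig, file.path(out_dir, "eligibility.csv"), row.names = FALSE)
    usable <- filtered[elig$passed]
    if (length(usable) == 0L) stop("no eligible assemblages", call. = FALSE)
    gr <- graft_all(tt, usable)
    write.csv(gr$report, file.path(out_dir, "graft_report.csv"),
              row.names = FALSE)
    failed <- gr$report$species[gr$report$attachment_level == "failed"]
    if (length(failed)) {
      usable <- lapply(usable, function(a) drop_plants(a, failed))
      usable <- Filter(function(a) check_eligibility(a)$passed, usable)
      if (length(usable) == 0L) stop("no eligible assemblages", call. = FALSE)
    }
    res <- run_full_analysis(usable, gr$tree, scopes = scopes, alpha = alpha)
  }
  write_csv_lossless(res$metrics, file.path(out_dir, "plant_metrics.csv"))
  write.csv(res$models, file.path(out_dir, "models.csv"), row.names = FALSE)
  write.csv(res$lrt, file.path(out_dir, "lrt.csv"), row.names = FALSE)
  write.csv(res$r2, file.path(out_dir, "r2.csv"), row.names = FALSE)
  writeLines(summarize_signs(res$models), file.path(out_dir, "summary.txt"))
  jsonlite::write_json(
    list(dataset_dir = dataset_dir, tree_path = tree_path, scopes = scopes,
         alpha = alpha,
         outputs = c("plant_metrics.csv", "models.csv", "lrt.csv", "r2.csv")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

# CSV with doubles at 17 significant digits, so a write/read round trip
# reproduces them bit-for-bit (stage isolation depends on this)
write_csv_lossless <- function(df, path) {
  isdbl <- vapply(df, is.double, TRUE)
  df[isdbl] <- lapply(df[isdbl], function(x)
    ifelse(is.na(x), NA, sprintf("%.17g", x)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# removes named plants from an assemblage (then cascades herbivores)
drop_plants <- function(a, plants) {
  keep <- !a$table$plants$species %in% plants
  it <- interaction_table(a$table$counts[keep, , drop = FALSE],
                          a$table$plants[keep, , drop = FALSE],
                          a$table$herbivores)
  drop_unusable_plants(assemblage(a$assemblage_id, it, a$metadata))
}

# refits the model stage from a stacked metrics table with a guild_scope column
fit_metrics_table <- function(met, scopes, alpha) {
  responses <- c("richness", "mean_jaccard", "mean_simpson", "mean_dprime")
  models <- list(); lrts <- list(); r2s <- list()
  for (scope in intersect(scopes, unique(met$guild_scope))) {
    sub <- met[met$guild_scope == scope, ]
    for (resp in responses) {
      res <- tryCatch({
        ans <- lrt_interaction(sub, model_spec(resp), alpha = alpha)
        list(ans = ans, fit = fallback_if_singular(ans$fit))
      }, error = function(e) NULL)
      if (is.null(res)) next
      co <- res$fit$coefficients
      co$scope <- scope; co$response <- resp
      co$re_variance <- res$fit$re_variance; co$re_sd <- res$fit$re_sd
      models[[paste(scope, resp)]] <- co
      lr <- res$ans$lrt; lr$scope <- scope; lr$response <- resp
      lrts[[paste(scope, resp)]] <- lr
      r2row <- data.frame(scope = scope, response = resp,
                          r2_marginal = NA_real_, r2_conditional = NA_real_,
                          mcfadden = NA_real_,
                          fallback_used = res$fit$fallback_used)
      if (res$fit$fallback_used) r2row$mcfadden <- res$fit$mcfadden
      else {
        r2 <- r2_nakagawa(res$fit)
        r2row$r2_marginal <- r2[["marginal"]]
        r2row$r2_conditional <- r2[["conditional"]]
      }
      r2s[[paste(scope, resp)]] <- r2row
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE))) else NULL
  list(models = bind(models), lrt = bind(lrts), r2 = bind(r2s), metrics = met)
}

summarize_signs <- function(models) {
  if (is.null(models)) return("no models fitted")
  out <- character()
  for (scope in unique(models$scope)) {
    out <- c(out, paste0("scope: ", scope))
    sub <- models[models$scope == scope & models$term %in% c("PI", "PO"), ]
    for (i in seq_len(nrow(sub))) {
      out <- c(out, sprintf(
        "  %-12s %-3s %s (stat = %.2f, p = %.3g)",
        sub$response[i], sub$term[i],
        ifelse(sub$estimate[i] < 0, "negative", "positive"),
        sub$statistic[i], sub$p_value[i]))
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `validate`, `graft`, `metrics`,
#' `fit` and `run`. Exit codes: 0 success, 1 runtime failure, 2
#' usage/config error. Intended for use from `Rscript`, e.g.
#' `Rscript -e 'herbphylo::run_cli()' simulate --out data --seed 7`.
#'
#' @param args character vector of CLI arguments (defaults to the
#'   command line).
#' @return exit status, invisibly (also used as the process exit code
#'   when run non-interactively).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      cat("usage: herbphylo <simulate|validate|graft|metrics|fit|run> [options]\n")
      return(invisible(2L))
    }
    cmd <- args[1]
    opt <- parse_cli_opts(args[-1])
    switch(cmd,
      simulate = {
        cmd_simulate(req(opt, "out"),
                     config = if (!is.null(opt$config)) opt$config else
                       simulation_config(),
                     seed = opt$seed)
        0L
      },
      validate = {
        ds <- read_dataset(req(opt, "dataset"))
        elig <- do.call(rbind, lapply(
          lapply(ds$assemblages, drop_unusable_plants), check_eligibility))
        print(elig)
        0L
      },
      graft = {
        ds <- read_dataset(req(opt, "dataset"))
        gr <- graft_all(ds$tree, lapply(ds$assemblages, drop_unusable_plants))
        if (!is.null(opt$out)) {
          dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
          write_tax_tree(gr$tree, file.path(opt$out, "grafted_tree.nwk"),
                         file.path(opt$out, "grafted_taxonomy.csv"))
          write.csv(gr$report, file.path(opt$out, "graft_report.csv"),
                    row.names = FALSE)
        }
        0L
      },
      metrics = ,
      fit = ,
      run = {
        scopes <- if (!is.null(opt$scope)) opt$scope else
          c("all", "endophage", "exophage")
        cmd_run(req(opt, "dataset"), req(opt, "out"),
                tree_path = opt$tree, scopes = scopes,
                alpha = if (!is.null(opt$alpha)) as.numeric(opt$alpha) else 0.05,
                from_metrics = opt$`from-metrics`)
        0L
      },
      {
        cat("unknown subcommand: ", cmd, "\n", sep = "")
        2L
      })
  },
  usage_error = function(e) {
    message(conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config error|unknown config|config file", conditionMessage(e)))
      2L else 1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop(structure(class = c("usage_error", "error", "condition"),
                     list(message = paste0("unexpected argument: ", a),
                          call = NULL)))
    }
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}

req <- function(opt, key) {
  if (is.null(opt[[key]])) {
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = paste0("missing required option --", key),
                        call = NULL)))
  }
  opt[[key]]
}
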