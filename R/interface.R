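# Configuration and run plumbing: a validated config object backed by
# YAML/JSON files, manifests for reproducibility, and the dispatch used by
# the command-line script in inst/scripts/lshgan-cli.R.

config_defaults <- function() {
  list(k = 5L, t = 1L, epochs = 2000L, mix_fraction = 0.5,
       hidden = c(16L, 16L), lr = 1e-3, adam_betas = c(0.9, 0.999),
       d_steps = 1L, g_steps = 1L, non_saturating = FALSE,
       n_tables = 8L, hash_bits = 16L,
       n_samples = 100L, n_features = 1000L, rho = 0.5,
       holdout_frac = 0.2, folds = 5L, ntree = 100L,
       ratio = 1.5, n_top = 500L, n_bins = 20L,
       seed = 1L, out_dir = ".", quiet = FALSE)
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration file, fills unset keys with the package
#' defaults (k = 5, t = 1, hidden 16-16, lr = 1e-3, ratio = 1.5, ...) and
#' rejects unknown keys. With \code{path = NULL} returns the defaults,
#' optionally overridden through \code{...}.
#'
#' @param path Configuration file (\code{.yaml}/\code{.yml}/\code{.json}),
#'   or \code{NULL}.
#' @param ... Named overrides applied after the file.
#' @return A list of class \code{"lshgan_config"}.
#' @export
lshgan_config <- function(path = NULL, ...) {
  cfg <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, list(...))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- utils::modifyList(cfg, user)
  validate_config(cfg)
  structure(cfg, class = "lshgan_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop(sprintf("invalid value for '%s': %s", key, what), call. = FALSE)
  }
  chk(cfg$k >= 1, "k", "must be >= 1")
  chk(cfg$t >= 1, "t", "must be >= 1")
  chk(cfg$epochs >= 1, "epochs", "must be >= 1")
  chk(cfg$lr > 0, "lr", "must be positive")
  chk(cfg$mix_fraction >= 0 && cfg$mix_fraction <= 1, "mix_fraction",
      "must lie in [0, 1]")
  chk(all(cfg$hidden >= 1), "hidden", "all widths must be >= 1")
  chk(abs(cfg$rho) < 1, "rho", "must satisfy |rho| < 1")
  chk(cfg$ratio > 0, "ratio", "must be positive")
  chk(cfg$holdout_frac > 0 && cfg$holdout_frac < 1, "holdout_frac",
      "must lie in (0, 1)")
  invisible(cfg)
}

#' @export
print.lshgan_config <- function(x, ...) {
  cat("lshgan configuration:\n")
  for (k in names(x))
    cat(sprintf("  %-14s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

#' Write a run manifest
#'
#' Records the seed, configuration, package version and timestamp of a run so
#' the artifact directory is self-describing and re-runnable.
#'
#' @param cfg An \code{"lshgan_config"}.
#' @param dir Output directory (created if needed).
#' @param command Name of the command being run.
#' @param elapsed Optional wall time in seconds.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(cfg, dir, command, elapsed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(command = command, seed = cfg$seed,
                   config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("lshgan")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   elapsed_sec = elapsed)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run a named workflow
#'
#' Programmatic equivalent of the command-line script: dispatches one of the
#' supported subcommands with a validated configuration and writes its
#' artifacts plus a manifest into \code{cfg$out_dir}.
#'
#' @param command One of \code{"simulate"}, \code{"sample"}, \code{"train"},
#'   \code{"generate"}, \code{"evaluate"}, \code{"select-genes"},
#'   \code{"score-clustering"}, \code{"theory"}, \code{"reproduce-table2"}.
#' @param cfg An \code{"lshgan_config"}.
#' @param ... Command-specific inputs (e.g. \code{x}, \code{model},
#'   \code{real}, \code{generated}); see the command-line script for the file
#'   interface.
#' @return The command's main artifact, invisibly.
#' @export
run_lshgan <- function(command, cfg = lshgan_config(), ...) {
  command <- match.arg(command, c("simulate", "sample", "train", "generate",
                                  "evaluate", "select-genes",
                                  "score-clustering", "theory",
                                  "reproduce-table2"))
  extra <- list(...)
  t0 <- proc.time()[["elapsed"]]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(command,
    simulate = {
      gm <- make_gaussian_mixture(n_samples = cfg$n_samples,
                                  n_features = cfg$n_features,
                                  rho = cfg$rho, seed = cfg$seed)
      write_labeled_csv(gm, file.path(cfg$out_dir, "simulated.csv"))
      gm
    },
    sample = {
      xs <- lsh_sampling(extra$x, k = cfg$k, t = cfg$t,
                         n_tables = cfg$n_tables, hash_bits = cfg$hash_bits,
                         seed = cfg$seed)
      writeLines(as.character(attr(xs, "indices")),
                 file.path(cfg$out_dir, "selected_indices.txt"))
      utils::write.csv(xs, file.path(cfg$out_dir, "subsample.csv"))
      xs
    },
    train = {
      fit <- lsh_gan(extra$x, k = cfg$k, t = cfg$t, epochs = cfg$epochs,
                     mix_fraction = cfg$mix_fraction, hidden = cfg$hidden,
                     lr = cfg$lr, betas = cfg$adam_betas,
                     d_steps = cfg$d_steps, g_steps = cfg$g_steps,
                     non_saturating = cfg$non_saturating,
                     n_tables = cfg$n_tables, hash_bits = cfg$hash_bits,
                     holdout = extra$holdout, seed = cfg$seed,
                     verbose = !cfg$quiet)
      saveRDS(fit, file.path(cfg$out_dir, "model.rds"))
      utils::write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
                       row.names = FALSE)
      fit
    },
    generate = {
      gen <- generate_cells(extra$model, extra$n %||% cfg$n_samples,
                            seed = cfg$seed)
      utils::write.csv(gen, file.path(cfg$out_dir, "generated.csv"))
      gen
    },
    evaluate = {
      rep <- eval_report(extra$real, extra$generated, folds = cfg$folds,
                         ntree = cfg$ntree, seed = cfg$seed)
      jsonlite::write_json(unclass(rep),
                           file.path(cfg$out_dir, "eval_report.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    },
    `select-genes` = {
      genes <- select_genes(extra$x, method = extra$method %||% "fano",
                            n_top = cfg$n_top)
      writeLines(genes, file.path(cfg$out_dir, "selected_genes.txt"))
      genes
    },
    `score-clustering` = {
      sc <- cluster_and_score(extra$x, extra$genes, extra$n_clusters,
                              extra$truth, seed = cfg$seed)
      jsonlite::write_json(sc[c("ari", "nmi")],
                           file.path(cfg$out_dir, "clustering_score.json"),
                           auto_unbox = TRUE, digits = NA)
      sc
    },
    theory = {
      tab <- theory_table(seed = cfg$seed)
      utils::write.csv(tab, file.path(cfg$out_dir, "theory_table.csv"),
                       row.names = FALSE)
      tab
    },
    `reproduce-table2` = {
      grid <- table2_experiment(scale = extra$scale %||% "reduced",
                                seed = cfg$seed,
                                mix_fraction = cfg$mix_fraction,
                                non_saturating = cfg$non_saturating)
      utils::write.csv(grid$grid, file.path(cfg$out_dir, "table2_grid.csv"))
      grid
    })
  write_manifest(cfg, cfg$out_dir, command,
                 elapsed = proc.time()[["elapsed"]] - t0)
  invisible(out)
}
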