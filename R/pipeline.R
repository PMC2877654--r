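#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input source must be given: either `input` (paths to trait,
#' community, and habitat tables on disk) or `simulation` (parameters for
#' the synthetic-data generators).  All analysis defaults are echoed into
#' the run report.
#'
#' @param input `NULL`, or a list with elements `traits` (path),
#'   `traits_meta` (optional sidecar path), `communities` (path), and
#'   optionally `habitat` (path).
#' @param simulation `NULL`, or a list of generator parameters:
#'   `rule`, `strength`, `n_sites`, `pool_size`, `richness_range`,
#'   `coupling` (any may be omitted to use the [assembly_scenario()] /
#'   [generate_habitat()] defaults).
#' @param n_reps random assemblages per richness level in the null model
#'   (default 500).
#' @param n_boot bootstrap replicates for the loading test (default 999).
#' @param alpha significance level used throughout (default 0.05).
#' @param seed root seed; per-stage seeds are derived from it.
#' @param linkage_candidates linkages scored by [select_clustering()].
#' @param retain_override optional fixed number of retained components,
#'   bypassing the broken-stick rule.
#' @param outdir optional directory; when set, all artifacts (tables,
#'   Newick tree, JSON report) are written there.
#' @return an object of class `run_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL, n_reps = 500L,
                            n_boot = 999L, alpha = 0.05, seed = 1L,
                            linkage_candidates = c("UPGMA", "WPGMA",
                                                   "complete", "single",
                                                   "Ward"),
                            retain_override = NULL, outdir = NULL) {
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of 'input' and 'simulation' must be given",
         call. = FALSE)
  }
  structure(
    list(input = input, simulation = simulation,
         n_reps = as.integer(n_reps), n_boot = as.integer(n_boot),
         alpha = alpha, seed = as.integer(seed),
         linkage_candidates = linkage_candidates,
         retain_override = retain_override, outdir = outdir),
    class = "run_config"
  )
}

#' Read / write a pipeline configuration as YAML
#' @param file path of a YAML config file.
#' @param config a [pipeline_config()].
#' @return a `run_config` (reader); the path, invisibly (writer).
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))], file)
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) simulate or ingest the trait matrix, community
#' table, and habitat table; (2) habitat ordination --- Box-Cox screening,
#' correlation-matrix PCA, bootstrapped-eigenvector loading test,
#' broken-stick (or overridden) retention, regression of SR on the retained
#' components with backward elimination; (3) functional space --- Gower
#' distances, clustering-method selection, regional dendrogram;
#' (4) observed FD per site; (5) richness-controlled null model;
#' (6) redundancy test, grouped Michaelis-Menten comparison, and the low-FD
#' verdict.  All randomness flows from the root seed through named
#' per-stage seeds, so a rerun with the same config reproduces every number.
#' Any stage failure aborts with the stage name and cause; no site or
#' species is ever dropped silently.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report` collecting per-stage results
#'   (see Details in the package vignette); printed compactly.
#' @examples
#' cfg <- pipeline_config(simulation = list(rule = "neutral"),
#'                        n_reps = 100, n_boot = 199, seed = 42)
#' rep <- run_pipeline(cfg)
#' rep$verdict$verdict
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("'config' must come from pipeline_config()", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  seeds <- derive_seeds(config$seed,
                        c("traits", "communities", "habitat", "nullmodel",
                          "bootstrap"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- stage 1: inputs ------------------------------------------------------
  dat <- stage("inputs", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      spec <- trait_spec()
      pool_size <- if (is.null(sim$pool_size)) 36L else as.integer(sim$pool_size)
      traits <- generate_trait_matrix(spec, pool_size, seed = seeds["traits"])
      scen <- assembly_scenario(
        rule = if (is.null(sim$rule)) "neutral" else sim$rule,
        strength = if (is.null(sim$strength)) 0 else sim$strength,
        richness_range = if (is.null(sim$richness_range)) c(2L, 18L)
                         else sim$richness_range,
        n_sites = if (is.null(sim$n_sites)) 29L else as.integer(sim$n_sites),
        pool_size = pool_size, seed = seeds["communities"])
      communities <- generate_communities(traits, scen)
      habitat <- generate_habitat(
        communities,
        coupling = if (is.null(sim$coupling)) 0.8 else sim$coupling,
        seed = seeds["habitat"])
      list(traits = traits, communities = communities, habitat = habitat,
           scenario = scen)
    } else {
      inp <- config$input
      traits <- if (is.null(inp$traits_meta)) read_trait_matrix(inp$traits)
                else read_trait_matrix(inp$traits, inp$traits_meta)
      communities <- read_community_table(inp$communities)
      habitat <- if (is.null(inp$habitat)) NULL
                 else read_habitat_table(inp$habitat)
      sp_diff <- c(setdiff(species_labels(traits),
                           colnames(community_matrix(communities))),
                   setdiff(colnames(community_matrix(communities)),
                           species_labels(traits)))
      if (length(sp_diff)) {
        stop("species sets of trait matrix and community table differ: ",
             paste(sp_diff, collapse = ", "))
      }
      list(traits = traits, communities = communities, habitat = habitat,
           scenario = NULL)
    }
  })
  SR <- species_richness(dat$communities)

  # -- stage 2: habitat ordination -----------------------------------------
  ordination <- if (is.null(dat$habitat)) NULL else stage("ordination", {
    prep <- prepare_habitat(dat$habitat)
    pca <- run_pca(prep$values)
    boot <- bootstrap_eigenvector_test(prep$values, n_boot = config$n_boot,
                                       alpha = config$alpha,
                                       seed = seeds["bootstrap"])
    k <- select_n_components(pca$eigenvalues,
                             override = config$retain_override)
    sr_fit <- if (k >= 1L) {
      regress_sr_on_pcs(pca$scores[, seq_len(k), drop = FALSE], SR,
                        threshold = config$alpha)
    } else NULL
    list(prep = prep, pca = pca, boot = boot, n_retained = k,
         sr_regression = sr_fit)
  })

  # -- stage 3: functional space -------------------------------------------
  space <- stage("trait_space", {
    d <- gower_distance(dat$traits)
    sel <- select_clustering(d, config$linkage_candidates)
    list(dist = d, selection = sel, tree = sel$trees[[sel$selected]])
  })

  # -- stages 4-5: observed FD and null model ------------------------------
  observed <- stage("fd", fd_table(space$tree, dat$communities))
  null_fd <- stage("nullmodel",
                   null_model_fd(space$tree, dat$communities,
                                 n_reps = config$n_reps,
                                 seed = seeds["nullmodel"]))

  # -- stage 6: inference ---------------------------------------------------
  inference <- stage("inference", {
    redundancy <- redundancy_test(observed$FD, observed$SR,
                                  alpha = config$alpha)
    mm <- fit_mm_grouped(c(observed$FD, null_fd$predicted_fd),
                         c(observed$SR, null_fd$SR),
                         rep(c("observed", "predicted"),
                             c(nrow(observed), nrow(null_fd))))
    verdict <- low_fd_verdict(mm, alpha = config$alpha)
    list(redundancy = redundancy, mm = mm, verdict = verdict)
  })

  report <- structure(
    list(package_version = as.character(utils::packageVersion("tadfd")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = config, seeds = seeds,
         scenario = dat$scenario,
         traits = dat$traits, communities = dat$communities,
         habitat = dat$habitat,
         ordination = ordination,
         selection = space$selection, tree = space$tree,
         fd_table = merge(observed,
                          null_fd[, c("site", "predicted_fd", "sd")],
                          by = "site", sort = FALSE),
         redundancy = inference$redundancy,
         mm = inference$mm, verdict = inference$verdict,
         runtime = proc.time()[["elapsed"]] - t0),
    class = "run_report"
  )
  if (!is.null(config$outdir)) write_run_artifacts(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== tadfd pipeline report ==\n")
  cat(sprintf("%d sites, %d-species pool; seed %d\n",
              nrow(x$fd_table), x$tree$n, x$config$seed))
  if (!is.null(x$ordination)) {
    pr <- 100 * x$ordination$pca$proportion
    cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%; retained %d\n",
                pr[1], pr[2], pr[3], x$ordination$n_retained))
    if (!is.null(x$ordination$sr_regression)) {
      sr <- x$ordination$sr_regression
      cat(sprintf("SR ~ PCs: retained %s; R^2 = %.3f\n",
                  paste(sr$retained, collapse = "+"), sr$r_squared))
    }
  }
  cat(sprintf("Clustering: %s selected (criterion %.4g)\n",
              x$selection$selected,
              x$selection$criterion[x$selection$selected]))
  cat(sprintf("Redundancy: %s (SR^2 p = %.3g); R^2 linear %.3f, quadratic %.3f\n",
              x$redundancy$verdict, x$redundancy$quadratic_term["p"],
              x$redundancy$r_squared["linear"],
              x$redundancy$r_squared["quadratic"]))
  e <- x$mm$estimates
  cat(sprintf("MM: Fmax obs %.3f vs pred %.3f (t = %.3f, df = %d, p = %.3g)\n",
              e["Fmax_obs"], e["Fmax_pred"], x$mm$t["dFmax"], x$mm$df,
              x$mm$p_one_sided["dFmax"]))
  cat("Verdict:", x$verdict$verdict, "\n")
  cat(sprintf("Runtime: %.1f s\n", x$runtime))
  invisible(x)
}

# Serialisable summary of a run report (numbers only; excludes runtime so
# that repeated runs with one seed are byte-identical on disk).
report_summary <- function(report) {
  ord <- report$ordination
  list(
    package_version = report$package_version,
    r_version = report$r_version,
    seed = report$config$seed,
    seeds = as.list(report$seeds),
    settings = list(n_reps = report$config$n_reps,
                    n_boot = report$config$n_boot,
                    alpha = report$config$alpha,
                    linkage_candidates = report$config$linkage_candidates),
    pca = if (is.null(ord)) NULL else list(
      proportion = as.numeric(ord$pca$proportion),
      n_retained = ord$n_retained,
      transformed_variables = ord$prep$transformed,
      significant_pc1 = rownames(ord$boot$flags)[ord$boot$flags[, 1]]),
    sr_regression = if (is.null(ord) || is.null(ord$sr_regression)) NULL
      else list(retained = ord$sr_regression$retained,
                r_squared = ord$sr_regression$r_squared,
                f = as.list(ord$sr_regression$f_statistic)),
    clustering = list(selected = report$selection$selected,
                      criterion = as.list(report$selection$criterion)),
    redundancy = list(verdict = report$redundancy$verdict,
                      r_squared = as.list(report$redundancy$r_squared),
                      quadratic_term = as.list(report$redundancy$quadratic_term)),
    mm = list(estimates = as.list(report$mm$estimates),
              se = as.list(report$mm$se), t = as.list(report$mm$t),
              df = report$mm$df,
              p_one_sided = as.list(report$mm$p_one_sided)),
    verdict = report$verdict$verdict
  )
}

# Write every artifact of a run to a directory.
write_run_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_trait_matrix(report$traits, file.path(outdir, "traits.tsv"))
  write_community_table(report$communities,
                        file.path(outdir, "communities.tsv"))
  if (!is.null(report$habitat)) {
    write_habitat_table(report$habitat, file.path(outdir, "habitat.tsv"))
  }
  write_distance_matrix(gower_distance(report$traits),
                        file.path(outdir, "gower.tsv"))
  write_dendrogram(report$tree, file.path(outdir, "dendrogram.nwk"))
  utils::write.table(report$fd_table, file.path(outdir, "fd_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
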