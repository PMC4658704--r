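#' Pipeline configuration
#'
#' Either real inputs (`fasta` + `metadata` paths) or a simulation
#' configuration ([sim_config()]), exactly one of the two; stage toggles and
#' per-stage parameters; one global seed from which every stage derives its
#' own stream (stage-name hashing), so stages are independently reproducible.
#'
#' @param fasta,metadata input paths (aligned FASTA; CSV `id,locality,lat,lon`).
#' @param simulation a [sim_config()] (alternative to file inputs).
#' @param out_dir output directory for artefacts and the manifest.
#' @param seed global integer seed.
#' @param stages named logical toggles: `network`, `landscape`, `skyline`,
#'   `fits`, `model_selection`, `dating`.
#' @param neutrality_reps replicates for neutrality-test p-values.
#' @param iterations,thin MH settings for the demographic fits.
#' @param ml_steps,ml_iterations path steps / per-step sweeps for the
#'   marginal-likelihood run.
#' @param skyline_groups skyline group count.
#' @param cell,alpha landscape grid cell (degrees) and IDW exponent.
#' @param c_low,c_high calibration window (years BP).
#' @param priors optional named list of prior specs for the two-epoch fit
#'   (defaults derived from the skyline; see [default_two_epoch_priors()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, metadata = NULL, simulation = NULL,
                            out_dir = tempfile("tideclock_run_"), seed = 1L,
                            stages = list(), neutrality_reps = 500,
                            iterations = 20000, thin = 10,
                            ml_steps = 16, ml_iterations = 4000,
                            skyline_groups = 10, cell = 0.05, alpha = 1,
                            c_low = 13000, c_high = 18000, priors = NULL) {
  have_files <- !is.null(fasta)
  have_sim <- !is.null(simulation)
  if (have_files == have_sim) {
    abort("supply exactly one of `fasta` (+ `metadata`) or `simulation`")
  }
  st <- utils::modifyList(
    list(network = TRUE, landscape = TRUE, skyline = TRUE, fits = TRUE,
         model_selection = TRUE, dating = TRUE),
    stages)
  structure(list(fasta = fasta, metadata = metadata, simulation = simulation,
                 out_dir = out_dir, seed = as.integer(seed), stages = st,
                 neutrality_reps = neutrality_reps, iterations = iterations,
                 thin = thin, ml_steps = ml_steps,
                 ml_iterations = ml_iterations,
                 skyline_groups = skyline_groups, cell = cell, alpha = alpha,
                 c_low = c_low, c_high = c_high, priors = priors),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (`simulation` as a nested block of [sim_config()] arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    s <- y$simulation
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; accept `n_samples`
    # as the documented spelling and repair the gotcha
    if (is.null(s$n)) s$n <- s$n_samples %||% s[["FALSE"]]
    demo <- do.call(two_epoch_model, s$demography %||% list(N1 = 0.01))
    sub <- do.call(hky_model, s$substitution %||% list())
    loc <- if (!is.null(s$localities)) as_tibble(s$localities) else NULL
    y$simulation <- sim_config(n = s$n %||% 84, L = s$L %||% 352,
                               demography = demo, substitution = sub,
                               localities = loc,
                               mode = s$mode %||% "panmictic",
                               stem = s$stem %||% 0.02,
                               seed = s$seed %||% (y$seed %||% 1L))
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: haplotype collapsing, diversity and neutrality tests,
#' the statistical-parsimony network, the genetic landscape surface (when
#' coordinates are available), the UPGMA genealogy, the Bayesian skyline, the
#' constant and two-epoch fits, path/stepping-stone model comparison, and
#' expansion dating. Each stage writes its artefact under `out_dir` and is
#' recorded in `manifest.json` (inputs, parameters, per-stage seed, package
#' version).
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return A named list of all stage results (class `pipeline_result`),
#'   including the manifest.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = cfg$seed,
                   version = as.character(utils::packageVersion("tideclock")),
                   stages = list())
  res <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seed = derive_seed(cfg$seed, name),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    say("stage %-16s done (%.1fs)", name,
        manifest$stages[[name]]$seconds)
    out
  }

  # --- inputs -----------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    ds <- t_stage("simulate", generate_dataset(cfg$simulation))
    aln <- ds$alignment; meta <- ds$metadata
    res$truth <- ds$truth
    write_alignment(aln, file.path(cfg$out_dir, "alignment.fasta"))
    write.csv(meta, file.path(cfg$out_dir, "metadata.csv"), row.names = FALSE)
    ape::write.tree(ds$genealogy,
                    file.path(cfg$out_dir, "true_genealogy.nwk"))
  } else {
    aln <- t_stage("read", read_alignment(cfg$fasta))
    meta <- if (!is.null(cfg$metadata)) read_metadata(cfg$metadata) else NULL
  }
  res$alignment <- aln; res$metadata <- meta

  # --- haplotypes, diversity, neutrality --------------------------------
  res$haplotypes <- t_stage("collapse", collapse_haplotypes(aln, meta))
  write.csv(res$haplotypes[, c("haplotype", "count", "sequence")],
            file.path(cfg$out_dir, "haplotypes.csv"), row.names = FALSE)
  res$diversity <- t_stage("diversity", diversity(aln))
  res$neutrality <- t_stage("neutrality", dplyr::bind_rows(
    tajimas_d(aln, p_method = "coalescent_sim", reps = cfg$neutrality_reps,
              seed = derive_seed(cfg$seed, "neutrality_D")),
    fus_fs(aln, p_method = "coalescent_sim", reps = cfg$neutrality_reps,
           seed = derive_seed(cfg$seed, "neutrality_FS"))))
  write.csv(dplyr::bind_rows(res$diversity %>% mutate(statistic = "diversity"),
                             res$neutrality),
            file.path(cfg$out_dir, "sumstats.csv"), row.names = FALSE)

  # --- haplotype network -------------------------------------------------
  if (cfg$stages$network) {
    res$network <- t_stage("network", build_network(res$haplotypes))
    write_network(res$network,
                  file.path(cfg$out_dir, "network_edges.csv"),
                  file.path(cfg$out_dir, "network_nodes.csv"))
    res$star_score <- star_score(res$network)
  }

  # --- landscape ---------------------------------------------------------
  if (cfg$stages$landscape && !is.null(meta)) {
    res$landscape <- t_stage("landscape", {
      d_raw <- pairwise_distance(aln, "raw_differences")
      conn <- build_connectivity(meta, d_raw)
      resid <- residual_distances(conn)
      surf <- interpolate_surface(
        resid, localities = conn$localities, cell = cfg$cell,
        alpha = cfg$alpha)
      write_surface(surf, file.path(cfg$out_dir, "landscape.csv"))
      list(connectivity = conn, residuals = resid, surface = surf)
    })
  }

  # --- genealogy + demographic inference --------------------------------
  d_sub <- t_stage("distances", pairwise_distance(aln, "TN93"))
  gen <- t_stage("upgma", upgma_genealogy(d_sub))
  ape::write.tree(gen, file.path(cfg$out_dir, "upgma_genealogy.nwk"))
  res$genealogy <- gen
  iv <- coalescent_intervals(gen)
  root_height <- max(iv$t_end)

  if (cfg$stages$skyline) {
    res$skyline <- t_stage("skyline", bayesian_skyline(
      iv, m = min(cfg$skyline_groups, nrow(iv)),
      iterations = cfg$iterations, thin = cfg$thin,
      seed = derive_seed(cfg$seed, "skyline")))
    write.csv(res$skyline$skyline, file.path(cfg$out_dir, "skyline.csv"),
              row.names = FALSE)
  }

  priors <- cfg$priors %||%
    default_two_epoch_priors(if (!is.null(res$skyline)) res$skyline$skyline,
                             root_height = root_height)

  if (cfg$stages$fits) {
    res$fit_constant <- t_stage("fit_constant", mh_sample(
      iv, "constant", priors["N0"] %>% setNames("N"),
      iterations = cfg$iterations, thin = cfg$thin,
      seed = derive_seed(cfg$seed, "fit_constant")))
    res$fit_two_epoch <- t_stage("fit_two_epoch", mh_sample(
      iv, "two_epoch", priors, iterations = cfg$iterations, thin = cfg$thin,
      seed = derive_seed(cfg$seed, "fit_two_epoch")))
    utils::write.table(res$fit_two_epoch$draws,
                       file.path(cfg$out_dir, "two_epoch_trace.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (cfg$stages$model_selection) {
    sched <- power_schedule(cfg$ml_steps)
    res$ml_constant <- t_stage("ml_constant", estimate_marginal(
      iv, "constant", priors["N0"] %>% setNames("N"), sched,
      iterations_per_step = cfg$ml_iterations, thin = cfg$thin,
      seed = derive_seed(cfg$seed, "ml_constant")))
    res$ml_two_epoch <- t_stage("ml_two_epoch", estimate_marginal(
      iv, "two_epoch", priors, sched,
      iterations_per_step = cfg$ml_iterations, thin = cfg$thin,
      seed = derive_seed(cfg$seed, "ml_two_epoch")))
    res$bayes_factors <- tibble(
      method = c("PS", "SS"),
      two_ln_bf = c(
        as.numeric(bayes_factor(res$ml_two_epoch, res$ml_constant, "ps")),
        as.numeric(bayes_factor(res$ml_two_epoch, res$ml_constant, "ss"))))
    write.csv(res$bayes_factors, file.path(cfg$out_dir, "bayes_factors.csv"),
              row.names = FALSE)
  }

  if (cfg$stages$dating && !is.null(res$fit_two_epoch)) {
    res$rates <- t_stage("dating", rate_window(
      res$fit_two_epoch$draws$t_trans, c_low = cfg$c_low,
      c_high = cfg$c_high))
    write.csv(res$rates, file.path(cfg$out_dir, "rates.csv"),
              row.names = FALSE)
  }

  manifest$parameters <- cfg[c("seed", "neutrality_reps", "iterations",
                               "thin", "ml_steps", "ml_iterations",
                               "skyline_groups", "cell", "alpha",
                               "c_low", "c_high")]
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:",
      paste(names(x$manifest$stages), collapse = ", "), "\n")
  if (!is.null(x$rates)) {
    env <- x$rates[x$rates$calibration == "envelope", ]
    cat(sprintf("calibrated rate envelope: %.2f-%.2f %%/site/MY\n",
                env$hpd_lower, env$hpd_upper))
  }
  invisible(x)
}
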