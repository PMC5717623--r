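# End-to-end pipeline: simulate -> repertoires -> rates -> networks ->
# permutation inference -> mixed models, with a reproducibility manifest.

.pipeline_read <- function(out_dir, file, stage, reader, ...) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    stop(sprintf("missing upstream output '%s' for stage '%s'", file, stage),
         call. = FALSE)
  }
  reader(path, ...)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order over a synthetic
#' dataset (or over CSVs a previous run left in `out_dir`), writing every
#' stage's outputs as CSV/JSON plus a run manifest with content hashes,
#' seeds and versions. Re-running with the same configuration reproduces
#' all outputs bit-for-bit.
#'
#' Stages: `simulate` (write scans/gestures/individuals/kin CSVs),
#' `repertoire` (sequence grouping, panthoot recipient assignment, observed
#' repertoires, kappa and repertoire-size networks), `rates` (per-behaviour
#' dyadic bonding-rate matrices), `networks` (centrality tables), `mrqap`
#' (proximity network regressed on the kappa network), `nodereg` (proximity
#' indegree regressed on kappa n-degree and sex), `glmm` (response presence
#' regressed on sequence homogeneous/heterogeneous repertoire sizes with a
#' focal random intercept).
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param stages which stages to run, in any order.
#' @param n_perm_mrqap permutations for the MRQAP stage.
#' @param n_perm_node permutations for the node-level stage.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir,
                         stages = c("simulate", "repertoire", "rates",
                                    "networks", "mrqap", "nodereg", "glmm"),
                         n_perm_mrqap = 2000, n_perm_node = 10000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, several.ok = TRUE)
  outputs <- character(0)
  note <- function(files) outputs <<- c(outputs, files)
  individuals <- scans <- gestures <- kin_pairs <- NULL
  reps <- NULL

  if ("simulate" %in% stages) {
    ds <- generate_dataset(config)
    individuals <- ds$individuals; scans <- ds$scans
    gestures <- ds$gestures; kin_pairs <- ds$kin_pairs
    write_individuals(individuals, file.path(out_dir, "individuals.csv"))
    write_kin_pairs(kin_pairs, file.path(out_dir, "kin_pairs.csv"))
    write_scans(scans, file.path(out_dir, "scans.csv"))
    write_gestures(gestures, file.path(out_dir, "gestures.csv"))
    utils::write.csv(ds$catalog, file.path(out_dir, "catalog.csv"), row.names = FALSE)
    note(c("individuals.csv", "kin_pairs.csv", "scans.csv", "gestures.csv",
           "catalog.csv"))
  }
  need_data <- function(stage) {
    if (is.null(individuals)) {
      individuals <<- .pipeline_read(out_dir, "individuals.csv", stage, read_individuals)
      kin_pairs <<- .pipeline_read(out_dir, "kin_pairs.csv", stage, read_kin_pairs)
      scans <<- .pipeline_read(out_dir, "scans.csv", stage, read_scans,
                               max_scan_index = config$scans_per_follow)
      gestures <<- .pipeline_read(out_dir, "gestures.csv", stage, read_gestures)
    }
  }

  if ("repertoire" %in% stages) {
    need_data("repertoire")
    catalog <- NULL
    cat_path <- file.path(out_dir, "catalog.csv")
    if (file.exists(cat_path)) {
      catalog <- utils::read.csv(cat_path, colClasses = "character")
    }
    gestures <- group_sequences(gestures)
    gestures <- suppressMessages(
      assign_panthoot_recipients(gestures, scans, dominance_order(individuals),
                                 scan_interval_min = config$scan_interval_min))
    reps <- build_repertoires(gestures, adults = individuals$id, catalog = catalog)
    write_gestures(gestures, file.path(out_dir, "gestures_sequenced.csv"))
    utils::write.csv(dyad_summary_table(reps),
                     file.path(out_dir, "dyad_repertoire_summary.csv"),
                     row.names = FALSE)
    write_matrix_csv(suppressMessages(kappa_matrix(reps, "all")),
                     file.path(out_dir, "kappa_all.csv"))
    for (m in GESTURE_MODALITIES) {
      write_matrix_csv(suppressMessages(kappa_matrix(reps, m)),
                       file.path(out_dir, sprintf("kappa_%s.csv", m)))
    }
    write_matrix_csv(repertoire_size_matrix(reps, "homogeneous"),
                     file.path(out_dir, "homog_size_all.csv"))
    write_matrix_csv(repertoire_size_matrix(reps, "heterogeneous"),
                     file.path(out_dir, "heterog_size_all.csv"))
    seq_tab <- sequence_homogeneity_table(gestures, reps)
    utils::write.csv(seq_tab, file.path(out_dir, "sequence_homogeneity.csv"),
                     row.names = FALSE)
    note(c("gestures_sequenced.csv", "dyad_repertoire_summary.csv", "kappa_all.csv",
           sprintf("kappa_%s.csv", GESTURE_MODALITIES),
           "homog_size_all.csv", "heterog_size_all.csv", "sequence_homogeneity.csv"))
  }

  if ("rates" %in% stages) {
    need_data("rates")
    utils::write.csv(bonding_rate_table(scans, ids = individuals$id),
                     file.path(out_dir, "bonding_rates.csv"), row.names = FALSE)
    for (b in BONDING_BEHAVIOURS) {
      write_matrix_csv(bonding_matrix(scans, b, ids = individuals$id),
                       file.path(out_dir, sprintf("rate_%s.csv", b)))
    }
    note(c("bonding_rates.csv", sprintf("rate_%s.csv", BONDING_BEHAVIOURS)))
  }

  if ("networks" %in% stages) {
    need_data("networks")
    kap <- .pipeline_read(out_dir, "kappa_all.csv", "networks", read_matrix_csv,
                          directed = FALSE)
    cent <- suppressMessages(centrality_table(kap))
    names(cent)[2] <- "kappa_n_degree"
    for (b in BONDING_BEHAVIOURS) {
      bm <- .pipeline_read(out_dir, sprintf("rate_%s.csv", b), "networks",
                           read_matrix_csv, directed = TRUE)
      ct <- suppressMessages(centrality_table(bm))
      cent[[paste0(b, "_outdegree")]] <- ct$outdegree[match(cent$id, ct$id)]
      cent[[paste0(b, "_indegree")]] <- ct$indegree[match(cent$id, ct$id)]
    }
    utils::write.csv(cent, file.path(out_dir, "centrality.csv"), row.names = FALSE)
    note("centrality.csv")
  }

  if ("mrqap" %in% stages) {
    y <- .pipeline_read(out_dir, "rate_proximity.csv", "mrqap", read_matrix_csv,
                        directed = TRUE)
    x <- .pipeline_read(out_dir, "kappa_all.csv", "mrqap", read_matrix_csv,
                        directed = FALSE)
    res <- mrqap_dsp(y, list(kappa = x), n_perm = n_perm_mrqap, seed = config$seed)
    jsonlite::write_json(
      list(outcome = "proximity", coefficients = as.list(res$coefficients),
           r_squared = res$r_squared, p_values = as.list(res$p_values),
           n_permutations = res$n_permutations, seed = res$seed,
           n_dyads_used = res$n_dyads_used, method = res$method),
      file.path(out_dir, "mrqap_proximity.json"), auto_unbox = TRUE, digits = NA)
    note("mrqap_proximity.json")
  }

  if ("nodereg" %in% stages) {
    need_data("nodereg")
    cent <- .pipeline_read(out_dir, "centrality.csv", "nodereg", utils::read.csv)
    y <- cent$proximity_indegree
    xs <- data.frame(kappa_n_degree = cent$kappa_n_degree,
                     male = as.integer(individuals$sex[match(cent$id, individuals$id)] == "male"))
    res <- node_level_regression(y, xs, n_perm = n_perm_node, seed = config$seed)
    jsonlite::write_json(
      list(outcome = "proximity_indegree", coefficients = as.list(res$coefficients),
           r_squared = res$r_squared, p_values = as.list(res$p_values),
           n_permutations = res$n_permutations, seed = res$seed,
           n_nodes_used = res$n_dyads_used, method = res$method),
      file.path(out_dir, "nodereg_proximity.json"), auto_unbox = TRUE, digits = NA)
    note("nodereg_proximity.json")
  }

  if ("glmm" %in% stages) {
    seq_tab <- .pipeline_read(out_dir, "sequence_homogeneity.csv", "glmm",
                              utils::read.csv)
    spec <- glmm_spec("response_present", c("homog_size", "heterog_size"),
                      group = "signaller_id", family = "binomial_logit")
    res <- fit_glmm(seq_tab, spec)
    out <- res$coefficients
    out$random_intercept_variance <- res$random_intercept_variance
    out$n_obs <- res$n_obs
    out$n_groups <- res$n_groups
    out$converged <- res$converged
    utils::write.csv(out, file.path(out_dir, "glmm_response_present.csv"),
                     row.names = FALSE)
    note("glmm_response_present.csv")
  }

  outputs <- unique(outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gesturenet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    outputs = lapply(setNames(outputs, outputs), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
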