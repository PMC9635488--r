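#' Pipeline configuration
#'
#' Reads and validates a JSON pipeline config. Analyses are named
#' `"orthography"`, `"phonology"`, `"ann_hidden"`, `"gpc"`, or a partial
#' pair `"model|control"` (e.g. `"ann_hidden|gpc"` correlates the network
#' hidden-layer RDM with the neural data after partialling out the rule
#' route RDM).
#'
#' @param path JSON file path, or a list already in config shape
#' @return validated config list of class `pipeline_config`
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  defaults <- list(
    seed = 1L, data_dir = "data", out_dir = "out",
    simulate = list(n_words = 200L, p_exception = 0.1, n_nonwords = 50L,
                    grid = c(24L, 24L, 24L), n_subjects = 18L, noise_sd = 1,
                    rois = list()),
    ann = list(epochs = 400L, n_hidden = 100L, learning_rate = 0.1,
               weight_init_halfwidth = 0.1, ramp_gain = 1,
               ramp_halflife = 100, n_instantiations = 20L),
    searchlight = list(radius = 3, min_occupancy_frac = 0.5),
    inference = list(fwhm_mm = 6, voxel_p = 0.001,
                     cluster_extent_mm3 = 234.9, connectivity = 18L),
    rdm = list(table_method = "pearson"),
    analyses = c("orthography", "phonology", "ann_hidden", "gpc"))
  known <- names(defaults)
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  merged <- utils::modifyList(defaults, cfg)
  # modifyList merges by name and so drops unnamed roi entries
  if (!is.null(cfg$simulate) && !is.null(cfg$simulate$rois))
    merged$simulate$rois <- cfg$simulate$rois
  for (sec in c("simulate", "ann", "searchlight", "inference", "rdm")) {
    bad <- setdiff(names(merged[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  base_names <- c("orthography", "phonology", "ann_hidden", "gpc")
  for (an in merged$analyses) {
    parts <- strsplit(an, "|", fixed = TRUE)[[1]]
    if (!all(parts %in% base_names) || length(parts) > 2L)
      stop("unknown analysis '", an, "'; use one of ",
           paste(base_names, collapse = ", "), " or 'model|control'")
  }
  structure(merged, class = "pipeline_config")
}

config_hash <- function(cfg, keys) {
  sub <- cfg[keys]
  digest_input <- jsonlite::toJSON(sub, auto_unbox = TRUE, digits = NA)
  # small rolling hash; only used for cache-invalidation bookkeeping
  h <- 0
  for (ch in utf8ToInt(as.character(digest_input)))
    h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

log_line <- function(stage, ...) {
  kv <- c(...)
  msg <- paste0("stage=", stage, " ",
                paste(names(kv), unname(kv), sep = "=", collapse = " "))
  message(format(Sys.time(), "%H:%M:%S "), msg)
}

#' Simulate a full synthetic dataset per the config
#'
#' Generates the lexicon, nonwords and derived rules; when a planted region
#' sources a model representation (ann_hidden or gpc), trains the network /
#' runs the rule route first so the planted features are the real model
#' features. Writes everything under `data_dir`.
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) the dataset list from [make_dataset()]
#' @export
stage_simulate <- function(cfg) {
  sim <- cfg$simulate
  t0 <- Sys.time()
  lspec <- synth_lexicon_spec(n_words = sim$n_words,
                              p_exception = sim$p_exception,
                              seed = cfg$seed)
  rois <- list()
  if (length(sim$rois)) {
    rois <- lapply(seq_len(if (is.data.frame(sim$rois)) nrow(sim$rois)
                           else length(sim$rois)), function(i) {
      r <- if (is.data.frame(sim$rois)) as.list(sim$rois[i, ]) else sim$rois[[i]]
      planted_roi_spec(unlist(r$center), r$radius %||% 3, r$source,
                       r$gain %||% 2)
    })
  }
  needs <- unique(vapply(rois, `[[`, character(1), "source"))
  features <- list()
  if (any(needs %in% c("ann_hidden", "gpc"))) {
    lex <- generate_lexicon(lspec)
    reps <- model_representations(lex, cfg, n_instantiations = 1L)
    features <- reps$features[intersect(needs, c("ann_hidden", "gpc"))]
  }
  ds <- make_dataset(cfg$data_dir, lexicon_spec = lspec,
                     n_nonwords = sim$n_nonwords,
                     grid = volume_grid(sim$grid),
                     rois = rois, features = features,
                     n_subjects = sim$n_subjects, noise_sd = sim$noise_sd,
                     seed = cfg$seed)
  writeLines(config_hash(cfg, c("seed", "simulate", "ann")),
             file.path(cfg$data_dir, ".hash"))
  log_line("simulate", n_words = sim$n_words, n_subjects = sim$n_subjects,
           elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 1))
  invisible(ds)
}

ann_config_from <- function(cfg, lex, seed) {
  ann_config(n_input = n_units(lex$ortho_scheme),
             n_hidden = cfg$ann$n_hidden,
             n_output = n_units(lex$phon_scheme),
             epochs = cfg$ann$epochs,
             learning_rate = cfg$ann$learning_rate,
             weight_init_halfwidth = cfg$ann$weight_init_halfwidth,
             seed = seed, ramp_gain = cfg$ann$ramp_gain,
             ramp_halflife = cfg$ann$ramp_halflife)
}

#' Model representations and accuracies for a lexicon
#'
#' Trains `n_instantiations` networks (seeds seed+1 ... seed+n), scores
#' training words (exact match) and nonwords (Jaccard and exact criteria),
#' builds per-instantiation hidden-layer RDMs and their mean, the rule
#' route representation and RDM, and the orthography/phonology RDMs.
#'
#' @param lex a [lexicon()]
#' @param cfg a [pipeline_config()]
#' @param nonwords optional [generate_nonwords()] set for accuracy scoring
#' @param rules optional [gpc_ruleset()]; derived from the lexicon if NULL
#' @param n_instantiations override of `cfg$ann$n_instantiations`
#' @return list: features (named matrices), rdms (named [rdm()]s),
#'   accuracies, history of instantiation 1
#' @export
model_representations <- function(lex, cfg, nonwords = NULL, rules = NULL,
                                  n_instantiations = NULL) {
  n_inst <- n_instantiations %||% cfg$ann$n_instantiations
  X <- encode_lexicon(lex, "orthography")
  P <- encode_lexicon(lex, "phonology")
  freq <- frequencies(lex)
  if (is.null(rules)) rules <- generate_rules(lex)
  hidden <- vector("list", n_inst)
  word_acc <- numeric(n_inst)
  nw_jacc <- numeric(n_inst)
  nw_exact <- numeric(n_inst)
  enc_nw <- if (!is.null(nonwords)) encode_nonwords(nonwords) else NULL
  history <- NULL
  for (i in seq_len(n_inst)) {
    acfg <- ann_config_from(cfg, lex, seed = cfg$seed + i)
    fit <- ann_train(initialize_model(acfg), X, P, freq)
    if (i == 1L) history <- fit$history
    read <- ann_read(fit$model, X, P, freq)
    hidden[[i]] <- read$hidden
    word_acc[i] <- mean(vapply(seq_len(nrow(P)), function(w)
      score_word(read$rounded[w, ], P[w, ]), logical(1)))
    if (!is.null(enc_nw)) {
      # nonwords carry no lexical frequency; external input uses the
      # nominal test frequency and the canonical target slots
      Tnw <- enc_nw$pool[enc_nw$target_idx, , drop = FALSE]
      nwread <- ann_read(fit$model, enc_nw$X, Tnw, enc_nw$freq)
      nw_jacc[i] <- mean(vapply(seq_len(nrow(enc_nw$X)), function(k)
        score_nonword(nwread$rounded[k, ], enc_nw$acceptable_idx[[k]],
                      enc_nw$pool, "jaccard"), logical(1)))
      nw_exact[i] <- mean(vapply(seq_len(nrow(enc_nw$X)), function(k)
        score_nonword(nwread$rounded[k, ], enc_nw$acceptable_idx[[k]],
                      enc_nw$pool, "exact"), logical(1)))
    }
  }
  ann_rdms <- lapply(hidden, function(h) compute_rdm(zscore_features(h)))
  gpc_rep <- gpc_representation(lex, rules)
  features <- list(orthography = X, phonology = P,
                   ann_hidden = hidden[[1L]], gpc = gpc_rep)
  rdms <- list(
    orthography = compute_rdm(zscore_features(X)),
    phonology = compute_rdm(zscore_features(P)),
    ann_hidden = average_rdms(ann_rdms),
    gpc = compute_rdm(zscore_features(gpc_rep)))
  list(features = features, rdms = rdms,
       accuracies = list(
         word_accuracy = mean(word_acc),
         word_accuracy_per_instantiation = word_acc,
         nonword_jaccard = if (!is.null(enc_nw)) mean(nw_jacc) else NA_real_,
         nonword_exact = if (!is.null(enc_nw)) mean(nw_exact) else NA_real_),
       history = history, rules = rules)
}

read_dataset <- function(cfg) {
  schemes <- paper_scale_schemes()
  lex <- read_lexicon_tsv(file.path(cfg$data_dir, "lexicon.tsv"),
                          schemes$ortho, schemes$phon)
  rules <- read_rules_tsv(file.path(cfg$data_dir, "rules.tsv"))
  maskn <- read_nifti(file.path(cfg$data_dir, "mask.nii"))
  grid <- volume_grid(dim(maskn$data), maskn$voxdim_mm, maskn$origin_mm)
  mask <- maskn$data > 0.5
  subs <- list()
  i <- 1L
  repeat {
    pre <- file.path(cfg$data_dir, sprintf("sub-%02d_beta", i))
    if (!file.exists(paste0(pre, ".nii"))) break
    subs[[i]] <- read_beta_series(pre, mask, sprintf("sub-%02d", i))
    i <- i + 1L
  }
  list(lexicon = lex, rules = rules, grid = grid, mask = mask,
       subjects = subs)
}

#' Train models and write their report (stage `train-models`)
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) the [model_representations()] result
#' @export
stage_train_models <- function(cfg) {
  t0 <- Sys.time()
  ds <- read_dataset(cfg)
  schemes <- paper_scale_schemes()
  lspec <- synth_lexicon_spec(n_words = cfg$simulate$n_words,
                              p_exception = cfg$simulate$p_exception,
                              seed = cfg$seed)
  lex <- generate_lexicon(lspec)   # regenerate to recover gp_map for nonwords
  nw <- generate_nonwords(lex, cfg$simulate$n_nonwords, seed = cfg$seed)
  reps <- model_representations(lex, cfg, nonwords = nw, rules = ds$rules)
  mdir <- file.path(cfg$out_dir, "models")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(reps$rdms))
    write_rdm_tsv(reps$rdms[[nm]], file.path(mdir, paste0("rdm_", nm, ".tsv")))
  tab <- build_correlation_table(reps$rdms, method = cfg$rdm$table_method)
  write.table(data.frame(model = rownames(tab), as.data.frame(unclass(tab)),
                         check.names = FALSE),
              file.path(mdir, "rdm_correlation_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(reps$history, file.path(mdir, "training_history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(reps$accuracies, file.path(mdir, "accuracies.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(config_hash(cfg, c("seed", "simulate", "ann", "rdm")),
             file.path(mdir, ".hash"))
  log_line("train-models",
           word_accuracy = round(reps$accuracies$word_accuracy, 4),
           elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 1))
  invisible(reps)
}

parse_analysis <- function(an) {
  parts <- strsplit(an, "|", fixed = TRUE)[[1]]
  list(model = parts[1], control = if (length(parts) == 2L) parts[2] else NULL)
}

#' Searchlight RSA over all configured analyses (stage `rsa`)
#'
#' For each analysis: per-subject searchlight maps (shared neural RDM per
#' sphere), smoothing, Fisher z, group t, cluster-extent thresholding.
#' Writes group t maps (NIfTI) and cluster tables (TSV).
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) named list of [group_inference()] results
#' @export
stage_rsa <- function(cfg) {
  t0 <- Sys.time()
  ds <- read_dataset(cfg)
  if (!length(ds$subjects)) stop("no beta series found in ", cfg$data_dir)
  mdir <- file.path(cfg$out_dir, "models")
  rdms <- list()
  for (nm in c("orthography", "phonology", "ann_hidden", "gpc")) {
    f <- file.path(mdir, paste0("rdm_", nm, ".tsv"))
    if (file.exists(f)) rdms[[nm]] <- read_rdm_tsv(f)
  }
  analyses <- list()
  for (an in cfg$analyses) {
    pa <- parse_analysis(an)
    if (is.null(rdms[[pa$model]]) ||
        (!is.null(pa$control) && is.null(rdms[[pa$control]])))
      stop("analysis '", an, "' needs RDM(s) not present in ", mdir,
           "; run the train-models stage first")
    analyses[[an]] <- list(model = rdms[[pa$model]],
                           control = if (is.null(pa$control)) NULL
                                     else rdms[[pa$control]])
  }
  slcfg <- searchlight_config(radius = cfg$searchlight$radius,
                              min_occupancy_frac = cfg$searchlight$min_occupancy_frac)
  gcfg <- group_inference_config(fwhm_mm = cfg$inference$fwhm_mm,
                                 voxel_p = cfg$inference$voxel_p,
                                 cluster_extent_mm3 = cfg$inference$cluster_extent_mm3,
                                 connectivity = cfg$inference$connectivity)
  rdir <- file.path(cfg$out_dir, "rsa")
  dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  if (length(analyses)) {
    subj_maps <- lapply(ds$subjects, function(bs)
      searchlight_multi(bs, analyses, slcfg))
    for (an in names(analyses)) {
      maps <- lapply(subj_maps, `[[`, an)
      gi <- group_inference(maps, ds$grid, ds$mask, gcfg)
      results[[an]] <- gi
      safe <- gsub("|", "_given_", an, fixed = TRUE)
      tm <- gi$t_map
      tm[is.na(tm)] <- 0
      write_nifti(tm, file.path(rdir, paste0("tmap_", safe, ".nii")),
                  voxdim_mm = ds$grid$voxdim_mm, origin_mm = ds$grid$origin_mm)
      write.table(gi$clusters, file.path(rdir, paste0("clusters_", safe, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log_line("rsa", analysis = an, n_clusters = nrow(gi$clusters))
    }
  }
  writeLines(config_hash(cfg, c("seed", "simulate", "ann", "searchlight",
                                "inference", "analyses")),
             file.path(rdir, ".hash"))
  log_line("rsa", n_analyses = length(analyses),
           elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 1))
  invisible(results)
}

#' Collate the run report (stage `report`)
#'
#' Gathers model accuracies, the RDM correlation table and per-analysis
#' cluster tables into `report.json` with provenance (config hash, seed,
#' package version). Re-running is idempotent.
#'
#' @param cfg a [pipeline_config()]
#' @return (invisibly) the report list
#' @export
stage_report <- function(cfg) {
  mdir <- file.path(cfg$out_dir, "models")
  rdir <- file.path(cfg$out_dir, "rsa")
  acc <- if (file.exists(file.path(mdir, "accuracies.json")))
    jsonlite::read_json(file.path(mdir, "accuracies.json"), simplifyVector = TRUE)
  else NULL
  tab_f <- file.path(mdir, "rdm_correlation_table.tsv")
  tab <- if (file.exists(tab_f)) read.delim(tab_f, check.names = FALSE) else NULL
  clusters <- list()
  for (an in cfg$analyses) {
    safe <- gsub("|", "_given_", an, fixed = TRUE)
    f <- file.path(rdir, paste0("clusters_", safe, ".tsv"))
    clusters[[an]] <- if (file.exists(f)) read.delim(f) else NULL
  }
  report <- list(
    provenance = list(
      config_hash = config_hash(cfg, setdiff(names(cfg), "out_dir")),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("readrsa"))),
    accuracies = acc, rdm_correlation_table = tab, clusters = clusters)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_line("report", path = file.path(cfg$out_dir, "report.json"))
  invisible(report)
}

#' Run the full pipeline
#' @param cfg a [pipeline_config()]
#' @return (invisibly) the report list
#' @export
run_pipeline <- function(cfg) {
  stage_simulate(cfg)
  stage_train_models(cfg)
  stage_rsa(cfg)
  stage_report(cfg)
}

#' Command-line entry point
#'
#' `readrsa_cli(c("<subcommand>", "--config", "path.json"))` with
#' subcommands `simulate`, `train-models`, `rsa`, `report`, `all`.
#' Returns the exit status (0 on success); use in a wrapper script as
#' `quit(status = readrsa_cli())`.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`)
#' @return integer exit status
#' @export
readrsa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: readrsa <simulate|train-models|rsa|report|all> --config <file.json>"
  status <- tryCatch({
    if (length(args) < 1L) stop(usage)
    sub <- args[[1L]]
    ci <- which(args == "--config")
    if (length(ci) != 1L || ci + 1L > length(args)) stop(usage)
    cfg <- pipeline_config(args[[ci + 1L]])
    switch(sub,
           "simulate" = stage_simulate(cfg),
           "train-models" = stage_train_models(cfg),
           "rsa" = stage_rsa(cfg),
           "report" = stage_report(cfg),
           "all" = run_pipeline(cfg),
           stop("unknown subcommand '", sub, "'\n", usage))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
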